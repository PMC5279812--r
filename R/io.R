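#' Load a run configuration
#'
#' Configurations are nested-key YAML documents with sections
#' \code{kind} (\code{floop}, \code{eclipse}, \code{eve}, \code{fit} or
#' \code{validate}), \code{params} (overrides for [simulation_params()]),
#' \code{chain}, \code{protrusion}/\code{protrusions}, \code{criteria},
#' \code{n_chains}, \code{seed}, \code{paired}, \code{out}.
#'
#' @param path YAML file path, or a list already in config form.
#' @return a named list of class \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$kind) ||
      !cfg$kind %in% c("floop", "eclipse", "eve", "fit", "validate"))
    stop("config error: 'kind' must be one of floop/eclipse/eve/fit/validate")
  structure(cfg, class = "run_config")
}

config_params <- function(cfg) {
  do.call(simulation_params,
          modifyList(list(), cfg$params %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(cfg)), f)
  unname(tools::md5sum(f))
}

run_stamp <- function(cfg) {
  list(config_hash = config_hash(cfg),
       version = as.character(packageVersion("loopsis")))
}

write_outputs <- function(out_dir, cfg, curves = NULL, summary = NULL,
                          name = cfg$kind) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- run_stamp(cfg)
  yaml::write_yaml(c(unclass(cfg), stamp),
                   file.path(out_dir, paste0(name, "_config.yaml")))
  files <- character(0)
  if (!is.null(curves)) {
    f <- file.path(out_dir, paste0(name, "_curve.csv"))
    con <- file(f, "w")
    writeLines(sprintf("# config_hash: %s  version: %s",
                       stamp$config_hash, stamp$version), con)
    write.csv(curves, con, row.names = FALSE)
    close(con)
    files <- c(files, f)
  }
  if (!is.null(summary)) {
    f <- file.path(out_dir, paste0(name, "_summary.json"))
    jsonlite::write_json(c(summary, stamp), f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Run a paired baseline/object F(L) experiment
#'
#' Builds the two-stage schedule from the configuration, generates the
#' baseline and object ensembles, and writes the F-curve CSV
#' (\code{length_bp}, \code{length_nm}, \code{P_base}, \code{SE_base},
#' \code{P_obj}, \code{SE_obj}, \code{F}, \code{SE_F}) plus a plateau
#' summary JSON.  By default the two ensembles use independent seeds
#' (\code{seed} and \code{seed + 1}); \code{paired: true} switches to the
#' variance-reduced mode in which the object ensemble is the exact subset
#' of baseline chains that avoid the object (shared per-chain streams).
#'
#' Config keys: \code{chain: {N1, N2, trailing_links}},
#' \code{protrusions: [{link, radius, phase}]}, \code{criteria:
#' {d_min, epsilon, domega}}, \code{n_chains}, \code{seed},
#' \code{paired}, \code{plateau_window}.
#'
#' @param config a [read_run_config()] result (or path, or list).
#' @param out_dir output directory (default from the config).
#' @return invisibly, a list with the curve and plateau summary.
#' @export
run_floop <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  if (cfg$kind != "floop") stop("config error: kind must be 'floop'")
  params <- config_params(cfg)
  out_dir <- out_dir %||% cfg$out %||% "."
  ch <- cfg$chain %||% list()
  N1 <- ch$N1 %||% 110L
  N2 <- ch$N2 %||% 100L
  segs <- data.frame(n_links = c(N1, N2),
                     link_length = c(params$l1, params$l2),
                     delta_i = c(params$delta_i_stage1,
                                 default_delta_i(params$w, params$l2)))
  paired <- isTRUE(cfg$paired)
  prot_cfg <- cfg$protrusions %||%
    (if (!is.null(cfg$protrusion)) list(cfg$protrusion) else list())
  prots <- lapply(prot_cfg, function(p)
    protrusion("on_chain", link = p$link, radius = p$radius,
               phase = p$phase %||% 0, enforce = !paired))
  crit_cfg <- cfg$criteria %||% list()
  crit <- loop_criteria(crit_cfg$d_min %||% params$d_min,
                        crit_cfg$epsilon %||% params$epsilon,
                        crit_cfg$domega %||% params$domega)
  n_chains <- cfg$n_chains %||% params$n_chains
  seed <- cfg$seed %||% params$seed
  trailing <- ch$trailing_links %||% 0L

  sched_obj <- growth_schedule(segs, protrusions = prots,
                               trailing_links = trailing, params = params)
  if (paired) {
    ens <- generate_ensemble(sched_obj, params, n_chains, seed,
                             criteria = list(crit))
    p_base <- looping_probability(ens, 1)
    p_obj <- looping_probability(ens, 2)
    fc <- paired_f_curve(ens, 2)
  } else {
    sched_base <- growth_schedule(segs, trailing_links = trailing,
                                  params = params)
    e_base <- generate_ensemble(sched_base, params, n_chains, seed,
                                criteria = list(crit))
    for (p in prots) p$enforce <- TRUE
    sched_obj <- growth_schedule(segs, protrusions = lapply(prots, function(p) {
      p$enforce <- TRUE; p
    }), trailing_links = trailing, params = params)
    e_obj <- generate_ensemble(sched_obj, params, n_chains, seed + 1,
                               criteria = list(crit))
    p_base <- looping_probability(e_base, 1)
    p_obj <- looping_probability(e_obj, 1)
    fc <- f_ratio(p_obj, p_base)
  }
  curve <- data.frame(length_bp = p_base$length_bp,
                      length_nm = p_base$length_nm,
                      P_base = p_base$p, SE_base = p_base$se,
                      P_obj = p_obj$p, SE_obj = p_obj$se,
                      F = fc$f, SE_F = fc$se)
  plat <- tryCatch(
    estimate_f_infinity(fc, window = cfg$plateau_window %||% NULL,
                        b = params$b),
    error = function(e) list(f_inf = NA, halfwidth = NA, window = 0,
                             flat = NA, slope_z = NA))
  summary <- list(F_inf = plat$f_inf, halfwidth = plat$halfwidth,
                  window = plat$window, flat = plat$flat,
                  slope_z = plat$slope_z, paired = paired,
                  n_chains = n_chains, seed = seed)
  write_outputs(out_dir, cfg, curves = curve, summary = summary)
  invisible(list(curve = curve, plateau = summary))
}

#' Run the eclipse-model estimates for a static-object scene
#'
#' Computes the rod (solid-angle) estimate, the terminating-segments
#' correction and, optionally, the quadratic fit inputs for a static
#' object, writing a JSON summary.
#'
#' Config keys: \code{scene: {distance, R_o, T}}, \code{criteria},
#' \code{n_points}.
#'
#' @param config config (path or list).
#' @param out_dir output directory.
#' @return invisibly, the summary list.
#' @export
run_eclipse <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  if (cfg$kind != "eclipse") stop("config error: kind must be 'eclipse'")
  params <- config_params(cfg)
  out_dir <- out_dir %||% cfg$out %||% "."
  sc <- cfg$scene %||% list()
  d <- sc$distance %||% 41.45
  R_o <- sc$R_o %||% 23
  crit_cfg <- cfg$criteria %||% list()
  crit <- loop_criteria(crit_cfg$d_min %||% params$d_min,
                        crit_cfg$epsilon %||% params$epsilon,
                        crit_cfg$domega %||% 4 * pi)
  n_pts <- cfg$n_points %||% 2e5
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  obj <- c(d, 0, 0)
  rod <- f_inf_static(obj, R_o, crit, params$w, n_points = n_pts)
  T_len <- sc$T %||% (d + R_o)
  ts <- suppressWarnings(
    terminating_segments_correction(T_len, crit, obj, R_o, params,
                                    n_pairs = n_pts))
  summary <- list(distance = d, R_o = R_o, T = T_len,
                  rod_f_inf = rod$f_inf, rod_se = rod$se,
                  terminating_segments_f_inf = ts$f_inf,
                  correction = ts$correction)
  write_outputs(out_dir, cfg, summary = summary)
  invisible(summary)
}

#' Run the enhancer (eve-type) looping comparison
#'
#' Loads an enhancer layout, generates one baseline ensemble with the
#' occupied sites as virtual protrusions, and reports the total
#' multi-activator looping probability of the bare and fully bound states
#' together with their paired ratio over a trailing window.
#'
#' Config keys: \code{layout} (TSV path), \code{chain_length_bp},
#' \code{domega}, \code{n_chains}, \code{seed}, \code{window_bp}.
#'
#' @param config config (path or list).
#' @param out_dir output directory.
#' @return invisibly, a list with curves and the plateau ratio.
#' @export
run_eve <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  if (cfg$kind != "eve") stop("config error: kind must be 'eve'")
  params <- config_params(cfg)
  out_dir <- out_dir %||% cfg$out %||% "."
  layout <- read_enhancer_layout(cfg$layout,
                                 chain_length_bp = cfg$chain_length_bp %||% 3900)
  res <- eve_state_comparison(layout, params,
                              domega = cfg$domega %||% 2 * pi * 0.1,
                              n_chains = cfg$n_chains %||% params$n_chains,
                              seed = cfg$seed %||% params$seed,
                              window_bp = cfg$window_bp %||% 150)
  write_outputs(out_dir, cfg, curves = res$curve, summary = res$summary)
  invisible(res)
}

#' Bare versus fully-bound enhancer looping from one run
#'
#' Generates a single ensemble in which every occupied site is a virtual
#' protrusion, then compares the bare baseline with the fully bound subset:
#' total looping probability summed over activators, its paired ratio
#' \eqn{F}, and the pooled plateau ratio over the trailing window.
#'
#' @param layout an [enhancer_layout()].
#' @param params a [simulation_params()].
#' @param domega angular acceptance of the activator criteria.
#' @param n_chains,seed sampling controls.
#' @param window_bp trailing window for the plateau ratio, bp.
#' @return list with \code{curve}, \code{summary}, \code{ensemble}.
#' @export
eve_state_comparison <- function(layout, params = simulation_params(),
                                 domega = 2 * pi * 0.1,
                                 n_chains = 1e5, seed = 1,
                                 window_bp = 150) {
  ls <- layout_to_schedule(layout, params, state = "fully_bound",
                           domega = domega, enforce = FALSE)
  sched <- ls$schedule
  n_prot <- length(sched$protrusions)
  grp <- list(seq_along(ls$criteria))
  grid_bp <- grid_lengths(sched, params)$bp
  lo <- which(grid_bp >= max(grid_bp) - window_bp)[1]
  hi <- length(grid_bp)
  win <- list(list(
    list(ensemble = 2, group = 1, lo = lo, hi = hi),
    list(ensemble = 1, group = 1, lo = lo, hi = hi)))
  ens <- generate_ensemble(sched, params, n_chains, seed,
                           criteria = ls$criteria, groups = grp,
                           ensembles = list(integer(0), seq_len(n_prot)),
                           windows = win)
  p_bare <- eve_looping_probability(ens, 1)
  p_bound <- eve_looping_probability(ens, 2)
  fc <- paired_f_curve(ens, 2)
  fw <- window_f(ens, 1, num = 1, den = 2)
  curve <- data.frame(length_bp = p_bare$length_bp,
                      length_nm = p_bare$length_nm,
                      P_base = p_bare$p, SE_base = p_bare$se,
                      P_obj = p_bound$p, SE_obj = p_bound$se,
                      F = fc$f, SE_F = fc$se,
                      dup_fraction = p_bound$dup_fraction)
  summary <- list(F_inf = fw$value, halfwidth = 1.96 * fw$se,
                  window_bp = window_bp, domega = domega,
                  n_chains = n_chains, seed = seed,
                  dup_fraction_max = max(p_bound$dup_fraction, na.rm = TRUE))
  list(curve = curve, summary = summary, ensemble = ens)
}

#' Quadratic eclipse fit from a result table
#'
#' Config keys: \code{data} (CSV with columns \code{R_o}, \code{f},
#' optionally \code{se}) or inline \code{radii}/\code{f_values}/
#' \code{errors}; \code{w}.
#'
#' @param config config (path or list).
#' @param out_dir output directory.
#' @return invisibly, the [fit_quadratic_eclipse()] object.
#' @export
run_fit <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  if (cfg$kind != "fit") stop("config error: kind must be 'fit'")
  out_dir <- out_dir %||% cfg$out %||% "."
  if (!is.null(cfg$data)) {
    df <- utils::read.csv(cfg$data, comment.char = "#")
    radii <- df$R_o; fv <- df$f; se <- df$se
  } else {
    radii <- unlist(cfg$radii); fv <- unlist(cfg$f_values)
    se <- if (is.null(cfg$errors)) NULL else unlist(cfg$errors)
  }
  fit <- fit_quadratic_eclipse(radii, fv, se, w = cfg$w %||% 4.6)
  summary <- list(A = fit$A, B = fit$B, r_squared = fit$r_squared,
                  cov = as.list(as.data.frame(fit$cov)))
  write_outputs(out_dir, cfg, summary = summary)
  invisible(fit)
}

#' Write a chain configuration as an XYZ trajectory frame
#'
#' Joints are tagged \code{C} (backward-segment joints \code{N}) and
#' protrusion centres \code{O}, one frame per chain; useful for visual
#' debugging in any molecular viewer.
#'
#' @param chains a [grow_chain()] result or list of them.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_xyz <- function(chains, path) {
  if (inherits(chains, "chain_conf")) chains <- list(chains)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    pc <- Filter(Negate(is.null), ch$prot_centers)
    n <- nrow(ch$joints) + length(pc)
    writeLines(c(sprintf("%d", n), "chain configuration"), con)
    tags <- c("C", rep("N", ch$n_backward),
              rep("C", max(0, nrow(ch$joints) - 1 - ch$n_backward)))
    for (i in seq_len(nrow(ch$joints))) {
      writeLines(sprintf("%s %.4f %.4f %.4f", tags[i],
                         ch$joints[i, 1], ch$joints[i, 2], ch$joints[i, 3]), con)
    }
    for (p in pc) {
      writeLines(sprintf("O %.4f %.4f %.4f", p[1], p[2], p[3]), con)
    }
  }
  invisible(path)
}

#' Save / load an ensemble checkpoint
#'
#' Checkpoints are single-file containers of the ensemble's named arrays
#' (length grid, per-length partition sums and looped weights, counts,
#' configuration echo and seed), written with \code{saveRDS}.  Checkpoints
#' of sub-ensembles can be reloaded and combined with [merge_ensembles()].
#'
#' @param ensemble a [generate_ensemble()] result.
#' @param path file path.
#' @return invisibly, the path (\code{write_ensemble}); the ensemble
#'   (\code{read_ensemble}).
#' @export
write_ensemble <- function(ensemble, path) {
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  e <- readRDS(path)
  stopifnot(inherits(e, "loop_ensemble"))
  e
}
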