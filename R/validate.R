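#' Naive rejection-sampling reference ensemble
#'
#' An independent implementation of the chain ensemble used as the central
#' correctness oracle: every bend is drawn directly from the elastic
#' Boltzmann density, the whole chain is materialised, and a chain is
#' discarded if \emph{any} joint pair (under the exclusion window) or
#' joint/protrusion pair overlaps.  All positions are kept, so observables
#' are plain averages over accepted chains.  Intended for short chains; the
#' growth kernel must agree with it within Monte-Carlo error.
#'
#' @param n_chains number of chains.
#' @param N links per chain.
#' @param l link length, nm.
#' @param a bending constant.
#' @param delta_i exclusion window.
#' @param w chain width, nm.
#' @param prot optional protrusion: list with \code{link}, \code{radius},
#'   \code{gamma}.
#' @param criteria optional [loop_criteria()] evaluated at the terminus.
#' @return list with \code{acceptance}, \code{r2_mean}, \code{r2_se},
#'   \code{loop_frac}, \code{loop_se}, \code{n_accept}.
#' @export
rejection_reference <- function(n_chains, N, l, a, delta_i = 1, w = 4.6,
                                prot = NULL, criteria = NULL) {
  n <- n_chains
  joints <- vector("list", N + 1)
  joints[[1]] <- matrix(0, n, 3)
  t_hat <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  u_hat <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  alive <- rep(TRUE, n)
  center <- NULL
  vcross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  for (i in seq_len(N)) {
    if (i > 1) {
      uu <- runif(n)
      ct <- if (a == 0) 2 * uu - 1 else {
        x <- 1 + log(uu + (1 - uu) * exp(-2 * a)) / a
        pmin(pmax(x, -1), 1)
      }
      st <- sqrt(1 - ct^2)
      phi <- runif(n, 0, 2 * pi)
      v_hat <- vcross(t_hat, u_hat)
      tn <- st * cos(phi) * u_hat + st * sin(phi) * v_hat + ct * t_hat
      tn <- tn / sqrt(rowSums(tn^2))
      # parallel transport of u by the minimal rotation t -> tn
      nv <- vcross(t_hat, tn)
      s2 <- rowSums(nv^2)
      ok <- s2 > 1e-28
      nh <- nv / sqrt(pmax(s2, 1e-300))
      # Rodrigues: u' = ca*u + sa*(nh x u) + (1-ca)(nh.u) nh, with ca = ct
      sa <- sqrt(pmax(s2, 0))
      un <- ct * u_hat + sa * vcross(nh, u_hat) +
        (1 - ct) * rowSums(nh * u_hat) * nh
      un[!ok, ] <- u_hat[!ok, , drop = FALSE]
      un <- un - tn * rowSums(un * tn)
      un <- un / sqrt(rowSums(un^2))
      u_hat <- un
      t_hat <- tn
    }
    joints[[i + 1]] <- joints[[i]] + l * t_hat
    # joint-joint overlaps under the exclusion window
    if (i - delta_i >= 0) {
      for (j in 0:(i - delta_i)) {
        d2 <- rowSums((joints[[i + 1]] - joints[[j + 1]])^2)
        alive <- alive & d2 >= w^2 * (1 - 1e-9)
      }
    }
    # protrusion placement and checks
    if (!is.null(prot)) {
      if (i == prot$link) {
        ur <- cos(prot$gamma) * u_hat + sin(prot$gamma) * vcross(t_hat, u_hat)
        center <- joints[[i + 1]] + (w / 2 + prot$radius) * ur
        rr2 <- (w / 2 + prot$radius)^2 * (1 - 1e-9)
        for (j in 0:i) {
          if (j == i) next
          d2 <- rowSums((center - joints[[j + 1]])^2)
          alive <- alive & d2 >= rr2
        }
      } else if (i > prot$link && !is.null(center)) {
        d2 <- rowSums((joints[[i + 1]] - center)^2)
        alive <- alive & d2 >= (w / 2 + prot$radius)^2 * (1 - 1e-9)
      }
    }
  }
  acc <- mean(alive)
  ends <- joints[[N + 1]][alive, , drop = FALSE]
  r2 <- rowSums(ends^2)
  out <- list(acceptance = acc,
              acceptance_se = sqrt(acc * (1 - acc) / n),
              r2_mean = mean(r2), r2_se = sd(r2) / sqrt(nrow(ends)),
              n_accept = nrow(ends))
  if (!is.null(criteria)) {
    lf <- vapply(seq_len(nrow(ends)), function(i)
      is_looped(ends[i, ], criteria), logical(1))
    p <- mean(lf)
    out$loop_frac <- p
    out$loop_se <- sqrt(p * (1 - p) / max(1, nrow(ends)))
  }
  out
}

check_entry <- function(name, value, target, tol, pass, note = "") {
  list(name = name, value = unname(value), target = unname(target),
       tol = unname(tol), pass = isTRUE(pass), note = note)
}

#' Run the built-in validation suite
#'
#' Executes the oracle checks that pin the sampler to independent ground
#' truth: phantom-chain bend-cosine and end-to-end moments against closed
#' forms, equivalence with the naive rejection sampler on a short chain
#' with a protrusion, the sphere solid-angle formula against brute-force
#' direction sampling, and bitwise determinism/mergeability of the kernel.
#' Failures are reported, never raised.
#'
#' @param config optional config (kind \code{validate}) with keys
#'   \code{seed}, \code{n_chains}, \code{out}.
#' @param out_dir output directory for the JSON report (optional).
#' @return a list of check entries plus \code{all_pass}, invisibly written
#'   as JSON when \code{out_dir} is given.
#' @export
run_validate <- function(config = list(kind = "validate"), out_dir = NULL) {
  cfg <- read_run_config(config)
  seed <- cfg$seed %||% 1
  n <- cfg$n_chains %||% 2e4
  out_dir <- out_dir %||% cfg$out
  params <- config_params(cfg)
  checks <- list()

  # phantom-chain closed forms
  for (a in c(0, 1, 10)) {
    Nlinks <- 400L
    segs <- data.frame(n_links = Nlinks, link_length = 1, delta_i = 1)
    sched <- growth_schedule(segs, params = params,
                             record_joints = Nlinks)
    # a is fixed directly by giving b = l * (forward map)
    p2 <- simulation_params(w = params$w, b = max(1, kuhn_ratio_from_a(a)),
                            l1 = 1, l2 = 1, n_chains = n, seed = seed)
    ens <- generate_ensemble(sched, p2, n, seed, self_avoid = FALSE,
                             collect_bend = TRUE, collect_r2 = TRUE)
    ct <- ens$bend$sum / ens$bend$n
    ct_se <- sqrt(max(ens$bend$sumsq / ens$bend$n - ct^2, 0) / ens$bend$n)
    ct_ref <- mean_bend_cosine(a)
    checks[[length(checks) + 1]] <- check_entry(
      sprintf("phantom_cos_theta_a%g", a), ct, ct_ref, 3 * ct_se,
      abs(ct - ct_ref) <= 3 * max(ct_se, 1e-12))
    r2 <- ens$R2[1, 1] / ens$Z[1, 1]
    r2_se <- sqrt(max(ens$R4[1, 1] / ens$Z[1, 1] - r2^2, 0) / ens$Z[1, 1])
    r2_ref <- phantom_chain_r2(Nlinks, 1, a)
    checks[[length(checks) + 1]] <- check_entry(
      sprintf("phantom_r2_a%g", a), r2, r2_ref, 3 * r2_se,
      abs(r2 - r2_ref) <= 3 * r2_se)
  }

  # rejection-sampler equivalence on a short self-avoiding chain
  {
    w <- params$w
    Nl <- 20L; l <- w
    a <- bending_constant_from_kuhn(params$b, l)
    crit <- loop_criteria(d_min = 0.5 * w, epsilon = 4 * w, domega = 4 * pi)
    prot <- list(link = 5L, radius = w, gamma = 0)
    set.seed(seed)
    ref <- rejection_reference(n, Nl, l, a, delta_i = 1, w = w,
                               prot = prot, criteria = crit)
    segs <- data.frame(n_links = Nl, link_length = l, delta_i = 1)
    sched <- growth_schedule(
      segs, protrusions = list(protrusion("on_chain", link = 5L, radius = w)),
      params = params, record_joints = Nl)
    psim <- simulation_params(w = w, b = params$b, l1 = l, l2 = l,
                              delta_i_stage1 = 1)
    ens <- generate_ensemble(sched, psim, n, seed + 7, criteria = list(crit),
                             collect_r2 = TRUE)
    acc <- ens$Z[1, 1] / ens$n_generated
    acc_se <- sqrt(acc * (1 - acc) / n)
    tol <- 3 * sqrt(acc_se^2 + ref$acceptance_se^2)
    checks[[length(checks) + 1]] <- check_entry(
      "rejection_acceptance", acc, ref$acceptance, tol,
      abs(acc - ref$acceptance) <= tol)
    r2 <- ens$R2[1, 1] / ens$Z[1, 1]
    r2_se <- sqrt(max(ens$R4[1, 1] / ens$Z[1, 1] - r2^2, 0) /
                    max(1, ens$Z[1, 1]))
    tol <- 3 * sqrt(r2_se^2 + ref$r2_se^2)
    checks[[length(checks) + 1]] <- check_entry(
      "rejection_r2", r2, ref$r2_mean, tol, abs(r2 - ref$r2_mean) <= tol)
    p <- ens$W[1, 1, 1] / ens$Z[1, 1]
    p_se <- sqrt(p * (1 - p) / max(1, ens$Z[1, 1]))
    tol <- 3 * sqrt(p_se^2 + ref$loop_se^2)
    checks[[length(checks) + 1]] <- check_entry(
      "rejection_loop_fraction", p, ref$loop_frac, tol,
      abs(p - ref$loop_frac) <= tol)
  }

  # solid angle vs brute-force direction sampling
  {
    set.seed(seed + 1)
    for (ratio in c(1.5, 3, 20)) {
      reff <- 1; d <- ratio * reff
      nd <- 2e5
      dirs <- uniform_directions(nd)
      hit <- ray_hits_sphere(matrix(0, nd, 3), dirs, c(d, 0, 0), reff)
      om_mc <- 4 * pi * mean(hit)
      om_se <- 4 * pi * sqrt(mean(hit) * (1 - mean(hit)) / nd)
      om <- solid_angle_sphere(d, reff)
      checks[[length(checks) + 1]] <- check_entry(
        sprintf("solid_angle_d%g", ratio), om_mc, om, 3 * om_se,
        abs(om_mc - om) <= 3 * om_se)
    }
  }

  # determinism and mergeability
  {
    segs <- data.frame(n_links = 60L, link_length = params$l2)
    sched <- growth_schedule(segs, params = params)
    e1 <- generate_ensemble(sched, params, 2000, seed)
    e2 <- generate_ensemble(sched, params, 2000, seed)
    ea <- generate_ensemble(sched, params, 1200, seed, chain_offset = 0)
    eb <- generate_ensemble(sched, params, 800, seed, chain_offset = 1200)
    em <- merge_ensembles(ea, eb)
    det <- identical(e1$Z, e2$Z) && identical(e1$W, e2$W)
    mrg <- identical(em$Z, e1$Z) && identical(em$W, e1$W)
    checks[[length(checks) + 1]] <- check_entry(
      "determinism", as.numeric(det), 1, 0, det)
    checks[[length(checks) + 1]] <- check_entry(
      "merge_additivity", as.numeric(mrg), 1, 0, mrg)
  }

  report <- list(checks = checks,
                 all_pass = all(vapply(checks, `[[`, logical(1), "pass")),
                 seed = seed, n_chains = n)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "validate_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
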