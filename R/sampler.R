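#' Describe a bound protrusion
#'
#' A protein bound to the chain is modelled as a hard sphere.  On-chain
#' protrusions attach to a stage-1 link (index in links = base pairs when
#' \code{l1} is one bp); negative link indices place the protrusion on the
#' backward (outside) segment grown from joint 0 in the \code{-t1} direction.
#' Static protrusions sit at a fixed laboratory position.
#'
#' @param kind \code{"on_chain"} or \code{"static"}.
#' @param link signed link index (on-chain only).
#' @param radius protrusion radius \code{R_o}, nm.
#' @param phase phase angle about the chain axis, radians (on-chain only).
#' @param position length-3 position, nm (static only).
#' @param enforce logical; \code{TRUE} makes the protrusion a hard wall
#'   during growth, \code{FALSE} records it as a virtual condition evaluated
#'   as a post-hoc subset selection (see [generate_ensemble()]).
#' @return an object of class \code{"protrusion"}.
#' @export
protrusion <- function(kind = c("on_chain", "static"), link = NULL,
                       radius, phase = 0, position = NULL, enforce = TRUE) {
  kind <- match.arg(kind)
  stopifnot(radius > 0)
  if (kind == "on_chain") {
    stopifnot(!is.null(link), link != 0)
  } else {
    stopifnot(!is.null(position), length(position) == 3)
  }
  structure(list(kind = kind, link = if (is.null(link)) NULL else as.integer(link),
                 radius = radius, phase = phase, position = position,
                 enforce = isTRUE(enforce)),
            class = "protrusion")
}

#' Growth schedule for a chain ensemble
#'
#' Chains are grown in consecutive segments of declared link length; the
#' usual scheme is a stage-1 segment at base-pair resolution (where all
#' bound objects sit) followed by a stage-2 segment with links of one chain
#' width.  Optional extras: a leading flank (grown backward from joint 0
#' before the main chain), a trailing flank (extra links beyond the recorded
#' looping lengths: a loop of length L inside a longer chain), an outside
#' segment of length \code{Q} for protrusions at negative link index, and a
#' confining sphere centred at joint 0.
#'
#' @param segments data frame with columns \code{n_links},
#'   \code{link_length} and optionally \code{delta_i} (defaulting to
#'   [default_delta_i()]).
#' @param protrusions list of [protrusion()] objects.
#' @param leading_flank leading flank length, nm (grown backward).
#' @param trailing_links number of trailing stage-2 links: a chain counts at
#'   recorded length L only while alive \code{trailing_links} links past L.
#' @param outside_Q length of the backward segment hosting negative-index
#'   protrusions, nm; must be at least 10 times the largest |K| used.
#' @param confinement_radius radius of the confining sphere centred at
#'   joint 0, nm; \code{NULL} for unconfined growth.
#' @param confinement_enforce logical; as for [protrusion()].
#' @param backward_segments optional explicit data frame (same columns as
#'   \code{segments}) overriding the derived backward composition.
#' @param record_joints optional integer vector of forward joint indices at
#'   which looping is recorded; default: every stage-2 joint that still has
#'   \code{trailing_links} links after it.
#' @param params a [simulation_params()] object supplying \code{w}, \code{b}
#'   and the stage-1 exclusion window.
#' @return an object of class \code{"growth_schedule"}.
#' @export
growth_schedule <- function(segments, protrusions = list(),
                            leading_flank = 0, trailing_links = 0,
                            outside_Q = 0, confinement_radius = NULL,
                            confinement_enforce = TRUE,
                            backward_segments = NULL,
                            record_joints = NULL,
                            params = simulation_params()) {
  stopifnot(is.data.frame(segments), all(segments$n_links >= 1),
            all(segments$link_length > 0))
  if (is.null(segments$delta_i)) {
    segments$delta_i <- vapply(segments$link_length, default_delta_i,
                               integer(1), w = params$w)
  }
  segments$n_links <- as.integer(segments$n_links)
  n_fwd <- sum(segments$n_links)

  neg <- vapply(protrusions, function(p)
    p$kind == "on_chain" && p$link < 0, logical(1))
  k_neg_max <- if (any(neg))
    max(vapply(protrusions[neg], function(p) -p$link, numeric(1))) else 0

  # backward composition: stage-1 resolution past the outermost backward
  # protrusion, then stage-2 out to max(leading_flank, outside_Q)
  if (is.null(backward_segments)) {
    bwd <- NULL
    l1 <- segments$link_length[1]
    if (k_neg_max > 0) {
      if (outside_Q <= 0) outside_Q <- 10 * params$b
      if (outside_Q < 10 * k_neg_max * l1) {
        stop("outside_Q must be at least 10 times the largest |K| (",
             10 * k_neg_max * l1, " nm)")
      }
      n1b <- min(n_fwd, k_neg_max + as.integer(ceiling(params$b / l1 / 2)))
      n1b <- max(n1b, k_neg_max + 1L)
      rest <- max(leading_flank, outside_Q) - n1b * l1
      bwd <- data.frame(n_links = n1b, link_length = l1,
                        delta_i = segments$delta_i[1])
      if (rest > 0) {
        bwd <- rbind(bwd, data.frame(
          n_links = as.integer(ceiling(rest / params$l2)),
          link_length = params$l2,
          delta_i = default_delta_i(params$w, params$l2)))
      }
    } else if (leading_flank > 0) {
      bwd <- data.frame(n_links = as.integer(ceiling(leading_flank / params$l2)),
                        link_length = params$l2,
                        delta_i = default_delta_i(params$w, params$l2))
    }
  } else {
    bwd <- backward_segments
    if (is.null(bwd$delta_i)) {
      bwd$delta_i <- vapply(bwd$link_length, default_delta_i,
                            integer(1), w = params$w)
    }
  }

  for (p in protrusions) {
    if (p$kind != "on_chain") next
    if (p$link > 0 && p$link > n_fwd)
      stop("protrusion link ", p$link, " beyond the declared forward segments")
    if (p$link < 0 && (is.null(bwd) || -p$link > sum(bwd$n_links)))
      stop("protrusion link ", p$link, " beyond the declared backward segments")
  }

  if (is.null(record_joints)) {
    # default grid: stage-2 joints (link length >= l2) of the forward chain
    lens <- rep(segments$link_length, segments$n_links)
    idx <- which(lens >= params$l2 - 1e-12)
    if (length(idx) == 0) idx <- seq_len(n_fwd)
    record_joints <- idx[idx + trailing_links <= n_fwd]
  }
  stopifnot(all(record_joints + trailing_links <= n_fwd))

  structure(list(segments = segments, backward_segments = bwd,
                 protrusions = protrusions,
                 trailing_links = as.integer(trailing_links),
                 confinement_radius = confinement_radius,
                 confinement_enforce = isTRUE(confinement_enforce),
                 record_joints = as.integer(record_joints)),
            class = "growth_schedule")
}

#' @export
print.growth_schedule <- function(x, ...) {
  cat("Growth schedule:", sum(x$segments$n_links), "forward links")
  if (!is.null(x$backward_segments))
    cat(" +", sum(x$backward_segments$n_links), "backward links")
  cat("\n  protrusions:", length(x$protrusions))
  if (!is.null(x$confinement_radius))
    cat("  confinement radius:", x$confinement_radius, "nm")
  cat("\n  recorded lengths:", length(x$record_joints),
      "(trailing links:", x$trailing_links, ")\n")
  invisible(x)
}

#' Looping acceptance criterion
#'
#' A chain terminus is looped when it falls in the radial shell
#' \code{[d_min, d_min + epsilon]} around the anchor and its direction from
#' the anchor lies inside the spherical cap of solid angle \code{|domega|}
#' about \code{+axis} (\code{domega > 0}) or \code{-axis}
#' (\code{domega < 0}); \code{domega = 4*pi} accepts every direction.
#'
#' Anchored criteria (\code{type = "end"}) use a fixed anchor and axis
#' (defaults: joint 0 and the lab x axis, the looping-volume orientation
#' \code{u0}).  Activator criteria (\code{type = "activator"}) anchor at the
#' centre of a bound protrusion, with the axis pointing from the chain to the
#' protrusion centre, recomputed for every chain configuration.
#'
#' @param d_min inner shell radius, nm.
#' @param epsilon shell thickness, nm.
#' @param domega signed angular acceptance, in (-4*pi, 4*pi].
#' @param anchor,axis fixed anchor point and unit axis (type \code{"end"}).
#' @param type \code{"end"} or \code{"activator"}.
#' @param activator index (into the schedule's protrusion list) of the
#'   activator protrusion anchoring the criterion.
#' @return an object of class \code{"loop_criteria"}.
#' @export
loop_criteria <- function(d_min, epsilon, domega = 2 * pi * 0.1,
                          anchor = c(0, 0, 0), axis = c(1, 0, 0),
                          type = c("end", "activator"), activator = NULL) {
  type <- match.arg(type)
  stopifnot(d_min >= 0, epsilon > 0, abs(domega) <= 4 * pi)
  if (type == "activator") stopifnot(!is.null(activator))
  axis <- axis / sqrt(sum(axis^2))
  structure(list(d_min = d_min, epsilon = epsilon, domega = domega,
                 anchor = anchor, axis = axis, type = type,
                 activator = if (is.null(activator)) NULL else as.integer(activator)),
            class = "loop_criteria")
}

#' Looping test for a single terminus position
#'
#' @param chain_end length-3 terminus position, nm.
#' @param criteria a [loop_criteria()] object (type \code{"end"}).
#' @return \code{TRUE} if the terminus satisfies the criterion.
#' @export
is_looped <- function(chain_end, criteria) {
  dr <- chain_end - criteria$anchor
  r <- sqrt(sum(dr^2))
  if (r < criteria$d_min || r > criteria$d_min + criteria$epsilon) return(FALSE)
  adom <- abs(criteria$domega)
  if (adom >= 4 * pi - 1e-12) return(TRUE)
  cosc <- 1 - adom / (2 * pi)
  s <- if (criteria$domega < 0) -1 else 1
  sum(dr * criteria$axis) * s / r >= cosc
}

# ---- kernel plumbing -------------------------------------------------------

seg_matrix <- function(seg, params) {
  a <- vapply(seg$link_length, function(l) bending_constant_from_kuhn(params$b, l),
              numeric(1))
  cbind(n = seg$n_links, l = seg$link_length, a = a, delta_i = seg$delta_i)
}

cond_list <- function(schedule) {
  conds <- lapply(schedule$protrusions, function(p) {
    if (p$kind == "on_chain") {
      list(type = "protrusion", link = p$link, radius = p$radius,
           gamma = p$phase, enforce = p$enforce)
    } else {
      list(type = "static", radius = p$radius, position = as.numeric(p$position),
           enforce = p$enforce)
    }
  })
  if (!is.null(schedule$confinement_radius)) {
    conds <- c(conds, list(list(type = "confinement",
                                radius = schedule$confinement_radius,
                                enforce = schedule$confinement_enforce)))
  }
  conds
}

crit_list <- function(criteria, schedule) {
  lapply(criteria, function(cr) {
    if (cr$type == "end") {
      list(type = "end", anchor = as.numeric(cr$anchor),
           axis = as.numeric(cr$axis), d_min = cr$d_min, eps = cr$epsilon,
           domega = cr$domega)
    } else {
      list(type = "activator", cond = cr$activator, d_min = cr$d_min,
           eps = cr$epsilon, domega = cr$domega)
    }
  })
}

kernel_config <- function(schedule, params, n_chains, seed, criteria,
                          groups, ensembles, windows, chain_offset = 0,
                          self_avoid = TRUE, collect_bend = FALSE,
                          collect_r2 = FALSE, return_chain = 0L) {
  grid <- schedule$record_joints
  win_items <- lapply(windows, function(wn) {
    lapply(wn, function(it) as.integer(c(it$ensemble, it$group, it$lo, it$hi)))
  })
  list(w = params$w,
       self_avoid = self_avoid,
       n_chains = as.double(n_chains),
       chain_offset = as.double(chain_offset),
       seed = as.double(seed),
       eval_offset = as.integer(schedule$trailing_links),
       collect_bend = collect_bend,
       collect_r2 = collect_r2,
       return_chain = as.integer(return_chain),
       fwd_segments = seg_matrix(schedule$segments, params),
       bwd_segments = if (is.null(schedule$backward_segments)) NULL else
         seg_matrix(schedule$backward_segments, params),
       conditions = cond_list(schedule),
       record_joints = as.integer(grid),
       criteria = crit_list(criteria, schedule),
       criteria_groups = lapply(groups, as.integer),
       ensembles = lapply(ensembles, as.integer),
       windows = win_items)
}

grid_lengths <- function(schedule, params) {
  lens <- rep(schedule$segments$link_length, schedule$segments$n_links)
  cum <- cumsum(lens)
  nm <- cum[schedule$record_joints]
  list(nm = nm, bp = nm / params$bp_nm)
}

#' Generate a weighted chain ensemble
#'
#' Grows \code{n_chains} chains under the schedule, accumulating the
#' partition sum and looping statistics at every recorded length.  Bend
#' angles come from the exact elastic Boltzmann density, so a surviving
#' chain's Rosenbluth weight is 1 and the partition sum \code{Z(L)} equals
#' the number of chains still alive at length L; estimators are ratios of
#' looped weight to \code{Z}.
#'
#' Conditions (protrusions, confinement) flagged \code{enforce = FALSE} are
#' \emph{virtual}: growth ignores them, but the first step at which each
#' would have been violated is tracked, and \code{ensembles} selects subsets
#' of chains that never violate a given set of virtual conditions.  Because
#' conditions consume no randomness, such a subset is chain-for-chain
#' identical to an enforced run with the same per-chain seeds, which makes
#' paired (variance-reduced) comparisons against the baseline exact.
#'
#' @param schedule a [growth_schedule()].
#' @param params a [simulation_params()].
#' @param n_chains number of chains.
#' @param seed RNG seed (each chain derives an independent stream from
#'   \code{seed} and its global index \code{chain_offset + i}).
#' @param criteria list of [loop_criteria()] (default: one end-anchored
#'   criterion with the parameter defaults).
#' @param groups list of integer vectors grouping criteria; a group's looped
#'   value is the \emph{sum} of its members' indicators (used for
#'   multi-activator looping).  Default: one group per criterion.
#' @param ensembles list of integer vectors of virtual-condition indices
#'   (indices into the schedule's protrusion list, with the confinement
#'   sphere last if virtual).  The first ensemble should be
#'   \code{integer(0)}, the baseline.  Default: baseline plus, when any
#'   virtual condition exists, one ensemble with all of them.
#' @param windows list of windows for pooled-statistics output; each window
#'   is a list of up to 4 items \code{list(ensemble =, group =, lo =, hi =)}
#'   (grid-point index range).  Per-chain window sums and their full cross
#'   moments are accumulated for delta-method errors on pooled ratios.
#' @param chain_offset global index offset (for mergeable sub-ensembles).
#' @param self_avoid logical; \code{FALSE} disables chain-chain hard walls
#'   (phantom chain).
#' @param collect_bend,collect_r2 accumulate bend-cosine moments and
#'   per-length mean-square end-to-end distances (validation aids).
#' @return an object of class \code{"loop_ensemble"}.
#' @export
generate_ensemble <- function(schedule, params = simulation_params(),
                              n_chains = params$n_chains, seed = params$seed,
                              criteria = NULL, groups = NULL, ensembles = NULL,
                              windows = list(), chain_offset = 0,
                              self_avoid = TRUE, collect_bend = FALSE,
                              collect_r2 = FALSE) {
  if (n_chains < 1) stop("n_chains must be at least 1 (empty ensemble)")
  if (is.null(criteria)) {
    criteria <- list(loop_criteria(params$d_min, params$epsilon, params$domega))
  }
  if (is.null(groups)) groups <- as.list(seq_along(criteria))
  conds <- cond_list(schedule)
  virt <- which(!vapply(conds, function(c) isTRUE(c$enforce), logical(1)))
  if (is.null(ensembles)) {
    ensembles <- list(integer(0))
    if (length(virt) > 0) ensembles <- c(ensembles, list(virt))
  }
  stopifnot(all(unlist(ensembles) %in% virt))
  for (wn in windows) {
    stopifnot(length(wn) <= 4)
  }
  cfg <- kernel_config(schedule, params, n_chains, seed, criteria, groups,
                       ensembles, windows, chain_offset, self_avoid,
                       collect_bend, collect_r2)
  raw <- cpp_run_ensemble(cfg)
  gl <- grid_lengths(schedule, params)
  out <- structure(list(
    lengths_nm = gl$nm, lengths_bp = gl$bp,
    Z = raw$Z, W = raw$W, dup = raw$dup,
    n_generated = raw$n_generated, n_discarded = raw$n_discarded,
    n_complete = raw$n_complete,
    bend = if (raw$bend_n > 0)
      list(sum = raw$bend_sum, sumsq = raw$bend_sumsq, n = raw$bend_n) else NULL,
    R2 = raw$R2, R4 = raw$R4,
    window_moments = raw$windows, windows = windows,
    schedule = schedule, params = params,
    criteria = criteria, groups = groups, ensembles = ensembles,
    seed = seed, chain_offset = chain_offset, n_chains = n_chains,
    self_avoid = self_avoid), class = "loop_ensemble")
  if (out$n_complete == 0)
    stop("every chain was discarded before completing the schedule: Z = 0")
  out
}

#' @export
print.loop_ensemble <- function(x, ...) {
  cat(sprintf("Chain ensemble: %g chains (%g discarded), %d recorded lengths\n",
              x$n_generated, x$n_discarded, length(x$lengths_nm)))
  cat(sprintf("  L = %.1f .. %.1f nm (%.0f .. %.0f bp), %d ensemble(s)\n",
              min(x$lengths_nm), max(x$lengths_nm),
              min(x$lengths_bp), max(x$lengths_bp), nrow(x$Z)))
  invisible(x)
}

#' Merge independently generated sub-ensembles
#'
#' Sub-ensembles generated with the same configuration but disjoint chain
#' index ranges (\code{chain_offset}) add exactly: the merged accumulators
#' are identical to a single run over the union of indices.
#'
#' @param ... \code{loop_ensemble} objects.
#' @return a merged \code{loop_ensemble}.
#' @export
merge_ensembles <- function(...) {
  es <- list(...)
  stopifnot(length(es) >= 1)
  out <- es[[1]]
  for (e in es[-1]) {
    stopifnot(identical(e$lengths_nm, out$lengths_nm),
              identical(e$ensembles, out$ensembles))
    out$Z <- out$Z + e$Z
    out$W <- out$W + e$W
    out$dup <- out$dup + e$dup
    out$n_generated <- out$n_generated + e$n_generated
    out$n_discarded <- out$n_discarded + e$n_discarded
    out$n_complete <- out$n_complete + e$n_complete
    if (!is.null(out$R2) && !is.null(e$R2)) out$R2 <- out$R2 + e$R2
    if (!is.null(out$bend) && !is.null(e$bend)) {
      out$bend$sum <- out$bend$sum + e$bend$sum
      out$bend$sumsq <- out$bend$sumsq + e$bend$sumsq
      out$bend$n <- out$bend$n + e$bend$n
    }
    if (length(out$window_moments) > 0) {
      for (i in seq_along(out$window_moments)) {
        out$window_moments[[i]]$n <- out$window_moments[[i]]$n +
          e$window_moments[[i]]$n
        out$window_moments[[i]]$S <- out$window_moments[[i]]$S +
          e$window_moments[[i]]$S
        out$window_moments[[i]]$M <- out$window_moments[[i]]$M +
          e$window_moments[[i]]$M
      }
    }
  }
  out
}

#' Grow a single chain configuration
#'
#' Runs the growth kernel for one chain (by global index) and returns its
#' full trajectory: joint positions, forward link frames, Rosenbluth weight
#' (1 for a surviving chain, 0 for a discarded one) and the placed
#' protrusion centres.
#'
#' @param schedule a [growth_schedule()].
#' @param params a [simulation_params()].
#' @param seed RNG seed.
#' @param index global chain index (different indices give independent
#'   chains under the same seed).
#' @param self_avoid logical.
#' @return an object of class \code{"chain_conf"}: a list with
#'   \code{joints} (matrix, first row = joint 0 ... for a chain with a
#'   backward segment the backward joints come first after the origin row;
#'   \code{contour} gives each joint's signed arc-length coordinate),
#'   \code{u_fwd}, \code{t_fwd} (frames of forward links),
#'   \code{rosenbluth_weight}, \code{discarded}, \code{prot_centers}.
#' @export
grow_chain <- function(schedule, params = simulation_params(),
                       seed = params$seed, index = 1, self_avoid = TRUE) {
  crit <- list(loop_criteria(params$d_min, params$epsilon, params$domega))
  cfg <- kernel_config(schedule, params, n_chains = index, seed = seed,
                       criteria = crit, groups = list(1L),
                       ensembles = list(integer(0)), windows = list(),
                       self_avoid = self_avoid, return_chain = index)
  raw <- cpp_run_ensemble(cfg)
  ch <- raw$chain
  structure(list(joints = ch$joints, contour = ch$contour,
                 u_fwd = ch$u_fwd, t_fwd = ch$t_fwd,
                 n_backward = ch$n_backward,
                 rosenbluth_weight = if (ch$discarded) 0 else 1,
                 discarded = ch$discarded, death_step = ch$death_step,
                 prot_centers = ch$prot_centers,
                 viol_steps = ch$viol_steps),
            class = "chain_conf")
}

#' @export
print.chain_conf <- function(x, ...) {
  cat(sprintf("Chain configuration: %d joints placed%s, weight %g\n",
              nrow(x$joints),
              if (x$discarded) " (discarded)" else "", x$rosenbluth_weight))
  invisible(x)
}

#' Weighted ensemble average over explicit chain configurations
#'
#' \eqn{\langle f\rangle = \sum_j f(x_j) w_j / Z} with \eqn{Z = \sum_j w_j}.
#' Intended for small explicitly materialised ensembles (validation); large
#' runs use the streaming accumulators of [generate_ensemble()].
#'
#' @param chains list of [grow_chain()] results (or any objects with
#'   \code{rosenbluth_weight}).
#' @param observable function mapping a chain to a numeric scalar.
#' @return the weighted average.
#' @export
ensemble_average <- function(chains, observable) {
  w <- vapply(chains, function(c) c$rosenbluth_weight, numeric(1))
  Z <- sum(w)
  if (Z <= 0) stop("Z = 0: ensemble average undefined")
  f <- vapply(chains[w > 0], observable, numeric(1))
  sum(f * w[w > 0]) / Z
}

#' Whole-joint-inside confinement test
#'
#' A joint passes when its entire hard sphere lies inside the confining
#' sphere: \code{|joint - center| + w/2 <= radius}.
#'
#' @param joint length-3 position, nm.
#' @param radius confining-sphere radius, nm.
#' @param center sphere centre (default: origin, i.e. joint 0).
#' @param w chain width, nm.
#' @return \code{TRUE} if the joint sphere is fully inside.
#' @export
confinement_check <- function(joint, radius, center = c(0, 0, 0), w = 4.6) {
  stopifnot(radius > 0)
  sqrt(sum((joint - center)^2)) + w / 2 <= radius
}
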