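#' Built-in protein radii for the eve 3/7 system
#'
#' Hard-sphere radii for the transcription factors of the Drosophila
#' melanogaster eve 3/7 enhancer, modelled as globular proteins: dStat
#' (86 kDa), Zld (146 kDa), bare Knirps (46 kDa), Knirps bound to CtBP
#' dimers (130 kDa), and the full putative 450 kDa
#' repressor--co-repressor--HDAC complex.
#'
#' @return named numeric vector of radii, nm.
#' @examples
#' builtin_protein_radii()[["Knirps"]]   # 2.38
#' @export
builtin_protein_radii <- function() {
  c(dStat = 3.04, Zld = 3.75, Knirps = 2.38,
    Knirps_CtBP = 3.59, full_complex = 5.83)
}

#' Radius of a protein by name
#' @param name protein name (see [builtin_protein_radii()]).
#' @return radius, nm.
#' @export
protein_radius <- function(name) {
  tab <- builtin_protein_radii()
  if (!name %in% names(tab))
    stop("unknown protein '", name, "'; known: ",
         paste(names(tab), collapse = ", "))
  tab[[name]]
}

#' Globular-protein radius from molecular mass
#'
#' Cube-root scaling \eqn{R = c\,M^{1/3}} with the prefactor fitted (mean of
#' \eqn{R/M^{1/3}}) to the five tabulated (mass, radius) pairs of
#' [builtin_protein_radii()]: (86, 3.04), (146, 3.75), (46, 2.38),
#' (130, 3.59), (450, 5.83) in (kDa, nm).  Tabulated values always take
#' precedence; this helper covers masses outside the table (each tabulated
#' radius is reproduced to better than 8 percent).
#'
#' @param mass_kda molecular mass, kDa.
#' @return radius, nm.
#' @export
mass_to_radius <- function(mass_kda) {
  stopifnot(all(mass_kda > 0))
  masses <- c(86, 146, 46, 130, 450)
  radii <- c(3.04, 3.75, 2.38, 3.59, 5.83)
  mean(radii / masses^(1 / 3)) * mass_kda^(1 / 3)
}

#' Helical phase of a binding site from DNA native twist
#'
#' Although the twist degree of freedom carries no elastic energy in the
#' chain model, the geometry of a natural enhancer is recreated by phasing
#' each bound protein around the chain axis according to its position:
#' \eqn{\gamma = (\mathrm{position\ in\ bp}) \times \mathrm{twist}
#' \bmod 2\pi}, with native twist \eqn{2\pi/10.5} per bp.  Fractional
#' positions are rounded to the nearest stage-1 link (links are the only
#' addressable sites); the phase uses the rounded position.
#'
#' @param position_bp binding-site position, bp.
#' @param native_twist twist per bp, radians.
#' @return phase angle in \code{[0, 2*pi)}.
#' @export
phase_from_position <- function(position_bp, native_twist = 2 * pi / 10.5) {
  stopifnot(all(position_bp >= 0))
  (round(position_bp) * native_twist) %% (2 * pi)
}

#' Enhancer layout
#'
#' A description of an enhancer--promoter chain: total length in bp, a site
#' table (position, protein, role, occupancy) and the native twist used for
#' helical phasing.
#'
#' @param sites data frame with columns \code{position_bp}, \code{name},
#'   \code{role} (\code{"activator"} or \code{"repressor"}),
#'   \code{occupied} (logical) and optionally \code{radius_nm} (defaulting
#'   to the built-in table by protein name).
#' @param chain_length_bp total enhancer-promoter separation, bp.
#' @param native_twist radians per bp.
#' @return an object of class \code{"enhancer_layout"}.
#' @export
enhancer_layout <- function(sites, chain_length_bp = 3900,
                            native_twist = 2 * pi / 10.5) {
  stopifnot(is.data.frame(sites),
            all(c("position_bp", "name", "role", "occupied") %in% names(sites)))
  if (is.null(sites$radius_nm)) {
    sites$radius_nm <- vapply(as.character(sites$name), protein_radius,
                              numeric(1))
  }
  stopifnot(all(sites$position_bp > 0),
            all(sites$position_bp < chain_length_bp),
            all(diff(sites$position_bp) > 0),
            all(sites$radius_nm > 0),
            all(sites$role %in% c("activator", "repressor")))
  structure(list(sites = sites, chain_length_bp = chain_length_bp,
                 native_twist = native_twist),
            class = "enhancer_layout")
}

#' @export
print.enhancer_layout <- function(x, ...) {
  cat(sprintf("Enhancer layout: %d sites on %d bp (%d occupied)\n",
              nrow(x$sites), x$chain_length_bp, sum(x$sites$occupied)))
  print(x$sites, row.names = FALSE)
  invisible(x)
}

#' Read an enhancer layout from a tab-separated file
#'
#' Expected columns: \code{position_bp}, \code{name}, \code{role},
#' \code{occupied} and optionally \code{radius_nm}.
#'
#' @param path file path.
#' @param ... passed to [enhancer_layout()].
#' @return an [enhancer_layout()] object.
#' @export
read_enhancer_layout <- function(path, ...) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$occupied <- as.logical(df$occupied)
  enhancer_layout(df, ...)
}

#' Import binding sites from BED-like intervals
#'
#' Converts 0-based half-open intervals \code{[start, end)} to site
#' positions at the interval midpoint, rounded to the nearest bp (midpoint
#' of \code{[start, end)} is \code{(start + end)/2} in 0-based coordinates,
#' reported 1-based).
#'
#' @param bed data frame with columns \code{start}, \code{end},
#'   \code{name}, and optionally \code{role}, \code{occupied}.
#' @return a site data frame suitable for [enhancer_layout()].
#' @export
sites_from_bed <- function(bed) {
  stopifnot(all(c("start", "end", "name") %in% names(bed)),
            all(bed$end > bed$start))
  # 0-based midpoint -> 1-based bp; half-bp midpoints round up
  pos <- as.integer(floor((bed$start + bed$end) / 2 + 0.5)) + 1L
  data.frame(position_bp = pos, name = bed$name,
             role = if (is.null(bed$role)) "activator" else bed$role,
             occupied = if (is.null(bed$occupied)) TRUE else bed$occupied,
             stringsAsFactors = FALSE)
}

#' Translate an enhancer layout into a growth schedule
#'
#' Builds the two-stage schedule for the enhancer-promoter chain: stage-1
#' (one link per bp) covers every binding site, stage 2 completes the chain
#' to its full length.  Occupied sites become on-chain protrusions at their
#' stage-1 links with helical phases from [phase_from_position()];
#' activator sites are additionally returned with activator-anchored
#' looping criteria (\eqn{d_{min} = w/2 + R_{activator}},
#' \eqn{\varepsilon} = 3 nm).  In the \code{"fully_bound"} state the
#' placement is checked for protrusion-protrusion overlap on the straight
#' chain, which would make the geometry infeasible.
#'
#' @param layout an [enhancer_layout()].
#' @param params a [simulation_params()].
#' @param state \code{"bare"} (no protrusions) or \code{"fully_bound"}.
#' @param domega angular acceptance for the activator criteria.
#' @param epsilon shell thickness for the activator criteria, nm.
#' @param enforce logical; \code{FALSE} creates virtual protrusions for
#'   paired baseline/bound comparisons from one run.
#' @param trailing_links,stage1_pad passed through to the schedule:
#'   \code{stage1_pad} adds bp-resolution links beyond the last site.
#' @return list with \code{schedule}, \code{criteria} (activator-anchored,
#'   one per activator; empty in the bare state only if no activators),
#'   \code{activators} (protrusion indices), and \code{state}.
#' @export
layout_to_schedule <- function(layout, params = simulation_params(),
                               state = c("fully_bound", "bare"),
                               domega = 2 * pi * 0.1, epsilon = 3,
                               enforce = TRUE, trailing_links = 0,
                               stage1_pad = 10L) {
  state <- match.arg(state)
  sites <- layout$sites
  l1 <- params$l1
  n_total_links <- as.integer(round(layout$chain_length_bp * params$bp_nm / l1))
  k <- as.integer(round(sites$position_bp))   # one stage-1 link per bp
  n1 <- min(n_total_links, max(k) + stage1_pad)
  rest_nm <- (n_total_links - n1) * l1
  segs <- data.frame(n_links = n1, link_length = l1,
                     delta_i = params$delta_i_stage1)
  if (rest_nm > 0) {
    segs <- rbind(segs, data.frame(
      n_links = as.integer(round(rest_nm / params$l2)),
      link_length = params$l2,
      delta_i = default_delta_i(params$w, params$l2)))
  }
  occupied <- if (state == "bare") rep(FALSE, nrow(sites)) else sites$occupied
  prots <- list()
  act_idx <- integer(0)
  act_rows <- which(sites$role == "activator")
  for (i in which(occupied | seq_len(nrow(sites)) %in% act_rows)) {
    # activators are always placed (they anchor the looping criteria);
    # in the bare state they are virtual so the chain carries no hard walls
    enf <- enforce && occupied[i]
    prots <- c(prots, list(protrusion(
      "on_chain", link = k[i], radius = sites$radius_nm[i],
      phase = phase_from_position(sites$position_bp[i], layout$native_twist),
      enforce = enf)))
    if (i %in% act_rows) act_idx <- c(act_idx, length(prots))
  }
  if (state == "fully_bound")
    check_layout_feasible(sites, k, params, layout$native_twist)
  sched <- growth_schedule(segs, protrusions = prots,
                           trailing_links = trailing_links, params = params)
  criteria <- lapply(act_idx, function(j) {
    loop_criteria(d_min = params$w / 2 + prots[[j]]$radius, epsilon = epsilon,
                  domega = domega, type = "activator", activator = j)
  })
  list(schedule = sched, criteria = criteria, activators = act_idx,
       state = state)
}

# protrusion-protrusion overlap on the straight reference chain
check_layout_feasible <- function(sites, k, params,
                                  native_twist = 2 * pi / 10.5) {
  occ <- which(sites$occupied)
  if (length(occ) < 2) return(invisible(TRUE))
  w <- params$w; l1 <- params$l1
  # straight chain along +z, u = +x: centre of site i
  cen <- function(i) {
    g <- phase_from_position(sites$position_bp[i], native_twist)
    r <- w / 2 + sites$radius_nm[i]
    c(r * cos(g), r * sin(g), k[i] * l1)
  }
  for (ii in seq_along(occ)) {
    for (jj in seq_len(ii - 1)) {
      i <- occ[ii]; j <- occ[jj]
      if (sqrt(sum((cen(i) - cen(j))^2)) <
          sites$radius_nm[i] + sites$radius_nm[j]) {
        stop("infeasible layout: protrusions at ", sites$position_bp[i],
             " and ", sites$position_bp[j],
             " bp overlap on the straight chain")
      }
    }
  }
  invisible(TRUE)
}

#' Recover site positions from a schedule (round trip)
#'
#' @param schedule a [growth_schedule()] produced by [layout_to_schedule()].
#' @param params a [simulation_params()].
#' @return integer vector of site positions, bp.
#' @export
schedule_site_positions <- function(schedule, params = simulation_params()) {
  ks <- vapply(schedule$protrusions, function(p)
    if (p$kind == "on_chain") p$link else NA_integer_, integer(1))
  round(ks[!is.na(ks)] * params$l1 / params$bp_nm)
}
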