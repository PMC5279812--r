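#' Physical and numerical parameters of the chain model
#'
#' Container for the constants of the discrete semi-flexible chain: the
#' chain cross-section diameter \code{w}, the Kuhn length \code{b}, the two
#' link lengths of the two-stage growth scheme (\code{l1} at base-pair
#' resolution, \code{l2} at chain-width resolution), the neighbour-exclusion
#' window for stage 1, the default looping-volume parameters, and the
#' base-pair length used for bp/nm conversion.
#'
#' Defaults describe bare dsDNA: \code{w} = 4.6 nm, \code{b} = 106 nm,
#' \code{l1} = 0.34 nm (one base pair), \code{l2} = \code{w}.  The default
#' looping volume is the radial shell \code{[d_min, d_min + epsilon]} =
#' \code{[w, 3w]} intersected with a cone of solid angle
#' \code{domega} = 2*pi*0.1 about the lab x axis.
#'
#' @param w chain cross-section diameter, nm.
#' @param b Kuhn length, nm.
#' @param l1 stage-1 link length, nm.
#' @param l2 stage-2 link length, nm (defaults to \code{w}).
#' @param bp_nm base-pair length, nm.
#' @param delta_i_stage1 neighbour-exclusion window for stage-1 links; the
#'   default is \code{ceiling((4/3) * w / l1)}, which satisfies the
#'   requirement \code{delta_i >= w / l}.
#' @param d_min,epsilon,domega default looping-volume parameters (nm, nm,
#'   steradians; \code{domega} may be negative, see [loop_criteria()]).
#' @param n_chains default ensemble size.
#' @param seed default RNG seed.
#' @return An object of class \code{"sim_params"} (a named list).
#' @examples
#' p <- simulation_params()
#' p$delta_i_stage1   # 19 for w = 4.6 nm, l1 = 0.34 nm
#' @export
simulation_params <- function(w = 4.6, b = 106, l1 = 0.34, l2 = w,
                              bp_nm = 0.34,
                              delta_i_stage1 = default_delta_i(w, l1),
                              d_min = w, epsilon = 2 * w,
                              domega = 2 * pi * 0.1,
                              n_chains = 1e5, seed = 1L) {
  stopifnot(w > 0, b > 0, l1 > 0, l2 > 0, bp_nm > 0)
  if (delta_i_stage1 < w / l1) {
    stop("delta_i_stage1 must satisfy delta_i >= w/l1 (got ", delta_i_stage1,
         " < ", w / l1, ")")
  }
  structure(list(w = w, b = b, l1 = l1, l2 = l2, bp_nm = bp_nm,
                 delta_i_stage1 = as.integer(delta_i_stage1),
                 d_min = d_min, epsilon = epsilon, domega = domega,
                 n_chains = n_chains, seed = seed),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Chain model parameters\n")
  cat(sprintf("  w = %.3g nm, b = %.4g nm (b/w = %.3g)\n", x$w, x$b, x$b / x$w))
  cat(sprintf("  links: l1 = %.3g nm (delta_i = %d), l2 = %.3g nm\n",
              x$l1, x$delta_i_stage1, x$l2))
  cat(sprintf("  looping volume: d_min = %.3g nm, epsilon = %.3g nm, domega = %.4g sr\n",
              x$d_min, x$epsilon, x$domega))
  invisible(x)
}

#' Default neighbour-exclusion window
#'
#' For link length \code{l >= w} adjacent hard spheres cannot overlap and the
#' window is 1; for finer links the window is \code{ceiling((4/3) * w / l)},
#' which keeps spheres closer than about one chain width along the contour
#' from being tested against each other.
#'
#' @param w chain width, nm.
#' @param l link length, nm.
#' @return integer exclusion window.
#' @export
default_delta_i <- function(w, l) {
  if (l >= w) 1L else as.integer(ceiling((4 / 3) * w / l))
}

#' Bending energy of a joint
#'
#' Dimensionless elastic energy \eqn{\beta E = a (1 - \cos\theta)} of a bend
#' of zenith angle \code{theta}; the azimuthal angle does not enter
#' (azimuthal symmetry).
#'
#' @param theta bend angle, radians.
#' @param a dimensionless bending constant.
#' @return \eqn{a (1 - \cos\theta)}.
#' @examples
#' bending_energy(pi, 5)  # 2 a = 10
#' @export
bending_energy <- function(theta, a) {
  stopifnot(all(a >= 0))
  a * (1 - cos(theta))
}

#' Forward map from bending constant to Kuhn-to-link ratio
#'
#' The discrete chain with bend energy \eqn{a(1-\cos\theta)} has Kuhn length
#' \eqn{b} satisfying
#' \eqn{b/l = (a - 1 + a\coth a) / (a + 1 - a\coth a)}.
#'
#' @param a bending constant (vectorised).
#' @return the ratio \code{b/l}.
#' @seealso [bending_constant_from_kuhn()] for the inverse.
#' @export
kuhn_ratio_from_a <- function(a) {
  ifelse(a < 1e-6,
         1 + 2 * a / 3,                       # series limit, freely jointed at a = 0
         {
           ac <- a / tanh(a)
           (a - 1 + ac) / (a + 1 - ac)
         })
}

#' Bending constant from the Kuhn length
#'
#' Numerically inverts the relation
#' \eqn{b/l = (a - 1 + a\coth a)/(a + 1 - a\coth a)}
#' for the dimensionless bending constant \code{a} of a chain with Kuhn
#' length \code{b} and link length \code{l}.  The solution is found by
#' bracketed root finding to a relative tolerance of 1e-12; for large
#' \code{b/l} it approaches \code{(b/l + 1)/2}.
#'
#' @param b Kuhn length, nm.
#' @param l link length, nm.
#' @return the bending constant \code{a} (0 when \code{b == l}).
#' @examples
#' a <- bending_constant_from_kuhn(106, 4.6)
#' kuhn_ratio_from_a(a) * 4.6   # recovers 106
#' @export
bending_constant_from_kuhn <- function(b, l) {
  stopifnot(b > 0, l > 0)
  r <- b / l
  if (r < 1) stop("b/l must be >= 1: no non-negative bending constant exists")
  if (abs(r - 1) < 1e-12) return(0)
  upper <- (r + 1) / 2 + 2          # asymptote plus slack
  f <- function(a) kuhn_ratio_from_a(a) - r
  uniroot(f, c(1e-12, upper), tol = 1e-14 * upper)$root
}

#' Draw a bend angle pair from the elastic Boltzmann density
#'
#' The zenith angle has density proportional to
#' \eqn{\exp(-a(1-\cos\theta))\sin\theta}; it is drawn through the exact
#' inverse CDF \eqn{\cos\theta = 1 + \ln(u + (1-u)e^{-2a})/a} with \code{u}
#' uniform on (0, 1].  The azimuth is uniform on [0, 2\eqn{\pi}).  At
#' \code{a = 0} the direction is uniform on the sphere.
#'
#' @param a bending constant.
#' @param n number of draws.
#' @param u optional uniform variates (for reproducing a specific draw);
#'   a matrix with columns \code{u_theta}, \code{u_phi}.
#' @return a list with vectors \code{theta} and \code{phi}.
#' @export
sample_bend <- function(a, n = 1, u = NULL) {
  stopifnot(a >= 0)
  if (is.null(u)) u <- cbind(runif(n), runif(n))
  ut <- pmin(pmax(u[, 1], .Machine$double.xmin), 1)
  ct <- if (a == 0) 2 * ut - 1 else 1 + log(ut + (1 - ut) * exp(-2 * a)) / a
  ct <- pmin(pmax(ct, -1), 1)
  list(theta = acos(ct), phi = 2 * pi * u[, 2])
}

#' Propagate a link frame by a bend
#'
#' Given the orthonormal triad \code{(u, v, t)} of link \code{i-1}, returns
#' the triad of link \code{i} whose direction \code{t'} has zenith
#' \code{theta} and azimuth \code{phi} in the local frame.  The transverse
#' vector \code{u} is parallel transported (rotated by the minimal rotation
#' taking \code{t} to \code{t'}): the chain carries no intrinsic twist about
#' its axis.
#'
#' @param frame list with unit vectors \code{u}, \code{v}, \code{t}.
#' @param theta,phi bend angles, radians.
#' @return a frame list with the same structure.
#' @export
propagate_frame <- function(frame, theta, phi) {
  u <- frame$u; v <- frame$v; t <- frame$t
  tn <- sin(theta) * cos(phi) * u + sin(theta) * sin(phi) * v + cos(theta) * t
  n <- c(t[2] * tn[3] - t[3] * tn[2],
         t[3] * tn[1] - t[1] * tn[3],
         t[1] * tn[2] - t[2] * tn[1])
  s2 <- sum(n^2)
  if (s2 < 1e-28) {
    un <- if (cos(theta) > 0) u else -u
  } else {
    nh <- n / sqrt(s2)
    ca <- cos(theta); sa <- sqrt(s2)
    un <- ca * u + sa * c(nh[2] * u[3] - nh[3] * u[2],
                          nh[3] * u[1] - nh[1] * u[3],
                          nh[1] * u[2] - nh[2] * u[1]) +
      (1 - ca) * sum(nh * u) * nh
  }
  tn <- tn / sqrt(sum(tn^2))
  un <- un - sum(un * tn) * tn
  un <- un / sqrt(sum(un^2))
  vn <- c(tn[2] * un[3] - tn[3] * un[2],
          tn[3] * un[1] - tn[1] * un[3],
          tn[1] * un[2] - tn[2] * un[1])
  list(u = un, v = vn, t = tn)
}

#' Centre of a protrusion bound to a chain link
#'
#' The protrusion sphere touches the chain sphere at link \code{k}: its
#' centre sits at distance \code{w/2 + R_o} from the joint, in the direction
#' obtained by rotating the link's transverse vector \code{u} about the link
#' axis \code{t} by the phase angle \code{gamma} (right-handed rotation).
#'
#' @param r_k joint position (length-3 vector), nm.
#' @param u_hat,t_hat orthonormal link frame vectors.
#' @param gamma phase angle about the chain axis, radians (0 = in phase with
#'   \code{u}, pi = opposite side).
#' @param w chain width, nm.
#' @param R_o protrusion radius, nm.
#' @return the centre position, length-3 vector.
#' @export
protrusion_center <- function(r_k, u_hat, t_hat, gamma, w, R_o) {
  u_rot <- cos(gamma) * u_hat +
    sin(gamma) * c(t_hat[2] * u_hat[3] - t_hat[3] * u_hat[2],
                   t_hat[3] * u_hat[1] - t_hat[1] * u_hat[3],
                   t_hat[1] * u_hat[2] - t_hat[2] * u_hat[1])
  r_k + (w / 2 + R_o) * u_rot
}

#' Hard-wall overlap test for a growing chain
#'
#' Tests whether joint \code{i} overlaps any joint \code{0..(i - delta_i)}
#' (centre distance strictly below \code{w}: joint spheres have diameter
#' \code{w}; touching spheres are allowed) or any listed protrusion (centre
#' distance strictly below \code{w/2 + R_o}; an on-chain protrusion is only
#' tested when its link index \code{k} is below \code{i}).
#'
#' @param joints numeric matrix of joint positions, rows \code{0..i}.
#' @param i index of the joint being tested (1-based into the chain, i.e.
#'   row \code{i + 1} of \code{joints}).
#' @param delta_i neighbour-exclusion window.
#' @param w chain width, nm.
#' @param protrusions list of lists with fields \code{center} (length-3),
#'   \code{radius}, and optionally \code{link} (on-chain index \code{k}).
#' @return \code{TRUE} if any overlap exists.
#' @export
hard_wall_overlap <- function(joints, i, delta_i, w, protrusions = list()) {
  stopifnot(i >= 1, nrow(joints) >= i + 1)
  p <- joints[i + 1, ]
  jmax <- i - delta_i
  if (jmax >= 0) {
    prev <- joints[seq_len(jmax + 1), , drop = FALSE]
    d2 <- (prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 + (prev[, 3] - p[3])^2
    if (any(d2 < w^2 * (1 - 1e-9))) return(TRUE)
  }
  for (pr in protrusions) {
    if (!is.null(pr$link) && pr$link >= i) next
    if (sum((p - pr$center)^2) < (w / 2 + pr$radius)^2 * (1 - 1e-9)) return(TRUE)
  }
  FALSE
}

#' Mean-square end-to-end distance of the phantom discrete chain
#'
#' Closed form for the chain without hard walls:
#' \deqn{\langle R^2\rangle = N l^2\left[\frac{1+c}{1-c}
#'   - \frac{2c(1-c^N)}{N(1-c)^2}\right],\qquad c = \coth a - 1/a,}
#' reducing to \eqn{N l^2} for the freely jointed chain (\code{a = 0}).
#' Used as the independent oracle for the sampler with hard walls disabled.
#'
#' @param N number of links.
#' @param l link length, nm.
#' @param a bending constant.
#' @return mean-square end-to-end distance, nm^2.
#' @export
phantom_chain_r2 <- function(N, l, a) {
  stopifnot(N >= 1)
  if (a <= 0) return(N * l^2)
  c <- 1 / tanh(a) - 1 / a
  N * l^2 * ((1 + c) / (1 - c) - 2 * c * (1 - c^N) / (N * (1 - c)^2))
}

#' Mean bend cosine of the elastic Boltzmann density
#'
#' \eqn{\langle\cos\theta\rangle = \coth a - 1/a} (the Langevin function of
#' \code{a}); 0 for the freely jointed chain.
#'
#' @param a bending constant (vectorised).
#' @return mean cosine of the bend angle.
#' @export
mean_bend_cosine <- function(a) {
  ifelse(a < 1e-8, a / 3, 1 / tanh(pmax(a, 1e-300)) - 1 / pmax(a, 1e-300))
}
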