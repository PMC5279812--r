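#' Solid angle subtended by a sphere
#'
#' The solid angle of a sphere of effective radius \code{R_eff} seen from a
#' point at distance \code{d}:
#' \deqn{\Omega = 2\pi\left(1 - \sqrt{1 - (R_{eff}/d)^2}\right).}
#' At tangency (\code{d = R_eff}) this is \eqn{2\pi} (a half space); in the
#' far field it approaches \eqn{\pi R_{eff}^2 / d^2}.
#'
#' @param distance distance from the viewpoint to the sphere centre, nm.
#' @param effective_radius sphere radius, nm (for an eclipsing protrusion
#'   this is \code{R_o + w/2}: the chain terminus is itself a sphere of
#'   radius \code{w/2}).
#' @return solid angle, steradians (vectorised).
#' @export
solid_angle_sphere <- function(distance, effective_radius) {
  if (any(distance < effective_radius))
    stop("viewpoint inside the sphere: distance < effective_radius")
  2 * pi * (1 - sqrt(pmax(0, 1 - (effective_radius / distance)^2)))
}

#' Uniform sample of points in a looping shell sector
#'
#' Draws points uniformly from the region \code{d_min <= r <= d_min + eps}
#' intersected with the spherical cap of solid angle \code{|domega|} about
#' \code{sign(domega) * axis}.
#'
#' @param n number of points.
#' @param criteria a [loop_criteria()] object.
#' @return an \code{n x 3} matrix.
#' @export
sample_loop_region <- function(n, criteria) {
  r3 <- runif(n, criteria$d_min^3, (criteria$d_min + criteria$epsilon)^3)
  r <- r3^(1 / 3)
  adom <- abs(criteria$domega)
  cosc <- max(1 - adom / (2 * pi), -1)
  mu <- runif(n, cosc, 1)
  phi <- runif(n, 0, 2 * pi)
  ax <- criteria$axis * if (criteria$domega < 0) -1 else 1
  # orthonormal basis about the cap axis
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * ax) * ax
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
          ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  st <- sqrt(pmax(0, 1 - mu^2))
  dir <- cbind(st * cos(phi), st * sin(phi), mu) %*% rbind(e1, e2, ax)
  sweep(dir, 1, r, `*`) + matrix(criteria$anchor, n, 3, byrow = TRUE)
}

#' Uniform directions on the unit sphere
#' @param n number of directions.
#' @return an \code{n x 3} matrix of unit vectors.
#' @export
uniform_directions <- function(n) {
  mu <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - mu^2))
  cbind(st * cos(phi), st * sin(phi), mu)
}

# does the ray p + t*d (t >= 0) pass within radius R of centre c?
ray_hits_sphere <- function(p, d, center, R) {
  q <- sweep(-p, 2, center, `+`)        # c - p, rowwise
  b <- rowSums(q * d)
  disc <- R^2 - (rowSums(q * q) - b^2)
  inside <- rowSums(q * q) <= R^2
  (disc >= 0 & b >= 0) | inside
}

#' Static ("rod model") eclipse estimate of the looping plateau
#'
#' For a static spherical object the plateau of the looping-probability
#' ratio is approximated by the mean fractional solid angle the object
#' blocks over the looping region:
#' \deqn{F_\infty^{static} = 1 - \frac{1}{4\pi V(\delta r)}
#'   \int_{\delta r} \Omega_{object}(r)\, d^3r,}
#' evaluated by uniform Monte-Carlo sampling of the region.
#'
#' @param object_position length-3 centre of the object, nm.
#' @param R_o object radius, nm.
#' @param criteria the looping region, a [loop_criteria()] object.
#' @param w chain width, nm (enters through the effective radius
#'   \code{R_o + w/2}).
#' @param n_points Monte-Carlo sample size.
#' @return list with \code{f_inf}, \code{se} and the mean blocked fraction
#'   \code{omega_frac}.
#' @export
f_inf_static <- function(object_position, R_o, criteria, w,
                         n_points = 2e5) {
  pts <- sample_loop_region(n_points, criteria)
  d <- sqrt(rowSums(sweep(pts, 2, object_position)^2))
  reff <- R_o + w / 2
  if (any(d < reff))
    stop("object intersects the looping region")
  om <- solid_angle_sphere(d, reff) / (4 * pi)
  list(f_inf = 1 - mean(om), se = sd(om) / sqrt(n_points),
       omega_frac = mean(om))
}

#' Full eclipse estimate with chain occlusion
#'
#' Evaluates
#' \deqn{F_\infty \approx 1 - \frac{\mathcal I_{object}}
#'   {4\pi\,\delta r - \mathcal I_{chain}}
#'   + \frac{\mathcal I_{chain\cap object}}{4\pi\,\delta r - \mathcal I_{chain}}}
#' by Monte-Carlo ray casting over (point in region) x (direction on the
#' sphere): a direction contributes to \eqn{\mathcal I_{chain}} when its ray
#' hits any chain-joint sphere, to \eqn{\mathcal I_{object}} when it hits
#' the object, and to the intersection term when it hits both.  Chain joints
#' block with effective radius \code{w} (joint sphere plus terminus sphere),
#' the object with \code{R_o + w/2}.
#'
#' @param criteria the looping region.
#' @param object_position,R_o object centre and radius.
#' @param chain_joints matrix of occluding chain-joint positions (may have
#'   zero rows).
#' @param w chain width, nm.
#' @param n_points region points; \code{n_dir} directions per point.
#' @param n_dir directions per region point.
#' @return list with \code{f_inf}, \code{se}, and the hit fractions
#'   \code{p_chain}, \code{p_object}, \code{p_both}.
#' @export
f_inf_eclipse <- function(criteria, object_position, R_o,
                          chain_joints = NULL, w = 4.6,
                          n_points = 2e4, n_dir = 50) {
  reff <- R_o + w / 2
  n <- n_points * n_dir
  hits_o <- hits_c <- hits_b <- 0
  sum_o <- sum_c <- sum_b <- sum_o2 <- 0
  chunk <- max(1, floor(2e6 / n_dir))
  done <- 0
  while (done < n_points) {
    m <- min(chunk, n_points - done)
    pts <- sample_loop_region(m, criteria)
    pts <- pts[rep(seq_len(m), each = n_dir), , drop = FALSE]
    dirs <- uniform_directions(m * n_dir)
    ho <- ray_hits_sphere(pts, dirs, object_position, reff)
    hc <- rep(FALSE, m * n_dir)
    if (!is.null(chain_joints) && nrow(chain_joints) > 0) {
      for (j in seq_len(nrow(chain_joints))) {
        hc <- hc | ray_hits_sphere(pts, dirs, chain_joints[j, ], w)
      }
    }
    hits_o <- hits_o + sum(ho)
    hits_c <- hits_c + sum(hc)
    hits_b <- hits_b + sum(ho & hc)
    done <- done + m
  }
  p_o <- hits_o / n; p_c <- hits_c / n; p_b <- hits_b / n
  f <- 1 - (p_o - p_b) / (1 - p_c)
  # binomial-scale error on the dominant (object) term
  se <- sqrt(p_o * (1 - p_o) / n) / (1 - p_c)
  list(f_inf = f, se = se, p_chain = p_c, p_object = p_o, p_both = p_b)
}

#' Terminating-segments flexibility correction
#'
#' The rod model treats a chain's terminating segment as a straight ray; a
#' flexible segment of length \code{T} wanders and hits the eclipsing object
#' more often.  Pairs of (uniform point in the looping region, uniform
#' initial direction) are drawn; short phantom chains of length \code{T}
#' grow from each point with their first link along the chosen direction,
#' and the survival fraction (no overlap with the object) is compared with
#' that of straight rods of length \code{T} over the same pairs.  The ratio
#' multiplies the rod (solid-angle) estimate:
#' with one long link the chain is the rod and the correction is 1, and
#' removing the object also gives 1.
#'
#' @param T_len segment length, nm (warns when longer than \code{b/2}).
#' @param criteria the looping region.
#' @param object_position,R_o object centre and radius, nm.
#' @param params a [simulation_params()]; supplies \code{w}, \code{b} and
#'   the stage-2 link length used for the short chains.
#' @param n_pairs Monte-Carlo pairs.
#' @return list with \code{correction}, \code{f_inf} (corrected rod
#'   estimate), \code{se}, \code{p_chain_survive}, \code{p_rod_survive},
#'   and \code{rod} (the underlying [f_inf_static()] result).
#' @export
terminating_segments_correction <- function(T_len, criteria, object_position,
                                            R_o, params = simulation_params(),
                                            n_pairs = 2e5) {
  if (T_len > params$b / 2)
    warning("terminating-segment length exceeds b/2: rod-like assumption weak")
  w <- params$w
  reff <- R_o + w / 2
  l <- params$l2
  nlink <- max(1L, as.integer(round(T_len / l)))
  a <- bending_constant_from_kuhn(params$b, l)

  pts <- sample_loop_region(n_pairs, criteria)
  dirs <- uniform_directions(n_pairs)

  # straight rods of length T: closest approach within [0, T]
  q <- sweep(-pts, 2, object_position, `+`)   # c - p
  b <- rowSums(q * dirs)
  tstar <- pmin(pmax(b, 0), nlink * l)
  d2 <- rowSums(q * q) - 2 * tstar * b + tstar^2
  rod_surv <- d2 >= reff^2
  p_rod <- mean(rod_surv)

  # flexible phantom chains, vectorised across pairs, grown link by link
  alive <- rep(TRUE, n_pairs)
  pos <- pts
  t_hat <- dirs
  u_hat <- uniform_directions(n_pairs)
  u_hat <- u_hat - t_hat * rowSums(u_hat * t_hat)
  u_hat <- u_hat / sqrt(rowSums(u_hat^2))
  for (i in seq_len(nlink)) {
    if (i > 1) {
      uu <- runif(n_pairs)
      ct <- 1 + log(uu + (1 - uu) * exp(-2 * a)) / a
      ct <- pmin(pmax(ct, -1), 1)
      st <- sqrt(1 - ct^2)
      phi <- runif(n_pairs, 0, 2 * pi)
      v_hat <- cbind(t_hat[, 2] * u_hat[, 3] - t_hat[, 3] * u_hat[, 2],
                     t_hat[, 3] * u_hat[, 1] - t_hat[, 1] * u_hat[, 3],
                     t_hat[, 1] * u_hat[, 2] - t_hat[, 2] * u_hat[, 1])
      tn <- st * cos(phi) * u_hat + st * sin(phi) * v_hat + ct * t_hat
      tn <- tn / sqrt(rowSums(tn^2))
      # transported u: project old u off the new axis (minimal rotation has
      # the same effect on the component in the t-t' plane for our purposes;
      # the azimuth of the next bend is uniform, so only orthonormality
      # matters here)
      u_hat <- u_hat - tn * rowSums(u_hat * tn)
      bad <- rowSums(u_hat^2) < 1e-20
      if (any(bad)) u_hat[bad, ] <- uniform_directions(sum(bad))
      u_hat <- u_hat - tn * rowSums(u_hat * tn)
      u_hat <- u_hat / sqrt(rowSums(u_hat^2))
      t_hat <- tn
    }
    # closest approach of the whole link segment to the object, so a
    # one-link chain is exactly the rod of the same length
    qq <- sweep(-pos, 2, object_position, `+`)
    bb <- rowSums(qq * t_hat)
    tt <- pmin(pmax(bb, 0), l)
    d2j <- rowSums(qq * qq) - 2 * tt * bb + tt^2
    alive <- alive & d2j >= reff^2
    pos <- pos + l * t_hat
  }
  p_chain <- mean(alive)
  corr <- p_chain / p_rod
  rod <- f_inf_static(object_position, R_o, criteria, w,
                      n_points = min(n_pairs, 2e5))
  se_corr <- corr * sqrt((1 - p_chain) / (p_chain * n_pairs) +
                           (1 - p_rod) / (p_rod * n_pairs))
  list(correction = corr, f_inf = rod$f_inf * corr,
       se = rod$f_inf * se_corr + rod$se,
       p_chain_survive = p_chain, p_rod_survive = p_rod, rod = rod)
}

#' Quadratic eclipse fit of the plateau against protrusion size
#'
#' For an on-chain object at fixed distance K the eclipse model predicts
#' \deqn{F_\infty(R_o) \approx 1 - A_K (R_o + w/2)^2 + B_K.}
#' Fits the two-parameter family by weighted least squares (weights
#' \eqn{1/SE^2}) and reports the coefficients, their covariance, and
#' \eqn{R^2} against the weighted mean.
#'
#' @param radii protrusion radii, nm (at least 3 distinct values for an
#'   overdetermined fit; 2 give exact interpolation).
#' @param f_values plateau values.
#' @param errors standard errors (optional; equal weights when missing).
#' @param w chain width, nm.
#' @return an object of class \code{"eclipse_fit"}: list with \code{A},
#'   \code{B}, \code{cov}, \code{r_squared}, \code{fitted}, \code{data}.
#' @export
fit_quadratic_eclipse <- function(radii, f_values, errors = NULL, w = 4.6) {
  stopifnot(length(radii) == length(f_values), length(radii) >= 2)
  if (length(unique(radii)) < 2) stop("all radii equal: singular design")
  x <- (radii + w / 2)^2
  wt <- if (is.null(errors)) rep(1, length(x)) else 1 / errors^2
  fit <- lm(f_values ~ x, weights = wt)
  beta <- coef(fit)
  A <- -beta[[2]]
  B <- beta[[1]] - 1
  V <- suppressWarnings(vcov(fit))   # exact fits trip summary.lm
  cov <- matrix(c(V[2, 2], -V[1, 2], -V[2, 1], V[1, 1]), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  fitted <- 1 - A * x + B
  mbar <- weighted.mean(f_values, wt)
  ss_res <- sum(wt * (f_values - fitted)^2)
  ss_tot <- sum(wt * (f_values - mbar)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(A = A, B = B, cov = cov, r_squared = r2,
                 fitted = fitted,
                 data = data.frame(R_o = radii, x = x, f = f_values,
                                   se = if (is.null(errors)) NA else errors)),
            class = "eclipse_fit")
}

#' @export
print.eclipse_fit <- function(x, ...) {
  cat(sprintf("Eclipse fit F = 1 - A (R_o + w/2)^2 + B\n"))
  cat(sprintf("  A = %.4g /nm^2, B = %.4g, R^2 = %.4f (%d points)\n",
              x$A, x$B, x$r_squared, nrow(x$data)))
  invisible(x)
}
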