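#' Looping probability per recorded length
#'
#' The weighted fraction of looped configurations,
#' \eqn{P_{looped}(L) = \sum_j f_{looped}(x_j) w_j / Z(L)}, with a
#' weighted-binomial standard error
#' \eqn{\sqrt{p(1-p)/n_{eff}}}, \eqn{n_{eff} = (\sum w)^2 / \sum w^2}
#' (equal to \code{Z} under the unit-weight survival scheme).
#'
#' @param ensemble a [generate_ensemble()] result.
#' @param ensemble_index which ensemble (1 = baseline).
#' @param group which criterion group.
#' @return a data frame of class \code{"f_curve"} with columns
#'   \code{length_nm}, \code{length_bp}, \code{p}, \code{se}, \code{n_eff}.
#' @export
looping_probability <- function(ensemble, ensemble_index = 1, group = 1) {
  Z <- ensemble$Z[ensemble_index, ]
  if (all(Z == 0)) stop("Z = 0: looping probability undefined")
  W <- ensemble$W[, group, ensemble_index]
  p <- ifelse(Z > 0, W / Z, NA_real_)
  se <- ifelse(Z > 0, sqrt(pmax(p * (1 - p), 0) / pmax(Z, 1)), NA_real_)
  structure(data.frame(length_nm = ensemble$lengths_nm,
                       length_bp = ensemble$lengths_bp,
                       p = p, se = se, n_eff = Z),
            class = c("f_curve", "data.frame"))
}

#' Looping-probability ratio F(L)
#'
#' Pointwise ratio of two looping-probability curves,
#' \eqn{F(L) = P^{object}(L) / P^{baseline}(L)}, with first-order
#' independent-ratio error propagation.  Both curves must share the same
#' length grid; used for object/baseline ensembles generated with
#' independent seeds.  For the paired (common-chain) estimator see
#' [paired_f_curve()].
#'
#' @param p_object,p_baseline [looping_probability()] curves.
#' @return a data frame with columns \code{length_nm}, \code{length_bp},
#'   \code{f}, \code{se}.
#' @export
f_ratio <- function(p_object, p_baseline) {
  if (!isTRUE(all.equal(p_object$length_nm, p_baseline$length_nm)))
    stop("length grids differ")
  if (any(p_baseline$p == 0, na.rm = TRUE))
    stop("baseline probability is zero at some lengths")
  f <- p_object$p / p_baseline$p
  se <- f * sqrt((p_object$se / p_object$p)^2 +
                   (p_baseline$se / p_baseline$p)^2)
  structure(data.frame(length_nm = p_object$length_nm,
                       length_bp = p_object$length_bp,
                       f = f, se = se),
            class = c("f_curve", "data.frame"))
}

#' Paired F(L) from a virtual-condition subset
#'
#' When the object ensemble is a subset selection of the baseline chains
#' (virtual conditions, shared per-chain streams), \eqn{F(L)} is estimated
#' from the joint counts of one run: with \eqn{n} baseline-alive chains,
#' \eqn{A} of which avoid the object and \eqn{a} of which avoid it and loop,
#' and \eqn{\ell} looped baseline chains,
#' \eqn{F = (a/A) / (\ell/n)}.  The standard error comes from the
#' multinomial delta method; noise common to numerator and denominator
#' cancels, so an object that affects nothing gives \eqn{F \equiv 1} with
#' zero variance.
#'
#' @param ensemble a [generate_ensemble()] result with virtual conditions.
#' @param ensemble_index index of the subset ensemble.
#' @param baseline_index index of the baseline ensemble (default 1).
#' @param group criterion group.
#' @return a data frame with columns \code{length_nm}, \code{length_bp},
#'   \code{f}, \code{se}.
#' @export
paired_f_curve <- function(ensemble, ensemble_index, baseline_index = 1,
                           group = 1) {
  n <- ensemble$Z[baseline_index, ]
  A <- ensemble$Z[ensemble_index, ]
  l <- ensemble$W[, group, baseline_index]
  a <- ensemble$W[, group, ensemble_index]
  f <- se <- rep(NA_real_, length(n))
  ok <- n > 0 & A > 0 & l > 0
  f[ok] <- (a[ok] / A[ok]) / (l[ok] / n[ok])
  # multinomial cells over baseline-alive chains:
  # x1 = avoid & loop, x2 = avoid & !loop, x3 = !avoid & loop, x4 = rest
  for (g in which(ok)) {
    x1 <- a[g]; x2 <- A[g] - a[g]; x3 <- l[g] - a[g]
    x4 <- n[g] - x1 - x2 - x3
    p <- c(x1, x2, x3, x4) / n[g]
    if (x1 == 0) { se[g] <- NA_real_; next }
    cc <- c(1 / x1 - 1 / A[g] - 1 / l[g], -1 / A[g], -1 / l[g], 0) * n[g]
    v <- sum(p * cc^2) - sum(p * cc)^2
    se[g] <- f[g] * sqrt(max(v, 0) / n[g])
  }
  structure(data.frame(length_nm = ensemble$lengths_nm,
                       length_bp = ensemble$lengths_bp,
                       f = f, se = se),
            class = c("f_curve", "data.frame"))
}

#' Plateau of the looping-probability ratio
#'
#' \eqn{F_\infty} is the average of \eqn{F(L)} over a trailing window of
#' lengths where the curve is flat; its half-width is 1.96 times the
#' standard error of the window points.  A trailing linear fit provides a
#' flatness diagnostic: a slope inconsistent with zero at 2 SE downgrades to
#' a warning.
#'
#' @param curve an F-curve data frame (columns \code{length_nm}, \code{f},
#'   optionally \code{se}).
#' @param window number of trailing points; default: the smaller of 480 and
#'   the number of points with \code{length_nm > 5 * b}, falling back to the
#'   trailing half of the curve.
#' @param b Kuhn length used by the default window rule, nm.
#' @return a list with \code{f_inf}, \code{halfwidth} (1.96 SE; \code{NaN}
#'   for a single point), \code{window}, \code{flat} (logical diagnostic)
#'   and \code{slope_z} (trailing slope in SE units).
#' @export
estimate_f_infinity <- function(curve, window = NULL, b = 106) {
  f <- curve$f
  keep <- which(is.finite(f))
  if (length(keep) == 0) stop("no finite F values")
  if (is.null(window)) {
    tailpts <- sum(curve$length_nm[keep] > 5 * b)
    window <- if (tailpts >= 3) min(480L, tailpts) else
      max(1L, floor(length(keep) / 2))
  }
  if (window > length(keep)) stop("window larger than the curve")
  idx <- keep[seq(length(keep) - window + 1, length(keep))]
  fi <- mean(f[idx])
  se <- if (window > 1) sd(f[idx]) / sqrt(window) else NaN
  flat <- TRUE; slope_z <- 0
  if (window >= 3) {
    fit <- lm(f[idx] ~ curve$length_nm[idx])
    sl <- suppressWarnings(summary(fit))$coefficients  # constant curves are fine
    if (nrow(sl) == 2 && is.finite(sl[2, 2]) && sl[2, 2] > 0) {
      slope_z <- sl[2, 1] / sl[2, 2]
      flat <- abs(slope_z) <= 2
    }
    if (!flat)
      warning("plateau flatness check failed: trailing slope is ",
              signif(slope_z, 3), " SE from zero")
  }
  list(f_inf = fi, halfwidth = 1.96 * se, window = window,
       flat = flat, slope_z = slope_z)
}

# ---- pooled window statistics ---------------------------------------------

#' Delta-method statistics over pooled length windows
#'
#' [generate_ensemble()] accumulates, for every requested window, the
#' per-chain sums of looped counts (\code{sv}) and alive grid points
#' (\code{a}) of each window item, together with their full cross moments.
#' \code{window_stat} evaluates an arbitrary smooth statistic of the item
#' means and propagates the (correlated) Monte-Carlo error by the delta
#' method with a numerical gradient.  Correlation between items sharing
#' chains (paired subsets, overlapping windows) is handled exactly through
#' the cross moments.
#'
#' The statistic receives a numeric vector \code{c(sv1, a1, sv2, a2, ...)}
#' of per-chain means.  The pooled looping probability of item \code{i} is
#' \code{sv_i / a_i}; ratios of such terms give paired \eqn{F} values.
#'
#' @param ensemble a [generate_ensemble()] result with windows.
#' @param window window index.
#' @param stat function of the mean vector returning a scalar.
#' @return list with \code{value}, \code{se}, \code{n}.
#' @export
window_stat <- function(ensemble, window, stat) {
  wm <- ensemble$window_moments[[window]]
  n <- wm$n
  mu <- wm$S / n
  Sigma <- (wm$M / n - tcrossprod(mu)) / n   # covariance of the means
  v0 <- stat(mu)
  k <- length(mu)
  gr <- numeric(k)
  for (i in seq_len(k)) {
    h <- max(abs(mu[i]) * 1e-6, 1e-10)
    up <- mu; up[i] <- up[i] + h
    dn <- mu; dn[i] <- dn[i] - h
    gr[i] <- (stat(up) - stat(dn)) / (2 * h)
  }
  list(value = v0, se = sqrt(max(drop(t(gr) %*% Sigma %*% gr), 0)), n = n)
}

#' Pooled looping probability of a window item
#'
#' @param ensemble,window as in [window_stat()].
#' @param item item index within the window.
#' @return list with \code{value}, \code{se}, \code{n}.
#' @export
window_prob <- function(ensemble, window, item = 1) {
  i <- 2 * (item - 1)
  window_stat(ensemble, window, function(m) m[i + 1] / m[i + 2])
}

#' Pooled paired F between two window items
#'
#' \eqn{F = (sv_1/a_1) / (sv_2/a_2)} evaluated with full covariance, the
#' pooled analogue of [paired_f_curve()] (item 1 = object subset, item 2 =
#' baseline).
#'
#' @param ensemble,window as in [window_stat()].
#' @param num,den item indices of the numerator and denominator.
#' @return list with \code{value}, \code{se}, \code{n}.
#' @export
window_f <- function(ensemble, window, num = 1, den = 2) {
  i <- 2 * (num - 1); j <- 2 * (den - 1)
  window_stat(ensemble, window,
              function(m) (m[i + 1] / m[i + 2]) / (m[j + 1] / m[j + 2]))
}

#' Multi-activator looping probability
#'
#' Total looping probability of an enhancer state: the sum over activators
#' of the activator-anchored looping probabilities (overlapping acceptance
#' shells are not deduplicated).  The ensemble must have been generated with
#' activator-anchored criteria collected in one group, whose group value is
#' that sum.  A diagnostic reports the weight fraction of chains looped with
#' respect to two or more activators simultaneously (the double-counted
#' part).
#'
#' @param ensemble a [generate_ensemble()] result.
#' @param ensemble_index which ensemble.
#' @param group index of the activator group.
#' @return an \code{f_curve} data frame with an extra column
#'   \code{dup_fraction}.
#' @export
eve_looping_probability <- function(ensemble, ensemble_index = 1, group = 1) {
  Z <- ensemble$Z[ensemble_index, ]
  if (all(Z == 0)) stop("Z = 0: looping probability undefined")
  W <- ensemble$W[, group, ensemble_index]
  D <- ensemble$dup[, group, ensemble_index]
  p <- ifelse(Z > 0, W / Z, NA_real_)
  se <- ifelse(Z > 0, sqrt(pmax(p * (1 - p), 0) / pmax(Z, 1)), NA_real_)
  structure(data.frame(length_nm = ensemble$lengths_nm,
                       length_bp = ensemble$lengths_bp,
                       p = p, se = se, n_eff = Z,
                       dup_fraction = ifelse(W > 0, D / W, 0)),
            class = c("f_curve", "data.frame"))
}
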