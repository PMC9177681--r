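# Circular frame used throughout: angles in degrees in (-180, 180], with the
# 0 degree reference at the bottom of the y-axis (both control forces point
# downward, so 0 is the balance point) and anticlockwise positive. A
# direction theta corresponds to the Cartesian unit vector
# (sin theta, -cos theta).

.wrap180 <- function(deg) {
  w <- ((deg + 180) %% 360) - 180
  w[w == -180] <- 180                  # convention: half-open (-180, 180]
  w
}

#' Imbalance angle of predictive and reactive coupling
#'
#' Projects the two top-down coupling parameters onto orthogonal axes of a
#' circular space and returns the direction of their resultant force.
#' Negative predictive (belief-driven) coupling projects onto the +45
#' degree direction and positive onto -135; negative reactive (PE-driven)
#' coupling onto -45 and positive onto +135. The resultant's direction is
#' measured from the 0-degree reference (bottom of the y-axis,
#' anticlockwise positive) with the two-argument arctangent, so a positive
#' angle means predictive-dominant control and 0 means perfect balance.
#'
#' @param predictive,reactive coupling parameters (vectors of equal
#'   length); inhibitory modulation is negative.
#' @return imbalance angles in degrees in (-180, 180]; `NA` (with a
#'   warning) where the resultant is the zero vector.
#' @examples
#' resultant_angle(-1, -1)    # 0: perfectly balanced
#' resultant_angle(-1, 0)     # +45: purely predictive
#' @export
resultant_angle <- function(predictive, reactive) {
  stopifnot(length(predictive) == length(reactive))
  if (anyNA(predictive) || anyNA(reactive) ||
      !all(is.finite(predictive), is.finite(reactive)))
    stop("coupling parameters must be finite")
  s <- sqrt(2) / 2
  fx <- s * (reactive - predictive)
  fy <- s * (predictive + reactive)
  th <- atan2(fx, -fy) * 180 / pi
  zero <- fx == 0 & fy == 0
  if (any(zero)) {
    warning(sum(zero), " zero resultant(s): angle undefined")
    th[zero] <- NA_real_
  }
  th
}

#' Circular mean direction
#'
#' Mean direction of a sample of angles via the resultant of unit vectors
#' (the arithmetic mean is meaningless on the circle: the mean of +170 and
#' -170 degrees is 180, not 0).
#'
#' @param angles angles in degrees; `NA`s are dropped.
#' @return mean direction in degrees in (-180, 180], with the mean
#'   resultant length attached as attribute `rbar`.
#' @export
circular_mean <- function(angles) {
  a <- angles[!is.na(angles)] * pi / 180
  if (!length(a)) return(NA_real_)
  s <- mean(sin(a))
  c <- mean(cos(a))
  structure(.wrap180(atan2(s, c) * 180 / pi), rbar = sqrt(s^2 + c^2))
}

#' Bootstrap confidence interval of the circular mean
#'
#' Percentile bootstrap of the group circular mean. Bootstrap means are
#' expressed as wrapped deviations from the observed mean before taking
#' percentiles, so the interval behaves correctly across the +/-180 degree
#' discontinuity. A warning is issued when the mean resultant length is
#' close to zero (no meaningful mean direction).
#'
#' @param angles angles in degrees (>= 3 non-missing values).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list with `mean`, `ci` (length 2, degrees) and `rbar`.
#' @export
circular_mean_ci <- function(angles, n_boot = 2000, conf = 0.95,
                             seed = NULL) {
  a <- angles[!is.na(angles)]
  if (length(a) < 3) stop("need at least 3 angles")
  .check_seed(seed)
  m <- circular_mean(a)
  if (attr(m, "rbar") < 0.05)
    warning("mean resultant length near zero; CI unstable")
  dev <- vapply(seq_len(n_boot), function(b) {
    .wrap180(as.numeric(circular_mean(a[sample.int(length(a),
                                                   replace = TRUE)])) - m)
  }, numeric(1))
  q <- quantile(dev, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(mean = as.numeric(m), ci = .wrap180(as.numeric(m) + q),
       rbar = attr(m, "rbar"))
}

#' Watson's two-sample U2 test for circular data
#'
#' Nonparametric comparison of two samples of angles (the circular analogue
#' of the two-sample t test). The U2 statistic integrates the squared
#' difference of the two empirical circular distribution functions in a
#' rotation-invariant way; the p-value comes from a seeded permutation of
#' the group labels.
#'
#' @param a,b angle samples in degrees (each >= 8 values).
#' @param n_perm permutation count for the p-value.
#' @param seed integer seed.
#' @return list with `u2`, `p`, and the sample sizes.
#' @export
watson_two_sample <- function(a, b, n_perm = 1e4, seed = NULL) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 8 || length(b) < 8)
    stop("each sample needs at least 8 angles")
  .check_seed(seed)
  u2_stat <- function(a, b) {
    n <- length(a); m <- length(b); N <- n + m
    x <- c(a, b) %% 360
    lab <- c(rep(1L, n), rep(0L, m))[order(x)]
    cumA <- cumsum(lab) / n
    cumB <- cumsum(1L - lab) / m
    d <- cumA - cumB
    (n * m) / N^2 * (sum(d^2) - sum(d)^2 / N)
  }
  obs <- u2_stat(a, b)
  pool <- c(a, b)
  n <- length(a)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), n)
    u2_stat(pool[idx], pool[-idx])
  }, numeric(1))
  list(u2 = obs, p = (1 + sum(perm >= obs)) / (n_perm + 1),
       n = c(length(a), length(b)))
}
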