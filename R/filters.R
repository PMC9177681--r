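#' Belief-update filters for binary intrusion sequences
#'
#' Runs one of the three perceptual models over a binary outcome sequence
#' and returns the trial-by-trial belief trajectory. All filters predict the
#' probability that the upcoming cue triggers an intrusion *before* the
#' outcome is seen; the first prediction of every stream is 0.5.
#'
#' * `rw_filter()` - Rescorla-Wagner: fixed learning rate `alpha`,
#'   `V(t) = V(t-1) + alpha * (y(t) - V(t-1))`; the prediction for trial t
#'   is `V(t-1)`.
#' * `kf_filter()` - Kalman filter on the outcome level: gain recursion
#'   `K(t) = (K(t-1) + pi*omega) / (K(t-1) + pi*omega + 1)` with belief
#'   reliability `pi` and process uncertainty `omega`; the belief is moved
#'   by the gain-weighted prediction error of the previous trial.
#' * `hgf2_filter()` - two-level hierarchical Gaussian filter for binary
#'   outcomes: the first level is Bernoulli with prediction
#'   `muhat1 = sigmoid(mu2)`, the second level a Gaussian random walk with
#'   step variance `exp(omega)`; updates are prediction errors weighted by
#'   second-level uncertainty (`psi = 1/pi2`).
#'
#' The optional `items` argument switches from the *state* source (one
#' filter over the whole sequence) to the *item* source: one independent
#' filter per item, where the stream time index is the item's repetition
#' count, with results scattered back into chronological order.
#'
#' @param y integer vector of binary outcomes (1 = intrusion).
#' @param alpha RW learning rate in `[0, 1]`.
#' @param v0,mu0 initial prediction (default 0.5).
#' @param pi,omega KF belief reliability and process uncertainty (both > 0);
#'   for `hgf2_filter()`, `omega` is the log-volatility step size (native
#'   scale, may be negative).
#' @param k0 initial Kalman gain in `[0, 1]`.
#' @param mu2_0,sigma2_0 initial second-level mean and variance of the HGF.
#' @param items optional item labels, one per trial; when given, each item
#'   is filtered independently.
#' @return a data frame, one row per trial in input order, with at least
#'   `muhat` (the prediction in (0,1)) and `pe` (`y - muhat`); the HGF adds
#'   `mu2`, `sigma2`, `pihat1`, `psi`, `delta`, the KF adds `gain`, the RW
#'   adds `v`.
#' @examples
#' rw_filter(c(1, 1, 0), alpha = 0.5)$v        # 0.75 0.875 0.4375
#' hgf2_filter(rbinom(20, 1, 0.5), omega = -3)$muhat
#' @name filters
NULL

.items_to_grp <- function(y, items) {
  if (is.null(items)) return(list(grp = rep(1L, length(y)), ngrp = 1L))
  stopifnot(length(items) == length(y))
  f <- factor(items, levels = unique(items))
  list(grp = as.integer(f), ngrp = nlevels(f))
}

.check_binary <- function(y) {
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("outcomes must be binary (0/1)")
  y
}

#' @rdname filters
#' @export
rw_filter <- function(y, alpha, v0 = 0.5, items = NULL) {
  y <- .check_binary(y)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  g <- .items_to_grp(y, items)
  m <- rw_filter_cpp(y, g$grp, g$ngrp, alpha, v0)
  out <- data.frame(muhat = m[, "muhat"], v = m[, "v"])
  out$pe <- y - out$muhat
  out
}

#' @rdname filters
#' @export
kf_filter <- function(y, pi, omega, k0 = 0, mu0 = 0.5, items = NULL) {
  y <- .check_binary(y)
  if (!is.finite(pi) || pi <= 0 || !is.finite(omega) || omega <= 0)
    stop("pi and omega must be positive")
  if (k0 < 0 || k0 > 1) stop("initial gain must lie in [0, 1]")
  g <- .items_to_grp(y, items)
  m <- kf_filter_cpp(y, g$grp, g$ngrp, pi, omega, k0, mu0)
  out <- data.frame(muhat = m[, "muhat"], gain = m[, "gain"])
  out$pe <- y - out$muhat
  out
}

#' @rdname filters
#' @export
hgf2_filter <- function(y, omega, mu2_0 = 0, sigma2_0 = 1, items = NULL) {
  y <- .check_binary(y)
  if (!is.finite(omega)) stop("omega must be finite")
  if (!is.finite(sigma2_0) || sigma2_0 <= 0)
    stop("initial second-level variance must be positive")
  g <- .items_to_grp(y, items)
  m <- hgf2_filter_cpp(y, g$grp, g$ngrp, omega, mu2_0, sigma2_0)
  out <- as.data.frame(m)
  names(out)[1] <- "muhat"
  out$pe <- y - out$muhat
  out
}

.run_filter <- function(model, y, params, items = NULL) {
  switch(model,
         rw = rw_filter(y, alpha = params$alpha,
                        v0 = params$v0 %||% 0.5, items = items),
         kf = kf_filter(y, pi = params$pi, omega = params$omega,
                        k0 = params$k0 %||% 0, mu0 = params$mu0 %||% 0.5,
                        items = items),
         hgf2 = hgf2_filter(y, omega = params$omega,
                            mu2_0 = params$mu2_0 %||% 0,
                            sigma2_0 = params$sigma2_0 %||% 1, items = items),
         stop("unknown model: ", model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Item-wise belief trajectories
#'
#' Runs the chosen filter independently for every item's repetition history
#' and reassembles the per-item beliefs back into chronological trial order.
#' Items with fewer than two repetitions carry too little history to form an
#' item belief and are excluded with a warning.
#'
#' @param y binary outcome vector in chronological order.
#' @param items item label per trial.
#' @param model `"rw"`, `"kf"` or `"hgf2"`.
#' @param params named list of perceptual parameters for the filter.
#' @return the filter's trajectory data frame with extra columns `item`,
#'   `rep` (the within-item repetition index) and `trial` (original
#'   chronological position; rows of excluded items are dropped).
#' @export
item_trajectories <- function(y, items, model, params) {
  y <- .check_binary(y)
  stopifnot(length(items) == length(y))
  reps <- stats::ave(seq_along(y), items, FUN = seq_along)
  counts <- table(items)
  bad <- names(counts)[counts < 2]
  keep <- !(items %in% bad)
  if (length(bad))
    warning("excluding ", length(bad),
            " item(s) with fewer than 2 repetitions")
  out <- .run_filter(model, y[keep], params, items = items[keep])
  out$item <- items[keep]
  out$rep <- reps[keep]
  out$trial <- which(keep)
  out
}

#' Precision-weighted combination of state and item beliefs
#'
#' Fuses the state-source and item-source belief trajectories into the
#' combined source. For the HGF the two beliefs are averaged weighted by
#' their first-level Bernoulli prediction precisions
#' `pihat = 1 / (muhat * (1 - muhat))`; for the RW and KF models, which
#' carry no belief-level precision, the plain arithmetic mean is used. An
#' item belief only exists from the item's second repetition onward, so
#' earlier trials carry the state belief unchanged.
#'
#' @param state_traj trajectory data frame from the state-source filter.
#' @param item_traj trajectory data frame from [item_trajectories()] (must
#'   carry `rep` and `trial` columns).
#' @param model `"rw"`, `"kf"` or `"hgf2"`; decides the weighting rule.
#' @return data frame with columns `muhat` (combined belief), `muhat_state`,
#'   `muhat_item` (NA before an item's second repetition), `rep`, aligned
#'   with the state trajectory's trial order.
#' @export
combine_sources <- function(state_traj, item_traj, model) {
  n <- nrow(state_traj)
  ms <- .clamp01(state_traj$muhat)
  mi_full <- rep(NA_real_, n)
  rep_full <- rep(NA_integer_, n)
  mi_full[item_traj$trial] <- .clamp01(item_traj$muhat)
  rep_full[item_traj$trial] <- item_traj$rep
  use <- !is.na(rep_full) & rep_full >= 2L
  mc <- ms
  if (model == "hgf2") {
    ps <- 1 / (ms * (1 - ms))
    pi_ <- 1 / (mi_full * (1 - mi_full))
    mc[use] <- (ms[use] * ps[use] + mi_full[use] * pi_[use]) /
      (ps[use] + pi_[use])
  } else {
    mc[use] <- (ms[use] + mi_full[use]) / 2
  }
  data.frame(muhat = mc, muhat_state = state_traj$muhat,
             muhat_item = mi_full, rep = rep_full)
}

#' Belief trajectory for any model and belief source
#'
#' Convenience front-end running the perceptual filter under the requested
#' source. `"state"` filters the whole sequence, `"item"` filters each
#' item's history independently, `"combined"` precision-weights the two
#' (state beliefs filling in before an item's second repetition).
#'
#' @inheritParams item_trajectories
#' @param source `"state"`, `"item"` or `"combined"`.
#' @return trajectory data frame with a `muhat` column aligned with `y`
#'   (item source: rows of excluded items are dropped, see
#'   [item_trajectories()]).
#' @export
filter_beliefs <- function(y, model = c("hgf2", "kf", "rw"),
                           source = c("state", "item", "combined"),
                           params = list(), items = NULL) {
  model <- match.arg(model)
  source <- match.arg(source)
  if (source != "state" && is.null(items))
    stop("item labels are required for the ", source, " source")
  switch(source,
         state = .run_filter(model, y, params),
         item = item_trajectories(y, items, model, params),
         combined = {
           st <- .run_filter(model, y, params)
           it <- item_trajectories(y, items, model, params)
           out <- combine_sources(st, it, model)
           out$pe <- .check_binary(y) - out$muhat
           out
         })
}

#' Outcome prediction error
#'
#' The signed divergence between the experienced outcome and the predicted
#' intrusion belief, `PE = y - muhat`. A belief of 0.3 followed by an
#' intrusion (`y = 1`) leaves a prediction error of 0.7 to be handled by
#' reactive control. `pe_positive()` masks the non-intrusion trials (NA),
#' keeping only the positive prediction errors that index reactive control
#' demand.
#'
#' @param muhat predicted beliefs in (0, 1).
#' @param y binary outcomes.
#' @return numeric vector of prediction errors in (-1, 1).
#' @examples
#' compute_pe(0.3, 1)  # 0.7
#' @export
compute_pe <- function(muhat, y) {
  stopifnot(all(muhat > 0 & muhat < 1))
  .check_binary(y) - muhat
}

#' @rdname compute_pe
#' @export
pe_positive <- function(muhat, y) {
  pe <- compute_pe(muhat, y)
  pe[y != 1] <- NA_real_
  pe
}
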