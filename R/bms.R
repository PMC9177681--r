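#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects: model
#' frequencies in the population follow a Dirichlet distribution whose
#' posterior concentration is found by the standard variational update
#' (iterating subject-wise model responsibilities against the Dirichlet
#' natural parameters until convergence). From the posterior it reports
#' expected model frequencies, exceedance probabilities (XP, Monte-Carlo
#' from the posterior Dirichlet), the Bayesian omnibus risk (BOR, the
#' posterior probability - via free-energy comparison - that observed
#' frequency differences arose by chance under equal frequencies) and the
#' protected exceedance probabilities `PXP = XP * (1 - BOR) + BOR / K`.
#'
#' @param L numeric matrix of log model evidence, subjects in rows, models
#'   in columns (column names label the models).
#' @param alpha0 Dirichlet prior concentration per model (default 1).
#' @param n_samples Monte-Carlo draws for the exceedance probabilities.
#' @param tol convergence tolerance on the concentration parameters.
#' @param max_iter iteration cap for the variational update.
#' @param seed integer seed for the XP sampling.
#' @return object of class `tnt_bms`: list with `alpha` (posterior
#'   Dirichlet), `expected_freq`, `xp`, `bor`, `pxp`, `g` (subject x model
#'   responsibilities), and the free energies `F_rfx` and `F_null` behind
#'   the BOR.
#' @export
rfx_bms <- function(L, alpha0 = 1, n_samples = 1e6, tol = 1e-6,
                    max_iter = 1e4, seed = NULL) {
  L <- as.matrix(L)
  if (!all(is.finite(L))) stop("log-evidence matrix has non-finite entries")
  n <- nrow(L)
  K <- ncol(L)
  if (K < 2) stop("at least two models are required")
  if (n < 1) stop("at least one subject is required")
  models <- colnames(L) %||% paste0("m", seq_len(K))
  a0 <- rep(alpha0, K)
  alpha <- a0
  g <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    lg <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lg <- lg - apply(lg, 1, max)
    g <- exp(lg)
    g <- g / rowSums(g)
    alpha_new <- a0 + colSums(g)
    done <- max(abs(alpha_new - alpha)) < tol
    alpha <- alpha_new
    if (done) break
  }
  if (!done) stop("variational update did not converge in ", max_iter,
                  " iterations")
  # exceedance probabilities by posterior Dirichlet sampling
  .check_seed(seed)
  xp <- numeric(K)
  chunk <- 2e5
  left <- n_samples
  while (left > 0) {
    m <- min(chunk, left)
    r <- matrix(rgamma(m * K, shape = rep(alpha, each = m)), m, K)
    win <- max.col(r, ties.method = "first")
    xp <- xp + tabulate(win, K)
    left <- left - m
  }
  xp <- xp / n_samples
  F1 <- .rfx_free_energy(L, g, alpha, a0)
  F0 <- .null_free_energy(L)
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- xp * (1 - bor) + bor / K
  structure(list(models = models,
                 alpha = stats::setNames(alpha, models),
                 expected_freq = stats::setNames(alpha / sum(alpha), models),
                 xp = stats::setNames(xp, models),
                 bor = bor,
                 pxp = stats::setNames(pxp, models),
                 g = g, F_rfx = F1, F_null = F0, n = n),
            class = "tnt_bms")
}

# variational free energy of the random-effects model at the converged
# posterior q(r) = Dir(alpha), q(m_n) = Cat(g_n)
.rfx_free_energy <- function(L, g, alpha, a0) {
  dga <- digamma(alpha) - digamma(sum(alpha))
  elik <- sum(g * sweep(L, 2, dga, "+"))
  ent_m <- -sum(g[g > 0] * log(g[g > 0]))
  eprior <- lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * dga)
  ent_r <- sum(lgamma(alpha)) - lgamma(sum(alpha)) +
    (sum(alpha) - length(alpha)) * digamma(sum(alpha)) -
    sum((alpha - 1) * digamma(alpha))
  elik + ent_m + eprior + ent_r
}

# evidence of the null model: every subject draws its model from a fixed
# uniform frequency profile
.null_free_energy <- function(L) {
  mx <- apply(L, 1, max)
  sum(mx + log(rowMeans(exp(L - mx))))
}

#' @export
print.tnt_bms <- function(x, ...) {
  cat("<tnt_bms> ", x$n, " subjects, ", length(x$models), " models\n",
      sep = "")
  print(round(rbind(freq = x$expected_freq, xp = x$xp, pxp = x$pxp), 4))
  cat("BOR:", signif(x$bor, 4), "\n")
  invisible(x)
}

#' Family-level random-effects model selection
#'
#' Pools model evidence into families under a uniform within-family prior:
#' the per-subject log family evidence is the log-sum-exp of the member
#' models' evidence minus the log family size, after which the family-level
#' frequencies are compared with [rfx_bms()].
#'
#' @inheritParams rfx_bms
#' @param families named character/factor vector or list mapping each model
#'   (column of `L`) to a family label; every family must be nonempty and
#'   at least two families are required.
#' @return `tnt_bms` object over families.
#' @export
family_bms <- function(L, families, ...) {
  L <- as.matrix(L)
  stopifnot(length(families) == ncol(L))
  fam <- factor(unlist(families))
  if (nlevels(fam) < 2) stop("family comparison requires >= 2 families")
  Lf <- vapply(levels(fam), function(f) {
    sub <- L[, fam == f, drop = FALSE]
    mx <- apply(sub, 1, max)
    mx + log(rowMeans(exp(sub - mx)))   # log-sum-exp minus log size
  }, numeric(nrow(L)))
  Lf <- matrix(Lf, nrow = nrow(L), dimnames = list(NULL, levels(fam)))
  rfx_bms(Lf, ...)
}

#' Between-group test of a common model frequency profile
#'
#' Probability that the groups are samples from a single population with a
#' shared model frequency profile, obtained by comparing the random-effects
#' free energy of the pooled data against the sum of the group-wise free
#' energies, at equal prior odds.
#'
#' @param L_list list of log-evidence matrices, one per group, with
#'   identical model sets (columns).
#' @inheritParams rfx_bms
#' @return list with `p_equal` (posterior probability of the
#'   equal-frequency hypothesis), `F_pooled`, `F_split`, and the group and
#'   pooled `tnt_bms` fits.
#' @export
between_group_bms <- function(L_list, alpha0 = 1, seed = NULL, ...) {
  stopifnot(is.list(L_list), length(L_list) >= 2)
  K <- ncol(L_list[[1]])
  if (!all(vapply(L_list, ncol, 1L) == K))
    stop("groups must share the same model set")
  seeds <- .child_seeds(seed %||% 0, length(L_list) + 1)
  fits <- lapply(seq_along(L_list), function(i)
    rfx_bms(L_list[[i]], alpha0 = alpha0, seed = seeds[i], ...))
  pooled <- rfx_bms(do.call(rbind, L_list), alpha0 = alpha0,
                    seed = seeds[length(seeds)], ...)
  F_split <- sum(vapply(fits, function(f) f$F_rfx, numeric(1)))
  list(p_equal = 1 / (1 + exp(F_split - pooled$F_rfx)),
       F_pooled = pooled$F_rfx, F_split = F_split,
       pooled = pooled, groups = fits)
}

#' Bayesian model averaging of subject-level parameters
#'
#' Averages a parameter across the models of a family, weighting each
#' subject's per-model posterior mean by that subject's posterior
#' probability of using the model (computed within the subject's own
#' group).
#'
#' @param params subjects x models matrix of posterior parameter means.
#' @param model_post subjects x models matrix of model posterior
#'   probabilities; rows must sum to 1 (tolerance 1e-6).
#' @return numeric vector of subject-level model-averaged parameters.
#' @export
bma <- function(params, model_post) {
  params <- as.matrix(params)
  model_post <- as.matrix(model_post)
  stopifnot(all(dim(params) == dim(model_post)))
  if (any(abs(rowSums(model_post) - 1) > 1e-6))
    stop("model posterior rows must sum to 1")
  rowSums(params * model_post)
}
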