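# Simulation-based validation of the model space: falsification (can each
# model generate the observed session-wise decline of intrusions?),
# trajectory recovery, model recovery and parameter recovery, plus the
# power simulation for between-group differences in the perceptual
# parameter.

.model_label <- function(model, source) paste(model, source, sep = "-")

#' Model falsification against a target intrusion profile
#'
#' Simulates cohorts of virtual agents per model (perceptual parameters
#' drawn from the estimation priors, suppression factor tuned per model by
#' grid search) and summarises the generated binary ratings as session-wise
#' intrusion proportions. Each virtual subject's ratings are averaged
#' across the repeated simulations before being summarised. Reports the
#' mean difference (MD) between simulated and target proportions and the
#' mean per-subject correlation (MC) of the session profiles.
#'
#' @param models list of `c(model, source)` character pairs; default the
#'   three HGF sources.
#' @param design trial skeleton from [tnt_design()].
#' @param target_profile session-wise target intrusion proportions.
#' @param n_subjects,n_repeats virtual subjects and repeated simulations
#'   per subject (the study scale is 200 x 100; the desk default is
#'   reduced).
#' @param suppression optional named vector of suppression factors (names
#'   `model-source`); missing entries are tuned by [tune_suppression()].
#' @param grid suppression grid used when tuning.
#' @inheritParams simulate_agent
#' @param seed integer master seed.
#' @return list of per-model results: subject x session profile matrix,
#'   mean `profile`, `md`, `mc` and the suppression factor used.
#' @export
run_falsification <- function(models = list(c("hgf2", "state"),
                                            c("hgf2", "item"),
                                            c("hgf2", "combined")),
                              design = NULL,
                              target_profile = tnt_target_profile(),
                              n_subjects = 50, n_repeats = 20,
                              suppression = NULL,
                              grid = seq(0, 0.2, by = 0.01),
                              noise_sd = 0.3, nu = 1, seed = 1) {
  if (is.null(design)) design <- tnt_design(seed = seed)
  ns <- length(unique(design$session))
  stopifnot(length(target_profile) == ns)
  out <- list()
  mseeds <- .child_seeds(seed, length(models))
  for (mi in seq_along(models)) {
    model <- models[[mi]][1]
    source <- models[[mi]][2]
    lab <- .model_label(model, source)
    s <- suppression[lab]
    if (is.null(suppression) || is.na(s))
      s <- as.numeric(tune_suppression(model, source, target_profile, grid,
                                       design, noise_sd = noise_sd, nu = nu,
                                       seed = mseeds[mi]))
    sseeds <- .child_seeds(mseeds[mi] + 1, n_subjects * n_repeats)
    prof <- matrix(NA_real_, n_subjects, ns)
    k <- 0
    for (i in seq_len(n_subjects)) {
      acc <- matrix(0, n_repeats, ns)
      for (r in seq_len(n_repeats)) {
        k <- k + 1
        pars <- draw_perceptual_params(model, 1, seed = sseeds[k])[[1]]
        ag <- simulate_agent(design, model, source, pars, suppression = s,
                             noise_sd = noise_sd, nu = nu, seed = sseeds[k])
        acc[r, ] <- tapply(ag$data$outcome, ag$data$session, mean)
      }
      prof[i, ] <- colMeans(acc)
    }
    out[[lab]] <- list(profiles = prof,
                       profile = colMeans(prof),
                       md = mean(sweep(prof, 2, target_profile)),
                       mc = mean(apply(prof, 1, function(p)
                         suppressWarnings(cor(p, target_profile))),
                         na.rm = TRUE),
                       suppression = s)
  }
  out
}

.bayes_invert <- function(confusion) {
  # reverse inference under a uniform prior over generating models:
  # P(generator | selected) column-normalises the confusion matrix
  inv <- t(t(confusion) / colSums(confusion))
  inv[, colSums(confusion) == 0] <- NA_real_
  inv
}

#' Trajectory recovery across source models
#'
#' For every generating source, simulates agents, fits every candidate
#' source of the same perceptual family, and marks the candidate whose
#' fitted belief trajectory correlates best with the simulated (latent,
#' noiseless) one. Aggregated choices form a confusion matrix
#' (generator x selected) and its Bayes inversion under a uniform prior.
#' Simulations whose latent trajectory is constant (correlation undefined)
#' are discarded and counted.
#'
#' @param model perceptual family (`"hgf2"`, `"kf"`, `"rw"`).
#' @param sources candidate belief sources.
#' @param n_sims simulations per generating source.
#' @param design trial skeleton.
#' @param suppression named per-source suppression factors (tuned when
#'   missing).
#' @inheritParams run_falsification
#' @return list with `confusion`, `inversion`, `n_discarded`.
#' @export
trajectory_recovery <- function(model = "hgf2",
                                sources = c("state", "item", "combined"),
                                n_sims = 20, design = NULL,
                                suppression = NULL,
                                grid = seq(0, 0.2, by = 0.01),
                                noise_sd = 0.3, nu = 1, seed = 1) {
  if (is.null(design)) design <- tnt_design(seed = seed)
  ns <- length(sources)
  supp <- .resolve_suppression(model, sources, suppression, design, grid,
                               noise_sd, nu, seed)
  confusion <- matrix(0, ns, ns, dimnames = list(sources, sources))
  discarded <- 0
  gseeds <- .child_seeds(seed + 17, ns * n_sims)
  k <- 0
  for (gi in seq_len(ns)) {
    for (s in seq_len(n_sims)) {
      k <- k + 1
      pars <- draw_perceptual_params(model, 1, seed = gseeds[k])[[1]]
      ag <- simulate_agent(design, model, sources[gi], pars,
                           suppression = supp[gi], noise_sd = noise_sd,
                           nu = nu, seed = gseeds[k])
      if (sd(ag$belief_gen) == 0) {
        discarded <- discarded + 1
        next
      }
      cors <- vapply(sources, function(src) {
        f <- fit_model(ag$data$outcome, model, src,
                       items = ag$data$item_id, n_starts = 2,
                       seed = gseeds[k])
        th <- f$trajectory$muhat
        tr <- if (src == "item") ag$belief_gen[f$trajectory$trial] else
          ag$belief_gen
        if (sd(th) == 0) return(-Inf)
        cor(th, tr)
      }, numeric(1))
      confusion[gi, which.max(cors)] <- confusion[gi, which.max(cors)] + 1
    }
  }
  confusion <- confusion / pmax(rowSums(confusion), 1)
  list(confusion = confusion, inversion = .bayes_invert(confusion),
       n_discarded = discarded)
}

.resolve_suppression <- function(model, sources, suppression, design, grid,
                                 noise_sd, nu, seed) {
  vapply(seq_along(sources), function(i) {
    lab <- .model_label(model, sources[i])
    s <- suppression[lab]
    if (!is.null(suppression) && !is.na(s)) return(as.numeric(s))
    as.numeric(tune_suppression(model, sources[i],
                                design = design, grid = grid,
                                noise_sd = noise_sd, nu = nu,
                                seed = seed + i))
  }, numeric(1))
}

#' Model recovery by predictive accuracy
#'
#' Simulates data under each generating source and asks which candidate
#' source wins on model accuracy (minimum summed negative log-likelihood,
#' accumulated across each virtual subject's repeats before the argmin).
#' Accuracy ties split uniformly across the tied candidates.
#'
#' @inheritParams trajectory_recovery
#' @param n_subjects,n_repeats virtual subjects and repeats per subject.
#' @return list with `confusion` (row-stochastic), `inversion`.
#' @export
model_recovery <- function(model = "hgf2",
                           sources = c("state", "item", "combined"),
                           n_subjects = 10, n_repeats = 2, design = NULL,
                           suppression = NULL,
                           grid = seq(0, 0.2, by = 0.01),
                           noise_sd = 0.3, nu = 1, seed = 1) {
  if (is.null(design)) design <- tnt_design(seed = seed)
  ns <- length(sources)
  supp <- .resolve_suppression(model, sources, suppression, design, grid,
                               noise_sd, nu, seed)
  confusion <- matrix(0, ns, ns, dimnames = list(sources, sources))
  gseeds <- .child_seeds(seed + 31, ns * n_subjects * n_repeats)
  k <- 0
  for (gi in seq_len(ns)) {
    for (subj in seq_len(n_subjects)) {
      acc <- numeric(ns)
      for (r in seq_len(n_repeats)) {
        k <- k + 1
        pars <- draw_perceptual_params(model, 1, seed = gseeds[k])[[1]]
        ag <- simulate_agent(design, model, sources[gi], pars,
                             suppression = supp[gi], noise_sd = noise_sd,
                             nu = nu, seed = gseeds[k])
        acc <- acc + vapply(sources, function(src)
          fit_model(ag$data$outcome, model, src, items = ag$data$item_id,
                    n_starts = 2, seed = gseeds[k])$accuracy, numeric(1))
      }
      best <- which(abs(acc - min(acc)) < 1e-9)
      confusion[gi, best] <- confusion[gi, best] + 1 / length(best)
    }
  }
  confusion <- confusion / rowSums(confusion)
  list(confusion = confusion, inversion = .bayes_invert(confusion))
}

#' Parameter recovery
#'
#' Draws generating perceptual parameters from the estimation priors,
#' simulates an agent per draw, refits the same model, and correlates
#' fitted against generating parameters within each virtual subject,
#' averaging the correlation across subjects. The study scale is 200
#' subjects x 100 draws; the desk default is 50 x 20.
#'
#' @inheritParams trajectory_recovery
#' @param source belief source of the generating and fitted model.
#' @param n_subjects virtual subjects.
#' @param n_draws parameter draws (simulated datasets) per subject.
#' @param n_starts optimisation starts per fit.
#' @return list with `r_subject` (per-subject correlations of the primary
#'   perceptual parameter), `mean_r`, `se_r`, the per-draw truth/fit table
#'   and the suppression factor used. The primary parameter is `omega` for
#'   HGF/KF and `alpha` for RW.
#' @export
parameter_recovery <- function(model = "hgf2", source = "item",
                               n_subjects = 50, n_draws = 20,
                               design = NULL, suppression = NULL,
                               grid = seq(0, 0.2, by = 0.01),
                               noise_sd = 0.3, nu = 1, n_starts = 5,
                               seed = 1) {
  if (is.null(design)) design <- tnt_design(seed = seed)
  stopifnot(n_draws >= 2)
  lab <- .model_label(model, source)
  s <- suppression[lab]
  if (is.null(suppression) || is.na(s))
    s <- as.numeric(tune_suppression(model, source, design = design,
                                     grid = grid, noise_sd = noise_sd,
                                     nu = nu, seed = seed))
  pname <- if (model == "rw") "alpha" else "omega"
  dseeds <- .child_seeds(seed + 59, n_subjects * n_draws)
  truth <- fitted <- matrix(NA_real_, n_subjects, n_draws)
  flagged <- 0
  k <- 0
  for (i in seq_len(n_subjects)) {
    for (d in seq_len(n_draws)) {
      k <- k + 1
      pars <- draw_perceptual_params(model, 1, seed = dseeds[k])[[1]]
      ag <- simulate_agent(design, model, source, pars, suppression = s,
                           noise_sd = noise_sd, nu = nu, seed = dseeds[k])
      f <- fit_model(ag$data$outcome, model, source,
                     items = ag$data$item_id, n_starts = n_starts,
                     seed = dseeds[k])
      truth[i, d] <- pars[[pname]]
      fitted[i, d] <- f$params[[pname]]
    }
  }
  r_subject <- vapply(seq_len(n_subjects), function(i) {
    if (sd(fitted[i, ]) == 0 || sd(truth[i, ]) == 0) return(NA_real_)
    cor(truth[i, ], fitted[i, ])
  }, numeric(1))
  flagged <- sum(is.na(r_subject))
  list(r_subject = r_subject,
       mean_r = mean(r_subject, na.rm = TRUE),
       se_r = sd(r_subject, na.rm = TRUE) / sqrt(sum(!is.na(r_subject))),
       truth = truth, fitted = fitted, suppression = s,
       n_flagged = flagged, param = pname)
}

#' Power to detect a group difference in the perceptual parameter
#'
#' Simulates paired synthetic groups whose generating perceptual parameter
#' differs by `effect_size`, refits every agent, and reports the fraction
#' of datasets in which a two-sample t test on the fitted parameter
#' rejects at `alpha`. With `effect_size = 0` this estimates the type-I
#' error rate.
#'
#' @inheritParams parameter_recovery
#' @param effect_size difference between the group means of the generating
#'   parameter (native scale for omega; the study does not print the value
#'   it used, so it must be supplied).
#' @param n_per_group subjects per group.
#' @param n_datasets simulated experiments (a warning is issued below 20).
#' @param param_mean,param_sd generating distribution of the parameter in
#'   the reference group.
#' @param alpha test level.
#' @return list with `power`, per-dataset p-values and the settings.
#' @export
power_analysis <- function(model = "hgf2", source = "item", effect_size,
                           n_per_group = 20, n_datasets = 50,
                           param_mean = -3, param_sd = 1,
                           design = NULL, suppression = NULL,
                           grid = seq(0, 0.2, by = 0.01),
                           noise_sd = 0.3, nu = 1, alpha = 0.05,
                           n_starts = 3, seed = 1) {
  stopifnot(is.finite(effect_size))
  if (n_datasets < 20)
    warning("fewer than 20 datasets: power estimate will be unstable")
  if (is.null(design)) design <- tnt_design(seed = seed)
  lab <- .model_label(model, source)
  s <- suppression[lab]
  if (is.null(suppression) || is.na(s))
    s <- as.numeric(tune_suppression(model, source, design = design,
                                     grid = grid, noise_sd = noise_sd,
                                     nu = nu, seed = seed))
  pname <- if (model == "rw") "alpha" else "omega"
  dseeds <- .child_seeds(seed + 101, n_datasets)
  pvals <- vapply(seq_len(n_datasets), function(ds) {
    coh <- generate_cohort(c(a = n_per_group, b = n_per_group),
                           param_means = c(param_mean,
                                           param_mean + effect_size),
                           param_sd = param_sd, design = design,
                           model = model, source = source,
                           suppression = s, noise_sd = noise_sd, nu = nu,
                           seed = dseeds[ds])
    fit <- vapply(coh$agents, function(ag)
      fit_model(ag$data$outcome, model, source, items = ag$data$item_id,
                n_starts = n_starts, seed = dseeds[ds])$params[[pname]],
      numeric(1))
    t.test(fit[coh$truth$group == "a"],
           fit[coh$truth$group == "b"])$p.value
  }, numeric(1))
  list(power = mean(pvals < alpha), p_values = pvals,
       effect_size = effect_size, suppression = s)
}
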