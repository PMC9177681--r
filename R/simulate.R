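# Closed-loop virtual agents: at every trial the perceptual filter predicts
# the intrusion belief from the agent's own past ratings, the suppression
# factor shifts that belief downward (memory suppression prevents beliefs
# from tilting toward 1), Gaussian noise perturbs it, and the binary rating
# is the response that most improves the cumulative beta-model log-accuracy.

# mutable filter streams shared by the three perceptual models; `k` streams
# (1 for state source, one per item otherwise)
.new_streams <- function(model, params, k) {
  e <- new.env(parent = emptyenv())
  e$model <- model
  if (model == "hgf2") {
    e$mu2 <- rep(params$mu2_0 %||% 0, k)
    e$s2 <- rep(params$sigma2_0 %||% 1, k)
    e$eo <- exp(params$omega)
  } else if (model == "kf") {
    e$mu <- rep(params$mu0 %||% 0.5, k)
    e$K <- rep(params$k0 %||% 0, k)
    e$yprev <- numeric(k)
    e$seen <- logical(k)
    e$a <- params$pi * params$omega
  } else {
    e$v <- rep(params$v0 %||% 0.5, k)
    e$alpha <- params$alpha
  }
  e
}

.stream_predict <- function(e, g) {
  switch(e$model,
         hgf2 = plogis(min(max(e$mu2[g], -36), 36)),
         kf = {
           if (e$seen[g]) {
             e$K[g] <- (e$K[g] + e$a) / (e$K[g] + e$a + 1)
             e$mu[g] <- e$mu[g] + e$K[g] * (e$yprev[g] - e$mu[g])
           }
           e$mu[g]
         },
         rw = e$v[g])
}

.stream_update <- function(e, g, y) {
  switch(e$model,
         hgf2 = {
           mh <- plogis(min(max(e$mu2[g], -36), 36))
           w <- mh * (1 - mh)
           pi2 <- 1 / (e$s2[g] + e$eo) + w
           e$mu2[g] <- e$mu2[g] + (y - mh) / pi2
           e$s2[g] <- 1 / pi2
         },
         kf = {
           e$yprev[g] <- y
           e$seen[g] <- TRUE
         },
         rw = {
           e$v[g] <- e$v[g] + e$alpha * (y - e$v[g])
         })
  invisible(e)
}

#' Simulate a virtual suppression agent
#'
#' Generates a full binary intrusion-rating sequence for one virtual
#' participant on a TNT design. Beliefs start at 0.5, are propagated by the
#' chosen perceptual model closed-loop on the agent's own generated ratings
#' (the input at trial t is the rating at t-1), shifted downward by the
#' suppression factor, perturbed by Gaussian noise and clamped to (0, 1);
#' the rating is then the value (intrusion or not) that maximally improves
#' the cumulative beta-model log-accuracy, which with inverse decision noise
#' `nu = 1` amounts to an unbiased mapping (ties resolve to "no intrusion").
#'
#' @param design trial skeleton from [tnt_design()].
#' @param model,source perceptual model and belief source.
#' @param params named list of perceptual parameters (see [filter_beliefs()]).
#' @param suppression downward shift applied to the generated belief; a
#'   positive value makes the expected intrusion proportion decline across
#'   sessions.
#' @param noise_sd standard deviation of the Gaussian noise added to the
#'   suppressed belief before clamping.
#' @param nu inverse decision noise of the generative response mapping
#'   (fixed at 1 in the validation simulations).
#' @param seed integer seed; the outcome sequence is bit-reproducible.
#' @return list of class `tnt_agent` with `data` (the design plus an
#'   `outcome` column), `belief` (the noisy suppressed belief that produced
#'   each rating), `belief_gen` (its noiseless counterpart, used as the
#'   latent trajectory in recovery analyses), `belief_model` (the raw filter
#'   prediction) and the generating settings.
#' @export
simulate_agent <- function(design, model = c("hgf2", "kf", "rw"),
                           source = c("state", "item", "combined"),
                           params = list(), suppression = 0,
                           noise_sd = 0.3, nu = 1, seed = NULL) {
  model <- match.arg(model)
  source <- match.arg(source)
  stopifnot(is.finite(suppression), noise_sd >= 0, nu > 0)
  .check_seed(seed)
  n <- nrow(design)
  item <- as.integer(factor(design$item_id, levels = unique(design$item_id)))
  n_items <- max(item)
  st <- if (source != "item") .new_streams(model, params, 1L) else NULL
  it <- if (source != "state") .new_streams(model, params, n_items) else NULL
  reps <- integer(n_items)
  noise <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  y <- integer(n)
  raw <- theta <- gen <- numeric(n)
  for (t in seq_len(n)) {
    g <- item[t]
    reps[g] <- reps[g] + 1L
    mu <- switch(source,
                 state = .stream_predict(st, 1L),
                 item = .stream_predict(it, g),
                 combined = {
                   ms <- .stream_predict(st, 1L)
                   if (reps[g] >= 2L) {
                     mi <- .stream_predict(it, g)
                     if (model == "hgf2") {
                       msc <- .clamp01(ms); mic <- .clamp01(mi)
                       ps <- 1 / (msc * (1 - msc))
                       pi_ <- 1 / (mic * (1 - mic))
                       (msc * ps + mic * pi_) / (ps + pi_)
                     } else (ms + mi) / 2
                   } else ms
                 })
    raw[t] <- mu
    gen[t] <- .clamp01(mu - suppression)
    th <- .clamp01(mu - suppression + noise[t])
    theta[t] <- th
    # argmax over {0,1} of the cumulative beta log-accuracy: previous trials
    # cancel, leaving the single-trial log-density difference
    y[t] <- as.integer(beta_logpdf(th, 1, nu) > beta_logpdf(th, 0, nu))
    if (!is.null(st)) .stream_update(st, 1L, y[t])
    if (!is.null(it)) .stream_update(it, g, y[t])
  }
  data <- design
  data$outcome <- y
  structure(list(data = data, belief = theta, belief_gen = gen,
                 belief_model = raw, params = params, model = model,
                 source = source, suppression = suppression,
                 noise_sd = noise_sd, nu = nu),
            class = "tnt_agent")
}

#' Draw plausible perceptual parameters from the estimation priors
#'
#' Samples generating parameters from the same Gaussian priors used for MAP
#' estimation (HGF `omega ~ N(-3, 16)`; KF `log pi, log omega ~ N(0, 4)`;
#' RW `logit alpha ~ N(0, 1)`), mapped to their native scales.
#'
#' @param model `"rw"`, `"kf"` or `"hgf2"`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return list of `n` named parameter lists.
#' @export
draw_perceptual_params <- function(model = c("hgf2", "kf", "rw"), n = 1,
                                   seed = NULL) {
  model <- match.arg(model)
  .check_seed(seed)
  pr <- default_priors(model)
  perc <- setdiff(names(pr$mean), "lognu")
  draws <- lapply(seq_len(n), function(i) {
    par <- rnorm(length(perc), pr$mean[perc], pr$sd[seq_along(perc)])
    names(par) <- perc
    .par_native(model, par)
  })
  draws
}

#' Tune the suppression factor against a target intrusion profile
#'
#' Grid search for the suppression factor whose simulated session-wise
#' intrusion proportions (averaged over `n_agents` virtual agents with
#' prior-drawn perceptual parameters) are closest, in mean squared
#' difference, to the target profile. Ties resolve to the smallest factor.
#' Common random numbers are used across grid values, so the search is
#' deterministic given `seed`.
#'
#' @param model,source perceptual model and belief source.
#' @param target_profile per-session target intrusion proportions in `[0,1]`
#'   (default [tnt_target_profile()]).
#' @param grid candidate suppression factors (nonempty).
#' @param design trial skeleton; defaults to the canonical 144-trial design.
#' @param n_agents agents simulated per grid value.
#' @inheritParams simulate_agent
#' @return the selected suppression factor, with the grid losses attached as
#'   attribute `loss`.
#' @export
tune_suppression <- function(model = c("hgf2", "kf", "rw"),
                             source = c("state", "item", "combined"),
                             target_profile = tnt_target_profile(),
                             grid = seq(0, 0.2, by = 0.01),
                             design = NULL, n_agents = 20,
                             noise_sd = 0.3, nu = 1, seed = 1) {
  model <- match.arg(model)
  source <- match.arg(source)
  if (!length(grid)) stop("suppression grid is empty")
  stopifnot(all(target_profile >= 0 & target_profile <= 1))
  grid <- sort(grid)
  if (is.null(design)) design <- tnt_design(seed = seed)
  stopifnot(length(target_profile) == length(unique(design$session)))
  pars <- draw_perceptual_params(model, n_agents, seed = seed)
  aseeds <- .child_seeds(seed, n_agents)
  profile_for <- function(s) {
    prof <- vapply(seq_len(n_agents), function(a) {
      ag <- simulate_agent(design, model, source, pars[[a]], suppression = s,
                           noise_sd = noise_sd, nu = nu, seed = aseeds[a])
      tapply(ag$data$outcome, ag$data$session, mean)
    }, numeric(length(target_profile)))
    rowMeans(prof)
  }
  loss <- vapply(grid, function(s) mean((profile_for(s) - target_profile)^2),
                 numeric(1))
  structure(grid[which.min(loss)], loss = stats::setNames(loss, grid))
}

#' Simulate a multi-group cohort of virtual agents
#'
#' Draws a subject-specific perceptual parameter from a group-specific
#' Gaussian (`omega` for HGF/KF, logit-`alpha` for RW) and simulates one
#' agent per subject, storing the generating truth for recovery scoring.
#'
#' @param n_per_group integer vector of group sizes (>= 2 each); names are
#'   used as group labels.
#' @param param_means per-group mean of the perceptual parameter (native
#'   scale for `omega`, logit scale for RW `alpha`).
#' @param param_sd within-group standard deviation.
#' @inheritParams simulate_agent
#' @param design trial skeleton from [tnt_design()].
#' @return list with `agents` (list of `tnt_agent`) and `truth` (data frame
#'   of subject, group and generating parameter).
#' @export
generate_cohort <- function(n_per_group, param_means, param_sd = 1,
                            design, model = "hgf2", source = "item",
                            params = list(), suppression = 0,
                            noise_sd = 0.3, nu = 1, seed = NULL) {
  stopifnot(length(n_per_group) == length(param_means), all(n_per_group >= 2),
            all(is.finite(param_means)))
  .check_seed(seed)
  groups <- names(n_per_group) %||% paste0("group", seq_along(n_per_group))
  ntot <- sum(n_per_group)
  grp <- rep(groups, n_per_group)
  mu <- rep(param_means, n_per_group)
  theta_true <- rnorm(ntot, mu, param_sd)
  aseeds <- .child_seeds(seed %||% sample.int(1e6, 1), ntot)
  agents <- vector("list", ntot)
  for (i in seq_len(ntot)) {
    p <- params
    if (model == "rw") p$alpha <- plogis(theta_true[i]) else
      p$omega <- theta_true[i]
    agents[[i]] <- simulate_agent(design, model, source, p,
                                  suppression = suppression,
                                  noise_sd = noise_sd, nu = nu,
                                  seed = aseeds[i])
  }
  list(agents = agents,
       truth = data.frame(subject = seq_len(ntot), group = grp,
                          param = theta_true, stringsAsFactors = FALSE))
}

#' Synthetic predictive/reactive coupling pairs with angular structure
#'
#' Samples per-subject coupling parameter pairs whose resultant imbalance
#' angles concentrate at a requested group mean, for exercising the
#' circular group statistics. Angles are drawn from a (wrapped) Gaussian
#' around the group mean and mapped back to coupling space by decomposing
#' the resultant vector onto the predictive (+45 deg) and reactive (-45
#' deg) axes; vector magnitudes are log-normally jittered, which leaves the
#' angle untouched.
#'
#' @param n_per_group group sizes; names become group labels.
#' @param group_angle_means per-group mean imbalance angle, degrees in
#'   (-180, 180].
#' @param spread angular standard deviation in degrees (0 = identical
#'   angles).
#' @param magnitude mean resultant-vector magnitude.
#' @param seed optional integer seed.
#' @return data frame with `subject`, `group`, `predictive`, `reactive`.
#' @export
generate_coupling_fixtures <- function(n_per_group, group_angle_means,
                                       spread = 10, magnitude = 1,
                                       seed = NULL) {
  stopifnot(length(n_per_group) == length(group_angle_means),
            all(group_angle_means > -180 & group_angle_means <= 180))
  .check_seed(seed)
  groups <- names(n_per_group) %||% paste0("group", seq_along(n_per_group))
  grp <- rep(groups, n_per_group)
  mu <- rep(group_angle_means, n_per_group)
  ntot <- sum(n_per_group)
  th <- mu + if (spread > 0) rnorm(ntot, 0, spread) else 0
  th <- ((th + 180) %% 360) - 180
  r <- magnitude * exp(rnorm(ntot, 0, 0.3))
  rad <- th * pi / 180
  vx <- r * sin(rad)
  vy <- -r * cos(rad)
  s <- sqrt(2) / 2
  # u(+45) = (s, -s); u(-45) = (-s, -s); coupling = -projection
  data.frame(subject = seq_len(ntot), group = grp,
             predictive = -(vx * s + vy * -s),
             reactive = -(vx * -s + vy * -s),
             stringsAsFactors = FALSE)
}
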