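# Group-level statistics on model-averaged coupling parameters: one-tailed
# contrasts with BH-FDR within each effect family, bootstrap CIs and
# posterior probabilities of the group means, ROPE Bayes factors, and
# bootstrap Spearman correlations with clinical symptom scores.

.boot_mean <- function(x, n_boot, conf = 0.95) {
  bm <- vapply(seq_len(n_boot), function(b)
    mean(x[sample.int(length(x), replace = TRUE)]), numeric(1))
  list(ci = quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                     names = FALSE),
       pp = max(mean(bm < 0), mean(bm > 0)))
}

.boot_mean_diff <- function(x, y, n_boot, conf = 0.95) {
  bm <- vapply(seq_len(n_boot), function(b)
    mean(x[sample.int(length(x), replace = TRUE)]) -
      mean(y[sample.int(length(y), replace = TRUE)]), numeric(1))
  list(ci = quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                     names = FALSE),
       pp = max(mean(bm < 0), mean(bm > 0)))
}

#' ROPE Bayes factor for a one-sample effect
#'
#' Evidence for a non-negligible standardised effect: posterior draws of
#' Cohen's d are obtained from the noninformative normal model (scaled
#' inverse-chi-square variance, conditionally normal mean), the prior on d
#' is the default Cauchy(0, sqrt(2)/2), and the Bayes factor is the ratio
#' of prior to posterior mass inside the region of practical equivalence
#' `|d| < rope`. Values above 3/10/30/100 are conventionally read as
#' substantial/strong/very strong/decisive evidence for a real effect.
#'
#' @param x sample of (coupling) values.
#' @param rope half-width of the region of practical equivalence on
#'   Cohen's d.
#' @param n_mcmc posterior and prior draws.
#' @param seed integer seed.
#' @return list with `bf` (may be `Inf` when no posterior mass remains in
#'   the ROPE) and the interpretation `band`.
#' @export
rope_bayes_factor <- function(x, rope = 0.1, n_mcmc = 90000, seed = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  .check_seed(seed)
  sig2 <- (n - 1) * stats::var(x) / rchisq(n_mcmc, n - 1)
  mu <- rnorm(n_mcmc, mean(x), sqrt(sig2 / n))
  d_post <- mu / sqrt(sig2)
  d_prior <- rcauchy(n_mcmc, 0, sqrt(2) / 2)
  post_in <- mean(abs(d_post) < rope)
  prior_in <- mean(abs(d_prior) < rope)
  bf <- if (post_in == 0) Inf else prior_in / post_in
  band <- if (bf > 100) "decisive" else if (bf > 30) "very strong" else
    if (bf > 10) "strong" else if (bf > 3) "substantial" else "anecdotal"
  list(bf = bf, band = band)
}

#' Group contrasts on predictive and reactive coupling parameters
#'
#' Tests the four a priori one-tailed effect families on model-averaged
#' coupling parameters: (a) Control x Group interactions - the predictive
#' minus reactive difference compared between the case group and every
#' other group; (b) within-group control effects (predictive vs reactive,
#' paired); (c) negative reactive coupling; (d) negative predictive
#' coupling. p-values are Benjamini-Hochberg adjusted within each family.
#' Every row also carries a bootstrap CI of the relevant mean, the
#' bootstrap posterior probability that the mean differs from zero (Pp)
#' and, for the within-group effects, the ROPE Bayes factor.
#'
#' @param data data frame with columns `subject`, `group`, `region`,
#'   `predictive`, `reactive` (one row per subject x region).
#' @param case_group group label whose imbalance is hypothesised to be
#'   more negative in the interaction contrasts.
#' @param n_boot bootstrap resamples for CIs and Pp.
#' @param rope,n_mcmc see [rope_bayes_factor()].
#' @param seed integer seed.
#' @return data frame, one row per test, with `family`, `region`, `group`,
#'   `t`, `df`, `p`, `p_fdr`, `ci_lo`, `ci_hi`, `pp`, `bf`.
#' @export
coupling_contrasts <- function(data, case_group, n_boot = 2000, rope = 0.1,
                               n_mcmc = 90000, seed = NULL) {
  stopifnot(all(c("subject", "group", "region", "predictive", "reactive")
                %in% names(data)))
  .check_seed(seed)
  groups <- unique(data$group)
  if (!case_group %in% groups) stop("unknown case group: ", case_group)
  regions <- unique(data$region)
  rows <- list()
  add <- function(family, region, group, t, df, p, ci, pp, bf) {
    rows[[length(rows) + 1]] <<- data.frame(
      family = family, region = region, group = group,
      t = t, df = df, p = p, ci_lo = ci[1], ci_hi = ci[2],
      pp = pp, bf = bf, stringsAsFactors = FALSE)
  }
  for (r in regions) {
    dr <- data[data$region == r, ]
    dc <- dr[dr$group == case_group, ]
    diff_case <- dc$predictive - dc$reactive
    for (g in setdiff(groups, case_group)) {
      if (nrow(dc) < 3 || sum(dr$group == g) < 3) next
      dg <- dr[dr$group == g, ]
      diff_g <- dg$predictive - dg$reactive
      tt <- t.test(diff_case, diff_g, alternative = "less",
                   var.equal = TRUE)
      bt <- .boot_mean_diff(diff_case, diff_g, n_boot)
      add("interaction", r, paste(case_group, "vs", g),
          unname(tt$statistic), unname(tt$parameter), tt$p.value,
          bt$ci, bt$pp, NA_real_)
    }
    for (g in groups) {
      dg <- dr[dr$group == g, ]
      if (nrow(dg) < 3) next
      dif <- dg$predictive - dg$reactive
      for (eff in c("control", "reactive", "predictive")) {
        x <- switch(eff, control = dif, reactive = dg$reactive,
                    predictive = dg$predictive)
        tt <- t.test(x, alternative = "less")
        bt <- .boot_mean(x, n_boot)
        bf <- rope_bayes_factor(x, rope, n_mcmc)$bf
        add(eff, r, g, unname(tt$statistic), unname(tt$parameter),
            tt$p.value, bt$ci, bt$pp, bf)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (f in unique(out$family)) {
    i <- out$family == f
    out$p_fdr[i] <- p.adjust(out$p[i], method = "BH")
  }
  out[, c("family", "region", "group", "t", "df", "p", "p_fdr",
          "ci_lo", "ci_hi", "pp", "bf")]
}

#' Adjust symptom subscales for total severity
#'
#' Residualises each subscale on the total severity score (within one
#' group), so that correlations with the adjusted scores are not confounded
#' by overall symptom load. Residuals are uncorrelated with the total by
#' construction.
#'
#' @param scores data frame / matrix of subscale scores.
#' @param total total severity score, same length as `nrow(scores)`.
#' @return data frame of residualised scores.
#' @export
adjust_for_severity <- function(scores, total) {
  scores <- as.data.frame(scores)
  stopifnot(nrow(scores) == length(total))
  as.data.frame(lapply(scores, function(x) resid(lm(x ~ total))))
}

#' Bootstrap Spearman correlation
#'
#' @param x,y paired observations (pairwise-complete).
#' @param n_boot resamples (subjects resampled jointly).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return list with `rho`, `ci`, `n`.
#' @export
spearman_boot <- function(x, y, n_boot = 2000, conf = 0.95, seed = NULL) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  .check_seed(seed)
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  rb <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, replace = TRUE)
    suppressWarnings(cor(x[i], y[i], method = "spearman"))
  }, numeric(1))
  list(rho = cor(x, y, method = "spearman"),
       ci = quantile(rb, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                     names = FALSE, na.rm = TRUE),
       n = n)
}

#' Bootstrap difference between two Spearman correlations
#'
#' Dependent case (`x2` missing): the same predictor `x1` is correlated
#' with two symptom measures in the same subjects; subjects are resampled
#' jointly. Independent case: `cor(x1, y1)` vs `cor(x2, y2)` from disjoint
#' groups, resampled separately. Reports the bootstrap CI of the
#' difference, a normal-approximation Z value and its two-sided p.
#'
#' @param x1,y1 first correlation's paired observations.
#' @param y2 second symptom measure (dependent case) or second group's `y`.
#' @param x2 second group's predictor (independent case); `NULL` for the
#'   dependent case.
#' @param n_boot resamples.
#' @param conf confidence level of the reported CI (the study convention
#'   is 90% for correlation differences).
#' @param seed integer seed.
#' @return list with `diff` (rho1 - rho2), `ci`, `z`, `p`.
#' @export
spearman_diff_boot <- function(x1, y1, y2, x2 = NULL, n_boot = 2000,
                               conf = 0.90, seed = NULL) {
  .check_seed(seed)
  sp <- function(a, b) suppressWarnings(cor(a, b, method = "spearman"))
  if (is.null(x2)) {
    ok <- complete.cases(x1, y1, y2)
    x1 <- x1[ok]; y1 <- y1[ok]; y2 <- y2[ok]
    n <- length(x1)
    d0 <- sp(x1, y1) - sp(x1, y2)
    db <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, replace = TRUE)
      sp(x1[i], y1[i]) - sp(x1[i], y2[i])
    }, numeric(1))
  } else {
    ok1 <- complete.cases(x1, y1); ok2 <- complete.cases(x2, y2)
    x1 <- x1[ok1]; y1 <- y1[ok1]; x2 <- x2[ok2]; y2 <- y2[ok2]
    d0 <- sp(x1, y1) - sp(x2, y2)
    db <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(length(x1), replace = TRUE)
      j <- sample.int(length(x2), replace = TRUE)
      sp(x1[i], y1[i]) - sp(x2[j], y2[j])
    }, numeric(1))
  }
  z <- d0 / sd(db)
  list(diff = d0,
       ci = quantile(db, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                     names = FALSE, na.rm = TRUE),
       z = z, p = 2 * pnorm(-abs(z)))
}

#' Correlations between control imbalance and symptom dimensions
#'
#' Spearman correlations (with bootstrap CIs) between a per-subject control
#' measure (e.g. the predictive-minus-reactive coupling difference or the
#' imbalance angle) and each column of a symptom table, BH-FDR adjusted
#' across the family. Missing symptom scores are dropped pairwise and the
#' retained count reported.
#'
#' @param value per-subject control measure.
#' @param symptoms data frame of symptom scores (one column per dimension,
#'   rows aligned with `value`).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return data frame with `symptom`, `rho`, `ci_lo`, `ci_hi`, `n`, `p`,
#'   `p_fdr`.
#' @export
symptom_correlations <- function(value, symptoms, n_boot = 2000,
                                 seed = NULL) {
  symptoms <- as.data.frame(symptoms)
  stopifnot(length(value) == nrow(symptoms))
  seeds <- .child_seeds(seed %||% 0, ncol(symptoms))
  rows <- lapply(seq_along(symptoms), function(i) {
    y <- symptoms[[i]]
    sb <- spearman_boot(value, y, n_boot = n_boot, seed = seeds[i])
    ok <- complete.cases(value, y)
    p <- suppressWarnings(stats::cor.test(value[ok], y[ok],
                                          method = "spearman"))$p.value
    data.frame(symptom = names(symptoms)[i], rho = sb$rho,
               ci_lo = sb$ci[1], ci_hi = sb$ci[2], n = sb$n, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p, method = "BH")
  out
}

#' Combine the hippocampal subregions into a whole-hippocampus entry
#'
#' Adds a `wHIP` region whose predictive and reactive couplings combine the
#' rostral and caudal hippocampus rows (sum by default, mean optionally).
#'
#' @param data coupling data frame as in [coupling_contrasts()].
#' @param method `"sum"` or `"mean"`.
#' @param parts region labels to combine.
#' @param label label of the combined region.
#' @return the input with the combined region rows appended.
#' @export
combine_hippocampus <- function(data, method = c("sum", "mean"),
                                parts = c("rHIP", "cHIP"), label = "wHIP") {
  method <- match.arg(method)
  sub <- data[data$region %in% parts, ]
  if (!nrow(sub)) stop("no rows for regions: ", paste(parts, collapse = ", "))
  agg <- function(v) if (method == "sum") sum(v) else mean(v)
  sp <- split(sub, list(sub$subject, sub$group), drop = TRUE)
  comb <- do.call(rbind, lapply(sp, function(d)
    data.frame(subject = d$subject[1], group = d$group[1], region = label,
               predictive = agg(d$predictive), reactive = agg(d$reactive),
               stringsAsFactors = FALSE)))
  rownames(comb) <- NULL
  rbind(data, comb[, names(data)[names(data) %in% names(comb)]])
}

#' Read a deposited coupling-parameter table
#'
#' Loads a per-subject predictive/reactive coupling table from a
#' tab-separated file, with a column-mapping configuration so that
#' deposited files with different headers can be adapted without editing
#' them. The deposited data of the original cohort are distributed
#' separately (Zenodo record 6362400); this loader only requires the
#' five mapped columns.
#'
#' @param path TSV file path.
#' @param columns named character vector mapping the required names
#'   (`subject`, `group`, `region`, `predictive`, `reactive`) to the
#'   file's column names.
#' @return coupling data frame as used by [coupling_contrasts()].
#' @export
read_coupling_table <- function(path,
                                columns = c(subject = "subject",
                                            group = "group",
                                            region = "region",
                                            predictive = "predictive",
                                            reactive = "reactive")) {
  if (!file.exists(path))
    stop("coupling-parameter file not found: ", path,
         " (the deposited cohort data must be downloaded separately)")
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "region", "predictive", "reactive")
  stopifnot(all(need %in% names(columns)))
  missing <- setdiff(unname(columns[need]), names(raw))
  if (length(missing))
    stop("columns missing from ", path, ": ",
         paste(missing, collapse = ", "))
  out <- raw[, unname(columns[need])]
  names(out) <- need
  out
}
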