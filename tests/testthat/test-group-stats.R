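make_coupling <- function(seed = 1, shift_case = -0.6) {
  # three groups, one region: the case group has disproportionately more
  # negative predictive than reactive coupling
  set.seed(seed)
  n <- c(ctrl = 24, res = 24, case = 24)
  g <- rep(names(n), n)
  predictive <- rnorm(sum(n), -0.4, 0.3) +
    ifelse(g == "case", shift_case, 0)
  reactive <- rnorm(sum(n), -0.3, 0.3) + ifelse(g == "case", 0.3, 0)
  data.frame(subject = seq_len(sum(n)), group = g, region = "wHIP",
             predictive = predictive, reactive = reactive,
             stringsAsFactors = FALSE)
}

test_that("contrast table covers the four effect families with FDR", {
  dat <- make_coupling()
  ct <- coupling_contrasts(dat, case_group = "case", n_boot = 300,
                           n_mcmc = 5000, seed = 2)
  expect_setequal(unique(ct$family),
                  c("interaction", "control", "reactive", "predictive"))
  # planted interaction is detected against both other groups
  inter <- ct[ct$family == "interaction", ]
  expect_true(all(inter$p < 0.05))
  expect_true(all(inter$t < 0))
  # FDR adjustment matches the hand oracle within each family
  for (f in unique(ct$family)) {
    i <- ct$family == f
    expect_equal(ct$p_fdr[i], bh_oracle(ct$p[i]), tolerance = 1e-12)
  }
  # adjusted p nondecreasing in raw p within family
  for (f in unique(ct$family)) {
    sub <- ct[ct$family == f, ]
    sub <- sub[order(sub$p), ]
    expect_true(all(diff(sub$p_fdr) >= -1e-12))
  }
  # predictive coupling in the case group: strongly negative, decisive BF
  pc <- ct[ct$family == "predictive" & ct$group == "case", ]
  expect_lt(pc$p, 0.001)
  expect_gt(pc$pp, 0.99)
  expect_gt(pc$bf, 30)
})

test_that("BH oracle reproduces the worked adjustment example", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.05), "BH"),
               bh_oracle(c(0.01, 0.02, 0.04, 0.05)))
})

test_that("null coupling data produce calibrated interaction p-values", {
  set.seed(3)
  data_seeds <- sample.int(1e6, 40)
  pv <- vapply(data_seeds, function(ds) {
    dat <- make_coupling(seed = ds, shift_case = 0)
    dat$reactive <- dat$reactive - ifelse(dat$group == "case", 0.3, 0)
    ct <- suppressWarnings(
      coupling_contrasts(dat, case_group = "case", n_boot = 50,
                         n_mcmc = 2000, seed = ds))
    ct$p[ct$family == "interaction"]
  }, numeric(2))
  expect_lt(mean(pv < 0.05), 0.2)      # near the nominal one-tailed rate
  expect_gt(mean(pv < 0.5), 0.25)      # and not degenerate
})

test_that("severity adjustment removes the shared component", {
  set.seed(5)
  total <- rnorm(50, 20, 5)
  scores <- data.frame(a = 0.8 * total + rnorm(50),
                       b = -0.5 * total + rnorm(50))
  adj <- adjust_for_severity(scores, total)
  expect_lt(abs(cor(adj$a, total)), 1e-10)
  expect_lt(abs(cor(adj$b, total)), 1e-10)
})

test_that("symptom correlations report rho, CI and FDR", {
  set.seed(6)
  x <- rnorm(60)
  sym <- data.frame(avoid = -0.6 * x + rnorm(60, sd = 0.5),
                    unrelated = rnorm(60))
  sym$unrelated[1:3] <- NA            # pairwise deletion
  out <- symptom_correlations(x, sym, n_boot = 300, seed = 7)
  expect_equal(out$symptom, c("avoid", "unrelated"))
  expect_lt(out$rho[1], -0.4)
  expect_true(out$ci_lo[1] <= out$rho[1] & out$rho[1] <= out$ci_hi[1])
  expect_equal(out$n[2], 57)
  expect_equal(out$p_fdr, p.adjust(out$p, "BH"))
})

test_that("self-correlation is exactly one", {
  set.seed(8)
  x <- rnorm(30)
  sb <- spearman_boot(x, x, n_boot = 50, seed = 9)
  expect_equal(sb$rho, 1)
})

test_that("correlation-difference bootstrap covers a known gap", {
  # independent-groups case with a known rho difference ~ 0.4
  set.seed(10)
  n <- 80
  x1 <- rnorm(n); y1 <- 0.75 * x1 + rnorm(n, sd = sqrt(1 - 0.75^2))
  x2 <- rnorm(n); y2 <- 0.3 * x2 + rnorm(n, sd = sqrt(1 - 0.3^2))
  res <- spearman_diff_boot(x1, y1, y2 = y2, x2 = x2, n_boot = 400,
                            seed = 11)
  expect_true(res$ci[1] < res$diff & res$diff < res$ci[2])
  expect_gt(res$diff, 0.15)
  expect_gt(res$z, 1)
  # dependent case runs and is near zero for exchangeable symptoms
  y1b <- 0.5 * x1 + rnorm(n, sd = 0.8)
  y2b <- 0.5 * x1 + rnorm(n, sd = 0.8)
  dep <- spearman_diff_boot(x1, y1b, y2b, n_boot = 400, seed = 12)
  expect_lt(abs(dep$diff), 0.3)
})

test_that("hippocampal parts combine by sum or mean", {
  dat <- rbind(
    data.frame(subject = 1:2, group = "g", region = "rHIP",
               predictive = c(-0.2, -0.4), reactive = c(-0.1, 0.1)),
    data.frame(subject = 1:2, group = "g", region = "cHIP",
               predictive = c(-0.3, -0.1), reactive = c(-0.2, 0.3)))
  w <- combine_hippocampus(dat)
  ws <- w[w$region == "wHIP", ]
  ws <- ws[order(ws$subject), ]
  expect_equal(ws$predictive, c(-0.5, -0.5))
  expect_equal(ws$reactive, c(-0.3, 0.4))
  wm <- combine_hippocampus(dat, method = "mean")
  expect_equal(wm[wm$region == "wHIP", ]$predictive[order(
    wm[wm$region == "wHIP", ]$subject)], c(-0.25, -0.25))
})

test_that("fixture cohorts recover their group angle means", {
  fx <- generate_coupling_fixtures(c(a = 50, b = 50),
                                   group_angle_means = c(33, 7),
                                   spread = 20, seed = 13)
  th <- resultant_angle(fx$predictive, fx$reactive)
  cia <- circular_mean_ci(th[fx$group == "a"], n_boot = 500, seed = 14)
  cib <- circular_mean_ci(th[fx$group == "b"], n_boot = 500, seed = 15)
  expect_true(cia$ci[1] <= 33 && 33 <= cia$ci[2])
  expect_true(cib$ci[1] <= 7 && 7 <= cib$ci[2])
  wt <- watson_two_sample(th[fx$group == "a"], th[fx$group == "b"],
                          n_perm = 500, seed = 16)
  expect_lt(wt$p, 0.05)
})

test_that("the deposited-data loader validates its input contract", {
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(subject = 1:3, group = "g", region = "wHIP",
                   predictive = c(-0.1, -0.2, -0.3),
                   reactive = c(-0.1, 0, 0.1))
  write_events(df, tmp)
  got <- read_coupling_table(tmp)
  expect_equal(got$predictive, df$predictive)
  expect_error(read_coupling_table(tempfile()), "not found")
  bad <- tempfile(fileext = ".tsv")
  write_events(df[, 1:3], bad)
  expect_error(read_coupling_table(bad), "columns missing")
})
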