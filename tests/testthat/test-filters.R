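test_that("RW recursion matches the direct oracle and its limits", {
  # y = 1,1,0 at alpha = 0.5, V0 = 0.5: hand recursion gives
  # V = 0.75, 0.875, 0.4375 and predictions 0.5, 0.75, 0.875
  tr <- rw_filter(c(1, 1, 0), alpha = 0.5)
  expect_equal(tr$v, c(0.75, 0.875, 0.4375))
  expect_equal(tr$muhat, c(0.5, 0.75, 0.875))
  y <- rbinom(30, 1, 0.5)
  expect_equal(rw_filter(y, alpha = 1)$muhat[-1], as.numeric(y[-30]))
  expect_true(all(rw_filter(y, alpha = 0)$muhat == 0.5))
  expect_error(rw_filter(y, alpha = 1.2), "alpha")
})

test_that("Kalman gain converges to the fixed point of its recursion", {
  # K = (K + a)/(K + a + 1) has fixed point (-a + sqrt(a^2 + 4a))/2
  y <- rbinom(200, 1, 0.5)
  tr <- kf_filter(y, pi = 1, omega = 2)
  expect_equal(tail(tr$gain, 1), (-2 + sqrt(12)) / 2, tolerance = 1e-10)
  tr0 <- kf_filter(y, pi = 1e-9, omega = 1e-9)
  expect_true(all(diff(tr0$gain) <= 1e-8))
  expect_lt(tail(tr0$gain, 1), 1e-4)
  tr1 <- kf_filter(rep(1L, 50), pi = 1, omega = 1)
  expect_true(all(diff(tr1$muhat) >= 0))
  expect_error(kf_filter(y, pi = -1, omega = 1), "positive")
})

test_that("HGF predictions are sigmoid of mu2 and updates are signed", {
  y <- c(1L, 1L, 0L, 1L)
  tr <- hgf2_filter(y, omega = -2)
  expect_equal(tr$muhat[1], 0.5)                  # mu2_0 = 0
  expect_equal(tr$muhat[-1], plogis(tr$mu2[-4]))  # muhat(t)=sig(mu2(t-1))
  up <- hgf2_filter(rep(1L, 20), omega = -2)
  expect_true(all(diff(up$mu2) > 0))              # y=1 with muhat<1
  expect_equal(tr$pe, y - tr$muhat)
})

test_that("beliefs stay in (0,1) and variances positive on long inputs", {
  set.seed(42)
  for (om in c(-8, -3, 2)) {
    y <- rbinom(10000, 1, 0.5)
    tr <- hgf2_filter(y, omega = om)
    expect_true(all(tr$muhat > 0 & tr$muhat < 1))
    expect_true(all(tr$sigma2 > 0))
  }
})

test_that("uncertainty-weighted learning: updates grow with sigma2", {
  lo <- hgf2_filter(c(1L, 1L), omega = -3, sigma2_0 = 0.5)
  hi <- hgf2_filter(c(1L, 1L), omega = -3, sigma2_0 = 4)
  expect_gt(abs(hi$mu2[1]), abs(lo$mu2[1]))
})

test_that("KF at its gain fixed point reduces to RW", {
  # starting the gain at the fixed point of its recursion
  # (pi*omega = alpha^2 / (1 - alpha)) keeps K = alpha for every trial,
  # and the KF prediction recursion then equals the RW one
  set.seed(5)
  y <- rbinom(60, 1, 0.4)
  alpha <- 0.35
  kf <- kf_filter(y, pi = 1, omega = alpha^2 / (1 - alpha), k0 = alpha)
  expect_true(all(abs(kf$gain - alpha) < 1e-12))
  rw <- rw_filter(y, alpha = alpha)
  expect_equal(kf$muhat, rw$muhat, tolerance = 1e-10)
})

test_that("item trajectories run per item and reassemble chronologically", {
  d <- full_design(seed = 3)
  set.seed(9)
  y <- rbinom(nrow(d), 1, 0.5)
  tr <- item_trajectories(y, d$item_id, "hgf2", list(omega = -2))
  expect_equal(nrow(tr), 144)
  expect_equal(tr$trial, seq_len(144))
  # each item's subtrajectory equals an independent filter run
  for (it in unique(d$item_id)[1:3]) {
    idx <- which(d$item_id == it)
    solo <- hgf2_filter(y[idx], omega = -2)
    expect_equal(tr$muhat[tr$item == it], solo$muhat)
  }
  # first repetition of every item starts at the initial belief
  expect_true(all(tr$muhat[tr$rep == 1] == 0.5))
})

test_that("items with fewer than two repetitions are excluded", {
  y <- c(1L, 0L, 1L, 0L, 1L)
  items <- c("a", "b", "a", "b", "c")
  expect_warning(tr <- item_trajectories(y, items, "rw",
                                         list(alpha = 0.5)),
                 "fewer than 2")
  expect_equal(nrow(tr), 4)
  expect_false("c" %in% tr$item)
})

test_that("single-item design makes item and state sources coincide", {
  d <- tnt_design(1, 8, 1)
  y <- rbinom(8, 1, 0.5)
  st <- filter_beliefs(y, "hgf2", "state", list(omega = -2))
  it <- filter_beliefs(y, "hgf2", "item", list(omega = -2),
                       items = d$item_id)
  expect_equal(st$muhat, it$muhat)
})

test_that("combined beliefs are precision-weighted and convex", {
  d <- full_design(seed = 4)
  set.seed(11)
  y <- rbinom(nrow(d), 1, 0.5)
  st <- filter_beliefs(y, "hgf2", "state", list(omega = -2))
  it <- item_trajectories(y, d$item_id, "hgf2", list(omega = -2))
  cb <- combine_sources(st, it, "hgf2")
  use <- !is.na(cb$rep) & cb$rep >= 2
  # convexity: combined always lies between the state and item beliefs
  lohi <- cbind(pmin(st$muhat[use], cb$muhat_item[use]),
                pmax(st$muhat[use], cb$muhat_item[use]))
  expect_true(all(cb$muhat[use] >= lohi[, 1] - 1e-12 &
                    cb$muhat[use] <= lohi[, 2] + 1e-12))
  # before an item's second repetition the state belief carries over
  expect_equal(cb$muhat[!use], st$muhat[!use])
  # equal precisions (symmetric beliefs) average exactly
  st2 <- st; it2 <- it
  st2$muhat[] <- 0.3
  it2$muhat[] <- 0.7          # same Bernoulli precision as 0.3
  cb2 <- combine_sources(st2, it2, "hgf2")
  expect_equal(cb2$muhat[!is.na(cb2$rep) & cb2$rep >= 2], rep(0.5, sum(use)),
               tolerance = 1e-12)
  # dominant precision: item belief at the clamp bound takes over
  it3 <- it
  it3$muhat[] <- 1 - 1e-5     # clamped to 1 - 1e-4, precision ~ 1e4
  cb3 <- combine_sources(st, it3, "hgf2")
  expect_true(all(abs(cb3$muhat[use] - (1 - 1e-4)) < 0.05))
  # RW/KF combination is the arithmetic mean
  strw <- filter_beliefs(y, "rw", "state", list(alpha = 0.4))
  itrw <- item_trajectories(y, d$item_id, "rw", list(alpha = 0.4))
  cbrw <- combine_sources(strw, itrw, "rw")
  ms_cl <- pmin(pmax(strw$muhat[use], 1e-4), 1 - 1e-4)
  expect_equal(cbrw$muhat[use], (ms_cl + cbrw$muhat_item[use]) / 2)
})

test_that("prediction error is outcome minus belief, masked for PE+", {
  expect_identical(compute_pe(0.3, 1), 0.7)
  expect_identical(compute_pe(0.5, 0), -0.5)
  pe <- pe_positive(c(0.3, 0.5, 0.8), c(1, 0, 1))
  expect_equal(pe, c(0.7, NA, 0.2))
})
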