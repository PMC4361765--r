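test_that("Schaefer projection matches closed forms and the scalar oracle", {
  # carrying-capacity equilibrium with no catch
  expect_equal(schaefer_project(0.3, 1000, 1, rep(0, 25)), rep(1000, 26))
  # one-step hand arithmetic: 500 + 0.2*500*0.5 - 50 = 500
  expect_equal(schaefer_project(0.2, 1000, 0.5, 50), c(500, 500))
  set.seed(11)
  for (i in 1:10) {
    r <- runif(1, 0.1, 1); K <- runif(1, 1e3, 1e5); b0 <- runif(1, 0.3, 1)
    ct <- runif(20, 0, 0.05 * K)
    expect_equal(schaefer_project(r, K, b0, ct),
                 schaefer_bruteforce(r, K, b0, ct), tolerance = 1e-12)
  }
  expect_error(schaefer_project(0.2, 1000, 0.5, c(10, NA)), "NA")
})

test_that("depletion prior switches on resilience and the catch ratio", {
  declining <- c(10, 40, 100, 60, 30)   # final/peak = 0.3
  steady <- c(10, 40, 100, 80, 60)      # final/peak = 0.6
  p1 <- select_depletion_prior(declining, 0.4)
  expect_equal(p1$mode, "constrained_low")
  expect_equal(c(p1$lower, p1$upper), c(0.01, 0.4))
  p2 <- select_depletion_prior(steady, 0.4)
  expect_equal(p2$mode, "constrained_high")
  expect_equal(c(p2$lower, p2$upper), c(0.3, 0.7))
  p3 <- select_depletion_prior(declining, 0.7)
  expect_equal(p3$mode, "uniform")
  expect_equal(c(p3$lower, p3$upper), c(0.01, 1))
  # well-managed threshold is exactly 0.6
  expect_equal(select_depletion_prior(steady, 0.6)$mode, "uniform")
  expect_error(select_depletion_prior(rep(0, 12), 0.4), "degenerate")
})

test_that("parameter sampling is seeded, bounded and log-uniform", {
  catches <- c(5, 20, 50, 30, 10)
  s1 <- sample_rk(1000, catches, seed = 99)
  s2 <- sample_rk(1000, catches, seed = 99)
  expect_identical(s1, s2)
  expect_true(all(s1$K >= max(catches)))
  expect_true(all(s1$K <= 100 * max(catches)))
  b <- c(0.2, 1.0)  # default "medium" resilience bounds
  expect_true(all(s1$r >= b[1] & s1$r <= b[2]))
  # distributional oracle: log r uniform on the log bounds (KS test)
  s3 <- sample_rk(10000, catches, seed = 5)
  ks <- suppressWarnings(stats::ks.test(log(s3$r), "punif", log(0.2), log(1)))
  expect_gt(ks$p.value, 0.01)
  ksK <- suppressWarnings(stats::ks.test(log(s3$K), "punif",
                                         log(50), log(5000)))
  expect_gt(ksK$p.value, 0.01)
})

test_that("initial depletion rule follows the first-catch-to-peak ratio", {
  developing <- c(5, 20, 50, 100, 80)   # first < 0.5 * peak
  exploited <- c(80, 100, 90, 70, 60)   # first >= 0.5 * peak
  sd1 <- sample_rk(500, developing, seed = 1)
  expect_true(all(sd1$B0_fraction >= 0.5 & sd1$B0_fraction <= 0.9))
  sd2 <- sample_rk(500, exploited, seed = 1)
  expect_true(all(sd2$B0_fraction >= 0.3 & sd2$B0_fraction <= 0.6))
})

test_that("viability filter enforces collapse, ceiling and depletion-window rules", {
  catches <- rep(0, 15)
  prior_full <- list(mode = "uniform", lower = 0.01, upper = 1)
  # zero catch from unfished start: trajectory constant at K, viable only
  # if the prior window includes depletion 1
  samples <- data.frame(r = c(0.3, 0.5), K = c(1000, 2000), B0_fraction = c(1, 1))
  fv <- filter_viable(samples, catches, prior_full)
  expect_equal(fv$n_viable, 2)
  prior_low <- list(mode = "constrained_low", lower = 0.01, upper = 0.4)
  fv2 <- filter_viable(samples, catches, prior_low)
  expect_equal(fv2$n_viable, 0)
  # a collapsing pair is excluded even when its endpoint is in the window
  crash <- data.frame(r = 0.05, K = 100, B0_fraction = 0.5)
  heavy <- c(30, 30, 5, rep(0, 10))
  traj <- schaefer_project(0.05, 100, 0.5, heavy)
  expect_lt(min(traj) / 100, 0.01)
  expect_equal(filter_viable(crash, heavy, prior_full)$n_viable, 0)
  # retained trajectories satisfy the bounds by construction
  set.seed(3)
  catches2 <- c(10, 30, 60, 40, 20, 10, 8, 6, 5, 5)
  s <- sample_rk(2000, catches2, seed = 8)
  fv3 <- filter_viable(s, catches2, prior_low)
  if (fv3$n_viable > 0) {
    depl <- fv3$trajectories / fv3$samples$K
    expect_true(all(depl >= 0.01 - 1e-12))
    expect_true(all(depl <= 1 + 1e-12))
    final <- depl[, ncol(depl)]
    expect_true(all(final >= 0.01 & final <= 0.4))
  }
})

test_that("an unfished stock under near-zero catch assesses near carrying capacity", {
  # analytic limit: unfished Schaefer stock sits at K = 2 * BMSY
  fit <- assess_stock(rep(5, 20), resilience = 0.8, n = 5000, seed = 3,
                      stock_id = "unfished")
  final <- fit$bbmsy[length(fit$bbmsy)]
  expect_gt(final, 1.5)
  expect_lte(final, 2)
})

test_that("stock assessment is deterministic given the seed and order-independent", {
  catches <- c(NA, NA, 10, 25, 60, 90, 120, 100, 70, 50, 40, 35, 30, 28)
  f1 <- assess_stock(catches, resilience = 0.4, n = 2000, seed = 17,
                     stock_id = "S1")
  f2 <- assess_stock(catches, resilience = 0.4, n = 2000, seed = 17,
                     stock_id = "S1")
  expect_identical(f1, f2)
  # leading nulls are trimmed, series keeps calendar alignment
  expect_equal(length(f1$years), length(catches) - 2 + 1)
  # a different stock id gives a different derived stream
  f3 <- assess_stock(catches, resilience = 0.4, n = 2000, seed = 17,
                     stock_id = "S2")
  expect_false(identical(f1$viable_pairs, f3$viable_pairs))
})

test_that("stock assessment enforces the minimum series length", {
  expect_error(assess_stock(c(5, 6, 7), resilience = 0.5, n = 100, seed = 1),
               "3 catch years")
  expect_silent(suppressWarnings(
    assess_stock(c(5, 6, 7), resilience = 0.5, n = 100, seed = 1,
                 min_years = 3, stock_id = "short")))
})

test_that("depletion estimates are invariant to rescaling catches and K", {
  set.seed(21)
  r <- 0.4; K <- 1e4
  u <- seq(0.05, 0.45, length.out = 30)
  B <- K; ct <- numeric(30)
  for (t in 1:30) { ct[t] <- u[t] * B; B <- B + r * B * (1 - B / K) - ct[t] }
  f1 <- assess_stock(ct, resilience = 0.4, n = 3000, seed = 9, stock_id = "sc")
  f2 <- assess_stock(ct * 1000, resilience = 0.4, n = 3000, seed = 9,
                     stock_id = "sc")
  expect_equal(f1$bbmsy, f2$bbmsy, tolerance = 1e-10)
})
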