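test_that("stock resilience is the catch-weighted mean of regional scores", {
  expect_equal(stock_resilience(c(A = 10), c(A = 0.8)), 0.8)
  expect_equal(stock_resilience(c(A = 50, B = 50), c(A = 0.4, B = 0.8)), 0.6)
  expect_equal(stock_resilience(c(A = 75, B = 25), c(A = 0.8, B = 0.4)), 0.7)
  expect_error(stock_resilience(c(A = 10, B = 5), c(A = 0.5)), "B")
  expect_error(stock_resilience(c(A = 0, B = 0), c(A = 0.5, B = 0.5)),
               "no positive catch")
})

test_that("piecewise status scoring hits its printed anchor points", {
  expect_equal(stock_status_score(1.00), 1)
  expect_equal(stock_status_score(0.95), 1)
  expect_equal(stock_status_score(1.05), 1)
  expect_equal(stock_status_score(0.5), 0.5)
  # 1 - 0.5*(2.05 - 1.05) = 0.5
  expect_equal(stock_status_score(2.05), 0.5)
  # linear term hits zero, floor binds
  expect_equal(stock_status_score(3.05), 0.25)
  expect_error(stock_status_score(0), "> 0")
})

test_that("status scoring is monotone up to the buffer and floored beyond it", {
  b <- seq(0.01, 1.05, by = 0.01)
  s <- stock_status_score(b)
  expect_true(all(diff(s) >= -1e-12))
  b2 <- seq(1.05, 5, by = 0.05)
  s2 <- stock_status_score(b2)
  expect_true(all(diff(s2) <= 1e-12))
  expect_true(all(s2 >= 0.25))
  expect_true(all(stock_status_score(runif(100, 0.01, 6)) <= 1))
  # the discontinuity below the buffer is kept as printed: 0.94 scores 0.94,
  # 0.95 jumps to 1
  expect_equal(stock_status_score(0.94), 0.94)
})

test_that("taxonomic penalties shrink the species-level median by level", {
  expect_equal(penalized_proxy_bbmsy(5, 1.0), 0.90)
  expect_equal(penalized_proxy_bbmsy(1, 1.0), 0.01)
  expect_equal(penalized_proxy_bbmsy(3, 0.8), 0.40)
  # monotone non-decreasing in resolution level for a fixed median
  expect_true(all(diff(penalized_proxy_bbmsy(1:5, 1.3)) > 0))
  expect_error(penalized_proxy_bbmsy(6, 1), "1..5")
  expect_error(penalized_proxy_bbmsy(2, 0), "> 0")
})

test_that("mean catch runs from the first non-null record, counting zeros", {
  expect_equal(mean_catch_from_first_nonnull(c(NA, NA, 10, 20)), 15)
  expect_equal(mean_catch_from_first_nonnull(5), 5)
  expect_equal(mean_catch_from_first_nonnull(c(NA, 10, 0, 20)), 10)
  expect_true(is.na(mean_catch_from_first_nonnull(c(NA, NA))))
})

test_that("fisheries status is the catch-weighted geometric mean of stock scores", {
  expect_equal(fisheries_status(rep(0.7, 5), runif(5, 1, 10))$x_fis, 0.7)
  expect_equal(fisheries_status(c(1, 0.25), c(1, 1))$x_fis, 0.5)
  expect_equal(fisheries_status(c(1, 0.25), c(0.9, 0.1))$x_fis, 0.25^0.1)
  expect_warning(out <- fisheries_status(numeric(0), numeric(0)), "no stocks")
  expect_true(is.na(out$x_fis))
})

test_that("weighted geometric mean obeys its inequalities and oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    ss <- runif(n, 0.05, 1)
    w <- runif(n, 0.1, 5)
    x <- fisheries_status(ss, w)$x_fis
    expect_equal(x, geomean_bruteforce(ss, w), tolerance = 1e-12)
    # geometric mean never exceeds the arithmetic mean
    expect_lte(x, sum(w / sum(w) * ss) + 1e-12)
    # invariant to rescaling all catches
    expect_equal(fisheries_status(ss, 3.7 * w)$x_fis, x, tolerance = 1e-12)
    # worsening one stock strictly lowers the status
    ss2 <- ss; ss2[1] <- ss2[1] * 0.5
    expect_lt(fisheries_status(ss2, w)$x_fis, x)
  }
})

test_that("regional scoring joins assessments, proxies and weights correctly", {
  # two species-level stocks in area A1 (bbmsy 0.8 and 1.2 in the final
  # year) and one genus-level taxon (level 5) that takes 0.9 * median = 0.9
  assessments <- data.frame(
    stock_id = rep(c("sp1", "sp2"), each = 2),
    year = rep(c(2009, 2010), 2),
    bbmsy = c(0.7, 0.8, 1.1, 1.2))
  catch <- expand.grid(region_id = "R1", stock_id = c("sp1", "sp2", "gen1"),
                       year = 2001:2010, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  catch$catch_tonnes <- 100
  info <- data.frame(stock_id = c("sp1", "sp2", "gen1"),
                     area_id = "A1", taxon_level = c(6, 6, 5))
  st <- fisheries_goal_status(assessments, catch, info)
  # SS: sp1 -> 0.8 (below buffer), sp2 -> 1 - 0.5*(1.2 - 1.05) = 0.925,
  # gen1 -> proxy 0.9 * median(0.8, 1.2) = 0.9 -> SS 0.9
  expected <- geomean_bruteforce(c(0.8, 1 - 0.5 * (1.2 - 1.05), 0.9), c(1, 1, 1))
  expect_equal(st$status[st$region_id == "R1"], expected, tolerance = 1e-12)
  contrib <- attr(st, "contributions")
  expect_equal(sort(contrib$stock_id), c("gen1", "sp1", "sp2"))
  expect_equal(sum(contrib$weight), 1, tolerance = 1e-9)
})

test_that("proxy falls back to the nearest prior year and excludes orphans", {
  assessments <- data.frame(stock_id = "sp1", year = c(2005, 2006),
                            bbmsy = c(1.0, 1.0))
  catch <- expand.grid(region_id = "R1", stock_id = c("sp1", "gen1", "gen2"),
                       year = 2001:2010, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  catch$catch_tonnes <- 50
  info <- data.frame(stock_id = c("sp1", "gen1", "gen2"),
                     area_id = c("A1", "A1", "A9"), taxon_level = c(6, 4, 4))
  st <- fisheries_goal_status(assessments, catch, info)
  audit <- attr(st, "audit")
  # gen1's proxy uses the 2006 median (prior to its last catch year 2010)
  expect_true(any(grepl("gen1.*prior year 2006", audit)))
  # gen2 sits in an area with no species-level stocks at all
  expect_true(any(grepl("gen2.*excluded", audit)))
  contrib <- attr(st, "contributions")
  expect_false("gen2" %in% contrib$stock_id)
  expected <- geomean_bruteforce(c(1, stock_status_score(0.8 * 1.0)), c(1, 1))
  expect_equal(st$status, expected, tolerance = 1e-12)
})
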