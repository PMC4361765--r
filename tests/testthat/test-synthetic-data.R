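test_that("worlds are reproducible bit-identically from the seed", {
  w1 <- synthetic_world(n_regions = 6, n_stocks = 8, n_areas = 2,
                        years = 1980:2000, seed = 12)
  w2 <- synthetic_world(n_regions = 6, n_stocks = 8, n_areas = 2,
                        years = 1980:2000, seed = 12)
  expect_identical(w1, w2)
  w3 <- synthetic_world(n_regions = 6, n_stocks = 8, n_areas = 2,
                        years = 1980:2000, seed = 13)
  expect_false(identical(w1$catch, w3$catch))
})

test_that("catch histories carry the constructed archetype signatures", {
  w <- synthetic_world(n_regions = 8, n_stocks = 16, n_areas = 2,
                       years = 1950:2010, seed = 4, catch_cv = 0)
  truth <- w$truth_bbmsy
  for (s in w$truth_stocks$stock_id) {
    ts <- w$truth_stocks[w$truth_stocks$stock_id == s, ]
    tb <- truth[truth$stock_id == s, ]
    ct <- tb$catch_true[!is.na(tb$catch_true)]
    bb <- tb$bbmsy_true
    if (ts$archetype == "one_way_trip") {
      # catch peaks then declines; biomass declines monotonically after
      # the catch peak
      peak <- which.max(ct)
      expect_lt(ct[length(ct)], max(ct))
      expect_true(all(diff(bb[peak:length(bb)]) <= 1e-9))
    }
    if (ts$archetype == "lightly_fished") {
      # harvest under 2% of K leaves the stock near carrying capacity
      expect_true(all(ct < 0.02 * ts$K_true))
      expect_gt(bb[length(bb)], 1.8)
    }
  }
})

test_that("noisy reported catch is mean-unbiased around the true catch", {
  w <- synthetic_world(n_regions = 6, n_stocks = 8, n_areas = 2,
                       years = 1950:2010, seed = 10, catch_cv = 0.1)
  # aggregate reported catch per stock-year vs truth
  agg <- stats::aggregate(catch_tonnes ~ stock_id + year, data = w$catch,
                          FUN = sum)
  key <- paste(agg$stock_id, agg$year)
  tr <- w$truth_bbmsy
  m <- match(key, paste(tr$stock_id, tr$year))
  ratio <- agg$catch_tonnes / tr$catch_true[m]
  ratio <- ratio[is.finite(ratio)]
  expect_equal(mean(ratio), 1, tolerance = 0.02)
  expect_equal(stats::sd(ratio), 0.1, tolerance = 0.03)
})

test_that("goal layers have the configured supports and moments", {
  w <- synthetic_world(n_regions = 125, n_stocks = 8, n_areas = 2,
                       years = 1990:2005, seed = 6, na_rate = 0.1)
  gl <- w$goal_layers
  ok <- !is.na(gl$status)
  expect_true(all(gl$status[ok] >= 0 & gl$status[ok] <= 1))
  expect_true(all(abs(gl$trend) <= 1))
  expect_true(all(gl$pressure >= 0 & gl$pressure <= 1))
  expect_true(all(gl$resilience >= 0 & gl$resilience <= 1))
  # Beta(2,2) statuses: sample mean within 3 SE of 0.5
  x <- gl$status[ok & gl$goal_id %in% c("AO", "NP", "CS", "CP", "LE", "SP", "CW", "BD")]
  se <- sqrt(0.05) / sqrt(length(x))  # Beta(2,2) variance = 1/20
  expect_lt(abs(mean(x) - 0.5), 3 * se)
  # NA injection close to the configured rate
  pre <- gl[gl$goal_id %in% c("AO", "NP", "CS", "CP", "LE", "SP", "CW", "BD"), ]
  expect_lt(abs(mean(is.na(pre$status)) - 0.1), 0.035)
  # tourism inputs never violate the labor-force constraint
  with(w$tourism, expect_true(all(
    tourism_employment <= labor_force * (1 - unemployment_rate))))
})

test_that("prior switching is exercised on both sides by construction", {
  w <- synthetic_world(n_regions = 8, n_stocks = 16, n_areas = 2,
                       years = 1950:2010, seed = 2)
  res <- stats::setNames(w$resilience$resilience, w$resilience$region_id)
  srs <- vapply(split(w$catch, w$catch$stock_id), function(d) {
    cr <- vapply(split(d, d$region_id), function(dd)
      mean_catch_from_first_nonnull(dd$catch_tonnes[order(dd$year)]),
      numeric(1))
    stock_resilience(cr[!is.na(cr)], res)
  }, numeric(1))
  arch <- stats::setNames(w$truth_stocks$archetype, w$truth_stocks$stock_id)
  managed <- arch[names(srs)] %in% c("managed_recovery", "lightly_fished")
  expect_true(all(srs[managed] >= 0.6))
  expect_true(all(srs[!managed] < 0.6))
})

test_that("truth tables alone score parameter recovery without re-simulation", {
  w <- synthetic_world(n_regions = 6, n_stocks = 8, n_areas = 2,
                       years = 1960:2000, seed = 9)
  tr <- w$truth_bbmsy
  expect_setequal(unique(tr$stock_id), w$truth_stocks$stock_id)
  # bbmsy_true is exactly biomass / (K/2)
  K <- stats::setNames(w$truth_stocks$K_true, w$truth_stocks$stock_id)
  expect_equal(tr$bbmsy_true, unname(tr$biomass_true / (K[tr$stock_id] / 2)),
               tolerance = 1e-12)
  # one terminal year beyond the simulated range
  expect_equal(max(tr$year), 2001)
})
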