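# Parameter-recovery harness: assess every stock of a synthetic world with
# the catch-only model and compare final-year B/BMSY and final-decade trend
# against the simulated truth.
#
# Trend convention: OLS slope of B/BMSY over the last 10 catch years; the
# true trend is classified rising/stable/falling with a meaningful-change
# threshold of 0.01 per year, and the estimate agrees when it has the same
# sign (directional truth) or magnitude below the threshold (stable truth).

recovery_study <- function(world, n_draws = 10000, seed = world$params$seed,
                           flat_eps = 0.01) {
  res <- stats::setNames(world$resilience$resilience, world$resilience$region_id)
  yrs <- sort(unique(world$catch$year))
  slope10 <- function(y) {
    t <- seq_along(y)
    sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  }
  rows <- lapply(split(world$truth_stocks, world$truth_stocks$stock_id), function(ts) {
    s <- ts$stock_id
    d <- world$catch[world$catch$stock_id == s, ]
    agg <- vapply(split(d$catch_tonnes, d$year), function(v) {
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
    }, numeric(1))[as.character(yrs)]
    cr <- vapply(split(d, d$region_id), function(dd) {
      mean_catch_from_first_nonnull(dd$catch_tonnes[order(dd$year)])
    }, numeric(1))
    sr <- stock_resilience(cr[!is.na(cr)], res)
    fit <- assess_stock(agg, years = yrs, resilience = sr, n = n_draws,
                        seed = seed, stock_id = s, r_category = ts$r_category)
    tr <- world$truth_bbmsy[world$truth_bbmsy$stock_id == s, ]
    nb <- length(fit$bbmsy)
    if (fit$unassessable) {
      return(data.frame(stock_id = s, archetype = ts$archetype,
                        r_true = ts$r_true, n_viable = 0, prior = fit$prior$mode,
                        est_final = NA_real_, true_final = tr$bbmsy_true[nb - 1],
                        est_slope = NA_real_, true_slope = NA_real_,
                        trend_ok = NA))
    }
    win <- (nb - 10):(nb - 1)  # last 10 catch years; terminal row nb is projection
    est_slope <- slope10(fit$bbmsy[win])
    true_slope <- slope10(tr$bbmsy_true[win])
    trend_ok <- if (abs(true_slope) < flat_eps) abs(est_slope) < flat_eps
                else sign(est_slope) == sign(true_slope)
    data.frame(stock_id = s, archetype = ts$archetype, r_true = ts$r_true,
               n_viable = fit$n_viable, prior = fit$prior$mode,
               est_final = fit$bbmsy[nb - 1], true_final = tr$bbmsy_true[nb - 1],
               est_slope = est_slope, true_slope = true_slope,
               trend_ok = trend_ok)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
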