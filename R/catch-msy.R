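# Catch-only stock assessment: a stock-reduction analysis that samples
# (r, K) pairs for a Schaefer surplus-production model, keeps those whose
# implied biomass trajectory is consistent with the catch history and a
# prior on final depletion, and summarises the retained trajectories as a
# B/BMSY time series.

# r prior bounds by resilience category (the established catch-only
# convention for life-history classes).
r_category_bounds <- list(
  very_low = c(0.015, 0.1),
  low      = c(0.05, 0.5),
  medium   = c(0.2, 1.0),
  high     = c(0.6, 1.5)
)

#' Project a Schaefer surplus-production model under a catch history
#'
#' Logistic biomass dynamics with annual removals:
#' \deqn{B_{t+1} = B_t + r B_t (1 - B_t/K) - C_t,\qquad B_1 = d_0 K}
#' The trajectory is returned for every catch year plus one terminal year
#' and is deliberately not clamped: negative or above-K values signal an
#' inviable parameter pair to the downstream filter.
#'
#' @param r intrinsic growth rate (per year), > 0.
#' @param K carrying capacity (tonnes).
#' @param B0_fraction initial depletion, biomass in the first year as a
#'   fraction of K.
#' @param catches numeric vector of annual catches (tonnes), no NA.
#' @return numeric vector of biomass, length `length(catches) + 1`.
#' @examples
#' schaefer_project(0.2, 1000, 0.5, 50) # c(500, 500)
#' @export
schaefer_project <- function(r, K, B0_fraction, catches) {
  if (anyNA(catches)) stopf("'catches' contains NA")
  if (r <= 0) stopf("'r' must be > 0")
  if (B0_fraction <= 0 || B0_fraction > 1) stopf("'B0_fraction' must be in (0, 1]")
  drop(project_pairs(r, K, B0_fraction, catches))
}

# Vectorized projection over parameter pairs: rows are (r, K, b0) draws,
# columns are years (length(catches) + 1).
project_pairs <- function(r, K, b0, catches) {
  n <- length(r)
  Tn <- length(catches)
  B <- matrix(NA_real_, n, Tn + 1)
  b <- b0 * K
  B[, 1] <- b
  for (t in seq_len(Tn)) {
    b <- b + r * b * (1 - b / K) - catches[t]
    B[, t + 1] <- b
  }
  B
}

#' Choose the prior on final depletion for a stock
#'
#' Stocks in well-managed fisheries (resilience score >= 0.6) get an
#' uninformative (uniform) prior on final depletion, because declining
#' catch there often reflects declining effort rather than declining
#' biomass. Poorly regulated stocks keep the constrained prior keyed to the
#' ratio of final-year catch to peak catch: below 0.5 the stock is assumed
#' depleted (bounds 0.01--0.4), otherwise moderately exploited (0.3--0.7).
#'
#' @param catches annual catch series (tonnes); leading NAs allowed.
#' @param resilience governance-based resilience score in \[0,1\] for this
#'   stock (catch-weighted across the regions where it is caught; see
#'   [stock_resilience()]).
#' @param uniform_bounds depletion bounds used in uniform mode; the lower
#'   bound must be positive so B/BMSY stays defined.
#' @return list with `mode` (`"uniform"`, `"constrained_low"` or
#'   `"constrained_high"`), `lower`, `upper`.
#' @export
select_depletion_prior <- function(catches, resilience,
                                   uniform_bounds = c(0.01, 1)) {
  c0 <- catches[!is.na(catches)]
  if (length(c0) == 0 || max(c0) <= 0) stopf("degenerate catch series (no positive catch)")
  check_range(resilience, "resilience", 0, 1)
  if (uniform_bounds[1] <= 0 || uniform_bounds[1] >= uniform_bounds[2] ||
      uniform_bounds[2] > 1)
    stopf("'uniform_bounds' must satisfy 0 < lower < upper <= 1")
  if (resilience >= 0.6) {
    list(mode = "uniform", lower = uniform_bounds[1], upper = uniform_bounds[2])
  } else if (c0[length(c0)] / max(c0) < 0.5) {
    list(mode = "constrained_low", lower = 0.01, upper = 0.4)
  } else {
    list(mode = "constrained_high", lower = 0.3, upper = 0.7)
  }
}

#' Sample candidate Schaefer parameter pairs
#'
#' Draws `n` candidate parameter sets: `r` log-uniform on its resilience
#' bounds, `K` log-uniform on `[max catch, k_multiplier * max catch]`, and
#' initial depletion uniform on \[0.5, 0.9\] when the series starts well
#' below its peak (fishery caught while developing) or \[0.3, 0.6\] when it
#' starts near the peak (already exploited).
#'
#' @param n number of draws.
#' @param catches annual catch series (tonnes); leading NAs allowed.
#' @param r_bounds length-2 interval for r; overrides `r_category`.
#' @param r_category resilience category naming a conventional r interval:
#'   `"very_low"` (0.015--0.1), `"low"` (0.05--0.5), `"medium"` (0.2--1.0,
#'   the default when life history is unknown) or `"high"` (0.6--1.5).
#' @param k_multiplier upper K bound as a multiple of the maximum catch.
#' @param seed integer seed; draws are reproducible given it.
#' @return data frame with columns `r`, `K`, `B0_fraction`.
#' @export
sample_rk <- function(n, catches, r_bounds = NULL, r_category = "medium",
                      k_multiplier = 100, seed = 1) {
  if (n < 1) stopf("'n' must be >= 1")
  if (is.null(r_bounds)) {
    if (!r_category %in% names(r_category_bounds))
      stopf("unknown r_category '%s'", r_category)
    r_bounds <- r_category_bounds[[r_category]]
  }
  if (length(r_bounds) != 2 || r_bounds[1] <= 0 || r_bounds[1] >= r_bounds[2])
    stopf("'r_bounds' must be an increasing positive interval")
  c0 <- catches[!is.na(catches)]
  if (length(c0) == 0 || max(c0) <= 0) stopf("degenerate catch series (no positive catch)")
  cmax <- max(c0)
  b0_bounds <- if (c0[1] < 0.5 * cmax) c(0.5, 0.9) else c(0.3, 0.6)
  with_seed(seed, {
    data.frame(
      r = exp(stats::runif(n, log(r_bounds[1]), log(r_bounds[2]))),
      K = exp(stats::runif(n, log(cmax), log(k_multiplier * cmax))),
      B0_fraction = stats::runif(n, b0_bounds[1], b0_bounds[2])
    )
  })
}

#' Filter parameter pairs to those viable under the catch history
#'
#' A pair is viable when its projected biomass never collapses (drops below
#' `collapse_frac * K`), never exceeds K, and ends at a final depletion
#' inside the prior bounds.
#'
#' @param samples data frame from [sample_rk()].
#' @param catches annual catch series with no NA (trimmed of leading nulls).
#' @param prior depletion prior from [select_depletion_prior()].
#' @param collapse_frac collapse threshold as a fraction of K.
#' @return list with `samples` (viable rows), `trajectories` (viable-row
#'   biomass matrix, years in columns), `viable` (logical mask over the
#'   input), `n_sampled`, `n_viable`.
#' @export
filter_viable <- function(samples, catches, prior, collapse_frac = 0.01) {
  if (nrow(samples) == 0) stopf("'samples' is empty")
  if (anyNA(catches)) stopf("'catches' contains NA")
  B <- project_pairs(samples$r, samples$K, samples$B0_fraction, catches)
  bmin <- do.call(pmin, as.data.frame(B))
  bmax <- do.call(pmax, as.data.frame(B))
  depl_final <- B[, ncol(B)] / samples$K
  viable <- bmin >= collapse_frac * samples$K & bmax <= samples$K &
    depl_final >= prior$lower & depl_final <= prior$upper
  list(samples = samples[viable, , drop = FALSE],
       trajectories = B[viable, , drop = FALSE],
       viable = viable,
       n_sampled = nrow(samples),
       n_viable = sum(viable))
}

#' Assess a stock from its catch history alone
#'
#' Runs the full catch-only assessment for one stock: chooses the final-
#' depletion prior from the stock's resilience score, samples candidate
#' Schaefer (r, K) pairs, filters them to those consistent with the catch
#' history, and summarises the retained trajectories as a B/BMSY series
#' (BMSY = K/2 under the Schaefer model).
#'
#' By default per-pair depletion trajectories \eqn{B_t/K} are averaged
#' arithmetically across viable pairs and doubled, which keeps every pair's
#' contribution on a common scale; `mean_mode = "biomass"` instead averages
#' raw biomass and divides by the mean K / 2.
#'
#' If no viable pair is found, sampling is retried once with
#' `retry_factor` times as many draws; if still empty the stock is flagged
#' unassessable (`$unassessable = TRUE`, NA series) rather than erroring,
#' so multi-stock runs can continue.
#'
#' @param catches annual catch series (tonnes); leading NAs are trimmed.
#' @param years calendar years aligned with `catches` (consecutive).
#' @param resilience governance resilience score in \[0,1\].
#' @param n number of (r, K) draws (default 10000).
#' @param seed integer run seed; the stock's own stream is derived from
#'   `(seed, stock_id)` so results are independent of assessment order.
#' @param stock_id identifier used in the derived seed and in output.
#' @param r_category,r_bounds,k_multiplier passed to [sample_rk()].
#' @param uniform_bounds,collapse_frac passed to the prior and filter.
#' @param mean_mode `"depletion"` (default) or `"biomass"`; see Details.
#' @param min_years minimum number of non-null catch years required.
#' @param retry_factor multiplier on `n` for the single retry.
#' @return an object of class `catch_msy_fit` with elements `stock_id`,
#'   `years` (catch years plus one terminal year), `bbmsy`, `mean_biomass`,
#'   `viable_pairs`, `n_sampled`, `n_viable`, `prior`, `seed`,
#'   `unassessable`.
#' @export
assess_stock <- function(catches, years = NULL, resilience, n = 10000,
                         seed = 1, stock_id = "stock",
                         r_category = "medium", r_bounds = NULL,
                         k_multiplier = 100, uniform_bounds = c(0.01, 1),
                         collapse_frac = 0.01,
                         mean_mode = c("depletion", "biomass"),
                         min_years = 10, retry_factor = 10) {
  mean_mode <- match.arg(mean_mode)
  if (is.null(years)) years <- seq_along(catches)
  if (length(years) != length(catches)) stopf("'years' and 'catches' differ in length")
  if (any(diff(years) != 1)) stopf("'years' must be consecutive")
  first <- which(!is.na(catches))[1]
  if (is.na(first)) stopf("all-null catch series for stock '%s'", stock_id)
  catches <- catches[first:length(catches)]
  years <- years[first:length(years)]
  if (anyNA(catches)) stopf("interior null catches for stock '%s'", stock_id)
  if (any(catches < 0)) stopf("negative catch for stock '%s'", stock_id)
  if (length(catches) < min_years)
    stopf("stock '%s' has %d catch years; %d required", stock_id,
          length(catches), min_years)

  prior <- select_depletion_prior(catches, resilience, uniform_bounds)
  sseed <- stock_seed(seed, stock_id)
  draw <- function(nn, offset) {
    s <- sample_rk(nn, catches, r_bounds = r_bounds, r_category = r_category,
                   k_multiplier = k_multiplier,
                   seed = (sseed + offset) %% 2147483629)
    filter_viable(s, catches, prior, collapse_frac)
  }
  fv <- draw(n, 0)
  n_total <- n
  if (fv$n_viable == 0) {
    fv <- draw(n * retry_factor, 1)
    n_total <- n_total + n * retry_factor
  }

  out <- list(stock_id = stock_id,
              years = c(years, years[length(years)] + 1),
              catches = catches,
              prior = prior,
              n_sampled = n_total,
              n_viable = fv$n_viable,
              seed = sseed,
              mean_mode = mean_mode,
              unassessable = fv$n_viable == 0)
  if (out$unassessable) {
    out$viable_pairs <- fv$samples
    out$mean_biomass <- out$bbmsy <- rep(NA_real_, length(out$years))
  } else {
    B <- fv$trajectories
    K <- fv$samples$K
    out$viable_pairs <- fv$samples
    out$mean_biomass <- colMeans(B)
    out$bbmsy <- if (mean_mode == "depletion") {
      2 * colMeans(B / K)
    } else {
      colMeans(B) / (mean(K) / 2)
    }
  }
  class(out) <- "catch_msy_fit"
  out
}

#' @export
print.catch_msy_fit <- function(x, ...) {
  cat("Catch-only (catch-MSY) stock assessment:", x$stock_id, "\n")
  cat(sprintf("  years %d-%d, prior %s [%.2f, %.2f]\n",
              x$years[1], x$years[length(x$years) - 1],
              x$prior$mode, x$prior$lower, x$prior$upper))
  cat(sprintf("  viable pairs: %d of %d sampled\n", x$n_viable, x$n_sampled))
  if (x$unassessable) {
    cat("  UNASSESSABLE: no viable (r, K) pairs\n")
  } else {
    cat(sprintf("  final B/BMSY: %.3f\n", x$bbmsy[length(x$bbmsy)]))
  }
  invisible(x)
}

#' @export
summary.catch_msy_fit <- function(object, ...) {
  est <- coef(object)
  cat("Catch-only (catch-MSY) stock assessment:", object$stock_id, "\n")
  cat(sprintf("  %d viable of %d sampled (r, K) pairs; prior %s [%.2f, %.2f]\n",
              object$n_viable, object$n_sampled, object$prior$mode,
              object$prior$lower, object$prior$upper))
  if (!object$unassessable) {
    cat(sprintf("  r (median): %.3f   K (median): %.0f t   MSY (median rK/4): %.0f t\n",
                est["r"], est["K"], est["MSY"]))
    bb <- object$bbmsy
    cat(sprintf("  B/BMSY: first %.3f, final %.3f (min %.3f, max %.3f)\n",
                bb[1], bb[length(bb)], min(bb), max(bb)))
  } else {
    cat("  UNASSESSABLE\n")
  }
  invisible(est)
}

#' @export
coef.catch_msy_fit <- function(object, ...) {
  if (object$unassessable)
    return(c(r = NA_real_, K = NA_real_, MSY = NA_real_))
  with(object$viable_pairs,
       c(r = stats::median(r), K = stats::median(K),
         MSY = stats::median(r * K / 4)))
}

#' @export
plot.catch_msy_fit <- function(x, ...) {
  if (x$unassessable) {
    graphics::plot.new()
    graphics::title(main = paste(x$stock_id, "(unassessable)"))
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  yr <- x$years[-length(x$years)]
  plot(yr, x$catches, type = "h", lwd = 2, xlab = "year",
       ylab = "catch (t)", main = x$stock_id, ...)
  plot(x$years, x$bbmsy, type = "l", lwd = 2, xlab = "year",
       ylab = "B/BMSY", ylim = c(0, max(2, x$bbmsy)))
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
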