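# Seeded synthetic-world generator. Emulates the statistical structure of
# the engine's real inputs (catch statistics, mariculture yields, tourism
# employment, per-goal status layers) with known ground truth, so every
# stage of the engine is testable without external data.

#' Generate a synthetic assessment world
#'
#' Builds a reproducible world: regions grouped into fishing areas and
#' split into well-managed (fisheries resilience >= 0.6) and
#' poorly-managed halves; stocks with true Schaefer parameters and one of
#' four effort archetypes (`one_way_trip`, `boom_bust`,
#' `managed_recovery`, `lightly_fished`); catch histories forward-simulated
#' from the true dynamics with lognormal observation noise; and per-goal
#' status/trend/pressure/resilience layers plus mariculture and tourism
#' inputs drawn from bounded, skewed distributions.
#'
#' Managed archetypes (`managed_recovery`, `lightly_fished`) are caught
#' only in well-managed regions and exploitation archetypes
#' (`one_way_trip`, `boom_bust`) only in poorly-managed ones, so the
#' catch-weighted stock resilience lands on the intended side of the
#' prior-switching threshold and both prior modes are exercised.
#'
#' @param n_regions number of reporting regions.
#' @param n_stocks number of stocks (taxa) with catch histories.
#' @param n_areas number of FAO-style fishing areas.
#' @param years calendar years simulated.
#' @param seed integer seed; the world is bit-identical given it.
#' @param catch_cv lognormal observation-noise CV on reported catch.
#' @param na_rate fraction of non-modelled goal-status cells set NA.
#' @param coarse_frac fraction of stocks reported above species level.
#' @param status_shape,pressure_shape,resilience_shape Beta shape pairs for
#'   the non-modelled goal layers.
#' @param trend_sd SD of the truncated-normal trend layer.
#' @param constant_status if non-NULL, a single value c: every goal's
#'   status is exactly c (including precomputed fisheries, mariculture and
#'   tourism statuses), all trends 0 and pressure = resilience, so the
#'   engine's fixed point Index = 100 c holds for every region.
#' @return an object of class `ohi_world`: a list of input tables
#'   (`catch`, `stock_info`, `resilience`, `goal_layers`, `mariculture`,
#'   `coastal_population`, `tourism`) and truth tables (`truth_stocks`,
#'   `truth_bbmsy`), plus the generating parameters.
#' @export
synthetic_world <- function(n_regions = 12, n_stocks = 40, n_areas = 3,
                            years = 1950:2010, seed = 1,
                            catch_cv = 0.1, na_rate = 0, coarse_frac = 0.2,
                            status_shape = c(2, 2), pressure_shape = c(2, 5),
                            resilience_shape = c(5, 2), trend_sd = 0.1,
                            constant_status = NULL) {
  if (n_regions < 2 * n_areas) stopf("need at least two regions per area")
  params <- list(n_regions = n_regions, n_stocks = n_stocks,
                 n_areas = n_areas, years = years, seed = seed,
                 catch_cv = catch_cv, na_rate = na_rate,
                 coarse_frac = coarse_frac, status_shape = status_shape,
                 pressure_shape = pressure_shape,
                 resilience_shape = resilience_shape, trend_sd = trend_sd,
                 constant_status = constant_status)
  world <- structure(list(params = params), class = "ohi_world")

  world$regions <- with_seed(seed, {
    region_id <- sprintf("R%02d", seq_len(n_regions))
    area_id <- sprintf("A%d", rep_len(seq_len(n_areas), n_regions))
    # alternate management type within each area
    managed <- logical(n_regions)
    for (a in unique(area_id)) {
      ix <- which(area_id == a)
      managed[ix] <- seq_along(ix) %% 2 == 1
    }
    resilience <- ifelse(managed,
                         stats::runif(n_regions, 0.6, 0.9),
                         stats::runif(n_regions, 0.2, 0.55))
    data.frame(region_id = region_id, area_id = area_id,
               managed = managed, resilience = round(resilience, 4))
  })

  fish <- generate_catch_histories(world)
  world$stock_info <- fish$stock_info
  world$truth_stocks <- fish$truth_stocks
  world$truth_bbmsy <- fish$truth_bbmsy
  world$catch <- fish$catch
  world$resilience <- world$regions[, c("region_id", "resilience")]

  lay <- generate_goal_layers(world)
  world$goal_layers <- lay$goal_layers
  world$mariculture <- lay$mariculture
  world$coastal_population <- lay$coastal_population
  world$tourism <- lay$tourism
  world
}

# Harvest-rate schedule per effort archetype; u_t is the fraction of
# biomass removed each year, scaled by the stock's true r.
effort_schedule <- function(archetype, r, n_years) {
  s <- seq(0, 1, length.out = n_years)
  switch(archetype,
    one_way_trip = 1.2 * r * s,
    boom_bust = r * ifelse(s <= 0.5, 2.2 * s, 1.1 - 1.0 * (s - 0.5)),
    managed_recovery = 0.8 * r * ifelse(s <= 0.5, 2 * s, 1 - 1.375 * (s - 0.5)),
    lightly_fished = rep(0.02 * r, n_years),
    stopf("unknown effort archetype '%s'", archetype))
}

#' Simulate catch histories with known biomass truth
#'
#' Forward-simulates each stock's Schaefer dynamics under its effort
#' archetype from an unfished start, records the exact biomass and B/BMSY
#' trajectories, applies mean-unbiased lognormal observation noise to the
#' catches, and allocates each stock's reported catch to the regions of
#' its area (managed archetypes to well-managed regions and conversely).
#' Stocks begin reporting at a staggered year, so catch series carry
#' realistic leading nulls.
#'
#' @param world an `ohi_world` (at least `params` and `regions`).
#' @return list of `stock_info` (stock_id, area_id, taxon_level),
#'   `truth_stocks` (true r, K, archetype, resilience band),
#'   `truth_bbmsy` (stock_id, year, biomass_true, bbmsy_true, catch_true)
#'   and `catch` (region_id, stock_id, year, catch_tonnes).
#' @export
generate_catch_histories <- function(world) {
  p <- world$params
  regions <- world$regions
  archetypes <- c("one_way_trip", "boom_bust", "managed_recovery", "lightly_fished")
  with_seed(stock_seed(p$seed, "catch-histories"), {
    n <- p$n_stocks
    stock_id <- sprintf("S%03d", seq_len(n))
    archetype <- rep_len(archetypes, n)
    r_true <- stats::runif(n, 0.1, 0.8)
    K_true <- exp(stats::runif(n, log(5e3), log(5e5)))
    area_id <- sprintf("A%d", rep_len(seq_len(p$n_areas), n))
    n_coarse <- round(p$coarse_frac * n)
    taxon_level <- rep(6L, n)
    if (n_coarse > 0) {
      coarse_ix <- sample(seq_len(n), n_coarse)
      taxon_level[coarse_ix] <- sample(1:5, n_coarse, replace = TRUE)
    }
    # resilience category from true r, standing in for life-history
    # knowledge; every category interval contains the true r
    r_cat <- ifelse(r_true < 0.4, "low", ifelse(r_true < 0.7, "medium", "high"))
    start_offset <- sample(0:15, n, replace = TRUE)

    yrs <- p$years
    Tn <- length(yrs)
    truth_rows <- vector("list", n)
    catch_rows <- vector("list", n)
    for (i in seq_len(n)) {
      u <- effort_schedule(archetype[i], r_true[i], Tn)
      B <- numeric(Tn + 1)
      Ct <- numeric(Tn)
      B[1] <- K_true[i]
      for (t in seq_len(Tn)) {
        Ct[t] <- u[t] * B[t]
        B[t + 1] <- B[t] + r_true[i] * B[t] * (1 - B[t] / K_true[i]) - Ct[t]
        B[t + 1] <- max(B[t + 1], 1e-6 * K_true[i])
      }
      truth_rows[[i]] <- data.frame(
        stock_id = stock_id[i], year = c(yrs, yrs[Tn] + 1),
        biomass_true = c(B), bbmsy_true = c(B) / (K_true[i] / 2),
        catch_true = c(Ct, NA))
      noise <- stats::rlnorm(Tn, -0.5 * log(1 + p$catch_cv^2),
                             sqrt(log(1 + p$catch_cv^2)))
      reported <- Ct * noise
      reported[seq_len(start_offset[i])] <- NA  # pre-reporting era
      # split across 1-3 regions of the stock's area and management type
      pool <- regions$region_id[regions$area_id == area_id[i] &
                                  regions$managed ==
                                  (archetype[i] %in% c("managed_recovery", "lightly_fished"))]
      if (length(pool) == 0) pool <- regions$region_id[regions$area_id == area_id[i]]
      k <- sample(seq_len(min(3, length(pool))), 1)
      regs <- sample(pool, k)
      share <- stats::runif(k); share <- share / sum(share)
      catch_rows[[i]] <- do.call(rbind, lapply(seq_len(k), function(j) {
        data.frame(region_id = regs[j], stock_id = stock_id[i], year = yrs,
                   catch_tonnes = reported * share[j])
      }))
    }
    list(
      stock_info = data.frame(stock_id = stock_id, area_id = area_id,
                              taxon_level = taxon_level),
      truth_stocks = data.frame(stock_id = stock_id, area_id = area_id,
                                archetype = archetype, r_true = r_true,
                                K_true = K_true, taxon_level = taxon_level,
                                r_category = r_cat,
                                start_year = yrs[1] + start_offset),
      truth_bbmsy = do.call(rbind, truth_rows),
      catch = do.call(rbind, catch_rows)
    )
  })
}

# Truncated normal on [-1, 1] by rejection (vectorized refill).
rtrunc_norm <- function(n, mean = 0, sd = 0.1) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- abs(x) > 1)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate goal layers and mariculture/tourism inputs
#'
#' Draws bounded per-region layers for the precomputed (non-modelled)
#' goals -- statuses from a Beta distribution, trends from a truncated
#' normal on \[-1,1\], pressures and resilience from Beta distributions --
#' plus right-skewed mariculture yields with per-species sustainability and
#' coastal population, and tourism employment inputs with small,
#' right-skewed employment shares. Modelled goals (FIS, MAR, TR) get layer
#' rows with NA status carrying their trend/pressure/resilience. In
#' constant-status mode every status is the constant, trends are 0 and
#' pressure equals resilience.
#'
#' @param world an `ohi_world` (at least `params` and `regions`).
#' @return list of `goal_layers`, `mariculture`, `coastal_population`,
#'   `tourism` data frames.
#' @export
generate_goal_layers <- function(world) {
  p <- world$params
  regions <- world$regions$region_id
  nR <- length(regions)
  precomputed <- c("AO", "NP", "CS", "CP", "LE", "SP", "CW", "BD")
  modelled <- c("FIS", "MAR", "TR")
  goals <- c(precomputed, modelled)
  with_seed(stock_seed(p$seed, "goal-layers"), {
    grid <- expand.grid(region_id = regions, goal_id = goals,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    nr <- nrow(grid)
    if (!is.null(p$constant_status)) {
      c0 <- p$constant_status
      grid$status <- c0
      grid$trend <- 0
      grid$pressure <- 0.5
      grid$resilience <- 0.5
    } else {
      grid$status <- stats::rbeta(nr, p$status_shape[1], p$status_shape[2])
      grid$status[grid$goal_id %in% modelled] <- NA
      grid$trend <- rtrunc_norm(nr, 0, p$trend_sd)
      grid$pressure <- stats::rbeta(nr, p$pressure_shape[1], p$pressure_shape[2])
      grid$resilience <- stats::rbeta(nr, p$resilience_shape[1], p$resilience_shape[2])
      if (p$na_rate > 0) {
        pre <- which(grid$goal_id %in% precomputed)
        drop <- pre[stats::runif(length(pre)) < p$na_rate]
        grid$status[drop] <- NA
      }
    }

    yrs_mar <- utils::tail(p$years, 10)
    mar <- do.call(rbind, lapply(seq_len(nR), function(i) {
      ns <- sample(1:3, 1)
      do.call(rbind, lapply(seq_len(ns), function(s) {
        base <- stats::rlnorm(1, 7, 1.2)
        growth <- stats::runif(1, 0.98, 1.08)
        data.frame(region_id = regions[i],
                   species = sprintf("%s_sp%d", regions[i], s),
                   year = yrs_mar,
                   yield_tonnes = base * growth^(seq_along(yrs_mar) - 1) *
                     stats::rlnorm(length(yrs_mar), 0, 0.1),
                   sustainability = round(stats::rbeta(1, 5, 2), 4))
      }))
    }))
    pop <- data.frame(region_id = regions,
                      coastal_population = round(stats::rlnorm(nR, 12, 1)))
    labor <- stats::rlnorm(nR, 11, 0.8)
    unemp <- stats::rbeta(nR, 2, 18)
    share <- stats::rbeta(nR, 1.5, 30)
    tour <- data.frame(region_id = regions,
                       tourism_employment = round(share * labor * (1 - unemp)),
                       labor_force = round(labor),
                       unemployment_rate = round(unemp, 4),
                       sustainability = round(stats::rbeta(nR, 5, 2), 4))
    list(goal_layers = grid, mariculture = mar, coastal_population = pop,
         tourism = tour)
  })
}

#' @export
print.ohi_world <- function(x, ...) {
  p <- x$params
  cat(sprintf("Synthetic assessment world: %d regions, %d stocks, %d areas, %d-%d (seed %d)\n",
              p$n_regions, p$n_stocks, p$n_areas, min(p$years), max(p$years),
              p$seed))
  if (!is.null(p$constant_status))
    cat(sprintf("  constant-status mode: all statuses = %.3f\n", p$constant_status))
  cat(sprintf("  archetypes: %s\n",
              paste(names(table(x$truth_stocks$archetype)), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic world's input files
#'
#' Emits the CSV dialects the engine consumes, plus the truth tables.
#'
#' @param world an `ohi_world`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("catch", "stock_info", "resilience", "goal_layers",
            "mariculture", "coastal_population", "tourism",
            "truth_stocks", "truth_bbmsy")
  files <- file.path(dir, paste0(tabs, ".csv"))
  for (i in seq_along(tabs)) write_layer(world[[tabs[i]]], files[i])
  invisible(files)
}
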