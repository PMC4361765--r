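# Fisheries sub-goal: turn per-stock B/BMSY into a regional status score.
# Stocks are assessed at FAO-major-area scale; status is aggregated at
# reporting-region scale with catch-share weights.

# Taxonomic-resolution penalty multipliers for taxa reported coarser than
# species level (g = 6 is species, no penalty). Coarse reporting signals
# weak monitoring, so the proxy B/BMSY shrinks toward collapse as g drops.
taxon_penalty <- c(`1` = 0.01, `2` = 0.25, `3` = 0.50, `4` = 0.80, `5` = 0.90)

#' Catch-weighted resilience score of a stock
#'
#' A stock caught in several regions inherits a governance resilience score
#' equal to the mean of the regional fisheries-resilience scores weighted
#' by the stock's mean catch in each region:
#' \deqn{S_r = \sum_z r_z c_z / \sum_j c_j}
#'
#' @param catch_by_region named numeric vector of the stock's mean catch
#'   (tonnes) per region; at least one positive.
#' @param regional_resilience named numeric vector of regional resilience
#'   scores in \[0,1\].
#' @return scalar resilience score in \[0,1\].
#' @examples
#' stock_resilience(c(A = 75, B = 25), c(A = 0.8, B = 0.4)) # 0.7
#' @export
stock_resilience <- function(catch_by_region, regional_resilience) {
  if (any(catch_by_region < 0)) stopf("catches must be >= 0")
  if (sum(catch_by_region) <= 0) stopf("stock has no positive catch")
  missing_r <- setdiff(names(catch_by_region), names(regional_resilience))
  if (length(missing_r) > 0)
    stopf("no resilience score for region(s): %s", paste(missing_r, collapse = ", "))
  r <- regional_resilience[names(catch_by_region)]
  check_range(r, "resilience", 0, 1)
  sum(r * catch_by_region) / sum(catch_by_region)
}

#' Piecewise stock-status score from B/BMSY
#'
#' Scores a stock against the target B/BMSY = 1 with a 5% error buffer.
#' Below the buffer the score equals B/BMSY itself (direct proportionality
#' of the over-fishing penalty); inside the buffer the score is 1; above it
#' the score declines at rate `over_penalty` (under-harvesting is penalized
#' at half the over-harvesting rate by default) down to a floor so that
#' exceptionally productive years are not unduly punished:
#' \deqn{SS = \cases{b & b < 0.95 \cr 1 & 0.95 \le b \le 1.05 \cr
#'   \max\{1 - \alpha (b - 1.05), \beta\} & b > 1.05}}
#'
#' @param bbmsy positive B/BMSY value(s).
#' @param over_penalty slope \eqn{\alpha} of the under-harvest penalty
#'   (default 0.5).
#' @param floor minimum score \eqn{\beta} for under-harvested stocks
#'   (default 0.25).
#' @param buffer half-width of the no-penalty band around 1 (default 0.05).
#' @return stock status score(s) in (0, 1\].
#' @examples
#' stock_status_score(c(0.5, 1, 2.05, 3.05)) # 0.5 1 0.5 0.25
#' @export
stock_status_score <- function(bbmsy, over_penalty = 0.5, floor = 0.25,
                               buffer = 0.05) {
  if (any(is.na(bbmsy))) stopf("'bbmsy' contains NA")
  if (any(bbmsy <= 0)) stopf("'bbmsy' must be > 0")
  if (over_penalty <= 0) stopf("'over_penalty' must be > 0")
  if (floor <= 0 || floor >= 1) stopf("'floor' must be in (0, 1)")
  if (buffer < 0 || buffer >= 1) stopf("'buffer' must be in [0, 1)")
  ifelse(bbmsy < 1 - buffer, bbmsy,
         ifelse(bbmsy <= 1 + buffer, 1,
                pmax(1 - over_penalty * (bbmsy - (1 + buffer)), floor)))
}

#' Proxy B/BMSY for coarsely reported taxa
#'
#' Taxa reported above species level cannot be assessed directly; they are
#' assigned the median species-level B/BMSY of their fishing area and year,
#' shrunk by a penalty that grows as taxonomic resolution coarsens
#' (level 5 = genus-like, multiplier 0.90, down to level 1, multiplier
#' 0.01).
#'
#' @param level taxonomic resolution level, integer 1..5.
#' @param species_level_median positive median of species-level (g = 6)
#'   B/BMSY estimates in the same area and year.
#' @return proxy B/BMSY value.
#' @examples
#' penalized_proxy_bbmsy(5, 1.0) # 0.90
#' penalized_proxy_bbmsy(1, 1.0) # 0.01
#' @export
penalized_proxy_bbmsy <- function(level, species_level_median) {
  if (!all(level %in% 1:5)) stopf("'level' must be an integer in 1..5")
  if (any(is.na(species_level_median)) || any(species_level_median <= 0))
    stopf("'species_level_median' must be > 0")
  unname(taxon_penalty[as.character(level)]) * species_level_median
}

#' Mean catch from the first non-null record
#'
#' The catch weight of a stock in a region is its catch averaged from the
#' first reported (non-null) year through the end of the series, counting
#' zeros (and treating later nulls as zero catch, i.e. non-reporting).
#'
#' @param series numeric catch series, possibly with leading NAs.
#' @return scalar mean catch (tonnes), or NA if the series is all null.
#' @examples
#' mean_catch_from_first_nonnull(c(NA, NA, 10, 20)) # 15
#' @export
mean_catch_from_first_nonnull <- function(series) {
  first <- which(!is.na(series))[1]
  if (is.na(first)) return(NA_real_)
  x <- series[first:length(series)]
  x[is.na(x)] <- 0
  mean(x)
}

#' Regional fisheries status as a weighted geometric mean
#'
#' Aggregates stock status scores into the fisheries status of one region:
#' \deqn{x_{FIS} = \prod_i SS_i^{C_i / \sum C_i}}
#' The geometric mean lets poorly performing stocks pull the score down
#' more than their catch share alone would, valuing catch diversity.
#'
#' @param ss positive stock status scores.
#' @param weights nonnegative catch weights (mean catch per stock); need
#'   not be normalized.
#' @param stock_id optional stock identifiers for the contribution table.
#' @return list with `x_fis` (status in (0,1\]) and `contributions` (data
#'   frame of stock_id, SS, normalized weight); `x_fis` is NA with a
#'   warning when no stock has positive weight.
#' @examples
#' fisheries_status(c(1, 0.25), c(1, 1))$x_fis # 0.5
#' @export
fisheries_status <- function(ss, weights, stock_id = NULL) {
  if (length(ss) == 0 || sum(weights) <= 0) {
    warnf("no stocks with positive catch weight; fisheries status NA")
    return(list(x_fis = NA_real_, contributions = NULL))
  }
  if (length(weights) != length(ss)) stopf("'ss' and 'weights' differ in length")
  if (any(ss <= 0)) stopf("stock status scores must be > 0")
  if (any(weights < 0)) stopf("'weights' must be >= 0")
  w <- weights / sum(weights)
  x <- exp(sum(w * log(ss)))
  if (is.null(stock_id)) stock_id <- paste0("stock", seq_along(ss))
  list(x_fis = x,
       contributions = data.frame(stock_id = stock_id, SS = ss, weight = w,
                                  row.names = NULL))
}

#' Fisheries sub-goal status for every reporting region
#'
#' End-to-end regional scoring: species-level (g = 6) stocks take their
#' assessed B/BMSY in their final assessed year; coarser taxa get the
#' penalized area-year median proxy (falling back to the nearest prior year
#' with species-level assessments in the same area, else excluded with a
#' warning); B/BMSY becomes a stock status score; and each region's status
#' is the geometric mean of the scores of the stocks it catches, weighted
#' by regional mean catch from the first non-null record.
#'
#' @param assessments data frame `stock_id, year, bbmsy` of species-level
#'   assessments (e.g. stacked [assess_stock()] results).
#' @param catch data frame `region_id, stock_id, year, catch_tonnes` of
#'   regional catch for all taxa (empty/NA = null record).
#' @param stock_info data frame `stock_id, area_id, taxon_level` mapping
#'   every taxon to its fishing area and resolution level (6 = species).
#' @param bbmsy_floor proxies are floored here to keep logs finite.
#' @return data frame `region_id, goal_id, status` (goal_id `"FIS"`), with
#'   a `contributions` attribute (per-region stock audit) and an `audit`
#'   attribute (character log of exclusions and fallbacks).
#' @export
fisheries_goal_status <- function(assessments, catch, stock_info,
                                  bbmsy_floor = 1e-4) {
  for (nm in c("stock_id", "year", "bbmsy")) {
    if (!nm %in% names(assessments)) stopf("'assessments' needs column '%s'", nm)
  }
  for (nm in c("region_id", "stock_id", "year", "catch_tonnes")) {
    if (!nm %in% names(catch)) stopf("'catch' needs column '%s'", nm)
  }
  for (nm in c("stock_id", "area_id", "taxon_level")) {
    if (!nm %in% names(stock_info)) stopf("'stock_info' needs column '%s'", nm)
  }
  audit <- character(0)

  # Current B/BMSY per assessed (species-level) stock: final assessed year.
  cur <- do.call(rbind, lapply(split(assessments, assessments$stock_id), function(d) {
    d <- d[!is.na(d$bbmsy), , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    d[which.max(d$year), c("stock_id", "year", "bbmsy")]
  }))
  info <- stock_info
  level_of <- stats::setNames(info$taxon_level, info$stock_id)
  area_of <- stats::setNames(info$area_id, info$stock_id)

  # Species-level medians per area and year (for proxies).
  sp <- assessments[!is.na(assessments$bbmsy) &
                      level_of[as.character(assessments$stock_id)] == 6, ]
  sp$area_id <- area_of[as.character(sp$stock_id)]
  med_tab <- stats::aggregate(bbmsy ~ area_id + year, data = sp, FUN = stats::median)

  area_year_median <- function(area, year) {
    hit <- med_tab[med_tab$area_id == area & med_tab$year <= year, , drop = FALSE]
    if (nrow(hit) == 0) return(list(median = NA_real_, year = NA_integer_))
    hit <- hit[which.max(hit$year), ]
    list(median = hit$bbmsy, year = hit$year)
  }

  # Resolve a current B/BMSY for every taxon appearing in the catch table.
  taxa <- unique(as.character(catch$stock_id))
  last_catch_year <- vapply(split(catch, catch$stock_id), function(d) {
    max(d$year[!is.na(d$catch_tonnes)])
  }, numeric(1))[taxa]
  bb <- stats::setNames(rep(NA_real_, length(taxa)), taxa)
  for (s in taxa) {
    g <- level_of[s]
    if (is.na(g)) {
      audit <- c(audit, sprintf("taxon %s missing from stock_info; excluded", s))
      next
    }
    if (g == 6) {
      hit <- cur[cur$stock_id == s, , drop = FALSE]
      if (nrow(hit) == 0) {
        audit <- c(audit, sprintf("species-level taxon %s has no assessment; excluded", s))
      } else {
        bb[s] <- hit$bbmsy[1]
      }
    } else {
      am <- area_year_median(area_of[s], last_catch_year[s])
      if (is.na(am$median)) {
        audit <- c(audit, sprintf(
          "taxon %s (level %d): no species-level median in area %s up to %d; excluded",
          s, g, area_of[s], as.integer(last_catch_year[s])))
      } else {
        if (am$year < last_catch_year[s]) {
          audit <- c(audit, sprintf(
            "taxon %s: proxy median taken from prior year %d", s, as.integer(am$year)))
        }
        bb[s] <- max(penalized_proxy_bbmsy(g, am$median), bbmsy_floor)
      }
    }
  }

  regions <- sort(unique(as.character(catch$region_id)))
  all_years <- sort(unique(catch$year))
  rows <- vector("list", length(regions))
  contribs <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    rg <- regions[i]
    d <- catch[catch$region_id == rg, , drop = FALSE]
    per_stock <- vapply(split(d, as.character(d$stock_id)), function(ds) {
      series <- ds$catch_tonnes[match(all_years, ds$year)]
      mean_catch_from_first_nonnull(series)
    }, numeric(1))
    per_stock <- per_stock[!is.na(per_stock) & per_stock > 0]
    sids <- names(per_stock)
    scored <- sids[!is.na(bb[sids])]
    dropped <- setdiff(sids, scored)
    if (length(dropped) > 0) {
      audit <- c(audit, sprintf("region %s: %d taxa without B/BMSY excluded (%s)",
                                rg, length(dropped), paste(dropped, collapse = ", ")))
    }
    if (length(scored) == 0) {
      warnf("region %s has no scorable stocks; fisheries status NA", rg)
      rows[[i]] <- data.frame(region_id = rg, goal_id = "FIS", status = NA_real_)
      next
    }
    ss <- stock_status_score(bb[scored])
    fs <- fisheries_status(ss, per_stock[scored], stock_id = scored)
    rows[[i]] <- data.frame(region_id = rg, goal_id = "FIS", status = fs$x_fis)
    contribs[[i]] <- cbind(region_id = rg, fs$contributions)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "contributions") <- do.call(rbind, contribs)
  attr(out, "audit") <- audit
  out
}
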