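# Mariculture sub-goal: sustainability-weighted yield per coastal capita,
# rescaled to a 95th-percentile reference.

#' Sustainability-weighted mariculture yield per capita
#'
#' \deqn{Y_M = \sum_k Y_k S_{M,k} / P_C}
#' Yield is adjusted by coastal population on the assumption that
#' workforce, coastal access and infrastructure scale with it.
#'
#' @param yields per-species yields (tonnes), >= 0.
#' @param sustainability per-species sustainability scores in \[0,1\].
#' @param population coastal population (> 0).
#' @return scalar weighted yield per capita.
#' @examples
#' mariculture_yield(c(100, 50), c(0.5, 1), 100) # 1
#' @export
mariculture_yield <- function(yields, sustainability, population) {
  if (length(yields) != length(sustainability))
    stopf("'yields' and 'sustainability' differ in length")
  if (any(yields < 0)) stopf("'yields' must be >= 0")
  check_range(sustainability, "sustainability", 0, 1)
  if (is.na(population) || population <= 0) stopf("'population' must be > 0")
  sum(yields * sustainability) / population
}

#' Mariculture reference point
#'
#' The reference is the 95th percentile, across regions, of each region's
#' maximum sustainability-weighted yield per capita over the years
#' assessed. A high percentile (rather than the maximum) is used because
#' per-capita yields are strongly right-skewed and the top regions are
#' outliers.
#'
#' @param ym data frame `region_id, year, ym` of per-region-year weighted
#'   yields, or a named vector of per-region maxima.
#' @param prob percentile (default 0.95).
#' @param type quantile interpolation type (default 7, linear between
#'   order statistics).
#' @return scalar reference yield, > 0.
#' @export
mariculture_reference <- function(ym, prob = 0.95, type = 7) {
  maxima <- if (is.data.frame(ym)) {
    vapply(split(ym$ym, ym$region_id), max, numeric(1), na.rm = TRUE)
  } else {
    ym
  }
  if (length(maxima) < 2) stopf("need >= 2 regions for a reference point")
  if (all(maxima <= 0)) stopf("no mariculture signal (all yields zero)")
  stats::quantile(maxima, probs = prob, type = type, names = FALSE)
}

#' Mariculture status
#'
#' \deqn{x_{MAR} = \min(Y_M / Y_{ref}, 1)}
#' Regions above the reference are capped at 1: status is a proportion of
#' a sustainable maximum and cannot meaningfully exceed it.
#'
#' @param ym per-region weighted yield(s) per capita.
#' @param reference reference yield from [mariculture_reference()].
#' @return status value(s) in \[0,1\].
#' @export
mariculture_status <- function(ym, reference) {
  if (is.na(reference) || reference <= 0) stopf("'reference' must be > 0")
  if (any(ym < 0, na.rm = TRUE)) stopf("'ym' must be >= 0")
  pmin(ym / reference, 1)
}

#' Mariculture sub-goal status for every region
#'
#' Computes per-region-year weighted yields from species-level records,
#' sets the cross-region reference, and scores each region on its final
#' assessed year.
#'
#' @param mariculture data frame `region_id, species, year, yield_tonnes,
#'   sustainability`.
#' @param population data frame `region_id, coastal_population`.
#' @param prob,type percentile convention, passed to
#'   [mariculture_reference()].
#' @return data frame `region_id, goal_id, status` (goal_id `"MAR"`), with
#'   the reference in attribute `reference`.
#' @export
mariculture_goal_status <- function(mariculture, population,
                                    prob = 0.95, type = 7) {
  for (nm in c("region_id", "species", "year", "yield_tonnes", "sustainability")) {
    if (!nm %in% names(mariculture)) stopf("'mariculture' needs column '%s'", nm)
  }
  for (nm in c("region_id", "coastal_population")) {
    if (!nm %in% names(population)) stopf("'population' needs column '%s'", nm)
  }
  pop <- stats::setNames(population$coastal_population, population$region_id)
  key <- interaction(mariculture$region_id, mariculture$year, drop = TRUE)
  ym_tab <- do.call(rbind, lapply(split(mariculture, key), function(d) {
    rg <- as.character(d$region_id[1])
    if (!rg %in% names(pop)) stopf("no coastal population for region %s", rg)
    data.frame(region_id = rg, year = d$year[1],
               ym = mariculture_yield(d$yield_tonnes, d$sustainability, pop[rg]))
  }))
  ref <- mariculture_reference(ym_tab, prob = prob, type = type)
  final <- do.call(rbind, lapply(split(ym_tab, ym_tab$region_id), function(d) {
    d[which.max(d$year), ]
  }))
  out <- data.frame(region_id = final$region_id, goal_id = "MAR",
                    status = mariculture_status(final$ym, ref))
  rownames(out) <- NULL
  attr(out, "reference") <- ref
  out
}
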