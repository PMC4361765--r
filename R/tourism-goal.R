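# Tourism & recreation goal: tourism employment share, corrected for
# unemployment and weighted by a sustainability index, rescaled to a
# 90th-percentile reference.

#' Direct tourism employment share
#'
#' \deqn{E_d = E_t / (L_t - L_t U_t)}
#' the proportion of the employed labor force working directly in travel
#' and tourism.
#'
#' @param employment tourism employment \eqn{E_t} (persons), >= 0.
#' @param labor_force total labor force \eqn{L_t} (persons), > 0.
#' @param unemployment unemployment rate \eqn{U_t} in \[0,1).
#' @return employment share(s) in \[0,1\].
#' @examples
#' direct_employment_share(10, 100, 0.5) # 0.2
#' @export
direct_employment_share <- function(employment, labor_force, unemployment) {
  if (any(employment < 0)) stopf("'employment' must be >= 0")
  if (any(labor_force <= 0)) stopf("'labor_force' must be > 0")
  check_range(unemployment, "unemployment", 0, 1)
  employed <- labor_force * (1 - unemployment)
  if (any(employed <= 0)) stopf("employed labor force must be > 0")
  bad <- employment > employed
  if (any(bad))
    stopf("tourism jobs exceed labor force (element %d)", which(bad)[1])
  employment / employed
}

#' Tourism & recreation status
#'
#' Raw regional scores (employment share times sustainability) are
#' rescaled to the 90th percentile across regions; regions at or above the
#' reference score 1 (reported as 100). The P90 reference is used because
#' the top raw scores are extreme outliers and most scores cluster near
#' zero.
#'
#' @param raw_scores per-region raw scores \eqn{E_d S_t}, >= 0.
#' @param prob reference percentile (default 0.90).
#' @param type quantile interpolation type (default 7).
#' @return list with `status` (per-region values in \[0,1\], same order as
#'   input) and `reference`.
#' @export
tourism_status <- function(raw_scores, prob = 0.9, type = 7) {
  if (length(raw_scores) < 2) stopf("need >= 2 regions for a reference point")
  if (any(raw_scores < 0, na.rm = TRUE)) stopf("raw scores must be >= 0")
  if (all(raw_scores[!is.na(raw_scores)] == 0))
    stopf("degenerate raw scores (all zero)")
  ref <- stats::quantile(raw_scores, probs = prob, type = type,
                         names = FALSE, na.rm = TRUE)
  list(status = pmin(raw_scores / ref, 1), reference = ref)
}

#' Tourism & recreation status for every region
#'
#' @param tourism data frame `region_id, tourism_employment, labor_force,
#'   unemployment_rate, sustainability`. Regions with any missing input
#'   get NA status (gap-filling happens, if at all, at the score level).
#' @param prob,type percentile convention.
#' @return data frame `region_id, goal_id, status` (goal_id `"TR"`), with
#'   the reference in attribute `reference`.
#' @export
tourism_goal_status <- function(tourism, prob = 0.9, type = 7) {
  for (nm in c("region_id", "tourism_employment", "labor_force",
               "unemployment_rate", "sustainability")) {
    if (!nm %in% names(tourism)) stopf("'tourism' needs column '%s'", nm)
  }
  complete <- stats::complete.cases(
    tourism[, c("tourism_employment", "labor_force", "unemployment_rate",
                "sustainability")])
  raw <- rep(NA_real_, nrow(tourism))
  raw[complete] <- with(tourism[complete, , drop = FALSE],
                        direct_employment_share(tourism_employment, labor_force,
                                                unemployment_rate) * sustainability)
  ts <- tourism_status(raw, prob = prob, type = type)
  out <- data.frame(region_id = tourism$region_id, goal_id = "TR",
                    status = ts$status)
  rownames(out) <- NULL
  attr(out, "reference") <- ts$reference
  out
}
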