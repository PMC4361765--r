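#' Likely future status of a goal
#'
#' Projects a goal's current status one assessment period ahead by modifying
#' it with its recent trend and the balance of cumulative pressures and
#' resilience:
#' \deqn{\hat x_F = (1+\delta)^{-1}\,[1 + \beta T + (1-\beta)(r - p)]\,x}
#' where \eqn{\delta} is a discount rate (default 0: ocean-health values are
#' largely time-independent) and \eqn{\beta} weights the trend against the
#' pressure--resilience difference (default 0.67, giving the trend twice the
#' importance of pressures and resilience).
#'
#' The raw response can leave \eqn{[0,1]} for extreme trend or
#' pressure--resilience imbalance; because status is a proportion of a
#' reference point, the result is clamped back to \eqn{[0,1]} by default.
#' Set `clamp = FALSE` to obtain the raw model response (e.g. for
#' sensitivity analysis, where the clamped function is flat at the
#' boundary).
#'
#' @param x current status, a fraction in \[0,1\] (NA propagates).
#' @param trend recent trend in \[-1,1\]; values outside are clamped with a
#'   warning.
#' @param pressure,resilience cumulative pressure and resilience scores in
#'   \[0,1\].
#' @param discount_rate discount rate \eqn{\delta \ge 0}.
#' @param trend_weight relative importance of trend \eqn{\beta \in [0,1]}.
#' @param clamp clamp the result to \[0,1\]?
#' @return numeric vector of likely future status values.
#' @examples
#' future_status(0.5, trend = 0.1, pressure = 0.3, resilience = 0.3) # 0.5335
#' future_status(1, trend = 0, pressure = 0.5, resilience = 0.5)     # 1
#' @export
future_status <- function(x, trend, pressure, resilience,
                          discount_rate = 0, trend_weight = 0.67,
                          clamp = TRUE) {
  check_range(x, "status", 0, 1, allow_na = TRUE)
  if (any(!is.na(trend) & abs(trend) > 1)) {
    warnf("trend values outside [-1, 1] clamped")
    trend <- pmin(pmax(trend, -1), 1)
  }
  check_range(pressure, "pressure", 0, 1)
  check_range(resilience, "resilience", 0, 1)
  check_range(trend_weight, "trend_weight", 0, 1)
  if (discount_rate < 0) stopf("'discount_rate' must be >= 0")
  out <- (1 + discount_rate)^-1 *
    (1 + trend_weight * trend + (1 - trend_weight) * (resilience - pressure)) * x
  if (clamp) out <- pmin(pmax(out, 0), 1)
  out
}

#' Goal score from current and likely future status
#'
#' A goal's score is the average of its current and likely future status,
#' reported on a 0--100 scale. NA pairs propagate; a mixed NA/non-NA pair is
#' an input error.
#'
#' @param x current status in \[0,1\] or NA.
#' @param x_future likely future status in \[0,1\] or NA.
#' @return numeric score in \[0,100\] (or NA).
#' @examples
#' goal_score(0.6, 0.8) # 70
#' @export
goal_score <- function(x, x_future) {
  mixed <- xor(is.na(x), is.na(x_future))
  if (any(mixed)) stopf("mixed NA/non-NA status pair (element %d)", which(mixed)[1])
  check_range(x, "status", 0, 1, allow_na = TRUE)
  check_range(x_future, "future status", 0, 1, allow_na = TRUE)
  100 * (x + x_future) / 2
}

#' Overall Index score from goal scores
#'
#' The Index is the weighted mean of the goal scores,
#' \eqn{I = \sum_i \alpha_i G_i} with weights summing to one. Goals scored
#' NA (not relevant to a region) are excluded and the remaining weights
#' renormalized, so a region is judged only on the goals that apply to it;
#' set `na_exclude = FALSE` to propagate NA instead.
#'
#' @param goal_scores numeric vector of per-goal scores in \[0,100\],
#'   possibly NA; names identify goals.
#' @param weights nonnegative goal weights (default equal); matched by name
#'   when both are named.
#' @param na_exclude drop NA goals and renormalize weights (default TRUE)?
#' @return scalar Index score in \[0,100\].
#' @examples
#' index_score(c(80, 60))      # 70
#' index_score(c(80, 60, NA))  # 70
#' @export
index_score <- function(goal_scores, weights = NULL, na_exclude = TRUE) {
  n <- length(goal_scores)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stopf("'weights' length %d != %d goals", length(weights), n)
  if (!is.null(names(weights)) && !is.null(names(goal_scores))) {
    if (!all(names(goal_scores) %in% names(weights)))
      stopf("weights missing for goals: %s",
            paste(setdiff(names(goal_scores), names(weights)), collapse = ", "))
    weights <- weights[names(goal_scores)]
  }
  if (any(weights < 0)) stopf("'weights' must be nonnegative")
  if (sum(weights) <= 0) stopf("'weights' must have a positive sum")
  check_range(goal_scores, "goal score", 0, 100, allow_na = TRUE)
  ok <- !is.na(goal_scores)
  if (!any(ok)) stopf("no scorable goals (all NA)")
  if (!na_exclude && !all(ok)) return(NA_real_)
  sum(weights[ok] * goal_scores[ok]) / sum(weights[ok])
}

#' Compare two assessments region by region
#'
#' Computes signed score deltas (`b - a`) per region and goal between two
#' assessments, e.g. two consecutive annual index calculations. Regions
#' present in only one table get NA deltas and a warning. Deltas are
#' computed on full precision, before any display rounding.
#'
#' @param a,b long-format score tables with columns `region_id`, `goal_id`,
#'   `score` (the `"Index"` goal id holds the overall score), as produced by
#'   [scores_table()] / [read_scores()].
#' @return an object of class `ohi_comparison`: a long data frame of deltas
#'   plus a summary (mean and SD of the Index deltas) available via
#'   `print()`.
#' @export
compare_assessments <- function(a, b) {
  for (nm in c("region_id", "goal_id", "score")) {
    if (!nm %in% names(a) || !nm %in% names(b))
      stopf("score tables need column '%s'", nm)
  }
  regions <- sort(unique(c(a$region_id, b$region_id)))
  unmatched <- c(setdiff(a$region_id, b$region_id), setdiff(b$region_id, a$region_id))
  if (length(unmatched) > 0)
    warnf("regions present in only one assessment: %s",
          paste(sort(unique(unmatched)), collapse = ", "))
  goals <- sort(unique(c(a$goal_id, b$goal_id)))
  grid <- expand.grid(region_id = regions, goal_id = goals,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$region_id, d$goal_id, sep = "\r")
  sa <- a$score[match(key(grid), key(a))]
  sb <- b$score[match(key(grid), key(b))]
  grid$score_a <- sa
  grid$score_b <- sb
  grid$delta <- sb - sa
  idx <- grid$delta[grid$goal_id == "Index"]
  out <- structure(
    list(deltas = grid,
         index_mean = mean(idx, na.rm = TRUE),
         index_sd = stats::sd(idx, na.rm = TRUE)),
    class = "ohi_comparison")
  out
}

#' @export
print.ohi_comparison <- function(x, ...) {
  n <- length(unique(x$deltas$region_id))
  cat("Assessment comparison over", n, "regions\n")
  cat(sprintf("Index delta (b - a): mean %.2f, SD %.2f\n",
              x$index_mean, x$index_sd))
  idx <- x$deltas[x$deltas$goal_id == "Index" & !is.na(x$deltas$delta), ]
  if (nrow(idx) > 0) {
    ord <- order(idx$delta, decreasing = TRUE)
    top <- utils::head(idx[ord, c("region_id", "delta")], 5)
    cat("Largest increases:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Pairwise Pearson correlations between goals
#'
#' Correlates each pair of goal scores across regions using
#' pairwise-complete observations (NA goals differ by region, so listwise
#' deletion would discard most of the table). Pairs with fewer than three
#' complete observations get an NA coefficient and a warning.
#'
#' @param scores either a long score table (`region_id`, `goal_id`,
#'   `score`) or a numeric matrix/data frame with regions as rows and goals
#'   as columns. The `"Index"` column, if present, is dropped.
#' @return an object of class `ohi_cor` with elements `r` (correlation
#'   matrix, unit diagonal), `p` (two-sided p-values) and `n` (complete
#'   observations per pair).
#' @export
goal_correlations <- function(scores) {
  m <- if (is.data.frame(scores) && all(c("region_id", "goal_id", "score") %in% names(scores))) {
    scores_wide(scores)
  } else {
    as.matrix(scores)
  }
  m <- m[, colnames(m) != "Index", drop = FALSE]
  g <- ncol(m)
  if (g < 2) stopf("need at least two goals to correlate")
  r <- p <- nobs <- matrix(NA_real_, g, g, dimnames = list(colnames(m), colnames(m)))
  diag(r) <- 1; diag(p) <- 0
  diag(nobs) <- colSums(!is.na(m))
  for (i in seq_len(g - 1)) {
    for (j in seq(i + 1, g)) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      nobs[i, j] <- nobs[j, i] <- sum(ok)
      if (sum(ok) < 3) {
        warnf("pair %s-%s has %d complete observations (< 3); correlation set NA",
              colnames(m)[i], colnames(m)[j], sum(ok))
        next
      }
      ct <- stats::cor.test(m[ok, i], m[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = nobs), class = "ohi_cor")
}

#' @export
print.ohi_cor <- function(x, digits = 2, ...) {
  cat("Pairwise Pearson goal correlations (pairwise-complete)\n")
  print(round(x$r, digits))
  sig <- sum(x$p < 0.05 & upper.tri(x$p), na.rm = TRUE)
  cat(sprintf("%d of %d pairs significant at p < 0.05\n",
              sig, sum(upper.tri(x$p))))
  invisible(x)
}

# Long score table -> regions x goals matrix.
scores_wide <- function(scores) {
  regions <- sort(unique(scores$region_id))
  goals <- unique(scores$goal_id)
  m <- matrix(NA_real_, length(regions), length(goals),
              dimnames = list(regions, goals))
  m[cbind(match(scores$region_id, regions), match(scores$goal_id, goals))] <-
    scores$score
  m
}
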