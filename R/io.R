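# CSV layer IO, run configuration, and the top-level assessment driver.

#' Read a long-format data layer
#'
#' Strict CSV reader for layer files: checks the expected columns are
#' present, coerces declared numeric columns (erroring with the row number
#' on non-numeric cells), turns empty cells into NA, and rejects duplicate
#' keys.
#'
#' @param path CSV file path.
#' @param columns character vector of required column names.
#' @param numeric_cols columns that must parse as numeric (default: all
#'   except identifier-like columns ending in `_id`, `species`,
#'   `archetype`, `r_category`, `goal_id`).
#' @param key_cols columns whose combination must be unique (NULL skips
#'   the check).
#' @return data frame.
#' @export
read_layer <- function(path, columns, numeric_cols = NULL, key_cols = NULL) {
  if (!file.exists(path)) stopf("layer file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing_cols <- setdiff(columns, names(d))
  if (length(missing_cols) > 0)
    stopf("%s: missing column(s) %s", basename(path),
          paste(missing_cols, collapse = ", "))
  if (is.null(numeric_cols)) {
    idlike <- grepl("_id$|^species$|^archetype$|^r_category$|^managed$", columns)
    numeric_cols <- columns[!idlike]
  }
  for (nm in numeric_cols) {
    if (is.character(d[[nm]])) {
      v <- suppressWarnings(as.numeric(d[[nm]]))
      bad <- which(!is.na(d[[nm]]) & is.na(v))
      if (length(bad) > 0)
        stopf("%s: non-numeric value in column '%s' at row %d", basename(path),
              nm, bad[1])
      d[[nm]] <- v
    }
  }
  if (!is.null(key_cols)) {
    key <- do.call(paste, c(d[key_cols], sep = "\r"))
    dup <- which(duplicated(key))
    if (length(dup) > 0)
      stopf("%s: duplicate key (%s) at row %d", basename(path),
            paste(unlist(d[dup[1], key_cols]), collapse = ", "), dup[1])
  }
  d
}

#' Write a data layer as CSV
#'
#' UTF-8, "." decimal, NA as empty cell; the byte-stable inverse of
#' [read_layer()].
#'
#' @param d data frame.
#' @param path output path.
#' @param digits significant digits for numeric columns (NULL = full
#'   precision via `format(..., digits = 15)`).
#' @return invisibly, `path`.
#' @export
write_layer <- function(d, path, digits = NULL) {
  d2 <- d
  for (nm in names(d2)) {
    if (is.numeric(d2[[nm]])) {
      v <- if (is.null(digits)) format(d2[[nm]], digits = 15, trim = TRUE,
                                       scientific = FALSE)
           else formatC(d2[[nm]], digits = digits, format = "f")
      v[is.na(d2[[nm]])] <- NA
      d2[[nm]] <- v
    }
  }
  utils::write.csv(d2, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Assessment run configuration
#'
#' Collects every tunable of a run: goal list and weights, future-status
#' parameters, stock-status parameters, catch-MSY settings, percentile
#' conventions, NA policy, seed and output precision. Round-trips through
#' YAML unchanged via [write_config()] / [read_config()].
#'
#' @param goals goal identifiers entering the Index (sub-goals FIS and MAR
#'   combine into FP first).
#' @param weights per-goal Index weights (default equal).
#' @param discount_rate,trend_weight future-status parameters.
#' @param over_penalty,ss_floor,ss_buffer stock-status parameters.
#' @param n_draws,k_multiplier,uniform_bounds,collapse_frac,min_years
#'   catch-MSY settings.
#' @param mean_mode `"depletion"` or `"biomass"` B/BMSY averaging.
#' @param mar_percentile,tr_percentile,quantile_type percentile reference
#'   conventions.
#' @param na_exclude exclude NA goals and renormalize Index weights?
#' @param use_precomputed goal ids whose status is taken from the goal-layer
#'   file even if a model exists for them (e.g. `c("FIS","MAR","TR")`).
#' @param seed integer run seed.
#' @param precision decimal places written to score files.
#' @return list of class `ohi_config`.
#' @export
ohi_config <- function(goals = c("FP", "AO", "NP", "CS", "CP", "LE", "TR",
                                 "SP", "CW", "BD"),
                       weights = NULL,
                       discount_rate = 0, trend_weight = 0.67,
                       over_penalty = 0.5, ss_floor = 0.25, ss_buffer = 0.05,
                       n_draws = 10000, k_multiplier = 100,
                       uniform_bounds = c(0.01, 1), collapse_frac = 0.01,
                       min_years = 10, mean_mode = "depletion",
                       mar_percentile = 0.95, tr_percentile = 0.9,
                       quantile_type = 7, na_exclude = TRUE,
                       use_precomputed = character(0),
                       seed = 1, precision = 6) {
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(goals)), goals)
  structure(list(goals = goals, weights = weights,
                 discount_rate = discount_rate, trend_weight = trend_weight,
                 over_penalty = over_penalty, ss_floor = ss_floor,
                 ss_buffer = ss_buffer, n_draws = n_draws,
                 k_multiplier = k_multiplier, uniform_bounds = uniform_bounds,
                 collapse_frac = collapse_frac, min_years = min_years,
                 mean_mode = mean_mode, mar_percentile = mar_percentile,
                 tr_percentile = tr_percentile, quantile_type = quantile_type,
                 na_exclude = na_exclude, use_precomputed = use_precomputed,
                 seed = seed, precision = precision),
            class = "ohi_config")
}

#' @rdname ohi_config
#' @param config an `ohi_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  raw <- unclass(config)
  raw$weights <- as.list(raw$weights)  # keep goal names through YAML
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname ohi_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(ohi_config, raw[setdiff(names(raw), "weights")])
  if (!is.null(raw$weights)) cfg$weights <- unlist(raw$weights)
  cfg
}

# Conventional file names inside a layer directory.
layer_spec <- list(
  goal_layers = c("region_id", "goal_id", "status", "trend", "pressure", "resilience"),
  catch = c("region_id", "stock_id", "year", "catch_tonnes"),
  stock_info = c("stock_id", "area_id", "taxon_level"),
  resilience = c("region_id", "resilience"),
  mariculture = c("region_id", "species", "year", "yield_tonnes", "sustainability"),
  coastal_population = c("region_id", "coastal_population"),
  tourism = c("region_id", "tourism_employment", "labor_force",
              "unemployment_rate", "sustainability")
)

read_layer_dir <- function(dir) {
  layers <- list()
  for (nm in names(layer_spec)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(f)) {
      key <- switch(nm,
                    goal_layers = c("region_id", "goal_id"),
                    catch = c("region_id", "stock_id", "year"),
                    mariculture = c("region_id", "species", "year"),
                    resilience = "region_id",
                    coastal_population = "region_id",
                    tourism = "region_id",
                    stock_info = "stock_id")
      layers[[nm]] <- read_layer(f, layer_spec[[nm]], key_cols = key)
    }
  }
  layers
}

#' Run a full assessment
#'
#' Chains the goal models into region scores: assesses every species-level
#' stock with the catch-MSY model and scores the fisheries sub-goal,
#' scores mariculture and tourism against their percentile references,
#' merges precomputed statuses for the remaining goals, projects likely
#' future status, averages current and future status into goal scores,
#' combines the FIS and MAR sub-goals into food provision (FP, equal
#' sub-goal weights), and aggregates goal scores into the Index.
#'
#' @param layers a directory containing the layer CSVs (see
#'   [write_world()] for the dialects), an `ohi_world`, or a named list of
#'   data frames.
#' @param config an [ohi_config()].
#' @return an object of class `ohi_assessment` with `scores` (long table:
#'   region_id, goal_id, score, including sub-goals and the `Index` rows),
#'   `statuses`, `audit` (parameter/seed/gap log) and `config_hash`.
#' @export
run_assessment <- function(layers, config = ohi_config()) {
  if (is.character(layers)) layers <- read_layer_dir(layers)
  if (inherits(layers, "ohi_world")) {
    layers <- layers[intersect(names(layer_spec), names(layers))]
  }
  if (is.null(layers$goal_layers)) stopf("missing required layer: goal_layers")
  gl <- layers$goal_layers
  audit <- c(sprintf("config_hash=%s", object_hash(unclass(config))),
             sprintf("seed=%d", config$seed))

  subgoals <- list(FP = c("FIS", "MAR"))
  needed <- unique(c(unlist(subgoals[intersect(names(subgoals), config$goals)]),
                     setdiff(config$goals, names(subgoals))))
  modelled <- setdiff(intersect(c("FIS", "MAR", "TR"), needed),
                      config$use_precomputed)

  statuses <- gl[, c("region_id", "goal_id", "status")]
  replace_status <- function(statuses, st) {
    key <- paste(statuses$region_id, statuses$goal_id)
    hit <- match(paste(st$region_id, st$goal_id), key)
    new <- st[is.na(hit), , drop = FALSE]
    statuses$status[hit[!is.na(hit)]] <- st$status[!is.na(hit)]
    if (nrow(new) > 0) {
      # goal rows absent from the layer file get NA trend/pressure/resilience
      statuses <- rbind(statuses, new[, c("region_id", "goal_id", "status")])
    }
    statuses
  }

  if ("FIS" %in% modelled) {
    for (nm in c("catch", "stock_info", "resilience")) {
      if (is.null(layers[[nm]])) stopf("missing required layer: %s", nm)
    }
    fis <- compute_fisheries_layer(layers, config)
    statuses <- replace_status(statuses, fis$status)
    audit <- c(audit, fis$audit)
  }
  if ("MAR" %in% modelled) {
    for (nm in c("mariculture", "coastal_population")) {
      if (is.null(layers[[nm]])) stopf("missing required layer: %s", nm)
    }
    mar <- mariculture_goal_status(layers$mariculture, layers$coastal_population,
                                   prob = config$mar_percentile,
                                   type = config$quantile_type)
    statuses <- replace_status(statuses, mar)
    audit <- c(audit, sprintf("MAR reference=%.6g", attr(mar, "reference")))
  }
  if ("TR" %in% modelled) {
    if (is.null(layers$tourism)) stopf("missing required layer: tourism")
    tr <- tourism_goal_status(layers$tourism, prob = config$tr_percentile,
                              type = config$quantile_type)
    statuses <- replace_status(statuses, tr)
    audit <- c(audit, sprintf("TR reference=%.6g", attr(tr, "reference")))
  }

  # future-status projection + goal score with layer trend/pressure/resilience
  key_gl <- paste(gl$region_id, gl$goal_id)
  sc <- statuses[statuses$goal_id %in% needed, , drop = FALSE]
  m <- match(paste(sc$region_id, sc$goal_id), key_gl)
  trend <- ifelse(is.na(m), 0, gl$trend[m])
  pressure <- ifelse(is.na(m), 0.5, gl$pressure[m])
  resilience <- ifelse(is.na(m), 0.5, gl$resilience[m])
  trend[is.na(trend)] <- 0
  pressure[is.na(pressure)] <- 0.5
  resilience[is.na(resilience)] <- 0.5
  xf <- future_status(sc$status, trend, pressure, resilience,
                      discount_rate = config$discount_rate,
                      trend_weight = config$trend_weight)
  sc$score <- goal_score(sc$status, xf)

  regions <- sort(unique(sc$region_id))
  rows <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    d <- sc[sc$region_id == regions[i], , drop = FALSE]
    g <- stats::setNames(d$score, d$goal_id)
    # sub-goal combination (equal sub-goal weights)
    combined <- g
    for (parent in intersect(names(subgoals), config$goals)) {
      kids <- subgoals[[parent]]
      have <- kids[kids %in% names(g) & !is.na(g[kids])]
      combined[parent] <- if (length(have) > 0) mean(g[have]) else NA_real_
    }
    top <- combined[config$goals]
    names(top) <- config$goals
    idx <- index_score(top, config$weights, na_exclude = config$na_exclude)
    rows[[i]] <- data.frame(
      region_id = regions[i],
      goal_id = c(config$goals, setdiff(names(g), config$goals), "Index"),
      score = c(unname(top), unname(g[setdiff(names(g), config$goals)]), idx))
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  audit <- c(audit, sprintf("regions=%d goals=%d", length(regions),
                            length(config$goals)))
  structure(list(scores = scores, statuses = statuses, config = config,
                 audit = audit,
                 config_hash = object_hash(unclass(config))),
            class = "ohi_assessment")
}

# Catch-MSY + fisheries sub-goal over a layer list; returns status df + audit.
compute_fisheries_layer <- function(layers, config) {
  catch <- layers$catch
  info <- layers$stock_info
  res <- stats::setNames(layers$resilience$resilience,
                         layers$resilience$region_id)
  audit <- character(0)
  yrs <- sort(unique(catch$year))
  species <- info$stock_id[info$taxon_level == 6]
  r_cat_tab <- if (!is.null(layers$truth_stocks)) {
    stats::setNames(layers$truth_stocks$r_category, layers$truth_stocks$stock_id)
  } else NULL
  assessments <- vector("list", length(species))
  for (i in seq_along(species)) {
    s <- species[i]
    d <- catch[catch$stock_id == s, , drop = FALSE]
    # area-level series: stock catch summed over regions
    agg <- vapply(split(d$catch_tonnes, d$year), function(v) {
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
    }, numeric(1))
    series <- agg[as.character(yrs)]
    cr <- vapply(split(d, d$region_id), function(dd) {
      mean_catch_from_first_nonnull(dd$catch_tonnes[order(dd$year)])
    }, numeric(1))
    cr <- cr[!is.na(cr)]
    sr <- stock_resilience(cr, res)
    r_cat <- if (!is.null(r_cat_tab) && !is.na(r_cat_tab[s])) r_cat_tab[s] else "medium"
    fit <- tryCatch(
      assess_stock(series, years = yrs, resilience = sr, n = config$n_draws,
                   seed = config$seed, stock_id = s, r_category = r_cat,
                   k_multiplier = config$k_multiplier,
                   uniform_bounds = config$uniform_bounds,
                   collapse_frac = config$collapse_frac,
                   mean_mode = config$mean_mode,
                   min_years = config$min_years),
      error = function(e) e)
    if (inherits(fit, "error")) {
      audit <- c(audit, sprintf("stock %s skipped: %s", s, conditionMessage(fit)))
      next
    }
    audit <- c(audit, sprintf(
      "stock %s: prior=%s resilience=%.3f viable=%d/%d seed=%d%s",
      s, fit$prior$mode, sr, fit$n_viable, fit$n_sampled, fit$seed,
      if (fit$unassessable) " UNASSESSABLE" else ""))
    if (fit$unassessable) next
    assessments[[i]] <- data.frame(stock_id = s, year = fit$years,
                                   bbmsy = fit$bbmsy)
  }
  assessments <- do.call(rbind, assessments)
  if (is.null(assessments)) stopf("no assessable species-level stocks")
  st <- fisheries_goal_status(assessments, catch, info)
  audit <- c(audit, attr(st, "audit"))
  list(status = st, audit = audit, assessments = assessments)
}

#' @export
print.ohi_assessment <- function(x, ...) {
  idx <- x$scores[x$scores$goal_id == "Index", ]
  cat(sprintf("Ocean-health assessment: %d regions, %d goals\n",
              nrow(idx), length(x$config$goals)))
  cat(sprintf("Index: mean %.1f, range %.0f-%.0f\n",
              mean(idx$score, na.rm = TRUE), min(idx$score, na.rm = TRUE),
              max(idx$score, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.ohi_assessment <- function(object, ...) {
  m <- scores_wide(object$scores)
  cat("Goal score means across regions:\n")
  print(round(colMeans(m, na.rm = TRUE), 1))
  invisible(m)
}

#' @export
plot.ohi_assessment <- function(x, ...) {
  m <- scores_wide(x$scores)
  graphics::barplot(sort(m[, "Index"]), las = 2, ylim = c(0, 100),
                    ylab = "Index score", main = "Overall Index by region", ...)
  graphics::abline(h = mean(m[, "Index"], na.rm = TRUE), lty = 2)
  invisible(x)
}

#' Long score table of an assessment
#'
#' @param assessment an `ohi_assessment`.
#' @return data frame `region_id, goal_id, score` (goal_id `"Index"` rows
#'   carry the overall score).
#' @export
scores_table <- function(assessment) assessment$scores

#' Write / read a scores file
#'
#' Scores are written at the configured precision (full precision is kept
#' internally; display rounding is separate), so a write-read round trip
#' reproduces values exactly at the declared precision.
#'
#' @param assessment an `ohi_assessment` (or a long score table).
#' @param path CSV path.
#' @param precision decimal places (default from the assessment's config).
#' @return `read_scores()`: the long score table.
#' @export
write_scores <- function(assessment, path, precision = NULL) {
  d <- if (inherits(assessment, "ohi_assessment")) assessment$scores else assessment
  if (is.null(precision)) {
    precision <- if (inherits(assessment, "ohi_assessment"))
      assessment$config$precision else 6
  }
  d$score <- round(d$score, precision)
  write_layer(d, path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  read_layer(path, c("region_id", "goal_id", "score"),
             key_cols = c("region_id", "goal_id"))
}

#' Round half away from zero
#'
#' Display rounding used for reported integer scores (base `round()` uses
#' round-half-even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
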