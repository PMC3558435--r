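#' Pool occupancy reports by information-score-weighted mean
#'
#' The site occupancy is the weighted mean of the available report values,
#' with weights given by each report's information score:
#' \deqn{\bar{x}_w = \sum_i w_i x_i / \sum_i w_i.}
#' Full floating-point precision is retained; the summary also carries the
#' value rounded half-away to 1 decimal, the precision at which occupancy
#' is conventionally tabulated.
#'
#' @param x numeric vector of occupancy values (people per household or per
#'   structure), or a scored registry data frame with columns
#'   `occupancy_value` and `score`.
#' @param w weights (information scores); ignored when `x` is a data frame.
#' @return an `occupancy_summary` object with `weighted_mean`,
#'   `weighted_mean_1dp`, `total_weight`, `n_reports` and a `contributions`
#'   data frame of (x_i, w_i).
#' @export
weighted_mean_occupancy <- function(x, w = NULL) {
  if (is.data.frame(x)) {
    w <- x$score
    x <- x$occupancy_value
  }
  if (length(x) == 0L) stop("no occupancy information")
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x))
  if (any(!is.finite(x)) || any(x <= 0)) stop("occupancy values must be positive")
  if (any(w <= 0)) stop("weights must be positive")
  wm <- sum(w * x) / sum(w)
  structure(list(weighted_mean = wm,
                 weighted_mean_1dp = round_half_away(wm, 1),
                 total_weight = sum(w), n_reports = length(x),
                 contributions = data.frame(occupancy_value = x, weight = w)),
            class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat(sprintf(
    "Weighted mean occupancy: %.4g (%.1f at table precision), %d report%s, total weight %g\n",
    x$weighted_mean, x$weighted_mean_1dp, x$n_reports,
    if (x$n_reports == 1) "" else "s", x$total_weight))
  invisible(x)
}

#' People per structure from per-household occupancy
#'
#' Where the pooled occupancy is per household but structures hold several
#' households (e.g. long multi-household sheds with about 5 households per
#' shed, giving 6.5 x 5 = 32.5 people per structure), the per-structure
#' occupancy is the product of the household occupancy and the
#' households-per-structure multiplier. The multiplier defaults to 1, i.e.
#' one household (or one per-structure report) per structure.
#'
#' @param occupancy_per_household people per household (positive).
#' @param households_per_structure households per residential structure
#'   (>= 1).
#' @return people per structure.
#' @export
effective_structure_occupancy <- function(occupancy_per_household,
                                          households_per_structure = 1) {
  stopifnot(occupancy_per_household > 0)
  if (households_per_structure < 1)
    stop("households_per_structure must be >= 1")
  occupancy_per_household * households_per_structure
}

#' Population estimate from a structure count and occupancy
#'
#' The estimator is the product of (i) the consensus residential structure
#' count and (ii) the mean people per residential structure, rounded half
#' away from zero to a whole number of people.
#'
#' @param mean_structure_count consensus residential structure count
#'   (non-negative integer, from [consensus_mean_count()]).
#' @param structure_occupancy people per residential structure (positive).
#' @param provenance optional list recording the inputs (counts, reports,
#'   scores) that produced the estimate.
#' @return a `population_estimate` object with `mean_structure_count`,
#'   `structure_occupancy`, `population` and `provenance`.
#' @export
estimate_population <- function(mean_structure_count, structure_occupancy,
                                provenance = list()) {
  if (mean_structure_count < 0) stop("structure count must be non-negative")
  if (structure_occupancy <= 0) stop("structure occupancy must be positive")
  structure(list(mean_structure_count = as.integer(mean_structure_count),
                 structure_occupancy = structure_occupancy,
                 population = as.integer(
                   round_half_away(mean_structure_count * structure_occupancy)),
                 provenance = provenance),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("Population estimate: %s structures x %.4g per structure = %s people\n",
              format(x$mean_structure_count, big.mark = ","),
              x$structure_occupancy,
              format(x$population, big.mark = ",")))
  invisible(x)
}

#' Site configuration
#'
#' @param name site name.
#' @param analysis_date analysis date (`Date` or parseable string).
#' @param site_kind `"camp"` or `"urban"` (controls report eligibility).
#' @param households_per_structure households per residential structure
#'   (>= 1; default 1).
#' @param reference_population optional reference ("gold standard")
#'   population figure for validation.
#' @param count_override optional residential count to use in place of the
#'   consensus mean, e.g. a comparable-area count when the analysts covered
#'   different extents.
#' @param category_map optional named logical vector mapping structure
#'   categories to residential status (needed when marks are supplied).
#' @return a `site_config` object.
#' @export
site_config <- function(name, analysis_date, site_kind = c("camp", "urban"),
                        households_per_structure = 1,
                        reference_population = NULL, count_override = NULL,
                        category_map = NULL) {
  site_kind <- match.arg(site_kind)
  if (households_per_structure < 1)
    stop("households_per_structure must be >= 1")
  structure(list(name = name, analysis_date = as_date_strict(analysis_date),
                 site_kind = site_kind,
                 households_per_structure = households_per_structure,
                 reference_population = reference_population,
                 count_override = count_override,
                 category_map = category_map),
            class = "site_config")
}

#' Remote imagery-based population estimate for one site
#'
#' The main fitting function. Runs the full estimation chain for a site:
#' tabulates duplicate analyst counts (or accepts them directly), takes the
#' consensus mean residential count, filters and scores the occupancy-report
#' registry under the hierarchy of evidence, pools occupancy by
#' information-score-weighted mean, applies the households-per-structure
#' multiplier, and multiplies count by occupancy to estimate the population.
#' When the site configuration carries a reference population, the estimate
#' is validated against it.
#'
#' @param counts per-analyst residential structure counts: a numeric vector
#'   (one count per analyst), a `count_table` from [tabulate_counts()], or a
#'   `structure_marks` data frame (tabulated internally; requires
#'   `category_map` in `site`).
#' @param reports occupancy-report registry data frame (see
#'   [score_reports()] for columns). Ineligible reports are filtered out and
#'   logged, not an error — unless none survive.
#' @param site a [site_config()].
#' @param rubric a [load_rubric()] object.
#' @param compat logical; when `TRUE` the pooled occupancy is rounded
#'   half-away to 1 decimal before multiplication, matching hand computation
#'   from tabulated occupancies. Default `FALSE` (full precision).
#' @return an object of class `popest`; see [print.popest()],
#'   [summary.popest()], [coef.popest()], [confint.popest()].
#' @examples
#' reports <- data.frame(report_id = "r1", occupancy_value = 6.0,
#'                       unit = "per_structure", provenance = "site_current",
#'                       method = "census_registration_surveillance",
#'                       collection_date = "2005-06-01")
#' fit <- popest(c(5423, 6208), reports,
#'               site_config("Breidjing", "2006-01-30"))
#' fit
#' @export
popest <- function(counts, reports, site, rubric = default_rubric(),
                   compat = FALSE) {
  stopifnot(inherits(site, "site_config"))
  count_table <- NULL
  if (inherits(counts, "structure_marks")) {
    count_table <- tabulate_counts(counts)
    analyst_counts <- count_table$residential_count
  } else if (inherits(counts, "count_table") ||
             (is.data.frame(counts) && "residential_count" %in% names(counts))) {
    count_table <- counts
    analyst_counts <- counts$residential_count
  } else {
    analyst_counts <- as.numeric(counts)
  }
  mean_count <- if (!is.null(site$count_override))
    as.integer(site$count_override) else consensus_mean_count(analyst_counts)

  agreement <- if (length(analyst_counts) == 2L)
    pairwise_agreement(analyst_counts[1], analyst_counts[2]) else NULL

  filt <- filter_eligible(reports, site$analysis_date, site$site_kind)
  if (!nrow(filt$eligible)) stop("no occupancy information")
  scored <- score_reports(filt$eligible, site$analysis_date, rubric)
  occ <- weighted_mean_occupancy(scored)

  # a registry that is entirely per-structure needs no multiplier
  all_per_structure <- all(scored$unit == "per_structure")
  multiplier <- if (all_per_structure) 1 else site$households_per_structure
  pooled <- if (compat) occ$weighted_mean_1dp else occ$weighted_mean
  structure_occ <- effective_structure_occupancy(pooled, multiplier)

  est <- estimate_population(mean_count, structure_occ,
                             provenance = list(
                               analyst_counts = analyst_counts,
                               count_override = site$count_override,
                               scored_reports = scored,
                               rubric_version = rubric$version,
                               compat = compat))
  validation <- if (!is.null(site$reference_population))
    compare_reference(est$population, site$reference_population) else NULL

  structure(list(site = site, count_table = count_table,
                 analyst_counts = analyst_counts, agreement = agreement,
                 mean_structure_count = mean_count,
                 excluded_reports = filt$excluded, scored_reports = scored,
                 occupancy = occ, households_per_structure = multiplier,
                 structure_occupancy = structure_occ,
                 information_index = information_index(scored),
                 estimate = est, population = est$population,
                 validation = validation, compat = compat,
                 rubric_version = rubric$version),
            class = "popest")
}

#' @describeIn popest compact display of the fitted estimate.
#' @param x,object a `popest` object.
#' @param ... unused.
#' @export
print.popest <- function(x, ...) {
  cat("Remote imagery-based population estimate -- ", x$site$name, "\n", sep = "")
  cat(sprintf("  Consensus residential structure count: %s (%d analyst count%s%s)\n",
              format(x$mean_structure_count, big.mark = ","),
              length(x$analyst_counts),
              if (length(x$analyst_counts) == 1) "" else "s",
              if (!is.null(x$site$count_override)) "; override applied" else ""))
  if (x$households_per_structure != 1)
    cat(sprintf("  Structure occupancy: %.4g x %g households/structure = %.4g\n",
                x$occupancy$weighted_mean, x$households_per_structure,
                x$structure_occupancy))
  else
    cat(sprintf("  Structure occupancy (weighted mean of %d report%s): %.4g\n",
                x$occupancy$n_reports,
                if (x$occupancy$n_reports == 1) "" else "s",
                x$structure_occupancy))
  cat(sprintf("  Estimated population: %s\n",
              format(x$population, big.mark = ",")))
  cat(sprintf("  Amount-of-information index: %d (%d report%s)\n",
              x$information_index, x$occupancy$n_reports,
              if (x$occupancy$n_reports == 1) "" else "s"))
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}

#' @describeIn popest full account: duplicate-count agreement, per-report
#'   scores and contributions, exclusions, validation.
#' @export
summary.popest <- function(object, ...) {
  structure(list(fit = object), class = "summary.popest")
}

#' @export
print.summary.popest <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$agreement)) {
    cat("\nDuplicate-count agreement (residential): ")
    cat(sprintf("%d (%.1f%%)\n", f$agreement$absolute_difference,
                f$agreement$relative_pct))
  }
  cat("\nScored occupancy reports:\n")
  cols <- intersect(c("report_id", "occupancy_value", "unit", "provenance",
                      "points_1", "points_2", "points_3", "score"),
                    names(f$scored_reports))
  print(f$scored_reports[, cols], row.names = FALSE)
  if (nrow(f$excluded_reports)) {
    cat("\nExcluded reports:\n")
    cols <- intersect(c("report_id", "exclusion_reason"),
                      names(f$excluded_reports))
    print(f$excluded_reports[, cols, drop = FALSE], row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn popest the three headline quantities: consensus count,
#'   structure occupancy, estimated population.
#' @export
coef.popest <- function(object, ...) {
  c(mean_structure_count = object$mean_structure_count,
    structure_occupancy = object$structure_occupancy,
    population = object$population)
}

#' Resampling interval for a population estimate
#'
#' An optional extension: a nonparametric percentile interval obtained by
#' resampling the occupancy reports with replacement (information-score
#' weights kept fixed per report) and recomputing the estimate. Occupancy
#' evidence is typically sparse (often 1-11 reports per site), so intervals
#' from so few reports are indicative at best and are not part of the core
#' method.
#'
#' @param object a [popest()] fit.
#' @param parm unused (the interval is on the population estimate).
#' @param level coverage level (default 0.95).
#' @param nboot number of resamples.
#' @param seed RNG seed.
#' @param ... unused.
#' @return matrix with the lower and upper percentile bounds.
#' @export
confint.popest <- function(object, parm = "population", level = 0.95,
                           nboot = 1000, seed = 1, ...) {
  sr <- object$scored_reports
  pops <- with_seed(seed, vapply(seq_len(nboot), function(b) {
    idx <- sample.int(nrow(sr), nrow(sr), replace = TRUE)
    occ <- weighted_mean_occupancy(sr$occupancy_value[idx], sr$score[idx])
    pooled <- if (object$compat) occ$weighted_mean_1dp else occ$weighted_mean
    so <- pooled * object$households_per_structure
    round_half_away(object$mean_structure_count * so)
  }, 0))
  a <- (1 - level) / 2
  ci <- stats::quantile(pops, c(a, 1 - a))
  out <- matrix(ci, nrow = 1,
                dimnames = list("population",
                                sprintf("%.1f %%", 100 * c(a, 1 - a))))
  out
}

#' @describeIn popest dot chart of report occupancy values sized by
#'   information score, with the pooled mean marked.
#' @export
plot.popest <- function(x, ...) {
  sr <- x$scored_reports
  graphics::plot(sr$occupancy_value, seq_len(nrow(sr)),
                 cex = 0.5 + 2 * sr$score / max(sr$score),
                 pch = 19, xlab = "Occupancy (people per unit)",
                 ylab = "Report", yaxt = "n",
                 main = paste0(x$site$name, ": occupancy reports"), ...)
  graphics::axis(2, at = seq_len(nrow(sr)),
                 labels = sr$report_id %||% seq_len(nrow(sr)), las = 1)
  graphics::abline(v = x$occupancy$weighted_mean, lty = 2)
  invisible(x)
}
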