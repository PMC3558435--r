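#' Load the hierarchy-of-evidence rubric
#'
#' Occupancy reports are weighted by an information score built from three
#' attributes: how representative the report is of the site and analysis
#' time-point, how robust its data-collection method is, and whether it
#' quantifies occupancy per residential structure rather than per household.
#' The per-attribute point values live in a small versioned JSON file so the
#' hierarchy can be refined without code changes; the packaged default gives
#' a maximum score of 10 x 10 x 10 = 1000.
#'
#' @param path optional path to an alternative rubric JSON; the packaged
#'   default is used when `NULL`.
#' @return a `rubric` list with components `version`, `representativeness`,
#'   `method` and `unit`, each a named numeric vector of points.
#' @export
load_rubric <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rubric.json", package = "remotepop")
  r <- jsonlite::fromJSON(path)
  for (a in c("representativeness", "method", "unit"))
    r[[a]] <- unlist(r[[a]])
  structure(r, class = "rubric")
}

default_rubric <- function() load_rubric()

#' Filter occupancy reports for eligibility
#'
#' Applies the inclusion rules for occupancy reports: collected within the
#' 10 years up to the analysis date (boundaries inclusive, whole-day
#' arithmetic), full text available, containing primary occupancy data, and
#' — for urban, non-camp sites — reflecting urban populations only. Undated
#' reports are excluded rather than guessed, since the 10-year window cannot
#' be verified without a date. The filter is idempotent.
#'
#' Flag columns (`full_text_available`, `has_primary_data`,
#' `urban_population`) default to `TRUE` when absent or `NA`.
#'
#' @param reports data frame of occupancy reports (see [score_reports()] for
#'   the expected columns).
#' @param analysis_date the site's analysis date (`Date` or parseable string).
#' @param site_kind `"camp"` or `"urban"`; the urban-population rule applies
#'   only to urban sites.
#' @return a list with `eligible` (subset of `reports`) and `excluded`
#'   (data frame of dropped reports with an `exclusion_reason` column).
#' @export
filter_eligible <- function(reports, analysis_date, site_kind = c("camp", "urban")) {
  site_kind <- match.arg(site_kind)
  analysis_date <- as_date_strict(analysis_date)
  n <- nrow(reports)
  flag <- function(col) {
    v <- reports[[col]] %||% rep(TRUE, n)
    v[is.na(v)] <- TRUE
    v
  }
  dates <- as_date_strict(reports$collection_date %||% rep(NA, n))
  reason <- rep(NA_character_, n)
  reason[is.na(dates)] <- "undated"
  ok <- is.na(reason)
  after <- ok & dates > analysis_date
  reason[after] <- "collected after analysis date"
  old <- ok & !after & dates < date_minus_years(analysis_date, 10)
  reason[old] <- "older than 10y window"
  reason[is.na(reason) & !flag("full_text_available")] <- "full text unavailable"
  reason[is.na(reason) & !flag("has_primary_data")] <- "no primary occupancy data"
  if (site_kind == "urban")
    reason[is.na(reason) & !flag("urban_population")] <- "non-urban"
  keep <- is.na(reason)
  excluded <- reports[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$exclusion_reason <- reason[!keep]
  else excluded$exclusion_reason <- character(0)
  list(eligible = reports[keep, , drop = FALSE], excluded = excluded)
}

#' Representativeness points (attribute 1)
#'
#' Scores how representative a report is of the site's population at the
#' analysis time-point. Site itself within 3 years of analysis scores 10;
#' a similar site in the same crisis region within 3 years scores 8; either,
#' collected 3-10 years before, scores 4; a pre-displacement report within
#' 10 years scores 2. Windows are boundary-inclusive (exactly 3 years counts
#' as within). The classifier is date-driven: a report declared
#' `site_current` or `region_current` but dated more than 3 years before the
#' analysis is scored 4, the previous-crisis-period level.
#'
#' @param provenance one of `"site_current"`, `"region_current"`,
#'   `"site_or_region_previous"`, `"pre_displacement"`.
#' @param collection_date date the report's data were collected.
#' @param analysis_date the site analysis date.
#' @param rubric a [load_rubric()] object.
#' @return points (numeric scalar).
#' @export
classify_representativeness <- function(provenance, collection_date, analysis_date,
                                        rubric = default_rubric()) {
  pts <- rubric$representativeness
  provenance <- match.arg(provenance, names(pts))
  collection_date <- as_date_strict(collection_date)
  analysis_date <- as_date_strict(analysis_date)
  if (is.na(collection_date) || !within_years(collection_date, analysis_date, 10))
    stop("report collection date outside the 10y eligibility window; ",
         "run filter_eligible() first")
  if (provenance == "pre_displacement") return(unname(pts["pre_displacement"]))
  recent <- within_years(collection_date, analysis_date, 3)
  if (!recent) return(unname(pts["site_or_region_previous"]))
  switch(provenance,
    site_current = unname(pts["site_current"]),
    region_current = unname(pts["region_current"]),
    site_or_region_previous = unname(pts["site_or_region_previous"]))
}

#' Method-robustness points (attribute 2)
#'
#' Census, systematic registration or ongoing demographic surveillance
#' scores 10; a large sample survey with no obvious technical flaw scores 8;
#' any other sample survey 6; a rapid assessment, site visit or programmatic
#' review 4; an anecdotal estimate 1. "Large" means strictly more than 200
#' households under simple or systematic random sampling, or strictly more
#' than 400 households in strictly more than 20 clusters under cluster
#' sampling. When a `design` is supplied it decides between the large-survey
#' and other-survey levels.
#'
#' @param method one of `"census_registration_surveillance"`,
#'   `"large_survey"`, `"other_survey"`, `"rapid_assessment"`, `"anecdotal"`;
#'   may be `NULL` when `design` is given (then the report is a survey).
#' @param design optional [survey_design()].
#' @inheritParams classify_representativeness
#' @return points (numeric scalar).
#' @export
classify_method <- function(method = NULL, design = NULL,
                            rubric = default_rubric()) {
  pts <- rubric$method
  if (!is.null(design)) {
    stopifnot(inherits(design, "survey_design"))
    lvl <- if (is_large_survey(design)) "large_survey" else "other_survey"
    if (!is.null(method) &&
        method %in% c("census_registration_surveillance", "rapid_assessment",
                      "anecdotal"))
      lvl <- method
    return(unname(pts[lvl]))
  }
  method <- match.arg(method, names(pts))
  unname(pts[method])
}

#' Describe a survey's sampling design
#'
#' @param scheme `"simple"`, `"systematic"` or `"cluster"`.
#' @param n_households number of households sampled.
#' @param n_clusters number of clusters (required for cluster sampling).
#' @param has_technical_flaw whether the survey has an obvious technical
#'   flaw (a flawed survey cannot score as "large").
#' @return a `survey_design` object.
#' @export
survey_design <- function(scheme = c("simple", "systematic", "cluster"),
                          n_households, n_clusters = NULL,
                          has_technical_flaw = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(n_households >= 0)
  if (scheme == "cluster" && is.null(n_clusters))
    stop("cluster design requires n_clusters")
  structure(list(scheme = scheme, n_households = n_households,
                 n_clusters = n_clusters,
                 has_technical_flaw = isTRUE(has_technical_flaw)),
            class = "survey_design")
}

is_large_survey <- function(d) {
  if (d$has_technical_flaw) return(FALSE)
  if (d$scheme == "cluster")
    d$n_households > 400 && d$n_clusters > 20
  else
    d$n_households > 200
}

#' Unit-congruence points (attribute 3)
#'
#' Scores whether the report quantifies mean occupancy of residential
#' structures (10), of households under a definition consistent with one
#' structure or compound, e.g. "people sleeping together under one roof"
#' (6), or of households with an unclear or incongruous definition (1).
#'
#' @param unit one of `"per_structure"`,
#'   `"per_household_consistent_with_structure"`, `"per_household_other"`.
#' @inheritParams classify_representativeness
#' @return points (numeric scalar).
#' @export
classify_unit <- function(unit, rubric = default_rubric()) {
  pts <- rubric$unit
  unit <- match.arg(unit, names(pts))
  unname(pts[unit])
}

#' Information score for one occupancy report
#'
#' The score is the product of the three attribute point values
#' (representativeness x method x unit), out of a possible 1000 maximum.
#' It is the weight the report receives when occupancy estimates are pooled.
#'
#' @param report a one-row data frame or list with fields `provenance`,
#'   `collection_date`, `method` (and optionally `sampling_scheme`,
#'   `n_households`, `n_clusters`, `has_technical_flaw`) and `unit`.
#' @inheritParams classify_representativeness
#' @return an `evidence_score` list with `points_representativeness`,
#'   `points_method`, `points_unit` and `score`.
#' @export
information_score <- function(report, analysis_date, rubric = default_rubric()) {
  design <- NULL
  scheme <- report$sampling_scheme %||% NA
  if (length(scheme) == 1 && !is.na(scheme) && nzchar(as.character(scheme))) {
    nh <- report$n_households %||% NA
    nc <- report$n_clusters %||% NULL
    if (length(nc) == 1 && is.na(nc)) nc <- NULL
    if (!is.na(nh))
      design <- survey_design(as.character(scheme), nh, nc,
                              isTRUE(report$has_technical_flaw %||% FALSE))
  }
  p1 <- classify_representativeness(as.character(report$provenance),
                                    report$collection_date, analysis_date, rubric)
  method <- report$method %||% NULL
  if (!is.null(method) && (length(method) != 1 || is.na(method))) method <- NULL
  p2 <- classify_method(if (is.null(method)) NULL else as.character(method),
                        design, rubric)
  p3 <- classify_unit(as.character(report$unit), rubric)
  structure(list(points_representativeness = p1, points_method = p2,
                 points_unit = p3, score = p1 * p2 * p3),
            class = "evidence_score")
}

#' @export
print.evidence_score <- function(x, ...) {
  cat(sprintf("Information score: %g x %g x %g = %g (max 1000)\n",
              x$points_representativeness, x$points_method, x$points_unit,
              x$score))
  invisible(x)
}

#' Score a registry of occupancy reports
#'
#' Vectorized [information_score()] over a report registry: appends columns
#' `points_1`, `points_2`, `points_3` and `score`. Expected columns:
#' `report_id`, `occupancy_value`, `unit`, `provenance`, `method`,
#' `n_households`, `n_clusters`, `sampling_scheme`, `collection_date`,
#' `citation` (survey-design and citation columns optional).
#'
#' @param reports data frame of eligible occupancy reports.
#' @inheritParams classify_representativeness
#' @return `reports` with scoring columns appended.
#' @export
score_reports <- function(reports, analysis_date, rubric = default_rubric()) {
  if (!nrow(reports)) {
    reports$points_1 <- reports$points_2 <- reports$points_3 <-
      reports$score <- numeric(0)
    return(reports)
  }
  sc <- lapply(seq_len(nrow(reports)), function(i)
    information_score(reports[i, , drop = FALSE], analysis_date, rubric))
  reports$points_1 <- vapply(sc, `[[`, 0, "points_representativeness")
  reports$points_2 <- vapply(sc, `[[`, 0, "points_method")
  reports$points_3 <- vapply(sc, `[[`, 0, "points_unit")
  reports$score <- vapply(sc, `[[`, 0, "score")
  reports
}

#' Amount-of-information index
#'
#' The site-level index is the sum of the information scores of all
#' available reports; it quantifies how much occupancy evidence backs the
#' estimate (a single weak report gives an index as low as 2; many strong
#' reports approach multiples of 1000).
#'
#' @param scores numeric vector of report scores, or a scored registry from
#'   [score_reports()], or a list of `evidence_score` objects.
#' @return integer sum (0 for no reports).
#' @export
information_index <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$score
  if (is.list(scores)) scores <- vapply(scores, `[[`, 0, "score")
  if (length(scores) == 0L) return(0L)
  as.integer(sum(scores))
}

#' Read an occupancy-report registry
#'
#' @param path CSV or JSON registry file.
#' @return data frame of reports with `collection_date` parsed as `Date`.
#' @export
read_registry <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$collection_date))
    df$collection_date <- as_date_strict(df$collection_date)
  df
}
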