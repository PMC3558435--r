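#' Run the full estimation pipeline from a configuration
#'
#' Executes the whole chain — read marks, tabulate duplicate counts,
#' consensus mean; read registry, eligibility filter, information scores,
#' weighted occupancy; population estimate; optional validation — and,
#' when an output directory is given, writes a machine-readable JSON
#' estimate record, a human-readable CSV row (mean count, occupancy,
#' estimate, reference, difference, index), and a plain-text stage log.
#' The JSON and CSV records are byte-stable across reruns with identical
#' inputs; timestamps live only in the log. Every record carries the MD5
#' digests of the input files and the rubric version used.
#'
#' @param config a list, or path to a JSON file, with components:
#'   \describe{
#'     \item{site}{list: `name`, `analysis_date`, optional `site_kind`,
#'       `households_per_structure`, `reference_population`,
#'       `count_override`.}
#'     \item{marks}{path(s) to marks file(s) (GeoJSON or CSV), or `counts`:
#'       a numeric vector of per-analyst residential counts.}
#'     \item{category_map}{named list/vector of logicals (required with
#'       `marks`).}
#'     \item{registry}{path to the occupancy-report registry (CSV/JSON), or
#'       a data frame.}
#'     \item{compat}{logical: pool occupancy at 1-decimal table precision.}
#'     \item{output_dir}{optional directory for the output records.}
#'   }
#' @return the [popest()] fit, invisibly, with the output record attached
#'   as attribute `"record"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  t0 <- Sys.time()
  timings <- character(0)
  tick <- function(name, start)
    timings <<- c(timings, sprintf("%s: %.3fs", name,
                                   as.numeric(Sys.time() - start, "secs")))

  sc <- stage("config", {
    s <- config$site
    if (is.null(s$name) || is.null(s$analysis_date))
      stop("site name and analysis_date are required")
    site_config(s$name, s$analysis_date,
                site_kind = s$site_kind %||% "camp",
                households_per_structure = s$households_per_structure %||% 1,
                reference_population = s$reference_population,
                count_override = s$count_override)
  })

  digests <- character(0)
  ts <- Sys.time()
  counts <- stage("structure counts", {
    if (!is.null(config$marks)) {
      cmap <- unlist(config$category_map)
      if (is.null(cmap)) stop("category_map is required with marks input")
      cmap <- stats::setNames(as.logical(cmap), names(cmap))
      paths <- unlist(config$marks)
      digests <- c(digests, tools::md5sum(paths))
      marks <- do.call(rbind, lapply(paths, read_marks, category_map = cmap))
      class(marks) <- c("structure_marks", "data.frame")
      marks
    } else if (!is.null(config$counts)) {
      as.numeric(unlist(config$counts))
    } else stop("either marks or counts must be supplied")
  })
  tick("structure counts", ts)

  ts <- Sys.time()
  registry <- stage("occupancy registry", {
    if (is.data.frame(config$registry)) config$registry
    else {
      digests <- c(digests, tools::md5sum(config$registry))
      read_registry(config$registry)
    }
  })
  tick("occupancy registry", ts)

  ts <- Sys.time()
  rubric <- load_rubric(config$rubric %||% NULL)
  fit <- stage("estimator", {
    popest(counts, registry, sc, rubric = rubric,
           compat = isTRUE(config$compat))
  })
  tick("estimator", ts)

  record <- list(
    site = sc$name,
    analysis_date = as.character(sc$analysis_date),
    analyst_counts = fit$analyst_counts,
    mean_structure_count = fit$mean_structure_count,
    weighted_mean_occupancy = fit$occupancy$weighted_mean,
    households_per_structure = fit$households_per_structure,
    structure_occupancy = fit$structure_occupancy,
    population = fit$population,
    information_index = fit$information_index,
    n_reports = fit$occupancy$n_reports,
    n_reports_excluded = nrow(fit$excluded_reports),
    compat = fit$compat,
    rubric_version = rubric$version,
    input_md5 = as.list(digests))
  if (!is.null(fit$validation))
    record$validation <- list(
      reference_population = sc$reference_population,
      absolute_difference = fit$validation$absolute_difference,
      relative_pct = fit$validation$relative_pct,
      band = fit$validation$band)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(record,
                         file.path(config$output_dir, "estimate.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    row <- data.frame(
      site = sc$name,
      mean_structure_count = fit$mean_structure_count,
      weighted_mean_occupancy = fit$occupancy$weighted_mean_1dp,
      households_per_structure = fit$households_per_structure,
      population = fit$population,
      reference_population = sc$reference_population %||% NA,
      absolute_difference = if (is.null(fit$validation)) NA else
        fit$validation$absolute_difference,
      relative_pct = if (is.null(fit$validation)) NA else
        fit$validation$relative_pct,
      information_index = fit$information_index,
      n_reports = fit$occupancy$n_reports)
    utils::write.csv(row, file.path(config$output_dir, "estimate.csv"),
                     row.names = FALSE)
    writeLines(c(paste("run started:", format(t0)), timings,
                 paste("run finished:", format(Sys.time()))),
               file.path(config$output_dir, "pipeline.log"))
  }
  attr(fit, "record") <- record
  invisible(fit)
}

#' Write structure marks to GeoJSON or CSV
#'
#' @param marks a `structure_marks` data frame.
#' @param path output path; `.geojson`/`.json` writes a FeatureCollection,
#'   anything else a CSV.
#' @return `path`, invisibly.
#' @export
write_marks <- function(marks, path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    feats <- lapply(seq_len(nrow(marks)), function(i) list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(marks$x[i], marks$y[i])),
      properties = list(analyst_id = marks$analyst_id[i],
                        category = marks$category[i])))
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(marks[, c("x", "y", "analyst_id", "category")], path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Write a duplicate-count table as CSV
#'
#' @param counts a `count_table` from [tabulate_counts()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}
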