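#' Read structure marks from a point annotation file
#'
#' Reads one analyst-placed point per assumed structure from either a GeoJSON
#' FeatureCollection of Point features (with properties `analyst_id` and
#' `category`) or a CSV with columns `x, y, analyst_id, category`. The
#' residential flag is never inferred from the category name: it is derived
#' from an explicit category-to-residential mapping, because independent
#' analysts routinely disagree on which non-residential structures (latrines,
#' warehouses, market shops) to mark at all.
#'
#' @param path path to the marks file.
#' @param category_map named logical vector mapping each category label to
#'   `TRUE` (residential) or `FALSE` (other), e.g.
#'   `c(hut = TRUE, tent = TRUE, latrine = FALSE)`.
#' @param format `"auto"` (default, by file extension), `"geojson"` or `"csv"`.
#' @return a `structure_marks` data frame with columns `x`, `y`,
#'   `analyst_id`, `category`, `residential` and (initially `NA`) `grid_cell`.
#' @seealso [assign_grid_cells()], [tabulate_counts()]
#' @export
read_marks <- function(path, category_map, format = c("auto", "geojson", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("marks file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      "geojson" else "csv"
  }
  df <- if (format == "geojson") read_marks_geojson(path) else read_marks_csv(path)
  as_structure_marks(df, category_map)
}

read_marks_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else stop("expected a GeoJSON FeatureCollection in ", path)
  if (length(feats) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      analyst_id = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Point"))
      stop("feature ", i, ": geometry is not a Point")
    cc <- unlist(f$geometry$coordinates)
    list(i = i, x = cc[1], y = cc[2],
         analyst_id = f$properties$analyst_id %||% NA_character_,
         category = f$properties$category %||% NA_character_)
  })
  df <- data.frame(
    x = vapply(rows, function(r) as.numeric(r$x), 0),
    y = vapply(rows, function(r) as.numeric(r$y), 0),
    analyst_id = vapply(rows, function(r) as.character(r$analyst_id), ""),
    category = vapply(rows, function(r) as.character(r$category), ""),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$analyst_id) | df$analyst_id == "" |
               is.na(df$category) | df$category == "")
  if (length(bad))
    stop("features missing analyst_id or category at index: ",
         paste(bad, collapse = ", "))
  df
}

read_marks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "analyst_id", "category")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("marks CSV missing columns: ", paste(miss, collapse = ", "))
  bad <- which(is.na(df$analyst_id) | df$analyst_id == "" |
               is.na(df$category) | df$category == "")
  if (length(bad))
    stop("rows missing analyst_id or category: ", paste(bad, collapse = ", "))
  df[need]
}

#' Build a structure-marks table from raw point records
#'
#' @param df data frame with columns `x`, `y`, `analyst_id`, `category`.
#' @inheritParams read_marks
#' @return a `structure_marks` data frame.
#' @export
as_structure_marks <- function(df, category_map) {
  stopifnot(is.data.frame(df))
  if (nrow(df)) {
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
      stop("mark coordinates must be finite")
    if (!is.logical(category_map) || is.null(names(category_map)))
      stop("category_map must be a named logical vector (category -> residential)")
    unknown <- setdiff(unique(df$category), names(category_map))
    if (length(unknown))
      stop("no residential mapping for category: ",
           paste(unknown, collapse = ", "))
    df$residential <- unname(category_map[df$category])
  } else {
    df <- data.frame(x = numeric(0), y = numeric(0),
                     analyst_id = character(0), category = character(0),
                     stringsAsFactors = FALSE)
    df$residential <- logical(0)
  }
  if (is.null(df$grid_cell)) df$grid_cell <- rep(NA_character_, nrow(df))
  class(df) <- c("structure_marks", "data.frame")
  df
}

#' Define a counting grid
#'
#' The counting protocol overlays square gridlines (200 m by default) on the
#' image so each analyst can sweep cells systematically. Cells are half-open
#' `[edge, edge + cell_size)` in both axes, zero-based from the origin, so a
#' mark on a shared edge belongs to exactly one cell.
#'
#' @param origin numeric length-2, the grid origin `(x0, y0)` in the marks'
#'   coordinate units.
#' @param cell_size side length of a square cell (default 200, i.e. 200 m
#'   when marks are in metres).
#' @param n_cols,n_rows grid extent in cells.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin = c(0, 0), cell_size = 200, n_cols = 1, n_rows = 1) {
  stopifnot(length(origin) == 2, is.finite(origin),
            cell_size > 0, n_cols >= 1, n_rows >= 1)
  structure(list(origin = as.numeric(origin), cell_size = as.numeric(cell_size),
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "grid_spec")
}

#' Assign each mark to a grid cell
#'
#' Cell indices are `floor((x - x0) / cell_size)` columns and the analogous
#' rows; labels are `"col,row"`. Because cells are half-open, a mark exactly
#' on an interior edge falls in the higher-index cell.
#'
#' @param marks a `structure_marks` data frame.
#' @param grid a [grid_spec()].
#' @param policy what to do with marks outside the grid extent: `"strict"`
#'   (error, reporting the offending coordinates), `"clip"` (drop them) or
#'   `"flag"` (keep with `NA` cell).
#' @return `marks` with `grid_cell`, `grid_col`, `grid_row` filled in.
#' @export
assign_grid_cells <- function(marks, grid, policy = c("strict", "clip", "flag")) {
  policy <- match.arg(policy)
  stopifnot(inherits(grid, "grid_spec"))
  if (!nrow(marks)) return(marks)
  col <- floor((marks$x - grid$origin[1]) / grid$cell_size)
  row <- floor((marks$y - grid$origin[2]) / grid$cell_size)
  outside <- col < 0 | col >= grid$n_cols | row < 0 | row >= grid$n_rows
  if (any(outside)) {
    if (policy == "strict") {
      i <- which(outside)[1]
      stop(sprintf("mark outside grid extent at (%g, %g)", marks$x[i], marks$y[i]))
    }
    if (policy == "clip") {
      marks <- marks[!outside, , drop = FALSE]
      col <- col[!outside]; row <- row[!outside]
      outside <- rep(FALSE, nrow(marks))
    }
  }
  marks$grid_col <- ifelse(outside, NA_integer_, as.integer(col))
  marks$grid_row <- ifelse(outside, NA_integer_, as.integer(row))
  marks$grid_cell <- ifelse(outside, NA_character_,
                            paste(col, row, sep = ","))
  marks
}

#' Tabulate structure counts per analyst
#'
#' Rolls marks up into the duplicate-count table used for consensus and
#' agreement: one row per analyst with residential, other and total counts.
#' The full per-category and (when cells are assigned) per-cell breakdowns
#' are attached as attributes `by_category` and `by_cell`.
#'
#' @param marks a `structure_marks` data frame (may be empty).
#' @return a `count_table` data frame with columns `analyst_id`,
#'   `residential_count`, `other_count`, `total_count`.
#' @export
tabulate_counts <- function(marks) {
  if (!nrow(marks)) {
    out <- data.frame(analyst_id = character(0),
                      residential_count = integer(0),
                      other_count = integer(0), total_count = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("count_table", "data.frame")
    return(out)
  }
  analysts <- sort(unique(marks$analyst_id))
  res <- vapply(analysts, function(a)
    sum(marks$analyst_id == a & marks$residential), 0L)
  oth <- vapply(analysts, function(a)
    sum(marks$analyst_id == a & !marks$residential), 0L)
  out <- data.frame(analyst_id = analysts,
                    residential_count = as.integer(res),
                    other_count = as.integer(oth),
                    total_count = as.integer(res + oth),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "by_category") <- table(marks$analyst_id, marks$category)
  if (!all(is.na(marks$grid_cell)))
    attr(out, "by_cell") <- table(marks$analyst_id, marks$grid_cell)
  class(out) <- c("count_table", "data.frame")
  out
}

#' Consensus structure count across analysts
#'
#' The consensus is the arithmetic mean of the per-analyst counts, rounded
#' half away from zero to an integer (so duplicate counts of 1501 and 1380
#' give 1441). A single analyst's count passes through unchanged; any number
#' of analysts is accepted, supporting crowd-sourced counting.
#'
#' @param counts numeric vector, one residential count per analyst.
#' @return integer consensus count.
#' @export
consensus_mean_count <- function(counts) {
  if (length(counts) == 0L || all(is.na(counts)))
    stop("no analyst counts supplied")
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) stop("counts must be non-negative")
  as.integer(round_half_away(mean(counts)))
}

#' Inter-analyst agreement for a duplicate count
#'
#' Absolute difference and relative percent difference between two analysts'
#' counts of the same structures, with the larger count as denominator
#' (so the relative difference is always between 0 and 100 percent). When
#' both counts are zero the relative difference is 0.
#'
#' @param count_a,count_b non-negative counts from two independent analysts.
#' @return an `agreement` list with `absolute_difference` and `relative_pct`
#'   (percent, rounded half-away to 1 decimal).
#' @export
pairwise_agreement <- function(count_a, count_b) {
  if (any(c(count_a, count_b) < 0)) stop("counts must be non-negative")
  ad <- abs(count_a - count_b)
  rel <- if (max(count_a, count_b) == 0) 0 else 100 * ad / max(count_a, count_b)
  structure(list(absolute_difference = ad,
                 relative_pct = round_half_away(rel, 1)),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("Duplicate-count agreement: |difference| = %d (%.1f%%)\n",
              as.integer(x$absolute_difference), x$relative_pct))
  invisible(x)
}
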