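#' Compare a population estimate against a reference figure
#'
#' The reference ("gold standard") figure comes from a census, exhaustive
#' registration or demographic surveillance. The comparison reports the
#' signed absolute difference (estimate minus reference) and the signed
#' relative difference in percent with the reference as denominator,
#' rounded half-away to 1 decimal for reporting (the unrounded value is
#' retained), plus the precision band.
#'
#' @param estimate estimated population (or a `population_estimate` /
#'   `popest` object).
#' @param reference reference population (positive).
#' @return a `validation_result` list with `absolute_difference`,
#'   `relative_pct`, `relative_pct_raw` and `band`.
#' @export
compare_reference <- function(estimate, reference) {
  if (inherits(estimate, "popest")) estimate <- estimate$population
  if (inherits(estimate, "population_estimate")) estimate <- estimate$population
  if (is.null(reference) || is.na(reference) || reference <= 0)
    stop("reference population must be positive")
  diff <- estimate - reference
  rel <- 100 * diff / reference
  structure(list(absolute_difference = diff,
                 relative_pct = round_half_away(rel, 1),
                 relative_pct_raw = rel,
                 band = precision_band(rel)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("  vs reference: %s%s (%s%.1f%%) -- %s precision\n",
              if (x$absolute_difference >= 0) "+" else "",
              format(x$absolute_difference, big.mark = ","),
              if (x$relative_pct >= 0) "+" else "", x$relative_pct, x$band))
  invisible(x)
}

#' Precision band for a relative difference
#'
#' Classifies the absolute relative difference against the reference into
#' `good` (< 10\%), `moderate` (10-30\%) or `poor` (> 30\%). The rule
#' operates on the integer-rounded absolute percent, so a site at +30.4\%
#' classifies as moderate while +30.5\% classifies as poor; the 1-decimal
#' value is always reported alongside the band.
#'
#' @param relative_pct signed relative difference in percent.
#' @return `"good"`, `"moderate"` or `"poor"` (character, same length as
#'   input).
#' @export
precision_band <- function(relative_pct) {
  r <- round_half_away(abs(relative_pct))
  ifelse(r < 10, "good", ifelse(r <= 30, "moderate", "poor"))
}

#' Tally precision bands over several sites
#'
#' @param results a list of `validation_result` objects (optionally named by
#'   site), or a data frame with columns `site` and `relative_pct`.
#' @return a `site_summary` list with `n_good`, `n_moderate`, `n_poor`,
#'   per-band site-name lists, and the per-site table.
#' @export
summarize_sites <- function(results) {
  if (is.data.frame(results)) {
    tab <- data.frame(site = results$site,
                      relative_pct = results$relative_pct,
                      band = precision_band(results$relative_pct),
                      stringsAsFactors = FALSE)
  } else {
    if (!length(results)) stop("at least one validation result required")
    tab <- data.frame(
      site = names(results) %||% as.character(seq_along(results)),
      relative_pct = vapply(results, `[[`, 0, "relative_pct"),
      band = vapply(results, `[[`, "", "band"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  sites_in <- function(b) tab$site[tab$band == b]
  structure(list(n_good = sum(tab$band == "good"),
                 n_moderate = sum(tab$band == "moderate"),
                 n_poor = sum(tab$band == "poor"),
                 good_sites = sites_in("good"),
                 moderate_sites = sites_in("moderate"),
                 poor_sites = sites_in("poor"),
                 table = tab),
            class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat("Precision vs reference population figures:\n")
  cat(sprintf("  good (<10%%):      %d site%s  [%s]\n", x$n_good,
              if (x$n_good == 1) "" else "s",
              paste(x$good_sites, collapse = ", ")))
  cat(sprintf("  moderate (10-30%%): %d site%s  [%s]\n", x$n_moderate,
              if (x$n_moderate == 1) "" else "s",
              paste(x$moderate_sites, collapse = ", ")))
  cat(sprintf("  poor (>30%%):      %d site%s  [%s]\n", x$n_poor,
              if (x$n_poor == 1) "" else "s",
              paste(x$poor_sites, collapse = ", ")))
  invisible(x)
}
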