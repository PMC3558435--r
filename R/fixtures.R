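fixture_path <- function(file)
  system.file("extdata", file, package = "remotepop")

#' Packaged study-site tables
#'
#' Returns the three packaged reference tables for the study sites: site
#' descriptions with reference ("gold standard") population figures,
#' duplicate structure counts by assumed class with the published
#' agreement cells, and the published estimation results (mean count,
#' pooled occupancy, estimate, validation cells, amount-of-information
#' index). Cells that the package's own rules cannot reproduce (one
#' total-row agreement cell computed against the smaller count, and the
#' footnoted comparable-area cells for the largest camp) are flagged
#' `known_discrepancy` so tests can assert the rule rather than the typo.
#'
#' @return a list of data frames: `sites`, `duplicate_counts`, `estimates`.
#' @export
site_fixtures <- function() {
  list(sites = utils::read.csv(fixture_path("sites.csv"),
                               stringsAsFactors = FALSE, check.names = FALSE),
       duplicate_counts = utils::read.csv(fixture_path("duplicate_counts.csv"),
                                          stringsAsFactors = FALSE),
       estimates = utils::read.csv(fixture_path("estimates.csv"),
                                   stringsAsFactors = FALSE))
}

#' Load the packaged fixture for one study site
#'
#' @param site_name one of the packaged study sites (the 11 validated sites
#'   plus "Kutupalong makeshift").
#' @return a `site_fixture` list with components `site` (description and
#'   reference estimate), `counts` (duplicate counts by class) and
#'   `estimate` (published mean count, occupancy, population and
#'   validation cells).
#' @examples
#' fx <- load_site_fixture("Breidjing")
#' fx$estimate$population
#' @export
load_site_fixture <- function(site_name) {
  fx <- site_fixtures()
  valid <- fx$sites$site
  if (!site_name %in% valid)
    stop("unknown site '", site_name, "'; valid sites: ",
         paste(valid, collapse = ", "))
  structure(list(
    site = fx$sites[fx$sites$site == site_name, , drop = FALSE],
    counts = fx$duplicate_counts[fx$duplicate_counts$site == site_name, ,
                                 drop = FALSE],
    estimate = fx$estimates[fx$estimates$site == site_name, , drop = FALSE]),
    class = "site_fixture")
}

#' @export
print.site_fixture <- function(x, ...) {
  cat("Study-site fixture:", x$site$site, "(", x$site$country, ")\n")
  if (nrow(x$estimate)) {
    e <- x$estimate
    cat(sprintf("  mean count %s, occupancy %.1f x %g, estimate %s",
                format(e$mean_count, big.mark = ","), e$occupancy_per_unit,
                e$households_multiplier,
                format(e$population, big.mark = ",")))
    if (!is.na(e$reference_population))
      cat(sprintf(", reference %s (%+.1f%%)",
                  format(e$reference_population, big.mark = ","), e$diff_pct))
    cat("\n")
  }
  invisible(x)
}
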