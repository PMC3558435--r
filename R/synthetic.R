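#' Specify a synthetic settlement
#'
#' Describes the ground truth for a simulated site: how many structures of
#' each category exist, how occupants are distributed over residential
#' structures, and how structures are laid out. Three layout patterns cover
#' the range seen in displaced settlements: `"uniform"` (stand-alone
#' dwellings), `"block_grid"` (planned camps organised in blocks) and
#' `"clustered"` (dense, slum-like clumps).
#'
#' @param n_structures named integer vector of structure counts per
#'   category, e.g. `c(hut = 400, latrine = 30)`.
#' @param occupancy_mean mean occupants per residential structure.
#' @param occupancy_dispersion coefficient of variation of per-structure
#'   occupancy (0 = every structure holds exactly the rounded mean).
#' @param households_per_structure households per residential structure
#'   (>= 1); occupancy reports expressed per household see
#'   `occupancy_mean / households_per_structure`.
#' @param non_residential character vector of category names that are not
#'   residential (all others are residential).
#' @param bbox bounding box `c(xmin, ymin, xmax, ymax)` in metres.
#' @param layout placement pattern, see above.
#' @return a `site_spec` object.
#' @export
site_spec <- function(n_structures, occupancy_mean = 5,
                      occupancy_dispersion = 0.3,
                      households_per_structure = 1,
                      non_residential = character(0),
                      bbox = c(0, 0, 1000, 1000),
                      layout = c("uniform", "block_grid", "clustered")) {
  layout <- match.arg(layout)
  if (is.null(names(n_structures)) || any(!nzchar(names(n_structures))))
    stop("n_structures must be a named vector of per-category counts")
  if (any(n_structures < 0)) stop("structure counts must be non-negative")
  if (occupancy_mean <= 0 || occupancy_dispersion < 0)
    stop("invalid occupancy distribution parameters")
  if (households_per_structure < 1)
    stop("households_per_structure must be >= 1")
  stopifnot(length(bbox) == 4, bbox[3] > bbox[1], bbox[4] > bbox[2])
  structure(list(n_structures = n_structures,
                 occupancy_mean = occupancy_mean,
                 occupancy_dispersion = occupancy_dispersion,
                 households_per_structure = households_per_structure,
                 non_residential = non_residential,
                 bbox = bbox, layout = layout),
            class = "site_spec")
}

place_structures <- function(n, bbox, layout) {
  if (n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0)))
  w <- bbox[3] - bbox[1]; h <- bbox[4] - bbox[2]
  switch(layout,
    uniform = data.frame(x = stats::runif(n, bbox[1], bbox[3]),
                         y = stats::runif(n, bbox[2], bbox[4])),
    block_grid = {
      k <- ceiling(sqrt(n))
      gx <- bbox[1] + (rep(seq_len(k), length.out = n) - 0.5) * w / k
      gy <- bbox[2] + (rep(seq_len(k), each = k)[seq_len(n)] - 0.5) * h / k
      jit <- 0.1 * min(w, h) / k
      data.frame(x = pmin(pmax(gx + stats::rnorm(n, 0, jit), bbox[1]), bbox[3]),
                 y = pmin(pmax(gy + stats::rnorm(n, 0, jit), bbox[2]), bbox[4]))
    },
    clustered = {
      k <- max(1L, as.integer(round(n / 25)))
      cx <- stats::runif(k, bbox[1], bbox[3])
      cy <- stats::runif(k, bbox[2], bbox[4])
      id <- sample.int(k, n, replace = TRUE)
      sd <- 0.03 * min(w, h)
      data.frame(x = pmin(pmax(cx[id] + stats::rnorm(n, 0, sd), bbox[1]), bbox[3]),
                 y = pmin(pmax(cy[id] + stats::rnorm(n, 0, sd), bbox[2]), bbox[4]))
    })
}

#' Generate a synthetic site
#'
#' Places structures according to the spec's layout and draws occupants per
#' residential structure from a discretized gamma distribution with the
#' stated mean and dispersion (coefficient of variation), floored at one
#' occupant. The true population is the sum of occupants over residential
#' structures. Deterministic given the seed.
#'
#' @param spec a [site_spec()].
#' @param seed RNG seed.
#' @return a `true_site` list with `structures` (data frame: `x`, `y`,
#'   `category`, `residential`, `occupants`), `true_population`,
#'   `mean_structure_occupancy` and the `spec`.
#' @export
generate_site <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "site_spec"))
  with_seed(seed, {
    cats <- names(spec$n_structures)
    parts <- lapply(cats, function(cat) {
      n <- spec$n_structures[[cat]]
      xy <- place_structures(n, spec$bbox, spec$layout)
      res <- !(cat %in% spec$non_residential)
      occ <- if (!res || n == 0L) rep(0L, n) else draw_occupants(
        n, spec$occupancy_mean, spec$occupancy_dispersion)
      data.frame(x = xy$x, y = xy$y, category = rep(cat, n),
                 residential = rep(res, n), occupants = occ,
                 stringsAsFactors = FALSE)
    })
    st <- do.call(rbind, parts)
    n_res <- sum(st$residential)
    pop <- sum(st$occupants)
    structure(list(structures = st,
                   true_population = pop,
                   n_residential = n_res,
                   mean_structure_occupancy = if (n_res) pop / n_res else NA_real_,
                   spec = spec),
              class = "true_site")
  })
}

draw_occupants <- function(n, mean, cv) {
  raw <- if (cv == 0) rep(mean, n) else {
    shape <- 1 / cv^2
    stats::rgamma(n, shape = shape, rate = shape / mean)
  }
  as.integer(pmax(1, round_half_away(raw)))
}

#' @export
print.true_site <- function(x, ...) {
  cat(sprintf("Synthetic site: %d structures (%d residential), true population %s\n",
              nrow(x$structures), x$n_residential,
              format(x$true_population, big.mark = ",")))
  invisible(x)
}

#' Specify an imperfect analyst
#'
#' Models the counting errors observed between independent analysts: missed
#' detections (per-category detection probability), spurious marks (false
#' positives such as straw bales or debris marked as dwellings, expressed as
#' expected spurious marks per true structure) and category confusion (a row
#' stochastic matrix over categories, e.g. tents marked as houses).
#'
#' @param detection detection probability in `[0, 1]`; scalar or named per
#'   category.
#' @param fp_rate expected false-positive marks per true structure (>= 0).
#' @param confusion optional square row-stochastic matrix with category
#'   names on both dimensions; identity when `NULL`.
#' @param fp_category category label given to false-positive marks; defaults
#'   to the site's first residential category.
#' @return an `analyst_model` object.
#' @export
analyst_model <- function(detection = 1, fp_rate = 0, confusion = NULL,
                          fp_category = NULL) {
  if (any(detection < 0 | detection > 1)) stop("detection must lie in [0, 1]")
  if (fp_rate < 0) stop("fp_rate must be non-negative")
  if (!is.null(confusion)) {
    stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
    if (any(abs(rowSums(confusion) - 1) > 1e-8))
      stop("confusion matrix rows must sum to 1")
  }
  structure(list(detection = detection, fp_rate = fp_rate,
                 confusion = confusion, fp_category = fp_category),
            class = "analyst_model")
}

#' Simulate one analyst's structure marks
#'
#' Each true structure is marked independently with the model's detection
#' probability; false positives are added as a Poisson count with the
#' stated per-structure rate, placed uniformly in the bounding box; marked
#' categories are then relabelled through the confusion matrix.
#' Deterministic given the seed.
#'
#' @param site a [generate_site()] result.
#' @param model an [analyst_model()].
#' @param analyst_id label for the simulated analyst.
#' @param seed RNG seed.
#' @return a `structure_marks` data frame (residential flags follow
#'   [site_category_map()]).
#' @export
simulate_analyst <- function(site, model, analyst_id = "A1", seed = 1) {
  stopifnot(inherits(site, "true_site"), inherits(model, "analyst_model"))
  st <- site$structures
  cmap <- site_category_map(site, model)
  with_seed(seed, {
    p <- if (is.null(names(model$detection)))
      rep(model$detection, nrow(st)) else {
        pv <- model$detection[st$category]
        pv[is.na(pv)] <- 1
        pv
      }
    hit <- stats::runif(nrow(st)) < p
    marks <- st[hit, c("x", "y", "category"), drop = FALSE]
    n_fp <- stats::rpois(1, model$fp_rate * nrow(st))
    if (n_fp > 0) {
      bb <- site$spec$bbox
      fp_cat <- model$fp_category %||% names(which(cmap))[1]
      marks <- rbind(marks, data.frame(
        x = stats::runif(n_fp, bb[1], bb[3]),
        y = stats::runif(n_fp, bb[2], bb[4]),
        category = rep(fp_cat, n_fp), stringsAsFactors = FALSE))
    }
    if (!is.null(model$confusion) && nrow(marks)) {
      cm <- model$confusion
      marks$category <- vapply(marks$category, function(cc) {
        if (!cc %in% rownames(cm)) return(cc)
        sample(colnames(cm), 1, prob = cm[cc, ])
      }, "")
    }
    marks$analyst_id <- rep(analyst_id, nrow(marks))
    rownames(marks) <- NULL
    as_structure_marks(marks[, c("x", "y", "analyst_id", "category")], cmap)
  })
}

#' Category-to-residential map implied by a synthetic site
#'
#' @param site a [generate_site()] result.
#' @param model optional [analyst_model()]; its confusion-matrix and
#'   false-positive categories are included in the map.
#' @return named logical vector suitable for [as_structure_marks()].
#' @export
site_category_map <- function(site, model = NULL) {
  cats <- names(site$spec$n_structures)
  if (!is.null(model)) {
    if (!is.null(model$confusion)) cats <- union(cats, colnames(model$confusion))
    if (!is.null(model$fp_category)) cats <- union(cats, model$fp_category)
  }
  stats::setNames(!(cats %in% site$spec$non_residential), cats)
}

#' Specify a bank of synthetic occupancy reports
#'
#' Each row of `tiers` describes one evidence tier: the rubric attribute
#' levels attached to its reports (`provenance`, `method`, `unit`), the
#' multiplicative `bias` applied to the true occupancy, the relative `noise`
#' (standard deviation of a multiplicative factor centred on 1, truncated
#' below at 0.05), and the number of reports `n` drawn from the tier.
#'
#' @param tiers data frame with columns `provenance`, `method`, `unit`,
#'   `bias`, `noise`, `n`.
#' @return a `report_model` object.
#' @export
report_model <- function(tiers = data.frame(
                           provenance = "site_current",
                           method = "other_survey",
                           unit = "per_household_consistent_with_structure",
                           bias = 1, noise = 0, n = 1,
                           stringsAsFactors = FALSE)) {
  stopifnot(is.data.frame(tiers),
            all(c("provenance", "method", "unit", "bias", "noise", "n")
                %in% names(tiers)))
  if (any(tiers$bias <= 0)) stop("bias must be positive")
  if (any(tiers$noise < 0)) stop("noise must be non-negative")
  structure(list(tiers = tiers), class = "report_model")
}

#' Simulate an occupancy-report registry for a synthetic site
#'
#' Report values are the site's true mean structure occupancy (converted to
#' per-household units where the tier reports households), multiplied by the
#' tier's bias and a noise factor. Collection dates are placed so each
#' tier's provenance level is honoured (current tiers ~1 year before the
#' analysis date, previous-period and pre-displacement tiers 5 years
#' before). Deterministic given the seed.
#'
#' @param site a [generate_site()] result.
#' @param model a [report_model()].
#' @param analysis_date analysis date the registry refers to.
#' @param seed RNG seed.
#' @return a registry data frame accepted by [score_reports()] / [popest()].
#' @export
simulate_reports <- function(site, model, analysis_date = "2020-01-01",
                             seed = 1) {
  stopifnot(inherits(site, "true_site"), inherits(model, "report_model"))
  analysis_date <- as_date_strict(analysis_date)
  true_occ <- site$mean_structure_occupancy
  hps <- site$spec$households_per_structure
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(model$tiers)), function(t) {
      tier <- model$tiers[t, ]
      if (tier$n == 0L) return(NULL)
      base <- if (tier$unit == "per_structure") true_occ else true_occ / hps
      fac <- pmax(0.05, 1 + stats::rnorm(tier$n, 0, tier$noise))
      cd <- if (tier$provenance %in% c("site_current", "region_current"))
        analysis_date - 365 else date_minus_years(analysis_date, 5)
      data.frame(report_id = sprintf("tier%d_r%d", t, seq_len(tier$n)),
                 occupancy_value = base * tier$bias * fac,
                 unit = tier$unit, provenance = tier$provenance,
                 method = tier$method,
                 collection_date = cd,
                 full_text_available = TRUE, has_primary_data = TRUE,
                 urban_population = TRUE,
                 citation = sprintf("synthetic tier %d", t),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Recovery experiment: estimator bias and RMSE against known truth
#'
#' Runs the full pipeline — generate site, simulate independent analysts,
#' consensus count, simulate and score occupancy reports, pooled occupancy,
#' population estimate — over `n_reps` replicates and summarises the signed
#' relative error of the estimate against the known true population. With a
#' perfect analyst and unbiased reports the mean relative error is zero in
#' expectation; with detection probability p (and no false positives or
#' report bias) it is p - 1.
#'
#' @param spec a [site_spec()].
#' @param analyst an [analyst_model()].
#' @param reports a [report_model()].
#' @param n_reps number of replicates (>= 1).
#' @param n_analysts number of independent analysts per replicate.
#' @param seed master RNG seed; replicate seeds are derived from it.
#' @param analysis_date analysis date used for scoring.
#' @return a `recovery_experiment` list with `mean_relative_error`, `rmse`
#'   (both on the relative-error scale), and per-replicate `rel_errors`,
#'   `estimates`, `truths`.
#' @export
run_recovery_experiment <- function(spec, analyst, reports, n_reps = 100,
                                    n_analysts = 2, seed = 1,
                                    analysis_date = "2020-01-01") {
  stopifnot(n_reps >= 1)
  seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, n_reps * (n_analysts + 2L)),
           nrow = n_reps))
  site_cf <- site_config("synthetic", analysis_date,
                         households_per_structure =
                           spec$households_per_structure)
  out <- vapply(seq_len(n_reps), function(r) {
    site <- generate_site(spec, seed = seeds[r, 1])
    marks <- do.call(rbind, lapply(seq_len(n_analysts), function(a)
      simulate_analyst(site, analyst, analyst_id = paste0("A", a),
                       seed = seeds[r, 1 + a])))
    class(marks) <- c("structure_marks", "data.frame")
    registry <- simulate_reports(site, reports, analysis_date,
                                 seed = seeds[r, n_analysts + 2])
    fit <- popest(marks, registry, site_cf)
    c(est = fit$population, truth = site$true_population)
  }, c(est = 0, truth = 0))
  rel <- (out["est", ] - out["truth", ]) / out["truth", ]
  structure(list(mean_relative_error = mean(rel),
                 rmse = sqrt(mean(rel^2)),
                 rel_errors = unname(rel),
                 estimates = unname(out["est", ]),
                 truths = unname(out["truth", ]),
                 n_reps = n_reps),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf(
    "Recovery experiment (%d replicates): mean relative error %+.2f%%, RMSE %.2f%%\n",
    x$n_reps, 100 * x$mean_relative_error, 100 * x$rmse))
  invisible(x)
}
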