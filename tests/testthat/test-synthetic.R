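test_that("site generation is deterministic and honours degenerate occupancy", {
  spec <- site_spec(c(hut = 100), occupancy_mean = 5,
                    occupancy_dispersion = 0)
  s1 <- generate_site(spec, seed = 3)
  expect_equal(s1$true_population, 500)
  expect_equal(generate_site(spec, seed = 3), s1)
  expect_false(identical(generate_site(spec, seed = 4)$structures,
                         s1$structures))

  empty <- generate_site(site_spec(c(hut = 0)), seed = 1)
  expect_equal(empty$true_population, 0)

  expect_error(site_spec(c(hut = 10), occupancy_mean = -1), "invalid")

  bb <- site_spec(c(hut = 300), layout = "clustered")$bbox
  cl <- generate_site(site_spec(c(hut = 300), layout = "clustered"), seed = 5)
  expect_true(all(cl$structures$x >= bb[1] & cl$structures$x <= bb[3]))
  expect_true(all(cl$structures$y >= bb[2] & cl$structures$y <= bb[4]))
})

test_that("non-residential categories carry no occupants", {
  spec <- site_spec(c(hut = 50, latrine = 10), occupancy_mean = 4,
                    occupancy_dispersion = 0, non_residential = "latrine")
  s <- generate_site(spec, seed = 2)
  expect_equal(s$n_residential, 50)
  expect_equal(s$true_population, 200)
  expect_true(all(s$structures$occupants[!s$structures$residential] == 0))
})

test_that("a perfect analyst reproduces the truth and a blind one marks nothing", {
  spec <- site_spec(c(hut = 80), occupancy_dispersion = 0)
  site <- generate_site(spec, seed = 1)
  perfect <- simulate_analyst(site, analyst_model(), "A1", seed = 2)
  expect_equal(nrow(perfect), 80)
  expect_equal(sort(perfect$x), sort(site$structures$x))
  expect_true(all(perfect$residential))

  blind <- simulate_analyst(site, analyst_model(detection = 0), "A1", seed = 2)
  expect_equal(nrow(blind), 0)
})

test_that("mark counts are binomial in the detection probability", {
  spec <- site_spec(c(hut = 1000), occupancy_dispersion = 0)
  site <- generate_site(spec, seed = 10)
  counts <- vapply(1:200, function(r)
    nrow(simulate_analyst(site, analyst_model(detection = 0.9), seed = r)),
    0L)
  se <- sqrt(1000 * 0.9 * 0.1 / 200)
  expect_lt(abs(mean(counts) - 900), 3 * se)
})

test_that("false positives and category confusion feed the residential count", {
  spec <- site_spec(c(hut = 200, latrine = 50), occupancy_dispersion = 0,
                    non_residential = "latrine")
  site <- generate_site(spec, seed = 6)
  am <- analyst_model(fp_rate = 0.2, fp_category = "hut")
  n_fp <- vapply(1:100, function(r)
    sum(simulate_analyst(site, am, seed = r)$residential) - 200, 0)
  expect_lt(abs(mean(n_fp) - 0.2 * 250), 3 * sqrt(0.2 * 250 / 100))

  cm <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("hut", "latrine"), c("hut", "latrine")))
  swapped <- simulate_analyst(site, analyst_model(confusion = cm), seed = 3)
  expect_equal(sum(swapped$category == "latrine"), 200)
  expect_equal(sum(swapped$category == "hut"), 50)
})

test_that("report tiers apply bias and noise around the true occupancy", {
  spec <- site_spec(c(hut = 100), occupancy_mean = 5, occupancy_dispersion = 0)
  site <- generate_site(spec, seed = 1)

  exact <- simulate_reports(site, report_model(), seed = 2)
  expect_equal(exact$occupancy_value, 5)

  two <- report_model(data.frame(
    provenance = c("site_current", "region_current"),
    method = "other_survey",
    unit = "per_household_consistent_with_structure",
    bias = c(0.8, 1.2), noise = 0, n = c(1, 1)))
  reg <- simulate_reports(site, two, seed = 2)
  wm <- weighted_mean_occupancy(score_reports(reg, "2020-01-01"))
  expect_gte(wm$weighted_mean, 0.8 * 5)
  expect_lte(wm$weighted_mean, 1.2 * 5)

  half <- report_model(data.frame(provenance = "site_current",
                                  method = "other_survey",
                                  unit = "per_structure",
                                  bias = 0.5, noise = 0, n = 1))
  reg <- simulate_reports(site, half, seed = 2)
  fit <- popest(100, reg, site_config("synthetic", "2020-01-01"))
  expect_equal(fit$population / site$true_population, 0.5, tolerance = 0.01)
})

test_that("the full pipeline recovers the truth and tracks detection loss", {
  spec <- site_spec(c(hut = 400), occupancy_mean = 5,
                    occupancy_dispersion = 0.3)
  noisy_reports <- report_model(data.frame(
    provenance = "site_current", method = "other_survey",
    unit = "per_household_consistent_with_structure",
    bias = 1, noise = 0.05, n = 3))

  unbiased <- run_recovery_experiment(spec, analyst_model(), noisy_reports,
                                      n_reps = 100, seed = 42)
  expect_lt(abs(unbiased$mean_relative_error), 0.01)

  lossy <- run_recovery_experiment(spec, analyst_model(detection = 0.8),
                                   noisy_reports, n_reps = 100, seed = 42)
  expect_lt(abs(lossy$mean_relative_error - (-0.20)), 0.015)
  expect_gte(lossy$rmse, abs(lossy$mean_relative_error))

  # deterministic end to end
  again <- run_recovery_experiment(spec, analyst_model(detection = 0.8),
                                   noisy_reports, n_reps = 100, seed = 42)
  expect_equal(again, lossy)

  # single replicate with all randomness off is exact
  exact <- run_recovery_experiment(
    site_spec(c(hut = 250), occupancy_mean = 4, occupancy_dispersion = 0),
    analyst_model(), report_model(), n_reps = 1, seed = 1)
  expect_equal(exact$mean_relative_error, 0)
  expect_equal(exact$rmse, 0)
})

test_that("estimates rise with detection probability and report bias", {
  spec <- site_spec(c(hut = 300), occupancy_mean = 5,
                    occupancy_dispersion = 0.2)
  mean_est <- function(p, bias) {
    rm <- report_model(data.frame(provenance = "site_current",
                                  method = "other_survey",
                                  unit = "per_structure",
                                  bias = bias, noise = 0, n = 2))
    mean(run_recovery_experiment(spec, analyst_model(detection = p), rm,
                                 n_reps = 20, seed = 9)$estimates)
  }
  by_p <- c(mean_est(0.6, 1), mean_est(0.8, 1), mean_est(1, 1))
  expect_true(all(diff(by_p) > 0))
  by_bias <- c(mean_est(0.9, 0.8), mean_est(0.9, 1.0), mean_est(0.9, 1.2))
  expect_true(all(diff(by_bias) > 0))
})

test_that("expected estimate matches detection x (1 + fp) x bias x truth", {
  spec <- site_spec(c(hut = 400), occupancy_mean = 5, occupancy_dispersion = 0)
  rm <- report_model(data.frame(provenance = "site_current",
                                method = "other_survey",
                                unit = "per_structure",
                                bias = 0.9, noise = 0, n = 1))
  ex <- run_recovery_experiment(spec, analyst_model(detection = 0.9,
                                                    fp_rate = 0.1),
                                rm, n_reps = 100, seed = 17)
  expected <- 0.9 * 1.1 * 0.9 - 1
  expect_lt(abs(ex$mean_relative_error - expected), 0.015)
})
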