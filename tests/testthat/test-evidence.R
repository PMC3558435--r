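analysis <- as.Date("2010-01-31")

test_that("eligibility rules exclude with the violated rule logged", {
  reports <- rbind(
    make_report("recent", collection_date = "2008-03-01"),
    make_report("too_old", collection_date = "1998-01-01"),
    make_report("future", collection_date = "2010-06-01"),
    make_report("undated", collection_date = NA),
    make_report("no_text", collection_date = "2008-03-01",
                full_text_available = FALSE),
    make_report("secondary", collection_date = "2008-03-01",
                has_primary_data = FALSE),
    make_report("rural", collection_date = "2008-03-01",
                urban_population = FALSE))

  camp <- filter_eligible(reports, analysis, "camp")
  expect_setequal(camp$eligible$report_id, c("recent", "rural"))
  reasons <- setNames(camp$excluded$exclusion_reason, camp$excluded$report_id)
  expect_equal(reasons[["too_old"]], "older than 10y window")
  expect_equal(reasons[["undated"]], "undated")
  expect_equal(reasons[["future"]], "collected after analysis date")
  expect_equal(reasons[["no_text"]], "full text unavailable")
  expect_equal(reasons[["secondary"]], "no primary occupancy data")

  urban <- filter_eligible(reports, analysis, "urban")
  expect_false("rural" %in% urban$eligible$report_id)
  expect_equal(urban$excluded$exclusion_reason[
    urban$excluded$report_id == "rural"], "non-urban")

  # idempotent: filtering the eligible subset drops nothing further
  again <- filter_eligible(camp$eligible, analysis, "camp")
  expect_equal(again$eligible, camp$eligible)
  expect_equal(nrow(again$excluded), 0)
})

test_that("ten-year window boundary is inclusive in whole days", {
  exactly_10y <- make_report("edge", collection_date = "2000-01-31")
  one_day_more <- make_report("past", collection_date = "2000-01-30")
  expect_equal(nrow(filter_eligible(exactly_10y, analysis)$eligible), 1)
  expect_equal(nrow(filter_eligible(one_day_more, analysis)$eligible), 0)
})

test_that("representativeness points follow site/region provenance and recency", {
  expect_equal(classify_representativeness("site_current", "2009-02-01",
                                           analysis), 10)
  expect_equal(classify_representativeness("region_current", "2008-02-01",
                                           analysis), 8)
  expect_equal(classify_representativeness("site_current", "2005-01-31",
                                           analysis), 4)  # 5y before: previous period
  expect_equal(classify_representativeness("site_or_region_previous",
                                           "2003-06-01", analysis), 4)
  expect_equal(classify_representativeness("pre_displacement", "2005-01-01",
                                           analysis), 2)
  # exactly 3y before counts as within 3y
  expect_equal(classify_representativeness("site_current", "2007-01-31",
                                           analysis), 10)
  expect_error(classify_representativeness("site_current", "1995-01-01",
                                           analysis), "10y")
})

test_that("method points honour the strict large-survey thresholds", {
  expect_equal(classify_method("census_registration_surveillance"), 10)
  expect_equal(classify_method("anecdotal"), 1)
  expect_equal(classify_method("rapid_assessment"), 4)
  expect_equal(classify_method(design = survey_design("cluster", 450, 30)), 8)
  expect_equal(classify_method(design = survey_design("cluster", 450, 20)), 6)
  expect_equal(classify_method(design = survey_design("cluster", 400, 30)), 6)
  expect_equal(classify_method(design = survey_design("simple", 201)), 8)
  expect_equal(classify_method(design = survey_design("simple", 200)), 6)
  expect_equal(classify_method(design = survey_design(
    "simple", 500, has_technical_flaw = TRUE)), 6)
  expect_error(survey_design("cluster", 450), "n_clusters")
})

test_that("unit points distinguish structures from household definitions", {
  expect_equal(classify_unit("per_structure"), 10)
  expect_equal(classify_unit("per_household_consistent_with_structure"), 6)
  expect_equal(classify_unit("per_household_other"), 1)
})

test_that("information score is the product of the three attribute points", {
  best <- information_score(make_report(collection_date = "2009-06-01"),
                            analysis)
  expect_equal(best$score, 1000)

  worst <- information_score(
    make_report(provenance = "pre_displacement", method = "anecdotal",
                unit = "per_household_other", collection_date = "2005-01-01"),
    analysis)
  expect_equal(worst$score, 2)

  mid <- information_score(
    make_report(provenance = "site_or_region_previous",
                method = "rapid_assessment", unit = "per_household_other",
                collection_date = "2004-01-01"),
    analysis)
  expect_equal(mid$score, 16)
  expect_equal(mid$points_representativeness * mid$points_method *
                 mid$points_unit, mid$score)
})

test_that("survey-design columns drive the method points when scoring a registry", {
  reg <- rbind(
    make_report("big", method = NA, sampling_scheme = "cluster",
                n_households = 500, n_clusters = 25,
                collection_date = "2009-06-01",
                unit = "per_household_consistent_with_structure"),
    make_report("small", method = NA, sampling_scheme = "simple",
                n_households = 50, collection_date = "2009-06-01",
                unit = "per_household_consistent_with_structure"))
  scored <- score_reports(reg, analysis)
  expect_equal(scored$points_2, c(8, 6))
  expect_equal(scored$score, c(10 * 8 * 6, 10 * 6 * 6))
})

test_that("every legal score factors into attribute points and improving one attribute never hurts", {
  rubric <- load_rubric()
  combos <- rubric_combos(rubric)
  scores <- combos$p1 * combos$p2 * combos$p3
  expect_true(all(scores >= 2 & scores <= 1000))
  expect_equal(max(scores), 1000)
  expect_equal(min(scores), 2)
  # monotonicity in each attribute, others fixed
  for (attr_i in 1:3) {
    others <- setdiff(1:3, attr_i)
    split_key <- interaction(combos[[others[1]]], combos[[others[2]]])
    for (grp in split(combos, split_key)) {
      ord <- order(grp[[attr_i]])
      s <- grp$p1[ord] * grp$p2[ord] * grp$p3[ord]
      expect_true(all(diff(s) >= 0))
    }
  }
})

test_that("information index sums scores, is permutation-invariant and additive", {
  expect_identical(information_index(16), 16L)
  expect_identical(information_index(c(1000, 2)), 1002L)
  expect_identical(information_index(numeric(0)), 0L)
  set.seed(4)
  combos <- rubric_combos()
  s <- sample(combos$p1 * combos$p2 * combos$p3, 12)
  expect_identical(information_index(s), information_index(rev(s)))
  expect_identical(information_index(s),
                   information_index(s[1:5]) + information_index(s[6:12]))
})
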