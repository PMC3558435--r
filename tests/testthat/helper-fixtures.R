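# Builders for small in-code fixtures used across the test files.

make_report <- function(report_id = "r1", occupancy_value = 6.0,
                        unit = "per_structure",
                        provenance = "site_current",
                        method = "census_registration_surveillance",
                        collection_date = "2005-06-01",
                        sampling_scheme = NA, n_households = NA,
                        n_clusters = NA, has_technical_flaw = FALSE,
                        full_text_available = TRUE, has_primary_data = TRUE,
                        urban_population = TRUE) {
  data.frame(report_id = report_id, occupancy_value = occupancy_value,
             unit = unit, provenance = provenance, method = method,
             collection_date = collection_date,
             sampling_scheme = sampling_scheme, n_households = n_households,
             n_clusters = n_clusters, has_technical_flaw = has_technical_flaw,
             full_text_available = full_text_available,
             has_primary_data = has_primary_data,
             urban_population = urban_population,
             stringsAsFactors = FALSE)
}

make_marks <- function(x, y, analyst_id, category,
                       category_map = c(hut = TRUE, tent = TRUE,
                                        latrine = FALSE)) {
  as_structure_marks(data.frame(x = x, y = y, analyst_id = analyst_id,
                                category = category,
                                stringsAsFactors = FALSE),
                     category_map)
}

# GeoJSON text for a 3-point file: two huts and a latrine by analyst A.
# drop_category_at: feature index whose category property is omitted.
geojson_three_points <- function(drop_category_at = integer(0)) {
  feat <- function(i, x, y, cat) {
    props <- if (i %in% drop_category_at) '{"analyst_id": "A"}'
      else sprintf('{"analyst_id": "A", "category": "%s"}', cat)
    sprintf('{"type": "Feature", "geometry": {"type": "Point", "coordinates": [%g, %g]}, "properties": %s}',
            x, y, props)
  }
  fs <- mapply(feat, 1:3, c(10, 20, 30), c(5, 15, 25),
               c("hut", "hut", "latrine"))
  paste0('{"type": "FeatureCollection", "features": [',
         paste(fs, collapse = ", "), ']}')
}

# All legal rubric point combinations and their products.
rubric_combos <- function(rubric = load_rubric()) {
  expand.grid(p1 = rubric$representativeness, p2 = rubric$method,
              p3 = rubric$unit)
}
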