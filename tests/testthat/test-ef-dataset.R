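test_that("compute_ef does the control-plot arithmetic and keeps negatives", {
  expect_equal(compute_ef(2.0, 1.0, 100), 0.01)
  expect_equal(compute_ef(1.37, 1.37, 250), 0.0)
  expect_equal(compute_ef(0.34, 1.94, 100), -0.016)
})

test_that("compute_ef rejects unusable inputs explicitly", {
  expect_error(compute_ef(2, 1, 0), "n_input")
  expect_error(compute_ef(2, 1, -50), "n_input")
  expect_error(compute_ef(2, 1, NA), "n_input")
  expect_error(compute_ef(2, NA, 100), "control")
})

test_that("compute_ef is linear in the treatment flux and antisymmetric", {
  t0 <- runif(20, 0, 5); c0 <- runif(20, 0, 5); n0 <- runif(20, 50, 400)
  expect_equal(compute_ef(2 * t0, c0, n0) - compute_ef(t0, c0, n0),
               t0 / n0)
  expect_equal(compute_ef(t0, c0, n0), -compute_ef(c0, t0, n0))
})

test_that("filter_studies drops each exclusion class with its reason code", {
  recs <- make_records(
    make_record("ok"),
    make_record("rice", flooded_rice = TRUE),
    make_record("lab", lab_or_model = TRUE),
    make_record("graze", grazed_excreta = TRUE),
    make_record("eef", enhanced_efficiency = TRUE),
    make_record("peat", organic_soil = TRUE),
    make_record("grey", peer_reviewed = FALSE),
    make_record("noctl", n2o_control = NA),
    make_record("non", n_input = 0)
  )
  out <- filter_studies(recs)
  expect_equal(out$retained$record_id, "ok")
  expect_equal(nrow(out$retained) + nrow(out$excluded), nrow(recs))
  got <- setNames(out$excluded$reason_code, out$excluded$record_id)
  expect_equal(got[["rice"]], "FLOODED_RICE")
  expect_equal(got[["lab"]], "LAB_STUDY")
  expect_equal(got[["graze"]], "GRAZED_EXCRETA")
  expect_equal(got[["eef"]], "ENHANCED_EFFICIENCY")
  expect_equal(got[["peat"]], "ORGANIC_SOIL")
  expect_equal(got[["grey"]], "NOT_PEER_REVIEWED")
  expect_equal(got[["noctl"]], "NO_CONTROL")
  expect_equal(got[["non"]], "NONPOSITIVE_N_INPUT")
})

test_that("filter_studies passes missing provenance flags with a warning and keeps rows intact", {
  recs <- make_records(make_record("a"), make_record("b"))
  recs$flooded_rice[2] <- NA
  expect_warning(out <- filter_studies(recs), "flooded_rice")
  expect_equal(out$retained$record_id, c("a", "b"))
  ## retained rows are the input rows, unmodified
  expect_equal(out$retained[, names(recs)], recs)
  ## empty input is not an error
  empty <- filter_studies(make_record()[0, ])
  expect_equal(nrow(empty$retained), 0)
  expect_equal(nrow(empty$excluded), 0)
})

test_that("climate classification follows the precipitation/PET rules with ties to wet", {
  expect_equal(classify_climate("tropical", annual_precip = 900), "dry")
  expect_equal(classify_climate("tropical", annual_precip = 1500), "wet")
  expect_equal(classify_climate("temperate_boreal", pet_ratio = 1.2), "wet")
  expect_equal(classify_climate("temperate_boreal", pet_ratio = 0.8), "dry")
  ## boundary: equality assigned to the wetter class, configurable
  expect_equal(classify_climate("temperate_boreal", pet_ratio = 1.0), "wet")
  expect_equal(classify_climate("tropical", annual_precip = 1000), "wet")
  expect_equal(classify_climate("temperate_boreal", pet_ratio = 1.0,
                                boundary = "dry"), "dry")
  ## missing covariate -> unclassifiable, unknown zone -> error
  expect_true(is.na(classify_climate("tropical", annual_precip = NA)))
  expect_error(classify_climate("mediterranean", annual_precip = 400), "zone")
})

test_that("fertilizer form pools synthetic with mixtures, keeps pure organic apart", {
  expect_equal(classify_fertilizer_form(TRUE, FALSE), "synthetic_mixed")
  expect_equal(classify_fertilizer_form(FALSE, TRUE), "organic")
  expect_equal(classify_fertilizer_form(TRUE, TRUE), "synthetic_mixed")
  expect_true(is.na(classify_fertilizer_form(FALSE, FALSE)))
})

test_that("covariate classes use the documented bins and thresholds", {
  d <- make_records(
    make_record("a", n_input = 100, usda_texture = "silty clay",
                soil_c_pct = 2.0, soil_ph = 7.0, length_days = 120,
                land_cover_raw = "undefined"),
    make_record("b", n_input = 100.5, usda_texture = "loamy sand",
                soil_c_pct = 1.99, soil_ph = 6.99, length_days = 301,
                land_cover_raw = "tree_plantation"),
    make_record("c", n_input = 300, usda_texture = NA,
                soil_c_pct = NA, soil_ph = NA, length_days = 200,
                land_cover_raw = "grassland")
  )
  cd <- classify_dataset(d)
  expect_equal(cd$n_rate, c("(0;100]", "(100;200]", "(200;300]"))
  expect_equal(cd$texture, c("fine", "medium_coarse", NA))
  expect_equal(cd$soil_c, c("high", "low_medium", NA))
  expect_equal(cd$alkalinity, c("basic", "acid", NA))
  expect_equal(cd$length, c("<=120", ">300", "(180;240]"))
  expect_equal(cd$land_cover, c("annual_bare", "perennial", "perennial"))
  ## ef derived on the way through
  expect_equal(cd$ef, (cd$n2o_treatment - cd$n2o_control) / cd$n_input)
})

test_that("every observation gets exactly one class per factor it has data for", {
  d <- classify_dataset(generate_ef_observations(ef_generator_config(seed = 11)))
  for (f in c("climate", "fertilizer_form", "n_rate", "land_cover", "length")) {
    expect_true(all(!is.na(d[[f]])), info = f)  # covariate always present here
  }
  ## texture/soil/pH may be missing: NA only where the covariate is missing
  expect_equal(is.na(d$texture), is.na(d$usda_texture))
  expect_equal(is.na(d$soil_c), is.na(d$soil_c_pct))
  expect_equal(is.na(d$alkalinity), is.na(d$soil_ph))
  ## irrigation is a dry-climate factor only
  expect_true(all(is.na(d$irrigation[d$climate == "wet"])))
  expect_true(all(!is.na(d$irrigation[d$climate == "dry"])))
})

test_that("locations merge by shared coordinates or by reference+soil+cover", {
  d <- make_records(
    make_record("r1", latitude = 10, longitude = 20, reference_id = "A",
                land_cover_raw = "annual_crop"),
    make_record("r2", latitude = 10, longitude = 20, reference_id = "B",
                land_cover_raw = "grassland"),           # same coords, all else differs
    make_record("r3", latitude = NA, longitude = NA, reference_id = "C",
                usda_texture = "clay", land_cover_raw = "annual_crop"),
    make_record("r4", latitude = NA, longitude = NA, reference_id = "C",
                usda_texture = "clay", land_cover_raw = "annual_crop"),
    make_record("r5", latitude = 50, longitude = -3, reference_id = "D"),
    make_record("r6", latitude = 51, longitude = -3, reference_id = "E")
  )
  loc <- assign_locations(d)
  expect_equal(loc[1], loc[2])
  expect_equal(loc[3], loc[4])
  expect_true(loc[5] != loc[6])
  expect_true(loc[1] != loc[3])
})

test_that("location assignment is a transitive partition, stable under reordering", {
  ## chain: a~b via coordinates, b~c via reference+soil+cover => one location
  d <- make_records(
    make_record("a", latitude = 1, longitude = 1, reference_id = "X",
                usda_texture = "loam", land_cover_raw = "annual_crop"),
    make_record("b", latitude = 1, longitude = 1, reference_id = "Y",
                usda_texture = "clay", land_cover_raw = "grassland"),
    make_record("c", latitude = 2, longitude = 2, reference_id = "Y",
                usda_texture = "clay", land_cover_raw = "grassland")
  )
  loc <- assign_locations(d)
  expect_equal(length(unique(loc)), 1L)
  shuffled <- d[c(3, 1, 2), ]
  loc2 <- assign_locations(shuffled)
  expect_equal(length(unique(loc2)), 1L)
  ## same ids for the same records regardless of row order
  expect_equal(setNames(loc, d$record_id)[shuffled$record_id],
               setNames(loc2, shuffled$record_id))
})

test_that("summarize_dataset counts match construction and handle empty input", {
  d <- classify_dataset(make_records(
    make_record("a", pet_ratio = 1.5), make_record("b", pet_ratio = 1.5),
    make_record("c", pet_ratio = 0.5)))
  s <- summarize_dataset(d, factors = "climate")
  expect_equal(s$n[s$class == "wet"], 2)
  expect_equal(s$n[s$class == "dry"], 1)
  s0 <- summarize_dataset(d[0, ], factors = "climate")
  expect_true(all(s0$n == 0))
})

test_that("the generated dataset is dominated by wet-climate observations", {
  d <- classify_dataset(generate_ef_observations(ef_generator_config(seed = 3)))
  share_wet <- mean(d$climate == "wet")
  expect_gt(share_wet, 0.65)
  expect_lt(share_wet, 0.85)
})
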