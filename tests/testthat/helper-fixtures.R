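## In-code fixtures shared across the test files.

## A minimal raw EF record with sane defaults; override any field.
make_record <- function(record_id = "R1", reference_id = "REF1",
                        latitude = 45.5, longitude = 3.2,
                        climate_zone = "temperate_boreal",
                        annual_precip = NA, pet_ratio = 1.2,
                        n2o_treatment = 2.0, n2o_control = 1.0, n_input = 100,
                        fertilizer_synthetic = TRUE, fertilizer_organic = FALSE,
                        land_cover_raw = "annual_crop", usda_texture = "loam",
                        soil_c_pct = 1.5, soil_ph = 6.5, length_days = 150,
                        irrigated = FALSE, flooded_rice = FALSE,
                        grazed_excreta = FALSE, enhanced_efficiency = FALSE,
                        organic_soil = FALSE, lab_or_model = FALSE,
                        peer_reviewed = TRUE) {
  data.frame(record_id = record_id, reference_id = reference_id,
             latitude = latitude, longitude = longitude,
             climate_zone = climate_zone, annual_precip = annual_precip,
             pet_ratio = pet_ratio, n2o_treatment = n2o_treatment,
             n2o_control = n2o_control, n_input = n_input,
             fertilizer_description = "urea",
             fertilizer_synthetic = fertilizer_synthetic,
             fertilizer_organic = fertilizer_organic,
             organic_state = "unspecified",
             land_cover_raw = land_cover_raw, usda_texture = usda_texture,
             soil_c_pct = soil_c_pct, soil_ph = soil_ph,
             length_days = length_days, irrigated = irrigated,
             flooded_rice = flooded_rice, grazed_excreta = grazed_excreta,
             enhanced_efficiency = enhanced_efficiency,
             organic_soil = organic_soil, lab_or_model = lab_or_model,
             peer_reviewed = peer_reviewed, stringsAsFactors = FALSE)
}

make_records <- function(...) do.call(rbind, list(...))

## Two-class dataset straight from the synthetic generator, keeping the
## generating truth as the model columns (location = true location).
gen_two_class <- function(seed, means = c(wet = 0.016, dry = 0.006),
                          n_loc = 30, m = 10,
                          var_location = 2e-4, var_residual = 4e-4) {
  d <- generate_ef_observations(ef_generator_config(
    factor_name = "climate", class_means = means,
    var_location = var_location, var_residual = var_residual,
    n_locations_per_class = rep(n_loc, length(means)),
    obs_per_location = m, seed = seed))
  data.frame(ef = d$ef, location = d$true_location, climate = d$true_class,
             stringsAsFactors = FALSE)
}

## Small OLS-route instance plus an arithmetic LSD oracle on it.
make_small_instance <- function(seed) {
  set.seed(seed)
  k <- sample(2:4, 1)
  classes <- paste0("cls", seq_len(k))
  mu <- runif(k, 0, 0.03)
  n_loc <- sample(3:6, 1)
  m <- sample(3:5, 1)
  rows <- do.call(rbind, lapply(seq_len(k), function(j) {
    data.frame(ef = rnorm(n_loc * m, mu[j], 0.01),
               location = paste0("L", j, "_", rep(seq_len(n_loc), each = m)),
               grp = classes[j], stringsAsFactors = FALSE)
  }))
  rows
}

## Hand-computed LSD pairwise p-values (OLS class means, pooled variance,
## containment residual df) -- the oracle for lsd_fisher on the OLS route.
oracle_lsd <- function(d, alpha = 0.05) {
  cls <- sort(unique(d$grp))
  n <- table(d$grp)[cls]
  ybar <- tapply(d$ef, d$grp, mean)[cls]
  rss <- sum((d$ef - ybar[d$grp])^2)
  s2 <- rss / (nrow(d) - length(cls))
  df <- nrow(d) - length(cls) - (length(unique(d$location)) - 1)
  pairs <- combn(length(cls), 2)
  data.frame(class1 = cls[pairs[1, ]], class2 = cls[pairs[2, ]],
             p = vapply(seq_len(ncol(pairs)), function(j) {
               i1 <- pairs[1, j]; i2 <- pairs[2, j]
               se <- sqrt(s2 * (1 / n[i1] + 1 / n[i2]))
               2 * pt(-abs((ybar[i1] - ybar[i2]) / se), df)
             }, numeric(1)), stringsAsFactors = FALSE)
}

## Asymptotic standard error of an empirical quantile of the triangular
## distribution (delta method with the analytic density).
triangular_density <- function(x, a, c, b) {
  ifelse(x <= c, 2 * (x - a) / ((b - a) * (c - a)),
         2 * (b - x) / ((b - a) * (b - c)))
}
quantile_se <- function(p, n, a, c, b) {
  q <- triangular_quantile(p, a, c, b)
  sqrt(p * (1 - p) / n) / triangular_density(q, a, c, b)
}
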