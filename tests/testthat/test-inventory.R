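test_that("triangular quantile matches symmetry, mode and a numeric inversion oracle", {
  expect_equal(triangular_quantile(0.5, 0.013, 0.016, 0.019), 0.016)
  ## the mode sits at its own CDF value
  a <- 0.003; c <- 0.010; b <- 0.030
  expect_equal(triangular_quantile((c - a) / (b - a), a, c, b), c)
  ## independent oracle: numeric inversion of the piecewise-quadratic CDF
  inv <- uniroot(function(x) triangular_cdf(x, a, c, b) - 0.975,
                 c(a, b), tol = 1e-12)$root
  expect_equal(triangular_quantile(0.975, a, c, b), inv, tolerance = 1e-9)
  expect_equal(triangular_quantile(0.975, a, c, b), 0.0263258,
               tolerance = 1e-5)
  expect_error(triangular_quantile(1.2, a, c, b), "0, 1")
  expect_error(triangular_quantile(-0.1, a, c, b), "0, 1")
  expect_error(triangular_quantile(0.5, 0.02, 0.01, 0.03), "lower <= mode")
})

test_that("sampling is reproducible, degenerate-safe and converges to closed forms", {
  sch <- ef_scheme("GL2006")
  d1 <- sample_ef(sch, 1000, seed = 7)
  d2 <- sample_ef(sch, 1000, seed = 7)
  expect_identical(d1, d2)
  expect_error(sample_ef(sch, 10), "seed")
  ## degenerate stratum: every draw equals the point mass
  deg <- ef_scheme("custom", strata = list(s = c(0.01, 0.01, 0.01)),
                   lookup = c(wet.synthetic = "s", wet.manure = "s",
                              dry.synthetic = "s", dry.manure = "s"))
  expect_true(all(sample_ef(deg, 500, seed = 1) == 0.01))
  ## 1e6 draws: sample mean near (a+c+b)/3, quantile near the inverse CDF
  x <- sample_ef(sch, 1e6, seed = 11)[, "all"]
  expect_lt(abs(mean(x) - triangular_mean(0.003, 0.010, 0.030)),
            3 * sd(x) / sqrt(1e6))
  q_emp <- quantile(x, 0.975, names = FALSE)
  expect_lt(abs(q_emp - triangular_quantile(0.975, 0.003, 0.010, 0.030)),
            3 * quantile_se(0.975, 1e6, 0.003, 0.010, 0.030))
})

test_that("cell emissions are Tier 1 arithmetic per stratum", {
  mr <- ef_scheme("MR2019")
  cells <- data.frame(cell_id = c("w", "d", "z"),
                      country_code = "XAA",
                      climate = c("wet", "dry", "wet"),
                      n_synthetic = c(100, 50, 0),
                      n_manure = c(0, 50, 0))
  e <- cell_emission(cells, mr)
  expect_equal(e$total[e$cell_id == "w"], 1.6)        # 100 x 0.016
  expect_equal(e$synthetic[e$cell_id == "d"], 0.25)   # 50 x 0.005
  expect_equal(e$manure[e$cell_id == "d"], 0.25)
  expect_equal(e$total[e$cell_id == "d"], 0.5)
  expect_equal(e$total[e$cell_id == "z"], 0)
  ## a scheme that does not cover a stratum names the offending pair
  partial <- ef_scheme("custom",
                       strata = list(w = c(0.013, 0.016, 0.019)),
                       lookup = c(wet.synthetic = "w", wet.manure = "w"))
  expect_error(cell_emission(cells, partial), "dry, synthetic")
})

test_that("the worked-example grid reproduces the reference global inventory points", {
  g <- worked_example_grid()
  expect_equal(sum(g$n_synthetic) + sum(g$n_manure), 103010, tolerance = 1e-9)
  gl <- run_inventory(g, ef_scheme("GL2006"), n_draws = 10, seed = 1,
                      scopes = "global")
  mr <- run_inventory(g, ef_scheme("MR2019"), n_draws = 10, seed = 1,
                      scopes = "global")
  pick <- function(est, comp) est$point[est$component == comp]
  expect_equal(pick(gl, "total"), 1030.1, tolerance = 0.1 / 1030)
  expect_equal(pick(mr, "total"), 1073.3, tolerance = 0.1 / 1073)
  expect_equal(pick(gl, "synthetic"), 696.2, tolerance = 0.1 / 696)
  expect_equal(pick(mr, "synthetic"), 882.0, tolerance = 0.1 / 882)
  expect_equal(pick(gl, "manure"), 333.9, tolerance = 0.1 / 334)
  expect_equal(pick(mr, "manure"), 191.3, tolerance = 0.1 / 191)
})

test_that("per-draw aggregation conserves mass across scopes and components", {
  g <- generate_fertilizer_grid(grid_generator_config(n_cells = 60,
                                                      n_countries = 6,
                                                      seed = 14))
  est <- run_inventory(g, ef_scheme("MR2019"), n_draws = 400, seed = 3,
                       keep_draws = TRUE)
  dr <- attr(est, "draws")
  for (comp in c("synthetic", "manure", "total")) {
    glob <- dr$global[[comp]][, 1]
    expect_equal(rowSums(dr$country[[comp]]), glob, tolerance = 1e-9)
    expect_equal(rowSums(dr$cell[[comp]]), glob, tolerance = 1e-9)
  }
  ## total = synthetic + manure for the point estimates at every scope
  for (sc in unique(est$scope)) {
    e <- est[est$scope == sc, ]
    tot <- e$point[e$component == "total"]
    expect_equal(e$point[e$component == "synthetic"] +
                   e$point[e$component == "manure"], tot, tolerance = 1e-12)
  }
})

test_that("inventory scales linearly in N and is seed-deterministic", {
  g <- generate_fertilizer_grid(grid_generator_config(n_cells = 40,
                                                      n_countries = 4,
                                                      seed = 15))
  sch <- ef_scheme("MR2019")
  e1 <- run_inventory(g, sch, n_draws = 2000, seed = 8)
  g2 <- g
  g2$n_synthetic <- g2$n_synthetic * 3
  g2$n_manure <- g2$n_manure * 3
  e2 <- run_inventory(g2, sch, n_draws = 2000, seed = 8)
  expect_equal(e2$point, 3 * e1$point, tolerance = 1e-12)
  expect_equal(e2$ci_low, 3 * e1$ci_low, tolerance = 1e-12)
  expect_equal(e2$ci_high, 3 * e1$ci_high, tolerance = 1e-12)
  ## identical seed -> identical output
  expect_equal(run_inventory(g, sch, n_draws = 2000, seed = 8), e1)
})

test_that("degenerate schemes collapse the interval and MR points follow mode arithmetic", {
  g <- worked_example_grid()
  deg <- ef_scheme("custom", strata = list(s = c(0.01, 0.01, 0.01)),
                   lookup = c(wet.synthetic = "s", wet.manure = "s",
                              dry.synthetic = "s", dry.manure = "s"))
  est <- run_inventory(g, deg, n_draws = 100, seed = 2, scopes = "global")
  expect_equal(est$ci_low, est$point, tolerance = 1e-12)
  expect_equal(est$ci_high, est$point, tolerance = 1e-12)
  ## MR2019 mode-based point = 0.005 N_dry + 0.016 N_wet_synth + 0.006 N_wet_man
  mr <- run_inventory(g, ef_scheme("MR2019"), n_draws = 10, seed = 1,
                      scopes = "global")
  wet <- g$climate == "wet"
  manual <- 0.005 * (sum(g$n_synthetic[!wet]) + sum(g$n_manure[!wet])) +
    0.016 * sum(g$n_synthetic[wet]) + 0.006 * sum(g$n_manure[wet])
  expect_equal(mr$point[mr$component == "total"], manual, tolerance = 1e-12)
})

test_that("unknown country codes are pooled under a sentinel with a warning", {
  g <- generate_fertilizer_grid(grid_generator_config(n_cells = 10,
                                                      n_countries = 2,
                                                      seed = 16))
  g$country_code[c(1, 5)] <- NA
  expect_warning(est <- run_inventory(g, ef_scheme("GL2006"), n_draws = 50,
                                      seed = 1, scopes = "country"), "XXX")
  expect_true("XXX" %in% est$unit)
})

test_that("scheme comparison reproduces the summary-table percent differences", {
  ## reference global/country inventory points, compared pairwise
  mk <- function(points) {
    data.frame(scope = "country", unit = names(points), component = "total",
               point = unname(points), ci_low = NA, ci_high = NA)
  }
  a <- mk(c(GLB = 1073.3, CHN = 316.2, IND = 118.6))
  b <- mk(c(GLB = 1030.1, CHN = 261.8, IND = 150.6))
  cmp <- compare_schemes(a, b)
  expect_equal(cmp$pct_rounded[match(c("GLB", "CHN", "IND"), cmp$unit)],
               c(4, 21, -21))
  expect_equal(cmp$abs_diff[cmp$unit == "GLB"], 43.2, tolerance = 1e-9)
  ## identical estimates -> zero difference; zero reference -> undefined pct
  z <- compare_schemes(mk(c(GLB = 5)), mk(c(GLB = 5)))
  expect_equal(z$abs_diff, 0)
  expect_equal(z$pct, 0)
  u <- compare_schemes(mk(c(GLB = 5)), mk(c(GLB = 0)))
  expect_true(is.na(u$pct))
})

test_that("difference maps give the single-stratum limits and mask zero cells", {
  gl <- ef_scheme("GL2006"); mr <- ef_scheme("MR2019")
  dry_grid <- data.frame(cell_id = paste0("c", 1:5), country_code = "XAA",
                         climate = "dry", n_synthetic = runif(5, 10, 100),
                         n_manure = 0)
  dm <- difference_map(dry_grid, mr, gl)
  expect_equal(dm$pct_diff, rep(-50, 5))   # 0.005 vs 0.010
  wet_grid <- transform(dry_grid, climate = "wet")
  dm2 <- difference_map(wet_grid, mr, gl)
  expect_equal(dm2$pct_diff, rep(60, 5))   # 0.016 vs 0.010
  zero <- transform(dry_grid, n_synthetic = 0)
  dm3 <- difference_map(zero, mr, gl)
  expect_equal(dm3$abs_diff, rep(0, 5))
  expect_true(all(is.na(dm3$pct_diff)))
  ## percent difference invariant to rescaling N within the stratum
  dm4 <- difference_map(transform(dry_grid, n_synthetic = n_synthetic * 7),
                        mr, gl)
  expect_equal(dm4$pct_diff, dm$pct_diff)
})
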