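#' Pipeline configuration
#'
#' One structured configuration drives every pipeline stage. It can be built
#' in R or read from a YAML file with the same field names. The seed is
#' mandatory for any stochastic stage; every stage writes a provenance
#' record (`provenance.json`: config digest, seed, package and R versions)
#' alongside its outputs, and identical config + seed give byte-identical
#' outputs.
#'
#' @param factors Factor columns to fit in the `fit` stage.
#' @param min_class_n Classes with n at or below this are dropped.
#' @param climate_boundary Tie rule at the wet/dry thresholds.
#' @param scheme,reference_scheme EF scheme names (or paths to YAML scheme
#'   files) for the inventory stage; `reference_scheme` is the comparison
#'   baseline.
#' @param n_draws Monte Carlo iterations.
#' @param seed Integer seed.
#' @param report_n2o_mass Also report emissions as Gg N2O (x 44/28); never
#'   the default unit.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(factors = c("climate", "fertilizer_form", "n_rate",
                                        "irrigation", "land_cover", "texture",
                                        "soil_c", "alkalinity", "length"),
                            min_class_n = 20, climate_boundary = "wet",
                            scheme = "MR2019", reference_scheme = "GL2006",
                            n_draws = 1e5, seed = NULL,
                            report_n2o_mass = FALSE) {
  structure(list(factors = factors, min_class_n = min_class_n,
                 climate_boundary = climate_boundary, scheme = scheme,
                 reference_scheme = reference_scheme, n_draws = n_draws,
                 seed = seed, report_n2o_mass = report_n2o_mass),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with `pipeline_config` fields.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg[intersect(names(cfg),
                                         names(formals(pipeline_config)))])
}

resolve_scheme <- function(x) {
  if (inherits(x, "ef_scheme")) return(x)
  if (x %in% c("GL2006", "MR2019")) return(ef_scheme(x))
  if (file.exists(x)) return(read_ef_scheme(x))
  stop("unknown EF scheme: `", x, "` (presets: GL2006, MR2019)", call. = FALSE)
}

write_provenance <- function(out_dir, config, stage) {
  cfg_plain <- unclass(config)
  rec <- list(stage = stage,
              config = cfg_plain,
              config_digest = config_digest(cfg_plain),
              seed = config$seed,
              package_version = as.character(utils::packageVersion("n2oef")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(rec)
}

config_digest <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Pipeline stage: filter and classify an EF table
#'
#' Reads the EF CSV, applies the study filters, derives the emission factor,
#' assigns the class labels and locations, and writes
#' `classified_dataset.csv` plus `exclusion_log.csv` (record_id,
#' reason_code) to `out_dir`.
#'
#' @param dataset_csv Path to the raw EF observation CSV.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the classified data frame and the
#'   exclusion log.
#' @export
cmd_classify <- function(dataset_csv, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  raw <- read_ef_csv(dataset_csv)
  flt <- filter_studies(raw)
  classified <- classify_dataset(flt$retained,
                                 climate_boundary = config$climate_boundary)
  write_ef_csv(classified, file.path(out_dir, "classified_dataset.csv"))
  write_ef_csv(flt$excluded, file.path(out_dir, "exclusion_log.csv"))
  write_provenance(out_dir, config, "classify")
  message(sprintf("classify: %d retained, %d excluded", nrow(classified),
                  nrow(flt$excluded)))
  invisible(list(classified = classified, excluded = flt$excluded))
}

#' Pipeline stage: fit the per-factor mixed models
#'
#' Fits one model per configured factor on the classified dataset and writes
#' `factor_results.csv` in the standard presentation (factor, class, n,
#' mean, 95 % CI, LSD letters, p, R^2, AIC). Factors that are unanalyzable
#' (fewer than two classes above the sample-size rule) are skipped with a
#' warning.
#'
#' @param classified_csv Path to the classified dataset.
#' @inheritParams cmd_classify
#' @return Invisibly, the list of fitted `factor_model` objects.
#' @export
cmd_fit <- function(classified_csv, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- read_ef_csv(classified_csv)
  models <- list()
  for (f in config$factors) {
    if (!f %in% names(d)) {
      warning("factor `", f, "` not present; skipped", call. = FALSE)
      next
    }
    m <- tryCatch(fit_factor_model(d, f, min_class_n = config$min_class_n),
                  error = function(e) {
                    warning("factor `", f, "` skipped: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(m)) models[[f]] <- m
  }
  if (length(models)) {
    write_ef_csv(factor_results_table(models),
                 file.path(out_dir, "factor_results.csv"))
  }
  write_provenance(out_dir, config, "fit")
  invisible(models)
}

#' Pipeline stage: Monte Carlo inventory and scheme comparison
#'
#' Runs the inventory under the configured scheme and the reference scheme,
#' writes `emissions_<scheme>.csv` for both (scope, unit, component, point,
#' ci_low, ci_high in Gg N2O-N), the country/global comparison
#' `scheme_comparison.csv`, and the per-cell `difference_map.csv`.
#'
#' @param grid_csv Path to the grid cell CSV.
#' @inheritParams cmd_classify
#' @return Invisibly, a list with both estimate tables and the comparison.
#' @export
cmd_inventory <- function(grid_csv, out_dir, config = pipeline_config()) {
  if (is.null(config$seed)) stop("config$seed is mandatory for the inventory",
                                 call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- read_grid_csv(grid_csv)
  sch_a <- resolve_scheme(config$scheme)
  sch_b <- resolve_scheme(config$reference_scheme)
  est_a <- run_inventory(grid, sch_a, n_draws = config$n_draws,
                         seed = config$seed)
  est_b <- run_inventory(grid, sch_b, n_draws = config$n_draws,
                         seed = config$seed + 1L)
  maybe_mass <- function(est) {
    if (config$report_n2o_mass) {
      est$point_n2o <- as_n2o_mass(est$point)
    }
    est
  }
  write_ef_csv(maybe_mass(est_a),
               file.path(out_dir, paste0("emissions_", sch_a$name, ".csv")))
  write_ef_csv(maybe_mass(est_b),
               file.path(out_dir, paste0("emissions_", sch_b$name, ".csv")))
  agg <- est_a$scope != "cell"
  cmp <- compare_schemes(est_a[agg, ], est_b[est_b$scope != "cell", ])
  write_ef_csv(cmp, file.path(out_dir, "scheme_comparison.csv"))
  dmap <- difference_map(grid, sch_a, sch_b)
  write_ef_csv(dmap, file.path(out_dir, "difference_map.csv"))
  write_provenance(out_dir, config, "inventory")
  invisible(list(estimates = est_a, reference = est_b, comparison = cmp,
                 difference_map = dmap))
}

#' Pipeline stage: write synthetic inputs
#'
#' Materializes a named preset as CSV files ready for the other stages.
#' Presets: `"ef-dataset"` (the default synthetic EF-observation table),
#' `"grid"` (a synthetic fertilizer grid) and `"worked-example-grid"` (the
#' deterministic global-2000 emulation grid).
#'
#' @param preset Preset name.
#' @inheritParams cmd_classify
#' @return Invisibly, the path of the file written.
#' @export
cmd_simulate <- function(preset, out_dir, config = pipeline_config()) {
  presets <- c("ef-dataset", "grid", "worked-example-grid")
  if (!preset %in% presets) {
    stop("unknown preset `", preset, "`; available: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  if (preset != "worked-example-grid" && is.null(config$seed)) {
    stop("config$seed is mandatory for stochastic presets", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- switch(preset,
    "ef-dataset" = {
      d <- generate_ef_observations(ef_generator_config(seed = config$seed))
      write_ef_csv(d, file.path(out_dir, "synthetic_ef_dataset.csv"))
    },
    "grid" = {
      g <- generate_fertilizer_grid(grid_generator_config(seed = config$seed))
      write_ef_csv(g, file.path(out_dir, "synthetic_grid.csv"))
    },
    "worked-example-grid" = {
      write_ef_csv(worked_example_grid(),
                   file.path(out_dir, "worked_example_grid.csv"))
    })
  write_provenance(out_dir, config, paste0("simulate:", preset))
  invisible(path)
}
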