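#' Draw emission factors for every stratum of a scheme
#'
#' One triangular draw per stratum per Monte Carlo iteration, shared by all
#' grid cells in that stratum; draws are independent across strata. Sharing
#' the draw within a stratum propagates the EF uncertainty as systematic
#' (the emission factor is one global unknown, not a cell-level lottery),
#' which is what keeps country and global confidence intervals as wide as
#' the EF's own.
#'
#' @param scheme An [ef_scheme()].
#' @param n_draws Number of Monte Carlo iterations (>= 1).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return Numeric matrix, `n_draws` rows, one named column per stratum.
#' @export
sample_ef <- function(scheme, n_draws, seed) {
  stopifnot(inherits(scheme, "ef_scheme"), n_draws >= 1)
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  draws <- vapply(scheme$strata, function(p) {
    rtriangular(n_draws, p[["lower"]], p[["mode"]], p[["upper"]])
  }, numeric(n_draws))
  if (n_draws == 1L) draws <- matrix(draws, nrow = 1,
                                     dimnames = list(NULL, names(scheme$strata)))
  draws
}

#' Tier 1 emission of a set of grid cells under fixed emission factors
#'
#' Per cell: synthetic emission = synthetic N x EF(climate, synthetic),
#' manure emission = manure N x EF(climate, manure), total = their sum.
#' With the default `efs` (the scheme modes) this is the mode-based point
#' estimate.
#'
#' @param cells Grid cell data frame (see [read_grid_csv()]).
#' @param scheme An [ef_scheme()].
#' @param efs Named numeric vector of EF values per stratum; defaults to the
#'   scheme modes.
#' @return Data frame `cell_id`, `synthetic`, `manure`, `total` in Gg N2O-N.
#' @export
cell_emission <- function(cells, scheme, efs = scheme_modes(scheme)) {
  cells <- validate_grid(cells)
  miss <- setdiff(names(scheme$strata), names(efs))
  if (length(miss)) stop("no EF value for stratum ", paste(miss, collapse = ", "),
                         call. = FALSE)
  s_syn <- stratum_of(scheme, cells$climate, "synthetic")
  s_man <- stratum_of(scheme, cells$climate, "manure")
  syn <- cells$n_synthetic * efs[s_syn]
  man <- cells$n_manure * efs[s_man]
  data.frame(cell_id = cells$cell_id,
             synthetic = unname(syn), manure = unname(man),
             total = unname(syn + man), stringsAsFactors = FALSE)
}

## units x strata matrices of N mass for one component; rows follow `units`
stratum_mass <- function(cells, scheme, component, unit_of, units) {
  strata <- names(scheme$strata)
  s <- stratum_of(scheme, cells$climate, component)
  mass <- if (component == "synthetic") cells$n_synthetic else cells$n_manure
  M <- matrix(0, length(units), length(strata), dimnames = list(units, strata))
  agg <- stats::aggregate(mass, by = list(unit = unit_of, stratum = s), FUN = sum)
  M[cbind(match(agg$unit, units), match(agg$stratum, strata))] <- agg$x
  M
}

#' Monte Carlo Tier 1 inventory over a fertilizer-N grid
#'
#' Computes direct soil N2O-N emissions per component (synthetic, manure,
#' total) at cell, country and global scope. Point estimates use the mode
#' EFs; 95 % confidence intervals are the empirical 2.5 and 97.5 quantiles
#' of the per-iteration aggregated totals, with one shared EF draw per
#' stratum per iteration. Aggregation is performed draw-by-draw, so the
#' global total equals the sum over countries and over cells at every
#' iteration.
#'
#' Cell-scope confidence intervals are computed only when `cell_ci = TRUE`
#' (they need the full draws-by-cells emission matrix); cell point estimates
#' are always reported.
#'
#' @param grid Grid cell data frame (see [read_grid_csv()]); flooded-rice N
#'   is expected to have been removed upstream (`rice_excluded`).
#' @param scheme An [ef_scheme()].
#' @param n_draws Monte Carlo iterations (default 100,000).
#' @param seed Mandatory integer seed.
#' @param probs Quantiles bounding the interval.
#' @param scopes Which aggregation scopes to report.
#' @param cell_ci Compute quantile CIs at cell scope.
#' @param keep_draws Attach the per-iteration totals (attribute `"draws"`:
#'   list of component -> scope -> iterations x units matrix) for
#'   conservation checks; memory-heavy, use with small grids.
#' @return Data frame of class `emission_estimates` with columns `scope`,
#'   `unit`, `component`, `point`, `ci_low`, `ci_high` (Gg N2O-N), plus
#'   attributes `n_draws`, `seed`, `scheme`.
#' @export
run_inventory <- function(grid, scheme, n_draws = 1e5, seed,
                          probs = c(0.025, 0.975),
                          scopes = c("global", "country", "cell"),
                          cell_ci = FALSE, keep_draws = FALSE) {
  grid <- validate_grid(grid)
  if (nrow(grid) == 0L) stop("empty grid", call. = FALSE)
  scopes <- match.arg(scopes, several.ok = TRUE)
  if (!all(grid$rice_excluded)) {
    warning("grid contains cells with rice N not excluded; EF1 does not ",
            "apply to flooded rice", call. = FALSE)
  }
  cc <- as.character(grid$country_code)
  unknown <- is.na(cc) | cc == ""
  if (any(unknown)) {
    warning(sum(unknown), " cell(s) with unknown country code collected under 'XXX'",
            call. = FALSE)
    cc[unknown] <- "XXX"
  }
  grid$country_code <- cc

  draws <- sample_ef(scheme, n_draws, seed)
  modes <- scheme_modes(scheme)
  components <- c("synthetic", "manure")

  unit_sets <- list(global = "GLOBAL",
                    country = sort(unique(grid$country_code)),
                    cell = as.character(grid$cell_id))
  unit_cols <- list(global = rep("GLOBAL", nrow(grid)),
                    country = grid$country_code,
                    cell = as.character(grid$cell_id))

  res <- list()
  draw_store <- list()
  for (scope in scopes) {
    units <- unit_sets[[scope]]
    M <- lapply(components, function(comp)
      stratum_mass(grid, scheme, comp, unit_cols[[scope]], units))
    names(M) <- components
    point <- lapply(M, function(m) drop(m %*% modes))
    point$total <- point$synthetic + point$manure
    want_ci <- scope != "cell" || cell_ci || keep_draws
    if (want_ci) {
      E <- lapply(M, function(m) draws %*% t(m))  # iterations x units
      E$total <- E$synthetic + E$manure
      if (keep_draws) draw_store[[scope]] <- E
    }
    for (comp in c(components, "total")) {
      if (want_ci && (scope != "cell" || cell_ci)) {
        qs <- apply(E[[comp]], 2, stats::quantile, probs = probs, names = FALSE)
        ci_low <- qs[1, ]; ci_high <- qs[2, ]
      } else {
        ci_low <- ci_high <- rep(NA_real_, length(units))
      }
      res[[length(res) + 1L]] <- data.frame(
        scope = scope, unit = units, component = comp,
        point = unname(point[[comp]]), ci_low = unname(ci_low),
        ci_high = unname(ci_high), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  attr(out, "scheme") <- scheme$name
  if (keep_draws) attr(out, "draws") <- draw_store
  class(out) <- c("emission_estimates", "data.frame")
  out
}

#' Compare emission estimates between two schemes
#'
#' Differences of point estimates, with the second argument as the
#' reference: absolute difference `a - b` in Gg N2O-N and percent difference
#' `100 (a - b) / b`. Percent differences are reported at full precision
#' (`pct`) and rounded to the nearest integer (`pct_rounded`) as presented
#' in summary tables; they are undefined (`NA`) where the reference is 0.
#'
#' @param est_a,est_b `emission_estimates` from [run_inventory()] on the
#'   same grid (matching scope/unit/component rows).
#' @return Data frame `scope`, `unit`, `component`, `point_a`, `point_b`,
#'   `abs_diff`, `pct`, `pct_rounded`.
#' @export
compare_schemes <- function(est_a, est_b) {
  key <- c("scope", "unit", "component")
  m <- merge(est_a[, c(key, "point")], est_b[, c(key, "point")],
             by = key, suffixes = c("_a", "_b"))
  if (nrow(m) != nrow(est_a)) {
    stop("estimates do not cover matching scope/unit/component rows", call. = FALSE)
  }
  m$abs_diff <- m$point_a - m$point_b
  m$pct <- ifelse(m$point_b == 0, NA_real_, 100 * m$abs_diff / m$point_b)
  m$pct_rounded <- round(m$pct)
  m
}

#' Per-cell difference layers between two EF schemes
#'
#' Mode-based per-cell emissions under each scheme, differenced absolutely
#' (Gg N2O-N) and in percent of the reference scheme `scheme_b`. Cells with
#' zero reference emission have the percent masked (`NA`). Output keeps the
#' input's cell geometry (one row per cell, input order).
#'
#' @param grid Grid cell data frame.
#' @param scheme_a,scheme_b [ef_scheme()] objects; `scheme_b` is the
#'   reference.
#' @param component `"total"`, `"synthetic"` or `"manure"`.
#' @return Data frame `cell_id`, `emission_a`, `emission_b`, `abs_diff`,
#'   `pct_diff`.
#' @export
difference_map <- function(grid, scheme_a, scheme_b, component = "total") {
  component <- match.arg(component, c("total", "synthetic", "manure"))
  a <- cell_emission(grid, scheme_a)[[component]]
  b <- cell_emission(grid, scheme_b)[[component]]
  data.frame(cell_id = grid$cell_id,
             emission_a = a, emission_b = b,
             abs_diff = a - b,
             pct_diff = ifelse(b == 0, NA_real_, 100 * (a - b) / b),
             stringsAsFactors = FALSE)
}
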