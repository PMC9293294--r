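#' Emission-factor schemes with triangular uncertainty
#'
#' An EF scheme maps every (climate, fertilizer component) stratum of the
#' grid to a triangular EF1 distribution (lower, mode, upper). Two presets
#' ship with the package:
#'
#' * `"GL2006"` — the 2006 IPCC Guidelines default: a single EF1 of 0.010
#'   with 95 % CI 0.003–0.030 applied to all nitrogen regardless of climate
#'   or form. The scheme has one stratum, so one Monte Carlo draw per
#'   iteration is shared by the entire grid.
#' * `"MR2019"` — the 2019 Methods Refinement disaggregation: dry climate
#'   (any form) 0.005 (0.000–0.011), wet climate synthetic and mixed
#'   fertilizer 0.016 (0.013–0.019), wet climate organic/manure fertilizer
#'   0.006 (0.001–0.011). Three strata with independent draws.
#'
#' Triangular parameterization: lower/upper are the 95 % CI bounds of the
#' disaggregated EF1 and the mode is its mean. Point estimates of emission
#' use the mode.
#'
#' @param name `"GL2006"`, `"MR2019"`, or `"custom"`.
#' @param strata For `"custom"`: named list of numeric `c(lower, mode,
#'   upper)` triplets, one per stratum.
#' @param lookup For `"custom"`: named character vector mapping
#'   `"<climate>.<component>"` keys (climate in wet/dry, component in
#'   synthetic/manure) to stratum names.
#' @param allow_negative Permit negative lower bounds (off by default).
#' @return An object of class `ef_scheme`.
#' @examples
#' ef_scheme("MR2019")
#' @export
ef_scheme <- function(name = c("GL2006", "MR2019", "custom"),
                      strata = NULL, lookup = NULL, allow_negative = FALSE) {
  name <- match.arg(name)
  if (name == "GL2006") {
    strata <- list(all = c(0.003, 0.010, 0.030))
    lookup <- c(wet.synthetic = "all", wet.manure = "all",
                dry.synthetic = "all", dry.manure = "all")
  } else if (name == "MR2019") {
    strata <- list(dry = c(0.000, 0.005, 0.011),
                   wet_synthetic = c(0.013, 0.016, 0.019),
                   wet_manure = c(0.001, 0.006, 0.011))
    lookup <- c(wet.synthetic = "wet_synthetic", wet.manure = "wet_manure",
                dry.synthetic = "dry", dry.manure = "dry")
  } else {
    if (is.null(strata) || is.null(lookup)) {
      stop("a custom scheme needs `strata` and `lookup`", call. = FALSE)
    }
  }
  for (s in names(strata)) {
    par <- as.numeric(strata[[s]])
    if (length(par) != 3) stop("stratum `", s, "` must be c(lower, mode, upper)",
                               call. = FALSE)
    check_triangular(par[1], par[2], par[3])
    if (par[1] < 0 && !allow_negative) {
      stop("stratum `", s, "` has a negative lower bound; set ",
           "`allow_negative = TRUE` to permit it", call. = FALSE)
    }
    strata[[s]] <- stats::setNames(par, c("lower", "mode", "upper"))
  }
  if (!all(lookup %in% names(strata))) {
    stop("lookup refers to undefined stratum: ",
         paste(setdiff(lookup, names(strata)), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, strata = strata, lookup = lookup),
            class = "ef_scheme")
}

#' @export
print.ef_scheme <- function(x, ...) {
  cat("EF scheme:", x$name, "-", length(x$strata), "stratum/strata\n")
  for (s in names(x$strata)) {
    p <- x$strata[[s]]
    keys <- names(x$lookup)[x$lookup == s]
    cat(sprintf("  %-15s triangular(%.3f, %.3f, %.3f)  <- %s\n",
                s, p["lower"], p["mode"], p["upper"], paste(keys, collapse = ", ")))
  }
  invisible(x)
}

## stratum name for each (climate, component) pair; errors name the pair
stratum_of <- function(scheme, climate, component) {
  key <- paste(climate, component, sep = ".")
  s <- scheme$lookup[key]
  if (anyNA(s)) {
    miss <- unique(key[is.na(s)])
    stop("scheme `", scheme$name, "` has no stratum for (",
         paste(gsub("\\.", ", ", miss), collapse = "), ("), ")", call. = FALSE)
  }
  unname(s)
}

## mode EFs as a named vector over strata
scheme_modes <- function(scheme) {
  vapply(scheme$strata, function(p) p[["mode"]], numeric(1))
}

#' Read an EF scheme from a YAML config file
#'
#' The file holds `name`, a `strata` mapping of `{lower, mode, upper}` and a
#' `lookup` mapping of `climate.component: stratum`. Presets can be named
#' directly (`name: GL2006` with no strata).
#'
#' @param path Path to a YAML file.
#' @return An `ef_scheme`.
#' @export
read_ef_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  nm <- cfg$name %||% "custom"
  if (nm %in% c("GL2006", "MR2019") && is.null(cfg$strata)) {
    return(ef_scheme(nm))
  }
  strata <- lapply(cfg$strata, function(s) {
    if (is.list(s)) c(s$lower, s$mode, s$upper) else as.numeric(s)
  })
  ef_scheme("custom", strata = strata, lookup = unlist(cfg$lookup),
            allow_negative = isTRUE(cfg$allow_negative))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
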