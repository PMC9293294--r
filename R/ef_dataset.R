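#' Compute a control-plot emission factor
#'
#' The per-experiment emission factor \eqn{EF_{1i}} is the fraction of applied
#' nitrogen emitted as N2O-N in excess of the unfertilized control:
#' \deqn{EF_{1i} = (N_2O_{Ti} - N_2O_{Ci}) / N_i}
#' where the treatment and control fluxes are cumulative over the same
#' experimental period. Negative values are legitimate (control out-emitting
#' the treatment) and are retained.
#'
#' Fluxes must be supplied in kg N2O-N ha^-1 period^-1 and the nitrogen input
#' in kg N ha^-1 period^-1; unit conversion (e.g. from g m^-2 or from N2O
#' molecular mass) is the caller's responsibility.
#'
#' @param n2o_treatment Cumulative N2O-N flux of the fertilized plot
#'   (kg N2O-N ha^-1).
#' @param n2o_control Cumulative N2O-N flux of the control plot over the same
#'   period (kg N2O-N ha^-1). A missing control cannot yield an emission
#'   factor and is an error here; use [filter_studies()] to drop such records
#'   with an audit trail instead.
#' @param n_input Nitrogen applied (kg N ha^-1); must be strictly positive.
#' @return Numeric vector of dimensionless emission factors.
#' @examples
#' compute_ef(2.0, 1.0, 100)    # 0.01
#' compute_ef(0.34, 1.94, 100)  # -0.016
#' @export
compute_ef <- function(n2o_treatment, n2o_control, n_input) {
  if (any(is.na(n_input)) || any(n_input <= 0)) {
    stop("`n_input` must be present and strictly positive for every observation",
         call. = FALSE)
  }
  if (any(is.na(n2o_control))) {
    stop("missing control flux: the observation cannot yield an emission factor",
         call. = FALSE)
  }
  if (any(is.na(n2o_treatment))) {
    stop("missing treatment flux", call. = FALSE)
  }
  (n2o_treatment - n2o_control) / n_input
}

## machine-readable exclusion reasons, in the order they are checked
.exclusion_checks <- list(
  NOT_PEER_REVIEWED    = function(d) !isTRUE_vec(d$peer_reviewed, default = TRUE),
  LAB_STUDY            = function(d) isTRUE_vec(d$lab_or_model),
  FLOODED_RICE         = function(d) isTRUE_vec(d$flooded_rice),
  GRAZED_EXCRETA       = function(d) isTRUE_vec(d$grazed_excreta),
  ENHANCED_EFFICIENCY  = function(d) isTRUE_vec(d$enhanced_efficiency),
  ORGANIC_SOIL         = function(d) isTRUE_vec(d$organic_soil),
  NO_CONTROL           = function(d) is.na(d$n2o_control),
  NONPOSITIVE_N_INPUT  = function(d) is.na(d$n_input) | d$n_input <= 0
)

## NA-tolerant elementwise isTRUE; `default` is what NA counts as
isTRUE_vec <- function(x, default = FALSE) {
  if (is.null(x)) return(rep(default, 0L))
  out <- as.logical(x)
  out[is.na(out)] <- default
  out
}

#' Apply the study inclusion and exclusion filters
#'
#' Drops records that cannot contribute a Tier 1 EF1 observation:
#' non-peer-reviewed sources, laboratory/greenhouse or modeling studies,
#' flooded rice fields (covered by EF1FR), grazed urine/dung deposition
#' (EF3PRP), enhanced-efficiency fertilizers, drained or managed organic
#' soils, records without a control plot, and records without a positive
#' nitrogen input. Each dropped record receives exactly one machine-readable
#' reason code (the first matching check, in the order above).
#'
#' Missing provenance flags are treated as pass-with-warning rather than as
#' silent exclusion, so the filter stays auditable.
#'
#' @param records Data frame of raw observations (see [read_ef_csv()] for the
#'   schema).
#' @return A list with elements `retained` (the surviving rows, unmodified)
#'   and `excluded` (data frame with `record_id` and `reason_code`).
#' @export
filter_studies <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    return(list(retained = records,
                excluded = data.frame(record_id = character(),
                                      reason_code = character(),
                                      stringsAsFactors = FALSE)))
  }
  flag_cols <- c("peer_reviewed", "lab_or_model", "flooded_rice",
                 "grazed_excreta", "enhanced_efficiency", "organic_soil")
  for (fc in flag_cols) {
    if (is.null(records[[fc]])) records[[fc]] <- NA
    if (anyNA(records[[fc]])) {
      warning(sprintf("missing `%s` flag on %d record(s): treated as not excluded",
                      fc, sum(is.na(records[[fc]]))), call. = FALSE)
    }
  }
  reason <- rep(NA_character_, nrow(records))
  for (code in names(.exclusion_checks)) {
    hit <- .exclusion_checks[[code]](records)
    reason[is.na(reason) & hit] <- code
  }
  keep <- is.na(reason)
  list(
    retained = records[keep, , drop = FALSE],
    excluded = data.frame(record_id = as.character(records$record_id[!keep]),
                          reason_code = reason[!keep],
                          stringsAsFactors = FALSE)
  )
}

#' Classify observations into wet or dry climate
#'
#' Follows the IPCC two-class convention: temperate/boreal zones are wet
#' where the ratio of annual precipitation to potential evapotranspiration
#' exceeds 1, tropical zones are wet where annual precipitation exceeds
#' 1000 mm. The defining inequalities are strict on both sides, leaving
#' exact equality open; ties are broken toward the wetter class by default
#' (`boundary = "wet"`).
#'
#' @param zone Character vector, `"temperate_boreal"` or `"tropical"`.
#' @param annual_precip Annual precipitation, mm yr^-1 (used for tropical
#'   observations).
#' @param pet_ratio Annual precipitation:PET ratio, dimensionless (used for
#'   temperate/boreal observations).
#' @param boundary Class assigned at exact equality with the threshold,
#'   `"wet"` (default) or `"dry"`.
#' @return Character vector `"wet"`/`"dry"`; `NA` where the required
#'   covariate is missing (unclassifiable for this factor only).
#' @export
classify_climate <- function(zone, annual_precip = NA_real_, pet_ratio = NA_real_,
                             boundary = c("wet", "dry")) {
  boundary <- match.arg(boundary)
  n <- max(length(zone), length(annual_precip), length(pet_ratio))
  zone <- rep_len(as.character(zone), n)
  annual_precip <- rep_len(as.numeric(annual_precip), n)
  pet_ratio <- rep_len(as.numeric(pet_ratio), n)
  bad <- !is.na(zone) & !zone %in% c("temperate_boreal", "tropical")
  if (any(bad)) {
    stop("unknown climate zone: ", paste(unique(zone[bad]), collapse = ", "),
         call. = FALSE)
  }
  crit <- ifelse(zone == "tropical", annual_precip / 1000, pet_ratio)
  wet <- if (boundary == "wet") crit >= 1 else crit > 1
  out <- ifelse(wet, "wet", "dry")
  out[is.na(zone) | is.na(crit)] <- NA_character_
  out
}

#' Classify the fertilizer form
#'
#' Pure organic fertilizer forms one class; synthetic fertilizer and mixtures
#' of synthetic and organic forms are pooled into a single
#' `"synthetic_mixed"` class (their mean emission factors are
#' indistinguishable, which is why the classes are merged).
#'
#' @param synthetic,organic Logical flags for the presence of each form in
#'   the applied fertilizer.
#' @return Character vector `"synthetic_mixed"`/`"organic"`; `NA` when
#'   neither flag is set.
#' @export
classify_fertilizer_form <- function(synthetic, organic) {
  n <- max(length(synthetic), length(organic))
  synthetic <- rep_len(as.logical(synthetic), n)
  organic <- rep_len(as.logical(organic), n)
  out <- rep(NA_character_, n)
  out[!is.na(organic) & organic & !is.na(synthetic) & !synthetic] <- "organic"
  out[!is.na(synthetic) & synthetic] <- "synthetic_mixed"
  out
}

.usda_fine <- c("sandy clay", "silty clay", "clay")
.usda_classes <- c(.usda_fine,
                   "sandy loam", "loam", "silt loam", "silt", "clay loam",
                   "sandy clay loam", "silty clay loam", "sand", "loamy sand")

classify_n_rate <- function(n_input) {
  as.character(cut(n_input, breaks = c(0, 100, 200, 300, Inf),
                   labels = c("(0;100]", "(100;200]", "(200;300]", ">300"),
                   right = TRUE))
}

classify_land_cover <- function(land_cover_raw) {
  annual <- c("annual_crop", "bare_soil", "undefined")
  perennial <- c("perennial_crop", "grassland", "agroforestry",
                 "tree_plantation", "managed_forest")
  out <- rep(NA_character_, length(land_cover_raw))
  out[land_cover_raw %in% annual] <- "annual_bare"
  out[land_cover_raw %in% perennial] <- "perennial"
  unknown <- !is.na(land_cover_raw) & is.na(out)
  if (any(unknown)) {
    stop("unknown land cover label: ",
         paste(unique(land_cover_raw[unknown]), collapse = ", "), call. = FALSE)
  }
  out
}

classify_texture <- function(usda_texture) {
  tx <- tolower(trimws(as.character(usda_texture)))
  tx[tx == ""] <- NA_character_
  unknown <- !is.na(tx) & !tx %in% .usda_classes
  if (any(unknown)) {
    warning("unrecognized USDA texture class: ",
            paste(unique(tx[unknown]), collapse = ", "),
            "; flagged unclassifiable", call. = FALSE)
    tx[unknown] <- NA_character_
  }
  ifelse(is.na(tx), NA_character_,
         ifelse(tx %in% .usda_fine, "fine", "medium_coarse"))
}

classify_soil_c <- function(soil_c_pct) {
  ifelse(is.na(soil_c_pct), NA_character_,
         ifelse(soil_c_pct >= 2, "high", "low_medium"))
}

classify_alkalinity <- function(soil_ph) {
  ifelse(is.na(soil_ph), NA_character_,
         ifelse(soil_ph >= 7, "basic", "acid"))
}

classify_length <- function(length_days) {
  as.character(cut(length_days, breaks = c(0, 120, 180, 240, 300, Inf),
                   labels = c("<=120", "(120;180]", "(180;240]",
                              "(240;300]", ">300"),
                   right = TRUE))
}

#' Assign every observation its factor class labels
#'
#' Adds one class column per controlling factor: `climate` (wet/dry),
#' `fertilizer_form` (synthetic_mixed/organic), `n_rate` (left-open
#' right-closed 100 kg N bins), `irrigation` (dry-climate observations only),
#' `land_cover` (annual croplands and bare soils vs perennial systems),
#' `texture` (fine vs medium and coarse USDA classes), `soil_c`
#' (< 2 % vs >= 2 % mass), `alkalinity` (pH < 7 vs >= 7), and `length`
#' (experimental-length bins in days). An observation missing the covariate
#' for one factor is `NA` for that factor only and still participates in the
#' other factors' models.
#'
#' @param observations Data frame in the [read_ef_csv()] schema; `ef` is
#'   derived with [compute_ef()] if absent.
#' @param climate_boundary Tie rule passed to [classify_climate()].
#' @return The input with the class columns (and `ef`, `location` via
#'   [assign_locations()]) appended.
#' @export
classify_dataset <- function(observations, climate_boundary = "wet") {
  d <- observations
  if (is.null(d$ef)) {
    d$ef <- compute_ef(d$n2o_treatment, d$n2o_control, d$n_input)
  }
  d$climate <- classify_climate(d$climate_zone, d$annual_precip, d$pet_ratio,
                                boundary = climate_boundary)
  d$fertilizer_form <- classify_fertilizer_form(d$fertilizer_synthetic,
                                                d$fertilizer_organic)
  d$n_rate <- classify_n_rate(d$n_input)
  d$irrigation <- ifelse(!is.na(d$climate) & d$climate == "dry" & !is.na(d$irrigated),
                         ifelse(d$irrigated, "irrigated", "rainfed"),
                         NA_character_)
  d$land_cover <- classify_land_cover(d$land_cover_raw)
  d$texture <- classify_texture(d$usda_texture)
  d$soil_c <- classify_soil_c(d$soil_c_pct)
  d$alkalinity <- classify_alkalinity(d$soil_ph)
  d$length <- classify_length(d$length_days)
  d$location <- assign_locations(d)
  d
}

#' Group observations into unique experimental locations
#'
#' Two observations belong to the same location when they share an identical
#' coordinate pair, or, failing that, when they come from the same
#' bibliographic reference with the same soil (USDA texture) and the same raw
#' land cover. The two rules are closed transitively, so the result is a
#' partition; coordinate identity takes precedence when the rules conflict.
#' Identifiers are stable under row reordering (components are numbered by
#' their smallest record id).
#'
#' @param observations Data frame with `record_id`, `latitude`, `longitude`,
#'   `reference_id`, `usda_texture`, `land_cover_raw`.
#' @return Character vector of location identifiers, one per row.
#' @export
assign_locations <- function(observations) {
  d <- observations
  n <- nrow(d)
  if (n == 0L) return(character(0))
  coord_key <- ifelse(is.na(d$latitude) | is.na(d$longitude), NA_character_,
                      paste0("C|", format(d$latitude, digits = 15), "|",
                             format(d$longitude, digits = 15)))
  ref_key <- ifelse(is.na(d$reference_id), NA_character_,
                    paste0("R|", d$reference_id, "|",
                           ifelse(is.na(d$usda_texture), "?", tolower(trimws(d$usda_texture))), "|",
                           ifelse(is.na(d$land_cover_raw), "?", d$land_cover_raw)))
  ## union-find over observations, linked through shared keys
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_by_key <- function(key) {
    ok <- !is.na(key)
    for (grp in split(which(ok), key[ok])) {
      if (length(grp) > 1L) {
        r <- find(grp[1L])
        for (j in grp[-1L]) parent[find(j)] <<- r
      }
    }
  }
  union_by_key(coord_key)
  union_by_key(ref_key)
  root <- vapply(seq_len(n), find, integer(1))
  ## stable naming: order components by their smallest record_id
  rid <- as.character(d$record_id)
  min_rid <- vapply(split(rid, root), min, character(1))
  comp_order <- names(sort(min_rid))
  id_map <- stats::setNames(sprintf("LOC%04d", seq_along(comp_order)), comp_order)
  unname(id_map[as.character(root)])
}

#' Tabulate the classified dataset
#'
#' Contingency counts of observations per class for every controlling
#' factor, optionally crossed with a grouping column (e.g. a geographic
#' region carried in the input).
#'
#' @param observations Classified data frame (see [classify_dataset()]).
#' @param by Optional name of a grouping column; `NULL` for overall counts.
#' @param factors Factor columns to tabulate.
#' @return Long data frame with columns `factor`, `class`, optional group,
#'   and `n`. Unclassifiable observations are counted under class
#'   `"unclassifiable"`.
#' @export
summarize_dataset <- function(observations, by = NULL,
                              factors = c("climate", "fertilizer_form",
                                          "n_rate", "irrigation", "land_cover",
                                          "texture", "soil_c", "alkalinity",
                                          "length")) {
  factors <- intersect(factors, names(observations))
  out <- lapply(factors, function(f) {
    cls <- observations[[f]]
    cls <- factor(ifelse(is.na(cls), "unclassifiable", as.character(cls)))
    if (is.null(by)) {
      tb <- table(class = cls)
      df <- as.data.frame(tb, stringsAsFactors = FALSE)
    } else {
      tb <- table(class = cls, group = observations[[by]])
      df <- as.data.frame(tb, stringsAsFactors = FALSE)
      names(df)[names(df) == "group"] <- by
    }
    names(df)[names(df) == "Freq"] <- "n"
    cbind(factor = rep(f, nrow(df)), df, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
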