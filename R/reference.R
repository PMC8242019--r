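#' Parametric healthy-reference spirometry model
#'
#' A reference model gives, for every stratum of ethnic background, sex,
#' age band and height band, the location and scale of a normal reference
#' distribution for each spirometry measure (FEV1 and FVC in mL, PEF in
#' mL/s, FEV1/FVC as a percentage). The lower limit of normal (LLN) for a
#' measure is the 5th percentile of its reference distribution in the
#' participant's stratum. This replaces published reference equations with
#' a transparent parametric stand-in; the 5th-percentile construction of
#' the LLN is preserved exactly.
#'
#' @name reference_model
NULL

ETHNIC_GROUPS <- c("Mexican", "Central American", "Dominican",
                   "Puerto Rican", "Cuban", "South American")
AGE_BANDS <- c("18-39", "40-59", "60+")
HEIGHT_BANDS <- c("<160", "160-172", ">=172")

age_band_of <- function(age_years) {
  as.character(cut(age_years, c(18, 40, 60, Inf), right = FALSE,
                   labels = AGE_BANDS, include.lowest = TRUE))
}

height_band_of <- function(height_cm) {
  as.character(cut(height_cm, c(-Inf, 160, 172, Inf), right = FALSE,
                   labels = HEIGHT_BANDS))
}

#' Build the default synthetic reference model
#'
#' Locations follow simple additive demographic effects (sex, height band,
#' age band, small ethnic-background shifts) chosen to reproduce
#' adult-population spirometry magnitudes (FVC ~ 3.5 L, FEV1/FVC ~ 80%,
#' PEF ~ 7 L/s); scales are homoscedastic within measure. This is a
#' synthetic stand-in for restricted published reference equations.
#'
#' @return Data frame with columns `ethnic_background`, `sex`, `age_band`,
#'   `height_band`, `measure` (fev1/fvc/ratio/pef), `location`, `scale`.
#' @export
default_reference_model <- function() {
  grid <- expand.grid(ethnic_background = ETHNIC_GROUPS,
                      sex = c("F", "M"),
                      age_band = AGE_BANDS,
                      height_band = HEIGHT_BANDS,
                      stringsAsFactors = FALSE)
  eth_shift <- stats::setNames(seq(-50, 50, length.out = 6), ETHNIC_GROUPS)
  age_fvc <- stats::setNames(c(200, 0, -350), AGE_BANDS)
  hgt_fvc <- stats::setNames(c(-300, 0, 300), HEIGHT_BANDS)
  age_ratio <- stats::setNames(c(84, 81, 77), AGE_BANDS)
  age_pef <- stats::setNames(c(300, 0, -600), AGE_BANDS)
  hgt_pef <- stats::setNames(c(-400, 0, 400), HEIGHT_BANDS)

  fvc_loc <- 3200 + 900 * (grid$sex == "M") + hgt_fvc[grid$height_band] +
    age_fvc[grid$age_band] + eth_shift[grid$ethnic_background]
  ratio_loc <- age_ratio[grid$age_band]
  fev1_loc <- fvc_loc * ratio_loc / 100
  pef_loc <- 5800 + 2300 * (grid$sex == "M") + hgt_pef[grid$height_band] +
    age_pef[grid$age_band] + eth_shift[grid$ethnic_background]

  locs <- cbind(fev1 = fev1_loc, fvc = fvc_loc, ratio = ratio_loc,
                pef = pef_loc)
  scales <- c(fev1 = 420, fvc = 480, ratio = 6.5, pef = 1500)
  out <- do.call(rbind, lapply(SPIRO_MEASURES, function(m) {
    cbind(grid, measure = m, location = unname(locs[, m]),
          scale = unname(scales[[m]]))
  }))
  rownames(out) <- NULL
  out
}

validate_reference_model <- function(ref) {
  needed <- c("ethnic_background", "sex", "age_band", "height_band",
              "measure", "location", "scale")
  missing_cols <- setdiff(needed, names(ref))
  if (length(missing_cols) > 0) {
    abort(sprintf("reference model missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          "arsmr_format_error")
  }
  assert_that(all(ref$scale > 0), "reference scales must be positive")
  key <- interaction(ref$ethnic_background, ref$sex, ref$age_band,
                     ref$height_band, ref$measure, drop = TRUE)
  assert_that(!anyDuplicated(key),
              "each stratum x measure must map to exactly one reference cell")
  invisible(ref)
}

#' Read/write a reference model as TSV
#'
#' @param path File path.
#' @return `read_reference_model` returns the validated data frame.
#' @export
read_reference_model <- function(path) {
  ref <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_reference_model(ref)
  ref
}

#' @rdname read_reference_model
#' @param ref Reference model data frame.
#' @export
write_reference_model <- function(ref, path) {
  validate_reference_model(ref)
  utils::write.table(ref, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Look up reference location/scale for each cohort row, one measure.
# Returns a data frame (location, scale) aligned to `strata` rows.
ref_lookup <- function(ref, strata, measure) {
  validate_reference_model(ref)
  sub <- ref[ref$measure == measure, ]
  key_ref <- paste(sub$ethnic_background, sub$sex, sub$age_band,
                   sub$height_band, sep = "\r")
  key_q <- paste(strata$ethnic_background, strata$sex,
                 age_band_of(strata$age_years),
                 height_band_of(strata$height_cm), sep = "\r")
  idx <- match(key_q, key_ref)
  if (anyNA(idx)) {
    abort(sprintf("unresolvable reference stratum (first: %s)",
                  key_q[which(is.na(idx))[1]]),
          "arsmr_lookup_error")
  }
  data.frame(location = sub$location[idx], scale = sub$scale[idx])
}

#' Lower limit of normal for a stratum and measure
#'
#' The LLN is the 5th percentile of the measure's reference distribution
#' in the participant's demographic stratum.
#'
#' @param ref Reference model data frame.
#' @param stratum Data frame (or list coercible to one) with columns
#'   `ethnic_background`, `sex`, `age_years`, `height_cm`; vectorized over
#'   rows.
#' @param measure One of `"fev1"`, `"fvc"`, `"ratio"`, `"pef"`.
#' @param percentile Reference percentile, default 5.
#' @return Numeric vector of thresholds, one per stratum row.
#' @export
lln_threshold <- function(ref, stratum, measure, percentile = 5) {
  measure <- match.arg(measure, SPIRO_MEASURES)
  stratum <- as.data.frame(stratum)
  ls <- ref_lookup(ref, stratum, measure)
  ls$location + stats::qnorm(percentile / 100) * ls$scale
}

#' Classify a measure against its lower limit of normal
#'
#' Strict inequality: a value exactly at the threshold counts as normal
#' (ties have probability ~0 for continuous measures; the strict convention
#' is conservative).
#'
#' @param value Measured values.
#' @param threshold LLN thresholds (recycled).
#' @return Logical vector, `TRUE` when below the LLN.
#' @export
classify_below_lln <- function(value, threshold) {
  value < threshold
}

#' Percent of predicted value
#'
#' @param value Measured values.
#' @param ref_location Reference (predicted) location; must be positive.
#' @return `100 * value / ref_location`.
#' @export
percent_predicted <- function(value, ref_location) {
  assert_that(all(ref_location > 0), "reference location must be positive")
  100 * value / ref_location
}
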