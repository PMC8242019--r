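#' Classify smoking history
#'
#' Never-smoking is defined as fewer than 100 cigarettes over a lifetime;
#' former smokers are grouped with ever smokers. Participants who did not
#' answer the smoking questions are excluded.
#'
#' @param cigarettes_lifetime Lifetime cigarette count (nonnegative).
#' @param current_smoker Logical; currently smoking (unused for the
#'   never/ever split but accepted for interface completeness).
#' @param answered Logical; whether the smoking questions were answered.
#' @return Factor with levels `never`, `ever`, `excluded`.
#' @export
classify_smoking <- function(cigarettes_lifetime, current_smoker = NULL,
                             answered = TRUE) {
  n <- length(cigarettes_lifetime)
  answered <- rep_len(answered, n)
  if (any(cigarettes_lifetime < 0, na.rm = TRUE)) {
    abort("negative lifetime cigarette count", "arsmr_validation_error")
  }
  out <- rep("excluded", n)
  ans <- answered & !is.na(cigarettes_lifetime)
  out[ans & cigarettes_lifetime < 100] <- "never"
  out[ans & cigarettes_lifetime >= 100] <- "ever"
  factor(out, levels = c("never", "ever", "excluded"))
}

#' Classify asthma history
#'
#' Lifetime asthma requires a yes to "have you ever had asthma?" and
#' "was it diagnosed by a medical doctor?" (with `broaden = TRUE`, the
#' sensitivity definition, self-report alone suffices). Lifetime asthma is
#' refined to `current` if the participant still has asthma or used an
#' anti-asthmatic medication in the last year, and `past` otherwise.
#' Missingness propagates: undetermined answers yield `missing`.
#'
#' @param ever,doctor,still,med_use_last_year Logical questionnaire
#'   answers (NA-tolerant).
#' @param broaden Sensitivity toggle: accept self-reported asthma without
#'   a doctor diagnosis.
#' @return Factor with levels `none`, `past`, `current`, `missing`.
#' @export
classify_asthma <- function(ever, doctor, still, med_use_last_year,
                            broaden = FALSE) {
  n <- length(ever)
  doctor <- rep_len(doctor, n); still <- rep_len(still, n)
  med <- rep_len(med_use_last_year, n)
  out <- rep("missing", n)

  out[!is.na(ever) & !ever] <- "none"
  lifetime <- !is.na(ever) & ever &
    (if (broaden) TRUE else (!is.na(doctor) & doctor))
  # ever == TRUE but doctor == FALSE and not broadened: no diagnosed asthma
  out[!is.na(ever) & ever & !broaden & !is.na(doctor) & !doctor] <- "none"

  cur <- (still %in% TRUE) | (med %in% TRUE)
  resolved <- !(is.na(still) & is.na(med))
  out[lifetime & cur] <- "current"
  out[lifetime & !cur & resolved] <- "past"
  # lifetime but both refinement answers missing stays "missing"
  factor(out, levels = c("none", "past", "current", "missing"))
}

#' Correct spirometry for asthma-medication use
#'
#' Medicated participants' measured FVC and FEV1 are multiplied by an
#' attenuation factor (default 0.88) to estimate their unmedicated values.
#' Sensitivity modes: `covariate` leaves volumes untouched and exports
#' medication use as a confounder; `exclude` flags medicated rows out.
#'
#' @param fev1_ml,fvc_ml Measured volumes (mL), positive.
#' @param med_use Logical medication-use indicator.
#' @param mode One of `"scale"`, `"covariate"`, `"exclude"`.
#' @param factor Attenuation factor, default 0.88 (a literature estimate
#'   attenuated for imperfect adherence; overridable).
#' @return Data frame with `fev1_ml`, `fvc_ml`, `excluded`,
#'   `med_covariate`.
#' @export
correct_for_medication <- function(fev1_ml, fvc_ml, med_use,
                                   mode = c("scale", "covariate", "exclude"),
                                   factor = 0.88) {
  mode <- match.arg(mode)
  assert_that(all(fev1_ml > 0, na.rm = TRUE) && all(fvc_ml > 0, na.rm = TRUE),
              "volumes must be positive")
  n <- length(fev1_ml)
  med <- rep_len(med_use, n) %in% TRUE
  out <- data.frame(fev1_ml = fev1_ml, fvc_ml = fvc_ml,
                    excluded = rep(FALSE, n), med_covariate = med)
  if (mode == "scale") {
    out$fev1_ml[med] <- fev1_ml[med] * factor
    out$fvc_ml[med] <- fvc_ml[med] * factor
  } else if (mode == "exclude") {
    out$excluded[med] <- TRUE
  }
  out
}

#' Spirometry inclusion filter
#'
#' A spirometry result is analyzable when the participant's effort was
#' rated maximal and the FVC quality grade is A, B or C; the strict
#' sensitivity mode additionally drops grade C ("potentially usable but
#' not meeting all standards").
#'
#' @param effort_maximal Logical.
#' @param fvc_quality Character grades among A/B/C/D/F.
#' @param strict Drop grade C as well.
#' @return Logical inclusion vector.
#' @export
spirometry_inclusion <- function(effort_maximal, fvc_quality,
                                 strict = FALSE) {
  fvc_quality <- toupper(as.character(fvc_quality))
  known <- fvc_quality %in% c("A", "B", "C", "D", "F") | is.na(fvc_quality)
  if (!all(known)) {
    abort(sprintf("unknown FVC quality grade: %s",
                  paste(unique(fvc_quality[!known]), collapse = ", ")),
          "arsmr_validation_error")
  }
  ok_grades <- if (strict) c("A", "B") else c("A", "B", "C")
  (effort_maximal %in% TRUE) & (fvc_quality %in% ok_grades)
}

#' Classify inferred rice exposure from grain servings
#'
#' Participants strictly above the empirical cutoff percentile (default
#' the 80th) of summed grain servings over two diet recalls are classified
#' as high inferred consumers of rice; those with missing recalls are
#' excluded. The realized cutoff (linear-interpolation quantile) is
#' returned so runs are auditable.
#'
#' @param grain_servings Per-participant summed servings; NA = recalls not
#'   completed.
#' @param percentile Cutoff percentile in (0, 100), default 80.
#' @return List with `label` (factor `high`/`low`/`excluded`) and
#'   `cutoff` (realized servings cutoff).
#' @export
classify_rice <- function(grain_servings, percentile = 80) {
  assert_that(percentile > 0 && percentile < 100,
              "percentile must be in (0,100)")
  if (all(is.na(grain_servings))) {
    abort("all grain servings missing; cannot locate cutoff",
          "arsmr_degenerate_error")
  }
  cutoff <- unname(stats::quantile(grain_servings, percentile / 100,
                                   na.rm = TRUE, type = 7))
  lab <- ifelse(is.na(grain_servings), "excluded",
                ifelse(grain_servings > cutoff, "high", "low"))
  list(label = factor(lab, levels = c("high", "low", "excluded")),
       cutoff = cutoff)
}

#' Apply all phenotyping rules to a cohort table
#'
#' Adds smoking class, asthma category, medication-corrected volumes,
#' spirometry inclusion, below-LLN flags for FEV1, FVC, FEV1/FVC and PEF,
#' percent-predicted values, and the rice-exposure stratum. The rice
#' cutoff is computed on the rows passing the smoking/diet exclusions
#' (logged in the attributes).
#'
#' @param cohort Cohort data frame (see [simulate_cohort()] for columns).
#' @param ref Reference model; default [default_reference_model()].
#' @param broaden_asthma,medication_mode,strict_quality,rice_percentile
#'   Phenotyping options mirroring the sensitivity toggles.
#' @param med_factor Medication attenuation factor.
#' @return The cohort with phenotype columns appended; attributes
#'   `rice_cutoff` and `lln_percentile` record realized settings.
#' @export
phenotype_cohort <- function(cohort, ref = default_reference_model(),
                             broaden_asthma = FALSE,
                             medication_mode = "scale",
                             strict_quality = FALSE,
                             rice_percentile = 80,
                             med_factor = 0.88) {
  ph <- cohort
  ph$smoking_class <- classify_smoking(ph$cigarettes_lifetime,
                                       answered = ph$smoking_answered %||% TRUE)
  ph$asthma_category <- classify_asthma(ph$asthma_ever, ph$asthma_doctor,
                                        ph$asthma_still, ph$asthma_med_use,
                                        broaden = broaden_asthma)
  ph$lifetime_asthma <- ifelse(ph$asthma_category == "missing", NA,
                               ph$asthma_category %in% c("past", "current"))
  ph$current_asthma <- ifelse(ph$asthma_category == "missing", NA,
                              ph$asthma_category == "current")
  ph$past_asthma <- ifelse(ph$asthma_category == "missing", NA,
                           ph$asthma_category == "past")

  med <- correct_for_medication(ph$fev1_ml, ph$fvc_ml, ph$asthma_med_use,
                                mode = medication_mode, factor = med_factor)
  ph$fev1_corr <- med$fev1_ml
  ph$fvc_corr <- med$fvc_ml
  ph$ratio_corr <- 100 * med$fev1_ml / med$fvc_ml
  ph$med_covariate <- med$med_covariate
  ph$included_in_spirometry <-
    spirometry_inclusion(ph$effort_maximal, ph$fvc_quality,
                         strict = strict_quality) & !med$excluded

  vals <- list(fev1 = ph$fev1_corr, fvc = ph$fvc_corr,
               ratio = ph$ratio_corr, pef = ph$pef_ml_s)
  for (m in SPIRO_MEASURES) {
    thr <- lln_threshold(ref, ph, m)
    loc <- ref_lookup(ref, ph, m)$location
    ph[[paste0(m, "_lln")]] <- classify_below_lln(vals[[m]], thr)
    ph[[paste0(m, "_pp")]] <- percent_predicted(vals[[m]], loc)
  }

  base <- ph$smoking_class != "excluded" & !is.na(ph$grain_servings)
  rice <- classify_rice(ifelse(base, ph$grain_servings, NA),
                        percentile = rice_percentile)
  ph$rice_class <- rice$label
  attr(ph, "rice_cutoff") <- rice$cutoff
  attr(ph, "lln_percentile") <- 5
  ph
}
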