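# End-to-end orchestration: simulate -> phenotype -> associate -> MR,
# across the four smoking x rice strata, with the sensitivity suite and
# an auditable exclusion ledger.

#' Pipeline run configuration
#'
#' @param simulation A [sim_config()] describing the synthetic cohort (or
#'   `NULL` if `cohort` is supplied).
#' @param cohort Optional pre-built `arsmr_sim` object to analyze instead
#'   of simulating.
#' @param instruments Instrument set; default the bundled three variants.
#' @param ref Reference model; default [default_reference_model()].
#' @param rice_percentile Rice-exposure cutoff percentile.
#' @param broaden_asthma,continuous_outcomes,percent_predicted_outcomes,
#'   medication_mode,strict_quality Sensitivity toggles.
#' @param pc_variance_threshold PC retention threshold for the MR step.
#' @param covariates Fixed-effect covariates for the association model.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(simulation = sim_config(), cohort = NULL,
                       instruments = NULL, ref = NULL,
                       rice_percentile = 80,
                       broaden_asthma = FALSE,
                       continuous_outcomes = FALSE,
                       percent_predicted_outcomes = FALSE,
                       medication_mode = "scale",
                       strict_quality = FALSE,
                       pc_variance_threshold = 0.99,
                       covariates = default_covariates(),
                       seed = 1L) {
  medication_mode <- match.arg(medication_mode,
                               c("scale", "covariate", "exclude"))
  structure(list(simulation = simulation, cohort = cohort,
                 instruments = instruments, ref = ref,
                 rice_percentile = rice_percentile,
                 broaden_asthma = broaden_asthma,
                 continuous_outcomes = continuous_outcomes,
                 percent_predicted_outcomes = percent_predicted_outcomes,
                 medication_mode = medication_mode,
                 strict_quality = strict_quality,
                 pc_variance_threshold = pc_variance_threshold,
                 covariates = covariates,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Ordered exclusion ledger
#'
#' Applies named keep-filters in order and records the count removed at
#' each step. Conservation holds by construction: input n equals final n
#' plus the sum of removals.
#'
#' @param cohort Data frame.
#' @param filters Named list of logical keep-masks (length nrow), applied
#'   in list order.
#' @return Data frame with columns `step`, `removed`, `remaining`.
#' @export
exclusion_ledger <- function(cohort, filters) {
  keep <- rep(TRUE, nrow(cohort))
  out <- data.frame(step = "input", removed = 0L,
                    remaining = nrow(cohort), stringsAsFactors = FALSE)
  for (nm in names(filters)) {
    f <- filters[[nm]] & keep
    removed <- sum(keep) - sum(f)
    keep <- f
    out <- rbind(out, data.frame(step = nm, removed = removed,
                                 remaining = sum(keep),
                                 stringsAsFactors = FALSE))
  }
  attr(out, "keep") <- keep
  out
}

# Tiny deterministic FNV-1a hash of a canonical character rendering; used
# only as a reproducibility fingerprint, not for security.
fingerprint <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 15,
                                              list.len = 1e6)),
             collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full MR pipeline
#'
#' Simulates (or accepts) a cohort, applies the phenotyping rules,
#' computes the exclusion ledger, stratifies by smoking history and
#' inferred rice consumption (high rice is primary; low rice is the
#' negative-control stratum), estimates per-variant associations with a
#' mixed model in every stratum, and combines them into MR estimates per
#' metabolite with the PC-IVW estimator.
#'
#' @param config A [run_config()].
#' @return List of class `arsmr_report`: `estimates` (MR table),
#'   `associations`, `ledger` (per analysis arm), `cutoffs`, `rho`,
#'   `config` echo, `truth`, and a reproducibility `fingerprint`.
#' @export
arsmr_run <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  instruments <- config$instruments %||% arsmr_instruments()
  ref <- config$ref %||% default_reference_model()

  sim <- config$cohort
  if (is.null(sim)) {
    simcfg <- config$simulation
    if (is.null(simcfg$seed)) {
      simcfg$seed <- derive_seed(config$seed, 1L)
    }
    sim <- simulate_cohort(simcfg, instruments = instruments, ref = ref)
  }
  ph <- phenotype_cohort(sim$cohort, ref = ref,
                         broaden_asthma = config$broaden_asthma,
                         medication_mode = config$medication_mode,
                         strict_quality = config$strict_quality,
                         rice_percentile = config$rice_percentile)

  base <- ph$smoking_class != "excluded" & !is.na(ph$grain_servings)
  ledger_asthma <- exclusion_ledger(ph, list(
    `smoking unanswered` = ph$smoking_class != "excluded",
    `diet unanswered` = !is.na(ph$grain_servings),
    `asthma questionnaire missing` = ph$asthma_category != "missing"))
  ledger_spiro <- exclusion_ledger(ph, list(
    `smoking unanswered` = ph$smoking_class != "excluded",
    `diet unanswered` = !is.na(ph$grain_servings),
    `spirometry effort/quality` = ph$included_in_spirometry))

  strata <- list(
    `never_high` = base & ph$smoking_class == "never" & ph$rice_class == "high",
    `ever_high` = base & ph$smoking_class == "ever" & ph$rice_class == "high",
    `never_low` = base & ph$smoking_class == "never" & ph$rice_class == "low",
    `ever_low` = base & ph$smoking_class == "ever" & ph$rice_class == "low")

  if (config$continuous_outcomes) {
    traits <- c("fev1_corr", "fvc_corr", "pef_ml_s")
    spiro_traits <- traits
  } else if (config$percent_predicted_outcomes) {
    traits <- c("fev1_pp", "fvc_pp", "pef_pp")
    spiro_traits <- traits
  } else {
    traits <- DEFAULT_TRAITS
    spiro_traits <- paste0(SPIRO_MEASURES, "_lln")
  }
  arm_filter <- stats::setNames(
    rep(list(ph$included_in_spirometry), length(spiro_traits)), spiro_traits)
  covariates <- config$covariates
  if (config$medication_mode == "covariate") {
    covariates <- c(covariates, "med_covariate")
  }

  set.seed(derive_seed(config$seed, 2L))
  assoc <- association_scan(ph, sim$clusters, instruments, traits,
                            strata, covariates, arm_filter)
  rho <- ld_from_dosages(as.matrix(
    ph[base, paste0("g_", instruments$rsid)]))
  dimnames(rho) <- list(instruments$rsid, instruments$rsid)
  estimates <- mr_table(assoc, instruments, rho,
                        config$pc_variance_threshold)

  report <- list(
    estimates = estimates,
    associations = assoc,
    ledger = list(asthma = ledger_asthma, spirometry = ledger_spiro),
    cutoffs = list(rice_cutoff = attr(ph, "rice_cutoff"),
                   rice_percentile = config$rice_percentile,
                   lln_percentile = attr(ph, "lln_percentile")),
    rho = rho,
    config = config,
    truth = sim$truth,
    n_input = nrow(ph)
  )
  report$fingerprint <- fingerprint(report[c("estimates", "ledger",
                                             "cutoffs")])
  class(report) <- "arsmr_report"
  report
}

#' Run the sensitivity suite
#'
#' Repeats the baseline run once per sensitivity toggle: broadened asthma
#' definition, continuous spirometry outcomes, percent-predicted
#' outcomes, medication handled as a covariate, medication-users excluded,
#' and strict (no grade C) spirometry quality. All runs share the
#' baseline's seed and cohort.
#'
#' @param config Baseline [run_config()].
#' @return Named list of `arsmr_report`s, `baseline` first.
#' @export
sensitivity_suite <- function(config = run_config()) {
  variants <- list(
    baseline = list(),
    broadened_asthma = list(broaden_asthma = TRUE),
    continuous_outcomes = list(continuous_outcomes = TRUE),
    percent_predicted = list(percent_predicted_outcomes = TRUE),
    medication_covariate = list(medication_mode = "covariate"),
    medication_excluded = list(medication_mode = "exclude"),
    strict_quality = list(strict_quality = TRUE)
  )
  lapply(variants, function(mods) {
    cfg <- config
    for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
    arsmr_run(cfg)
  })
}

#' Write a run report to a directory
#'
#' Emits `estimates.tsv`, `associations.tsv`, per-arm ledgers, and a JSON
#' report with config echo, realized cutoffs and fingerprint.
#'
#' @param report An `arsmr_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$estimates, "estimates.tsv")
  wt(report$associations, "associations.tsv")
  wt(report$ledger$asthma, "ledger_asthma.tsv")
  wt(report$ledger$spirometry, "ledger_spirometry.tsv")
  meta <- list(cutoffs = report$cutoffs,
               fingerprint = report$fingerprint,
               n_input = report$n_input,
               seed = report$config$seed)
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_truth(report$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Write / read the generative truth record
#'
#' The truth record (config plus realized generative quantities; latent
#' indicators are omitted) round-trips through JSON byte-identically,
#' which is the reproducibility contract for a run directory.
#'
#' @param truth Truth list from [simulate_cohort()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  truth$latent <- NULL
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a simulated cohort to a run directory
#'
#' Emits `cohort.tsv`, sparse-triplet TSVs for the three cluster kernels,
#' `truth.json`, and a minimal VCF (DS field) of the instrument variants.
#'
#' @param sim An `arsmr_sim` object.
#' @param dir Output directory.
#' @param instruments Instrument set used for the VCF site lines.
#' @export
write_simulation <- function(sim, dir, instruments = arsmr_instruments()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(sim$clusters)) {
    M <- methods::as(sim$clusters[[nm]], "TsparseMatrix")
    utils::write.table(
      data.frame(i = M@i + 1L, j = M@j + 1L, x = M@x),
      file.path(dir, sprintf("clusters_%s.tsv", nm)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_truth(sim$truth, file.path(dir, "truth.json"))
  write_vcf(sim$cohort, instruments, file.path(dir, "variants.vcf"))
  invisible(dir)
}

#' Minimal VCF round trip for the instrument dosages
#'
#' `write_vcf` emits an uncompressed VCFv4.2 with a `DS` FORMAT field (one
#' sample column per participant); `read_vcf_dosages` reads DS (or GT,
#' summed) back into a dosage matrix restricted to the requested rsids.
#'
#' @param cohort Cohort with `g_<rsid>` columns and `id`.
#' @param instruments Instrument set (site order, alleles, positions).
#' @param path VCF path.
#' @export
write_vcf <- function(cohort, instruments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT (counted) allele\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", cohort$id),
                     collapse = "\t")), con)
  for (i in seq_len(nrow(instruments))) {
    ds <- format(cohort[[paste0("g_", instruments$rsid[i])]])
    writeLines(paste(c(instruments$chrom[i], instruments$pos[i],
                       instruments$rsid[i], instruments$ref_allele[i],
                       instruments$effect_allele[i], ".", "PASS", ".",
                       "DS", ds), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_vcf
#' @param rsids Variants to extract; default all sites in the file.
#' @return `read_vcf_dosages` returns a numeric matrix, samples x
#'   variants, with an attribute `counted_allele` (the ALT allele).
#' @export
read_vcf_dosages <- function(path, rsids = NULL) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  assert_that(identical(header[1], "#CHROM"), "not a VCF file",
              "arsmr_format_error")
  samples <- header[-(1:9)]
  rows <- lapply(body[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  ids <- vapply(rows, `[[`, "", 3)
  if (is.null(rsids)) rsids <- ids
  missing_rs <- setdiff(rsids, ids)
  if (length(missing_rs) > 0) {
    abort(sprintf("variant(s) absent from VCF: %s",
                  paste(missing_rs, collapse = ", ")),
          "arsmr_format_error")
  }
  out <- sapply(rsids, function(rs) {
    r <- rows[[match(rs, ids)]]
    fmt <- strsplit(r[9], ":", fixed = TRUE)[[1]]
    fields <- r[-(1:9)]
    if ("DS" %in% fmt) {
      k <- match("DS", fmt)
      as.numeric(vapply(strsplit(fields, ":", fixed = TRUE),
                        `[[`, "", k))
    } else if ("GT" %in% fmt) {
      k <- match("GT", fmt)
      gt <- vapply(strsplit(fields, ":", fixed = TRUE), `[[`, "", k)
      vapply(strsplit(gsub("\\|", "/", gt), "/"), function(a) {
        sum(as.numeric(a))
      }, 0)
    } else {
      abort("VCF has neither DS nor GT", "arsmr_format_error")
    }
  })
  out <- matrix(out, ncol = length(rsids),
                dimnames = list(samples, rsids))
  alt <- vapply(rsids, function(rs) rows[[match(rs, ids)]][5], "")
  attr(out, "counted_allele") <- alt
  out
}
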