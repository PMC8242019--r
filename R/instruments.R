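#' Load a literature instrument table
#'
#' Reads a tab-separated table of instrument variants with per-metabolite
#' effect sizes on arsenic metabolism efficiency. One row per variant with
#' columns `rsid`, `chrom`, `pos`, `effect_allele`, `ref_allele`, and for
#' each metabolite in \{iAs, MMA, DMA\} a `beta_<m>` (percentage points of
#' the urinary metabolite per copy of the effect allele) and `se_<m>`
#' (standard error, same units). Positions are 1-based hg19.
#'
#' The bundled instrument (see [arsmr_instruments()]) holds the three
#' published variants: rs9527 and rs11191527 near *AS3MT* on chromosome 10,
#' and the *FTCD* missense variant rs61735836 on chromosome 21.
#'
#' @param path Path to a tab-separated instrument file.
#' @return An `instrument_set`: a data frame with the columns above, row
#'   order preserved from the file, carrying class `"instrument_set"`.
#' @export
load_instruments <- function(path) {
  assert_that(file.exists(path), sprintf("instrument file not found: %s", path),
              "arsmr_format_error")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("rsid", "chrom", "pos", "effect_allele", "ref_allele",
              paste0("beta_", METABOLITES), paste0("se_", METABOLITES))
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("instrument file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          "arsmr_format_error")
  }
  new_instrument_set(tab[needed])
}

#' The bundled three-variant arsenic-metabolism instrument
#'
#' Returns the packaged instrument set: three SNVs whose associations with
#' %iAs, %MMA and %DMA were reported genome-wide significant with linearly
#' modelled effects. Effect sizes are percentage points of the urinary
#' metabolite per effect-allele copy.
#'
#' @return An `instrument_set` with three rows (rs9527, rs11191527,
#'   rs61735836), in that order.
#' @export
arsmr_instruments <- function() {
  load_instruments(system.file("extdata", "instrument_weights.tsv",
                               package = "arsmr", mustWork = TRUE))
}

new_instrument_set <- function(tab) {
  tab$rsid <- as.character(tab$rsid)
  tab$chrom <- as.character(tab$chrom)
  tab$effect_allele <- toupper(as.character(tab$effect_allele))
  tab$ref_allele <- toupper(as.character(tab$ref_allele))
  num_cols <- c("pos", paste0("beta_", METABOLITES), paste0("se_", METABOLITES))
  for (cl in num_cols) tab[[cl]] <- as.numeric(tab[[cl]])
  validate_instrument_set(tab)
  rownames(tab) <- NULL
  class(tab) <- c("instrument_set", "data.frame")
  tab
}

validate_instrument_set <- function(tab) {
  assert_that(nrow(tab) >= 1, "instrument set must contain at least one variant")
  if (anyDuplicated(tab$rsid)) {
    abort("duplicate rsid in instrument set", "arsmr_validation_error")
  }
  if (anyNA(tab[c(paste0("beta_", METABOLITES), paste0("se_", METABOLITES))])) {
    abort("missing beta/se cell in instrument set", "arsmr_validation_error")
  }
  se <- as.matrix(tab[paste0("se_", METABOLITES)])
  if (any(se <= 0)) {
    abort("all standard errors must be strictly positive", "arsmr_validation_error")
  }
  assert_that(all(tab$pos > 0), "positions must be positive")
  ok_allele <- function(a) grepl("^[ACGT]+$", a)
  assert_that(all(ok_allele(tab$effect_allele)) && all(ok_allele(tab$ref_allele)),
              "alleles must be A/C/G/T strings")
  if (any(tab$effect_allele == tab$ref_allele)) {
    abort("effect and reference allele must differ", "arsmr_validation_error")
  }
  invisible(tab)
}

#' Audit the compositional closure of instrument effect sizes
#'
#' The three metabolite percentages partition measured urinary arsenic, so
#' for any variant the three effect sizes must sum to (approximately) zero:
#' raising %iAs and %MMA necessarily lowers %DMA. This audit reports the
#' per-variant sum and flags variants whose |sum| exceeds `tol`.
#'
#' @param instruments An `instrument_set`.
#' @param tol Tolerance in percentage points (default 0.05).
#' @return Data frame with columns `rsid`, `beta_sum`, `pass`.
#' @export
compositional_audit <- function(instruments, tol = 0.05) {
  stopifnot(inherits(instruments, "instrument_set"))
  s <- instruments$beta_iAs + instruments$beta_MMA + instruments$beta_DMA
  data.frame(rsid = instruments$rsid,
             beta_sum = s,
             pass = abs(s) <= tol,
             stringsAsFactors = FALSE)
}

strand_ambiguous <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  nchar(a) == 1 & nchar(b) == 1 & comp[a] == b
}

#' Harmonize instrument allele coding to a cohort's counted alleles
#'
#' Aligns the literature effect sizes with the allele the cohort's dosages
#' count. Where the cohort counts the literature reference allele, all
#' three metabolite betas are sign-flipped and the effect/reference labels
#' swapped; where it counts the effect allele the record is unchanged. No
#' strand inference is attempted: a counted allele matching neither
#' literature allele is an error, as is any strand-ambiguous (A/T or C/G)
#' variant, because a silent strand error would flip the causal direction.
#'
#' @param instruments An `instrument_set`.
#' @param cohort_coding Named character vector, `rsid -> counted allele`.
#' @return An `instrument_set` with aligned signs and allele labels.
#' @export
harmonize <- function(instruments, cohort_coding) {
  stopifnot(inherits(instruments, "instrument_set"))
  assert_that(!is.null(names(cohort_coding)),
              "cohort_coding must be a named vector (rsid -> allele)",
              "arsmr_harmonization_error")
  missing_rs <- setdiff(instruments$rsid, names(cohort_coding))
  if (length(missing_rs) > 0) {
    abort(sprintf("no cohort allele coding for: %s",
                  paste(missing_rs, collapse = ", ")),
          "arsmr_harmonization_error")
  }
  out <- as.data.frame(instruments)
  for (i in seq_len(nrow(out))) {
    counted <- toupper(cohort_coding[[out$rsid[i]]])
    eff <- out$effect_allele[i]; ref <- out$ref_allele[i]
    if (strand_ambiguous(eff, ref)) {
      abort(sprintf("%s is strand-ambiguous (%s/%s); refusing to harmonize",
                    out$rsid[i], eff, ref),
            "arsmr_harmonization_error")
    }
    if (counted == eff) {
      next
    } else if (counted == ref) {
      for (m in METABOLITES) {
        out[[paste0("beta_", m)]][i] <- -out[[paste0("beta_", m)]][i]
      }
      out$effect_allele[i] <- ref
      out$ref_allele[i] <- eff
    } else {
      abort(sprintf("counted allele %s for %s matches neither %s nor %s",
                    counted, out$rsid[i], eff, ref),
            "arsmr_harmonization_error")
    }
  }
  new_instrument_set(out)
}

#' Pairwise LD among instrument variants from dosages
#'
#' Computes the signed sample correlation matrix of dosage columns (the
#' composite r; with random mating this matches the haplotype-level r).
#' The diagonal is forced to exactly 1.
#'
#' @param dosages Numeric matrix, participants in rows and variants in
#'   columns, entries in \[0, 2\]. Column names (rsids) are propagated.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
ld_from_dosages <- function(dosages) {
  dosages <- as.matrix(dosages)
  assert_that(nrow(dosages) >= 2, "need at least two samples to estimate LD",
              "arsmr_degenerate_error")
  v <- apply(dosages, 2, stats::var)
  if (any(v <= 0 | !is.finite(v))) {
    bad <- colnames(dosages)[v <= 0 | !is.finite(v)] %||% which(v <= 0)
    abort(sprintf("zero-variance dosage column: %s",
                  paste(bad, collapse = ", ")),
          "arsmr_degenerate_error")
  }
  r <- stats::cor(dosages)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}
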