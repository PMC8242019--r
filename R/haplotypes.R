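#' Solve for the second allele frequency compatible with a (D', r²) target
#'
#' For two biallelic loci, fixing one allele frequency, a target D' and a
#' target r² jointly determine the other frequency (on the branch where the
#' second frequency is the smaller of the two). Used to pick simulator
#' defaults for the chromosome-10 instrument pair, whose published LD is
#' D' = 0.87 with r² = 0.28.
#'
#' @param maf_a Allele frequency at the first locus, in (0, 1).
#' @param dprime Target D' in (0, 1\].
#' @param r2 Target squared correlation, 0 < r2 <= dprime^2.
#' @return The compatible allele frequency at the second locus.
#' @export
ld_compatible_maf <- function(maf_a, dprime, r2) {
  assert_that(maf_a > 0 && maf_a < 1, "maf_a must be in (0,1)")
  assert_that(dprime > 0 && dprime <= 1, "dprime must be in (0,1]")
  assert_that(r2 > 0 && r2 <= dprime^2,
              sprintf("r2 must be in (0, dprime^2 = %.4f]", dprime^2),
              "arsmr_feasibility_error")
  # On the branch maf_b <= maf_a, Dmax = (1-maf_a)*maf_b, and
  # r2 = dprime^2 * (1-maf_a)*maf_b / (maf_a*(1-maf_b)) solves linearly.
  r2 * maf_a / (dprime^2 * (1 - maf_a) + r2 * maf_a)
}

haplotype_freqs <- function(maf_a, maf_b, target_dprime) {
  maf_a <- unname(maf_a); maf_b <- unname(maf_b)
  qa <- 1 - maf_a; qb <- 1 - maf_b
  dmax <- min(maf_a * qb, qa * maf_b)   # coupling (positive-D) bound
  D <- target_dprime * dmax
  h <- c(AB = maf_a * maf_b + D,
         Ab = maf_a * qb - D,
         aB = qa * maf_b - D,
         ab = qa * qb + D)
  if (any(h < -1e-12)) {
    abort(sprintf("infeasible (maf, D') combination; admissible D' range is [0, 1] at these frequencies but frequencies give negative haplotype mass (D = %.4g)", D),
          "arsmr_feasibility_error")
  }
  pmax(h, 0)
}

#' Simulate haplotype pairs for two linked loci
#'
#' Draws `n_hap` two-locus haplotypes from the four-haplotype distribution
#' with the given allele frequencies and normalized disequilibrium
#' D' (coupling phase, D >= 0). Used for the chromosome-10 instrument pair.
#'
#' @param maf_a,maf_b Allele frequencies of the counted alleles.
#' @param target_dprime Target D' in \[0, 1\].
#' @param n_hap Number of haplotypes to draw.
#' @param seed Optional integer seed.
#' @return Integer matrix `n_hap x 2` of 0/1 allele indicators with
#'   attributes `freqs` (expected haplotype frequencies), `counts`
#'   (realized haplotype counts) and `target` (maf_a, maf_b, dprime).
#' @export
simulate_haplotypes <- function(maf_a, maf_b, target_dprime, n_hap,
                                seed = NULL) {
  assert_that(maf_a > 0 && maf_a < 1 && maf_b > 0 && maf_b < 1,
              "allele frequencies must be in (0,1)")
  assert_that(target_dprime >= 0 && target_dprime <= 1,
              "target_dprime must be in [0,1]", "arsmr_feasibility_error")
  assert_that(n_hap >= 1, "n_hap must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  h <- haplotype_freqs(maf_a, maf_b, target_dprime)
  idx <- sample.int(4L, n_hap, replace = TRUE, prob = h)
  alle_a <- c(1L, 1L, 0L, 0L)[idx]
  alle_b <- c(1L, 0L, 1L, 0L)[idx]
  out <- cbind(a = alle_a, b = alle_b)
  attr(out, "freqs") <- h
  attr(out, "counts") <- tabulate(idx, 4L)
  attr(out, "target") <- c(maf_a = maf_a, maf_b = maf_b,
                           dprime = target_dprime)
  out
}

#' Realized D' and r² of a haplotype sample
#'
#' @param hap Matrix as returned by [simulate_haplotypes()].
#' @return Named vector with `dprime`, `r2`, `pA`, `pB`.
#' @export
haplotype_ld <- function(hap) {
  pA <- mean(hap[, 1]); pB <- mean(hap[, 2])
  pAB <- mean(hap[, 1] == 1 & hap[, 2] == 1)
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  c(dprime = if (dmax > 0) abs(D) / dmax else 0, r2 = r2, pA = pA, pB = pB)
}
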