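#' Simulation configuration
#'
#' Collects every generative parameter of the synthetic cohort. Defaults
#' encode the study's stated structure where printed (instrument effect
#' sizes; chr10 LD of D' = 0.87 with r² = 0.28; ~45% ever-smokers; top
#' fifth of grain consumers "high rice"; medication attenuation 0.88) and
#' field-realistic choices where not (allele frequencies, metabolite noise,
#' cluster variances) — see the methods vignette for the rationale of each
#' invented value.
#'
#' @param n_participants Cohort size.
#' @param maf Allele frequencies of the three counted alleles (rs9527,
#'   rs11191527, rs61735836). `NA` for the second frequency solves it from
#'   `target_dprime`/`target_r2` via [ld_compatible_maf()].
#' @param target_dprime,target_r2 LD targets for the chr10 pair.
#' @param theta Named causal log-odds per percentage point of the
#'   genetically driven %iAs score, per binary trait, applied only in the
#'   high-rice stratum (the low-rice stratum is a negative control by
#'   construction).
#' @param baseline_logodds Named baseline log-odds per binary trait
#'   (`current_asthma` is conditional on lifetime asthma).
#' @param causal_channel `"genetic"` (default): trait log-odds depend on
#'   the genotype-driven metabolite component; `"phenotype"`: on the full
#'   noisy %iAs value.
#' @param frac_high_rice,frac_ever_smoker Population fractions.
#' @param household_size_probs Named probabilities of household sizes.
#' @param sibling_pair_fraction Fraction of multi-person households that
#'   contain one declared full-sibling pair.
#' @param households_per_block_group Households per census block group.
#' @param variance_components Named variances (logit scale) for the
#'   kinship/household/block-group random effects.
#' @param metabolite_means,metabolite_sds,metabolite_cor Population means
#'   and within-person noise of (%iAs, %MMA); %DMA closes the composition
#'   to 100 exactly.
#' @param med_factor Simulated medication inflation (measured volumes of
#'   medicated participants are truth / `med_factor`).
#' @param n_smoking_missing,n_diet_missing Completely-at-random
#'   non-responder counts injected for exclusion plumbing.
#' @param asthma_missing_frac Fraction with missing asthma questionnaire.
#' @param frac_effort_maximal,quality_probs Spirometry quality generators.
#' @param grain_shape,grain_scale Gamma parameters for servings.
#' @param seed Optional integer master seed.
#' @param max_resample Bound on simplex resampling rounds for metabolites.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 5000,
                       maf = c(rs9527 = 0.45, rs11191527 = NA,
                               rs61735836 = 0.12),
                       target_dprime = 0.87, target_r2 = 0.28,
                       theta = c(lifetime_asthma = 0, current_asthma = 0,
                                 fvc_lln = 0, pef_lln = 0, ratio_lln = 0),
                       baseline_logodds = c(lifetime_asthma = stats::qlogis(0.155),
                                            current_asthma = stats::qlogis(0.45),
                                            fvc_lln = stats::qlogis(0.10),
                                            pef_lln = stats::qlogis(0.10),
                                            ratio_lln = stats::qlogis(0.10)),
                       causal_channel = c("genetic", "phenotype"),
                       frac_high_rice = 0.2, frac_ever_smoker = 0.45,
                       household_size_probs = c(`1` = 0.45, `2` = 0.30,
                                                `3` = 0.15, `4` = 0.10),
                       sibling_pair_fraction = 0.15,
                       households_per_block_group = 40,
                       variance_components = c(kinship = 0.10,
                                               household = 0.10,
                                               block_group = 0.05),
                       metabolite_means = c(iAs = 13, MMA = 14),
                       metabolite_sds = c(iAs = 3.5, MMA = 3.5),
                       metabolite_cor = 0.3,
                       med_factor = 0.88,
                       n_smoking_missing = 0, n_diet_missing = 0,
                       asthma_missing_frac = 0.02,
                       frac_effort_maximal = 0.95,
                       quality_probs = c(A = 0.45, B = 0.37, C = 0.12,
                                         D = 0.04, F = 0.02),
                       grain_shape = 2, grain_scale = 1.1356,
                       seed = NULL, max_resample = 50) {
  causal_channel <- match.arg(causal_channel)
  if (is.na(maf[2])) {
    maf[2] <- ld_compatible_maf(maf[1], target_dprime, target_r2)
  }
  cfg <- list(n_participants = n_participants, maf = maf,
              target_dprime = target_dprime, target_r2 = target_r2,
              theta = theta, baseline_logodds = baseline_logodds,
              causal_channel = causal_channel,
              frac_high_rice = frac_high_rice,
              frac_ever_smoker = frac_ever_smoker,
              household_size_probs = household_size_probs,
              sibling_pair_fraction = sibling_pair_fraction,
              households_per_block_group = households_per_block_group,
              variance_components = variance_components,
              metabolite_means = metabolite_means,
              metabolite_sds = metabolite_sds,
              metabolite_cor = metabolite_cor,
              med_factor = med_factor,
              n_smoking_missing = n_smoking_missing,
              n_diet_missing = n_diet_missing,
              asthma_missing_frac = asthma_missing_frac,
              frac_effort_maximal = frac_effort_maximal,
              quality_probs = quality_probs,
              grain_shape = grain_shape, grain_scale = grain_scale,
              seed = seed, max_resample = max_resample)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_participants >= 1, "n_participants must be >= 1",
              "arsmr_config_error")
  assert_that(all(cfg$maf > 0 & cfg$maf < 1),
              "allele frequencies must be in (0,1)", "arsmr_config_error")
  props <- c(cfg$frac_high_rice, cfg$frac_ever_smoker,
             cfg$sibling_pair_fraction, cfg$asthma_missing_frac,
             cfg$frac_effort_maximal)
  assert_that(all(props >= 0 & props <= 1),
              "proportions must be in [0,1]", "arsmr_config_error")
  assert_that(cfg$target_dprime >= 0 && cfg$target_dprime <= 1,
              "D' must be in [0,1]", "arsmr_config_error")
  assert_that(all(cfg$variance_components >= 0),
              "variance components must be nonnegative", "arsmr_config_error")
  assert_that(abs(cfg$metabolite_cor) < 1, "metabolite_cor must be in (-1,1)",
              "arsmr_config_error")
  invisible(cfg)
}

# Correlated polygenic/household/block-group random effects on the logit
# scale; siblings share half the polygenic variance.
cluster_effects <- function(cohort, vc) {
  n <- nrow(cohort)
  hh <- as.integer(factor(cohort$household_id))
  bg <- as.integer(factor(cohort$block_group_id))
  b_h <- stats::rnorm(max(hh), 0, sqrt(vc[["household"]]))[hh]
  b_g <- stats::rnorm(max(bg), 0, sqrt(vc[["block_group"]]))[bg]
  a <- stats::rnorm(n, 0, sqrt(0.5 * vc[["kinship"]]))
  # shared sibling component: same draw for both members of a pair
  pair_id <- sibling_pair_ids(cohort)
  shared <- stats::rnorm(max(pair_id, 1), 0, sqrt(0.5 * vc[["kinship"]]))
  own <- stats::rnorm(n, 0, sqrt(0.5 * vc[["kinship"]]))
  a <- ifelse(pair_id > 0, shared[pmax(pair_id, 1)], own) + a
  b_h + b_g + a
}

# Integer id per sibling pair (0 = not in a pair).
sibling_pair_ids <- function(cohort) {
  n <- nrow(cohort)
  pair_id <- integer(n)
  sib <- which(!is.na(cohort$sibling_of))
  if (length(sib) == 0) return(pair_id)
  j <- match(cohort$sibling_of[sib], cohort$id)
  if (anyNA(j)) {
    abort(sprintf("dangling sibling_of reference: %s",
                  cohort$sibling_of[sib][which(is.na(j))[1]]),
          "arsmr_validation_error")
  }
  key <- paste(pmin(sib, j), pmax(sib, j))
  pair_id[sib] <- match(key, unique(key))
  pair_id
}

# Inverse-CDF draw from N(loc, scale) conditioned on being below/above the
# p-th percentile according to `below`.
rtrunc_flag <- function(below, loc, scale, p = 0.05) {
  u <- stats::runif(length(below))
  pr <- ifelse(below, p * u, p + (1 - p) * u)
  stats::qnorm(pr, mean = loc, sd = scale)
}

#' Simulate a synthetic cohort
#'
#' Generates a participant-level table with the statistical structure the
#' analysis assumes: three instrument dosages with the configured LD
#' (chr10 pair from haplotypes, chr21 variant independent), urinary
#' metabolite percentages shifted by the literature effect sizes and
#' summing to 100 exactly, household/sibship/block-group clustering,
#' smoking and rice strata, asthma questionnaire answers, and spirometry
#' with latent below-LLN indicators whose log-odds depend on the %iAs
#' channel only in the high-rice stratum.
#'
#' @param config A [sim_config()].
#' @param instruments Instrument set providing the metabolite effect
#'   sizes; default [arsmr_instruments()].
#' @param ref Reference model for spirometry draws.
#' @return List of class `arsmr_sim` with elements `cohort` (data frame),
#'   `clusters` ([build_cluster_matrices()] output) and `truth` (every
#'   generative parameter plus realized quantities).
#' @export
simulate_cohort <- function(config = sim_config(),
                            instruments = arsmr_instruments(),
                            ref = default_reference_model()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_participants

  ## clustering: households -> block groups, optional sibling pairs
  sizes <- as.integer(names(config$household_size_probs))
  hh_sizes <- integer(0)
  while (sum(hh_sizes) < n) {
    hh_sizes <- c(hh_sizes, sample(sizes, 256, replace = TRUE,
                                   prob = config$household_size_probs))
  }
  hh_sizes <- hh_sizes[cumsum(hh_sizes) - hh_sizes < n]
  household_id <- rep(seq_along(hh_sizes), hh_sizes)[seq_len(n)]
  hh_sizes <- tabulate(household_id)
  block_group_id <- (seq_along(hh_sizes) - 1L) %/%
    config$households_per_block_group + 1L
  bg_of <- block_group_id[household_id]
  id <- sprintf("P%05d", seq_len(n))

  sibling_of <- rep(NA_character_, n)
  multi <- which(hh_sizes >= 2)
  with_pair <- multi[stats::runif(length(multi)) < config$sibling_pair_fraction]
  if (length(with_pair) > 0) {
    first_member <- match(with_pair, household_id)   # rows sorted by household
    sibling_of[first_member] <- id[first_member + 1L]
    sibling_of[first_member + 1L] <- id[first_member]
  }

  ## genotypes
  hap <- simulate_haplotypes(config$maf[1], config$maf[2],
                             config$target_dprime, 2L * n)
  g1 <- hap[seq(1, 2 * n, 2), 1] + hap[seq(2, 2 * n, 2), 1]
  g2 <- hap[seq(1, 2 * n, 2), 2] + hap[seq(2, 2 * n, 2), 2]
  g3 <- stats::rbinom(n, 2, config$maf[3])
  G <- cbind(g1, g2, g3)
  colnames(G) <- instruments$rsid

  ## demographics / design variables
  eth_probs <- c(Mexican = 0.37, `Central American` = 0.11,
                 Dominican = 0.093, `Puerto Rican` = 0.177,
                 Cuban = 0.178, `South American` = 0.072)
  ethnic_background <- sample(names(eth_probs), n, TRUE, eth_probs)
  sex <- sample(c("F", "M"), n, TRUE)
  age_years <- stats::runif(n, 18, 75)
  height_cm <- ifelse(sex == "M", stats::rnorm(n, 170, 7),
                      stats::rnorm(n, 157, 6))
  pcs <- matrix(stats::rnorm(5 * n), n, 5,
                dimnames = list(NULL, paste0("pc", 1:5)))
  pcs[, 1] <- pcs[, 1] + 0.5 * (match(ethnic_background, names(eth_probs)) - 3.5)
  sampling_weight <- stats::rlnorm(n, 0, 0.5)

  ## smoking
  ever <- stats::runif(n) < config$frac_ever_smoker
  cigarettes_lifetime <- ifelse(ever,
                                100L + stats::rpois(n, 3000),
                                sample(0:99, n, TRUE))
  smoking <- ifelse(!ever, "never",
                    ifelse(stats::runif(n) < 0.55, "current", "former"))
  smoking_answered <- rep(TRUE, n)
  if (config$n_smoking_missing > 0) {
    smoking_answered[sample.int(n, min(n, config$n_smoking_missing))] <- FALSE
  }

  ## rice exposure: quantile-split gamma keeps the generative high/low flag
  ## concordant with the empirical percentile classification
  high_rice <- stats::runif(n) < config$frac_high_rice
  u <- stats::runif(n)
  pu <- ifelse(high_rice, (1 - config$frac_high_rice) + config$frac_high_rice * u,
               (1 - config$frac_high_rice) * u)
  grain_servings <- stats::qgamma(pu, shape = config$grain_shape,
                                  scale = config$grain_scale)
  if (config$n_diet_missing > 0) {
    grain_servings[sample.int(n, min(n, config$n_diet_missing))] <- NA
  }

  ## metabolites: genetic shift + bivariate noise, DMA by closure.
  ## Literature effect sizes are per-variant (marginal) GWAS estimates, so
  ## the joint generative coefficients gamma are solved from the expected
  ## dosage covariance: beta_marginal = diag(vg)^-1 C gamma.
  vg <- 2 * config$maf * (1 - config$maf)
  hfreq <- haplotype_freqs(config$maf[1], config$maf[2],
                           config$target_dprime)
  Dhap <- hfreq[["AB"]] - config$maf[1] * config$maf[2]
  Cg <- diag(vg)
  Cg[1, 2] <- Cg[2, 1] <- 2 * Dhap
  gam_i <- solve(Cg, vg * instruments$beta_iAs)
  gam_m <- solve(Cg, vg * instruments$beta_MMA)
  bx_i <- as.numeric(G %*% gam_i)
  bx_m <- as.numeric(G %*% gam_m)
  int_i <- config$metabolite_means[["iAs"]] - mean(bx_i)
  int_m <- config$metabolite_means[["MMA"]] - mean(bx_m)
  sds <- config$metabolite_sds; rho_e <- config$metabolite_cor
  draw_noise <- function(m) {
    z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
    cbind(sds[["iAs"]] * z1,
          sds[["MMA"]] * (rho_e * z1 + sqrt(1 - rho_e^2) * z2))
  }
  e <- draw_noise(n)
  pct_iAs <- int_i + bx_i + e[, 1]
  pct_MMA <- int_m + bx_m + e[, 2]
  bad <- which(pct_iAs < 0 | pct_MMA < 0 | pct_iAs + pct_MMA > 100)
  tries <- 0
  while (length(bad) > 0) {
    tries <- tries + 1
    if (tries > config$max_resample) {
      abort("metabolite simplex resampling failed; noise too large for the configured means", "arsmr_config_error")
    }
    e2 <- draw_noise(length(bad))
    pct_iAs[bad] <- int_i + bx_i[bad] + e2[, 1]
    pct_MMA[bad] <- int_m + bx_m[bad] + e2[, 2]
    bad <- bad[pct_iAs[bad] < 0 | pct_MMA[bad] < 0 |
                 pct_iAs[bad] + pct_MMA[bad] > 100]
  }
  pct_DMA <- 100 - pct_iAs - pct_MMA

  ## causal channel score (centered)
  z_score <- if (config$causal_channel == "genetic") bx_i - mean(bx_i)
             else pct_iAs - mean(pct_iAs)

  skeleton <- data.frame(id = id, household_id = household_id,
                         block_group_id = bg_of, sibling_of = sibling_of,
                         stringsAsFactors = FALSE)
  eta_c <- cluster_effects(skeleton, config$variance_components)

  draw_binary <- function(trait) {
    eff <- ifelse(high_rice, config$theta[[trait]], 0)
    stats::runif(n) < expit(config$baseline_logodds[[trait]] +
                              eff * z_score + eta_c)
  }

  ## asthma questionnaire
  lifetime <- draw_binary("lifetime_asthma")
  current <- lifetime & draw_binary("current_asthma")
  extra_selfreport <- !lifetime & stats::runif(n) < 0.01
  asthma_ever <- lifetime | extra_selfreport
  asthma_doctor <- lifetime
  asthma_still <- current
  asthma_med_use <- (current & stats::runif(n) < 0.60) |
    (lifetime & !current & stats::runif(n) < 0.08) |
    (!lifetime & stats::runif(n) < 0.005)
  if (config$asthma_missing_frac > 0) {
    miss <- stats::runif(n) < config$asthma_missing_frac
    asthma_ever[miss] <- NA; asthma_doctor[miss] <- NA
    asthma_still[miss] <- NA
  }

  ## spirometry: latent below-LLN flags, values from truncated reference
  strata <- data.frame(ethnic_background = ethnic_background, sex = sex,
                       age_years = age_years, height_cm = height_cm)
  d_fvc <- draw_binary("fvc_lln")
  d_pef <- draw_binary("pef_lln")
  d_ratio <- draw_binary("ratio_lln")
  ls_fvc <- ref_lookup(ref, strata, "fvc")
  ls_pef <- ref_lookup(ref, strata, "pef")
  ls_ratio <- ref_lookup(ref, strata, "ratio")
  fvc <- rtrunc_flag(d_fvc, ls_fvc$location, ls_fvc$scale)
  pef <- pmax(rtrunc_flag(d_pef, ls_pef$location, ls_pef$scale), 500)
  ratio <- pmin(pmax(rtrunc_flag(d_ratio, ls_ratio$location, ls_ratio$scale),
                     35), 99)
  fvc <- pmax(fvc, 800)
  fev1 <- fvc * ratio / 100
  # medicated participants measure better than their unmedicated truth
  infl <- ifelse(asthma_med_use %in% TRUE, 1 / config$med_factor, 1)
  fev1_obs <- fev1 * infl
  fvc_obs <- fvc * infl
  effort_maximal <- stats::runif(n) < config$frac_effort_maximal
  fvc_quality <- sample(names(config$quality_probs), n, TRUE,
                        config$quality_probs)

  cohort <- data.frame(
    id = id, g_rs9527 = g1, g_rs11191527 = g2, g_rs61735836 = g3,
    ancestry_group = ethnic_background, ethnic_background = ethnic_background,
    pcs, sampling_weight = sampling_weight, log_weight = log(sampling_weight),
    household_id = household_id, block_group_id = bg_of,
    sibling_of = sibling_of,
    smoking = smoking, cigarettes_lifetime = cigarettes_lifetime,
    smoking_answered = smoking_answered,
    grain_servings = grain_servings, high_rice_true = high_rice,
    pct_iAs = pct_iAs, pct_MMA = pct_MMA, pct_DMA = pct_DMA,
    asthma_ever = asthma_ever, asthma_doctor = asthma_doctor,
    asthma_still = asthma_still, asthma_med_use = asthma_med_use,
    fev1_ml = fev1_obs, fvc_ml = fvc_obs, pef_ml_s = pef,
    fvc_quality = fvc_quality, effort_maximal = effort_maximal,
    age_years = age_years, height_cm = height_cm, sex = sex,
    stringsAsFactors = FALSE
  )

  truth <- list(
    config = unclass(config),
    realized = list(
      hap_ld = as.list(haplotype_ld(hap)),
      joint_coefficients = list(iAs = as.numeric(gam_i),
                                MMA = as.numeric(gam_m)),
      metabolite_intercepts = c(iAs = int_i, MMA = int_m),
      grain_cutoff_expected = stats::qgamma(1 - config$frac_high_rice,
                                            shape = config$grain_shape,
                                            scale = config$grain_scale),
      prevalence = list(lifetime_asthma = mean(lifetime),
                        current_asthma = mean(current),
                        fvc_lln = mean(d_fvc), pef_lln = mean(d_pef),
                        ratio_lln = mean(d_ratio)),
      n_households = length(hh_sizes),
      n_block_groups = max(bg_of)
    ),
    latent = list(fvc_lln = d_fvc, pef_lln = d_pef, ratio_lln = d_ratio,
                  lifetime_asthma = lifetime)
  )

  structure(list(cohort = cohort,
                 clusters = build_cluster_matrices(cohort),
                 truth = truth),
            class = "arsmr_sim")
}

#' Build cluster covariance kernels from a cohort table
#'
#' Returns sparse symmetric kernels with unit diagonal (GRM convention,
#' twice the kinship coefficient): the kinship kernel has 0.5 for declared
#' full-sibling pairs; household and block group are 0/1 same-label block
#' kernels.
#'
#' @param cohort Cohort data frame with `id`, `household_id`,
#'   `block_group_id`, `sibling_of` columns.
#' @return List of class `cluster_matrices` with sparse `kinship`,
#'   `household`, `block_group` matrices (n x n).
#' @export
build_cluster_matrices <- function(cohort) {
  n <- nrow(cohort)
  pair_id <- sibling_pair_ids(cohort)  # validates dangling references
  kin <- Matrix::Diagonal(n)
  if (any(pair_id > 0)) {
    ii <- which(pair_id > 0)
    jj <- match(cohort$sibling_of[ii], cohort$id)
    kin <- kin + Matrix::sparseMatrix(i = ii, j = jj, x = 0.5,
                                      dims = c(n, n))
  }
  block_kernel <- function(lab) {
    f <- as.integer(factor(lab))
    M <- Matrix::sparseMatrix(i = seq_len(n), j = f, x = 1)
    Matrix::tcrossprod(M)
  }
  structure(list(kinship = methods::as(kin, "CsparseMatrix"),
                 household = block_kernel(cohort$household_id),
                 block_group = block_kernel(cohort$block_group_id)),
            class = "cluster_matrices")
}
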