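# Helper: iid cohort with singleton clusters (every kernel diagonal, so
# the working covariance is proportional to I and GLS must equal OLS /
# plain GLM exactly, whatever the variance-component estimates).
iid_cohort <- function(n, seed, y_fun) {
  set.seed(seed)
  co <- data.frame(id = sprintf("I%05d", seq_len(n)),
                   household_id = seq_len(n),
                   block_group_id = seq_len(n),
                   sibling_of = NA_character_,
                   x1 = rnorm(n), x2 = rnorm(n),
                   g = rbinom(n, 2, 0.3))
  co$y <- y_fun(co)
  list(cohort = co, clusters = build_cluster_matrices(co))
}

test_that("gaussian path with diagonal kernels equals the OLS oracle", {
  d <- iid_cohort(800, 41, function(co) 1 + 0.5 * co$x1 - 0.2 * co$x2 +
                    0.3 * co$g + rnorm(800))
  null <- fit_null_model(d$cohort, "y", covariates = c("x1", "x2"),
                         clusters = d$clusters, family = "gaussian")
  res <- test_variant(null, d$cohort$g, "gv")
  ols <- lm(y ~ x1 + x2 + g, data = d$cohort)
  expect_equal(unname(null$beta), unname(coef(lm(y ~ x1 + x2,
                                                 data = d$cohort))),
               tolerance = 1e-6)
  expect_equal(res$beta_gy, unname(coef(ols)["g"]), tolerance = 1e-6)
  expect_true(null$converged)
})

test_that("binomial intercept-only fit recovers the logit prevalence", {
  d <- iid_cohort(3000, 42, function(co) rbinom(3000, 1, 0.2))
  null <- fit_null_model(d$cohort, "y", covariates = character(0),
                         clusters = d$clusters, family = "binomial")
  expect_equal(unname(null$beta[1]), qlogis(mean(d$cohort$y)),
               tolerance = 1e-4)
  # iid data: variance components near (possibly exactly at) zero
  expect_lt(max(null$sigma), 0.5)
})

test_that("constant trait and monomorphic dosage are degenerate", {
  d <- iid_cohort(100, 43, function(co) rep(0, 100))
  expect_error(fit_null_model(d$cohort, "y", covariates = "x1",
                              clusters = d$clusters),
               class = "arsmr_degenerate_error")
  d2 <- iid_cohort(100, 44, function(co) rnorm(100))
  null <- fit_null_model(d2$cohort, "y", covariates = "x1",
                         clusters = d2$clusters)
  expect_error(test_variant(null, rep(1, 100)),
               class = "arsmr_degenerate_error")
  expect_error(test_variant(null, d2$cohort$x1),
               class = "arsmr_collinearity_error")
})

test_that("generative effect is recovered with tight noise", {
  d <- iid_cohort(5000, 45, function(co) 0.5 * co$g + rnorm(5000, 0, 0.1))
  null <- fit_null_model(d$cohort, "y", covariates = c("x1", "x2"),
                         clusters = d$clusters, family = "gaussian")
  res <- test_variant(null, d$cohort$g)
  expect_lt(abs(res$beta_gy - 0.5), 3 * res$se_gy)
})

test_that("binary estimates live on the log-odds scale (duplication law)", {
  sim <- shared_sim("assoc", n_participants = 1500, seed = 46)
  ph <- phenotype_cohort(sim$cohort)
  one <- fit_null_model(ph, "fvc_lln", clusters = sim$clusters,
                        subset = ph$included_in_spirometry)
  r1 <- test_variant(one, ph$g_rs9527, "rs9527")

  dup <- rbind(ph, transform(ph, id = paste0(id, "b"),
                             household_id = household_id + 1e6,
                             block_group_id = block_group_id + 1e6,
                             sibling_of = ifelse(is.na(sibling_of), NA,
                                                 paste0(sibling_of, "b"))))
  cl2 <- build_cluster_matrices(dup)
  two <- fit_null_model(dup, "fvc_lln", clusters = cl2,
                        subset = dup$included_in_spirometry)
  r2 <- test_variant(two, dup$g_rs9527, "rs9527")
  expect_equal(r2$beta_gy, r1$beta_gy, tolerance = 0.02)
  expect_equal(r2$se_gy / r1$se_gy, 1 / sqrt(2), tolerance = 0.05)
})

test_that("type-I error of the variant test is nominal without clustering", {
  set.seed(47)
  n <- 300
  reject <- logical(500)
  for (r in seq_len(500)) {
    co <- data.frame(id = seq_len(n), household_id = seq_len(n),
                     block_group_id = rep(1:10, each = n / 10),
                     sibling_of = NA_character_,
                     x1 = rnorm(n), g = rbinom(n, 2, 0.3), y = rnorm(n))
    cl <- build_cluster_matrices(co)
    null <- fit_null_model(co, "y", covariates = "x1", clusters = cl,
                           family = "gaussian")
    reject[r] <- test_variant(null, co$g)$p < 0.05
  }
  # binomial 99% envelope around 0.05 for 500 draws
  expect_gt(mean(reject), 0.05 - 2.58 * sqrt(0.05 * 0.95 / 500))
  expect_lt(mean(reject), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 500))
})

test_that("CI coverage is nominal under modest clustering", {
  set.seed(48)
  n <- 400
  nb <- 20
  cover <- logical(500)
  for (r in seq_len(500)) {
    bg <- rep(seq_len(nb), each = n / nb)
    co <- data.frame(id = seq_len(n), household_id = seq_len(n),
                     block_group_id = bg, sibling_of = NA_character_,
                     x1 = rnorm(n), g = rbinom(n, 2, 0.3))
    co$y <- 0.3 * co$g + rnorm(nb, 0, 0.5)[bg] + rnorm(n)
    cl <- build_cluster_matrices(co)
    null <- fit_null_model(co, "y", covariates = "x1", clusters = cl,
                           family = "gaussian")
    res <- test_variant(null, co$g)
    cover[r] <- abs(res$beta_gy - 0.3) <= 1.96 * res$se_gy
  }
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("association_scan shape, error coding and determinism", {
  sim <- shared_sim("assoc", n_participants = 1500, seed = 46)
  ph <- phenotype_cohort(sim$cohort)
  ins <- arsmr_instruments()
  strata <- list(never = ph$smoking_class == "never",
                 ever = ph$smoking_class == "ever")
  tr <- c("lifetime_asthma", "fvc_lln")
  a1 <- association_scan(ph, sim$clusters, ins, traits = tr,
                         strata = strata)
  expect_equal(nrow(a1), 3 * 2 * 2)
  expect_setequal(unique(a1$trait), tr)

  # a stratum with no cases yields error-coded rows, not dropped rows
  ph0 <- ph
  ph0$lifetime_asthma[strata$never] <- FALSE
  a0 <- association_scan(ph0, sim$clusters, ins, traits = "lifetime_asthma",
                         strata = strata)
  bad <- a0[a0$stratum == "never", ]
  expect_equal(nrow(bad), 3)
  expect_true(all(bad$status == "arsmr_degenerate_error"))
  expect_true(all(is.na(bad$beta_gy)))

  a2 <- association_scan(ph, sim$clusters, ins, traits = tr,
                         strata = strata)
  expect_identical(a1, a2)
})
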