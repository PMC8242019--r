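test_that("psi matrix: closed forms and hand oracle", {
  expect_equal(psi_matrix(c(1, 1), c(1, 1), matrix(1, 2, 2)),
               matrix(1, 2, 2))
  bx <- c(2, -1, 0.5); se <- c(0.2, 0.4, 0.1)
  expect_equal(psi_matrix(bx, se, diag(3)), diag((bx / se)^2))

  # independent elementwise computation with the published %iAs betas
  bx1 <- tab1$beta_iAs
  rho <- diag(3); rho[1, 2] <- rho[2, 1] <- sqrt(0.28)
  psi <- psi_matrix(bx1, c(1, 1, 1), rho)
  oracle <- matrix(0, 3, 3)
  for (k in 1:3) for (l in 1:3) {
    oracle[k, l] <- bx1[k] * bx1[l] * rho[k, l]
  }
  expect_equal(psi, oracle)
  expect_error(psi_matrix(c(1, 2), c(1, 1, 1), diag(3)),
               class = "arsmr_validation_error")
  expect_error(psi_matrix(c(1, 2), c(1, 0), diag(2)),
               class = "arsmr_validation_error")
})

test_that("component selection: rank, orthogonality, sign convention", {
  psi1 <- tcrossprod(c(1, 2, 3))
  sel <- select_components(psi1, 0.99)
  expect_equal(sel$k, 1)

  bx <- c(2, -1, 0.5); se <- c(0.2, 0.4, 0.1)
  sel_full <- select_components(psi_matrix(bx, se, diag(3)), 1.0)
  expect_equal(sel_full$k, 3)
  expect_equal(crossprod(sel_full$W), diag(3), ignore_attr = TRUE)
  # deterministic sign: largest-magnitude entry positive
  expect_true(all(apply(sel_full$W, 2,
                        function(w) w[which.max(abs(w))] > 0)))
  expect_error(select_components(matrix(c(1, NA, NA, 1), 2)),
               class = "arsmr_validation_error")
})

test_that("duplicated variant collapses to one component (dedup oracle)", {
  bx <- c(1.5, 1.5); se <- c(0.2, 0.2)
  rho <- matrix(c(1, 1, 1, 1), 2)
  by <- c(0.3, 0.3)
  sel <- select_components(psi_matrix(bx, se, rho), 0.999)
  expect_equal(sel$k, 1)
  est <- pca_ivw(bx, by, se, rho, 0.999)
  dedup <- pca_ivw(bx[1], by[1], se[1], matrix(1), 1.0)
  expect_equal(est$theta, dedup$theta, tolerance = 1e-10)
  expect_equal(est$se_theta, dedup$se_theta, tolerance = 1e-10)
})

test_that("single instrument reduces to the Wald ratio", {
  est <- pca_ivw(2.71, 0.4, 0.15, matrix(1), 0.99)
  expect_equal(est$theta, 0.4 / 2.71, tolerance = 1e-12)
  expect_equal(est$se_theta, 0.15 / 2.71, tolerance = 1e-12)
  expect_equal(est$k_components, 1)
  oracle <- gls_ivw_oracle(2.71, 0.4, 0.15, matrix(1))
  expect_equal(est$theta, oracle$theta, tolerance = 1e-12)
})

test_that("independent instruments at full retention equal textbook IVW", {
  set.seed(51)
  for (i in 1:10) {
    J <- sample(2:5, 1)
    inst <- random_mr_instance(J)
    est <- pca_ivw(inst$beta_x, inst$beta_y, inst$se_y, diag(J), 1.0)
    ivw <- sum(inst$beta_x * inst$beta_y / inst$se_y^2) /
      sum(inst$beta_x^2 / inst$se_y^2)
    expect_equal(est$theta, ivw, tolerance = 1e-10)
    expect_equal(est$se_theta, sqrt(1 / sum(inst$beta_x^2 / inst$se_y^2)),
                 tolerance = 1e-10)
  }
})

test_that("perfect proportionality is recovered exactly", {
  set.seed(52)
  inst <- random_mr_instance(3)
  est <- pca_ivw(inst$beta_x, 0.2 * inst$beta_x, inst$se_y, inst$rho, 0.99)
  expect_equal(est$theta, 0.2, tolerance = 1e-10)
})

test_that("full-retention PCA-IVW equals the GLS oracle", {
  set.seed(53)
  for (i in 1:100) {
    inst <- random_mr_instance(sample(2:6, 1))
    est <- pca_ivw(inst$beta_x, inst$beta_y, inst$se_y, inst$rho, 1.0)
    orc <- gls_ivw_oracle(inst$beta_x, inst$beta_y, inst$se_y, inst$rho)
    expect_equal(est$theta, orc$theta, tolerance = 1e-8)
    expect_equal(est$se_theta, orc$se_theta, tolerance = 1e-8)
  }
})

test_that("harmonization invariance and scale equivariance", {
  set.seed(54)
  for (i in 1:20) {
    J <- 3
    inst <- random_mr_instance(J)
    base <- pca_ivw(inst$beta_x, inst$beta_y, inst$se_y, inst$rho, 1.0)
    # flip variant coding: signs of beta_x, beta_y and rho row/column
    for (j in 1:J) {
      s <- rep(1, J); s[j] <- -1
      flip <- pca_ivw(s * inst$beta_x, s * inst$beta_y, inst$se_y,
                      diag(s) %*% inst$rho %*% diag(s), 1.0)
      expect_equal(flip$theta, base$theta, tolerance = 1e-10)
      expect_equal(flip$se_theta, base$se_theta, tolerance = 1e-10)
    }
    cc <- runif(1, 0.5, 2) * sample(c(-1, 1), 1)
    scaled <- pca_ivw(cc * inst$beta_x, inst$beta_y, inst$se_y, inst$rho, 1.0)
    expect_equal(scaled$theta, base$theta / cc, tolerance = 1e-10)
  }
})

test_that("mr_table shape, CI bracketing and error propagation", {
  set.seed(55)
  ins <- arsmr_instruments()
  traits <- c("t1", "t2")
  strata <- c("s1", "s2")
  grid <- expand.grid(rsid = ins$rsid, trait = traits, stratum = strata,
                      stringsAsFactors = FALSE)
  grid$beta_gy <- rnorm(nrow(grid), 0, 0.1)
  grid$se_gy <- runif(nrow(grid), 0.05, 0.2)
  grid$n <- 1000L
  grid$p <- 0.5
  grid$status <- "ok"
  rho <- diag(3); rho[1, 2] <- rho[2, 1] <- 0.5
  dimnames(rho) <- list(ins$rsid, ins$rsid)

  mt <- mr_table(grid, ins, rho)
  expect_equal(nrow(mt), 3 * 2 * 2)
  ok <- mt[mt$status == "ok", ]
  expect_true(all(ok$ci_lo <= ok$or & ok$or <= ok$ci_hi))
  expect_true(all(ok$or > 0))
  expect_true(all(ok$k_components >= 1 & ok$k_components <= 3))

  grid2 <- grid
  grid2$status[grid2$trait == "t2" & grid2$stratum == "s1"] <-
    "arsmr_degenerate_error"
  grid2$beta_gy[grid2$status != "ok"] <- NA
  mt2 <- mr_table(grid2, ins, rho)
  bad <- mt2[mt2$trait == "t2" & mt2$stratum == "s1", ]
  expect_true(all(bad$status == "arsmr_degenerate_error"))
  expect_true(all(is.na(bad$theta)))
  expect_equal(sum(mt2$status == "ok"), 9)
})

test_that("sign coherence: %iAs and %DMA land on opposite sides of 1", {
  ins <- arsmr_instruments()
  theta_true <- log(1.4)
  beta_y <- theta_true * ins$beta_iAs
  rho <- diag(3); rho[1, 2] <- rho[2, 1] <- sqrt(0.28)
  e_ias <- pca_ivw(ins$beta_iAs, beta_y, rep(0.07, 3), rho)
  e_dma <- pca_ivw(ins$beta_DMA, beta_y, rep(0.07, 3), rho)
  expect_gt(e_ias$or_point, 1)
  expect_lt(e_dma$or_point, 1)
})
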