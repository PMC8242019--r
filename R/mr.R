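# Two-sample MR with correlated instruments: principal-components IVW.
#
# With J correlated variants, summary associations beta_x (variant ->
# metabolite, from the literature) and beta_y (variant -> trait, from the
# cohort) are combined through the eigenvectors of a weighted summary
# matrix Psi rather than the raw variants, which protects the type-I error
# against double-counting correlated signals.

#' Weighted summary matrix for PC-instrument construction
#'
#' `Psi[k, l] = beta_x[k] * beta_x[l] * rho[k, l] / (se_y[k] * se_y[l])`.
#' No normalization is applied.
#'
#' @param beta_x Variant-exposure effects (J-vector).
#' @param se_y Variant-outcome standard errors (J-vector, positive).
#' @param rho J x J signed LD correlation matrix.
#' @return Symmetric J x J matrix.
#' @export
psi_matrix <- function(beta_x, se_y, rho) {
  J <- length(beta_x)
  assert_that(length(se_y) == J && all(dim(rho) == c(J, J)),
              "beta_x, se_y and rho dimensions must agree")
  assert_that(all(se_y > 0), "se_y must be strictly positive")
  outer(beta_x, beta_x) * rho / outer(se_y, se_y)
}

#' Select principal components of the summary matrix
#'
#' Eigen-decomposes a symmetric Psi and retains the smallest number of
#' leading components whose cumulative eigenvalue share reaches
#' `variance_threshold`. Eigenvector signs follow a deterministic
#' convention (largest-magnitude element positive).
#'
#' @param psi Symmetric matrix from [psi_matrix()].
#' @param variance_threshold Fraction of summed eigenvalues to retain,
#'   default 0.99.
#' @return List with `W` (J x k eigenvector matrix), `k`, `eigenvalues`
#'   and `share` (cumulative eigenvalue shares).
#' @export
select_components <- function(psi, variance_threshold = 0.99) {
  assert_that(all(is.finite(psi)), "non-finite entries in psi")
  psi <- (psi + t(psi)) / 2
  eg <- eigen(psi, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  share <- cumsum(ev) / sum(ev)
  k <- which(share >= variance_threshold - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  W <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(W[, j]))
    if (W[i_max, j] < 0) W[, j] <- -W[, j]
  }
  list(W = W, k = k, eigenvalues = eg$values, share = share)
}

mr_wrap <- function(theta, se, k) {
  z <- theta / se
  list(theta = theta, se_theta = se, or_point = exp(theta),
       ci95 = c(exp(theta - 1.96 * se), exp(theta + 1.96 * se)),
       p = 2 * stats::pnorm(-abs(z)), k_components = k)
}

#' Principal-components IVW causal estimate
#'
#' Projects the summary statistics onto the retained components of
#' [psi_matrix()] and runs generalized inverse-variance weighting there:
#' with `bX = W' beta_x`, `bY = W' beta_y` and
#' `Omega = W' Sigma W` (`Sigma[k, l] = se_y[k] se_y[l] rho[k, l]`),
#' `theta = (bX' Omega^-1 bX)^-1 bX' Omega^-1 bY` with standard error
#' `sqrt((bX' Omega^-1 bX)^-1)`. Exposure-side uncertainty is ignored in
#' the point estimator (the standard two-sample NOME convention). With one
#' variant this reduces to the Wald ratio; with `rho = I` and full
#' retention, to textbook IVW.
#'
#' @param beta_x,se_y,rho As in [psi_matrix()].
#' @param beta_y Variant-outcome effects (log-odds per effect-allele copy
#'   for binary traits).
#' @param variance_threshold Passed to [select_components()].
#' @return List with `theta`, `se_theta`, `or_point`, `ci95`, `p`,
#'   `k_components`.
#' @export
pca_ivw <- function(beta_x, beta_y, se_y, rho, variance_threshold = 0.99) {
  J <- length(beta_x)
  assert_that(length(beta_y) == J, "beta_x and beta_y lengths must agree")
  psi <- psi_matrix(beta_x, se_y, rho)
  sel <- select_components(psi, variance_threshold)
  W <- sel$W
  Sigma <- outer(se_y, se_y) * rho
  bX <- as.numeric(crossprod(W, beta_x))
  bY <- as.numeric(crossprod(W, beta_y))
  Omega <- crossprod(W, Sigma %*% W)
  Oinv <- tryCatch(solve(Omega), error = function(e) {
    abort("projected covariance is singular; lower the variance threshold",
          "arsmr_numerical_error")
  })
  denom <- as.numeric(crossprod(bX, Oinv %*% bX))
  if (!is.finite(denom) || denom <= 0) {
    abort("projected covariance is singular; lower the variance threshold",
          "arsmr_numerical_error")
  }
  theta <- as.numeric(crossprod(bX, Oinv %*% bY)) / denom
  mr_wrap(theta, sqrt(1 / denom), sel$k)
}

#' Full-rank GLS IVW reference estimator
#'
#' `theta = (beta_x' Sigma^-1 beta_x)^-1 beta_x' Sigma^-1 beta_y` with
#' `Sigma[k, l] = se_y[k] se_y[l] rho[k, l]`. Serves as the independent
#' full-rank oracle for [pca_ivw()] (to which it is equivalent at
#' `variance_threshold = 1` on nonsingular inputs).
#'
#' @inheritParams pca_ivw
#' @return List with `theta`, `se_theta`, `or_point`, `ci95`, `p`,
#'   `k_components` (= J).
#' @export
gls_ivw_oracle <- function(beta_x, beta_y, se_y, rho) {
  Sigma <- outer(se_y, se_y) * rho
  Sinv <- tryCatch(solve(Sigma), error = function(e) {
    abort("singular outcome covariance", "arsmr_numerical_error")
  })
  denom <- as.numeric(crossprod(beta_x, Sinv %*% beta_x))
  theta <- as.numeric(crossprod(beta_x, Sinv %*% beta_y)) / denom
  mr_wrap(theta, sqrt(1 / denom), length(beta_x))
}

#' Assemble the MR estimate table
#'
#' One causal estimate per metabolite x trait x stratum, combining the
#' cohort association scan with the literature instrument weights through
#' [pca_ivw()]. Metabolites are analyzed one at a time (univariable MR per
#' metabolite). Cells with error-coded associations are error-coded, not
#' dropped.
#'
#' @param assoc Output of [association_scan()].
#' @param instruments Instrument set (defines variant order and weights).
#' @param rho LD matrix among the instrument variants, aligned to
#'   `instruments`.
#' @param variance_threshold PC retention threshold.
#' @return Data frame with columns `stratum`, `trait`, `metabolite`,
#'   `theta`, `se_theta`, `or`, `ci_lo`, `ci_hi`, `p`, `k_components`,
#'   `n`, `status`.
#' @export
mr_table <- function(assoc, instruments, rho, variance_threshold = 0.99) {
  cells <- unique(assoc[c("stratum", "trait")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- assoc[assoc$stratum == cells$stratum[i] &
                   assoc$trait == cells$trait[i], ]
    sub <- sub[match(instruments$rsid, sub$rsid), ]
    ok <- nrow(sub) == nrow(instruments) && all(sub$status == "ok") &&
      !anyNA(sub$beta_gy)
    for (m in METABOLITES) {
      if (ok) {
        est <- tryCatch(
          pca_ivw(instruments[[paste0("beta_", m)]], sub$beta_gy,
                  sub$se_gy, rho, variance_threshold),
          arsmr_error = function(e) e)
      } else {
        bad <- sub$status[!is.na(sub$status) & sub$status != "ok"]
        cls <- if (length(bad) > 0) bad[1] else "arsmr_incomplete_error"
        est <- structure(class = c(cls, "condition"),
                         list(message = "association cell failed"))
      }
      row <- if (inherits(est, "condition")) {
        data.frame(stratum = cells$stratum[i], trait = cells$trait[i],
                   metabolite = paste0("%", m), theta = NA_real_,
                   se_theta = NA_real_, or = NA_real_, ci_lo = NA_real_,
                   ci_hi = NA_real_, p = NA_real_, k_components = NA_integer_,
                   n = max(sub$n, 0), status = class(est)[1],
                   stringsAsFactors = FALSE)
      } else {
        data.frame(stratum = cells$stratum[i], trait = cells$trait[i],
                   metabolite = paste0("%", m), theta = est$theta,
                   se_theta = est$se_theta, or = est$or_point,
                   ci_lo = est$ci95[1], ci_hi = est$ci95[2], p = est$p,
                   k_components = est$k_components, n = max(sub$n, 0),
                   status = "ok", stringsAsFactors = FALSE)
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}
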