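# Mixed-model association of instrument dosages with pulmonary traits.
#
# The three random-effect kernels (kinship, household, block group) are all
# block-diagonal with respect to block group (households nest in block
# groups and declared siblings share a household), so every GLS/REML
# quantity is accumulated block by block: the working covariance of a block
# is V_b = s_kin K_b + s_hh H_b + s_bg J_b + phi diag(1/w_b).

VC_NAMES <- c("kinship", "household", "block_group")

default_covariates <- function() {
  c(paste0("pc", 1:5), "ancestry_group", "log_weight")
}

# Static per-block structures reused across REML evaluations. Distinct
# block groups share no kernel entries, so consecutive small groups are
# coalesced into superblocks (~64 rows) purely for loop efficiency; the
# per-superblock kernels stay exact (zeros across merged groups).
make_blocks <- function(cohort, clusters, rows, target = 64L) {
  bg <- cohort$block_group_id[rows]
  idx_by_block <- split(seq_along(rows), bg)
  sizes <- lengths(idx_by_block)
  super <- cumsum(sizes) %/% max(target, 1L)
  merged <- lapply(split(idx_by_block, super), function(l) {
    unlist(l, use.names = FALSE)
  })
  lapply(merged, function(loc) {
    gl <- rows[loc]
    list(loc = loc,
         K = lapply(clusters[VC_NAMES], function(M) {
           as.matrix(M[gl, gl, drop = FALSE])
         }))
  })
}

# One GLS/REML pass. X: design; z: working response; w: working weights
# (residual diag = phi / w). Returns the REML negative log-likelihood (up
# to constants), its gradient, GLS fixed effects and residual projections.
gls_pass <- function(blocks, X, z, w, sig, phi, need_grad = FALSE,
                     grad_phi = FALSE) {
  p <- ncol(X)
  XtViX <- matrix(0, p, p); XtViz <- numeric(p)
  ztViz <- 0; logdet <- 0
  trVi <- stats::setNames(numeric(3), VC_NAMES); trVi_phi <- 0
  Mc <- stats::setNames(rep(list(matrix(0, p, p)), 3), VC_NAMES)
  Mphi <- matrix(0, p, p)
  keep <- vector("list", length(blocks))

  for (b in seq_along(blocks)) {
    d <- blocks[[b]]
    loc <- d$loc
    rw <- phi / w[loc]
    V <- sig[1] * d$K$kinship + sig[2] * d$K$household +
      sig[3] * d$K$block_group
    diag(V) <- diag(V) + rw
    R <- tryCatch(chol(V), error = function(e) {
      abort("working covariance not positive definite", "arsmr_numerical_error")
    })
    Xb <- X[loc, , drop = FALSE]; zb <- z[loc]
    U <- backsolve(R, cbind(Xb, zb), transpose = TRUE)
    Ux <- U[, seq_len(p), drop = FALSE]; Uz <- U[, p + 1L]
    logdet <- logdet + 2 * sum(log(diag(R)))
    XtViX <- XtViX + crossprod(Ux)
    XtViz <- XtViz + as.numeric(crossprod(Ux, Uz))
    ztViz <- ztViz + sum(Uz^2)
    if (need_grad) {
      ViX <- backsolve(R, Ux)
      Viz <- backsolve(R, Uz)
      Vi <- chol2inv(R)
      for (cn in VC_NAMES) {
        Kc <- d$K[[cn]]
        trVi[cn] <- trVi[cn] + sum(Vi * Kc)
        Mc[[cn]] <- Mc[[cn]] + crossprod(ViX, Kc %*% ViX)
      }
      if (grad_phi) {
        rb <- rw / phi   # = 1/w
        trVi_phi <- trVi_phi + sum(diag(Vi) * rb)
        Mphi <- Mphi + crossprod(ViX, rb * ViX)
      }
      keep[[b]] <- list(ViX = ViX, Viz = Viz)
    } else {
      keep[[b]] <- list(R = R, Xb = Xb)
    }
  }

  XtViX_inv <- tryCatch(solve(XtViX), error = function(e) {
    abort("rank-deficient fixed-effect design", "arsmr_collinearity_error")
  })
  alpha <- as.numeric(XtViX_inv %*% XtViz)
  ztPz <- ztViz - sum(XtViz * alpha)
  nll <- 0.5 * (logdet +
                  as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
                  ztPz)
  out <- list(nll = nll, beta = alpha, XtViX_inv = XtViX_inv,
              logdet = logdet)
  if (need_grad) {
    r <- numeric(length(z))       # P z
    for (b in seq_along(blocks)) {
      loc <- blocks[[b]]$loc
      r[loc] <- keep[[b]]$Viz - keep[[b]]$ViX %*% alpha
    }
    grad <- stats::setNames(numeric(3), VC_NAMES)
    for (cn in VC_NAMES) {
      quad <- 0
      for (b in seq_along(blocks)) {
        loc <- blocks[[b]]$loc
        quad <- quad + sum(r[loc] * (blocks[[b]]$K[[cn]] %*% r[loc]))
      }
      trP <- trVi[cn] - sum(XtViX_inv * Mc[[cn]])
      grad[cn] <- 0.5 * (trP - quad)
    }
    if (grad_phi) {
      quad <- sum(r^2 / w)
      trP <- trVi_phi - sum(XtViX_inv * Mphi)
      grad <- c(grad, phi = 0.5 * (trP - quad))
    }
    out$grad <- grad
    out$Pz <- r
  }
  out
}

# REML estimation of the variance components by bounded quasi-Newton with
# analytic gradients; components are constrained nonnegative by boundary
# projection (L-BFGS-B lower bounds).
reml_fit <- function(blocks, X, z, w, family, sig_start = NULL,
                     phi_start = NULL, maxit = 100) {
  vz <- stats::var(z)
  if (family == "gaussian") {
    par0 <- c(sig_start %||% rep(0.05 * vz, 3), phi_start %||% (0.85 * vz))
    lower <- c(0, 0, 0, 1e-8 * vz)
    fn <- function(p) gls_pass(blocks, X, z, w, p[1:3], p[4])$nll
    gr <- function(p) gls_pass(blocks, X, z, w, p[1:3], p[4],
                               need_grad = TRUE, grad_phi = TRUE)$grad
  } else {
    par0 <- c(sig_start %||% rep(0.05, 3))
    lower <- c(0, 0, 0)
    fn <- function(p) gls_pass(blocks, X, z, w, p[1:3], 1)$nll
    gr <- function(p) gls_pass(blocks, X, z, w, p[1:3], 1,
                               need_grad = TRUE)$grad
  }
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B", lower = lower,
                      control = list(maxit = maxit, factr = 1e9))
  sig <- stats::setNames(opt$par[1:3], VC_NAMES)
  phi <- if (family == "gaussian") opt$par[4] else 1
  final <- gls_pass(blocks, X, z, w, sig, phi, need_grad = TRUE,
                    grad_phi = family == "gaussian")
  list(sigma = sig, phi = phi, beta = final$beta,
       XtViX_inv = final$XtViX_inv, Pz = final$Pz, nll = final$nll,
       converged = opt$convergence %in% c(0L, 1L),
       boundary = any(sig < 1e-6 * max(vz, 1)))
}

blup_from_Pz <- function(blocks, sig, Pz) {
  u <- numeric(length(Pz))
  for (b in seq_along(blocks)) {
    d <- blocks[[b]]; loc <- d$loc
    Vr <- sig[1] * d$K$kinship + sig[2] * d$K$household +
      sig[3] * d$K$block_group
    u[loc] <- Vr %*% Pz[loc]
  }
  u
}

build_design <- function(cohort, covariates, rows) {
  if (length(covariates) == 0) {
    return(matrix(1, length(rows), 1,
                  dimnames = list(NULL, "(Intercept)")))
  }
  df <- cohort[rows, covariates, drop = FALSE]
  mm <- stats::model.matrix(~ ., data = df)
  # drop aliased columns (e.g. an ancestry level absent from a stratum)
  qr_x <- qr(mm)
  if (qr_x$rank < ncol(mm)) {
    mm <- mm[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }
  mm
}

#' Fit the null (no-variant) mixed model for one trait
#'
#' Gaussian traits: REML estimation of the kinship, household and
#' block-group variance components plus a residual. Binary traits:
#' penalized quasi-likelihood — iterate a working linearized response with
#' the same three covariance kernels and unit dispersion, updating
#' BLUP-adjusted linear predictors until the fixed effects stabilize.
#' Fixed effects are the intercept, the top five principal components,
#' ancestry-group indicators and the log sampling weight (sampling weights
#' enter only as this fixed-effect covariate, never as analytic weights).
#'
#' @param cohort Cohort data frame (already restricted to the analysis
#'   arm; rows with missing trait or covariates are dropped here).
#' @param trait Column name of the outcome.
#' @param covariates Character vector of covariate columns.
#' @param clusters [build_cluster_matrices()] output aligned to `cohort`
#'   rows.
#' @param family `"binomial"` or `"gaussian"` (guessed from the column
#'   type when `NULL`).
#' @param subset Optional logical/integer row filter.
#' @param sig_start Optional warm-start variance components.
#' @param pql_maxit,pql_tol PQL outer-loop controls.
#' @return Object of class `arsmr_null` holding estimates, the working
#'   covariance (variance components + weights) and convergence
#'   diagnostics.
#' @export
fit_null_model <- function(cohort, trait, covariates = default_covariates(),
                           clusters, family = NULL, subset = NULL,
                           sig_start = NULL, pql_maxit = 30,
                           pql_tol = 1e-4) {
  y_all <- cohort[[trait]]
  assert_that(!is.null(y_all), sprintf("no trait column '%s'", trait))
  rows <- seq_len(nrow(cohort))
  if (!is.null(subset)) rows <- rows[subset[rows]]
  cc <- stats::complete.cases(cohort[rows, c(trait, covariates)])
  rows <- rows[cc]
  y <- y_all[rows]
  if (is.logical(y)) y <- as.numeric(y)
  if (is.null(family)) {
    family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  }
  if (stats::var(y) == 0 || length(y) < 10) {
    abort(sprintf("trait '%s' is constant or near-empty in this stratum",
                  trait), "arsmr_degenerate_error")
  }
  X <- build_design(cohort, covariates, rows)
  blocks <- make_blocks(cohort, clusters, rows)
  n <- length(y)

  if (family == "gaussian") {
    w <- rep(1, n)
    fit <- reml_fit(blocks, X, y, w, "gaussian", sig_start = sig_start)
    eta <- as.numeric(X %*% fit$beta)
    out <- list(z = y, w = w, eta = eta, pql_iter = 0L)
  } else {
    # plain GLM start values only; separation warnings here are harmless
    b0 <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial())$coefficients)
    b0[is.na(b0)] <- 0
    eta <- as.numeric(X %*% b0)
    sig <- sig_start %||% c(0.05, 0.05, 0.05)
    fit <- NULL
    for (it in seq_len(pql_maxit)) {
      mu <- expit(eta)
      w <- pmax(mu * (1 - mu), 1e-6)
      z <- eta + (y - mu) / w
      fit <- reml_fit(blocks, X, z, w, "binomial", sig_start = sig)
      sig <- fit$sigma
      u <- blup_from_Pz(blocks, sig, fit$Pz)
      eta_new <- as.numeric(X %*% fit$beta) + u
      delta <- max(abs(eta_new - eta)) / (1 + max(abs(eta)))
      # damp late iterations to break small limit cycles of the working
      # response around the optimum
      eta <- if (it > 8) (eta + eta_new) / 2 else eta_new
      if (delta < pql_tol) break
    }
    if (delta >= pql_tol * 100) {
      abort(sprintf("PQL did not converge for '%s' (last relative change %.2g after %d iterations)",
                    trait, delta, it), "arsmr_convergence_error")
    }
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    out <- list(z = eta + (y - mu) / w, w = w, eta = eta, pql_iter = it)
  }

  structure(c(list(trait = trait, family = family, rows = rows, X = X,
                   y = y, blocks = blocks, beta = fit$beta,
                   sigma = fit$sigma, phi = fit$phi,
                   XtViX_inv = fit$XtViX_inv, converged = fit$converged,
                   boundary = fit$boundary, n = n), out),
            class = "arsmr_null")
}

#' Wald test of a variant against a fitted null model
#'
#' Adds the dosage to the fixed-effect design and refits by generalized
#' least squares with the null model's variance components held fixed
#' (binary traits re-iterate the PQL working response with the variant in
#' the design, so large per-allele effects are not attenuated by the
#' null-model linearization). The estimate is per effect-allele copy on
#' the log-odds (binary) or trait-unit (gaussian) scale.
#'
#' @param null An `arsmr_null` fit.
#' @param dosages Dosage vector aligned to the rows of the cohort the null
#'   model was fitted on (it is subset by the null model's analysis rows).
#' @param rsid Variant label carried into the result.
#' @return One-row data frame: `rsid`, `trait`, `beta_gy`, `se_gy`, `n`,
#'   `p`, `status`.
#' @export
test_variant <- function(null, dosages, rsid = NA_character_) {
  stopifnot(inherits(null, "arsmr_null"))
  g <- dosages[null$rows]
  if (anyNA(g)) abort("missing dosages in analysis rows", "arsmr_validation_error")
  if (stats::var(g) == 0) {
    abort("monomorphic dosage", "arsmr_degenerate_error")
  }
  C <- cbind(null$X, dosage = g)
  p <- ncol(C)

  if (null$family == "gaussian") {
    fit <- gls_pass(null$blocks, C, null$z, null$w, null$sigma, null$phi)
    check_collinear(fit$XtViX_inv, p)
    gamma <- fit$beta[p]; se <- sqrt(fit$XtViX_inv[p, p])
  } else {
    eta <- null$eta
    gamma <- 0
    for (it in 1:15) {
      mu <- expit(eta)
      w <- pmax(mu * (1 - mu), 1e-6)
      z <- eta + (null$y - mu) / w
      fit <- gls_pass(null$blocks, C, z, w, null$sigma, 1,
                      need_grad = TRUE)
      check_collinear(fit$XtViX_inv, p)
      u <- blup_from_Pz(null$blocks, null$sigma, fit$Pz)
      eta <- as.numeric(C %*% fit$beta) + u
      if (abs(fit$beta[p] - gamma) < 1e-5 * (1 + abs(gamma))) {
        gamma <- fit$beta[p]; break
      }
      gamma <- fit$beta[p]
    }
    se <- sqrt(fit$XtViX_inv[p, p])
  }
  data.frame(rsid = rsid, trait = null$trait, beta_gy = unname(gamma),
             se_gy = unname(se), n = null$n,
             p = 2 * stats::pnorm(-abs(gamma / se)),
             status = "ok", stringsAsFactors = FALSE)
}

check_collinear <- function(XtViX_inv, p) {
  if (!all(is.finite(XtViX_inv)) || XtViX_inv[p, p] <= 0 ||
      XtViX_inv[p, p] > 1e8) {
    abort("dosage is collinear with the covariates",
          "arsmr_collinearity_error")
  }
}

#' Scan all instrument variants against all traits within strata
#'
#' One row per variant x trait x stratum. Cells whose fit fails carry the
#' error class in `status` (with NA estimates) rather than being dropped.
#'
#' @param cohort Phenotyped cohort data frame with `g_<rsid>` dosage
#'   columns.
#' @param clusters Cluster matrices aligned to `cohort`.
#' @param instruments Instrument set defining the variants and their
#'   order.
#' @param traits Character vector of trait columns.
#' @param strata Named list of logical row masks (default a single
#'   all-rows stratum).
#' @param covariates Covariate columns.
#' @param arm_filter Optional named list of additional logical masks per
#'   trait (e.g. spirometry inclusion for LLN traits).
#' @return Data frame with columns `rsid`, `trait`, `stratum`, `beta_gy`,
#'   `se_gy`, `n`, `p`, `status`.
#' @export
association_scan <- function(cohort, clusters, instruments,
                             traits = DEFAULT_TRAITS,
                             strata = list(all = rep(TRUE, nrow(cohort))),
                             covariates = default_covariates(),
                             arm_filter = NULL) {
  res <- list()
  for (sname in names(strata)) {
    for (trait in traits) {
      mask <- strata[[sname]]
      if (!is.null(arm_filter[[trait]])) mask <- mask & arm_filter[[trait]]
      null <- tryCatch(
        fit_null_model(cohort, trait, covariates, clusters, subset = mask),
        arsmr_error = function(e) e
      )
      for (rs in instruments$rsid) {
        g <- cohort[[paste0("g_", rs)]]
        row <- if (inherits(null, "condition")) {
          data.frame(rsid = rs, trait = trait, beta_gy = NA_real_,
                     se_gy = NA_real_, n = 0L, p = NA_real_,
                     status = class(null)[1], stringsAsFactors = FALSE)
        } else {
          tryCatch(test_variant(null, g, rsid = rs),
                   arsmr_error = function(e) {
                     data.frame(rsid = rs, trait = trait, beta_gy = NA_real_,
                                se_gy = NA_real_, n = null$n, p = NA_real_,
                                status = class(e)[1], stringsAsFactors = FALSE)
                   })
        }
        row$stratum <- sname
        res[[length(res) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, res)
  out[c("rsid", "trait", "stratum", "beta_gy", "se_gy", "n", "p", "status")]
}
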