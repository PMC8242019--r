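# Shared fixtures built in code; nothing is read from disk except the
# package's bundled instrument table.

tab1 <- list(
  rsid = c("rs9527", "rs11191527", "rs61735836"),
  beta_iAs = c(1.81, 1.32, 2.71),
  se_iAs = c(0.37, 0.27, 0.37),
  beta_MMA = c(2.01, 0.98, 2.42),
  se_MMA = c(0.28, 0.20, 0.29),
  beta_DMA = c(-3.82, -2.30, -5.09),
  se_DMA = c(0.48, 0.35, 0.51)
)

write_instrument_file <- function(tab = NULL) {
  if (is.null(tab)) {
    tab <- as.data.frame(arsmr_instruments())
  }
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A tiny hand-built cohort for cluster-matrix unit tests.
toy_cohort <- function() {
  data.frame(
    id = paste0("P", 1:6),
    household_id = c(1, 1, 1, 2, 3, 4),
    block_group_id = c(1, 1, 1, 1, 2, 2),
    sibling_of = c("P2", "P1", NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

# Memoized small simulations reused across test files.
.sim_cache <- new.env(parent = emptyenv())
shared_sim <- function(key = "default", ...) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_cohort(sim_config(...))
  }
  .sim_cache[[key]]
}

# Random nonsingular MR summary-statistic instance for oracle equivalence.
random_mr_instance <- function(J) {
  beta_x <- runif(J, 0.5, 3) * sample(c(-1, 1), J, TRUE)
  se_y <- runif(J, 0.05, 0.5)
  A <- matrix(rnorm(J * (J + 2)), J + 2, J)
  rho <- cov2cor(crossprod(A) + diag(J) * 0.1)
  list(beta_x = beta_x, beta_y = rnorm(J, 0, 0.3), se_y = se_y, rho = rho)
}

dosage_matrix <- function(cohort, instruments = arsmr_instruments()) {
  as.matrix(cohort[paste0("g_", instruments$rsid)])
}
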