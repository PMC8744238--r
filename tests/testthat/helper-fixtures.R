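# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

default_grid <- age_grid()

lt_cols <- function(grid = default_grid) {
  c("stratum", "year", "cause", paste0("q_", gsub("-", "_", grid$label)), "q5")
}

# A set where every age column equals q5: the identity schedule, an exact
# (a=0, b=1, c=0) fit with zero residuals.
make_identity_set <- function(q5 = seq(0.005, 0.05, length.out = 10),
                              cause = "all", grid = default_grid) {
  n <- length(q5)
  df <- tibble::tibble(stratum = paste0("s", seq_len(n)), year = 2000L,
                       cause = cause)
  for (lab in grid$label) df[[paste0("q_", gsub("-", "_", lab))]] <- q5
  df$q5 <- q5
  lifetable_set(df, grid)
}

# Records generated exactly on ln q_x = a_x + b_x ln q5 (+ c_x (ln q5)^2)
# + v_x * k_i, optionally with N(0, noise_sd) log-scale noise.
make_model_set <- function(q5, a, b, c = rep(0, length(a)),
                           v = rep(0, length(a)), k = rep(0, length(q5)),
                           noise_sd = 0, grid = default_grid,
                           cause = "all", strata = NULL) {
  n <- length(q5)
  L <- log(q5)
  lnq <- outer(rep(1, n), a) + outer(L, b) + outer(L^2, c) + outer(k, v)
  if (noise_sd > 0) lnq <- lnq + matrix(rnorm(n * length(a), 0, noise_sd), n)
  qm <- exp(lnq)
  df <- tibble::tibble(
    stratum = if (is.null(strata)) paste0("s", seq_len(n)) else strata,
    year = if (is.null(strata)) 2000L
           else as.integer(stats::ave(seq_len(n), strata, FUN = seq_along)) + 2000L,
    cause = cause)
  for (j in seq_along(grid$label)) {
    df[[paste0("q_", gsub("-", "_", grid$label[j]))]] <- qm[, j]
  }
  df$q5 <- qm[, ncol(qm)]
  lifetable_set(df, grid)
}

# Coefficients making the terminal age the identity (a=0,b=1,c=0) so that
# generated q5 equals the terminal column; younger ages a plausible gradient.
true_coefs <- function() {
  list(a = c(-1.2, -0.8, -0.5, -0.3, -0.15, 0),
       b = c(1.05, 1.03, 1.02, 1.01, 1.005, 1),
       c = c(0.015, 0.012, 0.008, 0.005, 0.002, 0))
}

# Unit-norm deviation vector with zero terminal entry and non-negative
# youngest entry (matching the fit's sign/norm convention).
true_v <- function() {
  v <- c(0.6, 0.5, 0.4, 0.3, 0.15, 0)
  v / sqrt(sum(v^2))
}

# Project k orthogonal to the OLS design columns {1, L, L^2} so the per-age
# regressions cannot absorb any of the v*k term and training_k is exactly
# recoverable.
orthogonalise_k <- function(k, L, degree = 2) {
  X <- if (degree == 2) cbind(1, L, L^2) else cbind(1, L)
  as.numeric(k - X %*% solve(crossprod(X), crossprod(X, k)))
}

# Brute-force normal-equation OLS oracle, independent of lm.fit's QR path.
ols_oracle <- function(X, y) as.numeric(solve(crossprod(X), crossprod(X, y)))

expect_monotone <- function(q) expect_true(all(diff(q) >= 0))
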