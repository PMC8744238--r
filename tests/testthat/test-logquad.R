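test_that("the identity schedule is fitted exactly with zero residual structure", {
  set <- make_identity_set()
  fit <- fit_logquad(set, cause = "all", degree = 2)
  expect_lt(max(abs(fit$coeffs$a)), 1e-10)
  expect_lt(max(abs(fit$coeffs$b - 1)), 1e-10)
  expect_lt(max(abs(fit$coeffs$c)), 1e-10)
  expect_equal(fit$coeffs$v, rep(0, 6))
  expect_equal(fit$coeffs$sigma, rep(0, 6))
  expect_equal(fit$training_k$k, rep(0, 10))

  # prediction from it is flat at q5, and calibration refuses (v = 0)
  sched <- predict_pattern(fit, q5 = 0.01, k = 0)
  expect_equal(sched$q, rep(0.01, 6), tolerance = 1e-12)
  expect_error(calibrate_k(fit, 0.01, "0-27d", 0.005),
               class = "logquad5_calibration_error")
})

test_that("OLS coefficients match the brute-force normal-equation oracle", {
  withr::local_seed(7)
  for (rep in 1:5) {
    n <- sample(5:10, 1)
    q5 <- exp(runif(n, log(0.003), log(0.06)))
    tc <- true_coefs()
    set <- make_model_set(q5, tc$a, tc$b, tc$c, noise_sd = 0.1)
    for (degree in c(2, 1)) {
      fit <- fit_logquad(set, degree = degree)
      L <- log(set$q5)
      X <- if (degree == 2) cbind(1, L, L^2) else cbind(1, L)
      qm <- logquad5:::lt_qmat(set)
      for (j in 1:6) {
        beta <- ols_oracle(X, log(qm[, j]))
        got <- unlist(fit$coeffs[j, c("a", "b", "c")])[seq_along(beta)]
        expect_lt(max(abs(got - beta)), 1e-8)
        if (degree == 1) expect_identical(fit$coeffs$c[j], 0)
      }
    }
  }
})

test_that("noise-free rank-1 construction recovers v and per-record k exactly", {
  withr::local_seed(11)
  q5 <- c(0.004, 0.008, 0.01, 0.02, 0.035)
  tc <- true_coefs()
  v <- true_v()
  k_raw <- c(-1, 0, 1, 2, -2)
  k <- orthogonalise_k(k_raw, log(q5), degree = 2)
  set <- make_model_set(q5, tc$a, tc$b, tc$c, v = v, k = k)
  fit <- fit_logquad(set, degree = 2)
  expect_lt(max(abs(fit$coeffs$v - v)), 1e-8)     # sign convention matches
  expect_lt(max(abs(sort(fit$training_k$k) - sort(k))), 1e-8)
  # sigma is zero after removing the rank-1 component
  expect_lt(max(fit$coeffs$sigma), 1e-8)

  # in-sample round trip: prediction at a training (q5, k) reproduces that
  # record (pick the record nearest the average pattern, where the generated
  # schedule is monotone and repair is a no-op)
  i <- which.min(abs(k))
  sched <- predict_pattern(fit, q5[i], k = fit$training_k$k[
    match(set$stratum[i], fit$training_k$stratum)])
  expect_lt(max(abs(sched$q - as.numeric(logquad5:::lt_qmat(set)[i, ]))), 1e-8)
})

test_that("v recovery improves as log-scale noise shrinks", {
  v <- true_v()
  tc <- true_coefs()
  angle <- function(a, b) acos(min(1, abs(sum(a * b)) /
                                     sqrt(sum(a^2) * sum(b^2))))
  angles <- sapply(c(0.2, 0.05, 0.01), function(s) {
    withr::local_seed(101)
    q5 <- exp(runif(40, log(0.003), log(0.06)))
    k <- rnorm(40)
    set <- make_model_set(q5, tc$a, tc$b, tc$c, v = v, k = k, noise_sd = s)
    fit <- fit_logquad(set)
    angle(fit$coeffs$v, v)
  })
  expect_true(all(diff(angles) < 0))
})

test_that("prediction is log-linear in k through the deviation vector", {
  synth <- make_mchss_like(seed = 2)
  fit <- fit_logquad(synth$set, cause = "all")
  q5 <- 0.015
  s0 <- exp(logquad5:::lnq_pattern(fit, q5, 0))
  s1 <- exp(logquad5:::lnq_pattern(fit, q5, 1))
  expect_equal(log(s1) - log(s0), fit$coeffs$v, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("calibration inverts prediction over a grid of shape values", {
  synth <- make_mchss_like(seed = 2)
  fit <- fit_logquad(synth$set, cause = "pneumonia")
  for (k_star in c(-2, -0.5, 0, 0.5, 2)) {
    for (q5 in c(0.001, 0.005, 0.02)) {
      q_anchor <- exp(logquad5:::lnq_pattern(fit, q5, k_star))[2]  # pre-repair
      expect_lt(abs(calibrate_k(fit, q5, "0-27d", q_anchor) - k_star), 1e-10)
    }
  }
  # anchoring at the k = 0 prediction returns exactly 0
  q_anchor0 <- exp(logquad5:::lnq_pattern(fit, 0.01, 0))[2]
  expect_equal(calibrate_k(fit, 0.01, "0-27d", q_anchor0), 0, tolerance = 1e-12)
  # zero observed anchor falls back to k = 0 with a warning
  expect_warning(k0 <- calibrate_k(fit, 0.01, "0-27d", 0), "k = 0")
  expect_identical(k0, 0)
})

test_that("anchored prediction reproduces the anchor to round-off pre-repair", {
  withr::local_seed(19)
  synth <- make_mchss_like(seed = 2)
  fit <- fit_logquad(synth$set, cause = "all")
  for (i in 1:25) {
    q5 <- exp(runif(1, log(0.002), log(0.08)))
    q_anchor <- q5 * runif(1, 0.2, 0.9)
    k <- calibrate_k(fit, q5, "0-27d", q_anchor)
    pred <- exp(logquad5:::lnq_pattern(fit, q5, k))[2]
    expect_lt(abs(pred - q_anchor) / q_anchor, 1e-12)
  }
})

test_that("monotone repair caps younger ages by older ones and is idempotent", {
  grid <- age_grid()
  mk <- function(q) logquad5:::new_age_schedule(grid, q, q5 = q[6], k = 0,
                                                cause = "all")
  # already monotone: unchanged, nothing repaired
  ok <- enforce_monotone(mk(c(0.001, 0.002, 0.004, 0.006, 0.008, 0.01)))
  expect_equal(attr(ok, "repaired"), character())

  # single violation: younger capped by older, only that label recorded
  one <- enforce_monotone(mk(c(0.001, 0.002, 0.004, 0.0080, 0.0079, 0.009)))
  expect_equal(one$q[4], 0.0079)
  expect_equal(attr(one, "repaired"), "0-11m")

  # strictly decreasing: everything collapses to the terminal value
  dec <- enforce_monotone(mk(c(0.06, 0.05, 0.04, 0.03, 0.02, 0.01)))
  expect_equal(dec$q, rep(0.01, 6))

  # cumulative-min oracle, idempotence, and never-increase
  withr::local_seed(5)
  for (i in 1:50) {
    q <- runif(6, 0, 0.05)
    fixed <- enforce_monotone(mk(q))
    expect_equal(fixed$q, rev(cummin(rev(q))))
    expect_monotone(fixed$q)
    expect_true(all(fixed$q <= q))
    expect_equal(enforce_monotone(fixed)$q, fixed$q)
  }
})

test_that("predicted schedules pin the terminal age to q5 exactly", {
  synth <- make_mchss_like(seed = 2)
  for (cause in c("all", "pneumonia", "injury")) {
    fit <- fit_logquad(synth$set, cause = cause)
    for (q5 in c(0.0007, 0.004, 0.03)) {
      sched <- predict_pattern(fit, q5, k = 0.7)
      expect_identical(sched$q[6], q5)
      expect_monotone(sched$q)
    }
  }
  expect_error(predict_pattern(fit, q5 = 0), "probability")
  expect_error(predict_pattern(fit, q5 = -0.1), "probability")
})

test_that("fit serialization round-trips exactly through JSON", {
  synth <- make_mchss_like(seed = 2)
  fit <- fit_logquad(synth$set, cause = "pneumonia")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_logquad_fit(fit, tmp)
  back <- read_logquad_fit(tmp)
  expect_identical(back$coeffs$a, fit$coeffs$a)
  expect_identical(back$coeffs$v, fit$coeffs$v)
  expect_identical(back$coeffs$sigma, fit$coeffs$sigma)
  expect_identical(back$training_k$k, fit$training_k$k)
  expect_identical(back$cause, fit$cause)
  expect_identical(back$degree, fit$degree)
  # a restored fit predicts identically
  expect_identical(predict_pattern(back, 0.004, 1.3)$q,
                   predict_pattern(fit, 0.004, 1.3)$q)
})

test_that("degenerate inputs raise the documented conditions", {
  set <- make_identity_set(q5 = c(0.01, 0.02, 0.03, 0.04))
  expect_error(fit_logquad(set, cause = "missing"), "missing")
  # too few distinct q5 values
  same <- make_identity_set(q5 = rep(0.01, 5))
  expect_error(fit_logquad(same), "distinct")
  # fewer than 2 complete-case records: SVD skipped with warning, v = 0
  # (one zero cell in 9 of 10 records, spread over ages so each per-age OLS
  # keeps enough nonzero records)
  df <- as.data.frame(make_identity_set())
  qcols <- setdiff(lt_cols(), c("stratum", "year", "cause", "q5"))
  for (i in 2:10) df[[qcols[((i - 2) %% 5) + 1]]][i] <- 0
  expect_warning(fit0 <- fit_logquad(lifetable_set(df)), "complete-case")
  expect_equal(fit0$coeffs$v, rep(0, 6))
})
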