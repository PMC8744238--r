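#' Configure a simulation study
#'
#' Defines the generating mechanism for the Monte Carlo validation: life
#' tables are drawn from the fitted model surface plus per-age Gaussian
#' noise on the log scale,
#' \deqn{\ln {}_xq_0 = a_x + b_x \ln q_5 + c_x (\ln q_5)^2 + v_x k + e_x,}
#' with \eqn{q_5 \sim U(q5\_range)}, \eqn{k} standard normal (or resampled
#' from the training shape parameters), and \eqn{e_x \sim N(0,
#' \sigma_x \cdot noise\_scale)} — `noise_scale = 1` reproduces the residual
#' error observed in the training data, 2 doubles it. Each replicate refits
#' the model on a fresh collection and predicts held-out hypothetical life
#' tables at low/moderate/high mortality and shape.
#'
#' @param base_fit A `logquad_fit` supplying the true coefficients, deviation
#'   vector and per-age error scales.
#' @param n_tables Life tables per simulated collection (default 120, the
#'   size of the empirical study population: 6 strata x 20 years).
#' @param q5_range Range of the uniform under-five mortality draw, as
#'   proportions (default 0.002--0.040, i.e. 2--40 deaths per 1000
#'   livebirths).
#' @param noise_scale Positive multiplier on `sigma` (1 or 2 in the study
#'   design).
#' @param k_distribution `"normal"` (standard normal), `"empirical"`
#'   (resample `base_fit$training_k`), or `"zero"` (degenerate at 0, for
#'   noise-free closure checks).
#' @param scenario_q5 Under-five levels of the hypothetical held-out life
#'   tables (default 0.001, 0.002, 0.003 — 1, 2, 3 per 1000).
#' @param scenario_k Shape values for the low/middle/high scenarios; default
#'   the 25th/50th/75th percentiles of the training shape parameters.
#' @param n_reps Number of Monte Carlo replicates.
#' @param seed Root seed; every replicate derives its own substream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(base_fit, n_tables = 120, q5_range = c(0.002, 0.040),
                       noise_scale = 1,
                       k_distribution = c("normal", "empirical", "zero"),
                       scenario_q5 = c(0.001, 0.002, 0.003),
                       scenario_k = NULL, n_reps = 1000, seed = 1) {
  k_distribution <- match.arg(k_distribution)
  stopifnot(inherits(base_fit, "logquad_fit"),
            length(q5_range) == 2, q5_range[1] > 0,
            q5_range[1] < q5_range[2], q5_range[2] <= 1,
            n_tables >= 10, n_reps >= 1, noise_scale > 0)
  if (is.null(scenario_k)) {
    if (nrow(base_fit$training_k) == 0) {
      stop("base_fit has no training_k; supply `scenario_k` explicitly",
           call. = FALSE)
    }
    scenario_k <- unname(stats::quantile(base_fit$training_k$k,
                                         c(0.25, 0.5, 0.75)))
  }
  if (k_distribution == "empirical" && nrow(base_fit$training_k) == 0) {
    stop("base_fit has no training_k for empirical k resampling", call. = FALSE)
  }
  out <- list(base_fit = base_fit, n_tables = as.integer(n_tables),
              q5_range = q5_range, noise_scale = noise_scale,
              k_distribution = k_distribution, scenario_q5 = scenario_q5,
              scenario_k = scenario_k, n_reps = as.integer(n_reps),
              seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

# Substream seed for replicate `rep_seed` under root seed `seed`:
# a fixed affine counter scheme folded into [0, 2^31 - 2]. Documented so any
# single replicate can be regenerated in isolation.
substream_seed <- function(seed, rep_seed) {
  as.integer((as.double(seed) * 69069 + as.double(rep_seed) * 1234567) %%
               2147483646) + 1L
}

#' Simulate one life-table collection
#'
#' Draws `n_tables` life tables from the configured mechanism. The terminal
#' age is pinned to the drawn `q5` and schedules are monotone-repaired, so
#' every generated collection is a valid [lifetable_set]. Deterministic
#' given `(cfg$seed, rep_seed)`.
#'
#' @param cfg A [sim_config()].
#' @param rep_seed Replicate counter (1-based).
#' @return A [lifetable_set]; the latent truth (per-record `k` and per-age
#'   noise draws) is attached as attribute `"truth"`.
#' @export
simulate_dataset <- function(cfg, rep_seed = 1) {
  fit <- cfg$base_fit
  grid <- fit$grid
  labels <- grid_labels(grid)
  sigma <- fit$coeffs$sigma
  if (all(sigma == 0) && cfg$noise_scale > 0) {
    warning("all per-age sigma are 0: simulated noise is degenerate",
            call. = FALSE)
  }
  set.seed(substream_seed(cfg$seed, rep_seed))
  n <- cfg$n_tables
  q5 <- stats::runif(n, cfg$q5_range[1], cfg$q5_range[2])
  k <- switch(cfg$k_distribution,
              normal = stats::rnorm(n),
              empirical = sample(fit$training_k$k, n, replace = TRUE),
              zero = rep(0, n))
  eps <- matrix(stats::rnorm(n * length(labels), 0,
                             rep(sigma * cfg$noise_scale, each = n)),
                nrow = n)
  L <- log(q5)
  lnq <- outer(rep(1, n), fit$coeffs$a) + outer(L, fit$coeffs$b) +
    outer(L^2, fit$coeffs$c) + outer(k, fit$coeffs$v) + eps
  qm <- exp(lnq)
  if (any(qm > 1)) {
    warning("simulated q > 1 clipped to 1", call. = FALSE)
    qm <- pmin(qm, 1)
  }
  qm[, length(labels)] <- q5
  # per-record downward cumulative-min repair
  qm <- t(apply(qm, 1, function(q) rev(cummin(rev(q)))))

  strata <- rep(c("east-urban", "east-rural", "mid-urban",
                  "mid-rural", "west-urban", "west-rural"), length.out = n)
  df <- tibble::tibble(stratum = strata,
                       year = stats::ave(seq_len(n), strata,
                                         FUN = seq_along) + 2000L,
                       cause = fit$cause)
  qdf <- tibble::as_tibble(as.data.frame(qm))
  names(qdf) <- q_col(labels)
  df <- dplyr::bind_cols(df, qdf)
  df$q5 <- q5
  out <- lifetable_set(df, grid)
  attr(out, "truth") <- list(k = k, eps = eps)
  out
}

#' Run the simulation study
#'
#' For each replicate: simulate a collection, refit the model, then for
#' every (scenario `q5`, scenario `k`) pair construct the true noise-free
#' schedule from the base fit, predict it with the refitted model both at
#' `k = 0` and with `k` anchored to the true neonatal value, and record
#' per-age absolute and relative errors. Per-replicate coefficient errors
#' (|a - a_true| etc. per age) and the angular error of the recovered
#' deviation vector are also kept.
#'
#' @param cfg A [sim_config()].
#' @param anchor_label Anchor age for the calibrated prediction (default
#'   `"0-27d"`).
#' @return A `sim_report`: list with `summary` (per scenario x age x method
#'   mean/SD of errors over replicates), `replicates` (per-replicate cell
#'   errors; `anchor_repaired` flags predictions whose anchor age was
#'   modified by monotone repair, the one case where the anchored
#'   prediction does not reproduce the anchor exactly), `param_errors`
#'   (per-replicate per-age coefficient errors and `v_angle`), `n_skipped`,
#'   and the config. Scenario `q5` values outside the training `q5_range`
#'   are flagged in `summary$extrapolated`.
#' @export
run_sim_study <- function(cfg, anchor_label = "0-27d") {
  stopifnot(inherits(cfg, "sim_config"))
  base <- cfg$base_fit
  labels <- grid_labels(base$grid)
  scenarios <- tidyr::expand_grid(q5 = cfg$scenario_q5, k = cfg$scenario_k)
  truth_scheds <- purrr::pmap(scenarios, function(q5, k) {
    predict_pattern(base, q5, k)
  })

  rep_rows <- list()
  par_rows <- list()
  n_skipped <- 0L
  for (r in seq_len(cfg$n_reps)) {
    ds <- withCallingHandlers(simulate_dataset(cfg, r),
                              warning = function(w) invokeRestart("muffleWarning"))
    fit_r <- tryCatch(fit_logquad(ds, cause = base$cause, degree = base$degree),
                      error = function(e) NULL)
    if (is.null(fit_r)) {
      n_skipped <- n_skipped + 1L
      next
    }
    v_true <- base$coeffs$v
    v_hat <- fit_r$coeffs$v
    cosang <- if (sum(v_true^2) > 0 && sum(v_hat^2) > 0) {
      min(1, abs(sum(v_true * v_hat)) /
            sqrt(sum(v_true^2) * sum(v_hat^2)))
    } else NA_real_
    par_rows[[length(par_rows) + 1L]] <- tibble::tibble(
      rep = r, label = labels,
      abs_err_a = abs(fit_r$coeffs$a - base$coeffs$a),
      abs_err_b = abs(fit_r$coeffs$b - base$coeffs$b),
      abs_err_c = abs(fit_r$coeffs$c - base$coeffs$c),
      v_angle = acos(cosang))
    for (sidx in seq_len(nrow(scenarios))) {
      truth <- truth_scheds[[sidx]]
      q5_s <- scenarios$q5[sidx]
      q_anchor <- truth$q[match(anchor_label, labels)]
      k_hat <- tryCatch(calibrate_k(fit_r, q5_s, anchor_label, q_anchor),
                        logquad5_calibration_error = function(e) 0,
                        warning = function(w) 0)
      for (m in list(list("logquad_anchored", k_hat),
                     list("logquad_k0", 0))) {
        pred <- predict_pattern(fit_r, q5_s, k = m[[2]])
        rep_rows[[length(rep_rows) + 1L]] <- tibble::tibble(
          rep = r, scenario_q5 = q5_s, scenario_k = scenarios$k[sidx],
          method = m[[1]], label = labels,
          abs_error = abs(pred$q - truth$q),
          rel_error = ifelse(truth$q > 0, abs(pred$q - truth$q) / truth$q,
                             NA_real_),
          anchor_repaired = anchor_label %in% attr(pred, "repaired"))
      }
    }
  }
  if (n_skipped > 0.05 * cfg$n_reps) {
    stop("more than 5% of replicates failed to fit (", n_skipped, " of ",
         cfg$n_reps, ")", call. = FALSE)
  }
  replicates <- dplyr::bind_rows(rep_rows)
  param_errors <- dplyr::bind_rows(par_rows)
  summary <- dplyr::summarise(
    dplyr::group_by(replicates, .data$scenario_q5, .data$scenario_k,
                    .data$method, .data$label),
    mean_abs_error = mean(.data$abs_error),
    sd_abs_error = stats::sd(.data$abs_error),
    mean_rel_error = mean(.data$rel_error, na.rm = TRUE),
    sd_rel_error = stats::sd(.data$rel_error, na.rm = TRUE),
    n_reps = dplyr::n(), .groups = "drop")
  summary$extrapolated <- summary$scenario_q5 < cfg$q5_range[1] |
    summary$scenario_q5 > cfg$q5_range[2]
  out <- list(summary = summary, replicates = replicates,
              param_errors = param_errors, n_skipped = n_skipped,
              config = cfg)
  class(out) <- "sim_report"
  out
}

#' @export
print.sim_report <- function(x, ...) {
  cat("<sim_report> ", x$config$n_reps, " replicates (", x$n_skipped,
      " skipped), noise scale ", x$config$noise_scale, "\n", sep = "")
  print(x$summary, n = 20)
  invisible(x)
}

#' @rdname run_sim_study
#' @param x A `sim_report`.
#' @param ... Unused.
#' @export
tidy.sim_report <- function(x, ...) x$summary

#' @rdname run_sim_study
#' @export
glance.sim_report <- function(x, ...) {
  tibble::tibble(n_reps = x$config$n_reps, n_skipped = x$n_skipped,
                 n_tables = x$config$n_tables,
                 noise_scale = x$config$noise_scale,
                 mean_abs_error = mean(x$summary$mean_abs_error))
}

#' Write simulation study outputs as tidy CSV
#'
#' Writes the per-scenario summary to `path` and, optionally, the
#' replicate-level errors to `replicates_path`. The configuration is echoed
#' as `#`-prefixed comment lines at the top of the summary file.
#'
#' @param report A `sim_report`.
#' @param path Summary output path.
#' @param replicates_path Optional replicate-level output path.
#' @return `path`, invisibly.
#' @export
write_sim_report <- function(report, path, replicates_path = NULL) {
  cfg <- report$config
  hdr <- c(
    paste0("# n_tables=", cfg$n_tables, " n_reps=", cfg$n_reps,
           " noise_scale=", cfg$noise_scale, " seed=", cfg$seed),
    paste0("# q5_range=", paste(cfg$q5_range, collapse = "-"),
           " k_distribution=", cfg$k_distribution),
    paste0("# scenario_q5=", paste(cfg$scenario_q5, collapse = ","),
           " scenario_k=", paste(signif(cfg$scenario_k, 6), collapse = ",")))
  writeLines(hdr, path)
  readr::write_csv(report$summary, path, append = TRUE, col_names = TRUE)
  if (!is.null(replicates_path)) {
    readr::write_csv(report$replicates, replicates_path)
  }
  invisible(path)
}
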