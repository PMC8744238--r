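#' Fit the log quadratic model for under-five age-specific mortality
#'
#' For each age cut point \eqn{x} of the grid, fits by ordinary least squares
#' \deqn{\ln {}_xq_0 = a_x + b_x \ln {}_5q_0 + c_x (\ln {}_5q_0)^2}
#' (natural logarithms; `degree = 1` drops the quadratic term) over the
#' records of one cause. The systematic deviation of individual life tables
#' from this average surface is captured by a rank-1 term \eqn{v_x k}: the
#' age deviation vector \eqn{v} is the first right singular vector of the
#' matrix of OLS residuals (records x ages), normalised to unit Euclidean
#' norm with a non-negative entry at the youngest included age, and each
#' training record's shape parameter \eqn{k} is the projection of its
#' residual vector onto \eqn{v}. `sigma` is the per-age standard deviation
#' of the residuals net of the \eqn{v k} component, the error scale used by
#' the simulation study.
#'
#' Zero cells (\eqn{q = 0}, a legal observation for rare causes) are
#' excluded from the per-age OLS since \eqn{\ln 0} is undefined; the
#' residual matrix for the SVD is assembled over complete-case records only
#' (all ages nonzero), unless a floor is supplied via `q_floor`.
#'
#' @param set A [lifetable_set].
#' @param cause Cause label to fit (`"all"` for all-cause).
#' @param degree 2 for the quadratic model, 1 for the log-linear variant.
#' @param q_floor Optional positive floor substituted for zero cells before
#'   taking logs (default `NULL`: exclusion, no imputation).
#' @return An object of class `logquad_fit`: a list with `grid`, `cause`,
#'   `degree`, `coeffs` (tibble: `label`, `a`, `b`, `c`, `v`, `sigma`,
#'   `n_fit`), `training_k` (tibble: `stratum`, `year`, `k`), and
#'   `n_complete` (records entering the SVD).
#' @examples
#' synth <- make_mchss_like(seed = 1)
#' fit <- fit_logquad(synth$set, cause = "pneumonia")
#' tidy(fit)
#' @export
fit_logquad <- function(set, cause = "all", degree = 2, q_floor = NULL) {
  grid <- lt_grid(set)
  labels <- grid_labels(grid)
  if (!degree %in% c(1, 2)) stop("`degree` must be 1 or 2", call. = FALSE)
  df <- set[set$cause == cause, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("no records for cause '", cause, "'", call. = FALSE)
  }
  qm <- lt_qmat(df, grid)
  if (!is.null(q_floor)) {
    stopifnot(is.numeric(q_floor), q_floor > 0)
    qm[qm == 0] <- q_floor
  }
  pos5 <- df$q5 > 0
  df <- df[pos5, , drop = FALSE]
  qm <- qm[pos5, , drop = FALSE]
  if (nrow(df) < 4 || length(unique(df$q5)) < 3) {
    stop("need >= 4 records with q5 > 0 and >= 3 distinct q5 values for cause '",
         cause, "'", call. = FALSE)
  }
  L <- log(df$q5)
  X <- if (degree == 2) cbind(1, L, L^2) else cbind(1, L)

  coef_mat <- matrix(0, nrow = length(labels), ncol = 3,
                     dimnames = list(labels, c("a", "b", "c")))
  n_fit <- integer(length(labels))
  fitted_ln <- matrix(NA_real_, nrow(df), length(labels))
  for (j in seq_along(labels)) {
    idx <- qm[, j] > 0
    n_fit[j] <- sum(idx)
    if (n_fit[j] < ncol(X)) {
      stop("too few nonzero records to fit age group '", labels[j], "' (",
           n_fit[j], ")", call. = FALSE)
    }
    fit_j <- stats::lm.fit(X[idx, , drop = FALSE], log(qm[idx, j]))
    if (fit_j$rank < ncol(X)) {
      stop("rank-deficient design for age group '", labels[j], "'",
           call. = FALSE)
    }
    coef_mat[j, seq_len(ncol(X))] <- fit_j$coefficients
    fitted_ln[, j] <- X %*% fit_j$coefficients
  }

  # residual matrix over complete-case records (all ages nonzero)
  complete <- rowSums(qm > 0) == length(labels)
  v <- rep(0, length(labels))
  sigma <- rep(0, length(labels))
  training_k <- tibble::tibble(stratum = character(), year = integer(),
                               k = double())
  n_complete <- sum(complete)
  if (n_complete < 2) {
    warning("fewer than 2 complete-case records: SVD skipped, v set to 0",
            call. = FALSE)
  } else {
    R <- log(qm[complete, , drop = FALSE]) - fitted_ln[complete, , drop = FALSE]
    if (max(abs(R)) < 1e-12) {
      # degenerate: residual matrix numerically zero
      training_k <- tibble::tibble(stratum = df$stratum[complete],
                                   year = df$year[complete],
                                   k = rep(0, n_complete))
    } else {
      sv <- svd(R)
      v <- sv$v[, 1]
      # sign convention: non-negative at the youngest included age
      first_inc <- which(v != 0)[1]
      if (!is.na(first_inc) && v[first_inc] < 0) v <- -v
      k_vec <- as.numeric(R %*% v)
      sigma <- apply(R - outer(k_vec, v), 2, stats::sd)
      training_k <- tibble::tibble(stratum = df$stratum[complete],
                                   year = df$year[complete], k = k_vec)
    }
  }

  out <- list(
    grid = grid, cause = cause, degree = as.integer(degree),
    coeffs = tibble::tibble(label = labels,
                            a = unname(coef_mat[, "a"]),
                            b = unname(coef_mat[, "b"]),
                            c = unname(coef_mat[, "c"]),
                            v = unname(v), sigma = unname(sigma),
                            n_fit = n_fit),
    training_k = training_k,
    n_records = nrow(df), n_complete = n_complete
  )
  class(out) <- "logquad_fit"
  out
}

#' @export
print.logquad_fit <- function(x, ...) {
  cat("<logquad_fit> cause '", x$cause, "', degree ", x$degree, ", ",
      x$n_records, " records (", x$n_complete, " complete-case)\n", sep = "")
  print(x$coeffs)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_logquad
#' @param x A `logquad_fit`.
#' @param ... Unused.
#' @export
tidy.logquad_fit <- function(x, ...) {
  tidyr::pivot_longer(x$coeffs, c("a", "b", "c", "v", "sigma"),
                      names_to = "term", values_to = "estimate")
}

#' @rdname fit_logquad
#' @export
glance.logquad_fit <- function(x, ...) {
  tibble::tibble(cause = x$cause, degree = x$degree,
                 n_records = x$n_records, n_complete = x$n_complete,
                 k_sd = if (nrow(x$training_k)) stats::sd(x$training_k$k) else NA_real_)
}

# internal: pre-repair log-scale prediction at every grid label
lnq_pattern <- function(fit, q5, k) {
  L <- log(q5)
  with(fit$coeffs, a + b * L + c * L^2 + v * k)
}

#' Predict an age schedule at a given mortality level and shape
#'
#' Evaluates the fitted model at under-five mortality `q5` and shape
#' parameter `k` (`k = 0` gives the average age pattern), then pins the
#' terminal cut point to `q5` exactly — `q5` is the model's own conditioning
#' variable — and repairs any monotonicity violations with
#' [enforce_monotone()].
#'
#' @param fit A `logquad_fit`.
#' @param q5 Under-five cumulative probability of dying, in (0, 1].
#' @param k Shape parameter (default 0).
#' @return An `age_schedule`: a tibble with columns `label`, `days`, `q`, and
#'   attributes `q5`, `k`, `cause`, `repaired` (labels modified by repair).
#' @examples
#' synth <- make_mchss_like(seed = 1)
#' fit <- fit_logquad(synth$set, cause = "all")
#' predict_pattern(fit, q5 = 0.01, k = 0)
#' @export
predict_pattern <- function(fit, q5, k = 0) {
  if (!is.numeric(q5) || length(q5) != 1 || q5 <= 0 || q5 > 1) {
    stop("`q5` must be a single probability in (0, 1]", call. = FALSE)
  }
  q <- exp(lnq_pattern(fit, q5, k))
  if (any(q > 1)) {
    warning("predicted q > 1 clipped to 1 (extrapolation far outside the ",
            "fitted range)", call. = FALSE)
    q <- pmin(q, 1)
  }
  q[length(q)] <- q5
  sched <- new_age_schedule(fit$grid, q, q5 = q5, k = k, cause = fit$cause)
  enforce_monotone(sched)
}

new_age_schedule <- function(grid, q, q5, k, cause, repaired = character()) {
  out <- tibble::tibble(label = grid_labels(grid), days = grid$days, q = q)
  attr(out, "grid") <- grid
  attr(out, "q5") <- q5
  attr(out, "k") <- k
  attr(out, "cause") <- cause
  attr(out, "repaired") <- repaired
  class(out) <- c("age_schedule", class(out))
  out
}

#' @export
print.age_schedule <- function(x, ...) {
  cat("<age_schedule> cause '", attr(x, "cause") %||% "?", "', q5 = ",
      format(attr(x, "q5")), ", k = ", format(attr(x, "k")), "\n", sep = "")
  if (length(attr(x, "repaired"))) {
    cat("repaired: ", paste(attr(x, "repaired"), collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}

#' Repair monotonicity violations in an age schedule
#'
#' Cumulative probabilities of dying cannot decrease with age, but
#' log-scale predictions occasionally do when adjacent true probabilities
#' are very close (mortality between the two cut points at or near zero).
#' Working from the oldest cut point down, each younger value is capped by
#' the older one: `q[younger] <- min(q[younger], q[older])`. Ties are
#' permitted; the terminal value is never modified. Idempotent, and never
#' increases any entry.
#'
#' @param schedule An `age_schedule`.
#' @return The repaired `age_schedule`; the `repaired` attribute accumulates
#'   the labels that were modified.
#' @export
enforce_monotone <- function(schedule) {
  q <- schedule$q
  fixed <- rev(cummin(rev(q)))
  changed <- schedule$label[fixed != q]
  schedule$q <- fixed
  attr(schedule, "repaired") <- union(attr(schedule, "repaired"), changed)
  schedule
}

#' Calibrate the shape parameter to an anchor age group
#'
#' Solves the model exactly for `k` so that the predicted cumulative
#' probability at `anchor_label` (by default the neonatal group, 0--27 days)
#' matches an observed value: \eqn{k = (\ln q_{anchor} - a - b\ln q_5 -
#' c(\ln q_5)^2) / v} evaluated at the anchor. This is how a fitted model is
#' tailored to a specific life table whose neonatal mortality is known.
#'
#' @param fit A `logquad_fit`.
#' @param q5 Under-five probability of the target life table.
#' @param anchor_label Grid label to anchor on (default `"0-27d"`).
#' @param q_anchor Observed cumulative probability at the anchor. A
#'   non-positive value (zero observed neonatal deaths) falls back to
#'   `k = 0` with a warning.
#' @return The calibrated `k` (scalar). If `v` is zero at the anchor the
#'   deviation term cannot move the anchor and a classed error
#'   (`logquad5_calibration_error`) instructs falling back to `k = 0`.
#' @export
calibrate_k <- function(fit, q5, anchor_label = "0-27d", q_anchor) {
  labels <- grid_labels(fit$grid)
  if (!anchor_label %in% labels) {
    stop("anchor label '", anchor_label, "' not in the age grid", call. = FALSE)
  }
  if (!is.numeric(q_anchor) || length(q_anchor) != 1) {
    stop("`q_anchor` must be a single number", call. = FALSE)
  }
  if (q_anchor <= 0) {
    warning("non-positive anchor probability: falling back to k = 0",
            call. = FALSE)
    return(0)
  }
  i <- match(anchor_label, labels)
  cf <- fit$coeffs[i, ]
  if (cf$v == 0) {
    stop(structure(class = c("logquad5_calibration_error", "error", "condition"),
                   list(message = paste0("age deviation v is 0 at '", anchor_label,
                                         "': cannot calibrate, fall back to k = 0"),
                        call = NULL)))
  }
  L <- log(q5)
  as.numeric((log(q_anchor) - cf$a - cf$b * L - cf$c * L^2) / cf$v)
}

#' Serialize a fitted model
#'
#' Writes a `logquad_fit` to JSON at full floating-point precision
#' (coefficients, age deviation vector, residual scales, per-record training
#' shape parameters, grid and metadata); [read_logquad_fit()] restores it
#' exactly.
#'
#' @param fit A `logquad_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logquad_fit <- function(fit, path) {
  # doubles as %.17g strings: decimal JSON round-trips bit-exactly
  enc <- function(x) sprintf("%.17g", x)
  payload <- list(
    cause = fit$cause, degree = fit$degree,
    n_records = fit$n_records, n_complete = fit$n_complete,
    norm = "unit Euclidean v, non-negative youngest entry; natural log",
    grid = list(label = fit$grid$label, days = fit$grid$days,
                month_days = enc(grid_month_days(fit$grid))),
    coeffs = list(label = fit$coeffs$label,
                  a = enc(fit$coeffs$a), b = enc(fit$coeffs$b),
                  c = enc(fit$coeffs$c), v = enc(fit$coeffs$v),
                  sigma = enc(fit$coeffs$sigma), n_fit = fit$coeffs$n_fit),
    training_k = list(stratum = fit$training_k$stratum,
                      year = fit$training_k$year,
                      k = enc(fit$training_k$k))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_logquad_fit
#' @export
read_logquad_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- age_grid(p$grid$label, p$grid$days, as.numeric(p$grid$month_days))
  coeffs <- tibble::tibble(label = p$coeffs$label,
                           a = as.numeric(p$coeffs$a),
                           b = as.numeric(p$coeffs$b),
                           c = as.numeric(p$coeffs$c),
                           v = as.numeric(p$coeffs$v),
                           sigma = as.numeric(p$coeffs$sigma),
                           n_fit = as.integer(p$coeffs$n_fit))
  training_k <- if (length(p$training_k$k)) {
    tibble::tibble(stratum = p$training_k$stratum,
                   year = as.integer(p$training_k$year),
                   k = as.numeric(p$training_k$k))
  } else {
    tibble::tibble(stratum = character(), year = integer(), k = double())
  }
  out <- list(grid = grid, cause = p$cause, degree = as.integer(p$degree),
              coeffs = coeffs, training_k = training_k,
              n_records = p$n_records, n_complete = p$n_complete)
  class(out) <- "logquad_fit"
  out
}
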