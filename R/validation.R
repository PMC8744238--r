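#' Per-age prediction errors for one record
#'
#' Compares a predicted age schedule to an observed record on the shared
#' grid: absolute error \eqn{|\hat q - q|} at every age, relative error
#' \eqn{|\hat q - q| / q} where the observed \eqn{q > 0}. Cells with
#' observed zero are excluded from the relative metric (the ratio is
#' undefined) and flagged.
#'
#' @param predicted An `age_schedule`.
#' @param observed A one-row [lifetable_set] (or a row of one).
#' @return A tibble with columns `label`, `observed`, `predicted`,
#'   `abs_error`, `rel_error` (`NA` when excluded), `excluded`.
#' @export
error_summary <- function(predicted, observed) {
  grid <- lt_grid(observed)
  if (!identical(grid_labels(grid), predicted$label)) {
    stop("predicted schedule and observed record use different age grids",
         call. = FALSE)
  }
  if (nrow(observed) != 1) stop("`observed` must be a single record", call. = FALSE)
  q_obs <- as.numeric(lt_qmat(observed, grid)[1, ])
  abs_err <- abs(predicted$q - q_obs)
  excl <- q_obs == 0
  tibble::tibble(
    label = predicted$label,
    observed = q_obs,
    predicted = predicted$q,
    abs_error = abs_err,
    rel_error = ifelse(excl, NA_real_, abs_err / q_obs),
    excluded = excl
  )
}

#' Leave-one-stratum-out cross-validation
#'
#' For each stratum in turn, fits the log quadratic model on the remaining
#' strata and predicts every held-out record three ways: the average pattern
#' (`k = 0`); the anchored pattern, with `k` calibrated so the predicted
#' anchor-age probability matches the held-out record's own observed value
#' (its `q5` and anchor probability are treated as known, the model's
#' intended prediction setting); and the constant-hazard
#' [standard_predict()] baseline calibrated to the same two quantities.
#' Absolute and relative errors are accumulated per (record, age) cell;
#' relative-error cells with observed zero are excluded and counted.
#'
#' Records whose anchor cannot be calibrated (zero observed anchor
#' probability, or zero deviation `v` at the anchor) fall back to `k = 0`
#' and are flagged in `fallbacks`.
#'
#' @param set A [lifetable_set] with at least 2 strata for the cause.
#' @param cause Cause label to validate.
#' @param anchor_label Grid label used both to calibrate `k` and as the
#'   neonatal probability of the baseline (default `"0-27d"`).
#' @param degree Polynomial degree passed to [fit_logquad()]; degree 1
#'   labels its methods `loglinear_*` instead of `logquad_*`.
#' @return An object of class `cv_report`: list with `cells` (one row per
#'   record x age x method), `folds` (per held-out stratum x age x method
#'   summaries), `pooled` (cell-weighted mean over folds), `fallbacks`, and
#'   the configuration. Errors are on the proportion scale; multiply by
#'   1000 for deaths per 1000 livebirths, by 100 for percent.
#' @examples
#' synth <- make_mchss_like(seed = 1)
#' cv <- loso_crossval(synth$set, cause = "all")
#' tidy(cv)
#' @export
loso_crossval <- function(set, cause = "all", anchor_label = "0-27d", degree = 2) {
  grid <- lt_grid(set)
  sub <- subset(set, causes = cause)
  strata <- unique(sub$stratum)
  if (length(strata) < 2) {
    stop("need at least 2 strata for cause '", cause, "'", call. = FALSE)
  }
  prefix <- if (degree == 2) "logquad" else "loglinear"
  m_k0 <- paste0(prefix, "_k0")
  m_anch <- paste0(prefix, "_anchored")

  cells <- list()
  fallbacks <- list()
  for (s in strata) {
    train <- subset(set, strata = setdiff(strata, s), causes = cause)
    fit <- fit_logquad(train, cause = cause, degree = degree)
    held <- subset(sub, strata = s)
    for (i in seq_len(nrow(held))) {
      rec <- held[i, , drop = FALSE]
      q5r <- rec$q5
      q_anchor <- lt_qmat(rec, grid)[1, anchor_label]
      pred_k0 <- predict_pattern(fit, q5r, k = 0)
      k_hat <- withCallingHandlers(
        tryCatch(calibrate_k(fit, q5r, anchor_label, q_anchor),
                 logquad5_calibration_error = function(e) NA_real_),
        warning = function(w) invokeRestart("muffleWarning"))
      fell_back <- is.na(k_hat) || k_hat == 0 && q_anchor <= 0
      if (is.na(k_hat)) k_hat <- 0
      if (fell_back) {
        fallbacks[[length(fallbacks) + 1L]] <-
          tibble::tibble(stratum = rec$stratum, year = rec$year,
                         reason = if (q_anchor <= 0) "zero anchor" else "zero v")
      }
      pred_anch <- predict_pattern(fit, q5r, k = k_hat)
      pred_std <- standard_predict(grid, q_neonatal = q_anchor, q5 = q5r)
      for (m in list(list(m_k0, pred_k0), list(m_anch, pred_anch),
                     list("standard", pred_std))) {
        es <- error_summary(m[[2]], rec)
        es$method <- m[[1]]
        es$fold <- s
        es$stratum <- rec$stratum
        es$year <- rec$year
        cells[[length(cells) + 1L]] <- es
      }
    }
  }
  cells <- dplyr::bind_rows(cells)
  cells <- dplyr::select(cells, "fold", "stratum", "year", "method",
                         "label", "observed", "predicted", "abs_error",
                         "rel_error", "excluded")

  summarise_cells <- function(df, by) {
    dplyr::summarise(
      dplyr::group_by(df, dplyr::across(dplyr::all_of(by))),
      mean_abs_error = mean(.data$abs_error),
      mean_rel_error = mean(.data$rel_error[!.data$excluded]),
      n_cells = dplyr::n(),
      n_excluded_zero_obs = sum(.data$excluded),
      .groups = "drop")
  }
  folds <- summarise_cells(cells, c("fold", "method", "label"))
  pooled <- summarise_cells(cells, c("method", "label"))
  pooled$label <- factor(pooled$label, levels = grid_labels(grid))
  pooled <- dplyr::arrange(pooled, .data$label, .data$method)
  pooled$label <- as.character(pooled$label)

  out <- list(cause = cause, anchor_label = anchor_label, degree = degree,
              methods = c(m_k0, m_anch, "standard"),
              cells = cells, folds = folds, pooled = pooled,
              fallbacks = if (length(fallbacks)) dplyr::bind_rows(fallbacks)
                          else tibble::tibble(stratum = character(),
                                              year = integer(),
                                              reason = character()),
              grid = grid)
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> cause '", x$cause, "', anchor '", x$anchor_label,
      "', degree ", x$degree, ", ", length(unique(x$folds$fold)),
      " folds\n", sep = "")
  cat("pooled errors (per 1000 livebirths / %):\n")
  show <- dplyr::mutate(x$pooled,
                        abs_per1000 = round(.data$mean_abs_error * 1000, 2),
                        rel_pct = round(.data$mean_rel_error * 100, 1))
  print(dplyr::select(show, "method", "label", "abs_per1000", "rel_pct",
                      "n_cells", "n_excluded_zero_obs"), n = Inf)
  invisible(x)
}

#' @rdname loso_crossval
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
tidy.cv_report <- function(x, ...) {
  tidyr::pivot_longer(x$pooled, c("mean_abs_error", "mean_rel_error"),
                      names_to = "metric", values_to = "value")
}

#' @rdname loso_crossval
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(cause = x$cause, anchor_label = x$anchor_label,
                 degree = x$degree, n_folds = length(unique(x$folds$fold)),
                 n_records = nrow(x$cells) / length(x$methods) /
                   length(grid_labels(x$grid)),
                 n_fallbacks = nrow(x$fallbacks))
}

#' Write a cross-validation report as tidy CSV
#'
#' One row per (fold, age label, method, metric); pooled rows carry
#' `fold = "(pooled)"`.
#'
#' @param report A `cv_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  folds <- tidyr::pivot_longer(report$folds,
                               c("mean_abs_error", "mean_rel_error"),
                               names_to = "metric", values_to = "value")
  pooled <- tidy(report)
  pooled$fold <- "(pooled)"
  out <- dplyr::bind_rows(folds, pooled)
  out$cause <- report$cause
  readr::write_csv(dplyr::select(out, "cause", "fold", "label", "method",
                                 "metric", "value", "n_cells",
                                 "n_excluded_zero_obs"), path)
  invisible(path)
}
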