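#' Ground-truth specification for the synthetic fixture generator
#'
#' Describes a sample-registration-style study population — six
#' geography-by-urbanicity strata observed over twenty years, with an
#' all-cause schedule and two cause-specific schedules (a pneumonia-like
#' cause concentrated in infancy and a rarer injury-like cause concentrated
#' in later childhood) — entirely through the log quadratic generating
#' mechanism, so every latent quantity is known and recoverable.
#'
#' The per-age coefficient tables are constructed, not taken from any
#' empirical source: for each cause the `k = 0` schedule is fixed at two
#' under-five levels as a fraction-of-q5 profile, a small curvature `c` is
#' chosen, and `(a, b)` are solved exactly through the two anchor points.
#' The terminal age has coefficients `(0, 1, 0)` with `v = 0` and
#' `sigma = 0`, so the terminal probability equals `q5` by construction.
#' Under-five levels decline log-linearly over the years within each
#' stratum, spanning realistic ranges (all-cause roughly 5--60 per 1000;
#' the cause-specific schedules roughly an order of magnitude lower), with
#' a small lognormal year-to-year wobble.
#'
#' @param grid An [age_grid()] (six default cut points).
#' @param strata Stratum labels (default the six geography x urbanicity
#'   cells).
#' @param years Observation years (default 1996--2015).
#' @param zero_inflation If `FALSE`, all zero-inflation probabilities are
#'   set to 0 (no masked cells); if `TRUE` (default) the cause-specific
#'   schedules mask a small share of young-age cells to zero, emulating
#'   observed 0.0 cells for rare causes.
#' @return A list of class `truth_spec` with elements `grid`, `strata`,
#'   `years`, and `causes` — a named list of per-cause tables
#'   (`coeffs` tibble with `a,b,c,v,sigma,zero_inflation` per label, and
#'   `q5_start`/`q5_end` named by stratum).
#' @export
synth_truth_spec <- function(grid = age_grid(),
                             strata = c("east-urban", "east-rural",
                                        "mid-urban", "mid-rural",
                                        "west-urban", "west-rural"),
                             years = 1996:2015,
                             zero_inflation = TRUE) {
  labels <- grid_labels(grid)
  n_age <- length(labels)
  stopifnot(n_age == 6)  # default profiles are written for the 6-point grid

  # two-point construction: ln q = a + b L + c L^2 through
  # (L1, ln(f1*Q1)) and (L2, ln(f2*Q2)) for chosen curvature c
  solve_ab <- function(frac1, Q1, frac2, Q2, c_vec) {
    L1 <- log(Q1); L2 <- log(Q2)
    y1 <- log(frac1 * Q1); y2 <- log(frac2 * Q2)
    b <- (y2 - y1) / (L2 - L1) - c_vec * (L2 + L1)
    a <- y1 - b * L1 - c_vec * L1^2
    list(a = a, b = b, c = c_vec)
  }
  unit_v <- function(raw) {
    if (sum(raw^2) == 0) return(raw)
    v <- raw / sqrt(sum(raw^2))
    if (v[which(v != 0)[1]] < 0) -v else v
  }

  make_cause <- function(frac1, Q1, frac2, Q2, c_vec, v_raw, sigma, zi,
                         q5_start, q5_end) {
    ab <- solve_ab(frac1, Q1, frac2, Q2, c_vec)
    # terminal age: identity by construction
    ab$a[n_age] <- 0; ab$b[n_age] <- 1; ab$c[n_age] <- 0
    list(coeffs = tibble::tibble(label = labels, a = ab$a, b = ab$b,
                                 c = ab$c, v = unit_v(v_raw), sigma = sigma,
                                 zero_inflation = if (zero_inflation) zi
                                                  else rep(0, n_age)),
         q5_start = q5_start, q5_end = q5_end)
  }

  causes <- list(
    all = make_cause(
      frac1 = c(0.28, 0.48, 0.68, 0.82, 0.93, 1), Q1 = 0.010,
      frac2 = c(0.34, 0.55, 0.74, 0.86, 0.945, 1), Q2 = 0.080,
      c_vec = c(0.020, 0.015, 0.010, 0.006, 0.003, 0),
      v_raw = c(0.55, 0.50, 0.40, 0.30, 0.15, 0),
      sigma = c(0.08, 0.06, 0.05, 0.04, 0.03, 0),
      zi = rep(0, n_age),
      q5_start = stats::setNames(c(0.014, 0.030, 0.022, 0.042, 0.034, 0.062),
                                 strata),
      q5_end = stats::setNames(c(0.005, 0.010, 0.007, 0.013, 0.011, 0.020),
                               strata)),
    pneumonia = make_cause(
      frac1 = c(0.10, 0.25, 0.55, 0.75, 0.92, 1), Q1 = 0.002,
      frac2 = c(0.14, 0.32, 0.62, 0.80, 0.94, 1), Q2 = 0.020,
      c_vec = c(0.025, 0.018, 0.010, 0.006, 0.003, 0),
      v_raw = c(0.60, 0.55, 0.40, 0.25, 0.12, 0),
      sigma = c(0.25, 0.20, 0.15, 0.12, 0.10, 0),
      zi = c(0.05, 0, 0, 0, 0, 0),
      q5_start = stats::setNames(c(0.0012, 0.0035, 0.0020, 0.0060, 0.0045,
                                   0.0100), strata),
      q5_end = stats::setNames(c(0.0004, 0.0010, 0.0006, 0.0016, 0.0012,
                                 0.0028), strata)),
    injury = make_cause(
      frac1 = c(0.04, 0.08, 0.25, 0.45, 0.72, 1), Q1 = 0.001,
      frac2 = c(0.05, 0.10, 0.30, 0.50, 0.75, 1), Q2 = 0.008,
      c_vec = c(0.020, 0.015, 0.010, 0.006, 0.003, 0),
      v_raw = c(0.50, 0.50, 0.45, 0.35, 0.20, 0),
      sigma = c(0.30, 0.25, 0.20, 0.15, 0.12, 0),
      zi = c(0.10, 0.05, 0, 0, 0, 0),
      q5_start = stats::setNames(c(0.0006, 0.0016, 0.0010, 0.0026, 0.0020,
                                   0.0042), strata),
      q5_end = stats::setNames(c(0.0003, 0.0007, 0.0004, 0.0010, 0.0008,
                                 0.0016), strata))
  )
  out <- list(grid = grid, strata = strata, years = years, causes = causes)
  class(out) <- "truth_spec"
  out
}

#' Generate a synthetic sample-registration-style life-table collection
#'
#' Draws, for every (stratum, year, cause), a full age schedule from the log
#' quadratic mechanism of the matching [synth_truth_spec()] cause: the
#' under-five level follows the stratum's declining trend with lognormal
#' wobble, a per-record shape `k ~ N(0, 1)` scales the age deviation vector,
#' per-age lognormal noise is added, the terminal age is pinned to `q5`, and
#' the schedule is monotone-repaired. Zero-inflation then masks cells to 0:
#' a masked age zeroes itself and all younger ages (no deaths observed up to
#' that cut point), so generated sets always satisfy the cumulative
#' invariants.
#'
#' @param spec A [synth_truth_spec()].
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list with `set` (a [lifetable_set] stacking all causes; 6
#'   strata x 20 years = 120 records per cause under the defaults) and
#'   `truth` (tibble of the latent `k`, per-age noise draws `eps_*` and
#'   masked-cell flags per record).
#' @examples
#' synth <- make_mchss_like(seed = 1)
#' dplyr::count(synth$set, cause)
#' @export
make_mchss_like <- function(spec = synth_truth_spec(), seed = 1) {
  set.seed(as.integer(seed))
  grid <- spec$grid
  labels <- grid_labels(grid)
  n_age <- length(labels)
  rows <- list()
  truth_rows <- list()
  for (cause_name in names(spec$causes)) {
    cz <- spec$causes[[cause_name]]
    cf <- cz$coeffs
    ny <- length(spec$years)
    for (s in spec$strata) {
      # log-linear decline with small lognormal wobble
      q5_path <- exp(seq(log(cz$q5_start[[s]]), log(cz$q5_end[[s]]),
                         length.out = ny) + stats::rnorm(ny, 0, 0.05))
      for (yi in seq_len(ny)) {
        q5 <- q5_path[yi]
        k <- stats::rnorm(1)
        eps <- stats::rnorm(n_age, 0, cf$sigma)
        L <- log(q5)
        q <- exp(cf$a + cf$b * L + cf$c * L^2 + cf$v * k + eps)
        q <- pmin(q, 1)
        q[n_age] <- q5
        q <- rev(cummin(rev(q)))
        # cumulative masking: a masked age zeroes all younger ages too
        mask_draw <- stats::runif(n_age) < cf$zero_inflation
        masked <- rep(FALSE, n_age)
        if (any(mask_draw)) {
          upto <- max(which(mask_draw))
          masked[seq_len(upto)] <- TRUE
          q[masked] <- 0
        }
        rows[[length(rows) + 1L]] <- c(list(stratum = s,
                                            year = spec$years[yi],
                                            cause = cause_name),
                                       stats::setNames(as.list(q),
                                                       q_col(labels)),
                                       list(q5 = q5))
        truth_rows[[length(truth_rows) + 1L]] <-
          c(list(stratum = s, year = spec$years[yi], cause = cause_name,
                 k = k),
            stats::setNames(as.list(eps), paste0("eps_", q_col(labels))),
            stats::setNames(as.list(masked), paste0("masked_", q_col(labels))))
      }
    }
  }
  set <- lifetable_set(dplyr::bind_rows(lapply(rows, tibble::as_tibble)),
                       grid)
  truth <- dplyr::bind_rows(lapply(truth_rows, tibble::as_tibble))
  list(set = set, truth = truth)
}

#' Write the synthetic fixture and its truth file
#'
#' The observable collection goes to the standard life-table CSV; the latent
#' truth (per-record `k`, per-age noise, masked flags) to a sibling CSV.
#' Together they determine every latent quantity of the generator.
#'
#' @param synth Result of [make_mchss_like()].
#' @param path Life-table CSV path.
#' @param truth_path Truth CSV path (default: `path` with `_truth` suffix).
#' @return `path`, invisibly.
#' @export
write_synth_fixture <- function(synth, path,
                                truth_path = sub("(\\.csv)?$", "_truth.csv",
                                                 path)) {
  write_lifetable_csv(synth$set, path)
  readr::write_csv(synth$truth, truth_path)
  invisible(path)
}
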