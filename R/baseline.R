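#' Constant-hazard baseline ("standard approach")
#'
#' The usual fallback when age-specific mortality below five is unknown:
#' assume a constant mortality hazard within the neonatal window (0--27
#' days) and another constant hazard from 1 to 59 months, calibrated so that
#' the schedule reproduces the observed neonatal probability at 28 days and
#' the under-five probability at 60 months exactly.
#'
#' The daily neonatal hazard solves \eqn{1 - e^{-28\lambda_1} = q_{neo}};
#' past 28 days (treated as exactly one month when splicing), the monthly
#' hazard solves \eqn{(1-q_{neo})e^{-m_T\lambda_2} = 1 - q_5} where
#' \eqn{m_T} is the number of months between 28 days and the terminal cut
#' point. Cumulative probabilities at each cut point are then
#' \eqn{q(t) = 1 - e^{-\lambda_1 t}} within the neonatal window and
#' \eqn{q(t) = 1 - (1-q_{neo}) e^{-\lambda_2 m(t)}} beyond it, with
#' \eqn{m(t) = (t - 28)/\mathrm{month\_days}}. `q_neonatal = 0` gives a flat
#' zero through 28 days; `q_neonatal = q5` gives a flat schedule thereafter.
#'
#' @param grid An [age_grid()]; its `month_days` attribute sets the
#'   day/month conversion.
#' @param q_neonatal Observed cumulative probability of dying by 28 days,
#'   with `0 <= q_neonatal <= q5`.
#' @param q5 Observed under-five probability, `q5 < 1`.
#' @param interpolation `"hazard"` (constant hazard, the default) or
#'   `"linear"` (linear in cumulative probability over time within each
#'   window; a sensitivity variant — at realistic magnitudes the two agree
#'   below reporting precision).
#' @return An `age_schedule` with `k = NA` and cause `"standard"`.
#' @examples
#' standard_predict(age_grid(), q_neonatal = 0.02, q5 = 0.05)
#' @export
standard_predict <- function(grid = age_grid(), q_neonatal, q5,
                             interpolation = c("hazard", "linear")) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.numeric(q_neonatal), is.numeric(q5),
            length(q_neonatal) == 1, length(q5) == 1)
  if (q_neonatal < 0 || q_neonatal > q5 || q5 >= 1) {
    stop("need 0 <= q_neonatal <= q5 < 1", call. = FALSE)
  }
  t_days <- grid$days
  neo_days <- 28
  md <- grid_month_days(grid)
  m_T <- (t_days[length(t_days)] - neo_days) / md
  q <- numeric(length(t_days))
  if (interpolation == "hazard") {
    lambda1 <- -log(1 - q_neonatal) / neo_days        # per day
    lambda2 <- -log((1 - q5) / (1 - q_neonatal)) / m_T # per month
    inside <- t_days <= neo_days
    q[inside] <- 1 - exp(-lambda1 * t_days[inside])
    m <- (t_days[!inside] - neo_days) / md
    q[!inside] <- 1 - (1 - q_neonatal) * exp(-lambda2 * m)
  } else {
    inside <- t_days <= neo_days
    q[inside] <- q_neonatal * t_days[inside] / neo_days
    m <- (t_days[!inside] - neo_days) / md
    q[!inside] <- q_neonatal + (q5 - q_neonatal) * m / m_T
  }
  # calibration identities, exact by construction
  q[t_days == neo_days] <- q_neonatal
  q[length(q)] <- q5
  new_age_schedule(grid, q, q5 = q5, k = NA_real_, cause = "standard")
}
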