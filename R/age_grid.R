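#' Under-five age grid
#'
#' Construct the ordered set of age cut points over which cumulative
#' probabilities of dying \eqn{{}_xq_0} are recorded. The default grid is the
#' six-group under-five grid used throughout the package: 0--6 and 0--27
#' completed days, and 0--5, 0--11, 0--23 and 0--59 completed months, the last
#' cut point being the under-five bound (60 months), so that \eqn{q} at the
#' terminal cut point is the under-five mortality \eqn{{}_5q_0}.
#'
#' @param label Character vector of unique age-group labels.
#' @param days Integer vector of strictly increasing upper bounds in days.
#' @param month_days Days per month used for hazard arithmetic (default
#'   30.4375, the mean Gregorian month).
#'
#' @return A tibble of class `age_grid` with columns `label` and `days`, and a
#'   `month_days` attribute.
#' @examples
#' age_grid()
#' @export
age_grid <- function(label = c("0-6d", "0-27d", "0-5m", "0-11m", "0-23m", "0-59m"),
                     days = c(7L, 28L, 183L, 365L, 730L, 1825L),
                     month_days = 30.4375) {
  stopifnot(length(label) == length(days), length(label) >= 3)
  if (anyDuplicated(label)) {
    stop("age grid labels must be unique", call. = FALSE)
  }
  if (any(diff(days) <= 0)) {
    stop("age grid upper bounds must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(month_days) || month_days <= 0) {
    stop("`month_days` must be a positive number", call. = FALSE)
  }
  out <- tibble::tibble(label = as.character(label), days = as.integer(days))
  attr(out, "month_days") <- month_days
  class(out) <- c("age_grid", class(out))
  out
}

#' @export
print.age_grid <- function(x, ...) {
  cat("<age_grid> ", nrow(x), " cut points, month = ",
      attr(x, "month_days"), " days\n", sep = "")
  NextMethod()
}

grid_labels <- function(grid) grid$label

grid_month_days <- function(grid) attr(grid, "month_days") %||% 30.4375

# CSV column name for an age label: "0-6d" -> "q_0_6d"
q_col <- function(label) paste0("q_", gsub("-", "_", label, fixed = TRUE))
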