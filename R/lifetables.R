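#' Life-table collections
#'
#' A life-table set is a tibble with one row per (stratum, year, cause)
#' record, carrying the cumulative probabilities of dying from birth to each
#' age cut point of an [age_grid()] in one column per label (`q_0_6d`, ...,
#' `q_0_59m` for the default grid) plus the under-five probability `q5`,
#' which must equal the terminal age column. Probabilities are always stored
#' as proportions internally; per-1000 inputs are converted at read time.
#'
#' @name lifetable_set
NULL

new_lifetable_set <- function(df, grid) {
  df <- tibble::as_tibble(df)
  attr(df, "grid") <- grid
  class(df) <- unique(c("lifetable_set", class(df)))
  df
}

#' Assemble a life-table set from a data frame
#'
#' @param df Data frame with columns `stratum`, `year`, `cause`, one `q_*`
#'   column per grid label, and `q5` (proportion scale).
#' @param grid An [age_grid()].
#' @return A `lifetable_set` tibble.
#' @export
lifetable_set <- function(df, grid = age_grid()) {
  cols <- c("stratum", "year", "cause", q_col(grid_labels(grid)), "q5")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::select(tibble::as_tibble(df), dplyr::all_of(cols))
  df$stratum <- as.character(df$stratum)
  df$year <- as.integer(df$year)
  df$cause <- as.character(df$cause)
  dup <- duplicated(df[c("stratum", "year", "cause")])
  if (any(dup)) {
    keys <- df[dup, c("stratum", "year", "cause")]
    stop("duplicate (stratum, year, cause) key(s): ",
         paste(do.call(paste, c(keys, sep = "/")), collapse = ", "),
         call. = FALSE)
  }
  new_lifetable_set(df, grid)
}

lt_grid <- function(set) {
  grid <- attr(set, "grid")
  if (is.null(grid)) stop("not a lifetable_set: no age grid attached", call. = FALSE)
  grid
}

# matrix of q values, rows = records, cols = grid labels
lt_qmat <- function(set, grid = lt_grid(set)) {
  m <- as.matrix(as.data.frame(set)[, q_col(grid_labels(grid)), drop = FALSE])
  colnames(m) <- grid_labels(grid)
  m
}

#' Read a life-table CSV
#'
#' Reads a delimited file with header
#' `stratum,year,cause,q_0_6d,...,q_0_59m,q5` (one `q_*` column per grid
#' label). The unit convention of the file must be declared: probabilities
#' are stored internally as proportions and `per1000` columns are divided by
#' 1000 on read.
#'
#' @param source Path (or connection) to a CSV file.
#' @param units Either `"proportion"` or `"per1000"` — the on-disk scale.
#' @param grid An [age_grid()].
#' @return A [lifetable_set] in proportion units.
#' @details The redundant `q5` column is cross-checked against the terminal
#'   age column at an absolute tolerance of 1e-9 on the proportion scale;
#'   disagreement, unparseable numerics and duplicate keys are errors naming
#'   the offending rows.
#' @export
read_lifetable_csv <- function(source, units = c("proportion", "per1000"),
                               grid = age_grid()) {
  units <- match.arg(units)
  qcols <- q_col(grid_labels(grid))
  df <- readr::read_csv(source, show_col_types = FALSE,
                        col_types = readr::cols(
                          stratum = readr::col_character(),
                          year = readr::col_integer(),
                          cause = readr::col_character(),
                          .default = readr::col_double()
                        ))
  missing_cols <- setdiff(c("stratum", "year", "cause", qcols, "q5"), names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num <- as.matrix(df[, c(qcols, "q5")])
  bad <- which(rowSums(is.na(num)) > 0)
  if (length(bad)) {
    stop("unparseable or missing numeric value(s) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (units == "per1000") {
    df[c(qcols, "q5")] <- df[c(qcols, "q5")] / 1000
  }
  mismatch <- which(abs(df$q5 - df[[qcols[length(qcols)]]]) > 1e-9)
  if (length(mismatch)) {
    stop("q5 column disagrees with terminal age column (", qcols[length(qcols)],
         ") beyond 1e-9 in row(s): ", paste(mismatch, collapse = ", "),
         call. = FALSE)
  }
  lifetable_set(df, grid)
}

#' Write a life-table CSV
#'
#' Inverse of [read_lifetable_csv()] for proportion units; a
#' read-write-read cycle reproduces the set exactly.
#'
#' @param set A [lifetable_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lifetable_csv <- function(set, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(set)), path)
  invisible(path)
}

#' Validate a life-table set
#'
#' Checks every record against the cumulative-probability invariants:
#' probabilities in \[0, 1\], non-decreasing along the age grid, `q5` equal to
#' the terminal age column, and cause-specific `q5` not exceeding the
#' matching all-cause `q5`. Zero cells are legal observations (a cause may
#' kill no one before an age cut point) and are counted per age label rather
#' than flagged, because they drive fitting exclusions downstream.
#'
#' @param set A [lifetable_set].
#' @return A list of class `lifetable_validation` with tibbles `errors`
#'   (`stratum`, `year`, `cause`, `rule`, `detail`), `warnings` (same shape)
#'   and `n_zero_cells` (`label`, `n`).
#' @export
validate_lifetables <- function(set) {
  grid <- lt_grid(set)
  labels <- grid_labels(grid)
  qm <- lt_qmat(set, grid)
  err <- list()
  add_err <- function(i, rule, detail) {
    tibble::tibble(stratum = set$stratum[i], year = set$year[i],
                   cause = set$cause[i], rule = rule, detail = detail)
  }
  for (i in seq_len(nrow(set))) {
    q <- qm[i, ]
    oob <- which(q < 0 | q > 1)
    if (length(oob)) {
      err[[length(err) + 1L]] <- add_err(i, "range",
        paste0("q out of [0,1] at ", paste(labels[oob], collapse = ", ")))
    }
    drops <- which(diff(q) < 0)
    for (j in drops) {
      err[[length(err) + 1L]] <- add_err(i, "monotone",
        paste0("q(", labels[j], ")=", format(q[j]), " > q(", labels[j + 1L],
               ")=", format(q[j + 1L])))
    }
    if (abs(q[length(q)] - set$q5[i]) > 1e-9) {
      err[[length(err) + 1L]] <- add_err(i, "q5_mismatch",
        paste0("terminal q=", format(q[length(q)]), " but q5=", format(set$q5[i])))
    }
  }
  # cause-specific q5 must not exceed the matching all-cause q5
  if (any(set$cause != "all") && any(set$cause == "all")) {
    allq5 <- set[set$cause == "all", c("stratum", "year", "q5")]
    names(allq5)[3] <- "q5_all"
    joined <- dplyr::inner_join(
      dplyr::mutate(set[set$cause != "all", c("stratum", "year", "cause", "q5")],
                    .row = which(set$cause != "all")),
      allq5, by = c("stratum", "year"))
    over <- joined[joined$q5 > joined$q5_all + 1e-12, , drop = FALSE]
    for (i in seq_len(nrow(over))) {
      err[[length(err) + 1L]] <- add_err(over$.row[i], "cause_exceeds_all",
        paste0("cause q5=", format(over$q5[i]), " > all-cause q5=",
               format(over$q5_all[i])))
    }
  }
  empty <- tibble::tibble(stratum = character(), year = integer(),
                          cause = character(), rule = character(),
                          detail = character())
  out <- list(
    errors = if (length(err)) dplyr::bind_rows(err) else empty,
    warnings = empty,
    n_zero_cells = tibble::tibble(label = labels,
                                  n = unname(colSums(qm == 0)))
  )
  class(out) <- "lifetable_validation"
  out
}

#' @export
print.lifetable_validation <- function(x, ...) {
  cat("<lifetable_validation> ", nrow(x$errors), " error(s), ",
      nrow(x$warnings), " warning(s), ", sum(x$n_zero_cells$n),
      " zero cell(s)\n", sep = "")
  if (nrow(x$errors)) print(x$errors)
  invisible(x)
}

#' Subset a life-table set
#'
#' Filter records by stratum, year and/or cause while preserving the grid.
#' An empty result is legal.
#'
#' @param x A [lifetable_set].
#' @param strata Optional character vector of strata to keep.
#' @param years Optional integer vector (e.g. `2004:2009`) of years to keep.
#' @param causes Optional character vector of causes to keep.
#' @param ... Unused.
#' @return A [lifetable_set].
#' @export
subset.lifetable_set <- function(x, strata = NULL, years = NULL, causes = NULL, ...) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(strata)) keep <- keep & x$stratum %in% strata
  if (!is.null(years)) keep <- keep & x$year %in% years
  if (!is.null(causes)) keep <- keep & x$cause %in% causes
  new_lifetable_set(tibble::as_tibble(as.data.frame(x))[keep, , drop = FALSE],
                    lt_grid(x))
}

#' Pivot a life-table set to long form
#'
#' One row per (record, age label), convenient for plotting and joins.
#'
#' @param set A [lifetable_set].
#' @return A tibble with columns `stratum`, `year`, `cause`, `label`, `days`,
#'   `q`, `q5`.
#' @export
lifetable_long <- function(set) {
  grid <- lt_grid(set)
  long <- tidyr::pivot_longer(tibble::as_tibble(as.data.frame(set)),
                              dplyr::all_of(q_col(grid_labels(grid))),
                              names_to = "label", values_to = "q")
  long$label <- grid_labels(grid)[match(long$label, q_col(grid_labels(grid)))]
  long$days <- grid$days[match(long$label, grid$label)]
  dplyr::select(long, "stratum", "year", "cause", "label", "days", "q", "q5")
}
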