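test_that("life-table CSV round-trips identically and converts per-1000 units", {
  set <- make_identity_set(q5 = c(0.010, 0.020, 0.004, 0.031))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_lifetable_csv(set, tmp)
  back <- read_lifetable_csv(tmp, units = "proportion")
  expect_identical(as.data.frame(back), as.data.frame(set))

  # write -> read -> write is byte-identical (plumbing inverse)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_lifetable_csv(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))

  # a per-1000 file with values x1000 reads to the same internal record
  per1000 <- set
  qcols <- setdiff(lt_cols(), c("stratum", "year", "cause"))
  per1000[qcols] <- per1000[qcols] * 1000
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(as.data.frame(per1000)), tmp3)
  back1000 <- read_lifetable_csv(tmp3, units = "per1000")
  expect_equal(as.data.frame(back1000), as.data.frame(set), tolerance = 1e-12)
})

test_that("single-record file reads to the expected probabilities", {
  q <- c(0.002, 0.004, 0.006, 0.008, 0.009, 0.010)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("stratum,year,cause,q_0_6d,q_0_27d,q_0_5m,q_0_11m,q_0_23m,q_0_59m,q5",
               paste0("s1,2000,all,", paste(q, collapse = ","), ",0.010")), tmp)
  set <- read_lifetable_csv(tmp)
  expect_equal(nrow(set), 1)
  expect_equal(set$q5, 0.010)
  expect_equal(as.numeric(logquad5:::lt_qmat(set)[1, ]), q)

  # same data in per-1000 units is the identical internal record
  writeLines(c("stratum,year,cause,q_0_6d,q_0_27d,q_0_5m,q_0_11m,q_0_23m,q_0_59m,q5",
               paste0("s1,2000,all,", paste(q * 1000, collapse = ","), ",10")),
             tmp)
  set1000 <- read_lifetable_csv(tmp, units = "per1000")
  expect_equal(as.data.frame(set1000), as.data.frame(set), tolerance = 1e-12)
})

test_that("malformed files are rejected with addressed errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  hdr <- "stratum,year,cause,q_0_6d,q_0_27d,q_0_5m,q_0_11m,q_0_23m,q_0_59m,q5"

  # q5 disagreeing with the terminal column
  writeLines(c(hdr, "s1,2000,all,0.002,0.004,0.006,0.008,0.009,0.010,0.020"),
             tmp)
  expect_error(read_lifetable_csv(tmp), "q5 column disagrees")

  # missing a required column
  writeLines(c("stratum,year,cause,q_0_6d,q5", "s1,2000,all,0.002,0.010"), tmp)
  expect_error(read_lifetable_csv(tmp), "q_0_27d")

  # unparseable numeric
  writeLines(c(hdr, "s1,2000,all,oops,0.004,0.006,0.008,0.009,0.010,0.010"),
             tmp)
  expect_error(suppressWarnings(read_lifetable_csv(tmp)), "row")

  # duplicate key
  writeLines(c(hdr,
               "s1,2000,all,0.002,0.004,0.006,0.008,0.009,0.010,0.010",
               "s1,2000,all,0.002,0.004,0.006,0.008,0.009,0.010,0.010"), tmp)
  expect_error(read_lifetable_csv(tmp), "duplicate")
})

test_that("validate_lifetables flags exactly the violated invariants", {
  set <- make_identity_set(q5 = c(0.01, 0.02, 0.03))
  rep0 <- validate_lifetables(set)
  expect_equal(nrow(rep0$errors), 0)
  expect_equal(nrow(rep0$warnings), 0)

  # non-monotone record names both offending labels
  bad <- as.data.frame(set)
  bad[1, c("q_0_6d", "q_0_27d", "q_0_5m", "q_0_11m", "q_0_23m", "q_0_59m")] <-
    c(0.002, 0.004, 0.006, 0.008, 0.007, 0.010)
  rep1 <- validate_lifetables(lifetable_set(bad))
  mono <- rep1$errors[rep1$errors$rule == "monotone", ]
  expect_equal(nrow(mono), 1)
  expect_match(mono$detail, "0-11m")
  expect_match(mono$detail, "0-23m")

  # zero cells are legal observations, counted not flagged
  zero <- as.data.frame(set)
  zero$q_0_6d[1] <- 0
  rep2 <- validate_lifetables(lifetable_set(zero))
  expect_equal(nrow(rep2$errors), 0)
  expect_equal(rep2$n_zero_cells$n[rep2$n_zero_cells$label == "0-6d"], 1)

  # out-of-range probability
  oob <- as.data.frame(set)
  oob$q_0_6d[2] <- -0.001
  rep3 <- validate_lifetables(lifetable_set(oob))
  expect_true(any(rep3$errors$rule == "range"))

  # cause q5 above the matching all-cause q5
  both <- dplyr::bind_rows(as.data.frame(set),
                           dplyr::mutate(as.data.frame(set)[1, ],
                                         cause = "pneumonia"))
  both[both$cause == "pneumonia", setdiff(lt_cols(), c("stratum", "year", "cause"))] <-
    both[both$cause == "pneumonia",
         setdiff(lt_cols(), c("stratum", "year", "cause"))] * 3
  rep4 <- validate_lifetables(lifetable_set(both))
  expect_true(any(rep4$errors$rule == "cause_exceeds_all"))
})

test_that("validation flags corrupted records if and only if an invariant fails", {
  withr::local_seed(42)
  synth <- make_mchss_like(synth_truth_spec(zero_inflation = FALSE), seed = 3)
  base <- as.data.frame(synth$set)[1:30, ]
  qcols <- setdiff(lt_cols(), c("stratum", "year", "cause", "q5"))
  for (i in 1:20) {
    df <- base
    corrupt <- runif(1) < 0.5
    if (corrupt) {
      row <- sample(nrow(df), 1)
      mode <- sample(c("swap", "negative", "q5"), 1)
      if (mode == "swap") {        # break monotonicity by swapping two ages
        j <- sample(length(qcols) - 2, 1)
        tmp <- df[[qcols[j]]][row]
        df[[qcols[j]]][row] <- df[[qcols[j + 1]]][row] * 1.5 + 1e-4
      } else if (mode == "negative") {
        df[[qcols[1]]][row] <- -abs(df[[qcols[1]]][row]) - 1e-6
      } else {
        df$q5[row] <- df$q5[row] + 0.01
      }
    }
    rep <- validate_lifetables(lifetable_set(df))
    expect_identical(nrow(rep$errors) > 0, corrupt)
  }
})

test_that("subsetting filters by stratum, year and cause, preserving the grid", {
  synth <- make_mchss_like(seed = 1)
  set <- synth$set
  all_cause <- subset(set, causes = "all")
  expect_equal(nrow(all_cause), 120)  # 6 strata x 20 years

  drop_one <- subset(all_cause,
                     strata = setdiff(unique(all_cause$stratum), "mid-rural"))
  expect_equal(nrow(drop_one), 100)   # 5 x 20

  mid_rural_0409 <- subset(all_cause, strata = "mid-rural", years = 2004:2009)
  expect_equal(nrow(mid_rural_0409), 6)

  # filtering a cause absent from the subset yields an empty, valid set
  empty <- subset(all_cause, causes = "pneumonia")
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "lifetable_set")

  # union over disjoint key sets == subset of the union
  a <- subset(set, strata = "east-urban")
  b <- subset(set, strata = "west-rural")
  ab <- subset(set, strata = c("east-urban", "west-rural"))
  expect_equal(dplyr::arrange(dplyr::bind_rows(as.data.frame(a), as.data.frame(b)),
                              stratum, year, cause),
               dplyr::arrange(as.data.frame(ab), stratum, year, cause))
})
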