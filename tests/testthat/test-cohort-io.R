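test_that("well-formed cohort files load; malformed rows are rejected with line numbers", {
  path <- write_toy_cohort()
  co <- load_cohort(path)
  expect_s3_class(co, "cohort")
  expect_equal(nrow(co), 3L)
  expect_equal(co$subject_id, c("S01", "S02", "S03"))
  expect_equal(nrow(attr(co, "rejected")), 0L)

  df <- toy_cohort_df()
  df$sdfr[2] <- 17            # outside the 15-word recall range
  df$age[3] <- -1
  path2 <- write_toy_cohort(df)
  expect_warning(co2 <- load_cohort(path2), "rejected 2")
  expect_equal(nrow(co2), 1L)
  rej <- attr(co2, "rejected")
  expect_setequal(rej$line, c(3L, 4L))  # header is line 1
  expect_match(rej$reason[rej$subject_id == "S02"], "sdfr")
})

test_that("structural cohort errors: missing column and duplicate ids", {
  df <- toy_cohort_df()
  df$ldcr <- NULL
  expect_error(load_cohort(write_toy_cohort(df)), "missing column.*ldcr")
  df2 <- toy_cohort_df()
  df2$subject_id[2] <- "S01"
  expect_error(load_cohort(write_toy_cohort(df2)), "S01")
})

test_that("cohort and metrics tables round-trip bit-exactly through write/read", {
  sim <- generate_cohort(sim_config(seed = 9))
  cpath <- tempfile(fileext = ".csv")
  mpath <- tempfile(fileext = ".csv")
  write_cohort(sim$cohort, cpath)
  write_tract_metrics(sim$metrics, mpath)
  co <- load_cohort(cpath)
  me <- load_tract_metrics(mpath)
  expect_identical(co$age, sim$cohort$age)
  expect_identical(co$sdfr, sim$cohort$sdfr)
  expect_identical(co$discrimination, sim$cohort$discrimination)
  expect_identical(me$fa, sim$metrics$fa)
  expect_identical(me$rd, sim$metrics$rd)
  # tab-separated dialect behaves the same
  tpath <- tempfile(fileext = ".tsv")
  write_cohort(sim$cohort, tpath, delim = "\t")
  expect_identical(load_cohort(tpath, delim = "\t")$ldcr, sim$cohort$ldcr)
})

test_that("metrics loader enforces vocabulary, ranges and uniqueness", {
  df <- toy_metrics_df()
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  me <- load_tract_metrics(path)
  expect_equal(nrow(me), nrow(df))

  bad <- df
  bad$fa[1] <- 1.4
  bad$tract[5] <- "arcuate"
  utils::write.table(bad, path, sep = ",", quote = FALSE, row.names = FALSE)
  expect_warning(me2 <- load_tract_metrics(path), "rejected 2")
  expect_equal(nrow(me2), nrow(df) - 2L)

  dup <- rbind(df, df[1, ])
  utils::write.table(dup, path, sep = ",", quote = FALSE, row.names = FALSE)
  expect_error(load_tract_metrics(path), "duplicated")
})

test_that("streamline aggregation is the mean of per-streamline means", {
  expect_equal(aggregate_streamline_metrics(list(c(1, 1), c(3, 3))), 2.0)
  # two-stage definition, not the pooled mean (which would be 2.0)
  expect_equal(aggregate_streamline_metrics(list(c(0, 2), 4)), 2.5)
  expect_error(aggregate_streamline_metrics(list()), "no streamlines")
  expect_error(aggregate_streamline_metrics(list(c(1, 2), numeric(0))),
               "at least one")
})

test_that("streamline aggregation matches a brute-force oracle and ignores ordering", {
  set.seed(7)
  for (rep in 1:10) {
    sl <- lapply(seq_len(10), function(i) rnorm(sample(1:50, 1)))
    # independently coded two-stage oracle
    oracle <- sum(vapply(sl, function(v) sum(v) / length(v), 1)) / length(sl)
    expect_equal(aggregate_streamline_metrics(sl), oracle,
                 tolerance = 1e-12)
    shuffled <- lapply(sample(sl), sample)
    expect_equal(aggregate_streamline_metrics(shuffled), oracle,
                 tolerance = 1e-12)
  }
  # data.frame/CSV form agrees with the list form
  df <- data.frame(streamline_id = rep(1:3, times = c(2, 1, 3)),
                   position_index = c(1, 2, 1, 1, 2, 3),
                   value = c(0, 2, 4, 1, 2, 3))
  expect_equal(aggregate_streamline_metrics(df),
               mean(c(1, 4, 2)))
  path <- tempfile(fileext = ".csv")
  utils::write.table(df[sample(nrow(df)), ], path, sep = ",",
                     quote = FALSE, row.names = FALSE)
  loaded <- load_streamline_samples(path)
  expect_equal(unname(lapply(loaded, as.numeric)),
               list(c(0, 2), 4, c(1, 2, 3)))
  expect_equal(aggregate_streamline_metrics(loaded), mean(c(1, 4, 2)))
})

test_that("analysis matrix applies listwise deletion, fixed column order and sorted rows", {
  co <- as_cohort(toy_cohort_df())
  me <- as_tract_metrics(toy_metrics_df(ids = sprintf("S%02d", 1:12)))
  co12 <- as_cohort(data.frame(
    subject_id = sprintf("S%02d", 12:1),  # reversed input order
    age = seq(4, 12, length.out = 12),
    sex = rep(c("F", "M"), 6),
    sdfr = rep(5:10, 2), ldfr = rep(6:11, 2), ldcr = rep(7:12, 2),
    stringsAsFactors = FALSE))
  am <- build_analysis_matrix(co12, me, "uncinate_fasciculus")
  expect_equal(am$x_names,
               c("left_fa", "left_rd", "left_ad",
                 "right_fa", "right_rd", "right_ad"))
  expect_equal(am$subject_ids, sort(co12$subject_id))
  expect_equal(nrow(am$X), 12L)

  # dropping one hemisphere row loses exactly that subject
  me2 <- me[!(me$subject_id == "S03" & me$tract == "uncinate_fasciculus" &
                me$hemisphere == "left"), ]
  expect_message(
    am2 <- build_analysis_matrix(co12, me2, "uncinate_fasciculus"),
    "S03")
  expect_equal(length(am2$subject_ids), 11L)
  expect_equal(am2$dropped, "S03")
  # the other tracts are unaffected
  expect_equal(length(build_analysis_matrix(co12, me2,
                                            "fornix")$subject_ids), 12L)

  expect_error(build_analysis_matrix(co12, me, "arcuate"))
  expect_error(build_analysis_matrix(co, me[me$subject_id %in%
                                              co$subject_id, ],
                                     "fornix"),
               "insufficient data")
})

test_that("one failed reconstruction in a 37-subject cohort gives n = 36 for that tract only", {
  sim <- generate_cohort(sim_config(seed = 2))
  am_uf <- suppressMessages(
    build_analysis_matrix(sim$cohort, sim$metrics, "uncinate_fasciculus"))
  am_cb <- build_analysis_matrix(sim$cohort, sim$metrics,
                                 "dorsal_cingulum")
  expect_equal(length(am_uf$subject_ids), 36L)
  expect_equal(length(am_cb$subject_ids), 37L)
  expect_equal(am_uf$dropped, sim$truth$failed_subjects)
})
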