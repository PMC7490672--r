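test_that("vector magnitude is the rounded Euclidean norm", {
  expect_equal(vector_magnitude(3, 4, 0), 5L)
  expect_equal(vector_magnitude(0, 0, 0), 0L)
  expect_equal(vector_magnitude(1, 2, 2), 3L)
  expect_equal(vector_magnitude(cbind(c(3, 1), c(4, 2), c(0, 2))),
               c(5L, 3L))
  expect_error(vector_magnitude(1, 2, NULL), "axis3")
  expect_error(vector_magnitude(1:3, 1:2, 1:3), "equal length")
})

test_that("reintegration sums complete windows and conserves counts", {
  expect_equal(reintegrate(c(100, 200, 300, 400), 15, 60), 1000L)
  expect_equal(reintegrate(rep(1L, 8), 15, 60), c(4L, 4L))
  s <- sample(0:50, 40, replace = TRUE)
  expect_identical(reintegrate(s, 15, 15), as.integer(s))
  expect_warning(out <- reintegrate(1:10, 15, 60), "partial")
  expect_equal(sum(out), sum(1:8))
  expect_error(reintegrate(1:4, 60, 15), "disaggregate")
  expect_error(reintegrate(1:4, 15, 40), "multiple")
  # conservation over complete windows, arbitrary series
  set.seed(8)
  s <- sample(0:999, 240, replace = TRUE)
  expect_equal(sum(reintegrate(s, 15, 60)), sum(s))
})

test_that("cpm conversion matches the epoch grid", {
  expect_equal(to_cpm(205, 15), 820)
  expect_equal(to_cpm(820, 60), 820)
  expect_equal(to_cpm(0, 15), 0)
  # 60-s cpm equals the sum of its four 15-s counts
  set.seed(4)
  s <- sample(0:400, 48, replace = TRUE)
  expect_equal(to_cpm(reintegrate(s, 15, 60), 60),
               as.numeric(colSums(matrix(s, nrow = 4))))
})

test_that("Choi detection flags >= 90-min zero runs and nothing shorter", {
  day <- rep(25L, 1200)  # 300 min of activity at 15 s
  z120 <- day; z120[401:880] <- 0L  # 120-min zero block
  wear <- detect_nonwear_choi(z120, 15)
  expect_identical(which(!wear), 401:880)
  z89 <- day; z89[401:(400 + 89 * 4)] <- 0L
  expect_true(all(detect_nonwear_choi(z89, 15)))
  expect_true(all(detect_nonwear_choi(day, 15)))
})

test_that("Choi tolerates short spikes flanked by long zero runs", {
  day <- rep(25L, 1200)
  # 45 min zeros, 2-min spike, 45 min zeros: one 92-min non-wear interval
  day[241:420] <- 0L
  day[421:428] <- 50L
  day[429:608] <- 0L
  wear <- detect_nonwear_choi(day, 15)
  expect_identical(which(!wear), 241:608)
  # same spike flanked by only 20 min of zeros is not merged
  day2 <- rep(25L, 1200)
  day2[241:320] <- 0L; day2[321:328] <- 50L; day2[329:408] <- 0L
  expect_true(all(detect_nonwear_choi(day2, 15)))
})

test_that("injected blocks are recovered exactly on noise-free days", {
  model <- sticky_state_model()
  em <- well_separated_emission()
  hits <- 0
  for (i in 1:10) {
    st <- simulate_states(model, 1200, seed = 100 + i)
    cts <- emit_counts(st, em, seed = 200 + i)
    nw <- inject_nonwear(cts$hip, 15,
                         nonwear_model(prob = 1, duration = c(90, 180)),
                         seed = 300 + i)
    wear <- detect_nonwear_choi(nw$counts, 15)
    expect_identical(!wear, nw$nonwear)
    hits <- hits + any(!wear)
  }
  expect_equal(hits, 10)
})

test_that("alignment keeps exactly the jointly worn epochs", {
  h <- rep(10L, 1200); w <- rep(30L, 1200)
  full <- align_pairs(h, w, 15)
  expect_equal(nrow(full), 1200)
  expect_equal(full$hip_cpm, rep(40, 1200))
  hip_wear <- rep(TRUE, 1200); hip_wear[1:480] <- FALSE
  part <- align_pairs(h, w, 15, hip_wear, rep(TRUE, 1200))
  expect_equal(part$epoch, 481:1200)
  expect_warning(none <- align_pairs(h, w, 15, rep(FALSE, 1200),
                                     rep(TRUE, 1200)),
                 "no epoch")
  expect_equal(nrow(none), 0)
  expect_error(align_pairs(h, w[1:100], 15), "mismatched")
})

test_that("exclusion removes participants with no valid matched days", {
  cfg <- simulation_config(n_participants = 6, n_days = 3,
                           day_minutes = 120, seed = 13,
                           nonwear = nonwear_model(prob = 0),
                           n_noncompliant = 2)
  study <- simulate_study(cfg)
  matched <- preprocess_study(study)
  exc <- exclude_participants(matched)
  expect_equal(length(unique(exc$matched$participant_id)), 4)
  expect_true(any(grepl("absent", exc$log$participant_id)) ||
                any(exc$log$decision == "excluded"))
  # a fully valid participant is retained
  expect_true("P001" %in% exc$matched$participant_id)
})

test_that("epoch CSV round trip preserves the study", {
  cfg <- simulation_config(n_participants = 2, n_days = 1, day_minutes = 10,
                           seed = 3, nonwear = nonwear_model(prob = 0))
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study_csv(study, dir)
  back <- read_study_csv(dir)
  expect_equal(back$hip_count, study$epochs$hip_count)
  expect_equal(back$wrist_count, study$epochs$wrist_count)
  expect_equal(attr(back, "epoch_length"), 15)
})

test_that("epoch CSV reader prefers vm and falls back to axes", {
  df <- data.frame(participant_id = "P1", day = 1, placement = "hip",
                   epoch_start = "2018-10-01T09:00:00", epoch_length_s = 15,
                   axis1 = c(3, 1), axis2 = c(4, 2), axis3 = c(0, 2),
                   vm = c(99, 98))
  p <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(df, p)
  expect_message(got <- read_epoch_csv(p), "using vm")
  expect_equal(got$vm, c(99L, 98L))
  df$vm <- NULL
  write_epoch_csv(df, p)
  expect_equal(read_epoch_csv(p)$vm, c(5L, 3L))
  df$axis2 <- NULL
  write_epoch_csv(df, p)
  expect_error(read_epoch_csv(p), "axis1..axis3 or vm")
})

test_that("ActiLife-style preamble is skipped by timestamp detection", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "------------ Data File Created By ActiGraph ------------",
    "Serial Number: XYZ123",
    "Start Time 09:00:00",
    "09:00:00,3,4,0",
    "09:00:15,1,2,2"
  ), p)
  got <- read_actilife_csv(p, epoch_length_s = 15)
  expect_equal(nrow(got), 2)
  expect_equal(got$vm, c(5L, 3L))
})
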