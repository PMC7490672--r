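test_that("confusion matrices count (reference, comparison) pairs", {
  ident <- confusion(c("SB", "LPA"), c("SB", "LPA"),
                     levels = intensity_levels())
  expect_equal(sum(diag(ident)), 2)
  expect_equal(sum(ident) - sum(diag(ident)), 0)
  m <- confusion(c("SB", "SB", "LPA"), c("SB", "LPA", "LPA"),
                 levels = intensity_levels())
  expect_equal(m["SB", "SB"], 1L)
  expect_equal(m["SB", "LPA"], 1L)
  expect_equal(m["LPA", "LPA"], 1L)
  expect_warning(z <- confusion(character(), character(),
                                levels = intensity_levels()), "empty")
  expect_true(all(z == 0))
  expect_error(confusion(1:3, 1:2), "equal length")
})

test_that("one-vs-rest metrics follow the 2x2 formulas", {
  m <- confusion(rep(c("SB", "LPA"), c(3, 2)), rep(c("SB", "LPA"), c(3, 2)),
                 levels = intensity_levels())
  got <- one_vs_rest_metrics(m, "SB")
  expect_equal(unname(got), c(100, 100, 0, 0))
  # TP=45 FN=15 FP=25 TN=15
  m2 <- matrix(c(45, 15, 25, 15), 2, 2, byrow = TRUE,
               dimnames = list(reference = c("SB", "rest"),
                               comparison = c("SB", "rest")))
  got2 <- one_vs_rest_metrics(m2, "SB")
  expect_equal(got2[["sensitivity"]], 75)
  expect_equal(got2[["specificity"]], 37.5)
  expect_equal(got2[["fpr"]], 62.5)
  expect_equal(got2[["fnr"]], 25)
  # absent reference class -> undefined, not 0 or 100
  m3 <- confusion(rep("SB", 4), rep(c("SB", "LPA"), 2),
                  levels = intensity_levels())
  expect_true(is.na(one_vs_rest_metrics(m3, "MPA")[["sensitivity"]]))
})

test_that("complement identities hold for every class on random matrices", {
  set.seed(19)
  for (trial in 1:50) {
    m <- random_confusion()
    for (lv in intensity_levels()) {
      v <- one_vs_rest_metrics(m, lv)
      if (!is.na(v[["specificity"]])) {
        expect_equal(v[["fpr"]], 100 - v[["specificity"]])
      }
      if (!is.na(v[["sensitivity"]])) {
        expect_equal(v[["fnr"]], 100 - v[["sensitivity"]])
      }
    }
  }
})

test_that("Cohen kappa matches the definition and its edge cases", {
  expect_equal(cohen_kappa(c("SB", "LPA", "MPA"), c("SB", "LPA", "MPA")), 1)
  # hand-evaluated binarised table: po = 0.60, pe = 0.54
  ref <- rep(c("pos", "pos", "neg", "neg"), c(45, 15, 25, 15))
  comp <- rep(c("pos", "neg", "pos", "neg"), c(45, 15, 25, 15))
  expect_equal(cohen_kappa(ref, comp, levels = c("pos", "neg")),
               0.06 / 0.46, tolerance = 1e-9)
  # both labelings constant and equal -> undefined
  expect_true(is.na(cohen_kappa(rep("SB", 5), rep("SB", 5),
                                levels = c("SB", "LPA"))))
  # independent labelings hover at zero
  set.seed(29)
  a <- sample(intensity_levels(), 100000, replace = TRUE)
  b <- sample(intensity_levels(), 100000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.01)
})

test_that("kappa equals brute-force evaluation on random matrices", {
  set.seed(37)
  for (trial in 1:60) {
    m <- random_confusion()
    if (sum(m) == 0) next
    expect_equal(accelcal:::kappa_from_matrix(m), brute_kappa(m),
                 tolerance = 1e-12)
  }
  # independent route: e1071 agreement coefficient
  set.seed(38)
  a <- sample(intensity_levels(), 2000, replace = TRUE, prob = c(6, 3, 1, 1))
  b <- ifelse(stats::runif(2000) < 0.7, a,
              sample(intensity_levels(), 2000, replace = TRUE))
  expect_equal(cohen_kappa(a, b),
               e1071::classAgreement(table(a, b))$kappa, tolerance = 1e-10)
})

test_that("overall agreement is the normalised trace", {
  d <- diag(c(5L, 3L, 2L, 1L))
  dimnames(d) <- list(reference = intensity_levels(),
                      comparison = intensity_levels())
  expect_equal(overall_agreement(d), 100)
  u <- matrix(10L, 4, 4, dimnames = dimnames(d))
  expect_equal(overall_agreement(u), 25)
  m <- u; diag(m) <- c(7151, 0, 0, 0); m[1, 2] <- 10000 - 7151 - 120
  expect_equal(overall_agreement(m), 100 * sum(diag(m)) / sum(m))
})

test_that("pooling MVPA never lowers overall agreement", {
  set.seed(41)
  for (trial in 1:30) {
    n <- 400
    ref <- as_intensity(sample(0:3, n, replace = TRUE,
                               prob = c(0.6, 0.3, 0.06, 0.04)))
    comp <- as_intensity(pmin(pmax(as.integer(ref) - 1 +
                                     sample(0:2, n, replace = TRUE), 1),
                              4) - 1)
    m4 <- confusion(ref, comp, intensity_levels())
    m3 <- confusion(group_mvpa(ref), group_mvpa(comp),
                    intensity_levels(TRUE))
    expect_gte(overall_agreement(m3), overall_agreement(m4))
  }
})

test_that("agreement reports carry the grouped MVPA block", {
  d <- make_linked_training(n = 3000, seed = 91)
  wl <- classify(d$wrist_cpm, kmeans_calibrate(d$wrist_cpm)$cuts)
  rep4 <- agreement_report(d$hip_label, wl, "kmeans")
  expect_equal(nrow(rep4$per_class), 5)
  expect_gte(rep4$overall_grouped["correct"], rep4$overall["correct"])
  # 3-level comparison: only SB / LPA / MVPA rows are defined
  jl <- classify(d$wrist_cpm, johansson_wrist(sb_upper = 2624))
  rep3 <- agreement_report(d$hip_label, jl, "johansson")
  expect_true(all(is.na(
    rep3$per_class[rep3$per_class$class %in% c("MPA", "VPA"), "kappa"])))
  expect_true(is.na(rep3$overall["correct"]))
  expect_false(is.na(rep3$overall_grouped["correct"]))
})

test_that("class tallies reproduce count shares with half-up rounding", {
  lab <- rep(intensity_levels(), c(640, 280, 55, 25))
  t <- tally_labels(lab)
  expect_equal(t$n[t$class == "Total"], 1000)
  expect_equal(t$n[t$class == "MVPA"], 80)
  expect_equal(sum(t$pct[1:4]), 100, tolerance = 0.11)
  expect_error(tally_from_counts(c(SB = 1, LPA = 2)), "named")
})

test_that("daily time partitions wear time and is additive", {
  allsb <- daily_time(rep("SB", 1200), 15)
  expect_equal(allsb[["SB"]], 300)
  expect_equal(allsb[["MVPA"]], 0)
  set.seed(43)
  lab <- sample(intensity_levels(), 800, replace = TRUE)
  dt <- daily_time(lab, 15)
  expect_equal(sum(dt[intensity_levels()]), 200)  # 800 epochs = 200 min
  # additivity over concatenated days
  lab2 <- sample(intensity_levels(), 400, replace = TRUE)
  expect_equal(daily_time(c(lab, lab2), 15),
               daily_time(lab, 15) + daily_time(lab2, 15))
})

test_that("daily estimate summaries handle degenerate day counts", {
  matched <- data.frame(participant_id = "P001", day = 1, epoch = 1:8,
                        hip_cpm = 0, wrist_cpm = 0)
  lab <- list(m = rep("SB", 8))
  est <- estimate_table(matched, lab, 15)
  expect_equal(est$summary$mean[est$summary$class == "SB"], 2)
  expect_true(is.na(est$summary$sd[est$summary$class == "SB"]))
  # two identical days -> SD 0; percentages sum to 100
  matched2 <- data.frame(participant_id = "P001", day = rep(1:2, each = 8),
                         epoch = rep(1:8, 2), hip_cpm = 0, wrist_cpm = 0)
  lab2 <- list(m = rep(c("SB", "LPA"), 8))
  est2 <- estimate_table(matched2, lab2, 15)
  s <- est2$summary
  expect_equal(s$sd[s$class == "SB"], 0)
  expect_equal(sum(s$pct[s$class %in% intensity_levels()]), 100)
})

test_that("paired bootstrap comparison flags real and null differences", {
  matched <- data.frame(participant_id = rep(sprintf("P%02d", 1:10),
                                             each = 8),
                        day = 1, epoch = rep(1:8, 10),
                        hip_cpm = 0, wrist_cpm = 0)
  set.seed(47)
  base <- sample(intensity_levels(), 80, replace = TRUE)
  est <- estimate_table(matched, list(a = base, b = base), 15)
  self <- compare_methods(est, "a", "b", "SB", seed = 3)
  expect_equal(self$difference, 0)
  expect_equal(self$ci, c(0, 0))
  # constant +2 min/day offset: flip 8 SB epochs per day to LPA
  shifted <- base
  for (d in unique(paste(matched$participant_id, matched$day))) {
    ix <- which(paste(matched$participant_id, matched$day) == d)
    shifted[ix] <- "LPA"
  }
  est2 <- estimate_table(matched, list(a = base, b = shifted), 15)
  cmp <- compare_methods(est2, "a", "b", "LPA", seed = 3)
  expect_gt(cmp$difference, 0)
  expect_false(cmp$covers_zero)
})

test_that("bootstrap interval covers a true null about 95% of the time", {
  set.seed(53)
  cover <- 0
  n_rep <- 100
  for (r in 1:n_rep) {
    d <- stats::rnorm(20, 0, 5)  # paired daily differences under the null
    boots <- vapply(1:400, function(i) {
      mean(d[sample.int(20, replace = TRUE)])
    }, numeric(1))
    ci <- stats::quantile(boots, c(0.025, 0.975))
    cover <- cover + (ci[1] <= 0 && ci[2] >= 0)
  }
  expect_gte(cover / n_rep, 0.88)
  expect_lte(cover / n_rep, 0.995)
})
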