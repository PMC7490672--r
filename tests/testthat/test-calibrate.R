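test_that("a single ROC dichotomy equalises sensitivity and specificity", {
  vals <- c(100, 200, 1000, 1100)
  pos <- c(FALSE, FALSE, TRUE, TRUE)
  got <- accelcal:::roc_threshold(vals, pos)
  expect_equal(got$threshold, 200)
  expect_equal(got$sensitivity, 1)
  expect_equal(got$specificity, 1)
  expect_error(accelcal:::roc_threshold(rep(7, 10), rep(c(TRUE, FALSE), 5)),
               "identical")
})

test_that("ROC threshold matches the brute-force scan on random data", {
  set.seed(17)
  for (trial in 1:40) {
    n <- sample(20:200, 1)
    vals <- sample(0:500, n, replace = TRUE)
    pos <- vals + stats::rnorm(n, 0, 150) > 250
    if (sum(pos) == 0 || sum(!pos) == 0 || length(unique(vals)) < 2) next
    expect_equal(accelcal:::roc_threshold(vals, pos)$threshold,
                 brute_roc(vals, pos))
  }
})

test_that("ROC calibration recovers a generating cut-point partition", {
  d <- make_linked_training(n = 4000, seed = 51)
  cal <- roc_calibrate(d$wrist_cpm, d$hip_label)
  relabelled <- classify(d$wrist_cpm, cal$cuts)
  expect_equal(as.character(relabelled), as.character(d$hip_label))
  expect_equal(cal$diagnostics$sensitivity, rep(1, 3))
  expect_equal(cal$diagnostics$specificity, rep(1, 3))
})

test_that("crossing ROC thresholds raise an error", {
  # pathological labelling: VPA sits in the middle of the cpm range
  x <- c(1:50, 301:350, 101:150, 201:250)
  y <- rep(c("SB", "LPA", "VPA", "MPA"), each = 50)
  expect_error(roc_calibrate(x, y), "crossing thresholds")
})

test_that("OLR recovers known ordinal-logit parameters within 3 SE", {
  set.seed(7)
  n <- 8000
  x <- round(stats::rlnorm(n, log(2000), 1))
  a <- c(6, 9, 11); b <- 0.002
  u <- stats::runif(n)
  Fm <- sapply(a, function(ak) stats::plogis(ak - b * x))
  y <- intensity_levels()[1 + (u > Fm[, 1]) + (u > Fm[, 2]) + (u > Fm[, 3])]
  fit <- olr_calibrate(x, y)
  d <- fit$diagnostics
  expect_true(d$converged)
  expect_true(all(abs(d$alpha - a) / d$se_alpha < 3))
  expect_lt(abs(d$beta - b) / d$se_beta, 3)
  # independent maximum-likelihood fit agrees
  pf <- suppressWarnings(MASS::polr(as_intensity(y) ~ x,
                                    method = "logistic"))
  expect_equal(d$alpha, unname(pf$zeta), tolerance = 1e-3)
  expect_equal(d$beta, unname(stats::coef(pf)), tolerance = 1e-3)
})

test_that("OLR argmax classes form contiguous cpm intervals", {
  d <- make_linked_training(n = 4000, seed = 61)
  fit <- olr_calibrate(d$wrist_cpm, d$hip_label)
  lab <- classify(d$wrist_cpm, fit$cuts)
  o <- order(d$wrist_cpm)
  expect_true(all(diff(as.integer(lab[o])) >= 0))
})

test_that("OLR refuses degenerate training tables", {
  expect_error(olr_calibrate(c(1, 2, 3), c("SB", "LPA", "MPA")),
               "must be present")
  expect_error(olr_calibrate(rep(5, 8), rep(intensity_levels(), 2)),
               "constant")
  # a class that never wins the argmax is an explicit error
  set.seed(42)
  x <- c(round(stats::runif(500, 0, 800)),
         round(stats::runif(400, 1000, 8000)),
         round(stats::runif(4, 1000, 8000)),
         round(stats::runif(150, 8500, 20000)))
  y <- rep(c("SB", "LPA", "MPA", "VPA"), c(500, 400, 4, 150))
  expect_error(olr_calibrate(x, y), "empty predicted class: MPA")
})

test_that("k-means DP solves small configurations exactly", {
  cal <- kmeans_calibrate(c(1, 2, 10, 11, 20, 21, 30, 31), k = 4)
  expect_equal(cal$cuts$boundaries, c(2, 11, 21))
  expect_equal(cal$diagnostics$tot_withinss, 4 * 0.25 * 2)
  degen <- kmeans_calibrate(c(0, 0, 0, 0, 1, 2, 3), k = 4)
  expect_equal(degen$diagnostics$tot_withinss, 0)
  expect_error(kmeans_calibrate(c(1, 1, 2, 2), k = 4), "distinct")
})

test_that("k-means DP equals exhaustive search and bounds Lloyd", {
  set.seed(23)
  for (trial in 1:60) {
    n <- sample(5:12, 1)
    x <- sample(0:100, n, replace = TRUE)
    if (length(unique(x)) < 4) next
    dp <- kmeans_calibrate(x, k = 4)
    ex <- brute_kmeans_wcss(x, 4)
    expect_equal(dp$diagnostics$tot_withinss, ex$wcss, tolerance = 1e-9)
  }
  x <- round(stats::rlnorm(400, log(800), 1))
  if (length(unique(x)) >= 4) {
    dp <- kmeans_calibrate(x, k = 4)$diagnostics$tot_withinss
    ll <- kmeans_calibrate(x, k = 4, method = "lloyd",
                           seed = 5)$diagnostics$tot_withinss
    expect_lte(dp, ll + 1e-6)
  }
})

test_that("class summaries report counts, moments and undefined flags", {
  s <- summarize_classes(c(1, 3), rep("SB", 2), levels = intensity_levels())
  expect_equal(s$mean[1], 2)
  expect_equal(s$sd[1], sqrt(2))
  expect_equal(s$n[-1], rep(0, 3))
  expect_true(all(is.na(s$mean[-1])))
  one <- summarize_classes(5, "LPA", levels = intensity_levels())
  expect_equal(one$n[2], 1)
  expect_true(is.na(one$sd[2]))
})

test_that("per-class means increase with intensity in every calibration", {
  d <- make_linked_training(n = 4000, seed = 71)
  for (cal in calibrate_all(d$wrist_cpm, d$hip_label)) {
    mu <- cal$classes$mean[cal$classes$n > 0]
    expect_true(all(diff(mu) > 0))
    expect_equal(sum(cal$classes$n), length(d$wrist_cpm))
  }
})

test_that("calibrations are invariant to epoch order", {
  d <- make_linked_training(n = 3000, seed = 81)
  set.seed(82)
  p <- sample(length(d$wrist_cpm))
  a <- calibrate_all(d$wrist_cpm, d$hip_label)
  b <- calibrate_all(d$wrist_cpm[p], d$hip_label[p])
  expect_identical(a$roc$cuts$boundaries, b$roc$cuts$boundaries)
  expect_identical(a$kmeans$cuts$boundaries, b$kmeans$cuts$boundaries)
  expect_equal(a$olr$cuts$boundaries, b$olr$cuts$boundaries,
               tolerance = 1e-8)
})
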