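#' Per-class count summaries
#'
#' Class-conditional count statistics in the layout of a calibration report:
#' per class, the number of epochs, observed lower and upper bound, mean and
#' sample SD (n - 1 denominator). Empty classes are reported with `n = 0`
#' and `NA` statistics (explicitly undefined, never silently zero).
#'
#' @param values numeric cpm values.
#' @param labels parallel factor of class labels.
#' @param levels class ordering; defaults to the factor's levels.
#' @return data frame with columns `level`, `n`, `lower`, `upper`, `mean`,
#'   `sd`, ordered lowest to highest intensity.
#' @export
summarize_classes <- function(values, labels, levels = NULL) {
  if (length(values) != length(labels)) {
    abort("values and labels must have equal length")
  }
  if (is.null(levels)) {
    levels <- if (is.factor(labels)) base::levels(labels)
      else intensity_levels()
  }
  labels <- factor(as.character(labels), levels = levels)
  out <- lapply(levels, function(lv) {
    v <- values[!is.na(labels) & labels == lv]
    data.frame(level = lv, n = length(v),
               lower = if (length(v)) min(v) else NA_real_,
               upper = if (length(v)) max(v) else NA_real_,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  do.call(rbind, out)
}

# internal: package a calibration into the common result structure
calibration_result <- function(method, cuts, values, diagnostics) {
  labels <- classify(values, cuts)
  cls <- summarize_classes(values, labels, levels = cuts$levels)
  if (sum(cls$n) != length(values)) {
    abort("internal error: class counts do not sum to the input size")
  }
  mu <- cls$mean[cls$n > 0]
  if (length(mu) > 1 && any(diff(mu) <= 0)) {
    abort("internal error: class means not strictly increasing")
  }
  structure(list(method = method, cuts = cuts, classes = cls,
                 diagnostics = diagnostics),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> method:", x$method, "\n")
  b <- x$cuts$boundaries
  lo <- c(0, b + 1); hi <- c(b, Inf)
  df <- x$classes
  cat(sprintf("  %-5s %8s %10s %10s %12s %12s\n",
              "class", "n", "lower", "upper", "mean", "sd"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-5s %8d %10s %10s %12s %12s\n", df$level[i], df$n[i],
                format(lo[i]), if (is.finite(hi[i])) format(hi[i]) else "Inf",
                ifelse(is.na(df$mean[i]), "undefined",
                       sprintf("%.2f", df$mean[i])),
                ifelse(is.na(df$sd[i]), "undefined",
                       sprintf("%.2f", df$sd[i]))))
  }
  invisible(x)
}

#' @export
as.data.frame.calibration_result <- function(x, ...) {
  b <- x$cuts$boundaries
  cbind(method = x$method, x$classes,
        cut_lower = c(0, b + 1), cut_upper = c(b, Inf))
}

# internal: one cumulative ROC dichotomy. positive = higher-intensity side,
# predicate cpm > t; candidates are the observed unique values, over which
# |sens - spec| is piecewise constant, so the finite scan is exact.
roc_threshold <- function(values, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) {
    abort("both sides of the dichotomy must be represented")
  }
  cand <- sort(unique(values))
  if (length(cand) < 2) {
    abort("all wrist cpm values are identical; no threshold separates ",
          "anything")
  }
  pos_le <- cumsum(tabulate(findInterval(values[positive], cand),
                            nbins = length(cand)))
  neg_le <- cumsum(tabulate(findInterval(values[!positive], cand),
                            nbins = length(cand)))
  sens <- (n_pos - pos_le) / n_pos
  spec <- neg_le / n_neg
  d <- abs(sens - spec)
  i <- which.min(d)  # first minimum = smallest threshold (deterministic)
  list(threshold = cand[i], sensitivity = sens[i], specificity = spec[i])
}

#' ROC threshold-search calibration
#'
#' Derives wrist cut points from hip-reference labels by three cumulative
#' dichotomies — SB vs above, SB+LPA vs above, below-VPA vs VPA. Each
#' dichotomy is scanned over the observed unique wrist cpm values
#' (positive = cpm above the threshold); the selected threshold minimises
#' the absolute difference between sensitivity and specificity, ties broken
#' toward the smallest threshold. The three thresholds become
#' `(t1, t2, t3)`; because the dichotomies are fitted independently they
#' can cross on pathological data, which is an error.
#'
#' @param wrist_cpm integer wrist cpm values.
#' @param hip_label parallel hip-reference intensity labels (4 levels).
#' @return a `calibration_result` with per-dichotomy sensitivity /
#'   specificity diagnostics.
#' @export
roc_calibrate <- function(wrist_cpm, hip_label) {
  hip_label <- as_intensity(hip_label)
  if (length(wrist_cpm) != length(hip_label)) {
    abort("wrist_cpm and hip_label must have equal length")
  }
  lv <- intensity_levels()
  res <- lapply(1:3, function(j) {
    roc_threshold(wrist_cpm, positive = as.integer(hip_label) > j)
  })
  th <- vapply(res, `[[`, numeric(1), "threshold")
  if (any(diff(th) <= 0)) {
    abort("crossing thresholds: the three dichotomies selected (",
          paste(th, collapse = ", "),
          "), which do not increase strictly")
  }
  cuts <- cut_point_set("roc", "wrist", floor(th))
  diag <- data.frame(
    boundary = paste(lv[1:3], lv[2:4], sep = "/"),
    threshold = th,
    sensitivity = vapply(res, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(res, `[[`, numeric(1), "specificity"))
  calibration_result("roc", cuts, wrist_cpm, diag)
}

# internal: negative penalised log-likelihood of the proportional-odds
# cumulative-logit model. theta = (a1, a2, a3, b) on the scaled-x scale;
# logit P(Y <= k) = a_k - b x.
olr_nll <- function(theta, x, y, ridge) {
  a <- theta[1:3]; b <- theta[4]
  if (any(diff(a) <= 0)) return(1e10 + sum(theta^2))
  eta <- outer(x, a, function(xx, aa) aa - b * xx)
  Fk <- cbind(0, stats::plogis(eta), 1)
  p <- Fk[cbind(seq_along(y), y + 1L)] - Fk[cbind(seq_along(y), y)]
  p <- pmax(p, 1e-300)
  -sum(log(p)) + ridge * b^2
}

olr_grad <- function(theta, x, y, ridge) {
  a <- theta[1:3]; b <- theta[4]
  if (any(diff(a) <= 0)) return(2 * theta)
  n <- length(y)
  eta <- outer(x, a, function(xx, aa) aa - b * xx)
  Fk <- cbind(0, stats::plogis(eta), 1)
  fk <- cbind(0, stats::dlogis(eta), 0)
  p <- pmax(Fk[cbind(seq_len(n), y + 1L)] - Fk[cbind(seq_len(n), y)], 1e-300)
  w_hi <- fk[cbind(seq_len(n), y + 1L)] / p   # d p / d a_{y}
  w_lo <- fk[cbind(seq_len(n), y)] / p        # d p / d a_{y-1} (negated)
  ga <- numeric(3)
  for (k in 1:3) {
    ga[k] <- -(sum(w_hi[y == k]) - sum(w_lo[y == k + 1L]))
  }
  gb <- sum(x * (w_hi - w_lo))
  c(ga, gb + 2 * ridge * b)
}

#' Ordinal (cumulative-logit) regression calibration
#'
#' Fits a proportional-odds model of the hip-reference intensity level on
#' wrist cpm (one predictor, three ordered intercepts, one slope) by
#' penalised maximum likelihood (ridge `1e-6` on the slope guards against
#' quasi-separable data), assigns each epoch to the class with the highest
#' predicted probability, and reads the cut points off the assignment: the
#' SB bound is the maximum cpm assigned SB; the MPA and VPA bounds are the
#' minimum cpm assigned to those classes (minus one on the integer grid);
#' LPA spans in between. With a positive slope the argmax class is
#' non-decreasing in cpm, so predicted classes form contiguous intervals.
#'
#' @param wrist_cpm integer wrist cpm values.
#' @param hip_label parallel hip-reference labels; all four classes must be
#'   present.
#' @param ridge ridge penalty on the (scaled) slope.
#' @param maxit optimiser iteration cap.
#' @return a `calibration_result`; diagnostics hold the fitted intercepts,
#'   slope (per cpm), standard errors and convergence status.
#' @export
olr_calibrate <- function(wrist_cpm, hip_label, ridge = 1e-6, maxit = 500) {
  hip_label <- as_intensity(hip_label)
  if (length(wrist_cpm) != length(hip_label)) {
    abort("wrist_cpm and hip_label must have equal length")
  }
  if (any(table(hip_label) == 0)) {
    abort("all four intensity classes must be present for supervised ",
          "calibration; missing: ",
          paste(names(which(table(hip_label) == 0)), collapse = ", "))
  }
  sx <- stats::sd(wrist_cpm)
  if (!is.finite(sx) || sx == 0) abort("wrist_cpm is constant")
  xs <- wrist_cpm / sx
  y <- as.integer(hip_label)
  # start from the empirical cumulative logits at slope 0
  cum <- cumsum(prop.table(table(y)))[1:3]
  theta0 <- c(unname(stats::qlogis(cum)), 1)
  fit <- stats::optim(theta0, olr_nll, olr_grad, x = xs, y = y,
                      ridge = ridge, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  a <- unname(fit$par[1:3]); b <- unname(fit$par[4])
  se <- rep(NA_real_, 4)
  H <- try(stats::optimHess(fit$par, olr_nll, olr_grad, x = xs, y = y,
                            ridge = ridge), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) se <- sqrt(diag(V))
  }
  # argmax-probability class per observed unique cpm value
  ux <- sort(unique(wrist_cpm))
  Fk <- cbind(0, stats::plogis(outer(ux / sx, a,
                                     function(xx, aa) aa - b * xx)), 1)
  pk <- Fk[, 2:5, drop = FALSE] - Fk[, 1:4, drop = FALSE]
  cls <- max.col(pk, ties.method = "first")
  assigned <- cls[match(wrist_cpm, ux)]
  lv <- intensity_levels()
  for (k in 1:4) {
    if (!any(assigned == k)) {
      abort("empty predicted class: ", lv[k],
            " receives no argmax assignments")
    }
  }
  t1 <- max(wrist_cpm[assigned == 1])
  t2 <- min(wrist_cpm[assigned == 3]) - 1
  t3 <- min(wrist_cpm[assigned == 4]) - 1
  if (!(t1 < t2 && t2 < t3)) {
    abort("derived OLR bounds are not strictly increasing: ",
          paste(c(t1, t2, t3), collapse = ", "))
  }
  cuts <- cut_point_set("olr", "wrist", c(t1, t2, t3))
  diag <- list(alpha = a, beta = b / sx, se_alpha = se[1:3],
               se_beta = se[4] / sx, ridge = ridge,
               converged = fit$convergence == 0,
               logLik = -(fit$value - ridge * b^2))
  calibration_result("olr", cuts, wrist_cpm, diag)
}

#' Univariate k-means calibration (k = 4)
#'
#' Unsupervised calibration: clusters the wrist cpm values alone into `k`
#' groups minimising the within-cluster sum of squares, orders clusters by
#' centroid, and reads the cut points off the cluster extrema (upper bound
#' of each of the first `k - 1` clusters). The default solver is an exact
#' dynamic programme over the sorted unique values — deterministic and
#' provably optimal, with no seed; `method = "lloyd"` runs the classic
#' iterative heuristic (via [stats::kmeans()], 10 restarts) for comparison.
#'
#' @param wrist_cpm integer wrist cpm values (at least `k` distinct).
#' @param k number of clusters; 4 a priori for the four intensity states.
#' @param method `"dp"` (exact, default) or `"lloyd"`.
#' @param nstart Lloyd restarts.
#' @param seed seed for Lloyd initialisation.
#' @return a `calibration_result`; diagnostics hold centroids and
#'   within-cluster sums of squares.
#' @export
kmeans_calibrate <- function(wrist_cpm, k = 4, method = c("dp", "lloyd"),
                             nstart = 10, seed = 1) {
  method <- match.arg(method)
  ux <- sort(unique(wrist_cpm))
  if (length(ux) < k) {
    abort("need at least ", k, " distinct values, got ", length(ux))
  }
  if (method == "dp") {
    w <- tabulate(findInterval(wrist_cpm, ux), nbins = length(ux))
    sol <- kmeans_dp_cpp(ux, w, as.integer(k))
    cl_u <- sol$cluster
    centers <- sol$centers
    withinss <- sol$withinss
    assigned <- cl_u[match(wrist_cpm, ux)]
  } else {
    set.seed(seed)
    km <- stats::kmeans(wrist_cpm, centers = k, nstart = nstart,
                        iter.max = 100)
    ord <- order(km$centers)
    relab <- match(seq_len(k), ord)
    assigned <- relab[km$cluster]
    centers <- sort(as.numeric(km$centers))
    withinss <- km$withinss[ord]
  }
  bounds <- vapply(seq_len(k - 1), function(j) max(wrist_cpm[assigned == j]),
                   numeric(1))
  cuts <- cut_point_set("kmeans", "wrist", floor(bounds))
  diag <- list(method = method, centers = centers, withinss = withinss,
               tot_withinss = sum(withinss))
  calibration_result("kmeans", cuts, wrist_cpm, diag)
}

#' Run all three calibrations on a labelled training table
#'
#' @param wrist_cpm wrist cpm values.
#' @param hip_label parallel hip-reference labels.
#' @param kmeans_method `"dp"` or `"lloyd"`.
#' @param olr_ridge ridge penalty for the ordinal fit.
#' @param seed seed for the Lloyd option.
#' @return named list of `calibration_result`s (`roc`, `olr`, `kmeans`).
#' @export
calibrate_all <- function(wrist_cpm, hip_label, kmeans_method = "dp",
                          olr_ridge = 1e-6, seed = 1) {
  list(
    roc = roc_calibrate(wrist_cpm, hip_label),
    olr = olr_calibrate(wrist_cpm, hip_label, ridge = olr_ridge),
    kmeans = kmeans_calibrate(wrist_cpm, method = kmeans_method, seed = seed)
  )
}
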