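#' Confusion matrix of reference vs comparison labels
#'
#' Rows are reference labels, columns comparison labels.
#'
#' @param reference,comparison equal-length label vectors/factors.
#' @param levels label set defining the matrix dimensions (default: the
#'   union of levels of the two inputs, in reference order).
#' @return integer matrix with class counts; a zero matrix with a warning
#'   for empty input.
#' @export
confusion <- function(reference, comparison, levels = NULL) {
  if (length(reference) != length(comparison)) {
    abort("reference and comparison must have equal length")
  }
  if (is.null(levels)) {
    levels <- if (is.factor(reference)) base::levels(reference)
      else unique(c(as.character(reference), as.character(comparison)))
  }
  if (!length(reference)) {
    warning("empty label sequences; zero confusion matrix", call. = FALSE)
  }
  r <- factor(as.character(reference), levels = levels)
  c_ <- factor(as.character(comparison), levels = levels)
  m <- table(reference = r, comparison = c_)
  matrix(as.integer(m), nrow = length(levels),
         dimnames = list(reference = levels, comparison = levels))
}

#' One-vs-rest classification metrics for a class
#'
#' Collapses the confusion matrix to 2x2 for the given class and reports
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and their
#' complements FPR `= 100 - specificity` and FNR `= 100 - sensitivity`,
#' all in percent. A `0/0` ratio is reported as `NA` (undefined), never as
#' 0 or 100.
#'
#' @param m confusion matrix from [confusion()].
#' @param class class (row/column name) to evaluate.
#' @return named numeric vector `sensitivity`, `specificity`, `fpr`, `fnr`.
#' @export
one_vs_rest_metrics <- function(m, class) {
  if (!class %in% rownames(m)) abort("class ", class, " not in the matrix")
  i <- which(rownames(m) == class)
  tp <- m[i, i]
  fn <- sum(m[i, -i])
  fp <- sum(m[-i, i])
  tn <- sum(m[-i, -i])
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  c(sensitivity = sens, specificity = spec,
    fpr = if (is.na(spec)) NA_real_ else 100 - spec,
    fnr = if (is.na(sens)) NA_real_ else 100 - sens)
}

# internal: kappa from a square confusion matrix
kappa_from_matrix <- function(m) {
  n <- sum(m)
  if (n == 0) return(NA_real_)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Cohen kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with `p_e` the
#' marginal-product chance agreement. When both labelings are constant and
#' equal (`p_e = 1`) kappa is undefined and `NA` is returned.
#'
#' @param reference,comparison equal-length label sequences.
#' @param levels label set (default: levels of `reference`).
#' @return kappa in `[-1, 1]`, or `NA` if undefined.
#' @export
cohen_kappa <- function(reference, comparison, levels = NULL) {
  kappa_from_matrix(confusion(reference, comparison, levels))
}

#' Per-class (one-vs-rest binarised) kappa
#'
#' Kappa of the binarised labelings "is class k" vs "is not class k" — the
#' construction behind a kappa-per-intensity-level row.
#'
#' @inheritParams cohen_kappa
#' @param class the class to binarise on.
#' @return kappa of the binarised sequences.
#' @export
class_kappa <- function(reference, comparison, class) {
  r <- ifelse(as.character(reference) == class, class, "rest")
  c_ <- ifelse(as.character(comparison) == class, class, "rest")
  cohen_kappa(r, c_, levels = c(class, "rest"))
}

#' Overall correct classification percentage
#'
#' @param m confusion matrix.
#' @return `trace / total * 100`; `NA` for an empty matrix.
#' @export
overall_agreement <- function(m) {
  n <- sum(m)
  if (n == 0) return(NA_real_)
  100 * sum(diag(m)) / n
}

#' Full agreement report of a wrist method against the hip reference
#'
#' Per-class sensitivity / specificity / FPR / FNR / kappa, overall
#' accuracy and kappa, and the same block with MPA and VPA pooled into
#' MVPA. A 3-level comparison labeling (e.g. a reference that does not
#' split MPA from VPA) is evaluated against the MVPA-grouped reference
#' only; its 4-class rows are reported as `NA`.
#'
#' @param reference 4-level hip-reference labels.
#' @param comparison wrist labels (4-level, or 3-level SB/LPA/MVPA).
#' @param method method name carried into the report.
#' @return object of class `agreement_report`: list with `per_class` (data
#'   frame, one row per 4-level class plus an MVPA row), `overall`
#'   (accuracy and kappa), `overall_grouped`, and `method`.
#' @export
agreement_report <- function(reference, comparison, method = "wrist") {
  reference <- as_intensity(reference)
  three_level <- all(as.character(comparison) %in%
                       intensity_levels(mvpa_grouped = TRUE)) &&
    any(as.character(comparison) == "MVPA")
  ref_g <- group_mvpa(reference)
  comp_g <- if (three_level) {
    as_intensity(as.character(comparison),
                 levels = intensity_levels(mvpa_grouped = TRUE))
  } else group_mvpa(as_intensity(comparison))

  rows <- list()
  if (!three_level) {
    comparison <- as_intensity(comparison)
    m4 <- confusion(reference, comparison, intensity_levels())
    for (lv in intensity_levels()) {
      met <- one_vs_rest_metrics(m4, lv)
      rows[[lv]] <- data.frame(class = lv, t(met),
                               kappa = class_kappa(reference, comparison,
                                                   lv))
    }
    overall <- c(correct = overall_agreement(m4),
                 kappa = kappa_from_matrix(m4))
  } else {
    for (lv in c("SB", "LPA")) {
      m3 <- confusion(ref_g, comp_g, intensity_levels(TRUE))
      met <- one_vs_rest_metrics(m3, lv)
      rows[[lv]] <- data.frame(class = lv, t(met),
                               kappa = class_kappa(ref_g, comp_g, lv))
    }
    for (lv in c("MPA", "VPA")) {
      rows[[lv]] <- data.frame(class = lv, sensitivity = NA_real_,
                               specificity = NA_real_, fpr = NA_real_,
                               fnr = NA_real_, kappa = NA_real_)
    }
    overall <- c(correct = NA_real_, kappa = NA_real_)
  }
  m3 <- confusion(ref_g, comp_g, intensity_levels(TRUE))
  met <- one_vs_rest_metrics(m3, "MVPA")
  rows[["MVPA"]] <- data.frame(class = "MVPA", t(met),
                               kappa = class_kappa(ref_g, comp_g, "MVPA"))
  per_class <- do.call(rbind, rows)
  rownames(per_class) <- NULL
  structure(list(method = method, per_class = per_class, overall = overall,
                 overall_grouped = c(correct = overall_agreement(m3),
                                     kappa = kappa_from_matrix(m3))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> method:", x$method, "\n")
  df <- x$per_class
  num <- vapply(seq_len(nrow(df)), function(i) {
    sprintf("  %-5s sens %6s  spec %6s  fpr %6s  fnr %6s  kappa %5s",
            df$class[i],
            ifelse(is.na(df$sensitivity[i]), "N/A",
                   sprintf("%.2f", df$sensitivity[i])),
            ifelse(is.na(df$specificity[i]), "N/A",
                   sprintf("%.2f", df$specificity[i])),
            ifelse(is.na(df$fpr[i]), "N/A", sprintf("%.2f", df$fpr[i])),
            ifelse(is.na(df$fnr[i]), "N/A", sprintf("%.2f", df$fnr[i])),
            ifelse(is.na(df$kappa[i]), "N/A", sprintf("%.2f", df$kappa[i])))
  }, character(1))
  cat(num, sep = "\n")
  ov <- function(v) {
    sprintf("correct %s%%, kappa %s",
            ifelse(is.na(v["correct"]), "N/A", sprintf("%.2f", v["correct"])),
            ifelse(is.na(v["kappa"]), "N/A", sprintf("%.2f", v["kappa"])))
  }
  cat("\n  overall (4-class):", ov(x$overall), "\n")
  cat("  overall (MVPA grouped):", ov(x$overall_grouped), "\n")
  invisible(x)
}

#' Epoch tally by intensity class
#'
#' The class-share table: per class the epoch count and the percentage of
#' all epochs (rounded half-up to one decimal), plus the total and the
#' MVPA (MPA + VPA) merge.
#'
#' @param labels intensity labels, or (via [tally_from_counts()]) a named
#'   count vector.
#' @return data frame with columns `class`, `n`, `pct`; the last rows are
#'   `MVPA` and `Total`.
#' @export
tally_labels <- function(labels) {
  labels <- as_intensity(labels)
  tally_from_counts(table(labels))
}

#' @rdname tally_labels
#' @param counts named vector of per-class epoch counts
#'   (names SB, LPA, MPA, VPA).
#' @export
tally_from_counts <- function(counts) {
  lv <- intensity_levels()
  counts <- counts[lv]
  if (any(is.na(counts))) abort("counts must be named SB, LPA, MPA, VPA")
  total <- sum(counts)
  pct <- round_half_up(100 * as.numeric(counts) / total, 1)
  mvpa <- sum(counts[c("MPA", "VPA")])
  data.frame(
    class = c(lv, "MVPA", "Total"),
    n = c(as.numeric(counts), mvpa, total),
    pct = c(pct, round_half_up(100 * mvpa / total, 1), 100)
  )
}

#' Daily minutes per intensity class
#'
#' `minutes_c = n_epochs(c) * epoch_length / 60`, plus the MVPA merge.
#' Input labels should cover worn epochs only; the minutes then sum to the
#' day's wear time.
#'
#' @param labels one participant-day's intensity labels (worn epochs).
#' @param epoch_length epoch length, seconds.
#' @return named numeric vector of minutes (SB, LPA, MPA, VPA, MVPA).
#' @export
daily_time <- function(labels, epoch_length) {
  labels <- as_intensity(labels)
  mins <- as.numeric(table(labels)) * epoch_length / 60
  names(mins) <- intensity_levels()
  c(mins, MVPA = unname(mins["MPA"] + mins["VPA"]))
}

#' Daily physical-activity estimates per method
#'
#' Computes per participant-day minutes in each class for every labelling
#' method, then per-method mean and sample SD across participant-days and
#' the percent of wear time (`mean minutes / mean wear minutes * 100`).
#'
#' @param matched matched epoch table (`participant_id`, `day` columns).
#' @param labels_by_method named list of label vectors parallel to
#'   `matched` rows (3-level labels allowed; their MPA/VPA minutes are
#'   `NA`).
#' @param epoch_length epoch length, seconds.
#' @return object of class `daily_estimates`: list with `per_day` (long
#'   data frame) and `summary` (method x class mean, sd, pct).
#' @export
estimate_table <- function(matched, labels_by_method, epoch_length) {
  stopifnot(nrow(matched) >= 1, length(labels_by_method) >= 1)
  key <- paste(matched$participant_id, matched$day)
  days <- unique(key)
  per_day <- list()
  for (m in names(labels_by_method)) {
    lab <- labels_by_method[[m]]
    if (length(lab) != nrow(matched)) {
      abort("labels for method ", m, " do not match the epoch table")
    }
    three <- all(as.character(lab) %in% intensity_levels(TRUE)) &&
      any(as.character(lab) == "MVPA")
    for (d in days) {
      sub <- as.character(lab[key == d])
      wear <- length(sub) * epoch_length / 60
      if (three) {
        cnt <- table(factor(sub, levels = intensity_levels(TRUE)))
        mins <- as.numeric(cnt) * epoch_length / 60
        row <- data.frame(method = m, day_key = d, wear_min = wear,
                          SB = mins[1], LPA = mins[2], MPA = NA_real_,
                          VPA = NA_real_, MVPA = mins[3])
      } else {
        mins <- daily_time(sub, epoch_length)
        row <- data.frame(method = m, day_key = d, wear_min = wear,
                          SB = mins["SB"], LPA = mins["LPA"],
                          MPA = mins["MPA"], VPA = mins["VPA"],
                          MVPA = mins["MVPA"])
      }
      per_day[[length(per_day) + 1]] <- row
    }
  }
  per_day <- do.call(rbind, per_day)
  rownames(per_day) <- NULL
  cls <- c("SB", "LPA", "MPA", "VPA", "MVPA")
  summ <- list()
  for (m in names(labels_by_method)) {
    sub <- per_day[per_day$method == m, ]
    mean_wear <- mean(sub$wear_min)
    for (cl in cls) {
      v <- sub[[cl]]
      summ[[length(summ) + 1]] <- data.frame(
        method = m, class = cl,
        mean = if (all(is.na(v))) NA_real_ else mean(v),
        sd = if (all(is.na(v)) || length(v) < 2) NA_real_
          else stats::sd(v),
        pct = if (all(is.na(v))) NA_real_
          else 100 * mean(v) / mean_wear)
    }
  }
  structure(list(per_day = per_day, summary = do.call(rbind, summ)),
            class = "daily_estimates")
}

#' @export
print.daily_estimates <- function(x, ...) {
  s <- x$summary
  cat("<daily_estimates> per-method daily minutes, mean (SD), % wear\n")
  for (m in unique(s$method)) {
    cat(" ", m, "\n")
    sub <- s[s$method == m, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-5s %s (%s) min, %s%%\n", sub$class[i],
                  ifelse(is.na(sub$mean[i]), "N/A",
                         sprintf("%.2f", sub$mean[i])),
                  ifelse(is.na(sub$sd[i]), "N/A",
                         sprintf("%.2f", sub$sd[i])),
                  ifelse(is.na(sub$pct[i]), "N/A",
                         sprintf("%.1f", sub$pct[i]))))
    }
  }
  invisible(x)
}

#' Paired comparison of two methods' daily estimates
#'
#' Paired mean difference in daily minutes (comparison minus reference)
#' with a seeded percentile bootstrap 95% interval over participant-days.
#' "No statistical difference" corresponds to the interval covering zero.
#'
#' @param estimates a `daily_estimates` object.
#' @param reference,comparison method names present in the estimates.
#' @param class one of SB, LPA, MPA, VPA, MVPA.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return list with `difference` (mean paired difference, minutes),
#'   `ci` (length-2 percentile interval), `covers_zero`, and `n_pairs`.
#' @export
compare_methods <- function(estimates, reference, comparison, class,
                            n_boot = 2000, seed = 1) {
  stopifnot(inherits(estimates, "daily_estimates"))
  pd <- estimates$per_day
  a <- pd[pd$method == reference, c("day_key", class)]
  b <- pd[pd$method == comparison, c("day_key", class)]
  mg <- merge(a, b, by = "day_key")
  d <- mg[[paste0(class, ".y")]] - mg[[paste0(class, ".x")]]
  d <- d[!is.na(d)]
  if (length(d) < 2) abort("need at least 2 paired participant-days")
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(d[sample.int(length(d), replace = TRUE)])
  }, numeric(1))
  ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  list(difference = mean(d), ci = ci,
       covers_zero = ci[1] <= 0 && ci[2] >= 0, n_pairs = length(d))
}
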