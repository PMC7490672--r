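#' Pipeline configuration
#'
#' One config drives the whole study end-to-end: simulate (or ingest) →
#' preprocess → hip-label → calibrate (three methods) → validate → report.
#'
#' @param simulation a [simulation_config()] (source = simulate), or `NULL`
#'   when `ingest_dir` is given.
#' @param ingest_dir directory with `manifest.csv` + epoch CSVs (source =
#'   ingest); ignored when `simulation` is given.
#' @param epoch_length analysis epoch length in seconds; `NULL` keeps the
#'   data's native grid (default 15 s — the grid on which the epoch totals
#'   of a 5-h preschool day come out at 1200/day).
#' @param reference hip-reference cut points (default [butte_hip()]).
#' @param johansson optional 3-level wrist [cut_point_set()] for the
#'   external-reference comparison column; `NULL` skips it with a notice.
#' @param choi list of [detect_nonwear_choi()] parameters.
#' @param kmeans_method `"dp"` or `"lloyd"`.
#' @param olr_ridge ridge penalty for the ordinal fit.
#' @param seed master seed for every random stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            ingest_dir = NULL,
                            epoch_length = NULL,
                            reference = butte_hip(),
                            johansson = NULL,
                            choi = list(window_min = 90, spike_tol_min = 2,
                                        flank_min = 30),
                            kmeans_method = "dp",
                            olr_ridge = 1e-6,
                            seed = 1) {
  if (is.null(simulation) && is.null(ingest_dir)) {
    abort("config needs either a simulation config or an ingest directory")
  }
  if (!is.null(johansson)) stopifnot(inherits(johansson, "cut_point_set"))
  structure(list(simulation = simulation, ingest_dir = ingest_dir,
                 epoch_length = epoch_length, reference = reference,
                 johansson = johansson, choi = choi,
                 kmeans_method = kmeans_method, olr_ridge = olr_ridge,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full calibration study
#'
#' Stages: (1) simulate or ingest epoch data; (2) non-wear detection and
#' hip/wrist alignment; (3) participant exclusion; (4) hip-reference
#' labelling and class tally; (5) three wrist calibrations; (6) per-method
#' agreement against the hip reference; (7) daily estimates. Identical
#' configs (including the seed) give identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return object of class `accel_bundle`: list with `tally`,
#'   `calibrations`, `agreement`, `estimates`, `matched`, `run_record`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- "simulate"
  bundle <- try({
    if (!is.null(config$simulation)) {
      study <- simulate_study(config$simulation)
      native <- config$simulation$epoch_length
    } else {
      study <- read_study_csv(config$ingest_dir)
      native <- attr(study, "epoch_length")
    }
    el <- config$epoch_length %||% native
    ep <- if (inherits(study, "accel_study")) study$epochs else study
    if (el != native) {
      stage <- "reintegrate"
      keys <- unique(ep[, c("participant_id", "day")])
      parts <- vector("list", nrow(keys))
      for (i in seq_len(nrow(keys))) {
        sub <- ep[ep$participant_id == keys$participant_id[i] &
                    ep$day == keys$day[i], ]
        sub <- sub[order(sub$epoch), ]
        h <- reintegrate(sub$hip_count, native, el)
        w <- reintegrate(sub$wrist_count, native, el)
        parts[[i]] <- data.frame(participant_id = sub$participant_id[1],
                                 day = sub$day[1], epoch = seq_along(h),
                                 hip_count = h, wrist_count = w)
      }
      ep <- do.call(rbind, parts)
    }
    attr(ep, "epoch_length") <- el

    stage <- "preprocess"
    matched <- do.call(preprocess_study,
                       c(list(ep, epoch_length = el), config$choi))
    n_enrolled <- length(unique(ep$participant_id))

    stage <- "exclude"
    exc <- exclude_participants(matched)
    matched <- exc$matched
    if (!nrow(matched)) abort("no matched epochs after exclusion")

    stage <- "label"
    hip_labels <- label_series(matched$hip_cpm, config$reference)
    tally <- tally_labels(hip_labels)

    stage <- "calibrate"
    cal <- calibrate_all(matched$wrist_cpm, hip_labels,
                         kmeans_method = config$kmeans_method,
                         olr_ridge = config$olr_ridge,
                         seed = substream_seed(config$seed, "kmeans"))

    stage <- "validate"
    labels_by_method <- list(hip_reference = hip_labels)
    agreement <- list()
    if (!is.null(config$johansson)) {
      jl <- label_series(matched$wrist_cpm, config$johansson)
      labels_by_method$johansson <- jl
      agreement$johansson <- agreement_report(hip_labels, jl, "johansson")
    } else {
      message("no Johansson boundaries configured; skipping that column")
    }
    for (m in names(cal)) {
      wl <- label_series(matched$wrist_cpm, cal[[m]]$cuts)
      labels_by_method[[m]] <- wl
      agreement[[m]] <- agreement_report(hip_labels, wl, m)
    }

    stage <- "estimate"
    estimates <- estimate_table(matched, labels_by_method, el)

    run_record <- list(
      config = config,
      package_version = as.character(utils::packageVersion("accelcal")),
      counts = c(enrolled = n_enrolled,
                 analyzable = length(unique(matched$participant_id)),
                 matched_epochs = nrow(matched)),
      exclusions = exc$log,
      started = t0, finished = Sys.time()
    )
    structure(list(tally = tally, calibrations = cal, agreement = agreement,
                   estimates = estimates, matched = matched,
                   run_record = run_record),
              class = "accel_bundle")
  }, silent = TRUE)
  if (inherits(bundle, "try-error")) {
    abort("pipeline failed at stage '", stage, "': ",
          attr(bundle, "condition")$message)
  }
  bundle
}

#' @export
print.accel_bundle <- function(x, ...) {
  rc <- x$run_record$counts
  cat("<accel_bundle> ", rc["enrolled"], " enrolled -> ", rc["analyzable"],
      " analyzable -> ", rc["matched_epochs"], " matched epochs\n",
      sep = "")
  cat("\nHip-reference class tally:\n")
  print(x$tally, row.names = FALSE)
  cat("\nDerived wrist cut points (cpm):\n")
  for (m in names(x$calibrations)) {
    b <- x$calibrations[[m]]$cuts$boundaries
    cat(sprintf("  %-7s t1 = %d, t2 = %d, t3 = %d\n", m, b[1], b[2], b[3]))
  }
  invisible(x)
}

#' Render a result bundle to files
#'
#' Writes CSV tables (class tally, calibration results, agreement,
#' daily estimates, run record counts) and, for `format = "markdown"`, a
#' single human-readable report. Rendering is deterministic: the same
#' bundle always produces byte-identical files.
#'
#' @param bundle an `accel_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"markdown"` (both may be given).
#' @return invisibly, the written file paths.
#' @export
write_report <- function(bundle, dir, format = "csv") {
  stopifnot(inherits(bundle, "accel_bundle"))
  bad <- setdiff(format, c("csv", "markdown"))
  if (length(bad)) {
    abort("unknown format(s): ", paste(bad, collapse = ", "),
          "; supported: csv, markdown")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  fmt_na <- function(x, digits = 2) {
    ifelse(is.na(x), "not computed", sprintf(paste0("%.", digits, "f"), x))
  }
  if ("csv" %in% format) {
    w <- function(df, name) {
      p <- file.path(dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    files <- c(files, w(bundle$tally, "tally.csv"))
    cals <- do.call(rbind, lapply(bundle$calibrations, as.data.frame))
    files <- c(files, w(cals, "calibration.csv"))
    agr <- do.call(rbind, lapply(names(bundle$agreement), function(m) {
      a <- bundle$agreement[[m]]
      cbind(method = m, a$per_class,
            overall_correct = unname(a$overall["correct"]),
            overall_kappa = unname(a$overall["kappa"]),
            grouped_correct = unname(a$overall_grouped["correct"]),
            grouped_kappa = unname(a$overall_grouped["kappa"]),
            row.names = NULL)
    }))
    files <- c(files, w(agr, "agreement.csv"))
    files <- c(files, w(bundle$estimates$summary, "daily_estimates.csv"))
    rc <- bundle$run_record$counts
    files <- c(files, w(data.frame(stage = names(rc), count = as.numeric(rc)),
                        "run_record.csv"))
  }
  if ("markdown" %in% format) {
    p <- file.path(dir, "report.md")
    con <- file(p, open = "wt", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    out <- function(...) cat(..., "\n", sep = "", file = con)
    out("# Wrist cut-point calibration report")
    rc <- bundle$run_record$counts
    out("")
    out("Enrolled: ", rc["enrolled"], "; analyzable: ", rc["analyzable"],
        "; matched epochs: ", rc["matched_epochs"])
    out("")
    out("## Hip-reference class tally")
    out("")
    out("| class | n | % |")
    out("|---|---|---|")
    for (i in seq_len(nrow(bundle$tally))) {
      out("| ", bundle$tally$class[i], " | ", bundle$tally$n[i], " | ",
          bundle$tally$pct[i], " |")
    }
    out("")
    out("## Derived wrist cut points (cpm)")
    out("")
    out("| method | class | lower | upper | n | mean (SD) |")
    out("|---|---|---|---|---|---|")
    for (m in names(bundle$calibrations)) {
      df <- as.data.frame(bundle$calibrations[[m]])
      for (i in seq_len(nrow(df))) {
        out("| ", m, " | ", df$level[i], " | ", df$cut_lower[i], " | ",
            ifelse(is.finite(df$cut_upper[i]), df$cut_upper[i], "Inf"),
            " | ", df$n[i], " | ", fmt_na(df$mean[i]), " (",
            fmt_na(df$sd[i]), ") |")
      }
    }
    out("")
    out("## Agreement with the hip reference")
    out("")
    out("| method | class | sens % | spec % | FPR % | FNR % | kappa |")
    out("|---|---|---|---|---|---|---|")
    for (m in names(bundle$agreement)) {
      a <- bundle$agreement[[m]]$per_class
      for (i in seq_len(nrow(a))) {
        out("| ", m, " | ", a$class[i], " | ", fmt_na(a$sensitivity[i]),
            " | ", fmt_na(a$specificity[i]), " | ", fmt_na(a$fpr[i]),
            " | ", fmt_na(a$fnr[i]), " | ", fmt_na(a$kappa[i]), " |")
      }
    }
    out("")
    out("| method | overall correct % | overall kappa |",
        " grouped correct % | grouped kappa |")
    out("|---|---|---|---|---|")
    for (m in names(bundle$agreement)) {
      a <- bundle$agreement[[m]]
      out("| ", m, " | ", fmt_na(a$overall["correct"]), " | ",
          fmt_na(a$overall["kappa"]), " | ",
          fmt_na(a$overall_grouped["correct"]), " | ",
          fmt_na(a$overall_grouped["kappa"]), " |")
    }
    out("")
    out("## Daily estimates (mean minutes, % of wear time)")
    out("")
    out("| method | class | mean | SD | % |")
    out("|---|---|---|---|---|")
    s <- bundle$estimates$summary
    for (i in seq_len(nrow(s))) {
      out("| ", s$method[i], " | ", s$class[i], " | ", fmt_na(s$mean[i]),
          " | ", fmt_na(s$sd[i]), " | ", fmt_na(s$pct[i], 1), " |")
    }
    files <- c(files, p)
  }
  invisible(files)
}
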