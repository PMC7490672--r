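#' Vector magnitude of triaxial counts
#'
#' Per-epoch Euclidean norm of the three axis counts,
#' `VM = sqrt(x^2 + y^2 + z^2)`, rounded half-up to an integer (device
#' exports carry integer VM).
#'
#' @param axis1,axis2,axis3 non-negative integer axis count vectors of equal
#'   length, or `axis1` may be a 3-column matrix / data frame.
#' @return integer VM vector.
#' @examples
#' vector_magnitude(3, 4, 0)  # 5
#' @export
vector_magnitude <- function(axis1, axis2 = NULL, axis3 = NULL) {
  if (is.matrix(axis1) || is.data.frame(axis1)) {
    m <- as.matrix(axis1)
    if (ncol(m) != 3) abort("need 3 axis columns, got ", ncol(m))
    axis1 <- m[, 1]; axis2 <- m[, 2]; axis3 <- m[, 3]
  }
  for (nm in c("axis1", "axis2", "axis3")) {
    v <- get(nm)
    if (is.null(v) || (length(axis1) > 0 && all(is.na(v)))) {
      abort("missing axis: ", nm)
    }
  }
  if (length(axis2) != length(axis1) || length(axis3) != length(axis1)) {
    abort("axis vectors must have equal length")
  }
  as.integer(round_half_up(sqrt(axis1^2 + axis2^2 + axis3^2)))
}

#' Re-integrate epochs to a longer epoch length
#'
#' Collapses counts onto a coarser grid by summation (e.g. 15-s to 60-s
#' epochs); total counts are conserved over complete windows. A trailing
#' partial window is dropped with a warning.
#'
#' @param counts integer count vector.
#' @param from source epoch length, seconds.
#' @param to target epoch length, seconds; a positive integer multiple of
#'   `from` (equal is the identity).
#' @return integer count vector on the target grid.
#' @examples
#' reintegrate(c(100, 200, 300, 400), 15, 60)  # 1000
#' @export
reintegrate <- function(counts, from, to) {
  if (to < from) abort("cannot disaggregate: target epoch (", to,
                       " s) is shorter than source (", from, " s)")
  if (to %% from != 0) abort("target epoch length must be a multiple of ",
                             from, " s")
  r <- to / from
  if (r == 1) return(as.integer(counts))
  n_full <- floor(length(counts) / r)
  if (n_full * r < length(counts)) {
    warning("dropping trailing partial window of ",
            length(counts) - n_full * r, " epoch(s)", call. = FALSE)
  }
  if (n_full == 0) return(integer())
  m <- matrix(counts[seq_len(n_full * r)], nrow = r)
  as.integer(colSums(m))
}

#' Convert epoch counts to counts per minute
#'
#' `cpm = count * 60 / epoch_length`: 15-s epochs scale by 4, 60-s epochs
#' are unchanged. Cut points are defined on the cpm scale, so every
#' classification goes through this conversion.
#'
#' @param counts count vector.
#' @param epoch_length epoch length in seconds.
#' @return numeric cpm vector.
#' @export
to_cpm <- function(counts, epoch_length) {
  counts * 60 / epoch_length
}

#' Choi non-wear detection
#'
#' Flags non-wear as runs of at least `window_min` consecutive zero-count
#' minutes, allowing interruptions of at most `spike_tol_min` minutes of
#' non-zero counts when flanked by at least `flank_min` minutes of zeros on
#' both sides. Detection runs on a 60-s grid derived from the data
#' (finer epochs are collapsed by summation); the resulting mask is expanded
#' back to the input grid. Defaults are the canonical parameterisation:
#' 90-min window, 2-min spike tolerance, 30-min flanks.
#'
#' @param counts epoch count vector for one contiguous day.
#' @param epoch_length epoch length in seconds (must divide 60).
#' @param window_min minimum non-wear run, minutes.
#' @param spike_tol_min maximum tolerated non-zero interruption, minutes.
#' @param flank_min zero-minutes required on each side of an interruption.
#' @return logical wear mask on the input epoch grid (`TRUE` = worn).
#' @export
detect_nonwear_choi <- function(counts, epoch_length,
                                window_min = 90, spike_tol_min = 2,
                                flank_min = 30) {
  stopifnot(length(counts) >= 1)
  if (60 %% epoch_length != 0 && epoch_length %% 60 != 0) {
    abort("epoch length ", epoch_length, " s does not tile the minute grid")
  }
  epm <- 60 / epoch_length
  if (epm >= 1) {
    n_min <- floor(length(counts) / epm)
    minute <- reintegrate(counts[seq_len(n_min * epm)], epoch_length, 60)
  } else {
    # epochs longer than a minute: treat each epoch as epoch_length/60 minutes
    minute <- rep(counts, each = epoch_length / 60)
    n_min <- length(minute)
  }
  z <- minute == 0
  r <- rle(z)
  # tolerate short non-zero spikes flanked by long zero runs on both sides
  if (length(r$lengths) >= 3) {
    for (i in 2:(length(r$lengths) - 1)) {
      if (!r$values[i] && r$lengths[i] <= spike_tol_min &&
          r$values[i - 1] && r$lengths[i - 1] >= flank_min &&
          r$values[i + 1] && r$lengths[i + 1] >= flank_min) {
        r$values[i] <- TRUE
      }
    }
  }
  z2 <- inverse.rle(r)
  r2 <- rle(z2)
  nonwear_min <- inverse.rle(list(
    lengths = r2$lengths,
    values = r2$values & r2$lengths >= window_min
  ))
  wear <- rep(TRUE, length(counts))
  if (epm >= 1) {
    wear[seq_len(n_min * epm)] <- rep(!nonwear_min, each = epm)
  } else {
    wear <- !nonwear_min[seq(1, length(nonwear_min), by = epoch_length / 60)]
  }
  wear
}

#' Align worn hip and wrist epochs for one participant-day
#'
#' Intersects the two wear masks on a common epoch grid and returns one row
#' per epoch worn on both placements, with counts expressed in cpm.
#'
#' @param hip_counts,wrist_counts equal-length epoch count vectors.
#' @param epoch_length epoch length in seconds (shared grid).
#' @param hip_wear,wrist_wear logical wear masks (default: all worn).
#' @return data frame with columns `epoch`, `hip_cpm`, `wrist_cpm`; one row
#'   per jointly worn epoch (empty, with a warning, if the masks do not
#'   intersect).
#' @export
align_pairs <- function(hip_counts, wrist_counts, epoch_length,
                        hip_wear = NULL, wrist_wear = NULL) {
  n <- length(hip_counts)
  if (length(wrist_counts) != n) {
    abort("mismatched epoch grids: hip has ", n, " epochs, wrist has ",
          length(wrist_counts))
  }
  if (is.null(hip_wear)) hip_wear <- rep(TRUE, n)
  if (is.null(wrist_wear)) wrist_wear <- rep(TRUE, n)
  if (length(hip_wear) != n || length(wrist_wear) != n) {
    abort("wear masks must match the epoch grid")
  }
  keep <- which(hip_wear & wrist_wear)
  if (!length(keep)) {
    warning("no epoch worn on both placements", call. = FALSE)
  }
  data.frame(epoch = keep,
             hip_cpm = to_cpm(hip_counts[keep], epoch_length),
             wrist_cpm = to_cpm(wrist_counts[keep], epoch_length))
}

#' Preprocess a simulated or ingested study to a matched epoch table
#'
#' For each participant-day: detect non-wear on both placements, intersect
#' wear masks, and express jointly worn epochs in cpm.
#'
#' @param study an `accel_study` (or a data frame shaped like its `epochs`
#'   element, with an `epoch_length` attribute or given explicitly).
#' @param epoch_length analysis epoch length in seconds; defaults to the
#'   study's generating epoch length.
#' @param ... parameters passed to [detect_nonwear_choi()].
#' @return data frame with one row per matched epoch: `participant_id`,
#'   `day`, `epoch`, `hip_cpm`, `wrist_cpm`.
#' @export
preprocess_study <- function(study, epoch_length = NULL, ...) {
  ep <- if (inherits(study, "accel_study")) study$epochs else study
  if (is.null(epoch_length)) {
    epoch_length <- if (inherits(study, "accel_study")) {
      study$config$epoch_length
    } else attr(study, "epoch_length") %||% 15
  }
  keys <- unique(ep[, c("participant_id", "day")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- ep[ep$participant_id == keys$participant_id[i] &
                ep$day == keys$day[i], ]
    sub <- sub[order(sub$epoch), ]
    hw <- detect_nonwear_choi(sub$hip_count, epoch_length, ...)
    ww <- detect_nonwear_choi(sub$wrist_count, epoch_length, ...)
    m <- suppressWarnings(
      align_pairs(sub$hip_count, sub$wrist_count, epoch_length, hw, ww))
    if (nrow(m)) {
      out[[i]] <- cbind(participant_id = keys$participant_id[i],
                        day = keys$day[i], m)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(participant_id = character(), day = integer(),
                      epoch = integer(), hip_cpm = numeric(),
                      wrist_cpm = numeric())
  }
  attr(res, "epoch_length") <- epoch_length
  attr(res, "n_enrolled") <- length(unique(ep$participant_id))
  attr(res, "n_days") <- length(unique(ep$day))
  rownames(res) <- NULL
  res
}

#' Apply the participant exclusion rule
#'
#' Participants whose matched data are missing on `max_missing_run` or more
#' consecutive monitoring days are excluded. With the default 3-day
#' protocol this removes participants with no valid matched epochs on any
#' day while retaining anyone with at least one valid day.
#'
#' @param matched matched epoch table from [preprocess_study()].
#' @param n_days number of scheduled days per participant (default: taken
#'   from the table attribute).
#' @param max_missing_run consecutive missing days triggering exclusion.
#' @return list with `matched` (filtered table) and `log` (data frame of
#'   participant, decision, reason).
#' @export
exclude_participants <- function(matched, n_days = NULL,
                                 max_missing_run = 3) {
  if (is.null(n_days)) n_days <- attr(matched, "n_days") %||%
      max(matched$day)
  enrolled <- attr(matched, "n_enrolled")
  ids <- sort(unique(matched$participant_id))
  logs <- list()
  keep <- character()
  for (pid in ids) {
    days_valid <- unique(matched$day[matched$participant_id == pid])
    missing <- !(seq_len(n_days) %in% days_valid)
    run <- if (any(missing)) max(rle(missing)$lengths[rle(missing)$values])
      else 0
    if (run >= max_missing_run) {
      logs[[pid]] <- data.frame(
        participant_id = pid, decision = "excluded",
        reason = paste0("matched data missing on ", run,
                        " consecutive day(s)"))
    } else {
      keep <- c(keep, pid)
      logs[[pid]] <- data.frame(participant_id = pid, decision = "retained",
                                reason = "")
    }
  }
  # participants enrolled but contributing zero matched epochs never appear
  # in the table; they are excluded by construction
  if (!is.null(enrolled) && enrolled > length(ids)) {
    logs[["_absent"]] <- data.frame(
      participant_id = sprintf("(%d absent from matched table)",
                               enrolled - length(ids)),
      decision = "excluded", reason = "no matched epochs on any day")
  }
  out <- matched[matched$participant_id %in% keep, ]
  attr(out, "epoch_length") <- attr(matched, "epoch_length")
  attr(out, "n_enrolled") <- enrolled
  attr(out, "n_days") <- n_days
  rownames(out) <- NULL
  list(matched = out, log = do.call(rbind, c(logs, make.row.names = FALSE)))
}

#' Read / write the epoch CSV dialect
#'
#' One header line with columns `participant_id, day, placement,
#' epoch_start, epoch_length_s, axis1, axis2, axis3, vm`; axis columns and
#' `vm` are each optional but at least one group must be present. If both
#' are present, `vm` wins and the axis columns are ignored with a notice.
#'
#' @param path CSV file path.
#' @return data frame with a guaranteed integer `vm` column.
#' @export
read_epoch_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "day", "placement", "epoch_length_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("epoch CSV missing column(s): ",
                          paste(miss, collapse = ", "))
  has_axes <- all(c("axis1", "axis2", "axis3") %in% names(df))
  has_vm <- "vm" %in% names(df) && !all(is.na(df$vm))
  if (!has_axes && !has_vm) {
    abort("epoch CSV needs either axis1..axis3 or vm")
  }
  if (has_vm) {
    if (has_axes) message("both axis and vm columns present; using vm")
    df$vm <- as.integer(df$vm)
  } else {
    df$vm <- vector_magnitude(df$axis1, df$axis2, df$axis3)
  }
  if (any(df$vm < 0, na.rm = TRUE)) abort("negative counts in ", path)
  df
}

#' @rdname read_epoch_csv
#' @param df data frame in the dialect above.
#' @export
write_epoch_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an ActiLife-style per-epoch CSV export
#'
#' Skips the metadata preamble by scanning for the first line whose first
#' comma-separated field parses as a timestamp (`HH:MM:SS` or an ISO
#' date-time), then reads the remainder as
#' `timestamp, axis1, axis2, axis3[, vm]`.
#'
#' @param path file path.
#' @param epoch_length_s epoch length of the export, seconds.
#' @return data frame with columns `epoch_start`, `axis1..3`, `vm`.
#' @export
read_actilife_csv <- function(path, epoch_length_s = 15) {
  lines <- readLines(path)
  first_field <- sub(",.*$", "", lines)
  is_ts <- grepl("^\\d{1,2}:\\d{2}:\\d{2}$", first_field) |
    grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}", first_field) |
    grepl("^\\d{1,2}/\\d{1,2}/\\d{2,4} \\d{1,2}:\\d{2}:\\d{2}", first_field)
  start <- which(is_ts)[1]
  if (is.na(start)) abort("no epoch rows found in ", path)
  body <- utils::read.csv(text = lines[start:length(lines)], header = FALSE)
  if (ncol(body) < 4) abort("expected timestamp plus 3 axis columns in ",
                            path)
  names(body)[1:4] <- c("epoch_start", "axis1", "axis2", "axis3")
  if (ncol(body) >= 5) names(body)[5] <- "vm"
  if (!"vm" %in% names(body)) {
    body$vm <- vector_magnitude(body$axis1, body$axis2, body$axis3)
  }
  body$epoch_length_s <- epoch_length_s
  body
}

#' Assemble a study from a simulator manifest directory
#'
#' Reads `manifest.csv` plus the per participant-day-placement epoch files
#' written by [write_study_csv()] and rebuilds the epoch table expected by
#' [preprocess_study()].
#'
#' @param dir directory containing `manifest.csv`.
#' @return data frame shaped like `accel_study$epochs` (without latent
#'   truth), with an `epoch_length` attribute.
#' @export
read_study_csv <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  keys <- unique(man[, c("participant_id", "day")])
  out <- vector("list", nrow(keys))
  el <- NULL
  for (i in seq_len(nrow(keys))) {
    pid <- keys$participant_id[i]; d <- keys$day[i]
    sel <- man[man$participant_id == pid & man$day == d, ]
    hip <- read_epoch_csv(file.path(dir, sel$file[sel$placement == "hip"]))
    wrist <- read_epoch_csv(file.path(dir,
                                      sel$file[sel$placement == "wrist"]))
    if (nrow(hip) != nrow(wrist)) {
      abort("mismatched epoch grids for ", pid, " day ", d)
    }
    el <- hip$epoch_length_s[1]
    out[[i]] <- data.frame(participant_id = pid, day = d,
                           epoch = seq_len(nrow(hip)),
                           hip_count = hip$vm, wrist_count = wrist$vm,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "epoch_length") <- el
  res
}
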