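#' Cut-point sets
#'
#' A cut-point set partitions the non-negative integer counts-per-minute
#' (cpm) scale into ordered intensity intervals. For the usual 4-level scale
#' the three boundaries `(t1, t2, t3)` define the intervals
#' `[0, t1]`, `[t1 + 1, t2]`, `[t2 + 1, t3]`, `[t3 + 1, Inf)` — a partition
#' with no gaps or overlaps on the integer grid. A 3-level set (two
#' boundaries, levels SB / LPA / MVPA) is supported for references that do
#' not split MPA from VPA.
#'
#' @param name short identifier, e.g. `"butte_hip"`.
#' @param placement `"hip"` or `"wrist"`.
#' @param boundaries strictly increasing non-negative integers; one fewer
#'   than the number of levels.
#' @param levels level names, default the 4-level scale.
#' @return an object of class `cut_point_set`.
#' @seealso [classify()], [label_series()], [butte_hip()], [johansson_wrist()]
#' @export
cut_point_set <- function(name, placement = c("hip", "wrist"), boundaries,
                          levels = intensity_levels()) {
  placement <- match.arg(placement)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != length(levels) - 1) {
    abort("need ", length(levels) - 1, " boundaries for ", length(levels),
          " levels, got ", length(boundaries))
  }
  if (any(!is.finite(boundaries)) || any(boundaries < 0)) {
    abort("cut-point boundaries must be finite and non-negative")
  }
  if (any(diff(boundaries) <= 0)) {
    abort("cut-point boundaries must be strictly increasing: ",
          paste(boundaries, collapse = ", "))
  }
  if (any(boundaries != floor(boundaries))) {
    abort("cut-point boundaries must be integers on the cpm scale")
  }
  structure(
    list(name = name, placement = placement,
         boundaries = boundaries, levels = levels),
    class = "cut_point_set"
  )
}

#' @export
print.cut_point_set <- function(x, ...) {
  cat("<cut_point_set> ", x$name, " (", x$placement, ")\n", sep = "")
  lo <- c(0, x$boundaries + 1)
  hi <- c(x$boundaries, Inf)
  for (i in seq_along(x$levels)) {
    cat(sprintf("  %-4s %s cpm\n", x$levels[i],
                if (is.finite(hi[i])) paste0(lo[i], "-", hi[i])
                else paste0(">= ", lo[i])))
  }
  invisible(x)
}

#' @export
as.data.frame.cut_point_set <- function(x, ...) {
  data.frame(
    name = x$name, placement = x$placement, level = x$levels,
    lower = c(0, x$boundaries + 1), upper = c(x$boundaries, Inf),
    stringsAsFactors = FALSE
  )
}

#' Butte preschool hip-reference cut points
#'
#' Vector-magnitude cpm cut points for preschool-age children wearing a hip
#' accelerometer: SB <= 820 cpm, LPA 821-3908, MPA 3909-6112, VPA >= 6113.
#' The VPA interval is taken as starting at 6113 cpm so the partition is
#' gapless on the integer grid.
#'
#' @return a 4-level [cut_point_set()].
#' @export
butte_hip <- function() {
  cut_point_set("butte_hip", "hip", c(820, 3908, 6112))
}

#' Johansson wrist reference (3-level)
#'
#' Wrist-worn reference for preschoolers separating SB, LPA and MVPA only;
#' the MVPA lower bound is 16716 cpm. The SB/LPA boundary is not part of
#' this package's presets and must be supplied from the original source.
#'
#' @param sb_upper integer cpm upper bound of sedentary behaviour. If `NULL`
#'   the preset cannot be built and an informative error is raised; callers
#'   that treat the Johansson comparison as optional should skip it (with a
#'   notice) when no boundary is available.
#' @param mvpa_lower integer cpm lower bound of MVPA (default 16716).
#' @return a 3-level [cut_point_set()] with levels SB / LPA / MVPA.
#' @export
johansson_wrist <- function(sb_upper = NULL, mvpa_lower = 16716) {
  if (is.null(sb_upper)) {
    abort("Johansson SB/LPA boundary is not shipped with the package; ",
          "supply sb_upper from the original calibration source")
  }
  cut_point_set("johansson_wrist", "wrist",
                c(sb_upper, mvpa_lower - 1),
                levels = intensity_levels(mvpa_grouped = TRUE))
}

#' Classify cpm values into intensity levels
#'
#' Total function on non-negative cpm values: values up to and including the
#' first boundary are the lowest level, and so on; values above the last
#' boundary are the highest level. Classification is monotone in cpm.
#'
#' @param cpm numeric vector of non-negative cpm values.
#' @param cuts a [cut_point_set()].
#' @return ordered factor of intensity labels, same length as `cpm`.
#' @examples
#' classify(c(0, 820, 821, 6113), butte_hip())
#' @export
classify <- function(cpm, cuts) {
  stopifnot(inherits(cuts, "cut_point_set"))
  if (length(cpm) && any(cpm < 0, na.rm = TRUE)) {
    abort("negative cpm value at position ",
          which(cpm < 0)[1], ": cpm must be >= 0")
  }
  idx <- findInterval(cpm, cuts$boundaries, left.open = TRUE) + 1L
  as_intensity(cuts$levels[idx], levels = cuts$levels)
}

#' Label a cpm series, reporting the epoch on error
#'
#' Elementwise [classify()]; invalid values raise an error naming the epoch
#' index so problems in long series can be located.
#'
#' @inheritParams classify
#' @return ordered factor of intensity labels.
#' @export
label_series <- function(cpm, cuts) {
  bad <- which(!is.na(cpm) & cpm < 0)
  if (length(bad)) {
    abort("negative cpm at epoch ", bad[1], " (", cpm[bad[1]], ")")
  }
  classify(cpm, cuts)
}
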