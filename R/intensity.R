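#' Physical activity intensity levels
#'
#' The four ordinal intensity levels used throughout: sedentary behaviour
#' (SB), light (LPA), moderate (MPA) and vigorous (VPA) physical activity.
#' MVPA is the merge of MPA and VPA.
#'
#' @param mvpa_grouped if `TRUE`, return the 3-level scale
#'   `c("SB", "LPA", "MVPA")` used when moderate and vigorous are pooled.
#' @return character vector of ordered level names.
#' @export
intensity_levels <- function(mvpa_grouped = FALSE) {
  if (mvpa_grouped) c("SB", "LPA", "MVPA") else c("SB", "LPA", "MPA", "VPA")
}

#' Coerce to an ordered intensity factor
#'
#' Accepts ordinal codes 0..3 (0 = SB), 1-based indices via level names, or
#' character labels. Unknown labels are an error rather than `NA`: silently
#' coercing corrupts downstream agreement statistics.
#'
#' @param x integer codes in 0..3, or character labels.
#' @param levels level set, default the 4-level scale.
#' @return ordered factor over `levels`.
#' @export
as_intensity <- function(x, levels = intensity_levels()) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (length(x) && (min(x) < 0 || max(x) > length(levels) - 1)) {
      abort("intensity codes must lie in 0..", length(levels) - 1)
    }
    x <- levels[x + 1]
  }
  bad <- setdiff(unique(x), c(levels, NA))
  if (length(bad)) {
    abort("unknown intensity label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = levels, ordered = TRUE)
}

#' Pool moderate and vigorous activity into MVPA
#'
#' Maps a 4-level label sequence onto the 3-level scale SB / LPA / MVPA;
#' SB and LPA are unchanged, MPA and VPA both become MVPA.
#'
#' @param labels factor or character vector of 4-level intensity labels.
#' @return ordered factor on `c("SB", "LPA", "MVPA")`, same length.
#' @examples
#' group_mvpa(c("SB", "LPA", "MPA", "VPA"))
#' @export
group_mvpa <- function(labels) {
  x <- as.character(labels)
  x[x %in% c("MPA", "VPA")] <- "MVPA"
  as_intensity(x, levels = intensity_levels(mvpa_grouped = TRUE))
}
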