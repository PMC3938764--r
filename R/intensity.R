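# Local-background correction and per-repeat intensity standardization.

.parse_pixels <- function(s) lapply(strsplit(s, ";", fixed = TRUE), as.numeric)

#' Correct CMAC intensities for local background
#'
#' Per channel: corrected mean = raw pixel mean - local background (the
#' background is estimated within a 1 um annulus at segmentation time and
#' carried in the `ch*_bg` columns); corrected total = corrected mean x
#' area. Negative corrected means are clamped to zero and flagged.
#'
#' @param cmacs Data frame with `ch1_pixels`/`ch2_pixels`
#'   (semicolon-joined per-pixel values), `ch1_bg`/`ch2_bg` and `area_um2`.
#' @return The input with added columns `ch1_mean_raw`, `ch2_mean_raw`,
#'   `ch1_mean_corr`, `ch2_mean_corr`, `ch1_total_corr`, `ch2_total_corr`
#'   and logical `bg_clamped`. Records with a missing background are
#'   flagged (`bg_missing`) and left uncorrected (`NA`).
#' @export
correct_local_background <- function(cmacs) {
  stopifnot(all(c("ch1_pixels", "ch2_pixels", "ch1_bg", "ch2_bg",
                  "area_um2") %in% names(cmacs)))
  p1 <- .parse_pixels(cmacs$ch1_pixels)
  p2 <- .parse_pixels(cmacs$ch2_pixels)
  cmacs$ch1_mean_raw <- vapply(p1, mean, numeric(1))
  cmacs$ch2_mean_raw <- vapply(p2, mean, numeric(1))
  cmacs$bg_missing <- !is.finite(cmacs$ch1_bg) | !is.finite(cmacs$ch2_bg)
  m1 <- cmacs$ch1_mean_raw - cmacs$ch1_bg
  m2 <- cmacs$ch2_mean_raw - cmacs$ch2_bg
  cmacs$bg_clamped <- !cmacs$bg_missing & (m1 < 0 | m2 < 0)
  m1 <- pmax(m1, 0); m2 <- pmax(m2, 0)
  m1[cmacs$bg_missing] <- NA_real_; m2[cmacs$bg_missing] <- NA_real_
  cmacs$ch1_mean_corr <- m1
  cmacs$ch2_mean_corr <- m2
  cmacs$ch1_total_corr <- m1 * cmacs$area_um2
  cmacs$ch2_total_corr <- m2 * cmacs$area_um2
  cmacs
}

#' Standardize CMAC intensities across experimental repeats
#'
#' Per recorded channel and experimental repeat, the divisor is the median
#' of all individual corrected CMAC mean intensities of reference-condition
#' (control) CMACs with area between 0.15 and 0.2 um2 -- a size window
#' above the optical and digital resolution of the acquisition. All
#' corrected intensity values in that repeat are divided by it.
#'
#' @param cmacs Output of [correct_local_background()].
#' @param reference_condition Condition providing the divisors (control).
#' @param area_window Area window in um2 (default `c(0.15, 0.2)`).
#' @return List with `cmacs` (standardized intensity columns) and
#'   `divisors` (data frame: repeat_id, channel, divisor, n_reference).
#'   A repeat with no reference CMACs in the window is flagged and left
#'   unstandardized.
#' @export
standardize_intensities <- function(cmacs, reference_condition = "control",
                                    area_window = c(0.15, 0.2)) {
  stopifnot(all(c("ch1_mean_corr", "ch2_mean_corr") %in% names(cmacs)))
  if (!reference_condition %in% cmacs$condition)
    stop("reference condition absent from dataset")
  reps <- unique(cmacs$repeat_id)
  div <- list()
  cmacs$standardization_failed <- FALSE
  for (r in reps) {
    in_rep <- cmacs$repeat_id == r
    ref <- in_rep & cmacs$condition == reference_condition &
      cmacs$area_um2 >= area_window[1] & cmacs$area_um2 <= area_window[2]
    n_ref <- sum(ref)
    if (n_ref == 0) {
      warning(sprintf("repeat %s: no reference CMACs in area window; standardization refused", r))
      cmacs$standardization_failed[in_rep] <- TRUE
      div[[length(div) + 1]] <- data.frame(repeat_id = r,
                                           channel = c("ch1", "ch2"),
                                           divisor = NA_real_,
                                           n_reference = 0L)
      next
    }
    d1 <- stats::median(cmacs$ch1_mean_corr[ref], na.rm = TRUE)
    d2 <- stats::median(cmacs$ch2_mean_corr[ref], na.rm = TRUE)
    for (col in c("ch1_mean_corr", "ch1_total_corr"))
      cmacs[[col]][in_rep] <- cmacs[[col]][in_rep] / d1
    for (col in c("ch2_mean_corr", "ch2_total_corr"))
      cmacs[[col]][in_rep] <- cmacs[[col]][in_rep] / d2
    div[[length(div) + 1]] <- data.frame(repeat_id = r,
                                         channel = c("ch1", "ch2"),
                                         divisor = c(d1, d2),
                                         n_reference = n_ref)
  }
  list(cmacs = cmacs, divisors = do.call(rbind, div))
}
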