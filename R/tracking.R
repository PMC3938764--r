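# Nearest-neighbor track linking and the object-level parsing filters.

#' Link per-frame detections into tracks by nearest-neighbor analysis
#'
#' Greedy mutual-nearest-neighbor assignment between consecutive frames:
#' candidate links are taken in order of increasing distance; links longer
#' than `max_displacement` are forbidden and unmatched detections open new
#' tracks. Ties are broken toward the smaller detection id.
#'
#' @param detections Data frame with columns `frame` (consecutive integer
#'   frame indices), `id` (unique within a frame), `x`, `y` (um).
#' @param max_displacement Maximal allowed inter-frame displacement (um);
#'   the CMAC gate is 2 um.
#' @return The input with an added integer `track_id` column.
#' @export
#' @examples
#' d <- data.frame(frame = c(0, 1), id = c(1, 1), x = c(0, 0.5), y = 0)
#' link_nearest_neighbor(d)$track_id  # one track of length 2
link_nearest_neighbor <- function(detections, max_displacement = 2) {
  stopifnot(all(c("frame", "id", "x", "y") %in% names(detections)))
  if (anyDuplicated(detections[, c("frame", "id")]))
    stop("duplicate (frame, id) detection")
  det <- detections[order(detections$frame, detections$id), , drop = FALSE]
  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  if (any(diff(frames) != 1) && length(frames) > 1)
    frames <- seq(min(frames), max(frames))
  next_track <- 1L
  prev_idx <- which(det$frame == frames[1])
  det$track_id[prev_idx] <- seq_len(length(prev_idx))
  next_track <- length(prev_idx) + 1L
  for (f in frames[-1]) {
    cur_idx <- which(det$frame == f)
    if (!length(cur_idx)) { prev_idx <- cur_idx; next }
    if (length(prev_idx)) {
      dmat <- outer(det$x[prev_idx], det$x[cur_idx], `-`)^2 +
              outer(det$y[prev_idx], det$y[cur_idx], `-`)^2
      dmat <- sqrt(dmat)
      dmat[dmat > max_displacement] <- Inf
      taken_prev <- rep(FALSE, length(prev_idx))
      taken_cur <- rep(FALSE, length(cur_idx))
      repeat {
        m <- which(dmat == min(dmat), arr.ind = TRUE)
        if (!is.finite(min(dmat))) break
        # tie-break: smallest previous id, then smallest current id
        ord <- order(det$id[prev_idx][m[, 1]], det$id[cur_idx][m[, 2]])
        i <- m[ord[1], 1]; j <- m[ord[1], 2]
        det$track_id[cur_idx[j]] <- det$track_id[prev_idx[i]]
        taken_prev[i] <- TRUE; taken_cur[j] <- TRUE
        dmat[i, ] <- Inf; dmat[, j] <- Inf
        if (all(!is.finite(dmat))) break
      }
    }
    new_idx <- cur_idx[is.na(det$track_id[cur_idx])]
    if (length(new_idx)) {
      det$track_id[new_idx] <- next_track + seq_along(new_idx) - 1L
      next_track <- next_track + length(new_idx)
    }
    prev_idx <- cur_idx
  }
  det
}

#' Apply the object-level parsing filters to CMAC tracks
#'
#' Three rules, applied in order: (1) records with a minor axis below one
#' pixel (0.21 um) are removed (they produce aberrant form factors);
#' (2) tracks observed in only a single time point are removed (noise
#' control, given the 2 um displacement gate); (3) tracks touching the
#' first or final frame of the sequence are flagged as censored so that
#' aggregate lifetime calculations can exclude their incomplete lifetimes.
#'
#' @param cmacs Data frame of linked CMAC records with columns
#'   `condition`, `repeat_id`, `cell_id`, `cmac_id`, `frame`,
#'   `minor_axis_um` (and any others, carried through).
#' @param min_minor_axis Minor-axis floor in um (one pixel).
#' @param first_frame,last_frame Sequence boundaries used for censoring;
#'   defaults to the observed range per (condition, repeat).
#' @return List with `cmacs` (surviving records plus logical columns
#'   `censored_start`, `censored_end`) and `report` (removal counts by rule).
#' @export
parse_cmac_tracks <- function(cmacs, min_minor_axis = 0.21,
                              first_frame = NULL, last_frame = NULL) {
  stopifnot(all(c("condition", "repeat_id", "cell_id", "cmac_id", "frame",
                  "minor_axis_um") %in% names(cmacs)))
  n0 <- nrow(cmacs)
  bad_axis <- cmacs$minor_axis_um < min_minor_axis
  cmacs <- cmacs[!bad_axis, , drop = FALSE]
  key <- paste(cmacs$condition, cmacs$repeat_id, cmacs$cell_id,
               cmacs$cmac_id, sep = "\r")
  len <- table(key)
  single <- key %in% names(len)[len < 2]
  cmacs <- cmacs[!single, , drop = FALSE]
  key <- key[!single]
  # censoring against the acquisition window, per condition/repeat
  grp <- paste(cmacs$condition, cmacs$repeat_id, sep = "\r")
  ff <- if (is.null(first_frame)) tapply(cmacs$frame, grp, min) else NULL
  lf <- if (is.null(last_frame)) tapply(cmacs$frame, grp, max) else NULL
  f0 <- if (is.null(first_frame)) unname(ff[grp]) else first_frame
  f1 <- if (is.null(last_frame)) unname(lf[grp]) else last_frame
  tmin <- stats::ave(cmacs$frame, key, FUN = min)
  tmax <- stats::ave(cmacs$frame, key, FUN = max)
  cmacs$censored_start <- tmin <= f0
  cmacs$censored_end <- tmax >= f1
  rownames(cmacs) <- NULL
  report <- list(n_input_records = n0,
                 removed_minor_axis = sum(bad_axis),
                 removed_single_frame = sum(single),
                 n_surviving_records = nrow(cmacs),
                 n_surviving_tracks = length(unique(key)),
                 n_censored_tracks = length(unique(key[cmacs$censored_start |
                                                         cmacs$censored_end])))
  list(cmacs = cmacs, report = report)
}
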