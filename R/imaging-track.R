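#' Link per-frame detections into cell tracks
#'
#' Greedy nearest-neighbor frame-to-frame assignment with global drift
#' compensation: for each consecutive frame pair the median displacement of
#' provisional nearest-neighbor matches (the advective flow common to all
#' cells) is subtracted before gating, so the gate tests residual per-cell
#' motion rather than the bulk drift. Unmatched detections start new tracks;
#' tracks shorter than `min_length` frames are dropped. Assignments where
#' several candidates fell inside the gate are recorded in the
#' `"ambiguities"` attribute.
#'
#' @param detections list with one [detect_cells()] data.frame per frame.
#' @param max_step gating radius in pixels on the drift-corrected
#'   displacement.
#' @param min_length minimum track length in frames.
#' @return List of `cell_track` objects, each a data.frame with columns
#'   `frame`, `x`, `y` and attribute `track_id`; the list carries the
#'   per-frame estimated `drift` and assignment `ambiguities` as attributes.
#' @export
link_tracks <- function(detections, max_step = 10, min_length = 2) {
  stopifnot(is.list(detections), length(detections) >= 2)
  n_frames <- length(detections)
  tracks <- list()     # each: list(frames, x, y, open)
  open_idx <- integer(0)  # indices into `tracks` of tracks seen last frame
  drift_log <- matrix(NA_real_, n_frames, 2)
  ambiguities <- NULL

  start_tracks <- function(det, f) {
    for (i in seq_len(nrow(det))) {
      tracks[[length(tracks) + 1]] <<- list(frames = f, x = det$x[i],
                                            y = det$y[i])
    }
    seq(length(tracks) - nrow(det) + 1, length.out = nrow(det))
  }
  d1 <- detections[[1]]
  if (nrow(d1) > 0) open_idx <- start_tracks(d1, 1L)

  for (f in 2:n_frames) {
    det <- detections[[f]]
    new_open <- integer(0)
    if (length(open_idx) > 0 && nrow(det) > 0) {
      px <- vapply(tracks[open_idx], function(t) tail(t$x, 1), numeric(1))
      py <- vapply(tracks[open_idx], function(t) tail(t$y, 1), numeric(1))
      # provisional nearest-neighbor displacements -> robust drift estimate
      dmat <- outer(px, det$x, "-")^2 + outer(py, det$y, "-")^2
      nn <- apply(dmat, 1, which.min)
      drift <- c(median(det$x[nn] - px), median(det$y[nn] - py))
      drift_log[f, ] <- drift
      # greedy assignment on drift-corrected distances, ascending
      res2 <- outer(px + drift[1], det$x, "-")^2 +
        outer(py + drift[2], det$y, "-")^2
      cand <- which(res2 <= max_step^2, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(res2[cand])
        used_t <- logical(length(open_idx)); used_d <- logical(nrow(det))
        n_cand_t <- tabulate(cand[, 1], nbins = length(open_idx))
        for (ci in ord) {
          ti <- cand[ci, 1]; di <- cand[ci, 2]
          if (used_t[ti] || used_d[di]) next
          used_t[ti] <- TRUE; used_d[di] <- TRUE
          gi <- open_idx[ti]
          tracks[[gi]]$frames <- c(tracks[[gi]]$frames, f)
          tracks[[gi]]$x <- c(tracks[[gi]]$x, det$x[di])
          tracks[[gi]]$y <- c(tracks[[gi]]$y, det$y[di])
          new_open <- c(new_open, gi)
          if (n_cand_t[ti] > 1) {
            ambiguities <- rbind(ambiguities,
                                 data.frame(frame = f, track = gi,
                                            n_candidates = n_cand_t[ti]))
          }
        }
        unmatched <- det[!used_d, , drop = FALSE]
      } else {
        unmatched <- det
      }
    } else {
      unmatched <- det
    }
    if (nrow(unmatched) > 0) {
      new_open <- c(new_open, start_tracks(unmatched, f))
    }
    open_idx <- new_open
  }

  keep <- vapply(tracks, function(t) length(t$frames) >= min_length, logical(1))
  out <- lapply(which(keep), function(i) {
    tr <- data.frame(frame = tracks[[i]]$frames, x = tracks[[i]]$x,
                     y = tracks[[i]]$y)
    attr(tr, "track_id") <- i
    class(tr) <- c("cell_track", "data.frame")
    tr
  })
  attr(out, "drift") <- drift_log
  attr(out, "ambiguities") <- ambiguities
  attr(out, "n_dropped") <- sum(!keep)
  out
}
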