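# dF/F computation, stimulus-triggered averaging, sensory peak maps and
# epoch splitting for spontaneous recordings.

#' Compute a dF/F movie
#'
#' `dff(t, p) = (F(t, p) - F0(p)) / F0(p)` with `F0` the per-pixel mean over
#' the baseline window. For spontaneous data the default baseline is the
#' full recording; for evoked data pass the pre-stimulus frames.
#'
#' @param movie T x H x W array of raw fluorescence.
#' @param baseline integer vector of baseline frame indices (default: all
#'   frames).
#' @param offset constant added to `F` before baseline division (for data
#'   with zero-valued pixels); default 0.
#' @return T x H x W dF/F array with attribute `baseline`.
#' @export
compute_dff <- function(movie, baseline = seq_len(dim(movie)[1]), offset = 0) {
  stopifnot(length(dim(movie)) == 3L, length(baseline) >= 1L,
            all(baseline >= 1), all(baseline <= dim(movie)[1]))
  movie <- movie + offset
  f0 <- apply(movie[baseline, , , drop = FALSE], c(2, 3), mean)
  nbad <- sum(f0 <= 0)
  if (nbad > 0) {
    stop(nbad, " pixels have non-positive baseline F0; ",
         "add a positive `offset` or restrict the mask")
  }
  dff <- sweep(sweep(movie, c(2, 3), f0, "-"), c(2, 3), f0, "/")
  attr(dff, "baseline") <- baseline
  dff
}

#' Stimulus-triggered average epoch
#'
#' Cuts a `(pre + post)`-frame window around each event (frames
#' `event - pre` to `event + post - 1`) and averages across events.
#'
#' @param dff T x H x W dF/F array.
#' @param event_frames integer stimulus-onset frames.
#' @param pre,post frames before / from the event (window length
#'   `pre + post`).
#' @return list with `epoch` (mean (pre+post) x H x W array), `trials`
#'   (n_events x (pre+post) x H x W array) and `stim_frame` (the in-epoch
#'   index of the event frame, `pre + 1`).
#' @export
stimulus_average <- function(dff, event_frames, pre, post) {
  Tn <- dim(dff)[1]
  lo <- event_frames - pre
  hi <- event_frames + post - 1
  bad <- lo < 1 | hi > Tn
  if (any(bad)) {
    stop("event windows out of movie bounds at frames: ",
         paste(event_frames[bad], collapse = ", "))
  }
  n <- length(event_frames)
  len <- pre + post
  trials <- array(0, c(n, len, dim(dff)[2], dim(dff)[3]))
  for (i in seq_len(n)) {
    trials[i, , , ] <- dff[lo[i]:hi[i], , , drop = FALSE]
  }
  epoch <- apply(trials, c(2, 3, 4), mean)
  list(epoch = epoch, trials = trials, stim_frame = pre + 1L)
}

#' Mean trace of an epoch over an ROI
#'
#' @param epoch L x H x W array.
#' @param roi_mask binary H x W matrix.
#' @return numeric vector of length L.
#' @export
roi_trace <- function(epoch, roi_mask) {
  sel <- roi_mask > 0
  apply(epoch, 1, function(fr) mean(fr[sel]))
}

#' Sensory peak map from an averaged epoch
#'
#' Per-pixel maximum dF/F over the frames after the stimulus, the peak pixel
#' (argmax; ties broken towards the smallest row, then column), and the
#' intensity-weighted centroid of pixels at or above
#' `centroid_frac * max`.
#'
#' @param avg_epoch L x H x W averaged epoch.
#' @param stim_frame_index in-epoch frame index of the stimulus; only frames
#'   strictly after it contribute.
#' @param centroid_frac activation threshold fraction for the centroid
#'   (default 0.75).
#' @return list of class `sensory_map` with `peak_map` (H x W), `peak_px`,
#'   `centroid_px`.
#' @export
peak_map <- function(avg_epoch, stim_frame_index, centroid_frac = 0.75) {
  L <- dim(avg_epoch)[1]
  stopifnot(stim_frame_index < L)
  post <- avg_epoch[(stim_frame_index + 1):L, , , drop = FALSE]
  pm <- apply(post, c(2, 3), max)
  mx <- max(pm)
  cand <- which(pm == mx, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  peak_px <- c(row = cand[1, 1], col = cand[1, 2])
  act <- pm >= centroid_frac * mx
  wsum <- sum(pm[act])
  centroid_px <- if (wsum > 0) {
    c(row = sum(row(pm)[act] * pm[act]) / wsum,
      col = sum(col(pm)[act] * pm[act]) / wsum)
  } else peak_px
  structure(list(peak_map = pm, peak_px = peak_px, centroid_px = centroid_px),
            class = "sensory_map")
}

#' @export
print.sensory_map <- function(x, ...) {
  cat(sprintf("sensory map: peak %.4f at (%d, %d), centroid (%.1f, %.1f)\n",
              max(x$peak_map), x$peak_px[1], x$peak_px[2],
              x$centroid_px[1], x$centroid_px[2]))
  invisible(x)
}

#' Split a recording into fixed-length epochs
#'
#' @param dff T x H x W array.
#' @param epoch_minutes epoch length in minutes (default 5).
#' @param frame_rate acquisition rate in Hz.
#' @return list of consecutive non-overlapping T_e x H x W segments; a
#'   trailing remainder shorter than one epoch is dropped with a warning.
#' @export
epoch_split <- function(dff, epoch_minutes = 5, frame_rate) {
  stopifnot(frame_rate > 0, epoch_minutes > 0)
  Tn <- dim(dff)[1]
  fpe <- round(epoch_minutes * 60 * frame_rate)
  n <- floor(Tn / fpe)
  if (n == 0) stop("recording shorter than one epoch")
  if (Tn %% fpe != 0) {
    warning(sprintf("dropping %d trailing frames (< 1 epoch)", Tn %% fpe))
  }
  lapply(seq_len(n), function(i) {
    dff[((i - 1) * fpe + 1):(i * fpe), , , drop = FALSE]
  })
}
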