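#' 50 Hz notch ("trap") filter
#'
#' Zero-phase biquad band-stop at 50 Hz (quality factor `Q`), applied
#' forwards and backwards so filtered peaks do not shift in time.
#'
#' @param rec a [continuous_recording()].
#' @param Q notch quality factor.
#' @return the filtered [continuous_recording()].
#' @export
notch_50hz <- function(rec, Q = 30) {
  if (rec$sfreq <= 100) stopf("sampling rate too low for a 50 Hz notch")
  des <- notch_biquad(50, rec$sfreq, Q)
  rec$signal <- t(filtfilt(des$b, des$a, t(rec$signal)))
  rec
}

#' 2-30 Hz zero-phase Butterworth band-pass
#'
#' 4th-order Butterworth prototype (8th-order band-pass), forward-backward.
#'
#' @param rec a [continuous_recording()].
#' @param low,high band edges in Hz.
#' @param order prototype order.
#' @return the filtered [continuous_recording()].
#' @export
bandpass_2_30 <- function(rec, low = 2, high = 30, order = 4) {
  if (rec$sfreq < 2 * high) stopf("sampling rate below 2x the upper band edge")
  des <- butter_bandpass(order, low, high, rec$sfreq)
  pad <- min(ncol(rec$signal) - 1, round(2 * rec$sfreq))
  rec$signal <- t(filtfilt(des$b, des$a, t(rec$signal), padlen = pad))
  rec
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' One epoch per event covering `tmin..tmax` ms around the flash onset.
#' Events whose window would leave the recording are dropped with a warning.
#'
#' @param rec a [continuous_recording()].
#' @param tmin,tmax epoch window in ms relative to stimulus onset.
#' @return an [epoch_set()]; `meta` keeps the surviving events' columns.
#' @export
segment_epochs <- function(rec, tmin = -200, tmax = 1200) {
  dt <- 1000 / rec$sfreq
  off <- round(tmin / dt):round(tmax / dt)
  n_smp <- length(off)                      # (tmax - tmin) * sfreq / 1000 + 1
  ok <- rec$events$sample + off[1] >= 1 &
    rec$events$sample + off[n_smp] <= ncol(rec$signal)
  if (any(!ok))
    warning(sprintf("dropping %d event(s) too close to the recording edge",
                    sum(!ok)))
  ev <- rec$events[ok, , drop = FALSE]
  data <- array(0, c(nrow(ev), nrow(rec$signal), n_smp))
  for (i in seq_len(nrow(ev)))
    data[i, , ] <- rec$signal[, ev$sample[i] + off]
  meta <- ev
  rownames(meta) <- NULL
  epoch_set(data, ev$label, meta, times = off * dt, sfreq = rec$sfreq,
            layout = rec$layout)
}

#' Censor the trials adjacent to each target
#'
#' The inter-trial interval is short enough that the P300 evoked by a target
#' bleeds into the neighbouring trials' windows, so for every target the
#' immediately preceding and immediately following trial *within the same
#' run* are removed. Targets themselves are always retained.
#'
#' @param es an [epoch_set()] whose `meta` has a `run` column and rows in
#'   presentation order within each run.
#' @return the censored [epoch_set()].
#' @export
censor_adjacent <- function(es) {
  if (is.null(es$meta$run)) stopf("censoring requires a 'run' column in meta")
  run_id <- es$meta$run
  if (!is.null(es$meta$block)) run_id <- paste(es$meta$block, run_id)
  if (!is.null(es$meta$subject))
    run_id <- paste(es$meta$subject, es$meta$session, es$meta$scenario, run_id)
  keep <- rep(TRUE, length(es$labels))
  for (ids in split(seq_along(es$labels), run_id)) {
    lab <- es$labels[ids]
    tpos <- which(lab == 1L)
    drop_pos <- setdiff(unique(c(tpos - 1L, tpos + 1L)), tpos)
    drop_pos <- drop_pos[drop_pos >= 1L & drop_pos <= length(ids)]
    keep[ids[drop_pos]] <- FALSE
  }
  epochs_subset(es, keep)
}

#' Linear detrend and crop to the analysis window
#'
#' Crops each epoch to `tmin..tmax` ms (201 samples at the defaults) and
#' removes the per-channel least-squares line over the cropped window.
#'
#' @param es an [epoch_set()] covering at least `tmin..tmax`.
#' @param tmin,tmax analysis window in ms.
#' @return the detrended, cropped [epoch_set()].
#' @export
detrend_and_crop <- function(es, tmin = -100, tmax = 700) {
  tol <- 1e-6
  sel <- which(es$times >= tmin - tol & es$times <= tmax + tol)
  n_expect <- round((tmax - tmin) * es$sfreq / 1000) + 1
  if (length(sel) != n_expect)
    stopf("epochs do not cover %g..%g ms (found %d of %d samples)",
          tmin, tmax, length(sel), n_expect)
  d <- dim(es$data)
  X <- matrix(aperm(es$data[, , sel, drop = FALSE], c(3, 2, 1)),
              nrow = length(sel))                   # samples x (ch * epoch)
  P <- cbind(1, seq_along(sel))
  X <- X - P %*% solve(crossprod(P), crossprod(P, X))
  data <- aperm(array(X, c(length(sel), d[2], d[1])), c(3, 2, 1))
  epoch_set(data, es$labels, es$meta, es$times[sel], es$sfreq, es$layout)
}

#' Full preprocessing chain
#'
#' Notch (optional) -> 2-30 Hz band-pass -> segmentation (-200..1200 ms) ->
#' target-adjacent censoring (optional) -> linear detrend + crop to
#' -100..700 ms, yielding the 8 x 201 epochs the classifier consumes.
#'
#' @param rec a [continuous_recording()].
#' @param notch apply the 50 Hz notch?
#' @param censor apply target-adjacent censoring?
#' @param low,high band-pass edges in Hz.
#' @param seg_window,out_window segmentation / analysis windows in ms.
#' @return an [epoch_set()].
#' @export
preprocess_recording <- function(rec, notch = TRUE, censor = TRUE,
                                 low = 2, high = 30,
                                 seg_window = c(-200, 1200),
                                 out_window = c(-100, 700)) {
  if (notch) rec <- notch_50hz(rec)
  rec <- bandpass_2_30(rec, low = low, high = high)
  es <- segment_epochs(rec, seg_window[1], seg_window[2])
  if (censor) es <- censor_adjacent(es)
  detrend_and_crop(es, out_window[1], out_window[2])
}
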