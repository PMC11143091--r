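#' Labelled epoch container
#'
#' The central data structure of the package: `n` trials of `channels x
#' samples` EEG (microvolts) plus a binary label vector and a per-trial
#' metadata table.
#'
#' @param data numeric array `n x channels x samples`.
#' @param labels binary vector (1 = target, 0 = standard), length `n`.
#' @param meta data.frame with one row per epoch.
#' @param times sample times in ms.
#' @param sfreq sampling rate in Hz.
#' @param layout a [channel_layout()].
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, meta = NULL, times, sfreq = 250,
                      layout = channel_layout()) {
  if (length(dim(data)) != 3L) stopf("epoch data must be n x channels x samples")
  n <- dim(data)[1]
  if (dim(data)[2] != length(layout$names))
    stopf("channel dimension (%d) does not match layout", dim(data)[2])
  if (dim(data)[3] != length(times))
    stopf("sample dimension (%d) does not match time axis", dim(data)[3])
  labels <- as.integer(labels)
  if (length(labels) != n || !all(labels %in% c(0L, 1L)))
    stopf("labels must be one 0/1 value per epoch")
  if (is.null(meta)) meta <- data.frame(label = labels)
  if (nrow(meta) != n) stopf("meta must have one row per epoch")
  structure(list(data = data, labels = labels, meta = meta,
                 times = as.numeric(times), sfreq = sfreq, layout = layout),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g..%g ms @ %g Hz)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times), x$sfreq))
  cat(sprintf("  targets: %d, standards: %d\n",
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Subset an epoch set by trial index or logical mask
#'
#' @param es an [epoch_set()].
#' @param idx integer or logical index over epochs.
#' @return the restricted [epoch_set()].
#' @export
epochs_subset <- function(es, idx) {
  epoch_set(es$data[idx, , , drop = FALSE], es$labels[idx],
            es$meta[idx, , drop = FALSE], es$times, es$sfreq, es$layout)
}

#' Concatenate epoch sets with identical geometry
#'
#' @param ... [epoch_set()] objects sharing times/layout.
#' @return the combined [epoch_set()].
#' @export
epochs_bind <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "epoch_set"))
    sets <- sets[[1]]
  base <- sets[[1]]
  data <- do.call(abind_first, lapply(sets, function(s) s$data))
  meta <- do.call(rbind, lapply(sets, function(s) s$meta))
  rownames(meta) <- NULL
  epoch_set(data, unlist(lapply(sets, function(s) s$labels)), meta,
            base$times, base$sfreq, base$layout)
}

# bind 3-d arrays along the first margin
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 0L))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Continuous multichannel recording with event markers
#'
#' @param signal numeric matrix `channels x samples` (microvolts).
#' @param sfreq sampling rate in Hz.
#' @param events data.frame with columns `sample` (1-based index), `label`
#'   (1 target / 0 standard) and optionally `run`; sorted by `sample`.
#' @param layout a [channel_layout()].
#' @return an object of class `continuous_recording`.
#' @export
continuous_recording <- function(signal, sfreq, events, layout = channel_layout()) {
  signal <- as.matrix(signal)
  if (nrow(signal) != length(layout$names))
    stopf("signal must be channels x samples matching the layout")
  events <- as.data.frame(events)
  if (!all(c("sample", "label") %in% names(events)))
    stopf("events need 'sample' and 'label' columns")
  if (is.unsorted(events$sample)) stopf("events must be sorted by sample index")
  if (nrow(events) && (min(events$sample) < 1 || max(events$sample) > ncol(signal)))
    stopf("event sample indices outside the recording")
  structure(list(signal = signal, sfreq = sfreq, events = events, layout = layout),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$sfreq, nrow(x$events)))
  invisible(x)
}

#' Write / read an epoch set as plain-text files
#'
#' `data` is stored as a TSV with one row per (epoch, channel) and one column
#' per sample; `meta` as a TSV; geometry as JSON. Everything round-trips.
#'
#' @param es an [epoch_set()].
#' @param prefix path prefix; files `<prefix>_data.tsv`, `<prefix>_meta.tsv`
#'   and `<prefix>_info.json` are written.
#' @return `prefix`, invisibly (`write`); an [epoch_set()] (`read`).
#' @export
write_epoch_set <- function(es, prefix) {
  d <- dim(es$data)
  flat <- matrix(aperm(es$data, c(2, 1, 3)), d[1] * d[2], d[3])
  write.table(format(flat, digits = 8, trim = TRUE, scientific = TRUE),
              paste0(prefix, "_data.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(es$meta, paste0(prefix, "_meta.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  info <- list(n = d[1], channels = es$layout$names, times = es$times,
               sfreq = es$sfreq, positions = es$layout$positions)
  jsonlite::write_json(info, paste0(prefix, "_info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(prefix) {
  info <- jsonlite::read_json(paste0(prefix, "_info.json"), simplifyVector = TRUE)
  flat <- as.matrix(read.table(paste0(prefix, "_data.tsv"), sep = "\t"))
  meta <- read.table(paste0(prefix, "_meta.tsv"), sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  n_ch <- length(info$channels)
  data <- aperm(array(flat, c(n_ch, info$n, length(info$times))), c(2, 1, 3))
  epoch_set(data, meta$label, meta, info$times, info$sfreq,
            channel_layout(info$channels, info$positions))
}

#' Write / read a continuous recording as plain-text files
#'
#' @param rec a [continuous_recording()].
#' @param prefix path prefix; `<prefix>_signal.tsv`, `<prefix>_events.tsv`
#'   and `<prefix>_info.json` are written.
#' @return `prefix`, invisibly (`write`); a [continuous_recording()] (`read`).
#' @export
write_recording <- function(rec, prefix) {
  write.table(format(t(rec$signal), digits = 8, trim = TRUE, scientific = TRUE),
              paste0(prefix, "_signal.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(rec$events, paste0(prefix, "_events.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sfreq = rec$sfreq, channels = rec$layout$names,
                            positions = rec$layout$positions),
                       paste0(prefix, "_info.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  info <- jsonlite::read_json(paste0(prefix, "_info.json"), simplifyVector = TRUE)
  sig <- t(as.matrix(read.table(paste0(prefix, "_signal.tsv"), sep = "\t")))
  ev <- read.table(paste0(prefix, "_events.tsv"), sep = "\t", header = TRUE)
  continuous_recording(sig, info$sfreq, ev,
                       channel_layout(info$channels, info$positions))
}
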