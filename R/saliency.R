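# Gradient saliency maps and the spatio-temporal quantifications derived
# from them: per-electrode and per-sample absolute-gradient profiles, the
# sliding-window "most varied interval" latency proxy, and the session-trend
# correlation.

#' Saliency map container
#'
#' Signed input gradients `M(i, j)` of one class score over channels x
#' samples, with provenance.
#'
#' @param values numeric matrix channels x samples.
#' @param times sample times in ms.
#' @param layout a [channel_layout()].
#' @param class_index class whose score was differentiated.
#' @param normalized has the map been max-|.|-scaled?
#' @param provenance free-form list (subject/session/scenario/n averaged).
#' @return an object of class `saliency_map`.
#' @export
saliency_map <- function(values, times, layout = channel_layout(),
                         class_index = 2L, normalized = FALSE,
                         provenance = list()) {
  values <- as.matrix(values)
  if (nrow(values) != length(layout$names)) stopf("row per channel required")
  if (ncol(values) != length(times)) stopf("column per sample required")
  rownames(values) <- layout$names
  structure(list(values = values, times = as.numeric(times), layout = layout,
                 class_index = class_index, normalized = normalized,
                 provenance = provenance),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d x %d, class %d, %s (n = %s)\n",
              nrow(x$values), ncol(x$values), x$class_index,
              if (x$normalized) "normalized" else "raw",
              x$provenance$n %||% "?"))
  invisible(x)
}

#' Compute the saliency map of an epoch (or mean over epochs)
#'
#' The gradient of the pre-softmax class score with respect to the input,
#' evaluated at the epoch itself; exactly the first-order-Taylor weight
#' vector of the network around that input. For a linear classifier this is
#' the weight vector itself, which anchors the test-suite.
#'
#' @param model an `eegnet_model` (or any object with an `input_gradient`
#'   method contract; see [input_gradient()]).
#' @param x an [epoch_set()] or `n x channels x samples` array.
#' @param class_index class whose score is attributed (2 = target).
#' @param average return one averaged map (`TRUE`) or a list of per-epoch
#'   maps?
#' @param normalize normalize per-epoch maps before averaging?
#' @return a [saliency_map()] (or list of them when `average = FALSE`).
#' @export
compute_saliency <- function(model, x, class_index = 2L, average = TRUE,
                             normalize = average) {
  es_times <- if (inherits(x, "epoch_set")) x$times else
    seq_len(model$cfg$n_samples)
  layout <- if (inherits(x, "epoch_set")) x$layout else channel_layout()
  g <- input_gradient(model, x, class_index = class_index)
  n <- dim(g)[1]
  maps <- lapply(seq_len(n), function(i)
    saliency_map(g[i, , ], es_times, layout, class_index,
                 provenance = list(n = 1L)))
  if (normalize) maps <- lapply(maps, normalize_map)
  if (!average) return(maps)
  average_maps(maps)
}

#' Normalize a saliency map to unit maximum absolute value
#'
#' Divides by `max(|values|)`, preserving sign; an all-zero map is returned
#' unchanged (flagged normalized).
#'
#' @param map a [saliency_map()].
#' @return the normalized [saliency_map()].
#' @export
normalize_map <- function(map) {
  m <- max(abs(map$values))
  if (m > 0) map$values <- map$values / m
  map$normalized <- TRUE
  map
}

#' Element-wise average of saliency maps
#'
#' @param maps list of [saliency_map()]s of identical shape and class.
#' @return the averaged [saliency_map()]; provenance records the total n.
#' @export
average_maps <- function(maps) {
  if (!length(maps)) stopf("empty list of maps")
  d <- dim(maps[[1]]$values)
  cls <- maps[[1]]$class_index
  acc <- 0; ntot <- 0L
  for (m in maps) {
    if (!all(dim(m$values) == d)) stopf("saliency map shape mismatch")
    if (m$class_index != cls) stopf("saliency map class mismatch")
    acc <- acc + m$values
    ntot <- ntot + (m$provenance$n %||% 1L)
  }
  out <- maps[[1]]
  out$values <- acc / length(maps)
  out$provenance$n <- ntot
  out
}

#' Spatial attribution profile
#'
#' Per-electrode mean of `|gradient|` across all samples: which electrodes
#' drive the classification.
#'
#' @param map a [saliency_map()].
#' @return named numeric vector, one non-negative value per electrode.
#' @export
spatial_profile <- function(map) {
  rowMeans(abs(map$values))
}

#' Temporal attribution profile
#'
#' Per-sample mean of `|gradient|` across electrodes: when the discriminative
#' signal occurs.
#'
#' @param map a [saliency_map()].
#' @return data.frame with `time` (ms) and `value`.
#' @export
temporal_profile <- function(map) {
  data.frame(time = map$times, value = colMeans(abs(map$values)))
}

#' Peak of a temporal profile inside a window
#'
#' @param profile data.frame from [temporal_profile()].
#' @param window inclusive window in ms.
#' @return list with `value` and `latency` (ms); ties break earliest.
#' @export
peak_gradient <- function(profile, window = c(300, 400)) {
  sel <- which(profile$time >= window[1] & profile$time <= window[2])
  if (!length(sel)) stopf("empty window")
  k <- sel[which.max(profile$value[sel])]   # which.max takes the first tie
  list(value = profile$value[k], latency = profile$time[k])
}

#' Most-varied sliding-window interval at one electrode
#'
#' Slides a `width` ms window in `step` ms increments over the epoch and
#' returns the window maximizing a statistic of `|gradient|` on the chosen
#' electrode's row (ties break earliest). The window center serves as the
#' P300-latency proxy for the session-trend analysis.
#'
#' @param map a [saliency_map()].
#' @param electrode electrode label (default `"Pz"`).
#' @param width,step window width and grid step in ms.
#' @param statistic window statistic: mean (default), sum or max of
#'   `|gradient|`.
#' @return list with `start`, `end`, `center` (ms) and `value`.
#' @export
most_varied_interval <- function(map, electrode = "Pz", width = 100, step = 5,
                                 statistic = c("mean", "sum", "max")) {
  statistic <- match.arg(statistic)
  ch <- match(electrode, map$layout$names)
  if (is.na(ch)) stopf("unknown electrode '%s'", electrode)
  row <- abs(map$values[ch, ])
  tmin <- min(map$times); tmax <- max(map$times)
  if (width > tmax - tmin) stopf("window wider than the epoch")
  starts <- seq(tmin, tmax - width, by = step)
  fun <- switch(statistic, mean = mean, sum = sum, max = max)
  vals <- vapply(starts, function(s) {
    fun(row[map$times >= s & map$times <= s + width])
  }, 0)
  k <- which.max(vals)                       # first tie = earliest window
  list(start = starts[k], end = starts[k] + width,
       center = starts[k] + width / 2, value = vals[k])
}

#' Session trend of a latency proxy
#'
#' Pearson correlation between session number and the per-session latency
#' values, with the exact t-transform p-value (`df = n - 2`).
#'
#' @param centers per-session latency values (ms).
#' @param sessions session numbers (default `1..length(centers)`).
#' @return list with `r`, `p`, `df`, `n`.
#' @export
latency_trend <- function(centers, sessions = seq_along(centers)) {
  pearson_cor(sessions, centers)
}

#' Per-session saliency interval table
#'
#' For each session (and scenario) in an epoch set: average the normalized
#' target-trial saliency maps, locate the most-varied interval at the chosen
#' electrode, and tabulate the results; the downstream trend statistic
#' consumes the `center` column.
#'
#' @param model a trained `eegnet_model`.
#' @param es an [epoch_set()] with `session` (and optionally `scenario`)
#'   metadata.
#' @param electrode,width,step,statistic see [most_varied_interval()].
#' @param class_index attributed class (2 = target).
#' @param targets_only restrict to target trials (default)?
#' @return data.frame with scenario, session, start, center, value.
#' @export
session_intervals <- function(model, es, electrode = "Pz", width = 100,
                              step = 5, statistic = "mean", class_index = 2L,
                              targets_only = TRUE) {
  if (targets_only) es <- epochs_subset(es, es$labels == 1L)
  scen <- es$meta$scenario %||% rep("all", length(es$labels))
  cells <- split(seq_along(es$labels), list(es$meta$session, scen),
                 drop = TRUE)
  rows <- lapply(cells, function(ci) {
    sub <- epochs_subset(es, ci)
    map <- compute_saliency(model, sub, class_index = class_index)
    iv <- most_varied_interval(map, electrode, width, step, statistic)
    data.frame(scenario = scen[ci[1]], session = es$meta$session[ci[1]],
               start = iv$start, end = iv$end, center = iv$center,
               value = iv$value, n = length(ci))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$scenario, out$session), ]
  rownames(out) <- NULL
  out
}

#' Linear classifier used as a saliency ground-truth oracle
#'
#' A linear class score `h_c(X) = <w_c, X> + b_c` whose input gradient is
#' its weight matrix exactly, independent of the input. Implements the same
#' `input_gradient` contract as the network, so it can be swapped into
#' [compute_saliency()].
#'
#' @param weights channels x samples weight matrix (class 2 score; class 1
#'   score is its negation).
#' @param bias scalar offset.
#' @return an object of class `linear_oracle`.
#' @export
linear_oracle <- function(weights, bias = 0) {
  structure(list(weights = as.matrix(weights), bias = bias,
                 cfg = list(n_channels = nrow(weights),
                            n_samples = ncol(weights), n_classes = 2L)),
            class = "linear_oracle")
}

#' @export
input_gradient.linear_oracle <- function(model, x, class_index = 2L, ...) {
  X <- if (inherits(x, "epoch_set")) x$data else x
  n <- dim(X)[1]
  sgn <- if (class_index == 2L) 1 else -1
  out <- array(0, dim(X))
  for (i in seq_len(n)) out[i, , ] <- sgn * model$weights
  out
}
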