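# Conventional ERP analysis at a single electrode plus the package's shared
# statistical primitives (paired t, Pearson). The primitives are implemented
# from their closed forms and cross-checked against stats::t.test /
# stats::cor.test in the test-suite.

#' Grand-average ERP waveform at one electrode
#'
#' Arithmetic mean across the selected trials.
#'
#' @param es an [epoch_set()].
#' @param electrode electrode label.
#' @param select optional logical/integer trial selection (e.g.
#'   `es$labels == 1`).
#' @return object of class `erp_waveform`: data.frame with `time` and
#'   `amplitude`, plus `n_trials` and `electrode` attributes.
#' @export
grand_average <- function(es, electrode = "Pz", select = NULL) {
  ch <- match(electrode, es$layout$names)
  if (is.na(ch)) stopf("unknown electrode '%s'", electrode)
  idx <- if (is.null(select)) seq_along(es$labels) else which(
    if (is.logical(select)) select else seq_along(es$labels) %in% select)
  if (!length(idx)) stopf("empty trial selection")
  amp <- colMeans(matrix(es$data[idx, ch, ], nrow = length(idx)))
  out <- data.frame(time = es$times, amplitude = amp)
  attr(out, "n_trials") <- length(idx)
  attr(out, "electrode") <- electrode
  class(out) <- c("erp_waveform", "data.frame")
  out
}

#' Measure an ERP component on a waveform
#'
#' Peak amplitude and its latency within the component's window (defaults:
#' P200 = 150-250 ms, P300 = 300-500 ms). Ties break earliest.
#'
#' @param wave an `erp_waveform` (or data.frame with `time`, `amplitude`).
#' @param component `"P200"` or `"P300"`, or a custom label with `window`.
#' @param window optional window override in ms.
#' @param measure `"peak"` (default) or `"mean"` over the window.
#' @return list with `component`, `window`, `measure`, `value` (uV) and
#'   `latency` (ms; `NA` for the mean measure).
#' @export
component_amplitude <- function(wave, component = c("P300", "P200"),
                                window = NULL, measure = c("peak", "mean")) {
  measure <- match.arg(measure)
  if (is.null(window)) {
    component <- match.arg(component)
    window <- switch(component, P200 = c(150, 250), P300 = c(300, 500))
  } else component <- component[1]
  sel <- which(wave$time >= window[1] & wave$time <= window[2])
  if (!length(sel)) stopf("component window outside the epoch")
  if (measure == "peak") {
    k <- sel[which.max(wave$amplitude[sel])]
    list(component = component, window = window, measure = measure,
         value = wave$amplitude[k], latency = wave$time[k])
  } else {
    list(component = component, window = window, measure = measure,
         value = mean(wave$amplitude[sel]), latency = NA_real_)
  }
}

#' Paired two-sided t-test (closed form)
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences, `df = n - 1`,
#' exact two-sided p from the t distribution.
#'
#' @param a,b equal-length per-subject values.
#' @return list with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stopf("paired samples must have equal length")
  d <- a - b
  n <- length(d)
  if (n < 2) stopf("need at least 2 pairs")
  s <- sd(d)
  if (s == 0) {
    # identical samples: t = 0 by continuity; a constant non-zero
    # difference has no finite t
    if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n))
    stopf("zero-variance differences: t undefined")
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, df = n - 1,
       p = 2 * pt(-abs(t_stat), df = n - 1),
       mean_diff = mean(d), n = n)
}

#' Pearson product-moment correlation with exact p (closed form)
#'
#' `r = cov(x, y) / (sd(x) sd(y))`; two-sided p via
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `df = n - 2`.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, non-constant.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch")
  n <- length(x)
  if (n < 3) stopf("need at least 3 points")
  if (sd(x) == 0 || sd(y) == 0) stopf("constant input: r undefined")
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc * xc) * sum(yc * yc))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  list(r = r, p = p, df = n - 2, n = n)
}

#' Independent two-sample t-test with pooled variance (closed form)
#'
#' Classical equal-variance t, `df = n1 + n2 - 2`, two-sided p. Used to
#' compare per-subject accuracy distributions of two models.
#'
#' @param a,b numeric samples (`>= 2` values each).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
ttest2 <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stopf("need at least 2 values per group")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) stopf("degenerate (zero) pooled variance")
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t_stat, df = n1 + n2 - 2,
       p = 2 * pt(-abs(t_stat), df = n1 + n2 - 2),
       mean_a = mean(a), mean_b = mean(b))
}
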