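make_rec <- function(signal_fun, dur = 8, fs = 250, events = NULL) {
  t <- seq(0, dur, by = 1 / fs)
  sig <- matrix(rep(signal_fun(t), each = 8), nrow = 8, byrow = FALSE)
  sig <- matrix(signal_fun(t), nrow = 8, ncol = length(t), byrow = TRUE)
  if (is.null(events)) events <- data.frame(sample = integer(0), label = integer(0))
  continuous_recording(sig, fs, events)
}

test_that("50 Hz notch: deep stop-band, transparent pass-band, zero phase", {
  t <- seq(0, 8, by = 1 / 250)
  r50 <- make_rec(function(t) sin(2 * pi * 50 * t))
  out50 <- notch_50hz(r50)
  expect_lte(rms(out50$signal[1, ]), 0.1 * rms(r50$signal[1, ]))  # >= 20 dB

  r10 <- make_rec(function(t) sin(2 * pi * 10 * t))
  out10 <- notch_50hz(r10)
  expect_lt(abs(rms(out10$signal[1, ]) / rms(r10$signal[1, ]) - 1), 0.05)

  rz <- make_rec(function(t) 0 * t)
  expect_equal(max(abs(notch_50hz(rz)$signal)), 0)
  expect_error(notch_50hz(continuous_recording(matrix(0, 8, 100), 80,
                                               data.frame(sample = integer(0),
                                                          label = integer(0)))),
               "sampling rate")

  # pass-band gain within +/- 1 dB below 45 Hz
  des <- notch_biquad(50, 250, 30)
  f <- seq(1, 45, by = 1)
  gain_db <- 20 * log10(Mod(p300net:::freq_response(des$b, des$a, f, 250))^2)
  expect_true(all(abs(gain_db) <= 1))
})

test_that("2-30 Hz band-pass meets its attenuation/preservation posts", {
  mk <- function(f) make_rec(function(t) sin(2 * pi * f * t))
  att <- function(f) {
    r <- mk(f)
    20 * log10(rms(bandpass_2_30(r)$signal[1, ]) / rms(r$signal[1, ]))
  }
  expect_lte(att(0.5), -12)
  expect_lte(att(45), -12)
  expect_lt(abs(att(10)), 20 * log10(1.05))    # 10 Hz within 5% RMS

  # DC offset removed
  rdc <- make_rec(function(t) rep(10, length(t)))
  expect_lt(abs(mean(bandpass_2_30(rdc)$signal[1, ])), 0.1)
  # zero in, zero out
  rz <- make_rec(function(t) 0 * t)
  expect_equal(max(abs(bandpass_2_30(rz)$signal)), 0)
  expect_error(bandpass_2_30(continuous_recording(matrix(0, 8, 100), 50,
                                                  data.frame(sample = integer(0),
                                                             label = integer(0)))),
               "sampling rate")
})

test_that("filters are zero-phase: an injected bump does not shift", {
  fs <- 250
  t <- seq(0, 8, by = 1 / fs)
  bump <- exp(-0.5 * ((t - 4) / 0.05)^2)       # 50 ms wide bump at 4 s
  rec <- make_rec(function(t) bump)
  for (out in list(notch_50hz(rec), bandpass_2_30(rec))) {
    expect_lte(abs(which.max(out$signal[1, ]) - which.max(bump)), 1)
  }
})

test_that("segmentation: sample counts, empty events, edge dropping", {
  fs <- 250
  sig <- matrix(rnorm(8 * 2000), 8)
  ev <- data.frame(sample = c(10L, 500L, 1000L, 1990L),
                   label = c(0L, 1L, 0L, 0L), run = 1L)
  rec <- continuous_recording(sig, fs, ev)
  expect_warning(es <- segment_epochs(rec, -200, 1200), "2 event")
  expect_identical(dim(es$data), c(2L, 8L, 351L))   # 1.4 s * 250 + 1
  expect_identical(es$meta$sample, c(500L, 1000L))
  # epoch content matches the raw slice
  expect_equal(es$data[1, , ], sig[, (500 - 50):(500 + 300)])

  rec0 <- continuous_recording(sig, fs,
                               data.frame(sample = integer(0), label = integer(0)))
  expect_identical(dim(segment_epochs(rec0)$data)[1], 0L)
})

test_that("censor_adjacent drops exactly the neighbours of each target", {
  mk_es <- function(labels, runs) {
    n <- length(labels)
    epoch_set(array(seq_len(n * 8 * 201), c(n, 8, 201)), labels,
              meta = data.frame(run = runs, label = labels),
              times = epoch_times(sim_config()))
  }
  # enumerated rule: [0,0,0,1,0,0,0,0] -> positions 3 and 5 (1-based) removed
  es <- mk_es(c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L), rep(1L, 8))
  out <- censor_adjacent(es)
  expect_identical(dim(out$data)[1], 6L)
  expect_identical(which(es$data[, 1, 1] %in% out$data[, 1, 1]),
                   c(1L, 2L, 4L, 6L, 7L, 8L))
  # run with no target unchanged
  es2 <- mk_es(rep(0L, 8), rep(1L, 8))
  expect_identical(dim(censor_adjacent(es2)$data)[1], 8L)
  # target first in run: only the following trial removed
  es3 <- mk_es(c(1L, 0L, 0L, 0L), rep(1L, 4))
  out3 <- censor_adjacent(es3)
  expect_identical(dim(out3$data)[1], 3L)
  expect_identical(out3$labels[1], 1L)
  # no cross-run censoring: last trial of run 1 precedes run 2's leading target
  es4 <- mk_es(c(0L, 0L, 1L, 0L), c(1L, 1L, 2L, 2L))
  expect_identical(dim(censor_adjacent(es4)$data)[1], 3L)
  # censoring never removes a target; counts match the closed form
  set.seed(8)
  for (rep in 1:5) {
    labels <- integer(0); runs <- integer(0)
    for (r in 1:6) {
      lab <- integer(8); lab[sample(8, 1)] <- 1L
      labels <- c(labels, lab); runs <- c(runs, rep(r, 8))
    }
    out <- censor_adjacent(mk_es(labels, runs))
    expect_identical(sum(out$labels), 6L)
    # closed form: 8 - 1 target - (neighbours of target inside the run)
    expected_n <- sum(vapply(split(labels, runs), function(lab) {
      tpos <- which(lab == 1L)
      8L - length(intersect(c(tpos - 1L, tpos + 1L), seq_len(8L)))
    }, 0L))
    expect_identical(dim(out$data)[1], expected_n)
  }
  expect_error(censor_adjacent(epoch_set(array(0, c(1, 8, 201)), 0L,
                                         meta = data.frame(label = 0L),
                                         times = epoch_times(sim_config()))),
               "run")
})

test_that("detrend_and_crop: annihilates lines, recovers sine, 201 samples", {
  times_full <- seq(-200, 1200, by = 4)
  n_t <- length(times_full)
  data <- array(0, c(2, 8, n_t))
  line <- 0.5 * times_full + 3
  sine <- sin(2 * pi * 7 * times_full / 1000)
  for (ch in 1:8) {
    data[1, ch, ] <- line
    data[2, ch, ] <- sine + line
  }
  es <- epoch_set(data, c(0L, 0L), meta = data.frame(label = c(0L, 0L)),
                  times = times_full)
  out <- detrend_and_crop(es)
  expect_identical(dim(out$data)[3], 201L)
  expect_equal(out$times, seq(-100, 700, by = 4))
  # a perfect line maps to (numerically) zero
  expect_lt(max(abs(out$data[1, , ])), 1e-9)
  # sine + line: sine recovered up to its own best-fit line
  crop <- which(times_full >= -100 & times_full <= 700)
  sref <- sine[crop]
  P <- cbind(1, seq_along(crop))
  sref <- sref - P %*% solve(crossprod(P), crossprod(P, sref))
  expect_lt(rms(out$data[2, 1, ] - sref), 1e-6)

  expect_error(detrend_and_crop(es, -300, 700), "cover")
})

test_that("full chain on a simulated continuous recording recovers the epochs", {
  cfg <- sim_config(seed = 31L, n_subjects = 1L, n_sessions = 1L,
                    blocks_per_session = 2L, runs_per_block = 8L,
                    noise = noise_spec(sigma = 2),
                    subject_lat_sd = 0, subject_amp_sd = 0)
  rec <- simulate_continuous(cfg, subject = 1L, session = 1L,
                             scenario = "social")
  es <- preprocess_recording(rec)
  expect_identical(dim(es$data)[2:3], c(8L, 201L))
  expect_identical(sum(es$labels), 16L)         # all targets survive censoring

  # reference: the identical chain on a noise-free rendering, i.e. the
  # injected template as the filters see it (in-band content)
  cfg0 <- cfg
  cfg0$noise <- noise_spec(sigma = 0)
  es0 <- preprocess_recording(simulate_continuous(cfg0, 1L, 1L, "social"))
  ref <- colMeans(matrix(es0$data[es0$labels == 1L, 6, ], nrow = sum(es0$labels)))
  got <- colMeans(matrix(es$data[es$labels == 1L, 6, ], nrow = sum(es$labels)))
  expect_gt(cor(got, ref), 0.95)
  # zero-phase chain: the filtered template still peaks at the injected
  # latency (+/- 1 sample) inside the P300 window
  win <- which(es0$times >= 300 & es0$times <= 500)
  expect_lte(abs(es0$times[win][which.max(ref[win])] - 400), 4)
})
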