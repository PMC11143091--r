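#' Standard 8-electrode montage used throughout the package
#'
#' The montage covers the centro-parietal strip where the P300 is maximal:
#' C3, Cz, C4, CPz, P3, Pz, P4, POz. Positions are schematic 2-D scalp
#' coordinates (anterior-posterior y, left-right x, arbitrary units) used only
#' to derive smooth topography weights.
#'
#' @param names electrode labels; must be 8 unique labels.
#' @param positions 8 x 2 numeric matrix of (x, y) coordinates.
#' @return an object of class `channel_layout`.
#' @export
channel_layout <- function(names = c("C3", "Cz", "C4", "CPz", "P3", "Pz", "P4", "POz"),
                           positions = NULL) {
  if (length(names) != 8L || anyDuplicated(names))
    stopf("layout must have exactly 8 unique channel names")
  if (is.null(positions)) {
    positions <- rbind(
      C3 = c(-0.5, 0.0), Cz = c(0.0, 0.0), C4 = c(0.5, 0.0),
      CPz = c(0.0, -0.25), P3 = c(-0.4, -0.5), Pz = c(0.0, -0.5),
      P4 = c(0.4, -0.5), POz = c(0.0, -0.75))
    rownames(positions) <- NULL
  }
  positions <- as.matrix(positions)
  if (!all(dim(positions) == c(8L, 2L))) stopf("positions must be 8 x 2")
  structure(list(names = as.character(names), positions = positions),
            class = "channel_layout")
}

#' ERP component template
#'
#' A single ERP component is modelled as a Gaussian bump in time projected
#' through a rank-1 spatial topography: real grand-average components are
#' smooth and unimodal, and a Gaussian gives direct control over the peak
#' latency and width that the recovery tests must find again.
#'
#' @param name component label, e.g. `"P300"`.
#' @param peak_latency peak time in ms post-stimulus.
#' @param width temporal spread (Gaussian sigma) in ms; must be positive.
#' @param amplitude peak amplitude in microvolts.
#' @param topography per-channel weight in `[0, 1]`, maximum exactly 1 at the
#'   focal electrode.
#' @return an object of class `component_spec`.
#' @export
component_spec <- function(name, peak_latency, width, amplitude, topography) {
  if (width <= 0) stopf("component width must be positive")
  topography <- as.numeric(topography)
  if (length(topography) != 8L) stopf("topography needs one weight per channel")
  if (any(topography < 0 | topography > 1)) stopf("topography weights must lie in [0, 1]")
  if (abs(max(topography) - 1) > 1e-12) stopf("max topography weight must be 1")
  structure(list(name = name, peak_latency = peak_latency, width = width,
                 amplitude = amplitude, topography = topography),
            class = "component_spec")
}

default_components <- function(layout = channel_layout()) {
  # parietal-maximal P300 (focal Pz), weaker frontocentral P200 (focal Cz)
  p300_topo <- c(0.30, 0.50, 0.30, 0.70, 0.80, 1.00, 0.80, 0.70)
  p200_topo <- c(0.60, 1.00, 0.60, 0.80, 0.50, 0.55, 0.50, 0.40)
  names(p300_topo) <- names(p200_topo) <- layout$names
  list(
    P200 = component_spec("P200", peak_latency = 200, width = 25,
                          amplitude = 3, topography = p200_topo),
    P300 = component_spec("P300", peak_latency = 400, width = 45,
                          amplitude = 5, topography = p300_topo))
}

#' Scenario effect structure
#'
#' @param label `"social"` or `"non-social"`.
#' @param p200_gain multiplicative gain on the P200 amplitude.
#' @param p300_latency_by_session 7 P300 peak latencies (ms), one per session.
#' @param discriminability scale factor on the target/non-target component
#'   contrast.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(label,
                          p200_gain = 1,
                          p300_latency_by_session = rep(400, 7),
                          discriminability = 1) {
  if (length(p300_latency_by_session) != 7L)
    stopf("need exactly 7 per-session P300 latencies")
  structure(list(label = label, p200_gain = p200_gain,
                 p300_latency_by_session = as.numeric(p300_latency_by_session),
                 discriminability = discriminability),
            class = "scenario_spec")
}

default_scenarios <- function() {
  list(
    social = scenario_spec("social", p200_gain = 1.5,
                           p300_latency_by_session = seq(400, 340, length.out = 7)),
    `non-social` = scenario_spec("non-social", p200_gain = 1,
                                 p300_latency_by_session = rep(400, 7)))
}

#' Background-noise model
#'
#' @param spectral_exponent exponent alpha of the 1/f^alpha power spectrum.
#' @param sigma per-channel noise standard deviation in microvolts.
#' @param channel_correlation common-source mixing coefficient in `[0, 1]`.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(spectral_exponent = 1, sigma = 4, channel_correlation = 0.3) {
  if (sigma < 0) stopf("noise sigma must be >= 0")
  if (channel_correlation < 0 || channel_correlation > 1)
    stopf("channel_correlation must lie in [0, 1]")
  structure(list(spectral_exponent = spectral_exponent, sigma = sigma,
                 channel_correlation = channel_correlation),
            class = "noise_spec")
}

#' Oddball-paradigm simulation configuration
#'
#' Defaults reproduce the recorded paradigm: 7 sessions, 20 blocks of 10 runs
#' of 8 trials with exactly one target per run (1:7 imbalance), 200 ms
#' stimulus-onset asynchrony with 100 ms flashes, 250 Hz sampling, epochs of
#' -100..700 ms (8 x 201).
#'
#' @param seed master integer seed.
#' @param n_subjects number of simulated subjects.
#' @param n_sessions number of training sessions (7).
#' @param blocks_per_session,runs_per_block,trials_per_run paradigm structure.
#' @param targets_per_run number of targets per run (1).
#' @param soa stimulus-onset asynchrony in ms.
#' @param flash flash duration in ms.
#' @param sfreq sampling rate in Hz.
#' @param layout a [channel_layout()].
#' @param scenarios named list of two [scenario_spec()] objects.
#' @param components named list of [component_spec()] objects.
#' @param noise a [noise_spec()].
#' @param subject_lat_sd per-subject latency jitter SD in ms.
#' @param subject_amp_sd per-subject relative amplitude jitter SD.
#' @param nontarget_gain component gain on non-target trials (0 = pure noise).
#' @param tmin,tmax epoch window in ms.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_subjects = 4L, n_sessions = 7L,
                       blocks_per_session = 20L, runs_per_block = 10L,
                       trials_per_run = 8L, targets_per_run = 1L,
                       soa = 200, flash = 100, sfreq = 250,
                       layout = channel_layout(),
                       scenarios = default_scenarios(),
                       components = default_components(layout),
                       noise = noise_spec(),
                       subject_lat_sd = 10, subject_amp_sd = 0.1,
                       nontarget_gain = 0,
                       tmin = -100, tmax = 700) {
  stopifnot(targets_per_run == 1L, trials_per_run >= 1L)
  cfg <- structure(list(
    seed = as.integer(seed), n_subjects = as.integer(n_subjects),
    n_sessions = as.integer(n_sessions),
    blocks_per_session = as.integer(blocks_per_session),
    runs_per_block = as.integer(runs_per_block),
    trials_per_run = as.integer(trials_per_run),
    targets_per_run = as.integer(targets_per_run),
    soa = soa, flash = flash, sfreq = sfreq, layout = layout,
    scenarios = scenarios, components = components, noise = noise,
    subject_lat_sd = subject_lat_sd, subject_amp_sd = subject_amp_sd,
    nontarget_gain = nontarget_gain, tmin = tmin, tmax = tmax),
    class = "sim_config")
  cfg
}

#' Epoch time axis in ms
#'
#' @param cfg a [sim_config()] (or anything with `tmin`, `tmax`, `sfreq`).
#' @return numeric vector of sample times; `-100..700` at 250 Hz gives 201.
#' @export
epoch_times <- function(cfg = sim_config()) {
  seq(cfg$tmin, cfg$tmax, by = 1000 / cfg$sfreq)
}

#' Evaluate an ERP component template on a time axis
#'
#' Gaussian bump `amplitude * exp(-((t - peak)/width)^2 / 2)`: unimodal,
#' peaks at `peak_latency` with value `amplitude`, and falls below 1% of the
#' peak outside roughly `peak_latency +/- 3 * width`.
#'
#' @param spec a [component_spec()].
#' @param times time axis in ms.
#' @return numeric vector of per-sample amplitudes (microvolts).
#' @export
component_waveform <- function(spec, times) {
  if (spec$width <= 0) stopf("component width must be positive")
  spec$amplitude * exp(-0.5 * ((times - spec$peak_latency) / spec$width)^2)
}

# 1/f^alpha colored noise, one series per column; standardized so every
# column has the requested sd. FFT spectral shaping of white noise.
colored_noise <- function(n_samples, n_series, spec) {
  if (spec$sigma == 0) return(matrix(0, n_samples, n_series))
  rho <- spec$channel_correlation
  extra <- if (rho > 0 && n_series > 1) 1L else 0L
  white <- matrix(rnorm(n_samples * (n_series + extra)), n_samples, n_series + extra)
  if (spec$spectral_exponent != 0) {
    freqs <- c(0, seq_len(n_samples - 1))
    freqs <- pmin(freqs, n_samples - freqs)   # two-sided FFT bin frequencies
    scale <- c(0, freqs[-1]^(-spec$spectral_exponent / 2)) # kill DC
    shaped <- Re(mvfft(mvfft(white) * scale, inverse = TRUE)) / n_samples
  } else {
    shaped <- white
  }
  shaped <- sweep(shaped, 2, apply(shaped, 2, sd), "/")
  if (extra == 1L) {
    common <- shaped[, n_series + 1L]
    shaped <- sqrt(1 - rho) * shaped[, seq_len(n_series), drop = FALSE] +
      sqrt(rho) * common
  }
  spec$sigma * shaped
}

# draw per-subject, per-component latency shifts (ms) and amplitude factors
subject_effects <- function(cfg, subject) {
  with_seed(derive_seed(cfg$seed, 101L, subject), {
    nm <- names(cfg$components)
    list(
      lat = stats::setNames(rnorm(length(nm), 0, cfg$subject_lat_sd), nm),
      amp = stats::setNames(pmax(0.1, rnorm(length(nm), 1, cfg$subject_amp_sd)), nm))
  })
}

# component sum (8 x T signal matrix) for one trial, without noise
trial_signal <- function(cfg, scenario, session, effects, target, times) {
  sig <- matrix(0, 8L, length(times))
  gain <- if (target) 1 else cfg$nontarget_gain
  if (gain == 0) return(sig)
  for (nm in names(cfg$components)) {
    comp <- cfg$components[[nm]]
    if (nm == "P300")
      comp$peak_latency <- scenario$p300_latency_by_session[session]
    if (nm == "P200")
      comp$amplitude <- comp$amplitude * scenario$p200_gain
    comp$peak_latency <- comp$peak_latency + effects$lat[[nm]]
    comp$amplitude <- comp$amplitude * effects$amp[[nm]] *
      scenario$discriminability * gain
    sig <- sig + outer(comp$topography, component_waveform(comp, times))
  }
  sig
}

#' Generate a single 8 x 201 epoch
#'
#' Draws from the current RNG stream (seed it for reproducibility). Target
#' epochs contain all configured components scaled by the scenario/session
#' rules projected through their topographies; non-target epochs contain
#' noise plus `nontarget_gain`-attenuated components.
#'
#' @param record list with `subject`, `session`, `scenario`, `label`.
#' @param cfg a [sim_config()].
#' @return numeric matrix, channels x samples (8 x 201 at the defaults).
#' @export
generate_epoch <- function(record, cfg = sim_config()) {
  scen <- cfg$scenarios[[record$scenario]]
  if (is.null(scen)) stopf("unknown scenario label '%s'", record$scenario)
  times <- epoch_times(cfg)
  effects <- subject_effects(cfg, record$subject)
  sig <- trial_signal(cfg, scen, record$session, effects,
                      target = record$label == 1L, times)
  noise <- t(colored_noise(length(times), 8L, cfg$noise))
  sig + noise
}

#' Generate a full labelled oddball dataset
#'
#' Per subject x session x scenario the schedule is `blocks_per_session`
#' blocks of `runs_per_block` runs of `trials_per_run` flashes with exactly
#' one target per run, so the target:non-target ratio is exactly 1:7 at the
#' default run length. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param scenarios optional character vector restricting which scenarios to
#'   simulate (default: all configured).
#' @return an [epoch_set()] whose `meta` table carries subject, session,
#'   scenario, block, run, trial position, label and the injected P300
#'   latency (ground truth for recovery tests; `NA` on non-targets).
#' @export
generate_dataset <- function(cfg = sim_config(), scenarios = names(cfg$scenarios)) {
  times <- epoch_times(cfg)
  n_t <- length(times)
  per_run <- cfg$trials_per_run
  runs <- cfg$blocks_per_session * cfg$runs_per_block
  n_per <- runs * per_run
  total <- cfg$n_subjects * cfg$n_sessions * length(scenarios) * n_per
  data <- array(0, c(total, 8L, n_t))
  meta <- vector("list", cfg$n_subjects * cfg$n_sessions * length(scenarios))
  idx <- 0L; mi <- 0L
  for (subj in seq_len(cfg$n_subjects)) {
    effects <- subject_effects(cfg, subj)
    for (sess in seq_len(cfg$n_sessions)) {
      for (si in seq_along(scenarios)) {
        sc_name <- scenarios[[si]]
        scen <- cfg$scenarios[[sc_name]]
        if (is.null(scen)) stopf("unknown scenario label '%s'", sc_name)
        set.seed(derive_seed(cfg$seed, subj, sess, si))
        target_pos <- sample.int(per_run, runs, replace = TRUE)
        labels <- integer(n_per)
        labels[(seq_len(runs) - 1L) * per_run + target_pos] <- 1L
        # signal templates for this cell (target / non-target)
        sig_t <- trial_signal(cfg, scen, sess, effects, TRUE, times)
        sig_n <- trial_signal(cfg, scen, sess, effects, FALSE, times)
        noise <- colored_noise(n_t * n_per, 8L, cfg$noise)
        for (tr in seq_len(n_per)) {
          ep <- t(noise[((tr - 1L) * n_t + 1L):(tr * n_t), , drop = FALSE])
          data[idx + tr, , ] <- ep + (if (labels[tr] == 1L) sig_t else sig_n)
        }
        true_lat <- ifelse(labels == 1L,
                           scen$p300_latency_by_session[sess] + effects$lat[["P300"]],
                           NA_real_)
        mi <- mi + 1L
        meta[[mi]] <- data.frame(
          subject = subj, session = sess, scenario = sc_name,
          block = rep(seq_len(cfg$blocks_per_session), each = cfg$runs_per_block * per_run),
          run = rep(seq_len(runs), each = per_run),
          trial = rep(seq_len(per_run), runs),
          label = labels, true_p300_latency = true_lat)
        idx <- idx + n_per
      }
    }
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  epoch_set(data, meta$label, meta, times = times, sfreq = cfg$sfreq,
            layout = cfg$layout)
}

#' Render one session cell as a continuous recording
#'
#' Places each trial's component response additively at its flash onset on a
#' continuous timeline (SOA `cfg$soa` ms between flashes, a gap between
#' runs), adds 1/f background noise over the whole record, and returns a
#' [continuous_recording()] with event markers. Used for round-trip testing
#' of the preprocessing chain.
#'
#' @param cfg a [sim_config()].
#' @param subject,session,scenario which cell to render.
#' @param run_gap silence between runs in ms.
#' @return a [continuous_recording()].
#' @export
simulate_continuous <- function(cfg = sim_config(), subject = 1L, session = 1L,
                                scenario = names(cfg$scenarios)[[1]],
                                run_gap = 2000) {
  scen <- cfg$scenarios[[scenario]]
  if (is.null(scen)) stopf("unknown scenario label '%s'", scenario)
  effects <- subject_effects(cfg, subject)
  times <- epoch_times(cfg)
  dt <- 1000 / cfg$sfreq
  per_run <- cfg$trials_per_run
  runs <- cfg$blocks_per_session * cfg$runs_per_block
  si <- match(scenario, names(cfg$scenarios))
  set.seed(derive_seed(cfg$seed, subject, session, si, 7L))
  target_pos <- sample.int(per_run, runs, replace = TRUE)

  soa_smp <- round(cfg$soa / dt)
  gap_smp <- round(run_gap / dt)
  edge <- round(2000 / dt)                       # lead-in / lead-out
  run_len <- per_run * soa_smp
  n_total <- 2L * edge + runs * run_len + (runs - 1L) * gap_smp
  onsets <- integer(0); labels <- integer(0)
  for (r in seq_len(runs)) {
    base <- edge + (r - 1L) * (run_len + gap_smp)
    on <- base + (seq_len(per_run) - 1L) * soa_smp + 1L
    lab <- integer(per_run); lab[target_pos[r]] <- 1L
    onsets <- c(onsets, on); labels <- c(labels, lab)
  }
  sig <- t(colored_noise(n_total, 8L, cfg$noise))
  resp_t <- trial_signal(cfg, scen, session, effects, TRUE, times)
  resp_n <- trial_signal(cfg, scen, session, effects, FALSE, times)
  # response support: only samples at t >= 0 are evoked by *this* flash
  post <- times >= 0
  span <- sum(post)
  for (k in seq_along(onsets)) {
    resp <- if (labels[k] == 1L) resp_t else resp_n
    cols <- onsets[k]:(onsets[k] + span - 1L)
    sig[, cols] <- sig[, cols] + resp[, post]
  }
  continuous_recording(sig, sfreq = cfg$sfreq,
                       events = data.frame(sample = onsets, label = labels,
                                           run = rep(seq_len(runs), each = per_run)),
                       layout = cfg$layout)
}
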