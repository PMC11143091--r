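# shared fixtures: everything is generated in code at test time

rms <- function(x) sqrt(mean(x^2))

# small but complete paradigm: full run structure, fewer blocks/sessions
tiny_sim <- function(seed = 42L, n_subjects = 1L, n_sessions = 1L,
                     blocks = 2L, runs = 3L, sigma = 4, ...) {
  sim_config(seed = seed, n_subjects = n_subjects, n_sessions = n_sessions,
             blocks_per_session = blocks, runs_per_block = runs,
             noise = noise_spec(sigma = sigma), ...)
}

# noise-free, linearly separable epoch set: targets carry the P300 template,
# standards are flat; optional tiny jitter keeps batch-norm variances sane
toy_separable <- function(n_target = 24L, n_standard = 72L, seed = 7L,
                          jitter = 0.01) {
  cfg <- sim_config(seed = seed, noise = noise_spec(sigma = 0),
                    subject_lat_sd = 0, subject_amp_sd = 0)
  times <- epoch_times(cfg)
  tpl <- matrix(0, 8, length(times))
  for (nm in names(cfg$components)) {
    comp <- cfg$components[[nm]]
    tpl <- tpl + outer(comp$topography, component_waveform(comp, times))
  }
  n <- n_target + n_standard
  labels <- c(rep(1L, n_target), rep(0L, n_standard))
  data <- array(0, c(n, 8, length(times)))
  set.seed(seed)
  for (i in seq_len(n)) {
    data[i, , ] <- jitter * matrix(rnorm(8 * length(times)), 8) +
      if (labels[i] == 1L) tpl else 0
  }
  epoch_set(data, labels,
            meta = data.frame(subject = 1L, session = 1L, scenario = "social",
                              run = seq_len(n), label = labels),
            times = times, sfreq = cfg$sfreq, layout = cfg$layout)
}

# fast training configuration for unit tests
fast_train <- function(seed = 1L, epochs = 15L, lr = 1e-3, ...) {
  train_config(learning_rate = lr, max_epochs = epochs, patience = 10L,
               seed = seed, ...)
}
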