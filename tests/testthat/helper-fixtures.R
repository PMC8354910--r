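# Shared fixtures built in code.

# small nuisance set with controllable base series
toy_nuisance <- function(csf, wm = csf, gs = csf, rp = NULL) {
  n <- length(csf)
  if (is.null(rp)) rp <- matrix(seq_len(6 * n) / (6 * n), n, 6)
  nuisance_set(csf = csf, wm = wm, gs = gs, rp = rp)
}

# run a subject's task sessions through preprocessing + trial extraction
subject_trials <- function(ds) {
  combine_trials(lapply(seq_along(ds$task_runs), function(s)
    extract_trials(preprocess_task_run(ds$task_runs[[s]], ds$task_nuisance[[s]]))))
}

# pipeline for one subject up to the cross-decoding decision
subject_crossdecode <- function(seed, rc_amplitude, n_null = 200,
                                n_voxels = 200) {
  scfg <- sim_config(n_voxels = n_voxels, rc_amplitude = rc_amplitude,
                     seed = seed)
  ds <- generate_subject(scfg)
  model <- train_decoder(subject_trials(ds))
  rest <- preprocess_rest_run(ds$rest_run, ds$rest_nuisance)
  cross_decode(model, rest, n_iterations = n_null, seed = seed + 7L)
}

# real-valued vector with a 1/f (pink) power spectrum, unit DC handling
pink_vector <- function(n) {
  f <- c(1, seq_len(n / 2), rev(seq_len(n / 2 - 1)))
  amps <- 1 / sqrt(f)
  ph <- runif(n / 2 - 1, 0, 2 * pi)
  spec <- complex(modulus = amps, argument = c(0, ph, 0, -rev(ph)))
  Re(stats::fft(spec, inverse = TRUE)) / n
}

# mean relative amplitude-spectrum error between a surrogate and its source
spectrum_error <- function(surrogate, original) {
  a1 <- Mod(stats::fft(as.numeric(surrogate)))
  a0 <- Mod(stats::fft(original))
  mean(abs(a1 - a0)) / mean(a0)
}
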