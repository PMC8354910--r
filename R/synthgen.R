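#' Simulation configuration
#'
#' Parameters of the synthetic-subject generator.  Timing defaults follow the
#' block design of the study being emulated: 18 s movement blocks interleaved
#' with 18 s rest blocks, four trials per class per session, TR 3 s (102 scans
#' per task session), and a 200-scan resting run.
#'
#' The resting run is generated under the additive mixture assumption the
#' analysis tests: each rest scan is a weighted sum of task-relevant
#' components (the wrist/finger ground-truth patterns modulated by slow,
#' band-limited time courses) and task-irrelevant components (white voxel
#' noise plus nuisance coupling).  `rc_amplitude = 0` gives a pure
#' task-irrelevant ("null world") resting run.
#'
#' @param n_voxels voxels per simulated ROI (>= 8).
#' @param n_sessions number of task sessions (>= 2, needed for
#'   leave-one-session-out cross-validation).
#' @param tr_seconds repetition time in seconds.
#' @param block_seconds duration of each movement/rest block; must be an
#'   integer multiple of `tr_seconds`.
#' @param trials_per_class_per_session movement blocks per class per session.
#' @param rest_scans scans in the resting run.
#' @param task_amplitude gain of the task-evoked pattern in task runs
#'   (0 = labels carry no information).
#' @param rc_amplitude gain of the task-relevant component in the resting run.
#' @param noise_sd standard deviation of i.i.d. Gaussian scan noise per voxel.
#' @param pattern_overlap target Pearson correlation between the wrist and
#'   finger ground-truth patterns, in `[0, 1)`.
#' @param nuisance_gain coupling strength of nuisance processes into voxel
#'   signals.
#' @param seed integer RNG seed; the whole subject dataset is reproducible
#'   from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_voxels = 200L,
                       n_sessions = 8L,
                       tr_seconds = 3,
                       block_seconds = 18,
                       trials_per_class_per_session = 4L,
                       rest_scans = 200L,
                       task_amplitude = 1.5,
                       rc_amplitude = 3,
                       noise_sd = 1,
                       pattern_overlap = 0.1,
                       nuisance_gain = 0.5,
                       seed = 1L) {
  cfg <- list(n_voxels = as.integer(n_voxels),
              n_sessions = as.integer(n_sessions),
              tr_seconds = tr_seconds,
              block_seconds = block_seconds,
              trials_per_class_per_session = as.integer(trials_per_class_per_session),
              rest_scans = as.integer(rest_scans),
              task_amplitude = task_amplitude,
              rc_amplitude = rc_amplitude,
              noise_sd = noise_sd,
              pattern_overlap = pattern_overlap,
              nuisance_gain = nuisance_gain,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_voxels < 8L) stop("n_voxels must be >= 8")
    if (n_sessions < 2L)
      stop("n_sessions must be >= 2 (leave-one-session-out CV needs >= 2 sessions)")
    if (tr_seconds <= 0) stop("tr_seconds must be positive")
    if (block_seconds <= 0) stop("block_seconds must be positive")
    if (abs(block_seconds / tr_seconds - round(block_seconds / tr_seconds)) > 1e-9)
      stop("block_seconds must be divisible by tr_seconds")
    if (trials_per_class_per_session < 1L)
      stop("trials_per_class_per_session must be positive")
    if (rest_scans < 2L) stop("rest_scans must be >= 2")
    if (rc_amplitude < 0) stop("rc_amplitude must be >= 0")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (pattern_overlap < 0 || pattern_overlap >= 1)
      stop("pattern_overlap must lie in [0, 1)")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

block_scans_of <- function(cfg) as.integer(round(cfg$block_seconds / cfg$tr_seconds))

#' Canonical double-gamma haemodynamic response function
#'
#' Response peak at 6 s, undershoot peak at 16 s, undershoot ratio 1/6,
#' scaled so the peak equals 1.
#'
#' @param t time in seconds (vector).
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h / max(dgamma(seq(0, 30, by = 0.01), shape = 6, rate = 1) -
            dgamma(seq(0, 30, by = 0.01), shape = 16, rate = 1) / 6)
}

# Convolve a per-scan boxcar with the canonical HRF sampled at TR,
# truncated to the run length.
hrf_convolve <- function(boxcar, tr) {
  n <- length(boxcar)
  kern <- canonical_hrf(seq(0, 32, by = tr))
  out <- convolve(boxcar, rev(kern), type = "open")[seq_len(n)]
  out
}

#' Generate ground-truth wrist/finger patterns
#'
#' Draws two unit-norm, zero-mean voxel patterns whose Pearson correlation
#' equals `pattern_overlap` (by explicit construction in the centred
#' subspace, so the realized overlap matches the target up to floating
#' point).
#'
#' @param config a [sim_config()].
#' @return List of class `ground_truth` with `wrist_pattern`,
#'   `finger_pattern` (unit Euclidean norm) and `realized_overlap`.
#' @export
generate_patterns <- function(config) {
  validate_sim_config(config)
  n <- config$n_voxels
  rho <- config$pattern_overlap
  for (attempt in 1:50) {
    z1 <- rnorm(n); z2 <- rnorm(n)
    c1 <- z1 - mean(z1)
    c2 <- z2 - mean(z2)
    if (sqrt(sum(c1^2)) < 1e-12) next
    u1 <- c1 / sqrt(sum(c1^2))
    e2 <- c2 - sum(c2 * u1) * u1
    if (sqrt(sum(e2^2)) < 1e-12) next
    u2 <- e2 / sqrt(sum(e2^2))
    wrist <- u1
    finger <- rho * u1 + sqrt(1 - rho^2) * u2
    finger <- finger / sqrt(sum(finger^2))
    realized <- as.numeric(cor(wrist, finger))
    if (abs(realized - rho) <= 0.05)
      return(structure(list(wrist_pattern = wrist, finger_pattern = finger,
                            realized_overlap = realized),
                       class = "ground_truth"))
  }
  stop("could not realize pattern_overlap = ", rho,
       " with n_voxels = ", n, " (infeasible configuration)")
}

# Random nuisance processes for one run: slow sinusoid + noise for
# CSF/WM/GS, random-walk motion parameters.  Each series standardized.
generate_nuisance <- function(n_scans, tr) {
  t_s <- (seq_len(n_scans) - 1L) * tr
  slow <- function() {
    f <- runif(1, 0.005, 0.04)
    x <- sin(2 * pi * f * t_s + runif(1, 0, 2 * pi)) + 0.3 * rnorm(n_scans)
    as.numeric(scale(x))
  }
  rp <- sapply(1:6, function(i) {
    x <- cumsum(rnorm(n_scans, sd = 0.1))
    as.numeric(scale(x))
  })
  nuisance_set(csf = slow(), wm = slow(), gs = slow(), rp = rp)
}

# Voxel-wise loadings of the 9 nuisance series, and their contribution.
nuisance_contribution <- function(nuis, n_voxels, gain) {
  base <- nuisance_base_matrix(nuis)
  loadings <- matrix(rnorm(n_voxels * ncol(base), sd = 1 / sqrt(ncol(base))),
                     ncol(base), n_voxels)
  gain * base %*% loadings
}

task_block_labels <- function(cfg, first_task) {
  stopifnot(first_task %in% c("Wrist", "Finger"))
  other <- if (first_task == "Wrist") "Finger" else "Wrist"
  bs <- block_scans_of(cfg)
  k <- cfg$trials_per_class_per_session
  blocks <- c("Rest", as.vector(rbind(rep(c(first_task, other), length.out = 2 * k),
                                      "Rest")))
  rep(blocks, each = bs)
}

#' Generate one block-design task run
#'
#' Timeline: an initial rest block, then `2 * trials_per_class_per_session`
#' movement blocks alternating between the two classes (starting with
#' `first_task`), each followed by a rest block.  With the default timing
#' (18 s blocks, TR 3 s, 4 trials per class) a session spans 306 s = 102
#' scans.  The voxel signal is the class pattern scaled by
#' `task_amplitude` and an HRF-convolved boxcar, plus nuisance coupling and
#' white Gaussian noise.
#'
#' @param config a [sim_config()].
#' @param truth a `ground_truth` from [generate_patterns()].
#' @param first_task `"Wrist"` or `"Finger"`.
#' @param session session id stored on the run.
#' @return List with `run` (a [bold_run()] carrying the schedule) and
#'   `nuisance` (the [nuisance_set()] used).
#' @export
generate_task_run <- function(config, truth, first_task = "Wrist", session = NA_integer_) {
  validate_sim_config(config)
  labels <- task_block_labels(config, first_task)
  n <- length(labels)
  tr <- config$tr_seconds
  nuis <- generate_nuisance(n, tr)

  conv_w <- hrf_convolve(as.numeric(labels == "Wrist"), tr)
  conv_f <- hrf_convolve(as.numeric(labels == "Finger"), tr)
  signal <- config$task_amplitude *
    (conv_w %o% truth$wrist_pattern + conv_f %o% truth$finger_pattern)
  noise <- matrix(rnorm(n * config$n_voxels, sd = config$noise_sd),
                  n, config$n_voxels)
  data <- signal + noise +
    nuisance_contribution(nuis, config$n_voxels, config$nuisance_gain)

  sched <- data.frame(scan_index = seq_len(n),
                      onset_s = (seq_len(n) - 1L) * tr,
                      label = labels,
                      stringsAsFactors = FALSE)
  list(run = bold_run(data, tr, schedule = sched, session = session),
       nuisance = nuis)
}

# Slow (band-limited below `cutoff_hz`) zero-mean unit-variance process.
slow_process <- function(n, tr, cutoff_hz = 0.1) {
  nyq <- 1 / (2 * tr)
  bf <- signal::butter(4, cutoff_hz / nyq, type = "low")
  x <- signal::filtfilt(bf, rnorm(4 * n))[n + seq_len(n)]  # discard edges
  as.numeric(scale(x))
}

#' Generate a resting-state run
#'
#' Each scan is `rc_amplitude * (a_w(t) * wrist + a_f(t) * finger)` plus
#' white voxel noise and nuisance coupling, where `a_w`, `a_f` are
#' independent slow (band-limited below 0.1 Hz) zero-mean, unit-variance
#' processes.  With `rc_amplitude = 0` the run contains only task-irrelevant
#' components.
#'
#' @inheritParams generate_task_run
#' @return List with `run` (a [bold_run()]), `nuisance`, and the latent
#'   coefficient series `a_wrist`, `a_finger`.
#' @export
generate_rest_run <- function(config, truth) {
  validate_sim_config(config)
  n <- config$rest_scans
  tr <- config$tr_seconds
  nuis <- generate_nuisance(n, tr)
  a_w <- slow_process(n, tr)
  a_f <- slow_process(n, tr)
  rc <- config$rc_amplitude *
    (a_w %o% truth$wrist_pattern + a_f %o% truth$finger_pattern)
  noise <- matrix(rnorm(n * config$n_voxels, sd = config$noise_sd),
                  n, config$n_voxels)
  data <- rc + noise +
    nuisance_contribution(nuis, config$n_voxels, config$nuisance_gain)
  list(run = bold_run(data, tr, session = NA_integer_),
       nuisance = nuis, a_wrist = a_w, a_finger = a_f)
}

#' Generate a complete synthetic subject
#'
#' Draws ground-truth patterns, `n_sessions` task runs with alternating
#' first task (odd sessions begin with Wrist, even sessions with Finger),
#' one resting run, and fresh nuisance processes per run.  Fully
#' reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List of class `subject_dataset` with elements `task_runs`
#'   (list of [bold_run()]), `task_nuisance`, `rest_run`, `rest_nuisance`,
#'   `truth`, `rest_latents`, and `config`.
#' @export
generate_subject <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  truth <- generate_patterns(config)
  task_runs <- vector("list", config$n_sessions)
  task_nuis <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    first <- if (s %% 2L == 1L) "Wrist" else "Finger"
    g <- generate_task_run(config, truth, first_task = first, session = s)
    task_runs[[s]] <- g$run
    task_nuis[[s]] <- g$nuisance
  }
  r <- generate_rest_run(config, truth)
  structure(list(task_runs = task_runs, task_nuisance = task_nuis,
                 rest_run = r$run, rest_nuisance = r$nuisance,
                 rest_latents = list(a_wrist = r$a_wrist, a_finger = r$a_finger),
                 truth = truth, config = config),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> %d task sessions (%d scans each), rest run (%d scans), %d voxels, seed %d\n",
              length(x$task_runs), nrow(x$task_runs[[1]]$data),
              nrow(x$rest_run$data), x$config$n_voxels, x$config$seed))
  invisible(x)
}

#' Resting-component amplitude for a target scan-pattern correlation
#'
#' Inverts the (approximate) variance budget of the resting-run generator to
#' find the `rc_amplitude` at which a rest scan's Pearson correlation with
#' one ground-truth pattern is about `r` (in RMS across scans):
#' `rc = sqrt(r^2 * n * v / (1 - 2 r^2))` with `v = noise_sd^2 +
#' nuisance_gain^2` the task-irrelevant per-voxel variance.  Approximate —
#' it treats the slow coefficient processes as unit-variance and ignores
#' their scan-to-scan fluctuation, so the realized RMS correlation runs
#' slightly below `r`.
#'
#' @param r target scan-pattern correlation, in `(0, 1/sqrt(2))`.
#' @param n_voxels,noise_sd,nuisance_gain generator settings.
#' @return The `rc_amplitude` value.
#' @export
rc_for_scan_correlation <- function(r, n_voxels, noise_sd = 1, nuisance_gain = 0.5) {
  stopifnot(r > 0, r < 1 / sqrt(2))
  v <- noise_sd^2 + nuisance_gain^2
  sqrt(r^2 * n_voxels * v / (1 - 2 * r^2))
}

#' Write a run's schedule as TSV
#'
#' Columns: `scan_index`, `onset_s`, `label`.
#'
#' @param run a [bold_run()] with a schedule.
#' @param path output file path.
#' @export
write_schedule_tsv <- function(run, path) {
  if (is.null(run$schedule)) stop("run has no schedule")
  utils::write.table(run$schedule, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
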