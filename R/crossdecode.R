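#' Task-relevancy index (RI) of a resting run
#'
#' Projects every resting scan onto the trained decoder:
#' `RI_t = x_t . w + b`, optionally unit-normalizing each scan first
#' (mirroring the treatment of task scans; default on).  A positive mean RI
#' indicates finger-like activity, a negative mean wrist-like activity.
#' When scans and weights are both mean-centred and unit-normed, each RI
#' value equals the Pearson correlation between the scan and the weight
#' map.
#'
#' @param rest a resting [bold_run()].
#' @param model an `rlr_decoder` with matching voxel count.
#' @param normalize_scans unit-normalize each scan before projection.
#' @return An object of class `ri_series`: list with `values` (one per
#'   scan), `n_scans` and `normalize_scans`.
#' @export
relevancy_index <- function(rest, model, normalize_scans = TRUE) {
  stopifnot(inherits(rest, "bold_run"), inherits(model, "rlr_decoder"))
  X <- rest$data
  if (ncol(X) != length(model$w))
    stop("rest run has ", ncol(X), " voxels but decoder expects ",
         length(model$w))
  if (normalize_scans) X <- t(apply(X, 1, normalize_scan))
  structure(list(values = drop(X %*% model$w) + model$b,
                 n_scans = nrow(X), normalize_scans = normalize_scans),
            class = "ri_series")
}

#' @export
print.ri_series <- function(x, ...) {
  cat(sprintf("<ri_series> %d scans, mean %.4g, SD %.4g\n",
              x$n_scans, mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Standard deviation of an RI series
#'
#' Sample standard deviation (n - 1 denominator) of the RI values; the
#' width of the RI distribution is the test statistic.  Invariant to the
#' decoder bias, which only shifts the series.
#'
#' @param ri an `ri_series` (or numeric vector of RI values).
#' @return Non-negative scalar.
#' @export
ri_sd <- function(ri) {
  v <- if (inherits(ri, "ri_series")) ri$values else as.numeric(ri)
  if (length(v) < 2L) stop("need at least 2 RI values to compute an SD")
  stats::sd(v)
}

#' IAAFT surrogate of a weight vector
#'
#' Iterative amplitude-adjusted Fourier transform surrogate over the voxel
#' index: the surrogate has exactly the same multiset of values as the
#' input (the final step is a rank-order remap onto the original values)
#' and approximately the same discrete-Fourier amplitude spectrum, while
#' the arrangement across voxels is randomized.  Iteration alternates
#' (i) imposing the original spectral magnitudes while keeping the current
#' phases with (ii) rank-remapping onto the original value multiset, until
#' the rank order stabilizes or `max_iter` is reached.
#'
#' @param w numeric vector (length >= 2).
#' @param max_iter maximum number of iterations.
#' @param spectrum_tol relative amplitude-spectrum error at which iteration
#'   may stop early.
#' @return The surrogate vector, with attributes `iterations`, `converged`
#'   and `spectrum_error` (mean relative amplitude error).
#' @export
iaaft_surrogate <- function(w, max_iter = 100L, spectrum_tol = 1e-3) {
  n <- length(w)
  if (n < 2L) stop("need at least 2 values")
  sorted_w <- sort(w)
  if (sorted_w[1] == sorted_w[n]) {        # constant vector: only one arrangement
    out <- w
    attr(out, "iterations") <- 0L
    attr(out, "converged") <- TRUE
    attr(out, "spectrum_error") <- 0
    return(out)
  }
  target_amp <- Mod(stats::fft(w))
  cur <- w[sample.int(n)]
  prev_rank <- integer(0)
  spec_err <- Inf
  for (it in seq_len(max_iter)) {
    ph <- stats::fft(cur)
    mod <- Mod(ph)
    ph <- ifelse(mod > 0, ph / mod, 1)      # unit-modulus phases
    y <- Re(stats::fft(target_amp * ph, inverse = TRUE)) / n
    rk <- rank(y, ties.method = "first")
    cur <- sorted_w[rk]
    spec_err <- mean(abs(Mod(stats::fft(cur)) - target_amp)) /
      mean(target_amp)
    if (identical(rk, prev_rank) || spec_err <= spectrum_tol) break
    prev_rank <- rk
  }
  attr(cur, "iterations") <- it
  attr(cur, "converged") <- spec_err <= spectrum_tol
  attr(cur, "spectrum_error") <- spec_err
  cur
}

#' Null distribution of RI spread under shuffled decoders
#'
#' Replicates `n_iterations` times: draw an IAAFT surrogate of the weight
#' vector (the bias is kept fixed), compute the RI of the resting run with
#' the surrogate decoder under identical options, and record the RI
#' standard deviation.  These SDs form the empirical null of
#' task-irrelevant spread.
#'
#' @param model an `rlr_decoder`.
#' @param rest a resting [bold_run()].
#' @param n_iterations number of surrogates (default 1000).
#' @param normalize_scans passed to [relevancy_index()].
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `null_distribution`: list with `sd_values`,
#'   `n_iterations`, `seed` and `convergence` (per-surrogate spectrum
#'   errors and iteration counts).
#' @export
build_null <- function(model, rest, n_iterations = 1000L,
                       normalize_scans = TRUE, seed = NULL) {
  stopifnot(inherits(model, "rlr_decoder"), inherits(rest, "bold_run"))
  if (!is.null(seed)) set.seed(seed)
  X <- rest$data
  if (normalize_scans) X <- t(apply(X, 1, normalize_scan))
  sd_values <- numeric(n_iterations)
  spec_err <- numeric(n_iterations)
  iters <- integer(n_iterations)
  for (i in seq_len(n_iterations)) {
    ws <- iaaft_surrogate(model$w)
    sd_values[i] <- stats::sd(drop(X %*% as.numeric(ws)) + model$b)
    spec_err[i] <- attr(ws, "spectrum_error")
    iters[i] <- attr(ws, "iterations")
  }
  structure(list(sd_values = sd_values, n_iterations = n_iterations,
                 seed = seed,
                 convergence = data.frame(iterations = iters,
                                          spectrum_error = spec_err)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d surrogate SDs, mean %.4g, SD %.4g\n",
              x$n_iterations, mean(x$sd_values), stats::sd(x$sd_values)))
  invisible(x)
}

#' Bias-correct the observed and null RI spreads
#'
#' Applies the two correction equations: the observed spread is reduced by
#' the null mean plus one (sample) standard deviation of the null,
#' `SD_RS <- SD_RS - (mean(SD_IC) + SD(SD_IC))`, and the null values are
#' centred, `SD_IC <- SD_IC - mean(SD_IC)`.  The extra `- SD(SD_IC)` term
#' makes the subsequent test conservative.
#'
#' @param sd_rs_raw observed RI standard deviation.
#' @param null a `null_distribution`.
#' @return List with `sd_rs_corrected` and `sd_ic_corrected` (centred null
#'   values, mean 0).
#' @export
correct_sds <- function(sd_rs_raw, null) {
  stopifnot(inherits(null, "null_distribution"))
  v <- null$sd_values
  if (length(v) < 1L) stop("empty null distribution")
  m <- mean(v)
  s <- if (length(v) >= 2L) stats::sd(v) else 0
  list(sd_rs_corrected = sd_rs_raw - (m + s),
       sd_ic_corrected = v - m)
}

#' Significance of the corrected RI spread
#'
#' The critical value is the k-th largest corrected null value with
#' `k = round(alpha * n)` (for 1000 surrogates at alpha = 0.05, the 50th
#' largest).  The observed corrected spread is significant iff it is
#' strictly greater than the critical value.  The empirical p-value uses
#' the add-one convention `(#\{null >= observed\} + 1) / (n + 1)`.
#'
#' @param sd_rs_corrected corrected observed spread.
#' @param sd_ic_corrected corrected null values.
#' @param alpha one-sided level in (0, 1); `alpha * n` must be >= 1.
#' @return List with `critical_value`, `critical_rank` (k), `empirical_p`
#'   and `significant`.
#' @export
test_significance <- function(sd_rs_corrected, sd_ic_corrected, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  n <- length(sd_ic_corrected)
  k <- round(alpha * n)
  if (k < 1L) stop("alpha * n must be >= 1 (n = ", n, ", alpha = ", alpha, ")")
  crit <- sort(sd_ic_corrected, decreasing = TRUE)[k]
  list(critical_value = crit,
       critical_rank = as.integer(k),
       empirical_p = (sum(sd_ic_corrected >= sd_rs_corrected) + 1) / (n + 1),
       significant = sd_rs_corrected > crit)
}

#' Full cross-decoding of a resting run
#'
#' Convenience wrapper chaining [relevancy_index()], [ri_sd()],
#' [build_null()], [correct_sds()] and [test_significance()].
#'
#' @param model trained `rlr_decoder`.
#' @param rest preprocessed resting [bold_run()].
#' @param n_iterations surrogates in the null (default 1000).
#' @param alpha one-sided level.
#' @param normalize_scans unit-normalize rest scans before projection.
#' @param seed optional seed for the surrogate draw.
#' @return An object of class `crossdecode_result` with fields
#'   `sd_rs_raw`, `sd_rs_corrected`, `sd_ic_corrected`, `critical_value`,
#'   `critical_rank`, `empirical_p`, `significant`, `ri`, `null`, `seed`.
#' @export
cross_decode <- function(model, rest, n_iterations = 1000L, alpha = 0.05,
                         normalize_scans = TRUE, seed = NULL) {
  ri <- relevancy_index(rest, model, normalize_scans = normalize_scans)
  sd_rs_raw <- ri_sd(ri)
  null <- build_null(model, rest, n_iterations = n_iterations,
                     normalize_scans = normalize_scans, seed = seed)
  corr <- correct_sds(sd_rs_raw, null)
  sig <- test_significance(corr$sd_rs_corrected, corr$sd_ic_corrected, alpha)
  structure(c(list(sd_rs_raw = sd_rs_raw,
                   sd_rs_corrected = corr$sd_rs_corrected,
                   sd_ic_corrected = corr$sd_ic_corrected),
              sig,
              list(alpha = alpha, ri = ri, null = null, seed = seed)),
            class = "crossdecode_result")
}

#' @export
print.crossdecode_result <- function(x, ...) {
  cat(sprintf(paste0("<crossdecode_result> SD_RS raw %.4g, corrected %.4g; ",
                     "critical %.4g (rank %d/%d); p = %.4g; %ssignificant\n"),
              x$sd_rs_raw, x$sd_rs_corrected, x$critical_value,
              x$critical_rank, x$null$n_iterations, x$empirical_p,
              if (x$significant) "" else "not "))
  invisible(x)
}
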