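#' Build noise regressors from nuisance series
#'
#' From the nine base nuisance series (CSF, WM, GS and six motion
#' parameters) this emits, for each base series: the series itself, its
#' temporal derivative (first difference with a leading zero so length is
#' preserved), its square, and its derivative's square — 36 noise columns in
#' total.  Every non-zero column is scaled so its maximum absolute value is
#' exactly 1 (sign-preserving); identically-zero columns are left zero.
#'
#' @param nuisance a [nuisance_set()].
#' @return An object of class `regressor_matrix`: list with `matrix`
#'   (scans x regressors) and `column_roles`.
#' @export
build_noise_regressors <- function(nuisance) {
  base <- nuisance_base_matrix(nuisance)
  n <- nrow(base)
  deriv <- apply(base, 2, function(x) c(0, diff(x)))
  cols <- cbind(base, deriv, base^2, deriv^2)
  roles <- rep(c("noise", "noise_derivative", "noise_quadratic",
                 "noise_derivative_quadratic"), each = ncol(base))
  colnames(cols) <- paste(roles, rep(colnames(base), times = 4), sep = ".")
  cols <- apply(cols, 2, normalize_max_abs)
  structure(list(matrix = cols, column_roles = roles),
            class = "regressor_matrix")
}

# divide by max |x| so the column attains max absolute value 1 exactly
normalize_max_abs <- function(x) {
  m <- max(abs(x))
  if (m == 0) x else x / m
}

#' @export
print.regressor_matrix <- function(x, ...) {
  cat(sprintf("<regressor_matrix> %d scans x %d regressors (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(unique(x$column_roles), collapse = ", ")))
  invisible(x)
}

#' Append trend and baseline regressors
#'
#' Adds a constant (baseline) column and a linear ramp scaled to `[-1, 1]`.
#' Calling this twice on the same matrix is an error (duplicate roles).
#'
#' @param reg a `regressor_matrix`.
#' @param n_scans number of scans; must match the matrix.
#' @return The augmented `regressor_matrix`.
#' @export
add_trend_regressors <- function(reg, n_scans) {
  stopifnot(inherits(reg, "regressor_matrix"))
  if (nrow(reg$matrix) != n_scans)
    stop("n_scans (", n_scans, ") does not match regressor matrix (",
         nrow(reg$matrix), " rows)")
  if (any(reg$column_roles %in% c("constant", "trend")))
    stop("trend/constant regressors already present")
  ramp <- if (n_scans == 1L) 0 else seq(-1, 1, length.out = n_scans)
  m <- cbind(reg$matrix, constant = rep(1, n_scans), trend = ramp)
  structure(list(matrix = m, column_roles = c(reg$column_roles, "constant", "trend")),
            class = "regressor_matrix")
}

# Moore-Penrose pseudoinverse via SVD (tolerance relative to largest
# singular value); keeps regress_out well-defined for rank-deficient or
# duplicated regressor columns.
pinv <- function(m, tol = .Machine$double.eps * max(dim(m))) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Regress nuisance/trend components out of a run
#'
#' Returns the residuals of the least-squares projection of every voxel
#' time series onto the regressor columns.  The projection uses the
#' pseudoinverse, so duplicated or rank-deficient regressors give the same
#' (unique) residuals as their independent span.
#'
#' @param run a [bold_run()].
#' @param reg a `regressor_matrix` with matching scan count.
#' @return A [bold_run()] of residuals (schedule and metadata preserved).
#' @export
regress_out <- function(run, reg) {
  stopifnot(inherits(run, "bold_run"), inherits(reg, "regressor_matrix"))
  r <- reg$matrix
  if (nrow(r) != nrow(run$data))
    stop("regressor rows (", nrow(r), ") do not match scans (", nrow(run$data), ")")
  beta <- pinv(r) %*% run$data
  out <- run
  out$data <- run$data - r %*% beta
  out
}

# Butterworth band-pass coefficients for a given TR; errors when the
# passband is infeasible at the sampling rate.
bandpass_coeffs <- function(tr, low_hz, high_hz, order) {
  nyq <- 1 / (2 * tr)
  if (high_hz >= nyq)
    stop("passband upper edge ", high_hz, " Hz is not below the Nyquist frequency ",
         signif(nyq, 4), " Hz for TR ", tr, " s")
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("passband must satisfy 0 < low_hz < high_hz")
  signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
}

#' Analytic power gain of the zero-phase band-pass filter
#'
#' Evaluates the squared magnitude response |H(f)|^2 of the Butterworth
#' band-pass design at frequency `f_hz` — the effective gain of the
#' forward-backward (zero-phase) application in [bandpass_filter()].
#'
#' @param f_hz frequency (Hz), vectorized.
#' @param tr repetition time in seconds.
#' @param low_hz,high_hz passband edges in Hz.
#' @param order Butterworth design order.
#' @return Power gain at `f_hz` (1 = fully passed).
#' @export
bandpass_gain <- function(f_hz, tr, low_hz = 0.010, high_hz = 0.10, order = 4) {
  bf <- bandpass_coeffs(tr, low_hz, high_hz, order)
  w <- 2 * pi * f_hz * tr  # radians per sample
  H <- vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(bf$b) - 1))
    num <- sum(bf$b * z)
    den <- sum(bf$a * exp(-1i * wi * (seq_along(bf$a) - 1)))
    Mod(num / den)
  }, numeric(1))
  H^2
}

#' Zero-phase band-pass filter a run
#'
#' Applies a Butterworth band-pass (default passband 0.010–0.10 Hz, fourth
#' order) forward and backward (zero phase) to every voxel time series.
#' Each series is demeaned first; the DC component lies outside the
#' passband, so output voxel means are ~0.
#'
#' @param run a [bold_run()].
#' @param low_hz,high_hz passband edges in Hz.
#' @param order Butterworth design order.
#' @return The filtered [bold_run()].
#' @export
bandpass_filter <- function(run, low_hz = 0.010, high_hz = 0.10, order = 4) {
  stopifnot(inherits(run, "bold_run"))
  if (nrow(run$data) <= 6 * order)
    stop("run too short (", nrow(run$data), " scans) for an order-", order,
         " zero-phase filter")
  bf <- bandpass_coeffs(run$tr, low_hz, high_hz, order)
  out <- run
  out$data <- apply(run$data, 2, function(x) signal::filtfilt(bf, x - mean(x)))
  out
}

# filter each regressor column the same way as the data, re-normalizing
# noise columns so the max-abs-1 invariant holds after filtering
bandpass_regressors <- function(reg, tr, low_hz, high_hz, order) {
  bf <- bandpass_coeffs(tr, low_hz, high_hz, order)
  m <- reg$matrix
  keep_roles <- c("constant", "trend")
  for (j in seq_len(ncol(m))) {
    if (reg$column_roles[j] %in% keep_roles) next
    m[, j] <- normalize_max_abs(signal::filtfilt(bf, m[, j] - mean(m[, j])))
  }
  structure(list(matrix = m, column_roles = reg$column_roles),
            class = "regressor_matrix")
}

#' Temporal preprocessing of a movement-task run
#'
#' Builds the full regressor matrix (36 noise columns plus constant and
#' trend) and regresses it out of the run.  No band-pass filter is applied
#' to task runs.
#'
#' @param run a [bold_run()].
#' @param nuisance the run's [nuisance_set()].
#' @return The residual [bold_run()].
#' @export
preprocess_task_run <- function(run, nuisance) {
  reg <- add_trend_regressors(build_noise_regressors(nuisance), nrow(run$data))
  regress_out(run, reg)
}

#' Temporal preprocessing of a resting-state run
#'
#' Per voxel: subtract the mean, apply the zero-phase band-pass
#' (0.010–0.10 Hz, fourth order by default), then regress out the noise
#' regressors — themselves passed through the same band-pass so that
#' frequencies already removed from the data cannot be reintroduced —
#' together with constant and trend columns.
#'
#' @param run a resting [bold_run()].
#' @param nuisance the run's [nuisance_set()].
#' @param low_hz,high_hz,order band-pass parameters.
#' @return The preprocessed [bold_run()]; voxel means are ~0.
#' @export
preprocess_rest_run <- function(run, nuisance, low_hz = 0.010, high_hz = 0.10,
                                order = 4) {
  filtered <- bandpass_filter(run, low_hz, high_hz, order)
  reg <- bandpass_regressors(build_noise_regressors(nuisance), run$tr,
                             low_hz, high_hz, order)
  reg <- add_trend_regressors(reg, nrow(run$data))
  regress_out(filtered, reg)
}
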