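test_that("noise regressors follow the base/derivative/quadratic scheme", {
  nuis <- toy_nuisance(csf = c(0, 2, 4))
  reg <- build_noise_regressors(nuis)
  expect_equal(ncol(reg$matrix), 36L)
  expect_equal(sort(unique(reg$column_roles)),
               sort(c("noise", "noise_derivative", "noise_quadratic",
                      "noise_derivative_quadratic")))
  m <- reg$matrix
  expect_equal(unname(m[, "noise.csf"]), c(0, 0.5, 1))            # / max|.| = 4
  expect_equal(unname(m[, "noise_derivative.csf"]), c(0, 1, 1))   # diff (0,2,2) / 2
  expect_equal(unname(m[, "noise_quadratic.csf"]), c(0, 0.25, 1)) # squares / 16
  expect_equal(unname(m[, "noise_derivative_quadratic.csf"]), c(0, 1, 1))
})

test_that("constant base series give all-zero derivative columns", {
  nuis <- toy_nuisance(csf = c(3, 3, 3, 3))
  m <- build_noise_regressors(nuis)$matrix
  expect_equal(unname(m[, "noise_derivative.csf"]), rep(0, 4))
  expect_equal(unname(m[, "noise.csf"]), rep(1, 4))
})

test_that("an already max-1 series squares element-wise", {
  nuis <- toy_nuisance(csf = c(0, 0.5, 1))
  m <- build_noise_regressors(nuis)$matrix
  expect_equal(unname(m[, "noise_quadratic.csf"]), c(0, 0.25, 1))
})

test_that("every non-zero noise column attains max |value| = 1 exactly", {
  set.seed(1)
  nuis <- toy_nuisance(csf = rnorm(50), wm = rnorm(50), gs = rnorm(50),
                       rp = matrix(rnorm(300), 50, 6))
  m <- build_noise_regressors(nuis)$matrix
  expect_true(all(abs(apply(m, 2, function(x) max(abs(x))) - 1) == 0))
})

test_that("nuisance series of unequal length are rejected", {
  expect_error(nuisance_set(csf = 1:5, wm = 1:4, gs = 1:5,
                            rp = matrix(0, 5, 6)), "same number of scans")
  expect_error(nuisance_set(csf = 1:5, wm = 1:5, gs = 1:5,
                            rp = matrix(0, 5, 4)), "6 motion")
})

test_that("trend regressors add a constant and a [-1, 1] ramp exactly once", {
  nuis <- toy_nuisance(csf = c(1, 2, 3))
  reg <- add_trend_regressors(build_noise_regressors(nuis), 3)
  m <- reg$matrix
  expect_equal(unname(m[, "trend"]), c(-1, 0, 1))
  expect_equal(sum(m[, "constant"]), 3)
  expect_error(add_trend_regressors(reg, 3), "already present")
  expect_error(add_trend_regressors(build_noise_regressors(nuis), 5),
               "does not match")
})

test_that("regress_out removes regressor-spanned signal and keeps orthogonal signal", {
  set.seed(42)
  n <- 40
  nuis <- toy_nuisance(csf = rnorm(n), wm = rnorm(n), gs = rnorm(n),
                       rp = matrix(rnorm(6 * n), n, 6))
  reg <- add_trend_regressors(build_noise_regressors(nuis), n)

  # data equal to a regressor column -> residual ~ 0
  run <- bold_run(cbind(reg$matrix[, 3], reg$matrix[, 10]), tr = 3)
  res <- regress_out(run, reg)
  expect_lte(max(abs(res$data)), 1e-8)

  # data orthogonal to all regressors -> unchanged
  x <- rnorm(n)
  ortho <- x - reg$matrix %*% restmvpa:::pinv(reg$matrix) %*% x
  run2 <- bold_run(matrix(ortho), tr = 3)
  res2 <- regress_out(run2, reg)
  expect_lte(max(abs(res2$data - ortho)), 1e-8)

  # residuals orthogonal to every regressor column
  run3 <- bold_run(matrix(rnorm(n * 5), n, 5), tr = 3)
  res3 <- regress_out(run3, reg)
  xp <- crossprod(reg$matrix, res3$data)
  expect_lte(max(abs(xp)) / max(abs(run3$data)), 1e-8)
})

test_that("duplicated regressor columns match the QR least-squares oracle", {
  set.seed(7)
  n <- 30
  base <- matrix(rnorm(n * 4), n, 4)
  dup <- cbind(base, base[, 2])                       # rank-deficient
  y <- matrix(rnorm(n * 3), n, 3)
  reg_dup <- structure(list(matrix = dup, column_roles = rep("noise", 5)),
                       class = "regressor_matrix")
  reg_base <- structure(list(matrix = base, column_roles = rep("noise", 4)),
                        class = "regressor_matrix")
  run <- bold_run(y, tr = 3)
  r_dup <- regress_out(run, reg_dup)$data
  r_base <- regress_out(run, reg_base)$data
  expect_equal(r_dup, r_base, tolerance = 1e-10)
  # independent oracle: QR-based least squares residuals
  oracle <- qr.resid(qr(base), y)
  expect_equal(r_dup, oracle, tolerance = 1e-8)
})

test_that("regress_out is idempotent", {
  set.seed(8)
  n <- 30
  nuis <- toy_nuisance(csf = rnorm(n), wm = rnorm(n), gs = rnorm(n),
                       rp = matrix(rnorm(6 * n), n, 6))
  reg <- add_trend_regressors(build_noise_regressors(nuis), n)
  run <- bold_run(matrix(rnorm(n * 4), n, 4), tr = 3)
  once <- regress_out(run, reg)
  twice <- regress_out(once, reg)
  expect_equal(once$data, twice$data, tolerance = 1e-8)
})

test_that("band-pass design passes 0.05 Hz and rejects DC and 0.15 Hz at TR 3", {
  expect_gte(bandpass_gain(0.05, tr = 3), 0.9)
  expect_lte(bandpass_gain(0.15, tr = 3), 0.2)
  expect_lte(bandpass_gain(0.001, tr = 3), 1e-4)
  # infeasible passband: upper edge beyond Nyquist for TR 3 (1/6 Hz)
  expect_error(bandpass_filter(bold_run(matrix(rnorm(100)), tr = 3),
                               high_hz = 0.2), "Nyquist")
})

test_that("filtering a constant series returns (near) zero", {
  run <- bold_run(matrix(5, 200, 2), tr = 3)
  out <- bandpass_filter(run)
  expect_lte(max(abs(out$data)), 1e-6 * 5)
})

test_that("an in-band sinusoid passes with empirical amplitude near 1", {
  t_s <- (0:199) * 3
  x <- sin(2 * pi * 0.05 * t_s)
  out <- bandpass_filter(bold_run(matrix(x), tr = 3))
  mid <- 50:150                                        # avoid edge transients
  expect_gte(max(abs(out$data[mid, 1])), 0.9)
  x_hi <- sin(2 * pi * 0.15 * t_s)
  out_hi <- bandpass_filter(bold_run(matrix(x_hi), tr = 3))
  expect_lte(max(abs(out_hi$data[mid, 1])), 0.2)
})

test_that("the zero-phase filter is linear", {
  set.seed(3)
  x <- matrix(rnorm(200), 200, 1)
  y <- matrix(rnorm(200), 200, 1)
  fa <- bandpass_filter(bold_run(2 * x + 3 * y, tr = 3))$data
  fb <- 2 * bandpass_filter(bold_run(x, tr = 3))$data +
    3 * bandpass_filter(bold_run(y, tr = 3))$data
  expect_equal(fa, fb, tolerance = 1e-8)
})

test_that("task-run preprocessing removes nuisance mixtures, keeps orthogonal signal", {
  set.seed(11)
  n <- 102
  nuis <- toy_nuisance(csf = rnorm(n), wm = rnorm(n), gs = rnorm(n),
                       rp = matrix(rnorm(6 * n), n, 6))
  reg <- add_trend_regressors(build_noise_regressors(nuis), n)

  # zero input -> zero residuals
  z <- preprocess_task_run(bold_run(matrix(0, n, 3), tr = 3), nuis)
  expect_lte(max(abs(z$data)), 1e-12)

  # pure nuisance mixture -> residual variance <= 1% of input variance
  mix <- reg$matrix %*% matrix(rnorm(ncol(reg$matrix) * 4), ncol(reg$matrix), 4)
  r <- preprocess_task_run(bold_run(mix, tr = 3), nuis)
  expect_lte(var(as.vector(r$data)) / var(as.vector(mix)), 0.01)

  # signal orthogonal to the regressor span passes through unchanged
  raw <- rnorm(n)
  ortho <- raw - reg$matrix %*% restmvpa:::pinv(reg$matrix) %*% raw
  rs <- preprocess_task_run(bold_run(matrix(ortho), tr = 3), nuis)
  expect_lte(max(abs(rs$data - ortho)), 1e-6)
})

test_that("rest-run preprocessing demeans, filters and regresses", {
  set.seed(12)
  n <- 200
  nuis <- toy_nuisance(csf = rnorm(n), wm = rnorm(n), gs = rnorm(n),
                       rp = matrix(rnorm(6 * n), n, 6))
  run <- bold_run(matrix(rnorm(n * 5) + 10, n, 5), tr = 3)
  out <- preprocess_rest_run(run, nuis)
  expect_lte(max(abs(colMeans(out$data))), 1e-8)

  # out-of-band voxel: 0.3 Hz aliases to 1/30 Hz at TR 3 s, which is in-band,
  # so test 0.15 Hz (below Nyquist, above passband) instead of an aliased tone
  t_s <- (0:(n - 1)) * 3
  tone <- sin(2 * pi * 0.15 * t_s)
  run2 <- bold_run(matrix(tone), tr = 3)
  out2 <- preprocess_rest_run(run2, nuis)
  expect_lte(var(out2$data[, 1]) / var(tone), 0.05)

  # nuisance-only rest run mostly removed
  base <- restmvpa:::nuisance_base_matrix(nuis)
  mix <- base %*% matrix(rnorm(9 * 4), 9, 4)
  run3 <- bold_run(mix, tr = 3)
  out3 <- preprocess_rest_run(run3, nuis)
  expect_lte(var(as.vector(out3$data)) / var(as.vector(mix)), 0.05)
})
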