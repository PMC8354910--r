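#' Normalize a scan to unit Euclidean norm
#'
#' @param x numeric voxel vector (non-zero).
#' @return `x / ||x||`, Euclidean norm 1.
#' @export
normalize_scan <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot normalize an all-zero scan")
  x / nrm
}

#' Extract per-trial patterns from a task run
#'
#' Groups consecutive scans sharing a movement label into blocks, drops the
#' first `drop_initial` scans of each block (haemodynamic carry-over from
#' the preceding rest), unit-normalizes each remaining scan, and averages
#' them into one pattern row per trial.  With 18 s blocks at TR 3 s each
#' block has 6 scans and a trial is the mean of its last 4 normalized scans.
#'
#' @param run a [bold_run()].
#' @param schedule data frame with per-scan `label` (defaults to the run's
#'   own schedule).
#' @param drop_initial scans dropped at the start of each movement block.
#' @return A `trial_set`: list with `patterns` (trials x voxels), `labels`
#'   (factor, levels Wrist/Finger) and `session_ids`.
#' @export
extract_trials <- function(run, schedule = run$schedule, drop_initial = 2L) {
  stopifnot(inherits(run, "bold_run"))
  if (is.null(schedule)) stop("no schedule supplied and run carries none")
  labels <- as.character(schedule$label)
  if (length(labels) != nrow(run$data))
    stop("schedule labels (", length(labels), ") do not match scans (",
         nrow(run$data), ")")
  blk <- rle(labels)
  ends <- cumsum(blk$lengths)
  starts <- ends - blk$lengths + 1L
  keep <- blk$values %in% c("Wrist", "Finger")
  pat <- list(); lab <- character(0)
  for (i in which(keep)) {
    if (blk$lengths[i] < drop_initial + 1L)
      stop("movement block of ", blk$lengths[i],
           " scans is too short to drop ", drop_initial, " scans")
    idx <- (starts[i] + drop_initial):ends[i]
    scans <- run$data[idx, , drop = FALSE]
    normed <- t(apply(scans, 1, normalize_scan))
    pat[[length(pat) + 1L]] <- colMeans(normed)
    lab <- c(lab, blk$values[i])
  }
  trial_set(do.call(rbind, pat),
            labels = lab,
            session_ids = rep(if (is.na(run$session)) 1L else run$session,
                              length(lab)))
}

#' Trial-pattern container
#'
#' @param patterns trials x voxels matrix of per-trial averaged unit-norm
#'   scans.
#' @param labels per-trial class labels (`"Wrist"`/`"Finger"`).
#' @param session_ids per-trial session index.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(patterns, labels, session_ids) {
  patterns <- as.matrix(patterns)
  labels <- factor(as.character(labels), levels = c("Wrist", "Finger"))
  if (anyNA(labels)) stop("labels must be 'Wrist' or 'Finger'")
  if (length(labels) != nrow(patterns) || length(session_ids) != nrow(patterns))
    stop("labels/session_ids must match the number of trial rows")
  structure(list(patterns = patterns, labels = labels,
                 session_ids = as.integer(session_ids)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %d voxels (%s), %d session(s)\n",
              nrow(x$patterns), ncol(x$patterns),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", "),
              length(unique(x$session_ids))))
  invisible(x)
}

#' Combine trial sets across sessions
#'
#' @param ... `trial_set` objects (or one list of them).
#' @return A single `trial_set`.
#' @export
combine_trials <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "trial_set")) sets <- sets[[1]]
  trial_set(do.call(rbind, lapply(sets, `[[`, "patterns")),
            labels = unlist(lapply(sets, function(s) as.character(s$labels))),
            session_ids = unlist(lapply(sets, `[[`, "session_ids")))
}

#' Train the wrist/finger decoder (L2-regularized logistic regression)
#'
#' Finds `(w, b)` minimizing the negative log-likelihood of
#' `P(y = Finger | x) = sigmoid(x . w + b)` plus `lambda/2 * ||w||^2`
#' (bias unpenalized), by damped Newton iteration.  Finger is the positive
#' class, so positive decoder output means finger-like.
#'
#' @param trials a `trial_set` containing both classes, >= 2 trials per
#'   class.
#' @param lambda L2 penalty strength (> 0).
#' @param tol convergence threshold on the Euclidean norm of the gradient.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `rlr_decoder`: list with `w`, `b`, `lambda`,
#'   `n_train`, `grad_norm`, `converged`.
#' @export
train_decoder <- function(trials, lambda = 1, tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(trials, "trial_set"), lambda > 0)
  counts <- table(trials$labels)
  if (any(counts < 2L))
    stop("need at least 2 trials per class (got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), ")")
  X <- trials$patterns
  y <- as.numeric(trials$labels == "Finger")
  n <- nrow(X); p <- ncol(X)
  theta <- numeric(p + 1L)            # (w, b)
  pen <- c(rep(lambda, p), 0)
  Xa <- cbind(X, 1)

  obj <- function(th) {
    eta <- drop(Xa %*% th)
    # log(1 + exp(.)) computed stably
    ll <- sum(ifelse(eta > 30, (1 - y) * eta,
                     ifelse(eta < -30, -y * eta,
                            log1p(exp(eta)) - y * eta)))
    ll + 0.5 * lambda * sum(th[1:p]^2)
  }
  grad_of <- function(th) {
    mu <- plogis(drop(Xa %*% th))
    drop(crossprod(Xa, mu - y)) + pen * th
  }

  g <- grad_of(theta)
  iter <- 0L
  while (sqrt(sum(g^2)) > tol && iter < max_iter) {
    mu <- plogis(drop(Xa %*% theta))
    s <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xa * s, Xa)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    # damped step: halve until the objective decreases
    f0 <- obj(theta); alpha <- 1
    repeat {
      cand <- theta - alpha * step
      if (obj(cand) <= f0 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    theta <- cand
    g <- grad_of(theta)
    iter <- iter + 1L
  }
  structure(list(w = theta[1:p], b = theta[p + 1L], lambda = lambda,
                 n_train = n, grad_norm = sqrt(sum(g^2)),
                 converged = sqrt(sum(g^2)) <= tol),
            class = "rlr_decoder")
}

#' @export
print.rlr_decoder <- function(x, ...) {
  cat(sprintf("<rlr_decoder> %d voxels, lambda %g, trained on %d trials (grad norm %.2e)\n",
              length(x$w), x$lambda, x$n_train, x$grad_norm))
  invisible(x)
}

#' Predict class probabilities from a trained decoder
#'
#' Probability of the Finger class is `sigmoid(x . w + b)`; the hard label
#' is Finger iff the probability exceeds 0.5 (a tie at exactly 0.5 is
#' called Wrist).
#'
#' @param object an `rlr_decoder`.
#' @param patterns matrix (trials x voxels) or a single voxel vector.
#' @param ... unused.
#' @return Data frame with `p_finger` and `label`.
#' @export
predict.rlr_decoder <- function(object, patterns, ...) {
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1L)
  if (ncol(patterns) != length(object$w))
    stop("pattern has ", ncol(patterns), " voxels but decoder expects ",
         length(object$w))
  p <- plogis(drop(patterns %*% object$w) + object$b)
  data.frame(p_finger = p,
             label = factor(ifelse(p > 0.5, "Finger", "Wrist"),
                            levels = c("Wrist", "Finger")))
}

#' Leave-one-session-out cross-validated accuracy
#'
#' For each session: train on all other sessions, test on the held-out
#' session's trials.  Accuracy is the fraction of correct labels over all
#' held-out trials.
#'
#' @param trials a `trial_set` spanning >= 2 sessions.
#' @param lambda L2 penalty passed to [train_decoder()].
#' @return List with `accuracy` (fraction), `n_trials`, and `folds`
#'   (per-session data frame of test counts and correct counts).
#' @export
loo_cv_accuracy <- function(trials, lambda = 1) {
  sessions <- sort(unique(trials$session_ids))
  if (length(sessions) < 2L)
    stop("leave-one-session-out CV needs >= 2 sessions")
  folds <- data.frame(session = sessions, n_test = 0L, n_correct = 0L)
  for (i in seq_along(sessions)) {
    s <- sessions[i]
    tr_idx <- trials$session_ids != s
    te_idx <- !tr_idx
    stopifnot(!any(trials$session_ids[tr_idx] == s))   # held-out never trained on
    model <- train_decoder(
      trial_set(trials$patterns[tr_idx, , drop = FALSE],
                trials$labels[tr_idx], trials$session_ids[tr_idx]),
      lambda = lambda)
    pred <- predict(model, trials$patterns[te_idx, , drop = FALSE])
    folds$n_test[i] <- sum(te_idx)
    folds$n_correct[i] <- sum(pred$label == trials$labels[te_idx])
  }
  list(accuracy = sum(folds$n_correct) / sum(folds$n_test),
       n_trials = sum(folds$n_test), folds = folds)
}

#' Threshold a weight map at the top fraction by magnitude
#'
#' Selects the `ceiling(fraction * n)` voxels with the largest absolute
#' weight (ties broken by lowest voxel index).  Positive-weight selections
#' are finger-related, negative-weight selections wrist-related.
#'
#' @param avg_w averaged voxel weight vector.
#' @param fraction fraction of voxels to keep (default top 10%).
#' @return List with integer index vectors `finger_voxels`, `wrist_voxels`,
#'   and `selected` (all kept voxels in selection order).
#' @export
threshold_weight_map <- function(avg_w, fraction = 0.10) {
  n <- length(avg_w)
  if (n == 0L) stop("empty weight vector")
  k <- ceiling(fraction * n)
  ord <- order(-abs(avg_w), seq_len(n))
  sel <- ord[seq_len(k)]
  list(finger_voxels = sort(sel[avg_w[sel] > 0]),
       wrist_voxels = sort(sel[avg_w[sel] < 0]),
       selected = sel)
}

#' Compare ROI accuracies against a control ROI
#'
#' Paired two-sided Wilcoxon signed-rank test of per-subject accuracies in
#' an ROI against the control ROI, Bonferroni-adjusted for the number of
#' ROIs tested (default 8).
#'
#' @param roi_accuracies per-subject accuracies for the ROI.
#' @param control_accuracies per-subject accuracies for the control ROI
#'   (same subject order).
#' @param n_rois Bonferroni family size.
#' @param alpha significance level applied to the adjusted p-value.
#' @return List with `p_raw`, `p_adjusted` (capped at 1) and `significant`.
#' @export
compare_to_control <- function(roi_accuracies, control_accuracies,
                               n_rois = 8L, alpha = 0.05) {
  if (length(roi_accuracies) != length(control_accuracies))
    stop("paired samples must have equal length")
  if (length(roi_accuracies) < 5L)
    stop("need at least 5 paired observations")
  d <- roi_accuracies - control_accuracies
  if (all(d == 0)) {
    p <- 1  # no non-zero differences: no evidence against the null
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(roi_accuracies, control_accuracies,
                         paired = TRUE, alternative = "two.sided")$p.value)
  }
  p_adj <- min(1, p * n_rois)
  list(p_raw = p, p_adjusted = p_adj, significant = p_adj < alpha)
}
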