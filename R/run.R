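#' fMRI run container
#'
#' A `bold_run` bundles a scans x voxels signal matrix with its sampling
#' interval (TR), an optional per-scan condition schedule, and a session
#' identifier.  All pipeline stages accept and return this container so that
#' metadata travels with the data.
#'
#' @param data numeric matrix, scans in rows, voxels in columns.
#' @param tr repetition time in seconds (sampling interval between scans).
#' @param schedule optional data frame with columns `scan_index`, `onset_s`
#'   and `label` (one row per scan; labels in `"Wrist"`, `"Finger"`, `"Rest"`).
#' @param session integer session identifier (NA for resting runs).
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr, schedule = NULL, session = NA_integer_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot(is.numeric(tr), length(tr) == 1L, tr > 0)
  if (!is.null(schedule)) {
    stopifnot(is.data.frame(schedule),
              all(c("scan_index", "onset_s", "label") %in% names(schedule)))
    if (nrow(schedule) != nrow(data))
      stop("schedule must have one row per scan (", nrow(data), " scans, ",
           nrow(schedule), " schedule rows)")
  }
  structure(list(data = data, tr = tr, schedule = schedule, session = session),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %d scans x %d voxels, TR %g s%s%s\n",
              nrow(x$data), ncol(x$data), x$tr,
              if (!is.na(x$session)) sprintf(", session %d", x$session) else "",
              if (!is.null(x$schedule)) ", with schedule" else ""))
  invisible(x)
}

#' @export
dim.bold_run <- function(x) dim(x$data)

n_scans <- function(run) nrow(run$data)
n_voxels_of <- function(run) ncol(run$data)

#' Nuisance time-series set
#'
#' Per-run nuisance signals used to build noise regressors: cerebrospinal
#' fluid (CSF), white matter (WM), global signal (GS) and six rigid-body
#' realignment (motion) parameters.
#'
#' @param csf,wm,gs numeric vectors, one value per scan.
#' @param rp numeric matrix, scans x 6 motion parameters.
#' @return An object of class `nuisance_set`.
#' @export
nuisance_set <- function(csf, wm, gs, rp) {
  rp <- as.matrix(rp)
  n <- length(csf)
  if (length(wm) != n || length(gs) != n || nrow(rp) != n)
    stop("all nuisance series must have the same number of scans")
  if (ncol(rp) != 6L)
    stop("rp must have 6 motion-parameter columns, got ", ncol(rp))
  structure(list(csf = as.numeric(csf), wm = as.numeric(wm),
                 gs = as.numeric(gs), rp = rp),
            class = "nuisance_set")
}

#' @export
print.nuisance_set <- function(x, ...) {
  cat(sprintf("<nuisance_set> CSF/WM/GS + 6 motion parameters, %d scans\n",
              length(x$csf)))
  invisible(x)
}

# 9 base nuisance columns in fixed order
nuisance_base_matrix <- function(nuis) {
  stopifnot(inherits(nuis, "nuisance_set"))
  m <- cbind(csf = nuis$csf, wm = nuis$wm, gs = nuis$gs, nuis$rp)
  colnames(m) <- c("csf", "wm", "gs", paste0("rp", 1:6))
  m
}
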