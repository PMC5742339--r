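#' Parcel time-series container
#'
#' Holds one subject-session matrix of parcel signals together with
#' parcel IDs, the sampling interval and provenance flags recording which
#' cleaning stages have run. The fixed stage order is trim -> filter ->
#' nuisance regression; re-running a stage that is already flagged is an
#' error, which keeps accidental double-filtering out of the pipeline.
#'
#' @param data Numeric matrix, timepoints x parcels.
#' @param parcel_ids Character vector of parcel IDs (defaults to column
#'   names).
#' @param tr_seconds Sampling interval, seconds.
#' @param stages Character vector of already-applied stages.
#' @param global_signal_variant Logical; TRUE when the confound set of the
#'   nuisance regression included the global WM+CSF mean.
#' @return An object of class `parcel_timeseries`.
#' @export
parcel_timeseries <- function(data, parcel_ids = colnames(data), tr_seconds,
                              stages = character(), global_signal_variant = FALSE) {
  data <- as.matrix(data)
  if (is.null(parcel_ids)) parcel_ids <- sprintf("p%03d", seq_len(ncol(data)))
  stopifnot(length(parcel_ids) == ncol(data), tr_seconds > 0)
  if (any(!is.finite(data))) stop("non-finite entries in parcel time series")
  colnames(data) <- parcel_ids
  structure(list(data = data, parcel_ids = as.character(parcel_ids),
                 tr_seconds = tr_seconds, stages = stages,
                 global_signal_variant = global_signal_variant),
            class = "parcel_timeseries")
}

#' @export
print.parcel_timeseries <- function(x, ...) {
  cat(sprintf("<parcel_timeseries> %d timepoints x %d parcels, TR %gs; stages: %s\n",
              nrow(x$data), ncol(x$data), x$tr_seconds,
              if (length(x$stages)) paste(x$stages, collapse = " -> ") else "(raw)"))
  invisible(x)
}

check_stage <- function(ts, stage) {
  if (stage %in% ts$stages) {
    stop(sprintf("stage '%s' has already been applied to this series", stage))
  }
  order <- c("trimmed", "filtered", "nuisance_regressed")
  pos <- match(stage, order)
  later <- ts$stages[match(ts$stages, order) > pos]
  if (length(later)) {
    stop(sprintf("stage '%s' cannot run after '%s' (fixed order: %s)",
                 stage, later[1], paste(order, collapse = " -> ")))
  }
  invisible(TRUE)
}

#' Drop lead volumes from a time series
#'
#' Removes the first `n_drop` rows (default 6), the volumes acquired
#' before magnetization equilibrium.
#'
#' @param ts A `parcel_timeseries` or plain matrix.
#' @param n_drop Number of initial volumes to drop.
#' @return Same type as the input, with the first `n_drop` rows removed.
#' @export
trim_volumes <- function(ts, n_drop = 6L) {
  n_drop <- as.integer(n_drop)
  drop_rows <- function(m) {
    if (n_drop < 0 || n_drop >= nrow(m)) {
      stop(sprintf("cannot drop %d volumes from a %d-volume series", n_drop, nrow(m)))
    }
    if (n_drop == 0) m else m[-seq_len(n_drop), , drop = FALSE]
  }
  if (inherits(ts, "parcel_timeseries")) {
    check_stage(ts, "trimmed")
    ts$data <- drop_rows(ts$data)
    ts$stages <- c(ts$stages, "trimmed")
    return(ts)
  }
  drop_rows(as.matrix(ts))
}

ideal_bandpass <- function(m, low_hz, high_hz, tr_seconds) {
  n <- nrow(m)
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz)) stop("need 0 <= low_hz < high_hz")
  if (high_hz > nyq + 1e-12) {
    stop(sprintf("high_hz %.4g exceeds the Nyquist frequency %.4g Hz", high_hz, nyq))
  }
  mu <- colMeans(m)
  m <- sweep(m, 2, mu)
  freq <- (seq_len(n) - 1) / (n * tr_seconds)
  freq <- pmin(freq, 1 / tr_seconds - freq)  # fold to [0, Nyquist]
  keep <- freq >= low_hz & freq <= high_hz
  sp <- mvfft(m)
  sp[!keep, ] <- 0
  Re(mvfft(sp, inverse = TRUE)) / n
}

#' Ideal frequency-domain band-pass filter
#'
#' Per column: demean, FFT, zero every frequency bin strictly outside
#' `[low_hz, high_hz]` (two-sided), inverse FFT. This is the ideal
#' ("brick-wall") filter; defaults pass the canonical low-frequency
#' fluctuation band 0.01-0.08 Hz.
#'
#' @param ts A `parcel_timeseries` or plain matrix.
#' @param low_hz,high_hz Pass-band edges in Hz.
#' @param tr_seconds Sampling interval; taken from the object when a
#'   `parcel_timeseries` is given.
#' @return Filtered object of the same type.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.08,
                            tr_seconds = NULL) {
  if (inherits(ts, "parcel_timeseries")) {
    check_stage(ts, "filtered")
    ts$data <- ideal_bandpass(ts$data, low_hz, high_hz, ts$tr_seconds)
    colnames(ts$data) <- ts$parcel_ids
    ts$stages <- c(ts$stages, "filtered")
    return(ts)
  }
  if (is.null(tr_seconds)) stop("tr_seconds required for matrix input")
  ideal_bandpass(as.matrix(ts), low_hz, high_hz, tr_seconds)
}

#' Regress nuisance signals out of parcel time series
#'
#' Ordinary least squares of each parcel signal on an intercept plus the
#' confound columns (six motion parameters, white-matter and CSF means,
#' optionally their global mean); the residual becomes the cleaned
#' signal. Confounds should be band-pass filtered with the same filter
#' as the data before calling (the pipeline does this) so that the
#' regression cannot reintroduce out-of-band energy.
#'
#' @param ts A `parcel_timeseries` or plain matrix.
#' @param confounds Numeric matrix, one row per timepoint.
#' @param global_signal Logical flag recorded in provenance when the
#'   confound set includes the global WM+CSF mean.
#' @return Residualized object of the same type.
#' @export
regress_nuisance <- function(ts, confounds, global_signal = FALSE) {
  m <- if (inherits(ts, "parcel_timeseries")) ts$data else as.matrix(ts)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(m)) {
    stop("confound rows must match time-series rows")
  }
  X <- cbind(`(intercept)` = 1, confounds)
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop(sprintf("confound matrix is rank deficient; collinear columns: %s",
                 paste(dropped, collapse = ", ")))
  }
  res <- qr.resid(qr_X, m)
  if (inherits(ts, "parcel_timeseries")) {
    check_stage(ts, "nuisance_regressed")
    ts$data <- res
    colnames(ts$data) <- ts$parcel_ids
    ts$stages <- c(ts$stages, "nuisance_regressed")
    ts$global_signal_variant <- isTRUE(global_signal)
    return(ts)
  }
  res
}

#' Identify parcels with zero residual variance
#'
#' Correlation is undefined for flat signals, so degenerate parcels are
#' flagged and must be handled (excluded) explicitly downstream.
#'
#' @param ts A `parcel_timeseries` or matrix.
#' @param tol SD threshold below which a parcel counts as flat.
#' @return Character vector of flagged parcel IDs (possibly empty).
#' @export
flag_degenerate_parcels <- function(ts, tol = 1e-12) {
  m <- if (inherits(ts, "parcel_timeseries")) ts$data else as.matrix(ts)
  ids <- if (inherits(ts, "parcel_timeseries")) ts$parcel_ids else
    colnames(m) %||% as.character(seq_len(ncol(m)))
  ids[apply(m, 2, sd) <= tol]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Framewise displacement (Power formula)
#'
#' `FD_t = sum |d translation_t| + radius * sum |d rotation_t|` with
#' rotations converted from degrees to radians and projected to arc
#' length on a sphere of the given radius (default 50 mm). The first
#' frame has FD 0 by convention.
#'
#' @param motion Timepoints x 6 matrix: translations (mm) then rotations
#'   (degrees).
#' @param sphere_radius_mm Head-sphere radius for the rotation term.
#' @return List with `fd` (per-frame series, mm) and `mean_fd` (mean over
#'   frames 2..T).
#' @export
framewise_displacement <- function(motion, sphere_radius_mm = 50) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6, nrow(motion) >= 2)
  d <- diff(motion)
  fd <- rowSums(abs(d[, 1:3, drop = FALSE])) +
    sphere_radius_mm * rowSums(abs(d[, 4:6, drop = FALSE]) * pi / 180)
  fd <- c(0, fd)
  list(fd = fd, mean_fd = mean(fd[-1]))
}

#' Motion-based subject exclusion
#'
#' Excludes a session when head position deviates from the first volume
#' by strictly more than `trans_mm` in any translation or `rot_deg` in
#' any rotation (default 2 mm / 2 degrees).
#'
#' @param motion Timepoints x 6 matrix (translations mm, rotations
#'   degrees).
#' @param trans_mm,rot_deg Exclusion thresholds.
#' @param sphere_radius_mm Passed to [framewise_displacement()] for the
#'   reported mean FD.
#' @return A one-row data.frame QC record: `mean_fd`, `max_trans`,
#'   `max_rot`, `excluded`.
#' @export
motion_exclusion <- function(motion, trans_mm = 2, rot_deg = 2,
                             sphere_radius_mm = 50) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6)
  dev <- sweep(motion, 2, motion[1, ])
  max_trans <- max(abs(dev[, 1:3]))
  max_rot <- max(abs(dev[, 4:6]))
  fd <- if (nrow(motion) >= 2) framewise_displacement(motion, sphere_radius_mm)$mean_fd else 0
  data.frame(mean_fd = fd, max_trans = max_trans, max_rot = max_rot,
             excluded = max_trans > trans_mm || max_rot > rot_deg)
}

#' Gray-matter-masked parcellation of voxel data
#'
#' Averages the signal over the voxels of each atlas parcel that fall
#' inside the gray-matter mask; parcels sharing fewer than
#' `min_common_voxels` voxels with the mask (default 5) are excluded and
#' reported.
#'
#' @param voxel_data 4D numeric array (x, y, z, time), or a NIfTI path
#'   readable by the RNifti package.
#' @param atlas_labels 3D integer array (0 = background) or NIfTI path.
#' @param gm_mask 3D binary array or NIfTI path.
#' @param min_common_voxels Minimum masked voxels for a parcel to be
#'   retained.
#' @param tr_seconds Sampling interval for the returned series.
#' @return List with `ts` (a `parcel_timeseries` over retained parcels)
#'   and `excluded` (data.frame of excluded parcel labels and their
#'   masked voxel counts).
#' @export
parcellate <- function(voxel_data, atlas_labels, gm_mask,
                       min_common_voxels = 5L, tr_seconds = 3) {
  voxel_data <- as_volume(voxel_data, 4)
  atlas_labels <- as_volume(atlas_labels, 3)
  gm_mask <- as_volume(gm_mask, 3)
  if (!identical(dim(voxel_data)[1:3], dim(atlas_labels)) ||
      !identical(dim(atlas_labels), dim(gm_mask))) {
    stop("voxel data, atlas and mask must share the same spatial grid")
  }
  labels <- sort(unique(as.integer(atlas_labels[atlas_labels > 0])))
  Tn <- dim(voxel_data)[4]
  flat <- matrix(voxel_data, ncol = Tn)  # voxels x time
  lab_vec <- as.integer(atlas_labels)
  mask_vec <- as.logical(gm_mask != 0)
  keep <- list(); excl_lab <- integer(); excl_n <- integer()
  sig <- list()
  for (lb in labels) {
    vox <- which(lab_vec == lb & mask_vec)
    if (length(vox) < min_common_voxels) {
      excl_lab <- c(excl_lab, lb); excl_n <- c(excl_n, length(vox))
    } else {
      sig[[as.character(lb)]] <- colMeans(flat[vox, , drop = FALSE])
    }
  }
  if (!length(sig)) stop("no parcel retained after gray-matter masking")
  m <- do.call(cbind, sig)
  colnames(m) <- sprintf("parcel_%d", as.integer(names(sig)))
  list(
    ts = parcel_timeseries(m, tr_seconds = tr_seconds),
    excluded = data.frame(label = excl_lab, masked_voxels = excl_n)
  )
}

as_volume <- function(x, ndim) {
  if (is.character(x)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI paths requires the RNifti package")
    }
    x <- as.array(RNifti::readNifti(x))
  }
  x <- unclass(x)
  if (length(dim(x)) != ndim) {
    stop(sprintf("expected a %dD array, got %dD", ndim, length(dim(x))))
  }
  x
}
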