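#' Specify a synthetic two-session connectivity dataset
#'
#' Defines the full parameterization of the synthetic generator: a
#' multi-subject, two-session (rest1/rest2) design in which session 2
#' differs from session 1 only by a planted Fisher-Z shift on the
#' connections between a designated seed parcel and a set of target
#' parcels. Defaults emulate a 44-subject, 463-parcel, 114-retained-volume
#' design at TR = 3 s with a focal seed-edge increase of 0.17 Fisher-Z
#' units.
#'
#' @param n_subjects Number of subjects.
#' @param n_parcels Number of parcels (nodes).
#' @param n_timepoints Retained timepoints per session, after trimming the
#'   lead volumes.
#' @param n_lead_volumes Extra volumes prepended to each session so that
#'   the trimming stage has something to remove.
#' @param tr_seconds Repetition time (sampling interval), seconds.
#' @param base_correlation_model `"block_community"` (equal contiguous
#'   communities with constant within/between correlation) or
#'   `"random_sparse"` (sparse random off-diagonal correlations, repaired
#'   to the nearest positive semidefinite correlation matrix).
#' @param community_count Number of communities for the block model.
#' @param within_community_r,between_community_r Correlations inside and
#'   between communities, each strictly inside (-1, 1).
#' @param sparse_density,sparse_r_max Density and magnitude bound of the
#'   nonzero entries for the `"random_sparse"` model.
#' @param seed_node Index of the seed parcel whose connections carry the
#'   planted effect.
#' @param effect_mode `"focal"` (one planted edge) or `"diffuse"` (many
#'   edges incident to the seed).
#' @param effect_targets Either an integer vector of target parcel
#'   indices, a single number in (0, 1] read as a fraction of parcels, or
#'   `NULL` for the mode default (focal: the first parcel outside the
#'   seed's community; diffuse: fraction 0.3).
#' @param delta_z Mean planted session-2 shift on the Fisher-Z scale
#'   (>= 0).
#' @param subject_sd_z Between-subject SD of the planted shift, Fisher-Z
#'   scale. One shift per subject is drawn and shared across that
#'   subject's planted edges.
#' @param ar_coefficient Lag-1 autocorrelation of each parcel series.
#' @param nuisance_amplitude SD of the added nuisance component relative
#'   to the unit-SD neural signal.
#' @param hf_noise_sd SD of an additional high-frequency noise component
#'   (white noise band-limited above the canonical 0.08 Hz pass band,
#'   emulating aliased physiological power) that nuisance regression
#'   cannot remove but band-pass filtering can. Default 0.
#' @param motion_step_sd_mm,motion_step_sd_deg Step SD of the random-walk
#'   motion parameters (translations mm, rotations degrees). The default
#'   0.019 yields a mean framewise displacement near 0.085 mm.
#' @param rng_seed Integer seed; identical spec + seed gives a
#'   bit-identical dataset.
#'
#' @return An object of class `gfc_synth_spec` (a validated list).
#' @seealso [generate_dataset()], [build_truth_covariances()]
#' @export
synthetic_spec <- function(n_subjects = 44L,
                           n_parcels = 463L,
                           n_timepoints = 114L,
                           n_lead_volumes = 6L,
                           tr_seconds = 3,
                           base_correlation_model = c("block_community", "random_sparse"),
                           community_count = 4L,
                           within_community_r = 0.3,
                           between_community_r = 0.1,
                           sparse_density = 0.1,
                           sparse_r_max = 0.3,
                           seed_node = 1L,
                           effect_mode = c("focal", "diffuse"),
                           effect_targets = NULL,
                           delta_z = 0.17,
                           subject_sd_z = 0.22,
                           ar_coefficient = 0.3,
                           nuisance_amplitude = 0.3,
                           hf_noise_sd = 0,
                           motion_step_sd_mm = 0.019,
                           motion_step_sd_deg = 0.019,
                           rng_seed = 1L) {
  spec <- list(
    n_subjects = as.integer(n_subjects),
    n_parcels = as.integer(n_parcels),
    n_timepoints = as.integer(n_timepoints),
    n_lead_volumes = as.integer(n_lead_volumes),
    tr_seconds = tr_seconds,
    base_correlation_model = match.arg(base_correlation_model),
    community_count = as.integer(community_count),
    within_community_r = within_community_r,
    between_community_r = between_community_r,
    sparse_density = sparse_density,
    sparse_r_max = sparse_r_max,
    seed_node = as.integer(seed_node),
    effect_mode = match.arg(effect_mode),
    effect_targets = effect_targets,
    delta_z = delta_z,
    subject_sd_z = subject_sd_z,
    ar_coefficient = ar_coefficient,
    nuisance_amplitude = nuisance_amplitude,
    hf_noise_sd = hf_noise_sd,
    motion_step_sd_mm = motion_step_sd_mm,
    motion_step_sd_deg = motion_step_sd_deg,
    rng_seed = as.integer(rng_seed)
  )
  class(spec) <- "gfc_synth_spec"
  validate_synth_spec(spec)
}

validate_synth_spec <- function(spec) {
  stopifnot(
    spec$n_subjects >= 1L,
    spec$n_parcels >= 2L,
    spec$n_timepoints >= 1L,
    spec$n_lead_volumes >= 0L,
    spec$tr_seconds > 0,
    spec$community_count >= 1L,
    spec$delta_z >= 0,
    spec$subject_sd_z >= 0,
    spec$nuisance_amplitude >= 0,
    spec$hf_noise_sd >= 0,
    spec$motion_step_sd_mm >= 0,
    spec$motion_step_sd_deg >= 0
  )
  for (r in c(spec$within_community_r, spec$between_community_r, spec$ar_coefficient)) {
    if (!(r > -1 && r < 1)) stop("correlation/AR parameters must lie strictly inside (-1, 1)")
  }
  if (spec$seed_node < 1L || spec$seed_node > spec$n_parcels) {
    stop("seed_node must be a parcel index in 1..n_parcels")
  }
  spec$effect_targets <- resolve_effect_targets(spec)
  if (spec$seed_node %in% spec$effect_targets) {
    stop("seed_node must not be among effect_targets")
  }
  spec
}

# Resolve effect_targets to an explicit, deterministic index vector.
resolve_effect_targets <- function(spec) {
  P <- spec$n_parcels
  others <- setdiff(seq_len(P), spec$seed_node)
  tg <- spec$effect_targets
  if (is.null(tg)) {
    if (spec$effect_mode == "focal") {
      comm <- community_assignment(P, spec$community_count)
      out <- others[comm[others] != comm[spec$seed_node]]
      tg <- if (length(out)) out[1] else others[1]
    } else {
      tg <- 0.3
    }
  }
  if (length(tg) == 1 && tg > 0 && tg < 1) {
    k <- max(1L, round(tg * P))
    tg <- others[seq_len(min(k, length(others)))]
  }
  tg <- as.integer(tg)
  if (any(tg < 1L | tg > P)) stop("effect_targets out of parcel range")
  if (anyDuplicated(tg)) stop("effect_targets must be unique")
  if (spec$effect_mode == "focal" && length(tg) != 1L) {
    stop("focal effect_mode requires exactly one target parcel")
  }
  sort(tg)
}

community_assignment <- function(n_parcels, community_count) {
  rep(seq_len(community_count),
      each = ceiling(n_parcels / community_count))[seq_len(n_parcels)]
}

#' Nearest positive-semidefinite correlation repair
#'
#' Clips negative eigenvalues at zero and rescales the diagonal back to
#' one. A matrix that is already PSD (up to numerical tolerance) is
#' returned unchanged.
#'
#' @param mat Symmetric matrix with unit diagonal.
#' @param tol Eigenvalue tolerance below which no repair is performed.
#' @return A PSD correlation matrix.
#' @export
psd_repair <- function(mat, tol = 1e-12) {
  e <- eigen(mat, symmetric = TRUE)
  if (min(e$values) >= -tol) return(mat)
  v <- pmax(e$values, 0)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(pmax(diag(out), .Machine$double.eps))
  out <- out / outer(d, d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

#' Ground-truth session correlation matrices
#'
#' Builds the session-1 correlation matrix from the base model, then
#' forms session 2 by shifting each planted seed-target edge on the
#' Fisher-Z scale: `r2 = tanh(atanh(r1) + delta_z)`. Both matrices are
#' repaired to the nearest PSD correlation matrix by eigenvalue clipping;
#' if the repair moves a planted edge by more than 0.01 the planted
#' design is unrealizable and an error names the offending edge.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `session1`, `session2` (correlation
#'   matrices), `planted` (data.frame of `i`, `j`, `delta_z`), and
#'   `targets`.
#' @export
build_truth_covariances <- function(spec) {
  spec <- validate_synth_spec(spec)
  P <- spec$n_parcels
  if (spec$base_correlation_model == "block_community") {
    comm <- community_assignment(P, spec$community_count)
    S1 <- matrix(spec$between_community_r, P, P)
    same <- outer(comm, comm, "==")
    S1[same] <- spec$within_community_r
    diag(S1) <- 1
  } else {
    S1 <- with_local_seed(spec$rng_seed, {
      S <- diag(1, P)
      up <- which(upper.tri(S))
      nz <- up[runif(length(up)) < spec$sparse_density]
      S[nz] <- runif(length(nz), -spec$sparse_r_max, spec$sparse_r_max)
      S[lower.tri(S)] <- t(S)[lower.tri(S)]
      S
    })
  }
  S1 <- psd_repair(S1)
  targets <- spec$effect_targets
  S2 <- S1
  z2 <- tanh(atanh(S1[spec$seed_node, targets]) + spec$delta_z)
  S2[spec$seed_node, targets] <- z2
  S2[targets, spec$seed_node] <- z2
  S2r <- psd_repair(S2)
  moved <- abs(S2r[spec$seed_node, targets] - S2[spec$seed_node, targets])
  if (any(moved > 0.01)) {
    bad <- targets[which.max(moved)]
    stop(sprintf(
      "PSD repair perturbed planted edge (%d, %d) by %.4f (> 0.01); effect not realizable",
      spec$seed_node, bad, max(moved)))
  }
  list(
    session1 = S1,
    session2 = S2r,
    planted = data.frame(i = spec$seed_node, j = targets,
                         delta_z = spec$delta_z),
    targets = targets
  )
}

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulate one session of parcel time series
#'
#' Draws a stationary AR(1) Gaussian multivariate series whose
#' cross-sectional correlation equals the subject-level correlation
#' matrix (the ground truth with any per-subject Fisher-Z offsets on the
#' planted edges mapped back through `tanh`), then adds nuisance
#' contamination: each parcel receives a random linear combination of
#' the standardized motion, white-matter and CSF regressors scaled to
#' `nuisance_amplitude` times the neural SD. Motion parameters are
#' random walks; WM/CSF are unit-SD AR(1) series. Uses the current RNG
#' stream (seed upstream for reproducibility).
#'
#' @param truth_corr PSD correlation matrix for this session.
#' @param spec A [synthetic_spec()].
#' @param subject_shift Scalar Fisher-Z offset added to the planted
#'   seed-target edges for this subject (0 for none).
#' @return List with `ts` (`(n_lead_volumes + n_timepoints) x n_parcels`
#'   matrix, columns named by parcel ID), `motion` (6-column matrix),
#'   `wm`, `csf` (vectors).
#' @export
simulate_session <- function(truth_corr, spec, subject_shift = 0) {
  P <- spec$n_parcels
  Tn <- spec$n_lead_volumes + spec$n_timepoints
  S <- truth_corr
  if (subject_shift != 0) {
    tg <- spec$effect_targets
    z <- tanh(atanh(S[spec$seed_node, tg]) + subject_shift)
    S[spec$seed_node, tg] <- z
    S[tg, spec$seed_node] <- z
    S <- psd_repair(S)
  }
  L <- tryCatch(chol(S), error = function(e) chol(psd_repair(S) + diag(1e-10, P)))
  E <- matrix(rnorm(Tn * P), Tn, P) %*% L
  phi <- spec$ar_coefficient
  X <- E
  if (phi != 0 && Tn > 1) {
    a <- sqrt(1 - phi^2)
    for (t in 2:Tn) X[t, ] <- phi * X[t - 1, ] + a * E[t, ]
  }
  motion <- cbind(
    matrix(rnorm(Tn * 3, sd = spec$motion_step_sd_mm), Tn, 3),
    matrix(rnorm(Tn * 3, sd = spec$motion_step_sd_deg), Tn, 3)
  )
  motion[1, ] <- 0
  motion <- apply(motion, 2, cumsum)
  if (Tn == 1) motion <- matrix(motion, 1, 6)
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  ar1_series <- function(n, phi) {
    e <- rnorm(n)
    x <- e
    if (phi != 0 && n > 1) {
      a <- sqrt(1 - phi^2)
      for (t in 2:n) x[t] <- phi * x[t - 1] + a * e[t]
    }
    x
  }
  wm <- ar1_series(Tn, phi)
  csf <- ar1_series(Tn, phi)
  if (spec$nuisance_amplitude > 0) {
    reg <- cbind(motion, wm, csf)
    reg <- apply(reg, 2, function(v) {
      s <- sd(v)
      if (s > 0) (v - mean(v)) / s else v * 0
    })
    W <- matrix(rnorm(ncol(reg) * P), ncol(reg), P)
    nui <- reg %*% W
    nsd <- apply(nui, 2, sd)
    nsd[nsd == 0] <- 1
    X <- X + sweep(nui, 2, nsd, "/") * spec$nuisance_amplitude
  }
  if (spec$hf_noise_sd > 0 && Tn >= 8) {
    nyq <- 1 / (2 * spec$tr_seconds)
    hf <- ideal_bandpass(matrix(rnorm(Tn * P), Tn, P),
                         low_hz = 0.09, high_hz = nyq,
                         tr_seconds = spec$tr_seconds)
    hsd <- apply(hf, 2, sd)
    hsd[hsd == 0] <- 1
    X <- X + sweep(hf, 2, hsd, "/") * spec$hf_noise_sd
  }
  colnames(X) <- parcel_ids(P)
  list(ts = X, motion = motion, wm = wm, csf = csf)
}

parcel_ids <- function(P) sprintf("p%03d", seq_len(P))

#' Generate a full synthetic two-session dataset
#'
#' Runs [build_truth_covariances()] and then [simulate_session()] for
#' every subject and session. Session 1 uses the ground-truth matrix as
#' is; session 2 applies a per-subject planted shift drawn from
#' `N(delta_z, subject_sd_z)` (one draw per subject, shared across that
#' subject's planted edges). The whole draw is seeded by `spec$rng_seed`,
#' so identical specs give bit-identical datasets.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `gfc_dataset`: list with `spec`, `subjects`
#'   (per subject, sessions `rest1`/`rest2` as returned by
#'   [simulate_session()]), `truth` (session matrices + planted-edge
#'   table + per-subject shifts), and `parcel_ids`.
#' @export
generate_dataset <- function(spec) {
  spec <- validate_synth_spec(spec)
  truth <- build_truth_covariances(spec)
  set.seed(spec$rng_seed)
  shifts <- spec$delta_z + rnorm(spec$n_subjects, 0, spec$subject_sd_z)
  subjects <- vector("list", spec$n_subjects)
  names(subjects) <- sprintf("S%03d", seq_len(spec$n_subjects))
  for (i in seq_len(spec$n_subjects)) {
    subjects[[i]] <- list(
      rest1 = simulate_session(truth$session1, spec, subject_shift = 0),
      rest2 = simulate_session(truth$session1, spec, subject_shift = shifts[i])
    )
  }
  structure(list(
    spec = spec,
    subjects = subjects,
    truth = list(session1 = truth$session1, session2 = truth$session2,
                 planted = truth$planted, subject_shifts = shifts),
    parcel_ids = parcel_ids(spec$n_parcels)
  ), class = "gfc_dataset")
}

#' @export
print.gfc_dataset <- function(x, ...) {
  cat(sprintf("<gfc_dataset> %d subjects x 2 sessions, %d parcels, %d+%d volumes (TR %gs)\n",
              x$spec$n_subjects, x$spec$n_parcels, x$spec$n_lead_volumes,
              x$spec$n_timepoints, x$spec$tr_seconds))
  cat(sprintf("  planted: %s, %d edge(s) at seed %d, delta_z %.3f (subject SD %.3f)\n",
              x$spec$effect_mode, nrow(x$truth$planted), x$spec$seed_node,
              x$spec$delta_z, x$spec$subject_sd_z))
  invisible(x)
}

#' Write a synthetic dataset to a directory of TSV/JSON files
#'
#' Emits, per subject-session, `<subj>_<sess>_ts.tsv` (timepoints x
#' parcels, header = parcel IDs), `<subj>_<sess>_motion.tsv`
#' (tx,ty,tz,rx,ry,rz) and `<subj>_<sess>_nuisance.tsv` (wm, csf), plus
#' `ground_truth.json` (planted edges, per-subject shifts, rng seed) and
#' `spec.json`.
#'
#' @param dataset A `gfc_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gfc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in names(dataset$subjects)) {
    for (sess in c("rest1", "rest2")) {
      s <- dataset$subjects[[subj]][[sess]]
      write_tsv_matrix(s$ts, file.path(dir, sprintf("%s_%s_ts.tsv", subj, sess)))
      write_tsv_matrix(s$motion, file.path(dir, sprintf("%s_%s_motion.tsv", subj, sess)))
      write_tsv_matrix(cbind(wm = s$wm, csf = s$csf),
                       file.path(dir, sprintf("%s_%s_nuisance.tsv", subj, sess)))
    }
  }
  truth <- list(
    planted = dataset$truth$planted,
    subject_shifts = dataset$truth$subject_shifts,
    rng_seed = dataset$spec$rng_seed,
    parcel_ids = dataset$parcel_ids
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  spec_out <- dataset$spec
  class(spec_out) <- NULL
  jsonlite::write_json(spec_out, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
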