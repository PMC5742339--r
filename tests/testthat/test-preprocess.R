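test_that("trim_volumes drops exactly the lead volumes", {
  m <- matrix(seq_len(120 * 2), 120, 2)
  expect_identical(nrow(trim_volumes(m, 6)), 114L)
  expect_identical(trim_volumes(m, 0), m)
  expect_error(trim_volumes(m[1:5, ], 6), "cannot drop")
  ts <- parcel_timeseries(m, tr_seconds = 3)
  tts <- trim_volumes(ts)
  expect_identical(unname(tts$data), unname(m[-(1:6), ]))
  expect_identical(tts$stages, "trimmed")
})

test_that("the ideal band-pass keeps in-band sinusoids and kills out-of-band power", {
  tr <- 3; n <- 1024
  t <- (seq_len(n) - 1) * tr
  # constant column is pure DC and must vanish
  const <- matrix(5, n, 1)
  expect_lt(max(abs(bandpass_filter(const, 0.01, 0.08, tr))), 1e-10)
  # 0.05 Hz sits mid-band
  s_in <- matrix(sin(2 * pi * 0.05 * t), n, 1)
  out <- bandpass_filter(s_in, 0.01, 0.08, tr)
  expect_gt(cor(out[, 1], s_in[, 1]), 0.999)
  # 0.15 Hz is in the stop band
  s_out <- matrix(sin(2 * pi * 0.15 * t), n, 1)
  filtered <- bandpass_filter(s_out, 0.01, 0.08, tr)
  expect_lt(sum(filtered^2) / sum(s_out^2), 0.01)
  expect_error(bandpass_filter(s_in, 0.01, 0.2, tr), "Nyquist")
})

test_that("parcellation averages gray-matter voxels and excludes sparse parcels", {
  dims <- c(4, 4, 2); Tn <- 5
  atlas <- array(0L, dims)
  atlas[1:2, 1:2, 1] <- 1L   # 4 voxels -> below the 5-voxel minimum
  atlas[3:4, , ] <- 2L       # 16 voxels
  mask <- array(1L, dims)
  vox <- array(rnorm(prod(dims) * Tn), c(dims, Tn))
  res <- parcellate(vox, atlas, mask, min_common_voxels = 5)
  expect_identical(res$excluded$label, 1L)
  expect_identical(res$excluded$masked_voxels, 4L)
  expect_identical(res$ts$parcel_ids, "parcel_2")
  # constant parcel value passes through as that constant
  vox2 <- vox; for (tt in seq_len(Tn)) {
    v <- vox2[, , , tt]; v[atlas == 2L] <- 7; vox2[, , , tt] <- v
  }
  res2 <- parcellate(vox2, atlas, mask, min_common_voxels = 5)
  expect_equal(unname(res2$ts$data[, 1]), rep(7, Tn))
  # one whole-volume parcel against a brute-force spatial mean
  atlas_all <- array(1L, dims)
  res3 <- parcellate(vox, atlas_all, mask, min_common_voxels = 5)
  brute <- vapply(seq_len(Tn), function(tt) mean(vox[, , , tt]), numeric(1))
  expect_equal(unname(res3$ts$data[, 1]), brute, tolerance = 1e-12)
  expect_error(parcellate(vox, atlas[1:3, , , drop = FALSE],
                          mask[1:3, , , drop = FALSE]), "grid")
})

test_that("nuisance regression is exact OLS with residuals orthogonal to confounds", {
  set.seed(1)
  n <- 80
  conf <- cbind(rnorm(n), rnorm(n), rnorm(n))
  # signal equal to a confound column: residual vanishes
  res0 <- regress_nuisance(matrix(conf[, 2], n, 1), conf)
  expect_lt(max(abs(res0)), 1e-8 * sd(conf[, 2]))
  # confounds with exactly zero sample covariance with the signal:
  # residual is the demeaned signal
  sig <- rnorm(n)
  sig_orth <- qr.resid(qr(cbind(1, conf)), sig) + 3  # orthogonal + offset
  res1 <- regress_nuisance(matrix(sig_orth, n, 1), conf)
  expect_equal(res1[, 1], sig_orth - mean(sig_orth), tolerance = 1e-8)
  # OLS orthogonality for generic signals
  m <- matrix(rnorm(n * 4), n, 4)
  res <- regress_nuisance(m, conf)
  for (k in 1:3) for (j in 1:4) {
    expect_lt(abs(cor(res[, j], conf[, k])), 1e-10)
  }
  # rank deficiency is reported with the collinear column
  bad <- cbind(a = conf[, 1], b = conf[, 1])
  expect_error(regress_nuisance(m, bad), "rank deficient")
})

test_that("framewise displacement follows the translation + arc-length formula", {
  motion <- matrix(0, 10, 6)
  motion[5:10, 1] <- 0.1  # one +0.1 mm step in x
  fd <- framewise_displacement(motion)
  expect_equal(fd$fd[5], 0.1)
  expect_equal(fd$fd[1], 0)
  expect_equal(sum(fd$fd != 0), 1L)

  rot <- matrix(0, 10, 6)
  rot[3:10, 4] <- 1  # one +1 degree step
  expect_equal(framewise_displacement(rot, 50)$fd[3], 50 * pi / 180,
               tolerance = 1e-12)
  expect_true(all(framewise_displacement(matrix(2, 8, 6))$fd == 0))
})

test_that("motion exclusion uses strict thresholds against the first volume", {
  m <- matrix(0, 20, 6)
  m[10, 1] <- 2.1
  expect_true(motion_exclusion(m)$excluded)
  expect_false(motion_exclusion(matrix(0, 20, 6))$excluded)
  m2 <- matrix(0, 20, 6)
  m2[10, 5] <- 2.0  # exactly at the boundary: not excluded
  expect_false(motion_exclusion(m2)$excluded)
  # deviation is measured from the first volume, not from zero
  m3 <- matrix(5, 20, 6)  # constant large offset
  expect_false(motion_exclusion(m3)$excluded)
})

test_that("the cleaning stages enforce their fixed order and never re-run", {
  ts <- parcel_timeseries(matrix(rnorm(200), 50, 4), tr_seconds = 3)
  ts <- trim_volumes(ts, 2)
  expect_error(trim_volumes(ts, 2), "already been applied")
  ts <- bandpass_filter(ts)
  expect_error(bandpass_filter(ts), "already been applied")
  # order violation: filtering before trimming blocks a later trim
  ts_oo <- bandpass_filter(parcel_timeseries(matrix(rnorm(200), 50, 4),
                                             tr_seconds = 3))
  expect_error(trim_volumes(ts_oo, 2), "cannot run after")
  conf <- matrix(rnorm(48 * 2), 48, 2)
  ts <- regress_nuisance(ts, conf)
  expect_error(regress_nuisance(ts, conf), "already been applied")
  expect_identical(ts$stages, c("trimmed", "filtered", "nuisance_regressed"))
})

test_that("filtering plus nuisance regression recovers the truth better than either alone", {
  spec <- synthetic_spec(n_subjects = 1, n_parcels = 20, n_timepoints = 400,
                         n_lead_volumes = 0, community_count = 2,
                         within_community_r = 0.4, between_community_r = 0.1,
                         delta_z = 0, subject_sd_z = 0,
                         nuisance_amplitude = 1.0, hf_noise_sd = 0.8,
                         rng_seed = 8)
  truth <- build_truth_covariances(spec)
  set.seed(8)
  s <- simulate_session(truth$session1, spec)
  conf_raw <- cbind(s$motion, wm = s$wm, csf = s$csf)
  frob <- function(m) sqrt(sum((cor(m) - truth$session1)^2))
  filt <- function(m) bandpass_filter(m, 0.01, 0.08, tr_seconds = 3)
  err_filter_only <- frob(filt(s$ts))
  err_regress_only <- frob(regress_nuisance(s$ts, conf_raw))
  err_both <- frob(regress_nuisance(filt(s$ts), filt(conf_raw)))
  expect_lt(err_both, err_filter_only)
  expect_lt(err_both, err_regress_only)
})
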