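test_that("ground-truth session matrices implement the planted Fisher-Z shift", {
  # zero effect: session 2 identical to session 1
  spec0 <- synthetic_spec(n_subjects = 4, n_parcels = 20, delta_z = 0,
                          subject_sd_z = 0, rng_seed = 1)
  tr0 <- build_truth_covariances(spec0)
  expect_identical(tr0$session1, tr0$session2)

  # focal edge: closed-form tanh/arctanh shift from r0 = 0.2 by 0.17
  spec1 <- synthetic_spec(n_subjects = 4, n_parcels = 20, community_count = 2,
                          within_community_r = 0.5, between_community_r = 0.2,
                          effect_mode = "focal", effect_targets = 15L,
                          delta_z = 0.17, rng_seed = 1)
  tr1 <- build_truth_covariances(spec1)
  expect_equal(tr1$session1[1, 15], 0.2)
  expect_equal(tr1$session2[1, 15], tanh(atanh(0.2) + 0.17), tolerance = 1e-12)
  expect_equal(tr1$session2[1, 15], 0.3564, tolerance = 1e-4)
  # off-planted entries untouched
  off <- tr1$session2; off[1, 15] <- off[15, 1] <- tr1$session1[1, 15]
  expect_lt(max(abs(off - tr1$session1)), 1e-6)
})

test_that("block-community base matrices are positive semidefinite", {
  spec <- synthetic_spec(n_subjects = 4, n_parcels = 30, community_count = 2,
                         within_community_r = 0.5, between_community_r = 0,
                         delta_z = 0.1)
  tr <- build_truth_covariances(spec)
  for (S in list(tr$session1, tr$session2)) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(diag(S), rep(1, 30))
    expect_equal(S, t(S))
  }
})

test_that("PSD repair clips eigenvalues and leaves PSD inputs untouched", {
  S <- diag(1, 5)
  expect_identical(psd_repair(S), S)
  bad <- matrix(0.9, 3, 3); diag(bad) <- 1
  bad[1, 2] <- bad[2, 1] <- -0.9  # not PSD
  fixed <- psd_repair(bad)
  expect_gte(min(eigen(fixed, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  expect_equal(diag(fixed), rep(1, 3))
})

test_that("an unrealizable planted effect fails loudly naming the edge", {
  # parcels 1 and 2 are near clones; flipping the sign of the 1-3 edge
  # while 2-3 stays strongly negative cannot be a correlation structure,
  # so the PSD repair must move the planted edge beyond the 0.01 bound
  spec <- synthetic_spec(n_subjects = 4, n_parcels = 3, community_count = 2,
                         within_community_r = 0.99, between_community_r = -0.8,
                         effect_mode = "focal", effect_targets = 3L,
                         delta_z = 2.2, rng_seed = 1)
  expect_error(build_truth_covariances(spec), "planted edge")
})

test_that("simulated sessions reproduce the target cross-correlation", {
  spec <- synthetic_spec(n_subjects = 1, n_parcels = 2, n_timepoints = 50000,
                         n_lead_volumes = 0, community_count = 1,
                         within_community_r = 0.6, ar_coefficient = 0,
                         nuisance_amplitude = 0, effect_targets = 2L,
                         delta_z = 0, subject_sd_z = 0, rng_seed = 11)
  truth <- build_truth_covariances(spec)
  set.seed(11)
  s <- simulate_session(truth$session1, spec)
  expect_equal(cor(s$ts)[1, 2], 0.6, tolerance = 0.01)
})

test_that("simulate_session is deterministic given the RNG state and honors motionless specs", {
  spec <- synthetic_spec(n_subjects = 1, n_parcels = 5, n_timepoints = 40,
                         motion_step_sd_mm = 0, motion_step_sd_deg = 0,
                         nuisance_amplitude = 0, effect_targets = 3L, rng_seed = 2)
  truth <- build_truth_covariances(spec)
  set.seed(99); s1 <- simulate_session(truth$session1, spec)
  set.seed(99); s2 <- simulate_session(truth$session1, spec)
  expect_identical(s1, s2)
  # motionless: constant motion table, FD identically zero
  expect_true(all(s1$motion == 0))
  expect_true(all(framewise_displacement(s1$motion)$fd == 0))
})

test_that("generate_dataset has the right shape, determinism and planted-edge count", {
  spec <- synthetic_spec(n_subjects = 3, n_parcels = 10, n_timepoints = 30,
                         rng_seed = 5)
  ds <- generate_dataset(spec)
  expect_length(ds$subjects, 3)
  all_ts <- unlist(lapply(ds$subjects, function(s) list(s$rest1$ts, s$rest2$ts)),
                   recursive = FALSE)
  expect_length(all_ts, 6)
  expect_identical(dim(all_ts[[1]]), c(36L, 10L))

  # byte-for-byte determinism of the serialized dataset
  ds2 <- generate_dataset(spec)
  expect_identical(serialize(ds, NULL), serialize(ds2, NULL))

  # diffuse fraction 0.3 of 100 parcels: exactly 30 seed-incident edges
  spec_d <- synthetic_spec(n_subjects = 2, n_parcels = 100, n_timepoints = 20,
                           effect_mode = "diffuse", effect_targets = 0.3,
                           delta_z = 0.05, rng_seed = 5)
  ds_d <- generate_dataset(spec_d)
  expect_identical(nrow(ds_d$truth$planted), 30L)
  expect_true(all(ds_d$truth$planted$i == spec_d$seed_node))
  expect_false(spec_d$seed_node %in% ds_d$truth$planted$j)
})

test_that("the planted shift is recovered on the Fisher-Z scale at scale", {
  # across-subject mean of the sample session delta on the planted edge
  # converges to delta_z (within 2 standard errors)
  spec <- synthetic_spec(n_subjects = 200, n_parcels = 6, n_timepoints = 2000,
                         n_lead_volumes = 0, community_count = 2,
                         within_community_r = 0.4, between_community_r = 0.1,
                         effect_mode = "focal", effect_targets = 4L,
                         delta_z = 0.3, subject_sd_z = 0.1,
                         nuisance_amplitude = 0, rng_seed = 42)
  ds <- generate_dataset(spec)
  dz <- vapply(ds$subjects, function(s) {
    atanh(cor(s$rest2$ts)[1, 4]) - atanh(cor(s$rest1$ts)[1, 4])
  }, numeric(1))
  se <- sd(dz) / sqrt(length(dz))
  expect_lt(abs(mean(dz) - 0.3), 2 * se + 1e-9)
})

test_that("spec validation rejects inconsistent designs", {
  expect_error(synthetic_spec(seed_node = 7, n_parcels = 5), "seed_node")
  expect_error(synthetic_spec(effect_targets = 1L), "seed_node must not be among")
  expect_error(synthetic_spec(within_community_r = 1), "inside")
  expect_error(synthetic_spec(effect_mode = "focal", effect_targets = c(2L, 3L)),
               "exactly one target")
})

test_that("written datasets round-trip through the TSV/JSON layout", {
  spec <- synthetic_spec(n_subjects = 2, n_parcels = 4, n_timepoints = 15,
                         rng_seed = 3)
  ds <- generate_dataset(spec)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "S001_rest1_ts.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  m <- gfconn:::read_tsv_matrix(file.path(dir, "S002_rest2_ts.tsv"))
  expect_equal(unname(m), unname(ds$subjects$S002$rest2$ts), tolerance = 1e-12)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  expect_equal(gt$rng_seed, 3)
  expect_equal(nrow(gt$planted), 1)
})
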