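test_that("phantom geometry nests GM inside WM inside the cord", {
  geom <- make_geometry(c(16L, 16L, 9L))
  # probabilities: WM + GM never exceed 1, so their total mass is bounded
  # by the cord voxel count
  expect_true(all(geom$wm_prob + geom$gm_prob <= 1 + 1e-12))
  expect_lte(sum(geom$wm_prob + geom$gm_prob), sum(geom$cord))
  # every confidently-GM voxel lies strictly inside the cord
  expect_true(all(geom$cord[geom$gm_prob > 0.5] == 1))
  # masks vanish outside the cord
  expect_true(all(geom$wm_prob[geom$cord == 0] == 0))
  expect_true(all(geom$gm_prob[geom$cord == 0] == 0))
  # per-slice levels split into three groups
  expect_equal(sort(unique(geom$levels)), 1:3)
  expect_error(make_geometry(c(6L, 6L, 3L)), "geometry")
  # gm_radius_frac = 0 gives a homogeneous all-WM cord
  hom <- make_geometry(c(12L, 12L, 3L), gm_radius_frac = 0)
  expect_equal(sum(hom$gm_prob), 0)
  expect_equal(hom$wm_prob, hom$cord)
})

test_that("eroding the convex cord removes exactly the boundary shell", {
  geom <- make_geometry(c(14L, 14L, 5L))
  eroded <- erode_mask(geom$cord, 1)
  expect_equal(eroded, erode_oracle(geom$cord, 1))
  expect_true(all(eroded <= geom$cord))
  expect_lt(sum(eroded), sum(geom$cord))
})

test_that("ground-truth sampling respects its degenerate limits", {
  # zero session effect: the two sessions are identical
  spec <- null_phantom_spec(n_subjects = 4L)
  tr <- sample_ground_truth(spec)
  s1 <- tr$params[tr$params$session == 1, c("F", "Dstar", "D")]
  s2 <- tr$params[tr$params$session == 2, c("F", "Dstar", "D")]
  expect_equal(s1, s2, ignore_attr = TRUE)
  # zero between-subject and session SD: every draw equals the tissue mean
  spec0 <- phantom_spec(n_subjects = 3L, grid = c(12L, 12L, 3L),
                        between_subject_sd = list(wm = c(F = 0, Dstar = 0, D = 0),
                                                  gm = c(F = 0, Dstar = 0, D = 0)),
                        session_effect_sd = list(wm = c(F = 0, Dstar = 0, D = 0),
                                                 gm = c(F = 0, Dstar = 0, D = 0)))
  tr0 <- sample_ground_truth(spec0)
  wm <- tr0$params[tr0$params$tissue == "wm", ]
  expect_true(all(wm$F == spec0$tissue_means$wm$F))
  expect_true(all(wm$D == spec0$tissue_means$wm$D))
  # all sampled truths inside the fitting bounds
  tr <- sample_ground_truth(phantom_spec(n_subjects = 50L, seed = 3L))
  with(tr$params, {
    expect_true(all(F >= 0 & F <= 0.20))
    expect_true(all(Dstar >= 0.3e-3 & Dstar <= 50e-3))
    expect_true(all(D >= 1.5e-4 & D <= 54e-4))
  })
})

test_that("subject-level WM F converges to the population mean", {
  spec <- phantom_spec(n_subjects = 200L, seed = 17L)
  tr <- sample_ground_truth(spec)
  f <- tr$params$F[tr$params$tissue == "wm" & tr$params$session == 1]
  se <- sqrt(0.0075^2 + spec$session_effect_sd$wm[["F"]]^2) / sqrt(200)
  expect_lt(abs(mean(f) - 0.0545), 3 * se)
})

test_that("noiseless simulation equals the forward model exactly", {
  spec <- null_phantom_spec(n_subjects = 1L)
  tr <- sample_ground_truth(spec)
  ds <- simulate_acquisition(spec, tr, 1, 1)
  wm_rows <- tr$params[tr$params$subject == 1 & tr$params$session == 1 &
                         tr$params$tissue == "wm", ]
  # pick a pure-WM voxel and compare every repetition frame to the model
  vox <- which(tr$geometry$labels == 1L)[1]
  dir_i <- 2  # anisotropy 0.9 on the second direction
  expected <- forward_signal(
    ivim_params(wm_rows$S0, wm_rows$F, wm_rows$Dstar,
                wm_rows$D * spec$anisotropy[dir_i]), spec$scheme)$values
  vol <- ds$volumes[[spec$directions[dir_i]]]
  flat <- matrix(vol, prod(spec$grid), nrow(ds$btable))
  for (ib in seq_along(expected)) {
    frames <- ds$btable$frame[ds$btable$b == spec$scheme$bvalues[ib]]
    expect_equal(unname(flat[vox, frames]), rep(expected[ib], 2))
  }
  # outside the cord: silence
  expect_true(all(flat[tr$geometry$labels == 0L, ] == 0))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  spec <- phantom_spec(n_subjects = 1L, grid = c(12L, 12L, 3L),
                       n_repetitions = 3L, seed = 5L)
  tr1 <- sample_ground_truth(spec)
  tr2 <- sample_ground_truth(spec)
  expect_identical(tr1$params, tr2$params)
  d1 <- simulate_acquisition(spec, tr1, 1, 2)
  d2 <- simulate_acquisition(spec, tr2, 1, 2)
  expect_identical(d1$volumes, d2$volumes)
})

test_that("repetition-averaged b0 SNR scales as sqrt(Nrep)", {
  spec <- phantom_spec(n_subjects = 1L, grid = c(14L, 14L, 3L),
                       n_repetitions = 20L, snr_single_rep = 27,
                       seed = 23L)
  tr <- sample_ground_truth(spec)
  ds <- simulate_acquisition(spec, tr, 1, 1)
  snr <- compute_snr_map(ds, tr$geometry$cord)
  # single-rep SNR 27 and 20 repetitions: 27 * sqrt(20) = 120.75, up to
  # sampling error of the 20-repetition SD estimate
  expect_gt(snr$summary[["mean"]], 109)
  expect_lt(snr$summary[["mean"]], 133)
  expect_equal(snr$n_excluded, 0)
})

test_that("Rician magnitude bias matches the analytic mean", {
  # direct Monte-Carlo check of the closed form
  nu <- 0.1; sigma <- 0.05
  set.seed(41)
  draws <- sqrt((nu + rnorm(4e4, 0, sigma))^2 + rnorm(4e4, 0, sigma)^2)
  expect_equal(mean(draws), rician_mean(nu, sigma), tolerance = 0.01)
  expect_gt(rician_mean(nu, sigma), nu)  # positive floor bias
  # and inside the simulator at low SNR and the highest b-value
  spec <- phantom_spec(n_subjects = 1L, grid = c(12L, 12L, 3L),
                       n_repetitions = 50L, snr_single_rep = 5,
                       seed = 31L)
  tr <- sample_ground_truth(spec)
  ds <- simulate_acquisition(spec, tr, 1, 1)
  wm_rows <- tr$params[tr$params$subject == 1 & tr$params$session == 1 &
                         tr$params$tissue == "wm", ]
  clean <- forward_signal(
    ivim_params(wm_rows$S0, wm_rows$F, wm_rows$Dstar,
                wm_rows$D * spec$anisotropy[1]), spec$scheme)$values
  vox <- which(tr$geometry$labels == 1L)
  frames <- ds$btable$frame[ds$btable$b == 650]
  flat <- matrix(ds$volumes[[1]], prod(spec$grid), nrow(ds$btable))
  obs <- mean(flat[vox, frames])
  expect_gt(obs, clean[14])  # magnitude bias lifts the mean
  expect_equal(obs, rician_mean(clean[14], 1 / 5), tolerance = 0.02)
})

test_that("simulate_dataset materializes all acquisitions consistently", {
  spec <- null_phantom_spec(n_subjects = 2L)
  sim <- simulate_dataset(spec)
  expect_length(sim$datasets, 2)
  expect_length(sim$datasets[[1]], 2)
  one <- simulate_acquisition(spec, sim$truth, 2, 1)
  expect_identical(sim$datasets[[2]][[1]]$volumes, one$volumes)
  expect_error(phantom_spec(snr_single_rep = -3), "invalid-spec")
})
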