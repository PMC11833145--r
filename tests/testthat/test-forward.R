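k39_muscle <- relax_params(15, c(0.6, 0.4), c(1.2, 8.1))

test_that("relaxation weight has the closed form and correct limits", {
  acq <- acq_params("K39", tr_ms = 40, te_ms = 0.4,
                    nominal_resolution_mm = c(8, 8, 32))
  # independent scalar arithmetic, written out
  expected <- (1 - exp(-40 / 15)) *
    (0.6 * exp(-0.4 / 1.2) + 0.4 * exp(-0.4 / 8.1))
  expect_equal(relaxation_weight(k39_muscle, acq), expected, tolerance = 1e-12)

  # TE = 0 and TR >> T1: full recovery, no decay
  acq0 <- acq_params("K39", tr_ms = 1e6, te_ms = 0,
                     nominal_resolution_mm = c(8, 8, 32))
  expect_equal(relaxation_weight(k39_muscle, acq0), 1, tolerance = 1e-12)
})

test_that("relaxation weight strictly decreases with TE", {
  tes <- c(0, 0.2, 0.4, 1, 2, 5)
  ws <- vapply(tes, function(te) {
    relaxation_weight(k39_muscle,
                      acq_params("K39", tr_ms = 40, te_ms = te,
                                 nominal_resolution_mm = c(8, 8, 32)))
  }, numeric(1))
  expect_true(all(diff(ws) < 0))
})

test_that("full-support unapodized kernel is a discrete delta", {
  acq <- acq_params("Na23", tr_ms = 120, te_ms = 0.3,
                    nominal_resolution_mm = c(2, 2, 2), hamming = FALSE)
  kern <- psf_kernel(acq, c(12, 12, 8), c(2, 2, 2))
  img <- kernel_image(kern)
  ctr <- floor(c(12, 12, 8) / 2) + 1
  expect_equal(img[ctr[1], ctr[2], ctr[3]], 1, tolerance = 1e-10)
  expect_lt(max(abs(img)[-((ctr[3] - 1) * 144 + (ctr[2] - 1) * 12 + ctr[1])]),
            1e-10)
})

test_that("kernels preserve DC: they sum to one", {
  for (res in list(c(8, 8, 32), c(2.5, 2.5, 15))) {
    acq <- acq_params("K39", tr_ms = 40, te_ms = 0.4,
                      nominal_resolution_mm = res)
    kern <- psf_kernel(acq, c(32, 40, 20), c(2, 2, 2))
    expect_equal(sum(kernel_image(kern)), 1, tolerance = 1e-10)
  }
})

test_that("potassium kernel width tracks the anisotropic nominal resolution", {
  kern <- psf_kernel(acq_preset("k39_da3drad"), c(64, 64, 128), c(2, 2, 2))
  fw <- kernel_fwhm(kern)
  expect_true(all(fw >= c(8, 8, 32)))
  expect_equal(fw[3] / fw[1], 32 / 8, tolerance = 0.05)
})

test_that("a too-coarse simulation grid is rejected", {
  expect_error(psf_kernel(acq_preset("na23_da3drad"), c(16, 16, 16),
                          c(4, 4, 4)), "finer")
})

test_that("noiseless simulation with a delta kernel is truth times weight", {
  spec <- tiny_two_region_spec()
  lm <- build_label_map(spec)
  gt <- ground_truth_maps(spec, lm)
  acq <- acq_params("K39", tr_ms = 40, te_ms = 0.4,
                    nominal_resolution_mm = c(2, 2, 4), hamming = FALSE)
  relax <- default_relaxation_table(spec)
  sim <- simulate_acquisition(gt$k, lm, spec, acq, relax)
  w <- relaxation_weight(relax$relax[[which(relax$name == "A" &
                                              relax$nucleus == "K39")]], acq)
  expect_equal(as.numeric(sim), as.numeric(gt$k) * w, tolerance = 1e-10)
})

test_that("the noiseless forward model is linear", {
  spec <- tiny_two_region_spec()
  lm <- build_label_map(spec)
  gt <- ground_truth_maps(spec, lm)
  acq <- acq_params("K39", tr_ms = 40, te_ms = 0.4,
                    nominal_resolution_mm = c(8, 8, 8))
  relax <- default_relaxation_table(spec)
  x <- gt$k
  y <- image_volume(array(as.numeric(gt$na), dim(x)), voxel_size(x))
  lin <- image_volume(array(2 * as.numeric(x) + 3 * as.numeric(y), dim(x)),
                      voxel_size(x))
  sim_lin <- simulate_acquisition(lin, lm, spec, acq, relax)
  sim_x <- simulate_acquisition(x, lm, spec, acq, relax)
  sim_y <- simulate_acquisition(y, lm, spec, acq, relax)
  expect_equal(as.numeric(sim_lin),
               2 * as.numeric(sim_x) + 3 * as.numeric(sim_y),
               tolerance = 1e-10)
})

test_that("simulation is reproducible for a fixed seed", {
  spec <- tiny_two_region_spec()
  lm <- build_label_map(spec)
  gt <- ground_truth_maps(spec, lm)
  acq <- acq_params("K39", tr_ms = 40, te_ms = 0.4,
                    nominal_resolution_mm = c(8, 8, 8))
  a <- simulate_acquisition(gt$k, lm, spec, acq, noise_sigma = 2, seed = 42)
  b <- simulate_acquisition(gt$k, lm, spec, acq, noise_sigma = 2, seed = 42)
  c_ <- simulate_acquisition(gt$k, lm, spec, acq, noise_sigma = 2, seed = 43)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_false(identical(as.numeric(a), as.numeric(c_)))
  expect_error(simulate_acquisition(gt$k, lm, spec, acq, noise_sigma = -1),
               "sigma")
})

test_that("background of a noisy empty image sits at the Rician floor", {
  n <- c(24, 24, 24)                    # > 1e4 voxels
  spec <- phantom_spec(n, c(2, 2, 2),
                       region_spec("A", 1L, 0, 0,
                                   geometry = cylinder(c(0, 0, 0), 4, 8)))
  lm <- build_label_map(spec)
  zero <- image_volume(array(0, n), c(2, 2, 2))
  acq <- acq_params("K39", tr_ms = 40, te_ms = 0.4,
                    nominal_resolution_mm = c(8, 8, 8))
  sim <- simulate_acquisition(zero, lm, spec, acq, noise_sigma = 1, seed = 3)
  expect_equal(mean(sim), sqrt(pi / 2), tolerance = 0.05)
})

test_that("acquisition presets reproduce the protocol table", {
  na <- acq_preset("na23_da3drad")
  expect_equal(c(na$tr_ms, na$te_ms), c(120, 0.3))
  expect_equal(na$nominal_resolution_mm, c(2.5, 2.5, 15))
  expect_equal(na$n_projections, 5384L)
  k <- acq_preset("k39_da3drad")
  expect_equal(c(k$tr_ms, k$te_ms), c(40, 0.4))
  expect_equal(k$nominal_resolution_mm, c(8, 8, 32))
  expect_equal(k$n_projections, 2960L)
  mese <- acq_preset("h1_mese")
  expect_equal(c(mese$esp_ms, mese$etl, mese$tr_ms), c(9.5, 32, 3000))
})
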