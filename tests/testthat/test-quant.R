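k39_acq_iso <- function(res = c(8, 8, 8)) {
  acq_params("K39", tr_ms = 40, te_ms = 0.4, nominal_resolution_mm = res)
}

test_that("region means equal direct summation, uniform and single-voxel cases", {
  spec <- tiny_two_region_spec()
  lm <- build_label_map(spec)
  gt <- ground_truth_maps(spec, lm)
  blur <- convolve_kernel(gt$k, psf_kernel(k39_acq_iso(), dim(lm),
                                           voxel_size(lm)))
  rm_ <- region_means(blur, lm)
  for (id in rm_$label_id) {
    expect_equal(rm_$mean[rm_$label_id == id],
                 sum(blur[lm == id]) / sum(lm == id), tolerance = 1e-12)
  }
  # uniform volume: every mean equals the constant
  unif <- image_volume(array(3.5, dim(lm)), voxel_size(lm))
  expect_true(all(abs(region_means(unif, lm)$mean - 3.5) < 1e-12))
  expect_error(region_means(blur, lm, expected_ids = c(1L, 9L)), "9")
})

test_that("a delta kernel gives the identity mixing matrix", {
  spec <- tiny_two_region_spec()
  lm <- build_label_map(spec)
  acq <- acq_params("K39", tr_ms = 40, te_ms = 0.4,
                    nominal_resolution_mm = voxel_size(lm), hamming = FALSE)
  M <- build_mixing_matrix(lm, psf_kernel(acq, dim(lm), voxel_size(lm)))
  expect_equal(M$M, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("mixing-matrix rows sum to one for any kernel", {
  spec <- tiny_two_region_spec()
  lm <- build_label_map(spec)
  M <- build_mixing_matrix(lm, psf_kernel(k39_acq_iso(), dim(lm),
                                          voxel_size(lm)))
  expect_true(all(abs(rowSums(M$M) - 1) < 1e-6))
  expect_true(all(M$M >= -1e-9 & M$M <= 1 + 1e-9))
})

test_that("a 1D three-region boxcar matches the brute-force convolution", {
  lab <- array(rep(c(1L, 2L, 3L), each = 4), c(12, 1, 1))
  lm <- image_volume(lab, c(1, 1, 1))
  # hand-built spatial boxcar (-1, 0, +1)/3 along x as a kernel object
  sk <- array(0, c(12, 1, 1)); sk[1] <- sk[2] <- sk[12] <- 1 / 3
  kern <- structure(list(transfer = fft(sk), grid_shape = c(12L, 1L, 1L),
                         voxel_size_mm = c(1, 1, 1), hamming = FALSE,
                         nominal_resolution_mm = c(3, 1, 1)),
                    class = "psf_kernel")
  M <- build_mixing_matrix(lm, kern)
  for (j in 1:3) {
    ind <- array(as.numeric(lab == j), c(12, 1, 1))
    blur <- brute_circ_conv(ind, list(x = c(0, 1, -1), y = c(0, 0, 0),
                                      z = c(0, 0, 0), w = rep(1 / 3, 3)))
    for (i in 1:3) {
      expect_equal(M$M[i, j], mean(blur[lab == i]), tolerance = 1e-12)
    }
  }
})

test_that("PVC with the identity matrix returns the input", {
  M <- structure(list(M = diag(3), label_ids = c(0L, 1L, 2L),
                      condition_number = 1), class = "mixing_matrix")
  out <- pvc_solve(c(0, 5, 7), M, known = c("0" = 0))
  expect_equal(out$corrected, c(0, 5, 7))
})

test_that("PVC inverts the noiseless forward model to machine precision", {
  spec <- tiny_two_region_spec()
  lm <- build_label_map(spec)
  gt <- ground_truth_maps(spec, lm)
  acq <- k39_acq_iso()
  relax <- default_relaxation_table(spec)
  sim <- simulate_acquisition(gt$k, lm, spec, acq, relax)
  kern <- psf_kernel(acq, dim(lm), voxel_size(lm))
  M <- build_mixing_matrix(lm, kern)
  out <- pvc_solve(region_means(sim, lm), M, known = c("0" = 0))
  # truth: region intensity = apparent concentration x relaxation weight
  for (nm in c("A", "B")) {
    id <- spec$regions$label_id[spec$regions$name == nm]
    w <- relaxation_weight(
      relax$relax[[which(relax$name == nm & relax$nucleus == "K39")]], acq)
    truth <- spec$regions$k_mM[spec$regions$name == nm] * w
    expect_lt(abs(out$corrected[out$label_id == id] - truth),
              1e-8 * max(truth, 1))
  }
})

test_that("a rank-deficient mixing matrix is an error", {
  Md <- matrix(c(1, 0, 0, 0, 0.5, 0.5, 0, 0.5, 0.5), 3, byrow = TRUE)
  M <- structure(list(M = Md, label_ids = c(0L, 1L, 2L),
                      condition_number = Inf), class = "mixing_matrix")
  expect_error(pvc_solve(c(0, 1, 1), M, known = c("0" = 0)), "rank deficient")
})

test_that("relaxation correction inverts the forward weighting", {
  acq <- k39_acq_iso()
  relax <- relax_params(15, c(0.6, 0.4), c(1.2, 8.1))
  w <- relaxation_weight(relax, acq)
  expect_equal(relaxation_correct(120 * w, relax, acq), 120,
               tolerance = 1e-12)
  # TE = 0, TR >> T1: identity
  acq0 <- acq_params("K39", tr_ms = 1e7, te_ms = 0,
                     nominal_resolution_mm = c(8, 8, 8))
  expect_equal(relaxation_correct(3.7, relax, acq0), 3.7, tolerance = 1e-9)
})

test_that("mismatched correction constants bias by the analytic weight ratio", {
  acq <- k39_acq_iso()
  biexp <- relax_params(15, c(0.6, 0.4), c(1.2, 8.1))
  mono_long <- relax_params(15, 1, 8.1)
  w_b <- (1 - exp(-40 / 15)) * (0.6 * exp(-0.4 / 1.2) + 0.4 * exp(-0.4 / 8.1))
  w_m <- (1 - exp(-40 / 15)) * exp(-0.4 / 8.1)
  corrected <- relaxation_correct(100 * w_b, mono_long, acq)
  expect_equal(corrected / 100, w_b / w_m, tolerance = 1e-12)
})

test_that("calibration on noiseless references is exact and invertible", {
  conc <- c(240, 210, 180, 150, 120)
  slope <- 0.0123; intercept <- 0.4
  cal <- calibrate(slope * conc + intercept, conc, nucleus = "K39")
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(apply_calibration(cal, slope * conc + intercept), conc,
               tolerance = 1e-8)
  # two points define the exact interpolating line
  cal2 <- calibrate(c(1, 3), c(10, 30))
  expect_equal(c(cal2$slope, cal2$intercept), c(0.1, 0), tolerance = 1e-12)
  # degenerate: equal intensities at distinct concentrations
  cal0 <- calibrate(rep(2, 5), conc)
  expect_error(apply_calibration(cal0, 1), "slope")
  expect_error(calibrate(c(1, 2), c(10, 10)), "distinct")
})

test_that("fat correction reproduces its closed-form values", {
  expect_equal(fat_correct(20, 0.5, 7.9), (20 - 3.95) / 0.5)   # 32.1
  expect_equal(fat_correct(20, 0.5, 7.9), 32.1)
  expect_equal(fat_correct(40, 0.5, 0), 80)                    # potassium
  expect_equal(fat_correct(13, 0, 7.9), 13)                    # ff = 0
  for (ff in c(0, 0.2, 0.4, 0.59, 0.9)) {
    expect_equal(fat_correct(7.9, ff, 7.9), 7.9)               # fixed point
  }
  expect_error(fat_correct(10, 1, 7.9), "ff")
})

test_that("fat correction is monotone in value and (above c_fat) in ff", {
  vals <- seq(5, 50, by = 5)
  expect_true(all(diff(fat_correct(vals, 0.3, 7.9)) > 0))
  ffs <- seq(0, 0.55, by = 0.05)
  expect_true(all(diff(fat_correct(20, ffs, 7.9)) > 0))   # value > c_fat
  expect_true(all(diff(fat_correct(3, ffs, 7.9)) < 0))    # value < c_fat
})

test_that("muscle records apply exclusion and the potassium fc identity", {
  base <- tibble::tibble(name = c("GM", "GL"), label_id = 1:2,
                         conc_mM = c(20, 25))
  kc <- tibble::tibble(name = c("GM", "GL"), label_id = 1:2,
                       conc_mM = c(80, 60))
  ff_table <- tibble::tibble(name = c("GM", "GL"), ff = c(0.4, 0.65),
                             water_t2_ms = c(25, 26))
  rec <- muscle_records(base, kc, ff_table)
  gm <- rec[rec$muscle == "GM", ]
  gl <- rec[rec$muscle == "GL", ]
  expect_equal(gm$atpc_fc_mM, gm$atpc_mM / (1 - gm$ff))
  expect_equal(gm$atsc_fc_mM, (20 - 7.9 * 0.4) / 0.6)
  expect_true(gl$excluded)
  expect_true(is.na(gl$atsc_fc_mM) && is.na(gl$atpc_fc_mM) &&
                is.na(gl$water_t2_ms))
  expect_equal(as.character(gl$ff_group), "excluded")
})

test_that("doubling muscle concentrations doubles the quantified values", {
  spec <- leg_phantom_spec(voxel_size_mm = 4,
                           test_region = list(na_mM = 30, k_mM = 100, ff = 0))
  spec2 <- spec
  mus <- !grepl("^REF", spec2$regions$name)
  spec2$regions$k_mM[mus] <- 2 * spec2$regions$k_mM[mus]
  acq <- acq_preset("k39_da3drad")
  q <- lapply(list(spec, spec2), function(s) {
    lm <- build_label_map(s)
    gt <- ground_truth_maps(s, lm)
    sim <- simulate_acquisition(gt$k, lm, s, acq)
    quantify_regions(sim, lm, s, acq)
  })
  m1 <- q[[1]]$conc_mM[q[[1]]$name == "TEST"]
  m2 <- q[[2]]$conc_mM[q[[2]]$name == "TEST"]
  expect_equal(m2, 2 * m1, tolerance = 1e-6)
})
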