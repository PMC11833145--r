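test_that("an empty spec voxelizes to an all-background map", {
  spec <- phantom_spec(c(8, 8, 4), c(2, 2, 2),
                       tibble::tibble(name = character(), label_id = integer(),
                                      na_mM = numeric(), k_mM = numeric(),
                                      ff = numeric(), water_t2_ms = numeric(),
                                      geometry = list()))
  lm <- build_label_map(spec)
  expect_true(all(lm == 0L))
  expect_equal(voxel_size(lm), c(2, 2, 2))
})

test_that("cylinder voxel count approaches the analytic volume and converges", {
  rv2 <- region_volumes(
    phantom_spec(c(30, 30, 30), c(2, 2, 2),
                 region_spec("A", 1L, 10, 10,
                             geometry = cylinder(c(0, 0, 0), 20, 40))))
  expect_lt(abs(rv2$voxel_volume_mm3 / rv2$analytic_volume_mm3 - 1), 0.02)
  # convergence on a deliberately grid-misaligned cylinder (an aligned one
  # can hit identical discretization error at both resolutions)
  geom <- cylinder(c(0.7, -0.3, 0.2), 17.3, 40.6)
  mk <- function(vox) {
    phantom_spec(round(60 / vox) * c(1, 1, 1), rep(vox, 3),
                 region_spec("A", 1L, 10, 10, geometry = geom))
  }
  err <- vapply(c(2, 0.5), function(v) {
    rv <- region_volumes(mk(v))
    abs(rv$voxel_volume_mm3 / rv$analytic_volume_mm3 - 1)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.01)
})

test_that("the default leg spec yields exactly the expected label set", {
  lm <- build_label_map(leg_phantom_spec())
  expect_identical(sort(unique(as.integer(lm))), 0:13)
  spec <- leg_phantom_spec(test_region = list(na_mM = 40, k_mM = 240, ff = 0))
  expect_identical(sort(unique(as.integer(build_label_map(spec)))), 0:14)
})

test_that("later-listed regions overwrite earlier ones on overlap", {
  regions <- dplyr::bind_rows(
    region_spec("big", 1L, 10, 10, geometry = cylinder(c(0, 0, 0), 10, 16)),
    region_spec("small", 2L, 20, 20, geometry = cylinder(c(0, 0, 0), 4, 16)))
  lm <- build_label_map(phantom_spec(c(16, 16, 8), c(2, 2, 2), regions))
  expect_true(all(c(1L, 2L) %in% unique(as.integer(lm))))
  expect_identical(lm[9, 9, 4], 2L)    # centre voxel claimed by the insert
})

test_that("out-of-grid geometry errors and names the region", {
  spec <- phantom_spec(c(8, 8, 4), c(2, 2, 2),
                       region_spec("huge", 1L, 1, 1,
                                   geometry = cylinder(c(0, 0, 0), 30, 4)))
  expect_error(build_label_map(spec), "huge")
})

test_that("ground-truth maps apply linear fat mixing with pure limits", {
  regions <- dplyr::bind_rows(
    region_spec("muscle", 1L, na_mM = 20, k_mM = 100, ff = 0.5,
                geometry = cylinder(c(-6, 0, 0), 5, 8)),
    region_spec("pure", 2L, na_mM = 20, k_mM = 100, ff = 0,
                geometry = cylinder(c(7, 0, 0), 3, 8)),
    region_spec("fat", 3L, na_mM = 20, k_mM = 100, ff = 1,
                geometry = cylinder(c(0, 6, 0), 2, 8)))
  spec <- phantom_spec(c(16, 16, 4), c(2, 2, 2), regions)
  lm <- build_label_map(spec)
  gt <- ground_truth_maps(spec, lm)
  expect_equal(unique(gt$k[lm == 1L]), 50)        # (1-ff)*100 with c_fat = 0
  expect_equal(unique(gt$na[lm == 1L]), (1 - 0.5) * 20 + 0.5 * 7.9)
  expect_equal(unique(gt$na[lm == 2L]), 20)       # ff = 0: pure muscle
  expect_equal(unique(gt$na[lm == 3L]), 7.9)      # ff = 1: pure fat
  expect_true(all(gt$na[lm == 0L] == 0))
  expect_true(all(gt$k[lm == 0L] == 0))
})

test_that("ground-truth maps are linear in the tissue and fat concentrations", {
  spec <- tiny_two_region_spec()
  lm <- build_label_map(spec)
  g1 <- ground_truth_maps(spec, lm, c_fat_na_mM = 7.9)
  spec2 <- spec
  spec2$regions$na_mM <- 2 * spec2$regions$na_mM
  g2 <- ground_truth_maps(spec2, lm, c_fat_na_mM = 2 * 7.9)
  expect_equal(as.numeric(g2$na), 2 * as.numeric(g1$na), tolerance = 1e-12)
})

test_that("reference compartments carry the holder concentrations", {
  spec <- leg_phantom_spec()
  lm <- build_label_map(spec)
  gt <- ground_truth_maps(spec, lm)
  refs <- reference_concentrations()
  for (i in 1:5) {
    id <- spec$regions$label_id[spec$regions$name == refs$name[i]]
    expect_equal(unique(gt$k[lm == id]), refs$k_mM[i])
    expect_equal(unique(gt$na[lm == id]), refs$na_mM[i])
  }
})

test_that("patient phantoms draw reproducible per-muscle fat fractions", {
  a <- leg_phantom_spec(cohort = "patient", seed = 11)
  b <- leg_phantom_spec(cohort = "patient", seed = 11)
  c_ <- leg_phantom_spec(cohort = "patient", seed = 12)
  expect_identical(a$regions$ff, b$regions$ff)
  expect_false(identical(a$regions$ff, c_$regions$ff))
  mus <- a$regions$ff[a$regions$name %in%
                        c("GM", "GL", "SOL", "TA", "TP", "PER", "EDL")]
  expect_true(all(mus >= 0.02 & mus <= 0.75))
})
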