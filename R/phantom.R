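#' Region specifications
#'
#' One row per tissue region or reference compartment of a digital phantom.
#' Concentrations are the ion concentrations of the *tissue compartment*
#' (muscle or solution); apparent voxel concentrations arise from fat mixing
#' in [ground_truth_maps()]. Geometry is a parametric, axis-aligned solid:
#'
#' * `cylinder(center, radius, height)` — circular cylinder along z,
#' * `tube(center, r_inner, r_outer, height)` — annular cylinder,
#' * `wedge(center, r_inner, r_outer, theta0, theta1, height)` — angular
#'   sector of an annulus (angles in radians, counter-clockwise from +x).
#'
#' All lengths in mm; `center` is in physical coordinates with the grid
#' centre at the origin.
#'
#' @param name Region label, e.g. `"GM"`, `"FAT"`, `"REF1"`.
#' @param label_id Positive integer, unique within a spec.
#' @param na_mM,k_mM Sodium / potassium concentration of the compartment (mM).
#' @param ff Fat fraction in `[0, 1]` (reference compartments: 0).
#' @param water_t2_ms 1H water T2 of the compartment (ms); `NA` where
#'   meaningless (pure fat, solutions).
#' @param geometry A geometry list as above.
#' @return A one-row tibble; bind rows to build the `regions` table of a
#'   [phantom_spec()].
#' @examples
#' region_spec("REF1", 9L, na_mM = 10, k_mM = 240, ff = 0,
#'             geometry = cylinder(c(-52, -48, 0), 5.5, 64))
#' @export
region_spec <- function(name, label_id, na_mM, k_mM, ff = 0,
                        water_t2_ms = NA_real_, geometry = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  label_id <- as.integer(label_id)
  if (is.na(label_id) || label_id <= 0L) abort("`label_id` must be a positive integer.")
  if (!is.finite(na_mM) || na_mM < 0) abort("`na_mM` must be >= 0.")
  if (!is.finite(k_mM) || k_mM < 0) abort("`k_mM` must be >= 0.")
  if (!is.finite(ff) || ff < 0 || ff > 1) abort("`ff` must lie in [0, 1].")
  if (is.null(geometry)) abort("`geometry` is required.")
  tibble::tibble(name = name, label_id = label_id, na_mM = na_mM, k_mM = k_mM,
                 ff = ff, water_t2_ms = water_t2_ms, geometry = list(geometry))
}

#' @rdname region_spec
#' @param center Length-3 centre (mm).
#' @param radius,r_inner,r_outer Radii (mm).
#' @param height Extent along z (mm).
#' @param theta0,theta1 Sector bounds (radians); the sector spans
#'   counter-clockwise from `theta0` to `theta1`.
#' @export
cylinder <- function(center, radius, height) {
  list(type = "cylinder", center = as.numeric(center),
       radius = as.numeric(radius), height = as.numeric(height))
}

#' @rdname region_spec
#' @export
tube <- function(center, r_inner, r_outer, height) {
  list(type = "tube", center = as.numeric(center),
       r_inner = as.numeric(r_inner), r_outer = as.numeric(r_outer),
       height = as.numeric(height))
}

#' @rdname region_spec
#' @export
wedge <- function(center, r_inner, r_outer, theta0, theta1, height) {
  list(type = "wedge", center = as.numeric(center),
       r_inner = as.numeric(r_inner), r_outer = as.numeric(r_outer),
       theta0 = as.numeric(theta0), theta1 = as.numeric(theta1),
       height = as.numeric(height))
}

#' Phantom specification
#'
#' Bundles the grid geometry with an ordered region table. On overlap,
#' later-listed regions overwrite earlier ones, so list from outside in
#' (leg, fat annulus, muscles, references, test inserts).
#'
#' @param grid_shape Integer triple, voxels per axis.
#' @param voxel_size_mm Positive triple (mm).
#' @param regions Tibble of [region_spec()] rows.
#' @param seed Integer recorded with the spec (used by stochastic variants).
#' @return A `phantom_spec` object.
#' @seealso [leg_phantom_spec()] for the default lower-leg phantom.
#' @export
phantom_spec <- function(grid_shape, voxel_size_mm, regions, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (nrow(regions) > 0 && anyDuplicated(regions$label_id)) {
    abort("region label_ids must be unique within a spec")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 regions = regions, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> grid ", paste(x$grid_shape, collapse = "x"),
      " @ ", paste(x$voxel_size_mm, collapse = "x"), " mm, ",
      nrow(x$regions), " regions\n", sep = "")
  print(x$regions, n = 5)
  invisible(x)
}

# per-muscle healthy apparent-concentration defaults (mM) and water T2 (ms);
# sodium/potassium values follow healthy-control muscle medians, water T2 ~25 ms
muscle_defaults <- function() {
  tibble::tribble(
    ~name, ~na_mM, ~k_mM, ~water_t2_ms,
    "GM",  21.2,  84.7, 26,
    "GL",  19.7,  65.7, 27,
    "SOL", 16.8, 100.1, 25,
    "TA",  13.0,  93.8, 25,
    "TP",  15.0,  79.1, 25,
    "PER", 15.7,  82.8, 26,
    "EDL", 13.5,  71.2, 25
  )
}

#' Reference compartment concentrations
#'
#' The five NaCl/K2HPO4 solution compartments of the external reference
#' holder, `[Na+]/[K+]` = 10/240, 20/210, 25/180, 30/150, 40/120 mM, in
#' listing order REF1..REF5.
#'
#' @return Tibble with columns `name`, `na_mM`, `k_mM`.
#' @export
reference_concentrations <- function() {
  tibble::tibble(name = paste0("REF", 1:5),
                 na_mM = c(10, 20, 25, 30, 40),
                 k_mM = c(240, 210, 180, 150, 120))
}

#' Default digital lower-leg phantom
#'
#' A calf cross-section built from analytic solids: an outer subcutaneous-fat
#' annulus, seven muscle regions (GM, GL, SOL, TA, TP, PER, EDL) as angular
#' wedges of the inner disk, and the five-compartment reference holder as
#' small tubes below the leg. The `"healthy"` cohort uses low fat fractions
#' and healthy-muscle concentrations; the `"patient"` cohort draws per-muscle
#' fat fractions from `ff_range` (seeded) and mixes concentrations
#' accordingly in [ground_truth_maps()].
#'
#' @param voxel_size_mm Isotropic ground-truth voxel size (mm); default 2.
#' @param grid_shape Voxels per axis; default covers a 128 x 160 x 80 mm
#'   field of view at the default voxel size.
#' @param cohort `"healthy"` or `"patient"`.
#' @param ff_range Patient per-muscle fat-fraction range (uniform draw).
#' @param healthy_ff Fat fraction given to healthy muscle (small, nonzero).
#' @param ref_radius_mm,ref_height_mm Reference tube geometry (not fixed by
#'   the holder's published description; exposed as configuration).
#' @param test_region Optional list `(na_mM, k_mM, ff)`: appends a cylindrical
#'   `TEST` region (radius 9 mm) inside the calf, overwriting muscle — used
#'   for recovery experiments against known concentrations.
#' @param seed Seed for the patient fat-fraction draw.
#' @return A [phantom_spec()].
#' @examples
#' spec <- leg_phantom_spec()
#' spec$regions$name
#' @export
leg_phantom_spec <- function(voxel_size_mm = 2,
                             grid_shape = NULL,
                             cohort = c("healthy", "patient"),
                             ff_range = c(0.02, 0.75),
                             healthy_ff = 0.04,
                             ref_radius_mm = 5.5,
                             ref_height_mm = 64,
                             test_region = NULL,
                             seed = 1L) {
  cohort <- match.arg(cohort)
  voxel_size_mm <- rep(as.numeric(voxel_size_mm), length.out = 3)
  if (is.null(grid_shape)) {
    grid_shape <- round(c(128, 160, 80) / voxel_size_mm)
  }
  mus <- muscle_defaults()
  if (cohort == "patient") {
    set.seed(as.integer(seed))
    ffs <- runif(nrow(mus), ff_range[1], ff_range[2])
  } else {
    ffs <- rep(healthy_ff, nrow(mus))
  }
  leg_c <- c(0, 20, 0)          # calf centre sits above the reference holder
  r_leg <- 42; r_mus <- 35; h <- 64
  ang <- seq(0, 2 * pi, length.out = nrow(mus) + 1)
  rows <- list(
    region_spec("FAT", 8L, na_mM = 7.9, k_mM = 0, ff = 1,
                geometry = tube(leg_c, r_mus, r_leg, h))
  )
  for (i in seq_len(nrow(mus))) {
    rows[[length(rows) + 1L]] <- region_spec(
      mus$name[i], i, na_mM = mus$na_mM[i], k_mM = mus$k_mM[i],
      ff = ffs[i], water_t2_ms = mus$water_t2_ms[i],
      geometry = wedge(leg_c, 0, r_mus, ang[i], ang[i + 1], h))
  }
  refs <- reference_concentrations()
  ref_x <- seq(-52, 52, length.out = 5)
  for (i in 1:5) {
    rows[[length(rows) + 1L]] <- region_spec(
      refs$name[i], 8L + i, na_mM = refs$na_mM[i], k_mM = refs$k_mM[i],
      ff = 0, geometry = cylinder(c(ref_x[i], -48, 0), ref_radius_mm,
                                  ref_height_mm))
  }
  if (!is.null(test_region)) {
    rows[[length(rows) + 1L]] <- region_spec(
      "TEST", 14L,
      na_mM = test_region$na_mM, k_mM = test_region$k_mM,
      ff = test_region$ff %||% 0,
      water_t2_ms = test_region$water_t2_ms %||% 25,
      geometry = cylinder(leg_c + c(0, 10, 0), 9, h))
  }
  phantom_spec(grid_shape, voxel_size_mm, dplyr::bind_rows(rows), seed = seed)
}

# logical mask of a geometry on the voxel-centre grid
geometry_mask <- function(geom, coords) {
  x <- coords[[1]]; y <- coords[[2]]; z <- coords[[3]]
  cx <- geom$center[1]; cy <- geom$center[2]; cz <- geom$center[3]
  nx <- length(x); ny <- length(y); nz <- length(z)
  r2 <- outer((x - cx)^2, (y - cy)^2, "+")        # nx x ny squared radius
  inz <- abs(z - cz) <= geom$height / 2
  plane <- switch(geom$type,
    cylinder = r2 <= geom$radius^2,
    tube = r2 >= geom$r_inner^2 & r2 <= geom$r_outer^2,
    wedge = {
      th <- atan2(rep(y - cy, each = nx), rep(x - cx, times = ny))
      dth <- (th - geom$theta0) %% (2 * pi)
      span <- (geom$theta1 - geom$theta0) %% (2 * pi)
      if (span == 0) span <- 2 * pi
      dim(th) <- c(nx, ny)
      r2 >= geom$r_inner^2 & r2 <= geom$r_outer^2 & (dth < span)
    },
    abort(paste0("unknown geometry type: ", geom$type))
  )
  array(plane, c(nx, ny, nz)) & rep(inz, each = nx * ny)
}

# physical bounding box of a geometry, used to validate containment
geometry_extent <- function(geom) {
  r <- switch(geom$type, cylinder = geom$radius, geom$r_outer)
  rbind(geom$center - c(r, r, geom$height / 2),
        geom$center + c(r, r, geom$height / 2))
}

#' Voxelize a phantom specification into a label map
#'
#' Deterministic voxelization by the voxel-centre-in-solid rule. Regions are
#' painted in listing order, so later regions overwrite earlier ones on
#' overlap. Unclaimed voxels keep the background label 0.
#'
#' @param spec A [phantom_spec()].
#' @return A `label_map`: integer [image_volume()] of label ids.
#' @examples
#' lm <- build_label_map(leg_phantom_spec(voxel_size_mm = 4))
#' table(lm)[1:3]
#' @export
build_label_map <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  coords <- grid_coords(spec$grid_shape, spec$voxel_size_mm)
  half <- spec$grid_shape * spec$voxel_size_mm / 2
  labels <- array(0L, spec$grid_shape)
  for (i in seq_len(nrow(spec$regions))) {
    geom <- spec$regions$geometry[[i]]
    ext <- geometry_extent(geom)
    if (any(ext[1, ] < -half - 1e-9) || any(ext[2, ] > half + 1e-9)) {
      abort(paste0("geometry of region '", spec$regions$name[i],
                   "' extends outside the grid"))
    }
    m <- geometry_mask(geom, coords)
    labels[m] <- spec$regions$label_id[i]
  }
  v <- image_volume(labels, spec$voxel_size_mm)
  class(v) <- c("label_map", class(v))
  v
}

#' Ground-truth concentration and fat-fraction maps
#'
#' Converts a label map into per-nucleus apparent-concentration maps and a
#' fat-fraction map. The apparent voxel concentration follows linear fat
#' mixing, `(1 - ff) * c_tissue + ff * c_fat`, with fat concentrations
#' defaulting to 7.9 mM sodium and 0 mM potassium. Background is 0.
#'
#' @param spec A [phantom_spec()].
#' @param labels Label map built from `spec` (built on the fly if omitted).
#' @param c_fat_na_mM,c_fat_k_mM Ion concentrations of fat tissue (mM).
#' @return List of [image_volume()]s: `na`, `k`, `ff`.
#' @examples
#' spec <- leg_phantom_spec(voxel_size_mm = 4)
#' gt <- ground_truth_maps(spec)
#' max(gt$k)   # potassium-richest reference compartment
#' @export
ground_truth_maps <- function(spec, labels = NULL,
                              c_fat_na_mM = 7.9, c_fat_k_mM = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(labels)) labels <- build_label_map(spec)
  reg <- spec$regions
  # lookup tables indexed by label id; background (0) -> slot 1
  maxid <- max(c(0L, reg$label_id))
  na_lut <- k_lut <- ff_lut <- numeric(maxid + 1L)
  na_lut[reg$label_id + 1L] <- (1 - reg$ff) * reg$na_mM + reg$ff * c_fat_na_mM
  k_lut[reg$label_id + 1L]  <- (1 - reg$ff) * reg$k_mM + reg$ff * c_fat_k_mM
  ff_lut[reg$label_id + 1L] <- reg$ff
  idx <- as.integer(labels) + 1L
  shape <- dim(labels)
  mk <- function(lut) image_volume(array(lut[idx], shape), voxel_size(labels))
  list(na = mk(na_lut), k = mk(k_lut), ff = mk(ff_lut))
}

#' Per-region voxel counts and analytic volumes
#'
#' @param spec A [phantom_spec()].
#' @param labels Label map built from `spec`.
#' @return Tibble with voxelized and analytic volumes (mm^3) per region.
#' @keywords internal
#' @export
region_volumes <- function(spec, labels = NULL) {
  if (is.null(labels)) labels <- build_label_map(spec)
  vox_mm3 <- prod(voxel_size(labels))
  tab <- table(factor(as.integer(labels), levels = spec$regions$label_id))
  analytic <- purrr::map_dbl(spec$regions$geometry, function(g) {
    switch(g$type,
      cylinder = pi * g$radius^2 * g$height,
      tube = pi * (g$r_outer^2 - g$r_inner^2) * g$height,
      wedge = {
        span <- (g$theta1 - g$theta0) %% (2 * pi)
        if (span == 0) span <- 2 * pi
        span / 2 * (g$r_outer^2 - g$r_inner^2) * g$height
      })
  })
  tibble::tibble(name = spec$regions$name, label_id = spec$regions$label_id,
                 n_voxels = as.integer(tab),
                 voxel_volume_mm3 = as.integer(tab) * vox_mm3,
                 analytic_volume_mm3 = analytic)
}
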