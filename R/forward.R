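#' Acquisition parameters
#'
#' Sequence settings of a density-adapted 3D radial X-nuclei acquisition (or
#' the 1H MESE, for completeness). Presets reproducing the study protocol are
#' available via [acq_preset()].
#'
#' @param nucleus `"Na23"`, `"K39"` or `"H1"`.
#' @param tr_ms,te_ms Repetition / echo time (ms); `tr_ms > te_ms >= 0`.
#' @param flip_deg Excitation flip angle (degrees).
#' @param nominal_resolution_mm Length-3 nominal voxel size (mm).
#' @param n_projections Number of radial spokes.
#' @param readout_duration_ms Readout window (ms).
#' @param out_voxel_mm Reconstruction voxel size (mm), default 1 mm isotropic.
#' @param hamming Apply Hamming apodization in k-space (default `TRUE`).
#' @return An `acq_params` list.
#' @export
acq_params <- function(nucleus = c("Na23", "K39", "H1"), tr_ms, te_ms,
                       flip_deg = 90, nominal_resolution_mm,
                       n_projections = NA_integer_,
                       readout_duration_ms = NA_real_,
                       out_voxel_mm = c(1, 1, 1), hamming = TRUE) {
  nucleus <- match.arg(nucleus)
  if (!(tr_ms > te_ms) || te_ms < 0) abort("need tr_ms > te_ms >= 0")
  nominal_resolution_mm <- rep(as.numeric(nominal_resolution_mm), length.out = 3)
  if (any(nominal_resolution_mm <= 0)) abort("resolutions must be positive")
  structure(list(nucleus = nucleus, tr_ms = tr_ms, te_ms = te_ms,
                 flip_deg = flip_deg,
                 nominal_resolution_mm = nominal_resolution_mm,
                 n_projections = as.integer(n_projections),
                 readout_duration_ms = readout_duration_ms,
                 out_voxel_mm = rep(as.numeric(out_voxel_mm), length.out = 3),
                 hamming = isTRUE(hamming)),
            class = "acq_params")
}

#' @rdname acq_params
#' @param name Preset name: `"na23_da3drad"`, `"k39_da3drad"` or `"h1_mese"`.
#'   Presets are stored as JSON under `inst/extdata/` and mirror the study's
#'   7 T protocol (sodium: TR 120 ms, TE 0.3 ms, 2.5 x 2.5 x 15 mm3, 5384
#'   spokes; potassium: TR 40 ms, TE 0.4 ms, 8 x 8 x 32 mm3, 2960 spokes).
#' @export
acq_preset <- function(name = c("na23_da3drad", "k39_da3drad", "h1_mese")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".json"), package = "ionmri",
                      mustWork = TRUE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(name, "h1_mese")) {
    return(mese_protocol(esp_ms = p$esp_ms, etl = p$etl,
                         exc_flip_deg = p$exc_flip_deg,
                         ref_flip_deg = p$ref_flip_deg, tr_ms = p$tr_ms))
  }
  acq_params(nucleus = p$nucleus, tr_ms = p$tr_ms, te_ms = p$te_ms,
             flip_deg = p$flip_deg,
             nominal_resolution_mm = p$nominal_resolution_mm,
             n_projections = p$n_projections,
             readout_duration_ms = p$readout_duration_ms,
             hamming = TRUE)
}

#' Relaxation parameters
#'
#' Longitudinal relaxation time plus a mono- or biexponential transverse
#' (T2*) decay, as appropriate for spin-3/2 nuclei: potassium in muscle
#' decays biexponentially with T2short* = 1.2 ms and T2long* = 8.1 ms, with
#' satellite/central-transition fractions defaulting to 0.6/0.4 elsewhere in
#' the package.
#'
#' @param t1_ms Longitudinal relaxation time (ms).
#' @param fractions Component fractions, non-negative, summing to 1.
#' @param t2star_ms Component T2* times (ms), same length as `fractions`.
#' @return A `relax_params` list.
#' @examples
#' relax_params(15, c(0.6, 0.4), c(1.2, 8.1))   # potassium in muscle
#' @export
relax_params <- function(t1_ms, fractions, t2star_ms) {
  fractions <- as.numeric(fractions); t2star_ms <- as.numeric(t2star_ms)
  if (t1_ms <= 0 || any(t2star_ms <= 0)) abort("relaxation times must be positive")
  if (length(fractions) != length(t2star_ms)) {
    abort("`fractions` and `t2star_ms` must have equal length")
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be non-negative and sum to 1")
  }
  structure(list(t1_ms = t1_ms, fractions = fractions, t2star_ms = t2star_ms),
            class = "relax_params")
}

#' Default relaxation constants per region and nucleus
#'
#' Muscle potassium T2* components are the measured biexponential pair
#' (1.2 / 8.1 ms); the remaining constants (T1 values, sodium muscle T2*,
#' solution relaxation) are literature-derived defaults and deliberately
#' configuration, not measurements: the quantification chain only requires
#' that the same constants be used for weighting and for correction.
#'
#' @param spec Optional [phantom_spec()]; rows are then emitted for exactly
#'   its regions (muscles and the TEST insert share muscle constants).
#' @return Tibble with columns `name`, `nucleus` and a `relax` list-column
#'   of [relax_params()].
#' @export
default_relaxation_table <- function(spec = NULL) {
  mk <- function(name, nucleus, relax) {
    tibble::tibble(name = name, nucleus = nucleus, relax = list(relax))
  }
  muscle_na  <- relax_params(30, c(0.6, 0.4), c(2.0, 13.0))
  muscle_k   <- relax_params(15, c(0.6, 0.4), c(1.2, 8.1))
  fat_na     <- relax_params(20, 1, 10)
  fat_k      <- relax_params(12, c(0.6, 0.4), c(1.2, 8.1))
  sol_na     <- relax_params(60, 1, 55)
  sol_k      <- relax_params(50, 1, 45)
  muscles <- muscle_defaults()$name
  names_all <- if (is.null(spec)) c(muscles, "TEST", "FAT", paste0("REF", 1:5))
               else spec$regions$name
  rows <- lapply(names_all, function(nm) {
    if (nm == "FAT") {
      dplyr::bind_rows(mk(nm, "Na23", fat_na), mk(nm, "K39", fat_k))
    } else if (grepl("^REF", nm)) {
      dplyr::bind_rows(mk(nm, "Na23", sol_na), mk(nm, "K39", sol_k))
    } else {
      dplyr::bind_rows(mk(nm, "Na23", muscle_na), mk(nm, "K39", muscle_k))
    }
  })
  dplyr::bind_rows(rows)
}

#' Relaxation weighting factor
#'
#' Signal attenuation of a 90-degree spoiled acquisition relative to full
#' relaxation: `w = (1 - exp(-TR/T1)) * sum_i f_i * exp(-TE/T2*_i)`, in
#' `(0, 1]`. The same factor scales the forward simulation and, inverted,
#' drives the relaxation-bias correction.
#'
#' @param relax A [relax_params()].
#' @param acq An [acq_params()].
#' @return Scalar weight in `(0, 1]`.
#' @examples
#' k_muscle <- relax_params(15, c(0.6, 0.4), c(1.2, 8.1))
#' relaxation_weight(k_muscle, acq_preset("k39_da3drad"))
#' @export
relaxation_weight <- function(relax, acq) {
  stopifnot(inherits(relax, "relax_params"), inherits(acq, "acq_params"))
  (1 - exp(-acq$tr_ms / relax$t1_ms)) *
    sum(relax$fractions * exp(-acq$te_ms / relax$t2star_ms))
}

#' Point-spread-function kernel of a coarse acquisition
#'
#' Models the acquisition + reconstruction chain (limited k-space extent set
#' by the nominal resolution, Hamming apodization against Gibbs ringing,
#' interpolation to the fine output grid) as a convolution kernel on the
#' simulation grid. The kernel is the inverse transform of a separable
#' k-space support window: per axis, frequencies up to
#' `1 / (2 * nominal_resolution)` are retained and (optionally) weighted by a
#' Hamming window. The transfer function is 1 at DC, so the kernel integrates
#' to 1.
#'
#' @param acq An [acq_params()].
#' @param grid_shape Integer triple of the simulation grid.
#' @param voxel_size_mm Simulation voxel size (mm); must be finer than or
#'   equal to the nominal resolution on every axis.
#' @return A `psf_kernel` holding the k-space transfer function (in FFT
#'   layout) plus grid metadata.
#' @export
psf_kernel <- function(acq, grid_shape, voxel_size_mm) {
  stopifnot(inherits(acq, "acq_params"))
  grid_shape <- as.integer(grid_shape)
  voxel_size_mm <- rep(as.numeric(voxel_size_mm), length.out = 3)
  if (any(acq$nominal_resolution_mm < voxel_size_mm - 1e-9)) {
    abort("nominal resolution is finer than the simulation grid voxel")
  }
  axes <- lapply(1:3, function(a) {
    n <- grid_shape[a]
    # FFT-layout frequencies in cycles/mm
    f <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1)) / (n * voxel_size_mm[a])
    fmax <- 1 / (2 * acq$nominal_resolution_mm[a])
    u <- f / fmax
    w <- as.numeric(abs(u) <= 1 + 1e-12)
    if (acq$hamming) w <- w * (0.54 + 0.46 * cos(pi * pmin(abs(u), 1)))
    w / w[1]                      # DC gain exactly 1
  })
  transfer <- outer(outer(axes[[1]], axes[[2]]), axes[[3]])
  structure(list(transfer = transfer, grid_shape = grid_shape,
                 voxel_size_mm = voxel_size_mm, hamming = acq$hamming,
                 nominal_resolution_mm = acq$nominal_resolution_mm),
            class = "psf_kernel")
}

#' @rdname psf_kernel
#' @param kernel A `psf_kernel`.
#' @param volume Numeric 3D array or [image_volume()] on the kernel's grid.
#' @return `convolve_kernel()`: the blurred volume (same class as input).
#' @export
convolve_kernel <- function(volume, kernel) {
  stopifnot(inherits(kernel, "psf_kernel"))
  if (!identical(dim(volume), kernel$grid_shape)) {
    abort("volume does not match the kernel grid")
  }
  out <- Re(fft(fft(array(as.numeric(volume), dim(volume))) * kernel$transfer,
                inverse = TRUE)) / length(volume)
  if (inherits(volume, "image_volume")) {
    out <- image_volume(out, voxel_size(volume))
  }
  out
}

#' @rdname psf_kernel
#' @return `kernel_image()`: the spatial kernel as an [image_volume()]
#'   centred in the grid, summing to 1.
#' @export
kernel_image <- function(kernel) {
  stopifnot(inherits(kernel, "psf_kernel"))
  k <- Re(fft(kernel$transfer, inverse = TRUE)) / prod(kernel$grid_shape)
  # rotate FFT layout so the peak sits at the grid centre voxel
  sh <- floor(kernel$grid_shape / 2)
  for (a in 1:3) {
    idx <- ((seq_len(kernel$grid_shape[a]) - 1 - sh[a]) %% kernel$grid_shape[a]) + 1
    k <- switch(a, k[idx, , , drop = FALSE], k[, idx, , drop = FALSE],
                k[, , idx, drop = FALSE])
  }
  image_volume(k, kernel$voxel_size_mm)
}

#' Full width at half maximum of the kernel along each axis
#'
#' Measured on the central 1D profiles of [kernel_image()] by linear
#' interpolation of the half-maximum crossings.
#'
#' @param kernel A `psf_kernel`.
#' @return Numeric length 3, FWHM in mm.
#' @export
kernel_fwhm <- function(kernel) {
  img <- kernel_image(kernel)
  ctr <- floor(kernel$grid_shape / 2) + 1
  vapply(1:3, function(a) {
    prof <- switch(a, img[, ctr[2], ctr[3]], img[ctr[1], , ctr[3]],
                   img[ctr[1], ctr[2], ])
    prof <- prof / max(prof)
    x <- (seq_along(prof) - ctr[a]) * kernel$voxel_size_mm[a]
    above <- prof >= 0.5
    i1 <- min(which(above)); i2 <- max(which(above))
    left <- if (i1 > 1) {
      x[i1 - 1] + (0.5 - prof[i1 - 1]) / (prof[i1] - prof[i1 - 1]) *
        (x[i1] - x[i1 - 1])
    } else x[i1]
    right <- if (i2 < length(prof)) {
      x[i2] + (0.5 - prof[i2]) / (prof[i2 + 1] - prof[i2]) *
        (x[i2 + 1] - x[i2])
    } else x[i2]
    right - left
  }, numeric(1))
}

# per-voxel relaxation-weight map from a label map and a relaxation table
weight_map <- function(labels, spec, relax_table, acq) {
  reg <- spec$regions
  tab <- dplyr::filter(relax_table, .data$nucleus == acq$nucleus)
  maxid <- max(c(0L, reg$label_id))
  lut <- numeric(maxid + 1L)      # background weight irrelevant (signal 0)
  for (i in seq_len(nrow(reg))) {
    row <- dplyr::filter(tab, .data$name == reg$name[i])
    if (nrow(row) == 0) {
      abort(paste0("no ", acq$nucleus, " relaxation entry for region '",
                   reg$name[i], "'"))
    }
    lut[reg$label_id[i] + 1L] <- relaxation_weight(row$relax[[1]], acq)
  }
  array(lut[as.integer(labels) + 1L], dim(labels))
}

#' Simulate a coarse-resolution X-nuclei acquisition
#'
#' Scales the ground-truth map voxel-wise by each region's relaxation weight,
#' blurs with the acquisition point-spread function, and adds Rician noise
#' (magnitude of the signal plus complex Gaussian noise of scale
#' `noise_sigma`). With `noise_sigma = 0` the output is the noiseless real
#' blurred volume. Reproducible given `seed`.
#'
#' @param truth Ground-truth apparent-concentration [image_volume()].
#' @param labels Label map on the same grid.
#' @param spec The [phantom_spec()] the labels came from.
#' @param acq An [acq_params()].
#' @param relax_table Relaxation table as from [default_relaxation_table()].
#' @param noise_sigma Complex Gaussian noise scale (signal units), `>= 0`.
#' @param seed Integer seed for the noise draw.
#' @param mode `"psf"` (kernel convolution) or `"kspace"` (radial sampling
#'   and gridding via [radial_sample_and_grid()]).
#' @return Simulated [image_volume()] on the truth grid.
#' @export
simulate_acquisition <- function(truth, labels, spec, acq,
                                 relax_table = default_relaxation_table(spec),
                                 noise_sigma = 0, seed = 1L,
                                 mode = c("psf", "kspace")) {
  mode <- match.arg(mode)
  check_same_grid(truth, labels, "truth and labels")
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    abort("`noise_sigma` must be >= 0")
  }
  w <- weight_map(labels, spec, relax_table, acq)
  weighted <- image_volume(as.array(truth) * w, voxel_size(truth))
  blurred <- if (mode == "psf") {
    kern <- psf_kernel(acq, dim(truth), voxel_size(truth))
    convolve_kernel(weighted, kern)
  } else {
    radial_sample_and_grid(weighted, acq, seed = seed)
  }
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    n <- length(blurred)
    mag <- sqrt((as.numeric(blurred) + rnorm(n, 0, noise_sigma))^2 +
                rnorm(n, 0, noise_sigma)^2)
    blurred <- image_volume(array(mag, dim(truth)), voxel_size(truth))
  }
  blurred
}
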