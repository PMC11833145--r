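#' Region mean signal intensities
#'
#' Arithmetic mean of a volume over each label of a segmentation, background
#' (label 0) included as its own row.
#'
#' @param volume An [image_volume()].
#' @param labels A label map on the same grid.
#' @param expected_ids Optional integer ids that must all be present and
#'   non-empty; a missing one raises an error naming the label.
#' @return Tibble with `label_id`, `n_voxels`, `mean`.
#' @export
region_means <- function(volume, labels, expected_ids = NULL) {
  check_same_grid(volume, labels, "volume and labels")
  ids <- sort(unique(as.integer(labels)))
  if (!is.null(expected_ids)) {
    missing <- setdiff(as.integer(expected_ids), ids)
    if (length(missing)) {
      abort(paste0("region label ", missing[1], " has no voxels"))
    }
  }
  f <- factor(as.integer(labels), levels = ids)
  tibble::tibble(label_id = ids,
                 n_voxels = as.integer(table(f)),
                 mean = as.numeric(tapply(as.numeric(volume), f, mean)))
}

#' Build the PSF mixing matrix of a segmentation
#'
#' Entry (i, j) is the mean, over the voxels of region i, of the kernel
#' convolved with the indicator of region j: the fraction of region i's
#' observed signal contributed by region j under the acquisition point
#' spread. Because the indicators partition the grid and the kernel
#' integrates to 1, each row sums to 1; background (label 0) is a full
#' row/column.
#'
#' @param labels A label map.
#' @param kernel A [psf_kernel()] on the same grid.
#' @return A `mixing_matrix`: list with the square matrix `M` (rows/cols in
#'   `label_ids` order), `label_ids`, and the matrix condition number.
#' @export
build_mixing_matrix <- function(labels, kernel) {
  stopifnot(inherits(kernel, "psf_kernel"))
  if (!identical(dim(labels), kernel$grid_shape)) {
    abort("labels do not match the kernel grid")
  }
  ids <- sort(unique(as.integer(labels)))
  lab <- as.integer(labels)
  f <- factor(lab, levels = ids)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    ind <- array(as.numeric(lab == ids[j]), dim(labels))
    blur <- convolve_kernel(ind, kernel)
    M[, j] <- as.numeric(tapply(as.numeric(blur), f, mean))
  }
  structure(list(M = M, label_ids = ids, condition_number = kappa(M)),
            class = "mixing_matrix")
}

#' Region-based partial volume correction
#'
#' Solves the linear mixing model `observed = M %*% true` for the true
#' (unblurred) region intensities by least squares. Entries of `known` (a
#' numeric vector named by label id, e.g. background `"0" = 0`) are held
#' fixed and their contribution moved to the data side; all rows still
#' constrain the solution. An ill-conditioned matrix triggers a warning and
#' a ridge-regularized solve, flagged in the output; a rank-deficient matrix
#' (e.g. duplicated regions) is an error.
#'
#' @param observed Region mean intensities in `M$label_ids` order, or a
#'   tibble from [region_means()].
#' @param M A [build_mixing_matrix()] result.
#' @param known Named numeric vector of fixed region intensities.
#' @param condition_threshold Condition number above which regularization
#'   kicks in.
#' @return Tibble `label_id`, `corrected`, `fixed` (logical), with attributes
#'   `condition_number` and `regularized`.
#' @export
pvc_solve <- function(observed, M, known = c("0" = 0),
                      condition_threshold = 1e8) {
  stopifnot(inherits(M, "mixing_matrix"))
  if (is.data.frame(observed)) {
    observed <- observed$mean[match(M$label_ids, observed$label_id)]
  }
  if (length(observed) != length(M$label_ids) || anyNA(observed)) {
    abort("`observed` must supply one mean per mixing-matrix region")
  }
  ids <- as.character(M$label_ids)
  known <- known[names(known) %in% ids]
  fixed <- ids %in% names(known)
  y <- observed
  A <- M$M
  if (any(fixed)) {
    y <- y - A[, fixed, drop = FALSE] %*% known[ids[fixed]]
    A <- A[, !fixed, drop = FALSE]
  }
  qa <- qr(A)
  if (qa$rank < ncol(A)) {
    abort("mixing matrix is rank deficient (duplicated or empty regions?)")
  }
  cn <- kappa(A)
  regularized <- FALSE
  if (cn > condition_threshold) {
    warn(paste0("mixing matrix condition number ", format(cn, digits = 3),
                " exceeds threshold; using ridge-regularized solve"))
    regularized <- TRUE
    lam <- 1e-8 * sum(diag(crossprod(A))) / ncol(A)
    x <- solve(crossprod(A) + lam * diag(ncol(A)), crossprod(A, y))
  } else {
    x <- qr.coef(qa, y)
  }
  corrected <- numeric(length(ids))
  corrected[fixed] <- known[ids[fixed]]
  corrected[!fixed] <- x
  out <- tibble::tibble(label_id = M$label_ids, corrected = corrected,
                        fixed = fixed)
  attr(out, "condition_number") <- cn
  attr(out, "regularized") <- regularized
  out
}

#' Relaxation-bias correction
#'
#' Inverts the acquisition's relaxation weighting: divides an intensity by
#' [relaxation_weight()] computed with the tissue- or solution-specific
#' constants. The exact inverse of the weighting applied in the forward
#' simulation when the same constants are used.
#'
#' @param intensity Numeric intensity (vectorized).
#' @param relax A [relax_params()].
#' @param acq An [acq_params()].
#' @return Corrected intensity.
#' @export
relaxation_correct <- function(intensity, relax, acq) {
  w <- relaxation_weight(relax, acq)
  if (!is.finite(w) || w < 1e-12) abort("relaxation weight underflow")
  intensity / w
}

#' Reference-phantom calibration
#'
#' Ordinary least-squares line through the relaxation-corrected intensities
#' of the external reference compartments against their known ion
#' concentrations, `intensity = slope * conc + intercept`. Fitted in this
#' direction because the measurement error lives in the intensities;
#' [apply_calibration()] inverts the line to map intensities to mM.
#'
#' @param ref_intensities Reference intensities (>= 2).
#' @param ref_concentrations_mM Known concentrations (mM), >= 2 distinct.
#' @param nucleus Label stored with the model.
#' @return A `calibration_model` with `slope`, `intercept`, `r_squared`.
#' @examples
#' cal <- calibrate(c(1.0, 2.1, 2.9), c(10, 20, 30))
#' apply_calibration(cal, 2.1)
#' @export
calibrate <- function(ref_intensities, ref_concentrations_mM,
                      nucleus = NA_character_) {
  x <- as.numeric(ref_concentrations_mM)
  y <- as.numeric(ref_intensities)
  if (length(x) != length(y) || length(unique(x)) < 2) {
    abort("calibration needs >= 2 references with distinct concentrations")
  }
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, nucleus = nucleus,
                 data = tibble::tibble(conc_mM = x, intensity = y)),
            class = "calibration_model")
}

#' @rdname calibrate
#' @param model A `calibration_model`.
#' @param intensity Intensities to convert (vectorized).
#' @return `apply_calibration()`: concentrations in mM.
#' @export
apply_calibration <- function(model, intensity) {
  stopifnot(inherits(model, "calibration_model"))
  scale <- max(abs(model$data$intensity), 1)
  if (!is.finite(model$slope) || abs(model$slope) < 1e-12 * scale ||
      model$slope < 0) {
    abort("calibration slope is non-positive or degenerate")
  }
  (intensity - model$intercept) / model$slope
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> ", x$nucleus, ": intensity = ",
      format(x$slope, digits = 4), " * conc + ",
      format(x$intercept, digits = 4), " (r^2 = ",
      format(x$r_squared, digits = 6), ")\n", sep = "")
  invisible(x)
}

#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, nucleus = x$nucleus,
                 n_refs = nrow(x$data))
}

#' @method autoplot calibration_model
#' @export
autoplot.calibration_model <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$conc_mM, y = .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "reference concentration (mM)", y = "intensity",
                  title = sprintf("%s calibration, r^2 = %.4f",
                                  object$nucleus %||% "", object$r_squared))
}

#' Fat correction of apparent tissue concentrations
#'
#' Rescales an apparent concentration to the remaining muscle tissue of a
#' partially fat-replaced region:
#' `value_fc = (value - c_fat * ff) / (1 - ff)`,
#' with fat concentrations of 7.9 mM for sodium and 0 mM for potassium, so
#' the potassium correction reduces to `aTPC / (1 - FF)`.
#'
#' @param value_mM Uncorrected apparent concentration (vectorized).
#' @param ff Fat fraction(s) in `[0, 1)`.
#' @param c_fat_mM Ion concentration of fat (mM).
#' @return Fat-corrected concentration (mM).
#' @examples
#' fat_correct(20, 0.5, 7.9)     # (20 - 3.95) / 0.5
#' fat_correct(40, 0.5, 0)       # potassium: 40 / 0.5
#' @export
fat_correct <- function(value_mM, ff, c_fat_mM = 7.9) {
  if (any(!is.finite(ff)) || any(ff < 0) || any(ff >= 1)) {
    abort("`ff` must lie in [0, 1); the correction is undefined at ff = 1")
  }
  (value_mM - c_fat_mM * ff) / (1 - ff)
}

# label-wise summary of a fat-fraction map: region median (or mean) FF
region_ff <- function(ff_map, labels, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  check_same_grid(ff_map, labels, "ff map and labels")
  ids <- sort(unique(as.integer(labels)))
  f <- factor(as.integer(labels), levels = ids)
  fun <- if (stat == "median") median else mean
  tibble::tibble(label_id = ids,
                 ff = as.numeric(tapply(as.numeric(ff_map), f, fun)))
}

#' Quantify region concentrations from one simulated acquisition
#'
#' The quantification chain for a single nucleus: region means over the
#' segmentation, region-based partial volume correction, relaxation-bias
#' correction with region-specific constants, and conversion to mM through
#' the five-compartment reference calibration.
#'
#' @param volume Simulated (or measured) [image_volume()].
#' @param labels Label map on the same grid.
#' @param spec The [phantom_spec()] describing regions (names, reference
#'   concentrations).
#' @param acq The [acq_params()] used for the acquisition.
#' @param relax_table Relaxation constants per region and nucleus.
#' @param background `"known_zero"` fixes the background intensity at 0 in
#'   the PVC; `"estimate"` solves for it jointly.
#' @return Tibble `name`, `label_id`, `conc_mM` with the fitted
#'   `calibration_model` and PVC diagnostics as attributes.
#' @export
quantify_regions <- function(volume, labels, spec, acq,
                             relax_table = default_relaxation_table(spec),
                             background = c("known_zero", "estimate")) {
  background <- match.arg(background)
  reg <- spec$regions
  rm_ <- region_means(volume, labels, expected_ids = reg$label_id)
  kern <- psf_kernel(acq, dim(volume), voxel_size(volume))
  M <- build_mixing_matrix(labels, kern)
  known <- if (background == "known_zero") c("0" = 0) else numeric(0)
  pvc <- pvc_solve(rm_, M, known = known)

  tab <- dplyr::filter(relax_table, .data$nucleus == acq$nucleus)
  out <- dplyr::inner_join(
    pvc, tibble::tibble(label_id = reg$label_id, name = reg$name),
    by = "label_id")
  out$corrected_relax <- vapply(seq_len(nrow(out)), function(i) {
    row <- dplyr::filter(tab, .data$name == out$name[i])
    relaxation_correct(out$corrected[i], row$relax[[1]], acq)
  }, numeric(1))

  is_ref <- grepl("^REF", out$name)
  if (sum(is_ref) < 2) abort("spec provides fewer than 2 reference compartments")
  conc_col <- if (acq$nucleus == "Na23") "na_mM" else "k_mM"
  ref_conc <- reg[[conc_col]][match(out$name[is_ref], reg$name)]
  cal <- calibrate(out$corrected_relax[is_ref], ref_conc, nucleus = acq$nucleus)
  res <- tibble::tibble(name = out$name, label_id = out$label_id,
                        conc_mM = apply_calibration(cal, out$corrected_relax))
  attr(res, "calibration") <- cal
  attr(res, "condition_number") <- attr(pvc, "condition_number")
  attr(res, "regularized") <- attr(pvc, "regularized")
  res
}

#' Assemble per-muscle records from both nuclei
#'
#' Joins the sodium and potassium quantifications with per-region fat
#' fraction and water T2, applies the fat correction using the region FF,
#' and flags regions whose FF exceeds the exclusion threshold: their water
#' T2 and fat-corrected values are reported as `NA` (the MESE fit and hence
#' the FF itself become unreliable there). Reference compartments,
#' subcutaneous fat and background are dropped; negative corrected
#' concentrations are kept as-is and flagged, never silently clamped.
#'
#' @param na_conc,k_conc Outputs of [quantify_regions()] for the two nuclei
#'   (either may be `NULL` to quantify a single nucleus).
#' @param ff_table Tibble `name`, `ff` and optionally `water_t2_ms`: measured
#'   region-median fat fractions (e.g. from [fit_mese_regions()] or
#'   [region_ff()] joined to names).
#' @param c_fat_na_mM,c_fat_k_mM Fat ion concentrations (mM).
#' @param exclusion_ff FF threshold above which fc values are withheld.
#' @param cohort `"patient"` or `"control"`, recorded per row and used for
#'   the FF group label.
#' @return Tibble of muscle records: `muscle`, `cohort`, `ff`,
#'   `water_t2_ms`, `atsc_mM`, `atpc_mM`, `atsc_fc_mM`, `atpc_fc_mM`,
#'   `ff_group`, `excluded`, `qc_negative`.
#' @export
muscle_records <- function(na_conc = NULL, k_conc = NULL, ff_table,
                           c_fat_na_mM = 7.9, c_fat_k_mM = 0,
                           exclusion_ff = 0.60,
                           cohort = c("patient", "control")) {
  cohort <- match.arg(cohort)
  if (is.null(na_conc) && is.null(k_conc)) abort("need at least one nucleus")
  base <- (na_conc %||% k_conc)[, "name"]
  keep <- !grepl("^REF", base$name) & base$name != "FAT"
  rec <- tibble::tibble(muscle = base$name[keep], cohort = cohort)
  grab <- function(tab) tab$conc_mM[match(rec$muscle, tab$name)]
  rec$atsc_mM <- if (!is.null(na_conc)) grab(na_conc) else NA_real_
  rec$atpc_mM <- if (!is.null(k_conc)) grab(k_conc) else NA_real_
  rec$ff <- ff_table$ff[match(rec$muscle, ff_table$name)]
  rec$water_t2_ms <- if ("water_t2_ms" %in% names(ff_table)) {
    ff_table$water_t2_ms[match(rec$muscle, ff_table$name)]
  } else NA_real_
  rec$excluded <- is.na(rec$ff) | rec$ff > exclusion_ff
  safe_fc <- function(v, ff, cf) {
    ifelse(is.na(v) | is.na(ff) | ff >= 1, NA_real_,
           (v - cf * ff) / (1 - ff))
  }
  rec$atsc_fc_mM <- ifelse(rec$excluded, NA_real_,
                           safe_fc(rec$atsc_mM, rec$ff, c_fat_na_mM))
  rec$atpc_fc_mM <- ifelse(rec$excluded, NA_real_,
                           safe_fc(rec$atpc_mM, rec$ff, c_fat_k_mM))
  rec$water_t2_ms[rec$excluded] <- NA_real_
  rec$ff_group <- assign_ff_group(rec$ff, cohort)
  rec$qc_negative <- (!is.na(rec$atsc_fc_mM) & rec$atsc_fc_mM < 0) |
    (!is.na(rec$atpc_fc_mM) & rec$atpc_fc_mM < 0)
  dplyr::select(rec, "muscle", "cohort", "ff", "water_t2_ms", "atsc_mM",
                "atpc_mM", "atsc_fc_mM", "atpc_fc_mM", "ff_group",
                "excluded", "qc_negative")
}
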