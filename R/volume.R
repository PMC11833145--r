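#' Image volumes
#'
#' A 3D scalar grid with voxel-size metadata: the common currency of the
#' simulation and quantification stages (ground-truth concentration maps,
#' simulated acquisitions, fat-fraction maps, label maps). Internally a plain
#' numeric (or integer, for labels) array with a `voxel_size_mm` attribute;
#' voxel indexing is 0-based in physical terms only through the voxel size —
#' phantoms are axis-aligned and no affine rotation is carried.
#'
#' @param data 3D numeric array.
#' @param voxel_size_mm Positive length-3 numeric, voxel edge lengths in mm.
#' @return An `image_volume`: the array with voxel-size metadata.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 2)), c(2, 2, 8))
#' voxel_size(v)
#' @export
image_volume <- function(data, voxel_size_mm) {
  if (length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    abort("`voxel_size_mm` must be 3 positive numbers.")
  }
  structure(data, voxel_size_mm = voxel_size_mm,
            class = c("image_volume", class(data)))
}

#' @rdname image_volume
#' @param x An `image_volume` or `label_map`.
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size_mm")
  if (is.null(vs)) abort("object carries no voxel size metadata")
  vs
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x), collapse = " x "),
      " voxels, ", paste(voxel_size(x), collapse = " x "), " mm\n", sep = "")
  cat("  range: [", format(min(x), digits = 4), ", ",
      format(max(x), digits = 4), "]\n", sep = "")
  invisible(x)
}

# voxel-centre physical coordinates along each axis, grid centred at 0 (mm)
grid_coords <- function(grid_shape, voxel_size_mm) {
  lapply(1:3, function(a) {
    n <- grid_shape[a]
    (seq_len(n) - (n + 1) / 2) * voxel_size_mm[a]
  })
}

# stop unless two volumes share grid shape and voxel size
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)) ||
      max(abs(voxel_size(a) - voxel_size(b))) > 1e-9) {
    abort(paste0(what, " must share grid shape and voxel size (got ",
                 paste(dim(a), collapse = "x"), " vs ",
                 paste(dim(b), collapse = "x"), ")"))
  }
  invisible(TRUE)
}
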