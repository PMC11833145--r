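#' Read and write volumes as NIfTI
#'
#' Lossless round trip of voxel data and voxel size through NIfTI-1 files
#' (`.nii` / `.nii.gz`). Only the voxel size is carried; phantoms are
#' axis-aligned, so no rotation part is used.
#'
#' @param path File path.
#' @param volume An [image_volume()] or `label_map`.
#' @return `read_volume()`: an [image_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) abort("expected a 3D NIfTI volume")
  image_volume(as.array(img), RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  RNifti::pixdim(img) <- voxel_size(volume)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and write phantom specifications as JSON
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `read_phantom_spec()`: a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  regions <- purrr::map(seq_len(nrow(spec$regions)), function(i) {
    r <- spec$regions[i, ]
    list(name = r$name, label_id = r$label_id, na_mM = r$na_mM,
         k_mM = r$k_mM, ff = r$ff, water_t2_ms = r$water_t2_ms,
         geometry = r$geometry[[1]])
  })
  jsonlite::write_json(
    list(grid_shape = spec$grid_shape, voxel_size_mm = spec$voxel_size_mm,
         seed = spec$seed, regions = regions),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map(p$regions, function(r) {
    geom <- r$geometry
    geom[] <- lapply(geom, function(x) if (is.list(x)) unlist(x) else x)
    region_spec(r$name, r$label_id, r$na_mM, r$k_mM, ff = r$ff,
                water_t2_ms = r$water_t2_ms %||% NA_real_, geometry = geom)
  })
  phantom_spec(unlist(p$grid_shape), unlist(p$voxel_size_mm),
               dplyr::bind_rows(rows), seed = p$seed %||% 1L)
}
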