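#' Write a scene ground truth as JSON
#'
#' Serializes the planted plaque table (with voxel sets), per-plaque
#' intensities, run-length-encoded vessel and astrocyte masks, and the
#' normalization areas. Masks are RLE over the linear voxel index
#' (column-major z, y, x) to keep the file plain text and compact.
#'
#' @param truth a \code{scene_truth}.
#' @param path output JSON path.
#' @return \code{read_scene_truth} returns the \code{scene_truth} (without
#'   the original \code{config}, which is stored alongside).
#' @export
write_scene_truth <- function(truth, path) {
  stopifnot(inherits(truth, "scene_truth"))
  rle_mask <- function(m) {
    r <- rle(as.logical(m))
    list(lengths = r$lengths, values = r$values)
  }
  payload <- list(
    field_shape = truth$field_shape,
    voxel_size = truth$voxel_size,
    plaques = truth$plaques,
    plaque_voxels = truth$plaque_voxels,
    plaque_intensity = as.data.frame(truth$plaque_intensity),
    vessel_mask_rle = rle_mask(truth$vessel_mask),
    astrocyte_mask_rle = rle_mask(truth$astrocyte_mask),
    areas = as.list(truth$areas))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_truth
#' @export
read_scene_truth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  unrle <- function(r, d) {
    array(inverse.rle(structure(list(lengths = r$lengths,
                                     values = r$values), class = "rle")),
          dim = d)
  }
  d <- as.integer(p$field_shape)
  structure(list(
    plaques = as.data.frame(p$plaques),
    plaque_voxels = lapply(p$plaque_voxels, as.integer),
    plaque_intensity = as.matrix(p$plaque_intensity),
    vessel_mask = unrle(p$vessel_mask_rle, d),
    astrocyte_mask = unrle(p$astrocyte_mask_rle, d),
    areas = unlist(p$areas),
    field_shape = d,
    voxel_size = as.numeric(p$voxel_size),
    config = NULL), class = "scene_truth")
}

#' Write / read an unmixed image as multi-channel TIFF + JSON sidecar
#'
#' Channels are the per-fluorophore abundance maps plus a final
#' root-mean-square spectral residual channel.
#'
#' @param x an \code{unmixed_image}.
#' @param path output TIFF path.
#' @return \code{read_unmixed_image} returns an \code{unmixed_image}.
#' @export
write_unmixed_image <- function(x, path) {
  stopifnot(inherits(x, "unmixed_image"))
  d <- dim(x$abundances)
  arr <- array(0, dim = c(d[1:3], d[4] + 1L))
  arr[, , , seq_len(d[4])] <- x$abundances
  arr[, , , d[4] + 1L] <- x$residual
  write_zc_tiff(arr, path,
                meta = list(kind = "unmixed_image",
                            channels = c(dimnames(x$abundances)[[4]],
                                         "rms_residual"),
                            voxel_size = x$voxel_size))
}

#' @rdname write_unmixed_image
#' @export
read_unmixed_image <- function(path) {
  r <- read_zc_tiff(path)
  d <- dim(r$data)
  k <- d[4] - 1L
  ab <- r$data[, , , seq_len(k), drop = FALSE]
  dimnames(ab) <- list(NULL, NULL, NULL, r$meta$channels[seq_len(k)])
  structure(list(abundances = ab,
                 residual = array(r$data[, , , d[4]], dim = d[1:3]),
                 voxel_size = r$meta$voxel_size),
            class = "unmixed_image")
}

#' Write a plaque table as CSV
#'
#' One row per plaque with one-hot connexin columns, class label,
#' compartment (if assigned), size and centroid; the voxel sets are not
#' serialized.
#'
#' @param plaques a plaque table from \code{\link{merge_channels}}.
#' @param path output CSV path.
#' @export
write_plaque_csv <- function(plaques, path) {
  write.csv(as.data.frame(plaques), path, row.names = FALSE)
  invisible(path)
}
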