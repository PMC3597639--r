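#' Lambda stack container
#'
#' A 4D spectral image (z, y, x, bin) with its spectral bin grid and voxel
#' geometry. Intensities are nonnegative arbitrary units.
#'
#' @param data numeric 4D array indexed (z, y, x, bin).
#' @param bin_centers strictly increasing wavelength bin centers (nm), one
#'   per spectral bin.
#' @param voxel_size numeric length-3, micrometres per voxel in (z, y, x).
#' @return object of class \code{lambda_stack}.
#' @export
lambda_stack <- function(data, bin_centers, voxel_size) {
  stopifnot(length(dim(data)) == 4,
            dim(data)[4] == length(bin_centers),
            length(voxel_size) == 3, all(voxel_size > 0),
            all(diff(bin_centers) > 0))
  if (any(data < 0)) stop("lambda stack intensities must be nonnegative")
  structure(list(data = data,
                 bin_centers = as.numeric(bin_centers),
                 voxel_size = as.numeric(voxel_size)),
            class = "lambda_stack")
}

#' @export
print.lambda_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "lambda_stack: %d z x %d y x %d x, %d bins (%.0f-%.0f nm), voxel %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], d[4], min(x$bin_centers), max(x$bin_centers),
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Write / read a lambda stack or multi-channel volume as TIFF + JSON sidecar
#'
#' Stacks are stored as multi-page 32-bit float TIFF in ZC page order
#' (channel fastest within each z-slice) with a JSON sidecar
#' (\code{<path>.json}) recording dimension sizes, channel/bin metadata and
#' voxel size, so a round trip is lossless up to float32 precision.
#'
#' @param x a \code{lambda_stack}.
#' @param path output TIFF path.
#' @return \code{read_lambda_stack} returns a \code{lambda_stack}.
#' @export
write_lambda_stack <- function(x, path) {
  stopifnot(inherits(x, "lambda_stack"))
  write_zc_tiff(x$data, path,
                meta = list(kind = "lambda_stack",
                            bin_centers = x$bin_centers,
                            voxel_size = x$voxel_size))
}

#' @rdname write_lambda_stack
#' @export
read_lambda_stack <- function(path) {
  r <- read_zc_tiff(path)
  lambda_stack(r$data, r$meta$bin_centers, r$meta$voxel_size)
}

# Shared low-level writer for (z, y, x, channel) arrays. TIFF pages carry the
# pixel data; everything else lives in the sidecar.
write_zc_tiff <- function(arr, path, meta) {
  d <- dim(arr)
  scale <- max(arr, 1e-12)  # writeTIFF stores [0,1] floats; keep scale in meta
  pages <- vector("list", d[1] * d[4])
  k <- 1L
  for (z in seq_len(d[1])) {
    for (ch in seq_len(d[4])) {
      pages[[k]] <- arr[z, , , ch] / scale
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta$dim <- d
  meta$page_order <- "ZC"
  meta$intensity_scale <- scale
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_zc_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- meta$dim
  arr <- array(0, dim = d)
  k <- 1L
  for (z in seq_len(d[1])) {
    for (ch in seq_len(d[4])) {
      arr[z, , , ch] <- pages[[k]] * meta$intensity_scale
      k <- k + 1L
    }
  }
  list(data = arr, meta = meta)
}
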