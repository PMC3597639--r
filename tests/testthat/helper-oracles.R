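# Independent brute-force oracles and tiny fixture builders shared by the
# suite. These deliberately avoid the package's own algorithms: the
# flood-fill oracle grows components by frontier dilation over the raw
# array, and mixtures are built by plain matrix arithmetic.

# Connected components by repeated frontier flooding. Returns a list of
# sorted integer voxel-index vectors, sorted by their smallest index.
flood_fill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  n1 <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = n1 == 1, "18" = n1 >= 1 & n1 <= 2,
                      "26" = n1 >= 1), , drop = FALSE]
  todo <- mask
  comps <- list()
  while (any(todo)) {
    seedvox <- which(todo)[1]
    comp <- array(FALSE, dim = d)
    comp[seedvox] <- TRUE
    frontier <- seedvox
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (i in seq_len(nrow(offs))) {
        z <- co[, 1] + offs[i, 1]
        y <- co[, 2] + offs[i, 2]
        x <- co[, 3] + offs[i, 3]
        ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
        if (!any(ok)) next
        lin <- (x[ok] - 1L) * d[1] * d[2] + (y[ok] - 1L) * d[1] + z[ok]
        new <- lin[todo[lin] & !comp[lin]]
        if (length(new)) {
          comp[new] <- TRUE
          nxt <- c(nxt, new)
        }
      }
      frontier <- unique(nxt)
    }
    idx <- which(comp)
    todo[idx] <- FALSE
    comps[[length(comps) + 1L]] <- sort(idx)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# Canonical form of a component list for set comparison.
canon_components <- function(comps) {
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, numeric(1)))]
}

# A small well-separated fingerprint set for fast exact tests.
toy_spectra <- function(k = 3, nbins = 12) {
  bins <- seq(450, 650, length.out = nbins)
  peaks <- seq(470, 630, length.out = k)
  m <- t(vapply(peaks, function(p) exp(-0.5 * ((bins - p) / 15)^2),
                numeric(nbins)))
  rownames(m) <- paste0("dye", seq_len(k))
  reference_spectra(m, bin_centers = bins)
}

# Build a noiseless lambda stack from an explicit abundance array.
stack_from_abundances <- function(ab, refs, voxel_size = c(1, 1, 1),
                                  offset = 0) {
  d <- dim(ab)
  S <- matrix(ab, nrow = prod(d[1:3]), ncol = d[4]) %*% unclass(refs) + offset
  lambda_stack(array(S, dim = c(d[1:3], ncol(refs))),
               attr(refs, "bin_centers"), voxel_size)
}

# A fast small scene configuration for pipeline-level tests.
small_scene <- function(seed = 1L, ...) {
  scene_config(field_shape = c(3L, 96L, 96L), seed = seed, ...)
}

# channel_objects built directly from explicit voxel sets (bypasses
# thresholding) for colocalization tests.
objects_from_voxels <- function(voxsets, d, channel,
                                voxel_size = c(1, 1, 1)) {
  arr <- array(0, dim = d)
  for (v in voxsets) arr[v] <- 10
  segment_channel(arr, threshold = 5, min_size = 1L, connectivity = 26L,
                  channel = channel, voxel_size = voxel_size)
}
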