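#' Planted per-fluorophore abundance maps of a scene
#'
#' Expands a \code{\link{scene_truth}} into the (z, y, x, K) abundance array
#' the renderer mixes through the emission fingerprints: each plaque
#' contributes its planted intensity to every member-connexin channel over
#' its voxels; the vessel mask drives the GS-lectin channel and the
#' astrocyte mask the GFAP channel.
#'
#' @param truth a \code{scene_truth} from \code{\link{build_scene}}.
#' @param channels channel order; default the six-marker order of
#'   \code{\link{default_spectra}} (by marker name).
#' @return numeric array (z, y, x, K) with channel dimnames (marker names).
#' @export
planted_abundances <- function(truth,
                               channels = c("GS-lectin", "Cx43", "Cx26",
                                            "Cx30", "Cx45", "GFAP")) {
  d <- truth$field_shape
  ab <- array(0, dim = c(d, length(channels)),
              dimnames = list(NULL, NULL, NULL, channels))
  nvox <- prod(d)
  for (i in seq_len(nrow(truth$plaques))) {
    pv <- truth$plaque_voxels[[i]]
    for (cx in class_members(truth$plaques$class[i])) {
      if (!cx %in% channels) next
      off <- (match(cx, channels) - 1L) * nvox
      ab[pv + off] <- ab[pv + off] + truth$plaque_intensity[i, cx]
    }
  }
  mk <- truth$config$marker_intensity
  if ("GS-lectin" %in% channels) {
    off <- (match("GS-lectin", channels) - 1L) * nvox
    ab[which(truth$vessel_mask) + off] <- mk[["GS-lectin"]]
  }
  if ("GFAP" %in% channels) {
    off <- (match("GFAP", channels) - 1L) * nvox
    ab[which(truth$astrocyte_mask) + off] <- mk[["GFAP"]]
  }
  ab
}

#' Render a scene into a noisy lambda stack
#'
#' Forward model of spectral acquisition, the process linear unmixing
#' inverts: per voxel the expected signal in bin l is
#' \code{background + autofluorescence + sum_k abundance_k * spectrum_k[l]},
#' then optional Poisson shot noise (expected counts \code{signal/gain},
#' scaled back by \code{gain}) followed by additive Gaussian read noise,
#' clamped at zero. With all noise terms zero the stack is the exact linear
#' mixture. Deterministic given \code{seed}.
#'
#' @param truth a \code{scene_truth}.
#' @param spectra a \code{\link{reference_spectra}} set whose markers cover
#'   the scene channels and whose bin grid matches the scene config.
#' @param config the \code{\link{scene_config}} (defaults to the one stored
#'   in \code{truth}).
#' @param seed RNG seed for the noise draws (default: scene seed + 1).
#' @return a \code{\link{lambda_stack}}.
#' @export
render_lambda_stack <- function(truth, spectra = default_spectra(truth$config$bin_centers),
                                config = truth$config, seed = config$seed + 1L) {
  stopifnot(inherits(truth, "scene_truth"),
            inherits(spectra, "reference_spectra"))
  bc <- attr(spectra, "bin_centers")
  if (length(bc) != length(config$bin_centers) ||
      any(abs(bc - config$bin_centers) > 1e-3)) {
    stop("spectral bin grid mismatch between spectra and scene config")
  }
  markers <- attr(spectra, "markers")
  if (is.null(markers)) markers <- rownames(spectra)
  ab <- planted_abundances(truth, channels = markers)
  d <- truth$field_shape
  nb <- length(bc)

  A <- matrix(ab, nrow = prod(d), ncol = dim(ab)[4])
  S <- A %*% unclass(spectra)                       # voxels x bins
  S <- S + config$noise$background + config$noise$autofluorescence

  with_seed(seed, {
    if (config$noise$poisson_gain > 0) {
      g <- config$noise$poisson_gain
      S[] <- rpois(length(S), S / g) * g
    }
    if (config$noise$read_sd > 0) {
      S[] <- S + rnorm(length(S), 0, config$noise$read_sd)
    }
  })
  S <- pmax(S, 0)
  lambda_stack(array(S, dim = c(d, nb)), bc, config$voxel_size)
}
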