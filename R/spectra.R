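#' Spectral bin centers of a lambda stack
#'
#' The acquisition model is a 32-image lambda stack covering 411--754 nm.
#' Bin centers are evenly spaced across the stated range, honouring both
#' endpoints (the nominal per-image bandwidth is therefore ~11 nm rather
#' than a rounded 10 nm).
#'
#' @param n_bins number of spectral bins (default 32).
#' @param range_nm two-element numeric, wavelength range in nm.
#' @return numeric vector of strictly increasing bin centers (nm).
#' @export
lambda_bin_centers <- function(n_bins = 32L, range_nm = c(411, 754)) {
  stopifnot(n_bins >= 2, length(range_nm) == 2, range_nm[2] > range_nm[1])
  seq(range_nm[1], range_nm[2], length.out = n_bins)
}

# Default emission peak (nm) for each fluorophore used in the six-marker
# staining: AMCA (GS isolectin B4, vessels), Alexa488 (Cx43), Alexa532 (Cx26),
# Cy3 (Cx30), Alexa594 (Cx45), Cy5 (GFAP).
DEFAULT_FLUOROPHORES <- data.frame(
  fluorophore = c("AMCA", "Alexa488", "Alexa532", "Cy3", "Alexa594", "Cy5"),
  marker      = c("GS-lectin", "Cx43", "Cx26", "Cx30", "Cx45", "GFAP"),
  peak_nm     = c(448, 519, 553, 569, 617, 670),
  stringsAsFactors = FALSE
)

# Skewed-Gaussian emission curve: Gaussian core with a slower exponential
# red tail, the qualitative shape of organic dye emission spectra.
skewed_emission <- function(wavelength_nm, peak_nm, sigma_nm = 18, tail_nm = 45) {
  d <- wavelength_nm - peak_nm
  core <- exp(-0.5 * (d / sigma_nm)^2)
  tail <- ifelse(d > 0, exp(-d / tail_nm), 0)
  pmax(core, 0.35 * tail)
}

#' Build a reference emission-fingerprint set
#'
#' Constructs the K x L matrix of per-fluorophore emission fingerprints over
#' the spectral bins ("emission fingerprinting"). Rows are normalized to unit
#' sum. Row rank is checked and the condition number recorded; rank-deficient
#' sets are rejected, naming the most collinear fluorophore pair.
#'
#' @param matrix K x L nonnegative matrix of fingerprints (rows = fluorophores).
#' @param fluorophores character vector of K fluorophore names.
#' @param bin_centers numeric vector of L wavelength bin centers (nm).
#' @param markers optional character vector mapping fluorophores to the
#'   biological marker each one reports (same length as \code{fluorophores}).
#' @return an object of class \code{reference_spectra}: the normalized matrix
#'   with attributes \code{bin_centers}, \code{markers} and \code{condition}.
#' @export
reference_spectra <- function(matrix, fluorophores = rownames(matrix),
                              bin_centers, markers = NULL) {
  matrix <- as.matrix(matrix)
  if (is.null(fluorophores)) {
    stop("fluorophore names are required")
  }
  stopifnot(nrow(matrix) == length(fluorophores),
            ncol(matrix) == length(bin_centers))
  if (any(!is.finite(matrix)) || any(matrix < 0)) {
    stop("fingerprints must be finite and nonnegative")
  }
  rs <- rowSums(matrix)
  if (any(rs <= 0)) {
    stop("degenerate fingerprint (all-zero spectrum) for: ",
         paste(fluorophores[rs <= 0], collapse = ", "))
  }
  m <- matrix / rs
  rownames(m) <- fluorophores
  colnames(m) <- sprintf("%.2f", bin_centers)

  sv <- svd(m, nu = 0, nv = 0)$d
  if (sv[length(sv)] < 1e-10 * sv[1]) {
    stop("reference spectra are rank deficient; most collinear pair: ",
         paste(most_collinear_pair(m), collapse = " / "))
  }
  structure(m,
            class = "reference_spectra",
            bin_centers = as.numeric(bin_centers),
            markers = markers,
            condition = sv[1] / sv[length(sv)])
}

most_collinear_pair <- function(m) {
  n <- m / sqrt(rowSums(m^2))
  cc <- n %*% t(n)
  diag(cc) <- -Inf
  ij <- arrayInd(which.max(cc), dim(cc))
  rownames(m)[sort(ij[1, ])]
}

#' @export
print.reference_spectra <- function(x, ...) {
  cat(sprintf("reference_spectra: %d fluorophores x %d bins (%.0f-%.0f nm), condition %.1f\n",
              nrow(x), ncol(x), min(attr(x, "bin_centers")),
              max(attr(x, "bin_centers")), attr(x, "condition")))
  mk <- attr(x, "markers")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-9s%s\n", rownames(x)[i],
                if (!is.null(mk)) paste0(" -> ", mk[i]) else ""))
  }
  invisible(x)
}

#' Default six-fluorophore fingerprint set
#'
#' Skewed-Gaussian emission models for AMCA, Alexa488, Alexa532, Cy3,
#' Alexa594 and Cy5, evaluated on the lambda-stack bin grid and mapped to
#' the markers they report (GS-lectin vessels, Cx43, Cx26, Cx30, Cx45, GFAP).
#' These model the named dyes; peak positions and widths are configurable.
#'
#' @param bin_centers spectral bin centers (nm).
#' @param peaks named numeric vector of peak wavelengths overriding defaults.
#' @return a \code{\link{reference_spectra}} object.
#' @export
default_spectra <- function(bin_centers = lambda_bin_centers(), peaks = NULL) {
  fl <- DEFAULT_FLUOROPHORES
  if (!is.null(peaks)) {
    stopifnot(all(names(peaks) %in% fl$fluorophore))
    fl$peak_nm[match(names(peaks), fl$fluorophore)] <- peaks
  }
  m <- t(vapply(fl$peak_nm, skewed_emission, numeric(length(bin_centers)),
                wavelength_nm = bin_centers))
  rownames(m) <- fl$fluorophore
  reference_spectra(m, fl$fluorophore, bin_centers, markers = fl$marker)
}

#' Read / write reference spectra as CSV
#'
#' CSV layout: one row per fluorophore; columns \code{fluorophore},
#' \code{marker}, then one column per wavelength bin (header = bin center nm).
#'
#' @param x a \code{reference_spectra} object.
#' @param path file path.
#' @return \code{read_spectra_csv} returns a \code{reference_spectra} object.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "reference_spectra"))
  m <- unclass(x)
  colnames(m) <- format(attr(x, "bin_centers"), digits = 12, trim = TRUE)
  df <- data.frame(fluorophore = rownames(x),
                   marker = attr(x, "markers") %||% NA_character_,
                   m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(all(c("fluorophore", "marker") %in% names(df)))
  bins <- as.numeric(names(df)[-(1:2)])
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  reference_spectra(m, df$fluorophore, bins,
                    markers = if (all(is.na(df$marker))) NULL else df$marker)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
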