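#' Extract reference emission fingerprints from ROIs
#'
#' Builds a \code{\link{reference_spectra}} set from regions of interest drawn
#' on a lambda stack, one ROI per fluorophore: row k is the mean spectrum over
#' ROI k, optionally background-subtracted (per-bin median over a designated
#' background ROI), clamped at zero and normalized to unit sum.
#'
#' @param stack a \code{\link{lambda_stack}}.
#' @param roi_masks named list of logical 3D arrays (z, y, x), one per
#'   fluorophore; names become the fluorophore names.
#' @param background_roi optional logical 3D array marking background voxels.
#' @param markers optional marker names (same order as \code{roi_masks}).
#' @return a \code{reference_spectra} object.
#' @export
extract_reference_spectra <- function(stack, roi_masks, background_roi = NULL,
                                      markers = NULL) {
  stopifnot(inherits(stack, "lambda_stack"), is.list(roi_masks),
            !is.null(names(roi_masks)))
  d <- dim(stack$data)
  nbin <- d[4]
  flat <- matrix(stack$data, nrow = prod(d[1:3]), ncol = nbin)

  bg <- rep(0, nbin)
  if (!is.null(background_roi)) {
    stopifnot(all(dim(background_roi) == d[1:3]))
    idx <- which(background_roi)
    if (length(idx) == 0) stop("background ROI is empty")
    bg <- apply(flat[idx, , drop = FALSE], 2, median)
  }

  m <- matrix(NA_real_, length(roi_masks), nbin)
  for (k in seq_along(roi_masks)) {
    mask <- roi_masks[[k]]
    stopifnot(all(dim(mask) == d[1:3]))
    idx <- which(mask)
    if (length(idx) == 0) {
      stop("empty ROI for fluorophore: ", names(roi_masks)[k])
    }
    spec <- pmax(colMeans(flat[idx, , drop = FALSE]) - bg, 0)
    if (sum(spec) <= 0) {
      stop("degenerate (all-zero) spectrum extracted for fluorophore: ",
           names(roi_masks)[k])
    }
    m[k, ] <- spec
  }
  reference_spectra(m, names(roi_masks), stack$bin_centers, markers = markers)
}

#' Per-voxel linear spectral unmixing
#'
#' Decomposes every voxel spectrum into weighted contributions of the
#' reference fingerprints by least squares: with \code{nonnegative = TRUE}
#' (default) solves min ||s - B x||_2 subject to x >= 0 per voxel, since
#' abundances are physical dye quantities; otherwise the unconstrained
#' solution. Voxels are independent (no spatial regularization), mirroring
#' online emission fingerprinting on the instrument.
#'
#' @param stack a \code{\link{lambda_stack}}.
#' @param refs a \code{\link{reference_spectra}} set on the same bin grid.
#' @param nonnegative constrain abundances to be nonnegative (default TRUE).
#' @param background add a flat constant-offset fingerprint column to absorb
#'   uniform background/autofluorescence (default FALSE); its abundance is
#'   returned as channel \code{"background"}.
#' @return an object of class \code{unmixed_image}: list with
#'   \code{abundances} (z, y, x, K array, dimnames on channel axis),
#'   \code{residual} (z, y, x root-mean-square spectral residual) and
#'   \code{voxel_size}.
#' @export
linear_unmix <- function(stack, refs, nonnegative = TRUE, background = FALSE) {
  stopifnot(inherits(stack, "lambda_stack"), inherits(refs, "reference_spectra"))
  bc <- attr(refs, "bin_centers")
  if (length(bc) != length(stack$bin_centers) ||
      any(abs(bc - stack$bin_centers) > 1e-3)) {   # nm; picometre differences are meaningless
    stop("spectral bin grid mismatch between stack and reference spectra")
  }
  d <- dim(stack$data)
  B <- t(unclass(refs))                      # bins x K
  # abundance channels are named by the biological marker each fluorophore
  # reports when that mapping is known, else by the fluorophore itself
  channels <- attr(refs, "markers") %||% rownames(refs)
  if (background) {
    B <- cbind(B, 1 / nrow(B))
    channels <- c(channels, "background")
  }
  sv <- svd(B, nu = 0, nv = 0)$d
  if (sv[length(sv)] < 1e-10 * sv[1]) {
    stop("unmixing system is rank deficient; most collinear pair: ",
         paste(most_collinear_pair(t(B)), collapse = " / "))
  }

  S <- matrix(stack$data, nrow = prod(d[1:3]), ncol = d[4])  # voxels x bins
  X <- if (nonnegative) nnls_batch(B, S) else t(qr.coef(qr(B), t(S)))

  # rms residual via ||s||^2 - 2 x.h + x'Gx, clamped against roundoff
  G <- crossprod(B)
  H <- S %*% B                               # voxels x K, rows h = B's
  ss <- rowSums(S^2)
  rss <- pmax(ss - 2 * rowSums(X * H) + rowSums((X %*% G) * X), 0)
  structure(list(
    abundances = array(X, dim = c(d[1:3], ncol(B)),
                       dimnames = list(NULL, NULL, NULL, channels)),
    residual = array(sqrt(rss / d[4]), dim = d[1:3]),
    voxel_size = stack$voxel_size),
    class = "unmixed_image")
}

#' @export
print.unmixed_image <- function(x, ...) {
  d <- dim(x$abundances)
  cat(sprintf("unmixed_image: %d z x %d y x %d x, %d channels [%s]\n",
              d[1], d[2], d[3], d[4],
              paste(dimnames(x$abundances)[[4]], collapse = ", ")))
  invisible(x)
}

#' Batched nonnegative least squares
#'
#' Solves min ||B x_i - s_i|| with x_i >= 0 for many right-hand sides.
#' For small K the exact solution is found by vectorized KKT screening over
#' all 2^K support sets: a support P is the answer iff the equality-
#' constrained solution on P is nonnegative and the gradient on the
#' complement is nonnegative (the objective is strictly convex, so the
#' KKT point is the unique global minimum). Larger K falls back to
#' per-column Lawson-Hanson.
#'
#' @param B bins x K design matrix (full column rank).
#' @param S n x bins matrix of spectra (one row per voxel).
#' @return n x K matrix of nonnegative solutions.
#' @keywords internal
nnls_batch <- function(B, S) {
  K <- ncol(B)
  n <- nrow(S)
  G <- crossprod(B)
  H <- S %*% B                               # rows are h_i = B' s_i
  X <- matrix(0, n, K)
  if (K > 10) {
    for (i in seq_len(n)) X[i, ] <- lh_nnls(G, H[i, ])
    return(X)
  }

  hs <- sqrt(rowSums(H^2))                   # per-voxel gradient scale
  tol <- 1e-9 * (hs + max(hs) * 1e-6)
  unsolved <- rep(TRUE, n)

  supports <- lapply(0:(2^K - 1), function(m) which(bitwAnd(m, 2^(0:(K - 1))) > 0))
  supports <- supports[order(-lengths(supports))]   # try full support first

  for (P in supports) {
    if (!any(unsolved)) break
    idx <- which(unsolved)
    if (length(P) == 0) {
      ok <- rowSums(H[idx, , drop = FALSE] > tol[idx]) == 0
      unsolved[idx[ok]] <- FALSE              # x = 0 already in X
      next
    }
    Gi <- solve(G[P, P, drop = FALSE])
    XP <- H[idx, P, drop = FALSE] %*% Gi      # candidate x on support P
    feas <- rowSums(XP < -tol[idx]) == 0
    if (!any(feas)) next
    XPc <- pmax(XP, 0)
    # dual feasibility on complement: w = h - G x <= tol
    Pc <- setdiff(seq_len(K), P)
    if (length(Pc) > 0) {
      W <- H[idx, Pc, drop = FALSE] - XPc %*% G[P, Pc, drop = FALSE]
      dual <- rowSums(W > tol[idx]) == 0
    } else dual <- rep(TRUE, length(idx))
    hit <- feas & dual
    if (any(hit)) {
      rows <- idx[hit]
      X[rows, P] <- XPc[hit, , drop = FALSE]
      unsolved[rows] <- FALSE
    }
  }
  # numerically awkward leftovers: exact active-set solver
  for (i in which(unsolved)) X[i, ] <- lh_nnls(G, H[i, ])
  X
}

# Lawson-Hanson active-set NNLS in normal-equation form:
# min x'Gx/2 - h'x subject to x >= 0, G positive definite.
lh_nnls <- function(G, h, tol = 1e-10 * max(abs(h), 1)) {
  K <- length(h)
  P <- logical(K)
  x <- numeric(K)
  for (outer in seq_len(30 * K)) {
    w <- h - as.vector(G %*% x)
    cand <- which(!P & w > tol)
    if (length(cand) == 0) break
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(K)
      s[P] <- solve(G[P, P, drop = FALSE], h[P])
      if (all(s[P] > -tol)) {
        x <- pmax(s, 0)
        x[!P] <- 0
        break
      }
      q <- which(P & s < 0 & x > s)
      alpha <- min(x[q] / (x[q] - s[q]))
      x <- x + alpha * (s - x)
      drop <- P & x <= tol
      x[drop] <- 0
      P[drop] <- FALSE
    }
  }
  x
}
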