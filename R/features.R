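## Volumetric features: Gaussian smoothing, vectorization of GM+WM maps,
## linear (dot-product) kernel matrices and summary tissue volumes.

## 1D Gaussian band (Toeplitz) matrix with zero-padding boundary semantics:
## row i holds the truncated, unit-sum kernel centred at i.
.gaussBand <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    M[cbind(i[ok], j[ok])] <- k[off + r + 1L]
  }
  M
}

## multiply matrix M along one axis of a 3D array
.applyAxis <- function(vol, M, axis) {
  d <- dim(vol)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  inv <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(2, 3, 1))
  v <- aperm(vol, perm)
  dp <- dim(v)
  out <- M %*% matrix(v, dp[1], dp[2] * dp[3])
  aperm(array(out, dp), inv)
}

#' Gaussian-smooth a 3D volume
#'
#' Separable Gaussian with per-axis sigma (in voxels) =
#' \code{fwhm / (voxel_size * 2 sqrt(2 ln 2))}, truncated at 4 sigma and
#' renormalized to unit sum; boundaries are zero-padded, so interior mass is
#' conserved. \code{fwhm_mm = 0} is the identity.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm smoothing kernel full width at half maximum in mm (>= 0).
#' @param voxel_size_mm voxel edge lengths in mm (length 1 or 3).
#' @return the smoothed array.
#' @export
smoothVolume <- function(vol, fwhm_mm, voxel_size_mm = c(1.5, 1.5, 1.5)) {
  if (length(dim(vol)) != 3L) stop("vol must be a 3D array")
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  sigma <- fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))
  out <- vol
  for (ax in 1:3)
    out <- .applyAxis(out, .gaussBand(dim(vol)[ax], sigma[ax]), ax)
  out
}

#' Vectorize tissue maps into a GM+WM feature vector
#'
#' GM and WM volumes are smoothed independently, flattened in fixed
#' column-major raster order (first axis fastest) and concatenated GM first.
#' Only dot products of these vectors matter downstream, so any consistent
#' raster order is equivalent.
#'
#' @param maps a \linkS4class{TissueMaps}.
#' @param fwhm_mm smoothing FWHM in mm (default 4).
#' @return numeric vector of length 2 x voxel count.
#' @export
vectorizeMaps <- function(maps, fwhm_mm = 4) {
  stopifnot(is(maps, "TissueMaps"))
  vs <- voxelSize(maps)
  c(as.vector(smoothVolume(gmMap(maps), fwhm_mm, vs)),
    as.vector(smoothVolume(wmMap(maps), fwhm_mm, vs)))
}

#' Feature matrix for a list of subjects
#'
#' @param maps_list named list of \linkS4class{TissueMaps}.
#' @param fwhm_mm smoothing FWHM in mm.
#' @return subjects x features matrix with subject ids as row names.
#' @export
featureMatrix <- function(maps_list, fwhm_mm = 4) {
  X <- t(vapply(maps_list, vectorizeMaps, fwhm_mm = fwhm_mm,
                FUN.VALUE = numeric(2 * prod(dim(gmMap(maps_list[[1L]]))))))
  rownames(X) <- names(maps_list)
  X
}

.asFeatureMatrix <- function(x) {
  if (is.list(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) != 1L)
      stop("feature vectors have unequal lengths")
    x <- do.call(rbind, x)
  }
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  x
}

#' Linear kernel (dot-product similarity) matrix
#'
#' \code{K[i, j]} is the dot product of subjects i and j's feature vectors.
#'
#' @param vectors subjects x features matrix (or list of equal-length
#'   vectors); row names become subject ids.
#' @return symmetric N x N matrix.
#' @export
linearKernel <- function(vectors) {
  X <- .asFeatureMatrix(vectors)
  tcrossprod(X)
}

#' Cross-kernel between test and training subjects
#'
#' @param train_vectors,test_vectors feature matrices (or lists of vectors)
#'   with a common feature length.
#' @return n_test x n_train matrix of dot products.
#' @export
crossKernel <- function(train_vectors, test_vectors) {
  Xtr <- .asFeatureMatrix(train_vectors)
  Xte <- .asFeatureMatrix(test_vectors)
  if (ncol(Xtr) != ncol(Xte))
    stop("train and test feature lengths differ")
  tcrossprod(Xte, Xtr)
}

#' Kernel validity checks
#'
#' Verifies symmetry (within 1e-10 relative) and positive semidefiniteness
#' (minimum eigenvalue >= -1e-8 x trace / N).
#'
#' @param K square numeric matrix.
#' @return TRUE invisibly, or an error.
#' @export
checkKernel <- function(K) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("K must be square")
  sc <- max(abs(K), 1e-300)
  if (max(abs(K - t(K))) > 1e-10 * sc) stop("K is not symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * sum(diag(K)) / nrow(K))
    stop("K is not positive semidefinite")
  invisible(TRUE)
}

#' Summary tissue volumes in litres
#'
#' Tissue volume = sum of probabilities x voxel volume; intracranial volume
#' (ICV) is the sum of the three compartments.
#'
#' @param maps a \linkS4class{TissueMaps}.
#' @return one-row data.frame: gm_l, wm_l, csf_l, icv_l (litres).
#' @export
summaryVolumes <- function(maps) {
  stopifnot(is(maps, "TissueMaps"))
  voxL <- prod(voxelSize(maps)) * 1e-6  # mm^3 -> litres
  gm <- sum(gmMap(maps)) * voxL
  wm <- sum(wmMap(maps)) * voxL
  csf <- sum(csfMap(maps)) * voxL
  data.frame(gm_l = gm, wm_l = wm, csf_l = csf, icv_l = gm + wm + csf)
}
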