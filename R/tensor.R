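# Diffusion tensor reconstruction: ordinary least squares on the
# log-signal (Stejskal-Tanner forward model), symmetric eigen-decomposition
# and a b0-intensity myocardium mask.

#' Fit diffusion tensors by log-linear least squares
#'
#' Solves `log(S_i / S0) = -b g_i' D g_i` per voxel by ordinary least
#' squares over the six unique tensor components. Voxels whose b = 0
#' signal is at or below the noise floor, or with any non-positive
#' diffusion-weighted sample, are masked invalid rather than clamped
#' (clamping biases ADC); their signals are never log-transformed.
#' No positive-definiteness is enforced: negative eigenvalues from noisy
#' fits are kept and visible downstream.
#'
#' @param dwi a `dwi_stack` (see [simulate_dwi()]).
#' @param scheme the matching [acquisition_scheme()].
#' @param noise_floor voxels with `s0 <= noise_floor` are masked (default 0).
#' @param mask optional logical array restricting the fit.
#' @return a [tensor_field()] whose mask marks valid fits.
#' @export
fit_tensor_lls <- function(dwi, scheme, noise_floor = 0, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_stack"), inherits(scheme, "acquisition_scheme"))
  g <- scheme$directions
  d <- dim(dwi$s0_volume)
  nd <- nrow(g)
  stopifnot(dim(dwi$dwi)[4] == nd)
  X <- -scheme$b_value * design_matrix(g)
  kap <- design_condition(X)
  if (!is.finite(kap) || kap > 1e6)
    stop("rank-deficient design (collinear directions); condition number ",
         format(kap))
  S <- matrix(dwi$dwi, ncol = nd)
  s0 <- as.vector(dwi$s0_volume)
  valid <- s0 > noise_floor & matrixStats::rowMins(S) > 0
  if (!is.null(mask)) valid <- valid & as.vector(mask)
  D <- array(0, c(d, 6L))
  if (any(valid)) {
    Y <- log(S[valid, , drop = FALSE] / s0[valid])
    pinv <- solve(crossprod(X), t(X))          # 6 x nd
    coef <- Y %*% t(pinv)                      # nvalid x 6
    Dm <- matrix(0, length(s0), 6L)
    Dm[valid, ] <- coef
    D <- array(Dm, c(d, 6L))
  }
  tensor_field(D, array(valid, d), dwi$voxel_dims)
}

#' Per-voxel symmetric eigen-decomposition of a tensor field
#'
#' Eigenvalues are sorted descending; the sign of each eigenvector is fixed
#' so that its largest-magnitude component is positive, making the output
#' deterministic. Voxels with non-finite components are masked.
#'
#' @param tensors a [tensor_field()].
#' @return object of class `tensor_eigensystem`: `values` (4D, dims x 3),
#'   `vectors` (5D, dims x 3 x 3; `[.., , j]` is the j-th eigenvector),
#'   `mask` and `voxel_dims`.
#' @export
eigendecompose <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_field"))
  d <- dim(tensors$D)[1:3]
  m <- matrix(tensors$D, ncol = 6L)
  idx <- which(tensors$mask)
  finite <- matrixStats::rowAlls(is.finite(m[idx, , drop = FALSE]))
  idx <- idx[finite]
  if (!length(idx)) stop("no valid voxels to decompose")
  vals <- array(NA_real_, c(d, 3L))
  vecs <- array(NA_real_, c(d, 3L, 3L))
  n123 <- prod(d)
  for (v in idx) {
    Dv <- matrix(c(m[v, 1], m[v, 4], m[v, 5],
                   m[v, 4], m[v, 2], m[v, 6],
                   m[v, 5], m[v, 6], m[v, 3]), 3L, 3L)
    e <- eigen(Dv, symmetric = TRUE)           # descending by default
    for (j in 1:3) {
      vec <- e$vectors[, j]
      if (vec[which.max(abs(vec))] < 0) vec <- -vec
      vecs[v + n123 * (j - 1L) * 3L + n123 * (0:2)] <- vec
    }
    vals[v + n123 * (0:2)] <- e$values
  }
  mask <- array(FALSE, d); mask[idx] <- TRUE
  structure(list(values = vals, vectors = vecs, mask = mask,
                 voxel_dims = tensors$voxel_dims),
            class = "tensor_eigensystem")
}

#' Myocardium mask from the non-diffusion-weighted volume
#'
#' Thresholds the b = 0 volume at a fraction of its 99th percentile and
#' keeps the largest 6-connected component. A stand-in for tensor-based
#' myocardial segmentation, adequate when the background signal is far
#' below tissue signal.
#'
#' @param dwi a `dwi_stack`.
#' @param threshold_fraction fraction of the 99th percentile of s0.
#' @return logical 3D array.
#' @export
myocardium_mask_from_b0 <- function(dwi, threshold_fraction = 0.2) {
  stopifnot(inherits(dwi, "dwi_stack"))
  s0 <- dwi$s0_volume
  if (all(s0 == 0)) stop("all-zero s0 volume; cannot derive a mask")
  thr <- threshold_fraction * quantile(s0, 0.99, names = FALSE)
  mask <- s0 > thr
  if (!any(mask)) stop("empty myocardium mask at threshold ", format(thr))
  cc <- connected_components_3d(mask)
  sizes <- tabulate(cc[cc > 0L])
  cc == which.max(sizes)
}
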