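# Tensor invariants: apparent diffusion coefficient (ADC), fractional
# anisotropy (FA) and tissue mode, plus the closed-form inverse mapping
# from an invariant triple back to eigenvalues. ADC measures the overall
# magnitude of isotropic diffusion, FA the magnitude of anisotropic
# diffusion (on [0, 1]) and mode the kind of anisotropy (on [-1, 1]:
# +1 rod-like, 0 orthotropic, -1 planar).

#' Tensor invariants from eigenvalues
#'
#' Computes ADC, FA and tissue mode from the three eigenvalues of a
#' diffusion tensor. Vectorized over voxels.
#'
#' ADC is the eigenvalue mean; FA is `sqrt(3/2)` times the ratio of the
#' deviatoric norm to the tensor norm; mode is `3*sqrt(6)` times the
#' determinant of the unit-norm deviatoric tensor. An isotropic tensor has
#' FA 0 and undefined (NaN) mode.
#'
#' @param l1,l2,l3 eigenvalues (any order), in mm^2/s.
#' @return list with numeric vectors `adc`, `fa`, `mode`.
#' @export
#' @examples
#' tensor_invariants_from_eigenvalues(2e-3, 1e-3, 1e-3)
tensor_invariants_from_eigenvalues <- function(l1, l2, l3) {
  adc <- (l1 + l2 + l3) / 3
  a1 <- l1 - adc; a2 <- l2 - adc; a3 <- l3 - adc
  na2 <- a1^2 + a2^2 + a3^2           # squared deviatoric norm
  nd2 <- l1^2 + l2^2 + l3^2           # squared tensor norm
  fa <- ifelse(nd2 > 0, sqrt(pmax(1.5 * na2 / nd2, 0)), 0)
  mode <- ifelse(na2 > 0, 3 * sqrt(6) * a1 * a2 * a3 / na2^1.5, NaN)
  mode <- pmin(pmax(mode, -1), 1)
  list(adc = adc, fa = fa, mode = mode)
}

#' Eigenvalues from an invariant triple
#'
#' Inverts (ADC, FA, mode) to the unique descending eigenvalue triple with
#' those invariants. The deviatoric norm is
#' `n = adc * fa * sqrt(3 / (1.5 - fa^2))` and, with `theta = acos(mode)/3`,
#' `lambda_i = adc + n * sqrt(2/3) * cos(theta - 2*pi*(i-1)/3)`.
#'
#' With `fa = 0` the isotropic triple `(adc, adc, adc)` is returned and
#' `mode` is ignored.
#'
#' @param adc apparent diffusion coefficient (> 0), mm^2/s.
#' @param fa fractional anisotropy in `[0, 1)`.
#' @param mode tissue mode in `[-1, 1]`.
#' @return 3-column matrix of eigenvalues, sorted descending per row.
#' @export
#' @examples
#' invariants_to_eigenvalues(1e-3, 0.40825, 1)
invariants_to_eigenvalues <- function(adc, fa, mode) {
  n <- max(length(adc), length(fa), length(mode))
  adc <- rep_len(adc, n); fa <- rep_len(fa, n); mode <- rep_len(mode, n)
  if (any(adc <= 0)) stop("adc must be positive")
  if (any(fa < 0 | fa >= sqrt(1.5))) stop("fa must lie in [0, sqrt(3/2))")
  bad_mode <- fa > 0 & (is.na(mode) | mode < -1 | mode > 1)
  if (any(bad_mode)) stop("mode must lie in [-1, 1]")
  mode[fa == 0] <- 1 # ignored; keeps acos defined
  nn <- adc * fa * sqrt(3 / (1.5 - fa^2))
  theta <- acos(mode) / 3
  ev <- cbind(adc + nn * sqrt(2 / 3) * cos(theta),
              adc + nn * sqrt(2 / 3) * cos(theta - 2 * pi / 3),
              adc + nn * sqrt(2 / 3) * cos(theta - 4 * pi / 3))
  colnames(ev) <- c("l1", "l2", "l3")
  ev
}

#' Invariant maps from a fitted tensor field
#'
#' Computes per-voxel ADC, FA and tissue mode directly from the six unique
#' tensor components, without an eigen-decomposition. Isotropic voxels get
#' FA 0 and NaN mode; zero tensors additionally get ADC 0 and are flagged
#' in `degenerate`.
#'
#' @param tensors a `tensor_field` (see [fit_tensor_lls()]).
#' @return object of class `invariant_maps`: 3D arrays `adc`, `fa`, `mode`
#'   (NA outside the valid mask), the logical `mask`, a logical `degenerate`
#'   array and `voxel_dims`.
#' @export
compute_invariants <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_field"))
  D <- tensors$D
  d <- dim(D)[1:3]
  idx <- which(tensors$mask)
  m <- matrix(D, ncol = 6L)[idx, , drop = FALSE]
  dxx <- m[, 1]; dyy <- m[, 2]; dzz <- m[, 3]
  dxy <- m[, 4]; dxz <- m[, 5]; dyz <- m[, 6]
  adc <- (dxx + dyy + dzz) / 3
  axx <- dxx - adc; ayy <- dyy - adc; azz <- dzz - adc
  na2 <- axx^2 + ayy^2 + azz^2 + 2 * (dxy^2 + dxz^2 + dyz^2)
  nd2 <- dxx^2 + dyy^2 + dzz^2 + 2 * (dxy^2 + dxz^2 + dyz^2)
  fa <- ifelse(nd2 > 0, sqrt(pmax(1.5 * na2 / nd2, 0)), 0)
  detA <- axx * (ayy * azz - dyz^2) - dxy * (dxy * azz - dyz * dxz) +
    dxz * (dxy * dyz - ayy * dxz)
  mode <- ifelse(na2 > 0, pmin(pmax(3 * sqrt(6) * detA / na2^1.5, -1), 1), NaN)
  mk <- function(v) { a <- array(NA_real_, d); a[idx] <- v; a }
  deg <- array(FALSE, d); deg[idx] <- nd2 == 0
  structure(list(adc = mk(adc), fa = mk(fa), mode = mk(mode),
                 mask = tensors$mask, degenerate = deg,
                 voxel_dims = tensors$voxel_dims),
            class = "invariant_maps")
}
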