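# Internal array utilities shared across modules: separable Gaussian
# smoothing, 3D connected components, integer translation, erosion,
# bicubic resampling weights, and chunked point-set distances.

#' @importFrom stats rnorm runif sd quantile median fft setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded routines do not
#' perturb the global random stream. A `NULL` seed runs the expression
#' unseeded.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible sub-seed from a root seed and a stream label,
# keeping the result inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L)
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Dense banded convolution matrix with reflected boundaries; rows sum to 1.
conv_matrix_1d <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    # reflect out-of-range indices
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    for (j in seq_along(idx)) M[i, idx[j]] <- M[i, idx[j]] + kernel[j]
  }
  M
}

#' Separable 3D Gaussian smoothing with reflected boundaries
#' @param x 3D numeric array.
#' @param sigma per-axis standard deviations in voxels (length 3; 0 skips an axis).
#' @return smoothed array, same dimensions.
#' @noRd
gaussian_smooth_3d <- function(x, sigma) {
  d <- dim(x)
  stopifnot(length(d) == 3L, length(sigma) == 3L)
  if (sigma[1] > 0) {
    M <- conv_matrix_1d(d[1], gaussian_kernel_1d(sigma[1]))
    x <- array(M %*% matrix(x, d[1]), d)
  }
  if (sigma[2] > 0) {
    M <- conv_matrix_1d(d[2], gaussian_kernel_1d(sigma[2]))
    x <- aperm(array(M %*% matrix(aperm(x, c(2, 1, 3)), d[2]), d[c(2, 1, 3)]),
               c(2, 1, 3))
  }
  if (sigma[3] > 0) {
    M <- conv_matrix_1d(d[3], gaussian_kernel_1d(sigma[3]))
    x <- aperm(array(M %*% matrix(aperm(x, c(3, 1, 2)), d[3]), d[c(3, 1, 2)]),
               c(2, 3, 1))
  }
  x
}

# Factor by which interior white-noise standard deviation shrinks under
# separable Gaussian smoothing; used to re-standardize latent fields.
smoothing_sd_factor <- function(sigma) {
  prod(vapply(sigma, function(s) sqrt(sum(gaussian_kernel_1d(s)^2)), 0))
}

#' Label 6-connected components of a 3D logical mask
#'
#' Frontier-based flood fill over linear indices; components are numbered
#' 1..k in discovery order.
#' @return integer array of component labels (0 outside the mask).
#' @noRd
connected_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- array(0L, d)
  n1 <- d[1]; n12 <- d[1] * d[2]
  remaining <- which(mask)
  inmask <- array(FALSE, d); inmask[remaining] <- TRUE
  comp <- 0L
  offs <- c(-1L, 1L, -n1, n1, -n12, n12)
  while (length(remaining)) {
    comp <- comp + 1L
    frontier <- remaining[1L]
    lab[frontier] <- comp
    inmask[frontier] <- FALSE
    while (length(frontier)) {
      nb <- integer(0)
      ai <- arrayInd(frontier, d)
      for (k in seq_along(offs)) {
        ok <- switch(k,
          ai[, 1] > 1L, ai[, 1] < d[1],
          ai[, 2] > 1L, ai[, 2] < d[2],
          ai[, 3] > 1L, ai[, 3] < d[3])
        nb <- c(nb, frontier[ok] + offs[k])
      }
      nb <- unique(nb[inmask[nb]])
      lab[nb] <- comp
      inmask[nb] <- FALSE
      frontier <- nb
    }
    remaining <- remaining[inmask[remaining]]
  }
  lab
}

#' Integer-voxel translation of a 3D array
#' @param shift integer 3-vector; positive moves content toward higher indices.
#' @param fill value for vacated voxels.
#' @noRd
translate_array <- function(x, shift, fill = 0L) {
  d <- dim(x)
  stopifnot(length(d) == 3L, length(shift) == 3L)
  shift <- as.integer(round(shift))
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { src[[a]] <- 1:(d[a] - s); dst[[a]] <- (1 + s):d[a] }
    else { src[[a]] <- (1 - s):d[a]; dst[[a]] <- 1:(d[a] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-neighbour binary erosion (border voxels are eroded).
erode_mask_3d <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (a in 1:3) for (s in c(-1L, 1L)) {
    sh <- integer(3); sh[a] <- s
    out <- out & translate_array(mask, sh, fill = FALSE)
  }
  out
}

# Keys bicubic interpolation kernel (a = -1/2).
keys_cubic <- function(x) {
  x <- abs(x)
  ifelse(x < 1, 1.5 * x^3 - 2.5 * x^2 + 1,
         ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
}

#' Bicubic resampling weight matrix along one axis
#'
#' Maps `n_src` samples to `n_dst` samples with voxel-center alignment;
#' `W %*% v` interpolates a column vector. Rows renormalized to sum to 1
#' after boundary clamping.
#' @noRd
resample_weights_1d <- function(n_src, n_dst) {
  scale <- n_src / n_dst
  W <- matrix(0, n_dst, n_src)
  for (i in seq_len(n_dst)) {
    u <- (i - 0.5) * scale + 0.5 # voxel-center alignment of the two grids
    base <- floor(u)
    js <- (base - 1L):(base + 2L)
    w <- keys_cubic(u - js)
    js <- pmin(pmax(js, 1L), n_src)
    for (k in seq_along(js)) W[i, js[k]] <- W[i, js[k]] + w[k]
  }
  sweep(W, 1, rowSums(W), "/")
}

# Block-average a 3D array along the third axis by an integer factor.
block_average_z <- function(x, factor) {
  d <- dim(x)
  stopifnot(d[3] %% factor == 0L)
  nz <- d[3] %/% factor
  out <- array(0, c(d[1], d[2], nz))
  for (k in seq_len(nz)) {
    sl <- x[, , ((k - 1L) * factor + 1L):(k * factor), drop = FALSE]
    out[, , k] <- rowMeans(matrix(sl, d[1] * d[2]), na.rm = FALSE) |>
      array(c(d[1], d[2]))
  }
  out
}

#' Minimum Euclidean distance (mm) from query points to a point set
#' @param query,set n x 3 matrices of voxel indices.
#' @param voxel_dims mm per voxel along each axis.
#' @return numeric vector of distances, one per query row.
#' @noRd
min_dist_mm <- function(query, set, voxel_dims) {
  qs <- sweep(query, 2, voxel_dims, "*")
  ss <- sweep(set, 2, voxel_dims, "*")
  out <- numeric(nrow(qs))
  chunk <- max(1L, floor(2e6 / max(1L, nrow(ss))))
  ss2 <- rowSums(ss^2)
  for (i0 in seq(1L, nrow(qs), by = chunk)) {
    idx <- i0:min(nrow(qs), i0 + chunk - 1L)
    q <- qs[idx, , drop = FALSE]
    d2 <- outer(rowSums(q^2), ss2, "+") - 2 * q %*% t(ss)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# Voxel-center coordinates (mm) of every voxel on a grid.
grid_coords_mm <- function(dims, voxel_dims) {
  list(x = (seq_len(dims[1]) - 0.5) * voxel_dims[1],
       y = (seq_len(dims[2]) - 0.5) * voxel_dims[2],
       z = (seq_len(dims[3]) - 0.5) * voxel_dims[3])
}

#' Write a 3D volume as NIfTI-1
#' @param x numeric or integer 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_dims voxel dimensions in mm.
#' @export
write_volume <- function(x, path, voxel_dims = c(1, 1, 1)) {
  img <- RNifti::asNifti(x, reference = NULL)
  RNifti::pixdim(img) <- voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array with voxel dimensions
#' @param path NIfTI file path.
#' @return list with `data` (array) and `voxel_dims` (mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), voxel_dims = RNifti::pixdim(img)[1:3])
}
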