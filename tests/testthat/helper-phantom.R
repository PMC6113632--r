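# Shared fixtures: small phantoms built in code and cached per session.

.fixture_env <- new.env(parent = emptyenv())

# 48 x 48 x 8 phantom spec, scaled-down annulus; fast enough for unit tests
small_spec <- function(heart_type = "infarcted", seed = 7L, ...) {
  phantom_spec(grid_dims_dti = c(48L, 48L, 8L),
               lv_geometry = list(center_mm = NULL, inner_radius_mm = 9,
                                  outer_radius_mm = 17, slices = NULL),
               heart_type = heart_type, seed = seed, ...)
}

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, expr, .fixture_env)
  get(key, envir = .fixture_env)
}

small_heart <- function() cached("small_heart", simulate_heart(small_spec()))

small_heart_processed <- function() {
  cached("small_heart_processed", process_heart(small_heart(), "inf_small"))
}

# SPD tensor field from random rotations of random positive eigenvalues
random_spd_components <- function(n, seed = 1L) {
  set.seed(seed)
  out <- matrix(0, n, 6L)
  for (i in seq_len(n)) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    lam <- sort(runif(3, 0.1e-3, 2e-3), decreasing = TRUE)
    D <- Q %*% diag(lam) %*% t(Q)
    out[i, ] <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  }
  out
}

# wrap a components matrix (n x 6) as a 1 x 1 x n tensor field
as_tensor_field <- function(comp, voxel_dims = c(1, 1, 1)) {
  n <- nrow(comp)
  D <- array(0, c(1, 1, n, 6))
  for (k in 1:6) D[1, 1, , k] <- comp[, k]
  tensor_field(D, array(TRUE, c(1, 1, n)), voxel_dims)
}

diag_tensor <- function(dxx, dyy, dzz) {
  as_tensor_field(matrix(c(dxx, dyy, dzz, 0, 0, 0), 1))
}
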