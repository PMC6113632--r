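# Diffusion acquisition scheme: one b = 0 measurement plus a set of unit
# gradient directions at a single b-value, with FSL-dialect bvec/bval I/O.

#' Construct an acquisition scheme
#'
#' @param b_value diffusion weighting in s/mm^2 (> 0), shared by all
#'   diffusion-weighted directions.
#' @param directions n x 3 matrix of unit gradient direction vectors
#'   (diffusion-weighted only; the scheme always contains exactly one
#'   additional non-diffusion-weighted measurement).
#' @return object of class `acquisition_scheme`.
#' @export
acquisition_scheme <- function(b_value, directions) {
  directions <- as.matrix(directions)
  stopifnot(is.numeric(b_value), length(b_value) == 1L, b_value > 0,
            ncol(directions) == 3L)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("gradient directions must be unit-norm (max deviation ",
         format(max(abs(nrm - 1))), ")")
  if (nrow(directions) < 6L)
    stop("at least 6 non-collinear directions are required")
  kap <- design_condition(design_matrix(directions))
  if (!is.finite(kap) || kap > 1e6)
    stop("gradient directions are collinear; design condition number ",
         format(kap))
  structure(list(b_value = b_value, directions = directions),
            class = "acquisition_scheme")
}

# Full-spectrum condition number (zero singular values give Inf, unlike
# kappa(exact = TRUE), which drops them).
design_condition <- function(X) {
  d <- svd(X, nu = 0, nv = 0)$d
  if (min(d) == 0) Inf else max(d) / min(d)
}

# Quadratic-form design matrix mapping the six unique tensor components
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) to g' D g per direction.
design_matrix <- function(g) {
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

#' Default 30-direction scheme at b = 1000 s/mm^2
#'
#' Loads the packaged table of 30 electrostatically spread unit directions
#' (plus the b = 0 measurement) mirroring a 30-direction cardiac DT-MRI
#' protocol.
#' @return an `acquisition_scheme`.
#' @export
default_gradient_scheme <- function() {
  read_gradient_table(
    system.file("extdata", "scheme30.bvec", package = "bzdti"),
    system.file("extdata", "scheme30.bval", package = "bzdti"))
}

#' Read a gradient table in FSL bvec/bval dialect
#'
#' `bvec` holds three rows (x, y, z components), one column per
#' measurement; `bval` one row of b-values. Zero-b columns mark the
#' non-diffusion-weighted measurement.
#'
#' @param bvec_path,bval_path file paths.
#' @return an `acquisition_scheme`.
#' @export
read_gradient_table <- function(bvec_path, bval_path) {
  if (!file.exists(bvec_path)) stop("bvec file not found: ", bvec_path)
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path)
  bvec <- as.matrix(read.table(bvec_path))
  bval <- as.numeric(unlist(read.table(bval_path)))
  if (nrow(bvec) != 3L) stop("bvec must have 3 rows (x/y/z components)")
  if (ncol(bvec) != length(bval)) stop("bvec and bval lengths differ")
  dw <- bval > 0
  if (sum(!dw) != 1L) stop("expected exactly one b = 0 measurement")
  b <- unique(bval[dw])
  if (length(b) != 1L) stop("a single non-zero b-value is expected")
  acquisition_scheme(b, t(bvec[, dw, drop = FALSE]))
}

#' Write a gradient table in FSL bvec/bval dialect
#' @param scheme an `acquisition_scheme`.
#' @param bvec_path,bval_path output paths.
#' @export
write_gradient_table <- function(scheme, bvec_path, bval_path) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  bvec <- rbind(c(0, scheme$directions[, 1]),
                c(0, scheme$directions[, 2]),
                c(0, scheme$directions[, 3]))
  write.table(format(bvec, digits = 8, scientific = FALSE), bvec_path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  cat(paste(c(0, rep(scheme$b_value, nrow(scheme$directions))),
            collapse = " "), "\n", file = bval_path)
  invisible(c(bvec_path, bval_path))
}

#' @importFrom utils read.table write.table
NULL
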