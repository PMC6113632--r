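# Spatial decorrelation: per-region, per-axis autocorrelation profiles of
# invariant maps, 1/e correlation lengths, and lattice decimation to
# statistically independent samples.

#' Spatial autocorrelation profile along one axis
#'
#' For each lag k, the Pearson correlation over all in-mask voxel pairs
#' separated by k voxels along the axis, after subtracting the region
#' mean. Lags with fewer than 30 pairs are truncated.
#'
#' @param values 3D numeric array (NaN/NA values excluded).
#' @param mask logical region mask.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @param max_lag largest lag to evaluate (default 10).
#' @param min_pairs minimum pair count for a lag to be reported.
#' @return object of class `acf_profile`: `axis`, integer `lags`
#'   (starting at 0), `acf` values in `[-1, 1]` with `acf[lag 0] = 1`,
#'   and `n_pairs`.
#' @export
estimate_acf <- function(values, mask, axis, max_lag = 10L, min_pairs = 30L) {
  d <- dim(values)
  stopifnot(length(d) == 3L, all(dim(mask) == d), axis %in% 1:3)
  ok <- mask & is.finite(values)
  v <- values
  mu <- mean(v[ok])
  s2 <- stats::var(v[ok])
  if (!is.finite(s2) || s2 == 0) stop("degenerate region: zero variance")
  v <- v - mu
  lags <- 0L; acfs <- 1; npairs <- sum(ok)
  for (k in seq_len(max_lag)) {
    sh <- integer(3); sh[axis] <- -k
    v2 <- translate_array(v, sh, fill = 0)
    ok2 <- translate_array(ok, sh, fill = FALSE)
    both <- ok & ok2
    n <- sum(both)
    if (k == 1L && n < 50L)
      stop("fewer than 50 in-mask voxel pairs at lag 1 (", n, ")")
    if (n < min_pairs) break
    a <- v[both]; b <- v2[both]
    r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    lags <- c(lags, k); acfs <- c(acfs, r); npairs <- c(npairs, n)
  }
  structure(list(axis = axis, lags = lags, acf = acfs, n_pairs = npairs),
            class = "acf_profile")
}

#' 1/e autocorrelation length of a profile
#'
#' The first lag at which the profile drops below `1/e`, linearly
#' interpolated between the bracketing lags, then rounded to the nearest
#' integer of at least 1 (rounded values are what decimation uses). If the
#' profile never drops below `1/e` within the available lags, the maximum
#' lag is returned with a warning.
#'
#' @param profile an `acf_profile`.
#' @param rounded if `FALSE`, return the interpolated (unrounded) crossing.
#' @return length in voxels.
#' @export
autocorrelation_length <- function(profile, rounded = TRUE) {
  stopifnot(inherits(profile, "acf_profile"))
  thr <- exp(-1)
  below <- which(profile$acf < thr)
  if (!length(below)) {
    warning("autocorrelation never drops below 1/e within available lags; ",
            "returning the maximum lag")
    return(max(profile$lags))
  }
  i <- below[1]
  if (i == 1L) return(if (rounded) 1L else profile$lags[1])
  l0 <- profile$lags[i - 1L]; l1 <- profile$lags[i]
  a0 <- profile$acf[i - 1L]; a1 <- profile$acf[i]
  x <- l0 + (a0 - thr) / (a0 - a1) * (l1 - l0)
  if (rounded) max(1L, as.integer(round(x))) else x
}

#' Decimate a region to spatially independent samples
#'
#' Keeps in-mask voxels on the lattice anchored at the region bounding-box
#' minimum with the given per-axis strides; non-finite values are dropped.
#'
#' @param values 3D numeric array.
#' @param mask logical region mask.
#' @param strides integer per-axis decimation strides (>= 1), typically
#'   the rounded autocorrelation lengths.
#' @param heart,region,invariant identifiers carried into the output.
#' @return object of class `region_sample_set`: a data frame with columns
#'   `heart`, `region`, `invariant`, `value`, plus attributes `strides`
#'   and `insufficient` (fewer than 10 samples).
#' @export
decimate <- function(values, mask, strides, heart = NA_character_,
                     region = NA_character_, invariant = NA_character_) {
  d <- dim(values)
  strides <- as.integer(strides)
  stopifnot(length(strides) == 3L, all(strides >= 1L), all(dim(mask) == d))
  idx <- which(mask)
  if (!length(idx)) {
    out <- data.frame(heart = character(0), region = character(0),
                      invariant = character(0), value = numeric(0))
    return(structure(out, strides = strides, insufficient = TRUE,
                     class = c("region_sample_set", "data.frame")))
  }
  ai <- arrayInd(idx, d)
  keep <- rep(TRUE, nrow(ai))
  for (a in 1:3) {
    x0 <- min(ai[, a])
    keep <- keep & ((ai[, a] - x0) %% strides[a] == 0L)
  }
  vals <- values[idx[keep]]
  vals <- vals[is.finite(vals)]
  out <- data.frame(heart = rep(heart, length(vals)),
                    region = rep(region, length(vals)),
                    invariant = rep(invariant, length(vals)),
                    value = vals)
  structure(out, strides = strides, insufficient = length(vals) < 10L,
            class = c("region_sample_set", "data.frame"))
}

#' Per-region decimation strides from estimated autocorrelation lengths
#'
#' Estimates the ACF of `values` within `mask` along each axis; the
#' in-plane x and y axes share one length (their unrounded crossings are
#' averaged before rounding), the through-plane axis is rounded
#' separately.
#'
#' @inheritParams estimate_acf
#' @return integer strides `c(x, y, z)` (x and y equal).
#' @export
region_strides <- function(values, mask, max_lag = 10L) {
  cont <- vapply(1:3, function(a) {
    p <- estimate_acf(values, mask, a, max_lag = max_lag)
    suppressWarnings(autocorrelation_length(p, rounded = FALSE))
  }, 0)
  inplane <- max(1L, as.integer(round(mean(cont[1:2]))))
  zlen <- max(1L, as.integer(round(cont[3])))
  c(inplane, inplane, zlen)
}
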