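# Rigid mask-to-mask registration: apex alignment through-plane, then a
# single global in-plane integer shift maximizing the summed 2D
# cross-correlation of binary masks.

#' Construct a rigid integer-voxel shift
#' @param dx,dy in-plane shift in voxels; `dz` in slices.
#' @export
rigid_shift <- function(dx, dy, dz) {
  structure(list(dx = as.integer(dx), dy = as.integer(dy),
                 dz = as.integer(dz)), class = "rigid_shift")
}

# Lowest-index (most apical, by convention) non-empty slice of a mask.
apex_slice <- function(mask, apex_low = TRUE) {
  counts <- apply(mask, 3, sum)
  ne <- which(counts > 0)
  if (!length(ne)) stop("empty mask; cannot locate the apex")
  if (apex_low) min(ne) else max(ne)
}

#' Through-plane alignment by the LV apex
#'
#' Returns `dz`, the apex slice index of `mask_a` minus that of `mask_b`;
#' translating `mask_a` by `-dz` slices aligns the apexes.
#'
#' @param mask_a,mask_b non-empty binary volumes.
#' @param apex_low logical; `TRUE` if the apex lies toward low slice
#'   indices (configuration of the acquisition axis).
#' @return integer slice offset.
#' @export
align_apex <- function(mask_a, mask_b, apex_low = TRUE) {
  apex_slice(mask_a, apex_low) - apex_slice(mask_b, apex_low)
}

#' Global in-plane shift by summed 2D cross-correlation
#'
#' After removing the through-plane offset `dz` from `mask_a`, finds the
#' single integer `(dx, dy)` maximizing the sum over slices of the 2D
#' cross-correlation between corresponding slice masks, i.e. the overlap
#' of `mask_a` with `mask_b` translated by `(dx, dy)`. The search window
#' is a quarter of the grid per axis; exact ties break toward the smallest
#' shift norm, then lexicographically.
#'
#' @param mask_a,mask_b binary volumes on a common grid.
#' @param dz through-plane offset of `mask_a` relative to `mask_b`
#'   (from [align_apex()]).
#' @return named integer vector `c(dx, dy)`.
#' @export
inplane_xcorr_shift <- function(mask_a, mask_b, dz = 0L) {
  d <- dim(mask_a)
  stopifnot(all(d == dim(mask_b)))
  a <- translate_array(mask_a * 1, c(0L, 0L, -as.integer(dz)), 0)
  b <- mask_b * 1
  # summed slice-wise circular cross-correlation via FFT:
  # C(u, v) = sum_z sum_xy a_z(x, y) * b_z(x - u, y - v)
  C <- matrix(0, d[1], d[2])
  for (z in seq_len(d[3])) {
    fa <- fft(a[, , z]); fb <- fft(b[, , z])
    C <- C + Re(fft(fa * Conj(fb), inverse = TRUE)) / (d[1] * d[2])
  }
  win <- pmax(1L, d[1:2] %/% 4L)
  sh <- function(i, n) ifelse(i - 1L > n %/% 2L, i - 1L - n, i - 1L)
  ux <- sh(seq_len(d[1]), d[1]); uy <- sh(seq_len(d[2]), d[2])
  ok <- outer(abs(ux) <= win[1], abs(uy) <= win[2], "&")
  C[!ok] <- -Inf
  best <- max(C)
  if (best <= 0) stop("masks do not overlap at any admissible shift")
  cand <- which(C >= best - 1e-9 * max(1, abs(best)), arr.ind = TRUE)
  dxs <- ux[cand[, 1]]; dys <- uy[cand[, 2]]
  ord <- order(dxs^2 + dys^2, dxs, dys)
  c(dx = dxs[ord[1]], dy = dys[ord[1]])
}

#' Apply a rigid integer translation to a label volume
#'
#' Pure voxel translation: no interpolation of labels; vacated voxels
#' become background.
#'
#' @param labels a [label_volume()].
#' @param shift a [rigid_shift()]; magnitudes must not exceed half the
#'   grid per axis.
#' @return translated [label_volume()].
#' @export
apply_rigid_translation <- function(labels, shift) {
  stopifnot(inherits(labels, "label_volume"), inherits(shift, "rigid_shift"))
  d <- dim(labels$labels)
  s <- c(shift$dx, shift$dy, shift$dz)
  if (any(abs(s) > d %/% 2L))
    stop("shift (", paste(s, collapse = ", "),
         ") exceeds half the grid extent")
  label_volume(translate_array(labels$labels, s, fill = 0L),
               labels$voxel_dims)
}

#' Register an LGE-derived mask to the DTI mask
#'
#' Convenience wrapper: apex alignment for `dz`, then the global in-plane
#' cross-correlation shift. The returned shift moves the LGE frame onto
#' the DTI frame (apply with [apply_rigid_translation()], negated
#' internally already).
#'
#' @param mask_lge,mask_dti binary myocardium masks on the DTI grid.
#' @param apex_low see [align_apex()].
#' @return a [rigid_shift()] to apply to LGE-frame volumes.
#' @export
register_masks <- function(mask_lge, mask_dti, apex_low = TRUE) {
  dz <- align_apex(mask_lge, mask_dti, apex_low = apex_low)
  dxy <- inplane_xcorr_shift(mask_lge, mask_dti, dz = dz)
  rigid_shift(-dxy[["dx"]], -dxy[["dy"]], -dz)
}
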