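# LGE signal-intensity segmentation of remote / border-zone / infarct
# myocardium, down-sampling of label maps to the DTI grid, morphological
# refinement, and the background-ROI SNR estimate.

#' Construct an LGE volume
#' @param si non-negative signal-intensity 3D array (arbitrary units).
#' @param voxel_dims voxel dimensions in mm.
#' @export
lge_volume <- function(si, voxel_dims) {
  stopifnot(length(dim(si)) == 3L, all(is.finite(si)), all(si >= 0))
  structure(list(si = si, voxel_dims = as.numeric(voxel_dims)),
            class = "lge_volume")
}

#' Signal-intensity statistics of remote and infarct seed ROIs
#'
#' @param lge an `lge_volume`.
#' @param remote_roi,infarct_roi disjoint, non-empty logical arrays on the
#'   LGE grid.
#' @return object of class `roi_stats` with per-ROI mean, sample SD and
#'   voxel count.
#' @export
compute_roi_stats <- function(lge, remote_roi, infarct_roi) {
  stopifnot(inherits(lge, "lge_volume"))
  if (!any(remote_roi) || !any(infarct_roi)) stop("empty ROI")
  if (any(remote_roi & infarct_roi)) stop("remote and infarct ROIs overlap")
  rv <- lge$si[remote_roi]; iv <- lge$si[infarct_roi]
  out <- list(mean_remote = mean(rv), sd_remote = sd(rv),
              mean_infarct = mean(iv), sd_infarct = sd(iv),
              n_remote = length(rv), n_infarct = length(iv))
  if (out$mean_infarct <= out$mean_remote)
    stop("infarct ROI mean (", format(out$mean_infarct),
         ") does not exceed remote ROI mean (", format(out$mean_remote),
         "); no hyperenhancement to threshold")
  structure(out, class = "roi_stats")
}

#' Segmentation thresholds from ROI statistics
#'
#' The infarct threshold is halfway between the remote and infarct ROI
#' means; the BZ lower threshold is two remote SDs above the remote mean.
#'
#' @param stats a `roi_stats`.
#' @return object of class `threshold_set` with `t_half` and `t_bz`.
#' @export
derive_thresholds <- function(stats) {
  stopifnot(inherits(stats, "roi_stats"))
  t_half <- (stats$mean_remote + stats$mean_infarct) / 2
  t_bz <- stats$mean_remote + 2 * stats$sd_remote
  if (t_bz >= t_half)
    stop("regions not separable: t_bz (", format(t_bz),
         ") >= t_half (", format(t_half), ")")
  structure(list(t_half = t_half, t_bz = t_bz), class = "threshold_set")
}

#' Threshold classification of myocardium on the LGE grid
#'
#' Within the myocardium mask: `SI >= t_half` is infarct,
#' `t_bz < SI < t_half` is BZ, `SI <= t_bz` is remote; outside the mask is
#' background. Boundary conventions are fixed: the halfway level itself is
#' infarct, the BZ lower level itself is remote.
#'
#' @param lge an `lge_volume`.
#' @param myo_mask logical myocardium mask on the LGE grid.
#' @param thr a `threshold_set`.
#' @return a [label_volume()] on the LGE grid.
#' @export
classify_lge <- function(lge, myo_mask, thr) {
  stopifnot(inherits(lge, "lge_volume"), inherits(thr, "threshold_set"))
  lab <- array(0L, dim(lge$si))
  lab[myo_mask] <- 1L
  lab[myo_mask & lge$si > thr$t_bz] <- 2L
  lab[myo_mask & lge$si >= thr$t_half] <- 3L
  label_volume(lab, lge$voxel_dims)
}

#' Myocardium mask from LGE signal intensity
#'
#' Same construction as [myocardium_mask_from_b0()], on the LGE volume:
#' threshold at a fraction of the 99th SI percentile, keep the largest
#' 6-connected component.
#' @param lge an `lge_volume`.
#' @param threshold_fraction fraction of the 99th percentile.
#' @export
lge_myocardium_mask <- function(lge, threshold_fraction = 0.2) {
  stopifnot(inherits(lge, "lge_volume"))
  if (all(lge$si == 0)) stop("all-zero LGE volume; cannot derive a mask")
  thr <- threshold_fraction * quantile(lge$si, 0.99, names = FALSE)
  mask <- lge$si > thr
  if (!any(mask)) stop("empty LGE myocardium mask at threshold ", format(thr))
  cc <- connected_components_3d(mask)
  sizes <- tabulate(cc[cc > 0L])
  cc == which.max(sizes)
}

#' Down-sample an LGE-grid label map to the DTI grid
#'
#' Each label is converted to a binary indicator volume; indicators are
#' block-averaged in the slice direction to match the slice thickness,
#' then resampled in-plane with bicubic interpolation. Each target voxel
#' takes the label with the largest resampled fraction, ties broken toward
#' the more severe label (infarct > BZ > remote > background).
#'
#' @param labels_lge a [label_volume()] on the LGE grid.
#' @param target_dims DTI grid size; each LGE axis must be an integer
#'   multiple of it.
#' @param target_voxel_dims DTI voxel dimensions in mm.
#' @return a [label_volume()] on the DTI grid.
#' @export
downsample_labels <- function(labels_lge, target_dims, target_voxel_dims) {
  stopifnot(inherits(labels_lge, "label_volume"))
  d <- dim(labels_lge$labels)
  target_dims <- as.integer(target_dims)
  if (any(d %% target_dims != 0L))
    stop("LGE grid (", paste(d, collapse = "x"),
         ") is not an integer multiple of the target grid (",
         paste(target_dims, collapse = "x"), ")")
  fz <- d[3] %/% target_dims[3]
  Wx <- resample_weights_1d(d[1], target_dims[1])
  Wy <- resample_weights_1d(d[2], target_dims[2])
  # fractions per candidate label, ordered by increasing severity so that
  # max.col(ties.method = "last") favours the more severe label
  cand <- c(0L, 1L, 2L, 3L)
  frac <- matrix(0, prod(target_dims), length(cand))
  for (k in seq_along(cand)) {
    ind <- block_average_z(array(as.numeric(labels_lge$labels == cand[k]), d),
                           fz)
    res <- array(0, target_dims)
    for (z in seq_len(target_dims[3]))
      res[, , z] <- Wx %*% ind[, , z] %*% t(Wy)
    frac[, k] <- as.vector(res)
  }
  best <- max.col(frac, ties.method = "last")
  label_volume(array(cand[best], target_dims), target_voxel_dims)
}

#' Morphological refinement of DTI-grid labels
#'
#' Two rules: (1) 6-connected infarct components of three or fewer voxels
#' are relabeled BZ; (2) BZ voxels farther than 3 mm (Euclidean distance
#' in mm) from the nearest surviving infarct voxel are relabeled remote.
#' Idempotent. If no infarct survives, all BZ becomes remote with a
#' warning.
#'
#' @param labels a [label_volume()] on the DTI grid.
#' @param min_island_voxels islands of at most this many voxels are
#'   removed (default 3).
#' @param bz_max_dist_mm BZ pruning distance in mm (default 3).
#' @return a refined [label_volume()].
#' @export
refine_labels <- function(labels, min_island_voxels = 3L, bz_max_dist_mm = 3) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  d <- dim(lab)
  cc <- connected_components_3d(lab == 3L)
  if (any(cc > 0L)) {
    sizes <- tabulate(cc[cc > 0L])
    small <- which(sizes <= min_island_voxels)
    if (length(small)) lab[cc %in% small] <- 2L
  }
  inf_idx <- which(lab == 3L)
  bz_idx <- which(lab == 2L)
  if (!length(inf_idx)) {
    if (length(bz_idx)) {
      warning("no infarct voxels survive refinement; relabeling all BZ as remote")
      lab[bz_idx] <- 1L
    }
  } else if (length(bz_idx)) {
    dmm <- min_dist_mm(arrayInd(bz_idx, d), arrayInd(inf_idx, d),
                       labels$voxel_dims)
    lab[bz_idx[dmm > bz_max_dist_mm]] <- 1L
  }
  label_volume(lab, labels$voxel_dims)
}

#' Signal-to-noise ratio from tissue and background ROIs
#'
#' The tissue ROI mean divided by the SD of an equal-area background ROI.
#'
#' @param volume 3D numeric array.
#' @param tissue_roi,background_roi non-empty logical arrays of equal
#'   voxel count.
#' @return unitless SNR.
#' @export
compute_snr <- function(volume, tissue_roi, background_roi) {
  nt <- sum(tissue_roi); nb <- sum(background_roi)
  if (nt == 0L || nb == 0L) stop("empty ROI")
  if (nt != nb)
    stop("tissue and background ROIs must have equal area (", nt,
         " vs ", nb, " voxels)")
  s <- sd(volume[background_roi])
  if (s == 0) stop("background ROI has zero SD")
  mean(volume[tissue_roi]) / s
}
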