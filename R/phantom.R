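# Synthetic phantom: a left-ventricular annulus with an infarct wedge and
# a surrounding border-zone (BZ) shell, realized as co-registered LGE and
# DWI volumes with known ground-truth labels and tensor statistics.
#
# Region invariant medians default to the pooled ex vivo values the
# pipeline is calibrated against; dispersions, fiber helix angles and the
# latent-field construction are the generator's own choices (see the
# methods vignette).

#' Per-region phantom parameters
#'
#' Signal-intensity and tensor-invariant targets for one tissue region.
#'
#' @param si_mean,si_sd LGE signal intensity mean and SD (arbitrary units).
#' @param adc_median median apparent diffusion coefficient, mm^2/s.
#' @param fa_median median fractional anisotropy, in `[0, 1)`.
#' @param mode_median median tissue mode, in `[-1, 1]`.
#' @param invariant_dispersion relative spread of each invariant around its
#'   median (log-scale SD for ADC, logit-scale spread for FA, absolute SD
#'   for mode).
#' @return object of class `region_params`.
#' @export
region_params <- function(si_mean, si_sd, adc_median, fa_median, mode_median,
                          invariant_dispersion = 0.15) {
  stopifnot(si_sd > 0, adc_median > 0, fa_median >= 0, fa_median < 1,
            mode_median >= -1, mode_median <= 1, invariant_dispersion >= 0)
  structure(list(si_mean = si_mean, si_sd = si_sd, adc_median = adc_median,
                 fa_median = fa_median, mode_median = mode_median,
                 invariant_dispersion = invariant_dispersion),
            class = "region_params")
}

default_region_params <- function() {
  list(
    normal  = region_params(100, 10, 0.563e-3, 0.470, 0.743),
    remote  = region_params(100, 10, 0.573e-3, 0.464, 0.666),
    bz      = region_params(160, 10, 0.647e-3, 0.417, 0.621),
    infarct = region_params(300, 10, 0.797e-3, 0.330, 0.515))
}

#' Full parameterization of the synthetic heart
#'
#' @param grid_dims_dti DTI grid size in voxels.
#' @param voxel_dims_dti DTI voxel dimensions in mm (default 1 x 1 x 3).
#' @param lge_upsampling integer upsampling factors per axis from the DTI
#'   to the LGE grid (default 3 x 3 x 9, giving ~0.33 mm isotropic LGE).
#' @param lv_geometry list: `center_mm` (in-plane annulus center),
#'   `inner_radius_mm`, `outer_radius_mm` (scalar or per-slice), `slices`
#'   (slice indices containing myocardium; the lowest is the apex).
#' @param infarct_wedge list: `theta_center_deg`, `theta_width_deg`,
#'   `transmural_fraction` (wall fraction from the endocardium),
#'   `slices`. A zero angular or transmural extent yields no infarct.
#' @param bz_shell_thickness_mm thickness of the BZ shell around the
#'   infarct, mm (> 0).
#' @param region_params named list of [region_params()] for `normal`,
#'   `remote`, `bz` and `infarct`.
#' @param fiber_model list: `helix_endo_deg`, `helix_epi_deg`, linearly
#'   interpolated across the wall (degrees, in `[-90, 90]`).
#' @param correlation_lengths named list (per region) of 1/e
#'   autocorrelation lengths in voxels per axis.
#' @param s0 non-diffusion-weighted signal level.
#' @param dwi_snr,lge_snr signal-to-noise ratios of the simulated DWI b = 0
#'   and LGE volumes (`Inf` for noiseless).
#' @param rigid_offset_mm 3-vector; rigid shift applied to the LGE frame,
#'   to be recovered by registration.
#' @param heart_type `"infarcted"` or `"normal"` (a normal heart has no
#'   wedge and its myocardium uses the `normal` region parameters).
#' @param seed integer seed driving all phantom randomness.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims_dti = c(96L, 96L, 16L),
                         voxel_dims_dti = c(1, 1, 3),
                         lge_upsampling = c(3L, 3L, 9L),
                         lv_geometry = list(center_mm = NULL,
                                            inner_radius_mm = 18,
                                            outer_radius_mm = 32,
                                            slices = NULL),
                         infarct_wedge = list(theta_center_deg = 270,
                                              theta_width_deg = 90,
                                              transmural_fraction = 0.65,
                                              slices = NULL),
                         bz_shell_thickness_mm = 3,
                         region_params = default_region_params(),
                         fiber_model = list(helix_endo_deg = 60,
                                            helix_epi_deg = -60),
                         correlation_lengths = list(normal = c(3, 3, 2),
                                                    remote = c(3, 3, 2),
                                                    bz = c(1, 1, 1),
                                                    infarct = c(2, 2, 1)),
                         s0 = 100, dwi_snr = 59, lge_snr = 10,
                         rigid_offset_mm = c(2, -1, 3),
                         heart_type = c("infarcted", "normal"),
                         seed = 1L) {
  heart_type <- match.arg(heart_type)
  grid_dims_dti <- as.integer(grid_dims_dti)
  lge_upsampling <- as.integer(lge_upsampling)
  if (is.null(lv_geometry$center_mm))
    lv_geometry$center_mm <- grid_dims_dti[1:2] * voxel_dims_dti[1:2] / 2
  if (is.null(lv_geometry$slices)) {
    nz <- grid_dims_dti[3]
    # leave two empty slices below the apex (headroom for through-plane
    # registration shifts) and one above the base
    lv_geometry$slices <- if (nz >= 6) 3:(nz - 1L) else seq_len(nz)
  }
  if (is.null(infarct_wedge$slices)) {
    s <- lv_geometry$slices
    infarct_wedge$slices <- if (length(s) >= 3) s[-c(1L, length(s))] else s
  }
  if (heart_type == "normal") infarct_wedge$theta_width_deg <- 0
  spec <- structure(list(
    grid_dims_dti = grid_dims_dti, voxel_dims_dti = voxel_dims_dti,
    lge_upsampling = lge_upsampling, lv_geometry = lv_geometry,
    infarct_wedge = infarct_wedge,
    bz_shell_thickness_mm = bz_shell_thickness_mm,
    region_params = region_params, fiber_model = fiber_model,
    correlation_lengths = correlation_lengths, s0 = s0,
    dwi_snr = dwi_snr, lge_snr = lge_snr,
    rigid_offset_mm = rigid_offset_mm, heart_type = heart_type,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(spec$lge_upsampling < 1L)) stop("upsampling factors must be >= 1")
  g <- spec$lv_geometry
  if (any(g$inner_radius_mm >= g$outer_radius_mm))
    stop("inner radius must be smaller than outer radius")
  if (spec$bz_shell_thickness_mm <= 0) stop("bz_shell_thickness_mm must be > 0")
  need <- c("normal", "remote", "bz", "infarct")
  if (!all(need %in% names(spec$region_params)))
    stop("region_params must contain all of: ", paste(need, collapse = ", "))
  fm <- spec$fiber_model
  if (abs(fm$helix_endo_deg) > 90 || abs(fm$helix_epi_deg) > 90)
    stop("helix angles must lie in [-90, 90] degrees")
  invisible(spec)
}

#' Construct a label volume
#'
#' Integer tissue labels on a stated grid: 0 background, 1 remote,
#' 2 border zone, 3 infarct.
#' @param labels integer 3D array with values in `{0, 1, 2, 3}`.
#' @param voxel_dims voxel dimensions in mm.
#' @export
label_volume <- function(labels, voxel_dims) {
  stopifnot(length(dim(labels)) == 3L, all(labels %in% 0:3),
            length(voxel_dims) == 3L)
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 voxel_dims = as.numeric(voxel_dims)),
            class = "label_volume")
}

# Per-slice annulus parameters expanded to the full slice range.
annulus_slices <- function(spec) {
  g <- spec$lv_geometry
  ns <- length(g$slices)
  list(slices = g$slices,
       ri = rep_len(g$inner_radius_mm, ns),
       ro = rep_len(g$outer_radius_mm, ns))
}

#' Ground-truth labels of the synthetic heart on the DTI grid
#'
#' Builds the LV annulus (remote), the infarct wedge and the BZ shell
#' (myocardium within `bz_shell_thickness_mm` of the infarct, Euclidean
#' distance in mm). Deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @return a [label_volume()] on the DTI grid.
#' @export
build_label_geometry <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$grid_dims_dti; vd <- spec$voxel_dims_dti
  ctr <- spec$lv_geometry$center_mm
  ann <- annulus_slices(spec)
  w <- spec$infarct_wedge
  bad <- setdiff(w$slices, ann$slices)
  if (w$theta_width_deg > 0 && w$transmural_fraction > 0 && length(bad))
    stop("infarct wedge lies outside the annulus at slice ", bad[1])

  co <- grid_coords_mm(d, vd)
  dx <- co$x - ctr[1]; dy <- co$y - ctr[2]
  r2d <- sqrt(outer(dx^2, dy^2, "+"))
  theta <- atan2(matrix(dy, d[1], d[2], byrow = TRUE),
                 matrix(dx, d[1], d[2])) * 180 / pi
  dtheta <- abs(((theta - w$theta_center_deg + 180) %% 360) - 180)

  labels <- array(0L, d)
  for (k in seq_along(ann$slices)) {
    z <- ann$slices[k]
    myo <- r2d >= ann$ri[k] & r2d <= ann$ro[k]
    sl <- ifelse(myo, 1L, 0L)
    if (w$theta_width_deg > 0 && w$transmural_fraction > 0 &&
        z %in% w$slices) {
      rmax <- ann$ri[k] + w$transmural_fraction * (ann$ro[k] - ann$ri[k])
      inf <- myo & dtheta <= w$theta_width_deg / 2 & r2d <= rmax
      sl[inf] <- 3L
    }
    labels[, , z] <- sl
  }

  inf_idx <- which(labels == 3L)
  if (length(inf_idx)) {
    inf_co <- arrayInd(inf_idx, d)
    cand <- which(labels == 1L)
    cand_co <- arrayInd(cand, d)
    # restrict to the infarct bounding box padded by the shell thickness
    pad <- ceiling(spec$bz_shell_thickness_mm / vd) + 1L
    keep <- rep(TRUE, nrow(cand_co))
    for (a in 1:3)
      keep <- keep & cand_co[, a] >= min(inf_co[, a]) - pad[a] &
                     cand_co[, a] <= max(inf_co[, a]) + pad[a]
    cand <- cand[keep]; cand_co <- cand_co[keep, , drop = FALSE]
    if (length(cand)) {
      dmm <- min_dist_mm(cand_co, inf_co, vd)
      labels[cand[dmm <= spec$bz_shell_thickness_mm]] <- 2L
    }
  }
  label_volume(labels, vd)
}

# Region name for a ground-truth label given the heart type.
label_region_name <- function(lab, heart_type) {
  if (heart_type == "normal" && lab == 1L) return("normal")
  c("remote", "bz", "infarct")[lab]
}

# Smoothed, re-standardized latent Gaussian field: unit marginal variance
# with the region's 1/e autocorrelation length per axis (sigma = L/2;
# lengths <= 1 stay white).
latent_field <- function(dims, lengths) {
  z <- array(rnorm(prod(dims)), dims)
  sigma <- ifelse(lengths > 1, lengths / 2, 0)
  if (any(sigma > 0)) {
    z <- gaussian_smooth_3d(z, sigma)
    z <- z / smoothing_sd_factor(sigma)
  }
  z
}

#' Sample a ground-truth diffusion tensor field
#'
#' Draws per-voxel invariants from each region's distribution (log-normal
#' ADC, logit-normal FA, clamped-normal mode; medians equal the region
#' medians), imposes the spec's spatial autocorrelation by smoothing the
#' latent Gaussian fields, maps the invariants to eigenvalues and orients
#' the principal eigenvector along a transmurally interpolated helix angle
#' (secondary eigenvector in-plane, tertiary radial). Seeded and
#' reproducible.
#'
#' @param labels a [label_volume()] from [build_label_geometry()].
#' @param spec the generating [phantom_spec()].
#' @return object of class `tensor_field` (see [fit_tensor_lls()]).
#' @export
sample_tensor_field <- function(labels, spec) {
  stopifnot(inherits(labels, "label_volume"))
  validate_phantom_spec(spec)
  d <- dim(labels$labels); vd <- labels$voxel_dims
  mask <- labels$labels > 0L
  idx <- which(mask)
  lab <- labels$labels[idx]

  inv <- with_seed(derive_seed(spec$seed, "tensor"), {
    adc <- fa <- mode <- numeric(length(idx))
    for (lv in sort(unique(lab))) {
      rg <- label_region_name(lv, spec$heart_type)
      rp <- spec$region_params[[rg]]
      cl <- spec$correlation_lengths[[rg]] %||% c(1, 1, 1)
      sel <- lab == lv
      vox <- idx[sel]
      zf <- list(adc = latent_field(d, cl), fa = latent_field(d, cl),
                 mode = latent_field(d, cl))
      disp <- rp$invariant_dispersion
      adc[sel] <- exp(log(rp$adc_median) + disp * zf$adc[vox])
      fa[sel] <- stats::plogis(stats::qlogis(max(rp$fa_median, 1e-6)) +
                               disp / (1 - rp$fa_median) * zf$fa[vox])
      mode[sel] <- pmin(pmax(rp$mode_median + disp * zf$mode[vox], -1), 1)
    }
    list(adc = adc, fa = fa, mode = mode)
  })

  ev <- invariants_to_eigenvalues(inv$adc, inv$fa, inv$mode)

  # transmural fiber orientation
  ai <- arrayInd(idx, d)
  co <- grid_coords_mm(d, vd)
  ctr <- spec$lv_geometry$center_mm
  px <- co$x[ai[, 1]] - ctr[1]; py <- co$y[ai[, 2]] - ctr[2]
  r <- sqrt(px^2 + py^2)
  ann <- annulus_slices(spec)
  ri <- ann$ri[match(ai[, 3], ann$slices)]
  ro <- ann$ro[match(ai[, 3], ann$slices)]
  tw <- pmin(pmax((r - ri) / (ro - ri), 0), 1)
  fm <- spec$fiber_model
  alpha <- (fm$helix_endo_deg + tw * (fm$helix_epi_deg - fm$helix_endo_deg)) *
    pi / 180
  phi <- atan2(py, px)
  # circumferential, radial and longitudinal unit vectors
  cx <- -sin(phi); cy <- cos(phi)
  e1 <- cbind(cos(alpha) * cx, cos(alpha) * cy, sin(alpha))
  e3 <- cbind(cos(phi), sin(phi), 0)             # radial
  e2 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
              e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
              e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1])

  comp <- function(u, v) ev[, 1] * e1[, u] * e1[, v] +
    ev[, 2] * e2[, u] * e2[, v] + ev[, 3] * e3[, u] * e3[, v]
  D <- array(0, c(d, 6L))
  put <- function(k, v) { a <- array(0, d); a[idx] <- v; D[, , , k] <<- a }
  put(1L, comp(1, 1)); put(2L, comp(2, 2)); put(3L, comp(3, 3))
  put(4L, comp(1, 2)); put(5L, comp(1, 3)); put(6L, comp(2, 3))

  tensor_field(D, mask, vd)
}

#' Construct a tensor field
#' @param D 4D array `dims x 6` of unique components in the order
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz (mm^2/s).
#' @param mask logical validity mask.
#' @param voxel_dims voxel dimensions in mm.
#' @export
tensor_field <- function(D, mask, voxel_dims) {
  stopifnot(length(dim(D)) == 4L, dim(D)[4] == 6L,
            all(dim(mask) == dim(D)[1:3]))
  structure(list(D = D, mask = mask, voxel_dims = as.numeric(voxel_dims)),
            class = "tensor_field")
}

#' Simulate a diffusion-weighted image stack
#'
#' Applies the single-tensor forward model `S_i = s0 * exp(-b g_i' D g_i)`
#' per voxel and direction, then Rician noise
#' `sqrt((S_i + n1)^2 + n2^2)` with `n ~ Normal(0, s0/snr)`. Background
#' voxels carry pure noise. The b = 0 volume receives the same noise model.
#'
#' @param tensors a `tensor_field`.
#' @param scheme an [acquisition_scheme()].
#' @param s0 non-diffusion-weighted signal.
#' @param snr signal-to-noise ratio (`Inf` for noiseless).
#' @param seed integer seed (`NULL` for the current RNG stream).
#' @return object of class `dwi_stack`: `s0_volume`, 4D `dwi` (one volume
#'   per direction) and `voxel_dims`.
#' @export
simulate_dwi <- function(tensors, scheme, s0 = 100, snr = Inf, seed = NULL) {
  stopifnot(inherits(tensors, "tensor_field"),
            inherits(scheme, "acquisition_scheme"))
  if (!(snr > 0)) stop("snr must be positive (use Inf for noiseless)")
  g <- scheme$directions
  nrm <- sqrt(rowSums(g^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("non-unit gradient direction")
  d <- dim(tensors$D)[1:3]
  nd <- nrow(g)
  m <- matrix(tensors$D, ncol = 6L)
  X <- design_matrix(g)                         # nd x 6
  Q <- m %*% t(X)                               # nvox x nd quadratic forms
  S <- s0 * exp(-scheme$b_value * Q)
  bg <- !tensors$mask
  S[bg, ] <- 0
  s0v <- ifelse(tensors$mask, s0, 0)
  with_seed(seed, {
    if (is.finite(snr)) {
      sig <- s0 / snr
      S <- sqrt((S + rnorm(length(S), 0, sig))^2 +
                rnorm(length(S), 0, sig)^2)
      s0v <- sqrt((s0v + rnorm(length(s0v), 0, sig))^2 +
                  rnorm(length(s0v), 0, sig)^2)
    }
    structure(list(s0_volume = array(s0v, d),
                   dwi = array(S, c(d, nd)),
                   voxel_dims = tensors$voxel_dims),
              class = "dwi_stack")
  })
}

#' Nearest-neighbour upsampling of labels to the LGE grid
#' @param labels a [label_volume()] on the DTI grid.
#' @param factors integer upsampling factors per axis.
#' @param voxel_dims_out voxel dimensions (mm) of the upsampled grid;
#'   defaults to the input dimensions divided by `factors`.
#' @export
upsample_labels_nn <- function(labels, factors,
                               voxel_dims_out = labels$voxel_dims / factors) {
  stopifnot(inherits(labels, "label_volume"), all(factors >= 1L))
  d <- dim(labels$labels)
  f <- as.integer(factors)
  up <- labels$labels[rep(seq_len(d[1]), each = f[1]),
                      rep(seq_len(d[2]), each = f[2]),
                      rep(seq_len(d[3]), each = f[3])]
  label_volume(up, voxel_dims_out)
}

#' Simulate a late gadolinium enhancement volume
#'
#' Each myocardial voxel draws signal intensity from its region's normal
#' distribution (`si_mean`, `si_sd`); the BZ mean sits strictly between
#' the remote and infarct means. Background voxels carry Rician pure noise
#' with `sigma = si_mean(remote) / lge_snr`. The whole frame (labels and
#' signal together) is rigidly translated by `spec$rigid_offset_mm`,
#' rounded to LGE voxels, which registration later recovers.
#'
#' @param labels_highres a [label_volume()] on the LGE grid
#'   (nearest-neighbour upsampled, see [upsample_labels_nn()]).
#' @param spec the generating [phantom_spec()].
#' @param seed integer seed; defaults to a stream derived from `spec$seed`.
#' @return object of class `lge_volume`: `si`, `voxel_dims`, and `labels`
#'   (the translated ground-truth labels in the LGE frame, for ROI seeding
#'   and QC only).
#' @export
simulate_lge <- function(labels_highres, spec,
                         seed = derive_seed(spec$seed, "lge")) {
  stopifnot(inherits(labels_highres, "label_volume"))
  validate_phantom_spec(spec)
  rp <- spec$region_params
  bzm <- rp$bz$si_mean
  if (!(bzm > rp$remote$si_mean && bzm < rp$infarct$si_mean))
    stop("BZ signal-intensity mean must lie strictly between remote and infarct")
  vd <- labels_highres$voxel_dims
  shift <- round(spec$rigid_offset_mm / vd)
  lab <- translate_array(labels_highres$labels, shift, fill = 0L)
  d <- dim(lab)
  with_seed(seed, {
    si <- array(0, d)
    bg <- lab == 0L
    if (is.finite(spec$lge_snr)) {
      base <- if (spec$heart_type == "normal") rp$normal else rp$remote
      sig <- base$si_mean / spec$lge_snr
      nbg <- sum(bg)
      si[bg] <- sqrt(rnorm(nbg, 0, sig)^2 + rnorm(nbg, 0, sig)^2)
    }
    for (lv in 1:3) {
      sel <- lab == lv
      if (!any(sel)) next
      p <- rp[[label_region_name(lv, spec$heart_type)]]
      si[sel] <- pmax(rnorm(sum(sel), p$si_mean, p$si_sd), 0)
    }
    structure(list(si = si, voxel_dims = vd,
                   labels = label_volume(lab, vd)),
              class = "lge_volume")
  })
}

#' Ground-truth-derived ROI seeds in the LGE frame
#'
#' Erodes the remote and infarct label masks by one voxel, mimicking
#' conservatively drawn regions of interest used for signal-intensity
#' statistics.
#' @param labels_lge_frame a [label_volume()] in the (translated) LGE frame.
#' @return list of logical arrays `remote` and `infarct`.
#' @export
phantom_roi_seeds <- function(labels_lge_frame) {
  stopifnot(inherits(labels_lge_frame, "label_volume"))
  lab <- labels_lge_frame$labels
  list(remote = erode_mask_3d(lab == 1L),
       infarct = erode_mask_3d(lab == 3L))
}
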