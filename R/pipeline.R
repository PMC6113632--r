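# End-to-end study orchestration: phantom generation, tensor fitting,
# invariant maps, LGE segmentation, registration, decorrelation and the
# pooled bootstrap statistics, mirroring the per-heart-then-pool design
# of the ex vivo analysis.

#' Simulate one synthetic heart
#'
#' Generates ground-truth labels, the tensor field, the DWI stack and the
#' LGE volume (with its rigid offset) from one [phantom_spec()].
#'
#' @param spec a [phantom_spec()].
#' @param scheme an [acquisition_scheme()] (default packaged 30-direction
#'   scheme).
#' @return list: `spec`, `labels_gt` (DTI grid), `tensors`, `dwi`, `lge`.
#' @export
simulate_heart <- function(spec, scheme = default_gradient_scheme()) {
  labels_gt <- build_label_geometry(spec)
  tensors <- sample_tensor_field(labels_gt, spec)
  dwi <- simulate_dwi(tensors, scheme, s0 = spec$s0, snr = spec$dwi_snr,
                      seed = derive_seed(spec$seed, "dwi"))
  hi <- upsample_labels_nn(labels_gt, spec$lge_upsampling)
  lge <- simulate_lge(hi, spec)
  list(spec = spec, labels_gt = labels_gt, tensors = tensors,
       dwi = dwi, lge = lge)
}

# Equal-area tissue/background ROIs on five equally spaced slices for the
# background-SD SNR estimate.
snr_rois <- function(intensity, tissue_mask, n_slices = 5L) {
  d <- dim(intensity)
  ne <- which(apply(tissue_mask, 3, any))
  sl <- unique(round(seq(min(ne), max(ne), length.out = min(n_slices,
                                                            length(ne)))))
  tis <- bgd <- array(FALSE, d)
  for (z in sl) {
    t_idx <- which(tissue_mask[, , z])
    b_idx <- which(!tissue_mask[, , z])
    n <- min(length(t_idx), length(b_idx))
    # corner-most background voxels sit farthest from tissue
    tis[, , z][t_idx[seq_len(n)]] <- TRUE
    bgd[, , z][b_idx[order(-abs(b_idx - median(b_idx)))][seq_len(n)]] <- TRUE
  }
  list(tissue = tis, background = bgd)
}

# Decorrelate one invariant map within one region; falls back to unit
# strides when the region is too small for ACF estimation.
decorrelate_region <- function(values, mask, heart, region, invariant,
                               max_lag = 10L) {
  strides <- tryCatch(region_strides(values, mask, max_lag = max_lag),
                      error = function(e) c(1L, 1L, 1L))
  decimate(values, mask, strides, heart = heart, region = region,
           invariant = invariant)
}

#' Process one simulated heart through the full pipeline
#'
#' Tensor fit, invariant maps, then (for infarcted hearts) the LGE chain:
#' seed-ROI statistics, thresholds, classification, down-sampling,
#' apex + cross-correlation registration, refinement. Ground-truth labels
#' are never consumed outside the phantom's own seed ROIs and QC. Each
#' labeled region of each invariant map is decorrelated by its estimated
#' autocorrelation lengths. Normal hearts contribute a single `normal`
#' region covering the b0-derived myocardium mask.
#'
#' @param heart list from [simulate_heart()].
#' @param heart_id identifier carried into the sample sets.
#' @param scheme the [acquisition_scheme()] used for the DWI.
#' @return list: `samples` (pooled [decimate()] output across regions and
#'   invariants), `labels` (final DTI-grid labels), `qc` (SNRs,
#'   registration shift, thresholds, strides).
#' @export
process_heart <- function(heart, heart_id, scheme = default_gradient_scheme()) {
  spec <- heart$spec
  myo_dti <- myocardium_mask_from_b0(heart$dwi)
  tensors <- fit_tensor_lls(heart$dwi, scheme, mask = myo_dti)
  inv <- compute_invariants(tensors)
  qc <- list()
  rois <- snr_rois(heart$dwi$s0_volume, myo_dti)
  qc$snr_dwi <- compute_snr(heart$dwi$s0_volume, rois$tissue, rois$background)

  if (spec$heart_type == "normal") {
    labels <- label_volume(array(ifelse(myo_dti, 1L, 0L),
                                 dim(myo_dti)), spec$voxel_dims_dti)
    region_names <- c(`1` = "normal")
  } else {
    seeds <- phantom_roi_seeds(heart$lge$labels)
    stats <- compute_roi_stats(heart$lge, seeds$remote, seeds$infarct)
    thr <- derive_thresholds(stats)
    myo_lge <- lge_myocardium_mask(heart$lge)
    lrois <- snr_rois(heart$lge$si, myo_lge)
    qc$snr_lge <- compute_snr(heart$lge$si, lrois$tissue, lrois$background)
    labs_lge <- classify_lge(heart$lge, myo_lge, thr)
    labs_ds <- downsample_labels(labs_lge, spec$grid_dims_dti,
                                 spec$voxel_dims_dti)
    shift <- register_masks(labs_ds$labels > 0L, myo_dti)
    reg <- apply_rigid_translation(labs_ds, shift)
    lab <- array(0L, dim(myo_dti))
    lab[myo_dti] <- 1L
    take <- myo_dti & reg$labels > 0L
    lab[take] <- reg$labels[take]
    labels <- refine_labels(label_volume(lab, spec$voxel_dims_dti))
    region_names <- c(`1` = "remote", `2` = "bz", `3` = "infarct")
    qc$thresholds <- thr
    qc$shift <- shift
    qc$shift_mm <- c(shift$dx, shift$dy, shift$dz) * spec$voxel_dims_dti
  }

  samples <- list(); strides_qc <- list()
  for (lv in names(region_names)) {
    rmask <- labels$labels == as.integer(lv)
    if (sum(rmask) < 10L) next
    for (iv in c("adc", "fa", "mode")) {
      ss <- decorrelate_region(inv[[iv]], rmask & inv$mask,
                               heart = heart_id,
                               region = region_names[[lv]], invariant = iv)
      strides_qc[[paste(region_names[[lv]], iv, sep = ".")]] <-
        attr(ss, "strides")
      samples[[length(samples) + 1L]] <- ss
    }
  }
  qc$strides <- strides_qc
  list(samples = do.call(rbind, samples), labels = labels, qc = qc)
}

#' Run configuration for a synthetic study
#'
#' @param n_infarcted,n_normal numbers of synthetic hearts per group.
#' @param grid_dims_dti,voxel_dims_dti phantom grid (shared by all hearts).
#' @param spec_overrides named list of additional [phantom_spec()]
#'   arguments applied to every heart.
#' @param bootstrap a [bootstrap_config()]; its seed is derived from
#'   `seed` when unset.
#' @param seed root seed; every heart and every bootstrap draws from a
#'   stream derived from it.
#' @param out_dir optional output directory for the serialized report.
#' @export
run_config <- function(n_infarcted = 7L, n_normal = 7L,
                       grid_dims_dti = c(96L, 96L, 16L),
                       voxel_dims_dti = c(1, 1, 3),
                       spec_overrides = list(),
                       bootstrap = bootstrap_config(),
                       seed = 1L, out_dir = NULL) {
  structure(list(n_infarcted = as.integer(n_infarcted),
                 n_normal = as.integer(n_normal),
                 grid_dims_dti = grid_dims_dti,
                 voxel_dims_dti = voxel_dims_dti,
                 spec_overrides = spec_overrides, bootstrap = bootstrap,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# Phantom spec for heart i of a study; rigid offsets vary per heart.
study_heart_spec <- function(config, i, heart_type) {
  hseed <- derive_seed(config$seed, paste0(heart_type, i))
  offset <- with_seed(derive_seed(hseed, "offset"), {
    c(sample(-2:2, 2, replace = TRUE) * config$voxel_dims_dti[1:2],
      sample(-1:1, 1) * config$voxel_dims_dti[3])
  })
  args <- c(list(grid_dims_dti = config$grid_dims_dti,
                 voxel_dims_dti = config$voxel_dims_dti,
                 heart_type = heart_type, seed = hseed,
                 rigid_offset_mm = offset),
            config$spec_overrides)
  do.call(phantom_spec, args[!duplicated(names(args))])
}

#' Run the full synthetic study
#'
#' Simulates and processes `n_normal` normal and `n_infarcted` infarcted
#' hearts independently, pools the decorrelated samples, and computes the
#' pooled bootstrapped median CIs per region and invariant, the bootstrap
#' repeated-measures ANOVA across remote/BZ/infarct per invariant, and
#' the normal-vs-remote two-group comparison per invariant. Fully
#' reproducible from the config seed.
#'
#' @param config a [run_config()].
#' @param scheme an [acquisition_scheme()].
#' @param progress print per-heart progress to stderr.
#' @return object of class `study_report`: `samples`, `median_table`,
#'   `anova`, `two_group`, `qc`, `config`.
#' @export
run_pipeline <- function(config = run_config(),
                         scheme = default_gradient_scheme(),
                         progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  all_samples <- list(); qc <- list()
  for (grp in c("normal", "infarcted")) {
    n <- if (grp == "normal") config$n_normal else config$n_infarcted
    for (i in seq_len(n)) {
      id <- paste0(grp, "_", i)
      if (progress) message("processing ", id)
      res <- tryCatch({
        spec <- study_heart_spec(config, i, grp)
        process_heart(simulate_heart(spec, scheme), id, scheme)
      }, error = function(e)
        stop("pipeline failed for heart ", id, ": ", conditionMessage(e),
             call. = FALSE))
      all_samples[[id]] <- res$samples
      qc[[id]] <- res$qc
    }
  }
  samples <- do.call(rbind, all_samples)
  rownames(samples) <- NULL
  cfg <- config$bootstrap
  if (is.null(cfg$seed)) cfg$seed <- derive_seed(config$seed, "bootstrap")

  regions <- c("normal", "remote", "bz", "infarct")
  invariants <- c("adc", "fa", "mode")
  rows <- list()
  for (rg in regions) for (iv in invariants) {
    v <- samples$value[samples$region == rg & samples$invariant == iv]
    if (length(v) < 10L) next
    ci <- bootstrap_median_ci(v, cfg)
    rows[[length(rows) + 1L]] <- data.frame(
      region = rg, invariant = iv, median = ci$median, lo = ci$lo,
      hi = ci$hi, n = ci$n)
  }
  median_table <- do.call(rbind, rows)

  anova <- list(); two_group <- list()
  inf_samples <- samples[samples$region %in% c("remote", "bz", "infarct"), ]
  for (iv in invariants) {
    sub <- inf_samples[inf_samples$invariant == iv, ]
    anova[[iv]] <- tryCatch(bootstrap_rm_anova(sub, cfg),
                            error = function(e) e)
    a <- samples$value[samples$region == "normal" & samples$invariant == iv]
    b <- samples$value[samples$region == "remote" & samples$invariant == iv]
    two_group[[iv]] <- if (length(a) >= 10L && length(b) >= 10L)
      bootstrap_two_group(a, b, cfg) else NULL
  }

  report <- structure(list(samples = samples, median_table = median_table,
                           anova = anova, two_group = two_group, qc = qc,
                           config = config), class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' Serialize a study report
#'
#' Writes the decorrelated samples and the median table as CSV and the
#' test results, QC and configuration as JSON.
#' @param report a `study_report`.
#' @param out_dir output directory (created if needed).
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$samples, file.path(out_dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(report$median_table, file.path(out_dir, "median_table.csv"),
                   row.names = FALSE)
  strip <- function(x) {
    if (inherits(x, "condition")) return(list(error = conditionMessage(x)))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(list(anova = strip(report$anova),
                            two_group = strip(report$two_group),
                            qc = strip(report$qc)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Write a small phantom fixture set
#'
#' Generates one small infarcted heart, writing the DWI stack, LGE volume,
#' ground-truth labels and ROI seeds as NIfTI-1, the gradient table as
#' bvec/bval text, and the generating spec as JSON so fixtures can be
#' regenerated and validated.
#'
#' @param output_dir writable directory.
#' @param seed integer seed.
#' @param grid_dims_dti fixture grid (default 64 x 64 x 8).
#' @return (invisibly) the list of written paths.
#' @export
make_fixture_suite <- function(output_dir, seed = 1L,
                               grid_dims_dti = c(64L, 64L, 8L)) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  L <- min(grid_dims_dti[1:2]) # annulus scaled to the in-plane extent (1 mm voxels)
  spec <- phantom_spec(grid_dims_dti = grid_dims_dti,
                       lv_geometry = list(center_mm = NULL,
                                          inner_radius_mm = 0.19 * L,
                                          outer_radius_mm = 0.345 * L,
                                          slices = NULL),
                       seed = seed)
  scheme <- default_gradient_scheme()
  heart <- simulate_heart(spec, scheme)
  p <- function(f) file.path(output_dir, f)
  paths <- c(
    dwi = p("dwi.nii.gz"), s0 = p("b0.nii.gz"), lge = p("lge.nii.gz"),
    labels = p("labels_gt.nii.gz"), roi_remote = p("roi_remote.nii.gz"),
    roi_infarct = p("roi_infarct.nii.gz"),
    bvec = p("scheme.bvec"), bval = p("scheme.bval"), spec = p("spec.json"))
  write_volume(heart$dwi$dwi, paths["dwi"], spec$voxel_dims_dti)
  write_volume(heart$dwi$s0_volume, paths["s0"], spec$voxel_dims_dti)
  write_volume(heart$lge$si, paths["lge"], heart$lge$voxel_dims)
  write_volume(heart$labels_gt$labels, paths["labels"], spec$voxel_dims_dti)
  seeds <- phantom_roi_seeds(heart$lge$labels)
  write_volume(seeds$remote * 1L, paths["roi_remote"], heart$lge$voxel_dims)
  write_volume(seeds$infarct * 1L, paths["roi_infarct"], heart$lge$voxel_dims)
  write_gradient_table(scheme, paths["bvec"], paths["bval"])
  jsonlite::write_json(phantom_spec_to_list(spec), paths["spec"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Serialize a phantom spec to a plain list (for JSON round-tripping)
#' @param spec a [phantom_spec()].
#' @export
phantom_spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$region_params <- lapply(spec$region_params, unclass)
  out
}

#' Rebuild a phantom spec from its serialized list form
#' @param x list as produced by [phantom_spec_to_list()] (or parsed JSON).
#' @export
phantom_spec_from_list <- function(x) {
  x$region_params <- lapply(x$region_params, function(p)
    do.call(region_params, p))
  x$lv_geometry <- lapply(x$lv_geometry, unlist)
  x$infarct_wedge <- lapply(x$infarct_wedge, unlist)
  x$fiber_model <- lapply(x$fiber_model, unlist)
  x$correlation_lengths <- lapply(x$correlation_lengths, unlist)
  for (f in c("grid_dims_dti", "voxel_dims_dti", "lge_upsampling",
              "rigid_offset_mm"))
    x[[f]] <- unlist(x[[f]])
  do.call(phantom_spec, x)
}
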