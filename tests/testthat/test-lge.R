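# LGE segmentation: ROI statistics, thresholds, classification,
# down-sampling, morphological refinement and SNR.

si_volume <- function(values) {
  lge_volume(array(values, c(length(values), 1, 1)), c(1, 1, 1))
}

test_that("ROI statistics use sample SD and guard ordering", {
  v <- lge_volume(array(c(95, 100, 105, 295, 300, 305), c(6, 1, 1)),
                  c(1, 1, 1))
  rroi <- array(c(rep(TRUE, 3), rep(FALSE, 3)), c(6, 1, 1))
  iroi <- array(c(rep(FALSE, 3), rep(TRUE, 3)), c(6, 1, 1))
  st <- compute_roi_stats(v, rroi, iroi)
  expect_equal(st$mean_remote, 100)
  expect_equal(st$mean_infarct, 300)
  expect_equal(st$sd_remote, 5)
  expect_equal(st$sd_infarct, 5)

  v2 <- lge_volume(array(c(100, 100, 100, 295, 300, 305), c(6, 1, 1)),
                   c(1, 1, 1))
  stc <- compute_roi_stats(v2, rroi, iroi)
  expect_equal(stc$mean_remote, 100)
  expect_equal(stc$sd_remote, 0)

  expect_error(compute_roi_stats(v, rroi, rroi), "overlap")
  expect_error(compute_roi_stats(v, iroi, rroi), "hyperenhancement")
})

test_that("thresholds follow the halfway and two-SD rules", {
  st <- structure(list(mean_remote = 100, sd_remote = 5, mean_infarct = 300,
                       sd_infarct = 5, n_remote = 50, n_infarct = 50),
                  class = "roi_stats")
  thr <- derive_thresholds(st)
  expect_equal(thr$t_half, 200)
  expect_equal(thr$t_bz, 110)

  st$sd_remote <- 0
  expect_equal(derive_thresholds(st)$t_bz, 100)

  st$mean_infarct <- 120; st$sd_remote <- 10
  expect_error(derive_thresholds(st), "not separable")
})

test_that("classification applies the stated boundary conventions", {
  thr <- structure(list(t_half = 200, t_bz = 110), class = "threshold_set")
  v <- si_volume(c(108, 150, 250, 200, 110, 50))
  myo <- array(c(rep(TRUE, 5), FALSE), c(6, 1, 1))
  lab <- classify_lge(v, myo, thr)$labels
  expect_identical(as.vector(lab), c(1L, 2L, 3L, 3L, 1L, 0L))
  # every myocardial voxel gets exactly one tissue label
  expect_true(all(lab[myo] %in% 1:3))
  expect_true(all(lab[!myo] == 0L))
})

test_that("raising the halfway threshold never grows the infarct", {
  set.seed(4)
  v <- lge_volume(array(runif(8 * 8 * 4, 0, 400), c(8, 8, 4)), c(1, 1, 1))
  myo <- array(TRUE, c(8, 8, 4))
  counts <- vapply(seq(120, 350, by = 10), function(th) {
    thr <- structure(list(t_half = th, t_bz = 110), class = "threshold_set")
    sum(classify_lge(v, myo, thr)$labels == 3L)
  }, 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("label down-sampling takes the majority fraction per block", {
  # uniform infarct block stays infarct
  lab <- label_volume(array(3L, c(3, 3, 9)), c(1 / 3, 1 / 3, 1 / 3))
  ds <- downsample_labels(lab, c(1, 1, 1), c(1, 1, 3))
  expect_identical(as.vector(ds$labels), 3L)

  # ~60/40 infarct/remote split in every z-column -> infarct majority
  a <- array(1L, c(3, 3, 9))
  a[, , 1:5] <- 3L
  ds <- downsample_labels(label_volume(a, c(1 / 3, 1 / 3, 1 / 3)),
                          c(1, 1, 1), c(1, 1, 3))
  expect_identical(as.vector(ds$labels), 3L)
  # flip the majority
  a[, , 1:5] <- 1L; a[, , 1:4] <- 3L
  ds <- downsample_labels(label_volume(a, c(1 / 3, 1 / 3, 1 / 3)),
                          c(1, 1, 1), c(1, 1, 3))
  expect_identical(as.vector(ds$labels), 1L)

  # all-background stays background; non-integer ratios are rejected
  bg <- label_volume(array(0L, c(6, 6, 6)), c(1, 1, 1))
  expect_true(all(downsample_labels(bg, c(2, 2, 2), c(3, 3, 3))$labels == 0L))
  expect_error(downsample_labels(bg, c(4, 4, 4), c(1, 1, 1)),
               "integer multiple")
})

test_that("small infarct islands are relabeled BZ and distant BZ pruned", {
  d <- c(20L, 20L, 3L)
  lab <- array(1L, d)
  lab[2:4, 2, 2] <- 3L                 # far 3-voxel island: removed, then
                                       # pruned to remote by the BZ rule
  lab[13, 10:12, 2] <- 3L              # near 3-voxel island: becomes BZ
  lab[10:11, 10:11, 2] <- 3L           # 4-voxel island: kept
  lv <- label_volume(lab, c(1, 1, 3))
  ref <- refine_labels(lv)$labels
  expect_true(all(ref[2:4, 2, 2] == 1L))
  expect_true(all(ref[13, 10:12, 2] == 2L))
  expect_true(all(ref[10:11, 10:11, 2] == 3L))

  # BZ distance rule: 2 mm in-plane kept, 4 mm relabeled remote,
  # one slice away (3 mm) kept at the boundary
  lab <- array(1L, d)
  lab[10:11, 10:11, 2] <- 3L
  lab[13, 10, 2] <- 2L                 # 2 mm from infarct
  lab[15, 10, 2] <- 2L                 # 4 mm away
  lab[10, 10, 3] <- 2L                 # 3.0 mm through-plane
  ref <- refine_labels(label_volume(lab, c(1, 1, 3)))$labels
  expect_identical(ref[13, 10, 2], 2L)
  expect_identical(ref[15, 10, 2], 1L)
  expect_identical(ref[10, 10, 3], 2L)

  # no infarct at all: every BZ voxel reverts to remote, with a warning
  lab <- array(1L, d); lab[5, 5, 1] <- 2L
  expect_warning(ref <- refine_labels(label_volume(lab, c(1, 1, 3))),
                 "no infarct")
  expect_true(all(ref$labels != 2L))
})

test_that("refinement is idempotent", {
  set.seed(11)
  for (i in 1:5) {
    lab <- array(sample(0:3, 14 * 14 * 4, replace = TRUE,
                        prob = c(0.4, 0.4, 0.1, 0.1)), c(14, 14, 4))
    lv <- label_volume(lab, c(1, 1, 3))
    once <- suppressWarnings(refine_labels(lv))
    twice <- suppressWarnings(refine_labels(once))
    expect_identical(once$labels, twice$labels)
  }
})

test_that("SNR is the tissue mean over the background SD", {
  vol <- array(0, c(10, 10, 1))
  vol[1:5, , 1] <- 590
  set.seed(2)
  vol[6:10, , 1] <- rnorm(50, 0, 10)
  tis <- array(FALSE, dim(vol)); tis[1:5, , 1] <- TRUE
  bgd <- array(FALSE, dim(vol)); bgd[6:10, , 1] <- TRUE
  expect_equal(compute_snr(vol, tis, bgd), 590 / sd(vol[bgd]))

  const <- vol; const[bgd] <- 1
  expect_error(compute_snr(const, tis, bgd), "zero SD")
  expect_error(compute_snr(vol, tis, bgd & vol > 1e9), "empty")
  tis2 <- tis; tis2[6, 1, 1] <- TRUE
  expect_error(compute_snr(vol, tis2, bgd), "equal area")
})

test_that("full LGE chain recovers ground truth on a low-noise phantom", {
  rp <- default_region_params()
  for (r in names(rp)) rp[[r]]$si_sd <- 0.5
  spec <- small_spec(region_params = rp, lge_snr = 200,
                     rigid_offset_mm = c(0, 0, 0))
  gt <- build_label_geometry(spec)
  hi <- upsample_labels_nn(gt, spec$lge_upsampling)
  lge <- simulate_lge(hi, spec)
  seeds <- phantom_roi_seeds(lge$labels)
  thr <- derive_thresholds(compute_roi_stats(lge, seeds$remote, seeds$infarct))
  labs <- classify_lge(lge, lge_myocardium_mask(lge), thr)
  ds <- downsample_labels(labs, spec$grid_dims_dti, spec$voxel_dims_dti)
  fin <- refine_labels(ds)$labels
  dice <- vapply(1:3, function(lv)
    2 * sum(fin == lv & gt$labels == lv) /
      (sum(fin == lv) + sum(gt$labels == lv)), 0)
  expect_true(all(dice >= 0.9))
})
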