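# Synthetic phantom: geometry, tensor sampling, DWI and LGE simulation.

test_that("wedge geometry matches a brute-force point-in-wedge oracle", {
  spec <- small_spec()
  labels <- build_label_geometry(spec)$labels

  # independent oracle: explicit loop over voxels, re-deriving membership
  d <- spec$grid_dims_dti; vd <- spec$voxel_dims_dti
  ctr <- spec$lv_geometry$center_mm
  ri <- spec$lv_geometry$inner_radius_mm; ro <- spec$lv_geometry$outer_radius_mm
  w <- spec$infarct_wedge
  n_inf <- 0L
  oracle_inf <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in w$slices) {
    x <- (i - 0.5) * vd[1] - ctr[1]; y <- (j - 0.5) * vd[2] - ctr[2]
    r <- sqrt(x^2 + y^2)
    if (r < ri || r > ro) next
    if (r > ri + w$transmural_fraction * (ro - ri)) next
    ang <- atan2(y, x) * 180 / pi
    dd <- abs(((ang - w$theta_center_deg + 180) %% 360) - 180)
    if (dd <= w$theta_width_deg / 2) {
      n_inf <- n_inf + 1L
      oracle_inf[i, j, k] <- TRUE
    }
  }
  expect_identical(sum(labels == 3L), n_inf)
  expect_identical(unname(which(labels == 3L)), which(oracle_inf))
})

test_that("degenerate wedge yields all-remote myocardium and BZ hugs the infarct", {
  spec0 <- small_spec()
  spec0$infarct_wedge$theta_width_deg <- 0
  lab0 <- build_label_geometry(spec0)$labels
  expect_true(all(lab0 %in% c(0L, 1L)))
  expect_gt(sum(lab0 == 1L), 0L)

  spec <- small_spec()
  lab <- build_label_geometry(spec)
  bz <- which(lab$labels == 2L); inf <- which(lab$labels == 3L)
  expect_gt(length(bz), 0L)
  d <- dim(lab$labels)
  dmm <- bzdti:::min_dist_mm(arrayInd(bz, d), arrayInd(inf, d),
                             lab$voxel_dims)
  expect_lte(max(dmm), spec$bz_shell_thickness_mm)

  # wedge slices outside the annulus slices are rejected, naming the slice
  bad <- small_spec()
  bad$lv_geometry$slices <- 2:8
  bad$infarct_wedge$slices <- 1:5
  expect_error(build_label_geometry(bad), "slice 1")
})

test_that("phantom volumes are deterministic given spec and seed", {
  spec <- small_spec(seed = 42L)
  h1 <- simulate_heart(spec)
  h2 <- simulate_heart(spec)
  expect_identical(h1$tensors$D, h2$tensors$D)
  expect_identical(h1$dwi$dwi, h2$dwi$dwi)
  expect_identical(h1$lge$si, h2$lge$si)
})

test_that("zero dispersion and unit correlation lengths give exact medians", {
  rp <- default_region_params()
  for (r in names(rp)) rp[[r]]$invariant_dispersion <- 0
  spec <- small_spec(region_params = rp,
                     correlation_lengths = list(normal = c(1, 1, 1),
                                                remote = c(1, 1, 1),
                                                bz = c(1, 1, 1),
                                                infarct = c(1, 1, 1)))
  labels <- build_label_geometry(spec)
  tf <- sample_tensor_field(labels, spec)
  inv <- compute_invariants(tf)
  rem <- labels$labels == 1L
  expect_equal(unique(round(inv$adc[rem], 12)), rp$remote$adc_median,
               tolerance = 1e-9)
  expect_equal(unique(round(inv$fa[rem], 9)), rp$remote$fa_median,
               tolerance = 1e-6)
  expect_equal(unique(round(inv$mode[rem], 9)), rp$remote$mode_median,
               tolerance = 1e-6)
})

test_that("sampled region ADC median converges to the target median", {
  h <- small_heart()
  inv <- compute_invariants(h$tensors)
  rem <- h$labels_gt$labels == 1L
  expect_gt(sum(rem), 1000L)
  med <- median(inv$adc[rem])
  target <- small_spec()$region_params$remote$adc_median
  expect_lt(abs(med - target) / target, 0.02)
})

test_that("noiseless DWI follows the closed-form decay and refits exactly", {
  # isotropic tensor at b = 1000: S = s0 * exp(-1)
  comp <- matrix(rep(c(1e-3, 1e-3, 1e-3, 0, 0, 0), 10), 10, byrow = TRUE)
  tf <- as_tensor_field(comp)
  scheme <- default_gradient_scheme()
  dwi <- simulate_dwi(tf, scheme, s0 = 100, snr = Inf)
  expect_equal(as.vector(dwi$dwi), rep(100 * exp(-1), length(dwi$dwi)),
               tolerance = 1e-9)

  comp <- random_spd_components(20, seed = 9)
  tf <- as_tensor_field(comp)
  fit <- fit_tensor_lls(simulate_dwi(tf, scheme, snr = Inf), scheme)
  expect_equal(matrix(fit$D, ncol = 6), comp, tolerance = 1e-9)

  bad <- scheme
  bad$directions[1, ] <- c(2, 0, 0)
  expect_error(simulate_dwi(tf, bad, snr = Inf), "unit")
})

test_that("Rician background noise has the expected Rayleigh moments", {
  d <- c(30L, 30L, 12L)
  tf <- tensor_field(array(0, c(d, 6)), array(FALSE, d), c(1, 1, 1))
  scheme <- default_gradient_scheme()
  dwi <- simulate_dwi(tf, scheme, s0 = 100, snr = 59, seed = 21L)
  sigma <- 100 / 59
  # pure-noise magnitude signal is Rayleigh: SD = sigma * sqrt(2 - pi/2)
  bg <- dwi$dwi[, , , 1:3]
  expect_gt(length(bg), 1e4)
  expect_lt(abs(sd(bg) - sigma * sqrt(2 - pi / 2)) /
              (sigma * sqrt(2 - pi / 2)), 0.05)
})

test_that("LGE simulation honours plateaus, sampling accuracy and the offset", {
  rp <- default_region_params()
  for (r in names(rp)) rp[[r]]$si_sd <- 1e-9
  spec <- small_spec(region_params = rp, lge_snr = Inf,
                     rigid_offset_mm = c(0, 0, 0))
  hi <- upsample_labels_nn(build_label_geometry(spec), spec$lge_upsampling)
  lge <- simulate_lge(hi, spec)
  vals <- sort(unique(round(lge$si[hi$labels > 0L])))
  expect_equal(vals, c(100, 160, 300))

  # sampling accuracy of the remote plateau under default noise
  spec2 <- small_spec(rigid_offset_mm = c(0, 0, 0))
  hi2 <- upsample_labels_nn(build_label_geometry(spec2), spec2$lge_upsampling)
  lge2 <- simulate_lge(hi2, spec2)
  rem <- hi2$labels == 1L
  expect_gt(sum(rem), 1e4)
  expect_lt(abs(mean(lge2$si[rem]) - 100) / 100, 0.02)

  # zero offset: label centroids coincide after down-sampling
  ds <- downsample_labels(lge2$labels, spec2$grid_dims_dti,
                          spec2$voxel_dims_dti)
  gt <- build_label_geometry(spec2)
  c1 <- colMeans(arrayInd(which(ds$labels > 0L), dim(ds$labels)))
  c2 <- colMeans(arrayInd(which(gt$labels > 0L), dim(gt$labels)))
  expect_equal(c1, c2, tolerance = 0.02)

  # BZ signal intensity must sit strictly between remote and infarct
  rp_bad <- default_region_params()
  rp_bad$bz$si_mean <- 90
  spec_bad <- small_spec(region_params = rp_bad)
  hi_bad <- upsample_labels_nn(build_label_geometry(spec_bad),
                               spec_bad$lge_upsampling)
  expect_error(simulate_lge(hi_bad, spec_bad), "strictly between")
})
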