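# Distribution-free bootstrap statistics for decorrelated invariant
# samples: per-bin histogram confidence intervals, median confidence
# intervals, a two-group median comparison, and a bootstrap analog to
# repeated-measures ANOVA (cell-median F with a region-effect-removed
# resampling null). All routines are seeded and reproducible.

#' Bootstrap configuration
#'
#' @param n_resamples_hist resamples for histogram and median CIs
#'   (default 1000).
#' @param n_resamples_test resamples for hypothesis tests (default 10000).
#' @param n_bins histogram bins (default 32).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @export
bootstrap_config <- function(n_resamples_hist = 1000L,
                             n_resamples_test = 10000L,
                             n_bins = 32L, ci_level = 0.95, seed = NULL) {
  stopifnot(n_resamples_hist >= 100L, n_resamples_test >= 100L,
            n_bins >= 1L, ci_level > 0, ci_level < 1)
  structure(list(n_resamples_hist = as.integer(n_resamples_hist),
                 n_resamples_test = as.integer(n_resamples_test),
                 n_bins = as.integer(n_bins), ci_level = ci_level,
                 seed = seed), class = "bootstrap_config")
}

# Column medians of resampled values: x resampled with replacement B
# times; returns length-B vector of medians. Chunked to bound memory.
resample_medians <- function(x, B, chunk = 2000L) {
  n <- length(x)
  out <- numeric(B)
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    m <- matrix(x[sample.int(n, n * b, replace = TRUE)], n, b)
    out[(done + 1L):(done + b)] <- matrixStats::colMedians(m)
    done <- done + b
  }
  out
}

#' Bootstrapped histograms with per-bin confidence intervals
#'
#' Shared equal-width bin edges span the pooled range of both groups.
#' Each resample draws with replacement and records normalized bin
#' frequencies; percentile CIs are formed per bin, and a bin is flagged
#' significantly different when the two groups' CIs do not overlap there.
#'
#' @param samples,comparator_samples numeric vectors (each n >= 30).
#' @param cfg a [bootstrap_config()].
#' @return object of class `histogram_ci`: `edges`, and per group the
#'   observed frequencies `freq`, CI bounds `lo`/`hi`, plus the per-bin
#'   `nonoverlap` flag.
#' @export
bootstrap_histogram <- function(samples, comparator_samples,
                                cfg = bootstrap_config()) {
  a <- samples[is.finite(samples)]; b <- comparator_samples[is.finite(comparator_samples)]
  if (length(a) < 30L || length(b) < 30L)
    stop("each group needs at least 30 samples")
  rng <- range(c(a, b))
  if (rng[1] == rng[2]) {
    warning("identical constant groups; degenerate single-bin histogram")
    return(structure(list(edges = c(rng[1], rng[1]),
                          freq_a = 1, freq_b = 1,
                          lo_a = 1, hi_a = 1, lo_b = 1, hi_b = 1,
                          nonoverlap = FALSE), class = "histogram_ci"))
  }
  edges <- seq(rng[1], rng[2], length.out = cfg$n_bins + 1L)
  bin_of <- function(x) pmin(pmax(findInterval(x, edges,
                                               rightmost.closed = TRUE), 1L),
                             cfg$n_bins)
  boot_freq <- function(x) {
    bi <- bin_of(x); n <- length(x)
    f <- matrix(0, cfg$n_bins, cfg$n_resamples_hist)
    for (r in seq_len(cfg$n_resamples_hist))
      f[, r] <- tabulate(bi[sample.int(n, n, replace = TRUE)],
                         nbins = cfg$n_bins) / n
    f
  }
  alpha <- (1 - cfg$ci_level) / 2
  with_seed(cfg$seed, {
    fa <- boot_freq(a); fb <- boot_freq(b)
    qa <- matrixStats::rowQuantiles(fa, probs = c(alpha, 1 - alpha))
    qb <- matrixStats::rowQuantiles(fb, probs = c(alpha, 1 - alpha))
    freq_a <- tabulate(bin_of(a), cfg$n_bins) / length(a)
    freq_b <- tabulate(bin_of(b), cfg$n_bins) / length(b)
    structure(list(edges = edges, freq_a = freq_a, freq_b = freq_b,
                   lo_a = qa[, 1], hi_a = qa[, 2],
                   lo_b = qb[, 1], hi_b = qb[, 2],
                   nonoverlap = qa[, 1] > qb[, 2] | qb[, 1] > qa[, 2]),
              class = "histogram_ci")
  })
}

#' Bootstrapped confidence interval of the median
#'
#' Percentile CI of the sample median over `n_resamples_hist` resamples
#' with replacement.
#'
#' @param samples numeric vector (n >= 10).
#' @param cfg a [bootstrap_config()].
#' @return object of class `median_ci` with `median`, `lo`, `hi`, `n`.
#' @export
bootstrap_median_ci <- function(samples, cfg = bootstrap_config()) {
  x <- samples[is.finite(samples)]
  if (length(x) < 10L) stop("at least 10 samples are required")
  alpha <- (1 - cfg$ci_level) / 2
  with_seed(cfg$seed, {
    med <- median(x)
    boots <- resample_medians(x, cfg$n_resamples_hist)
    q <- quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
    structure(list(median = med, lo = min(q[1], med), hi = max(q[2], med),
                   n = length(x)), class = "median_ci")
  })
}

# Within-subject F statistic on a hearts x regions table of cell
# summaries: MS(region) over MS(heart x region residual).
rm_anova_f <- function(M) {
  h <- nrow(M); r <- ncol(M)
  grand <- mean(M)
  rowm <- rowMeans(M); colm <- colMeans(M)
  ss_region <- h * sum((colm - grand)^2)
  resid <- M - outer(rowm, rep(1, r)) - outer(rep(1, h), colm) + grand
  ss_err <- sum(resid^2)
  (ss_region / (r - 1)) / (ss_err / ((h - 1) * (r - 1)))
}

#' Bootstrap analog to repeated-measures ANOVA
#'
#' Each (heart, region) cell is summarized by its median; the observed
#' statistic is the classical within-subject F on the hearts x regions
#' median table. The null distribution removes the region effect while
#' preserving heart effects: within each cell, samples are centered by
#' subtracting the cell median and adding the heart's overall median;
#' cells are then resampled with replacement and the F recomputed
#' `n_resamples_test` times. `p = (1 + #\{F* >= F_obs\}) / (1 + B)`.
#'
#' @param cells data frame with columns `heart`, `region`, `value`; every
#'   heart must have every region, with at least 5 samples per cell.
#' @param cfg a [bootstrap_config()].
#' @return object of class `anova_result`: `f_observed`, `p`,
#'   `medians` (hearts x regions), `n_resamples`.
#' @export
bootstrap_rm_anova <- function(cells, cfg = bootstrap_config()) {
  stopifnot(all(c("heart", "region", "value") %in% names(cells)))
  hearts <- unique(as.character(cells$heart))
  regions <- unique(as.character(cells$region))
  stopifnot(length(regions) >= 2L, length(hearts) >= 2L)
  cell_list <- vector("list", length(hearts) * length(regions))
  dim(cell_list) <- c(length(hearts), length(regions))
  for (i in seq_along(hearts)) for (j in seq_along(regions)) {
    v <- cells$value[cells$heart == hearts[i] & cells$region == regions[j]]
    v <- v[is.finite(v)]
    if (length(v) < 5L)
      stop("missing or underpopulated cell: heart ", hearts[i],
           ", region ", regions[j], " (n = ", length(v), ")")
    cell_list[[i, j]] <- v
  }
  M <- matrix(vapply(cell_list, median, 0), length(hearts), length(regions),
              dimnames = list(hearts, regions))
  f_obs <- rm_anova_f(M)
  # region-effect-removed samples, heart effects preserved
  null_cells <- cell_list
  for (i in seq_along(hearts)) {
    heart_med <- median(unlist(cell_list[i, ]))
    for (j in seq_along(regions))
      null_cells[[i, j]] <- cell_list[[i, j]] - M[i, j] + heart_med
  }
  B <- cfg$n_resamples_test
  with_seed(cfg$seed, {
    meds <- matrix(0, length(hearts) * length(regions), B)
    for (k in seq_along(null_cells))
      meds[k, ] <- resample_medians(null_cells[[k]], B)
    f_star <- vapply(seq_len(B), function(bb)
      rm_anova_f(matrix(meds[, bb], length(hearts), length(regions))), 0)
    p <- (1 + sum(f_star >= f_obs)) / (1 + B)
    structure(list(f_observed = f_obs, p = p, medians = M,
                   n_resamples = B), class = "anova_result")
  })
}

#' Bootstrap two-group comparison of medians
#'
#' Observed difference `median(a) - median(b)`; both groups are resampled
#' with replacement in each replicate and the two-sided p-value is
#' `2 * min(#\{d* <= 0\}, #\{d* >= 0\}) / B`, clipped to
#' `(1 / (1 + B), 1]`.
#'
#' @param samples_a,samples_b numeric vectors (each n >= 10).
#' @param cfg a [bootstrap_config()].
#' @return object of class `two_group_result`: `delta`, `p`, `ci`
#'   (percentile CI of the difference), `n_resamples`.
#' @export
bootstrap_two_group <- function(samples_a, samples_b,
                                cfg = bootstrap_config()) {
  a <- samples_a[is.finite(samples_a)]; b <- samples_b[is.finite(samples_b)]
  if (length(a) < 10L || length(b) < 10L)
    stop("each group needs at least 10 samples")
  B <- cfg$n_resamples_test
  alpha <- (1 - cfg$ci_level) / 2
  with_seed(cfg$seed, {
    delta <- median(a) - median(b)
    d_star <- resample_medians(a, B) - resample_medians(b, B)
    p <- 2 * min(sum(d_star <= 0), sum(d_star >= 0)) / B
    p <- min(max(p, 1 / (1 + B)), 1)
    structure(list(delta = delta, p = p,
                   ci = quantile(d_star, c(alpha, 1 - alpha), names = FALSE),
                   n_resamples = B), class = "two_group_result")
  })
}
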