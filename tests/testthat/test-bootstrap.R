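# Bootstrap statistics: histogram CIs, median CIs, repeated-measures
# ANOVA analog and the two-group comparison.

test_that("bootstrapped histograms normalize and flag separation correctly", {
  cfg <- bootstrap_config(seed = 5L)
  set.seed(6)
  x <- rnorm(600)
  h <- bootstrap_histogram(x[1:300], x[301:600], cfg)
  expect_equal(sum(h$freq_a), 1, tolerance = 1e-12)
  expect_equal(sum(h$freq_b), 1, tolerance = 1e-12)
  expect_length(h$freq_a, 32L)
  expect_true(all(h$lo_a <= h$hi_a))
  # two samples of one distribution: no bin separates the groups
  expect_false(any(h$nonoverlap))

  a <- rnorm(500); b <- rnorm(500, mean = 5)
  hs <- bootstrap_histogram(a, b, cfg)
  # the modal bins of each group must be flagged significantly different
  expect_true(hs$nonoverlap[which.max(hs$freq_a)])
  expect_true(hs$nonoverlap[which.max(hs$freq_b)])

  expect_error(bootstrap_histogram(rnorm(10), rnorm(100), cfg), "30")
  expect_warning(bootstrap_histogram(rep(1, 50), rep(1, 50), cfg),
                 "constant")
})

test_that("median CI covers the truth at the nominal rate", {
  cfg <- bootstrap_config(seed = 9L)
  const <- bootstrap_median_ci(rep(7, 25), cfg)
  expect_equal(c(const$median, const$lo, const$hi), c(7, 7, 7))

  x <- rexp(200)^2 # asymmetric
  ci <- bootstrap_median_ci(x, cfg)
  expect_true(ci$lo <= ci$median && ci$median <= ci$hi)
  expect_error(bootstrap_median_ci(rnorm(5), cfg), "10")

  # coverage simulation: log-normal, true median 1
  set.seed(17)
  hits <- 0L
  reps <- 400L
  for (r in seq_len(reps)) {
    ci <- bootstrap_median_ci(rlnorm(500), bootstrap_config(seed = r))
    hits <- hits + (ci$lo <= 1 && 1 <= ci$hi)
  }
  expect_gte(hits / reps, 0.92)
  expect_lte(hits / reps, 0.98)
})

test_that("histogram CI width shrinks roughly as 1/sqrt(n)", {
  width_at <- function(n) {
    set.seed(23)
    x <- rnorm(n); y <- rnorm(n)
    h <- bootstrap_histogram(x, y, bootstrap_config(seed = 23L))
    mean(h$hi_a - h$lo_a)
  }
  ratio <- width_at(100) / width_at(10000)
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})

test_that("observed rm-ANOVA F matches the classical within-subject F", {
  # 3 hearts x 3 regions, 5 samples per cell; compare against stats::aov
  set.seed(41)
  cells <- expand.grid(heart = paste0("h", 1:3),
                       region = c("remote", "bz", "infarct"),
                       rep = 1:5, stringsAsFactors = FALSE)
  shift <- c(remote = 0, bz = 1, infarct = 2)
  cells$value <- rnorm(nrow(cells)) + shift[cells$region] +
    rep(c(0, .5, 1), times = nrow(cells) / 3)
  res <- bootstrap_rm_anova(cells, bootstrap_config(n_resamples_test = 200L,
                                                    seed = 1L))
  med <- aggregate(value ~ heart + region, cells, median)
  fit <- summary(stats::aov(value ~ region + Error(heart / region),
                            data = med))
  f_aov <- fit[["Error: heart:region"]][[1]]["region", "F value"]
  expect_equal(res$f_observed, f_aov, tolerance = 1e-10)
})

test_that("rm-ANOVA reaches its p-value floor under strong separation", {
  set.seed(43)
  cells <- expand.grid(heart = paste0("h", 1:7),
                       region = c("remote", "bz", "infarct"),
                       rep = 1:20, stringsAsFactors = FALSE)
  shift <- c(remote = 0, bz = 5, infarct = 10) # >= 5 within-cell SDs
  cells$value <- rnorm(nrow(cells), sd = 1) + shift[cells$region]
  B <- 999L
  res <- bootstrap_rm_anova(cells, bootstrap_config(n_resamples_test = B,
                                                    seed = 2L))
  expect_equal(res$p, 1 / (1 + B))

  # a missing cell is reported by heart and region
  drop <- !(cells$heart == "h3" & cells$region == "bz")
  expect_error(bootstrap_rm_anova(cells[drop, ], bootstrap_config()),
               "h3.*bz")
})

test_that("rm-ANOVA null rejection rate is close to the nominal level", {
  set.seed(47)
  B <- 199L
  rejections <- 0L
  n_sims <- 120L
  for (s in seq_len(n_sims)) {
    cells <- expand.grid(heart = paste0("h", 1:5),
                         region = c("r1", "r2", "r3"),
                         rep = 1:15, stringsAsFactors = FALSE)
    cells$value <- rlnorm(nrow(cells)) +
      rep(rnorm(5, sd = 0.3), times = nrow(cells) / 5) # heart effects only
    res <- bootstrap_rm_anova(cells, bootstrap_config(n_resamples_test = B,
                                                      seed = 1000L + s))
    rejections <- rejections + (res$p <= 0.05)
  }
  rate <- rejections / n_sims
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("two-group comparison behaves under null, shift and identity", {
  cfg <- bootstrap_config(n_resamples_test = 999L, seed = 3L)
  set.seed(51)
  x <- rlnorm(200)
  res <- bootstrap_two_group(x, x, cfg)
  expect_equal(res$delta, 0)

  a <- rnorm(100); b <- a + 10
  res <- bootstrap_two_group(a, b, cfg)
  expect_equal(res$p, 1 / (1 + 999))
  expect_lt(res$delta, 0)

  null <- bootstrap_two_group(rnorm(100), rnorm(100), cfg)
  expect_true(null$p > 0 && null$p <= 1)
  expect_error(bootstrap_two_group(rnorm(5), rnorm(100), cfg), "10")
})

test_that("all bootstrap routines are reproducible under a fixed seed", {
  set.seed(61)
  x <- rlnorm(120); y <- rlnorm(120, meanlog = 0.5)
  cfg <- bootstrap_config(n_resamples_test = 500L, seed = 99L)
  expect_identical(bootstrap_median_ci(x, cfg), bootstrap_median_ci(x, cfg))
  expect_identical(bootstrap_two_group(x, y, cfg),
                   bootstrap_two_group(x, y, cfg))
  h1 <- bootstrap_histogram(x, y, cfg); h2 <- bootstrap_histogram(x, y, cfg)
  expect_identical(h1, h2)
  cells <- expand.grid(heart = paste0("h", 1:3),
                       region = c("a", "b", "c"), rep = 1:8,
                       stringsAsFactors = FALSE)
  cells$value <- rnorm(nrow(cells))
  expect_identical(bootstrap_rm_anova(cells, cfg),
                   bootstrap_rm_anova(cells, cfg))
})
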