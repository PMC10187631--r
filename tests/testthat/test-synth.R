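test_that("synth_config validates proportions, rates and mixtures", {
  expect_s3_class(synth_config(seed = 1), "synth_config")
  expect_error(synth_config(region_fractions = c(infarct = 0.5, bz = 0.6,
                                                 remote = -0.1)),
               "region_fractions")
  expect_error(synth_config(hvg_inflation_factor = 0.5), "inflation")
  expect_error(synth_config(planted_hvg_frac = 1.2), "proportions")
  expect_error(synth_config(apd_dist_by_region = list(
    bz = list(means = 1, sds = 1, weights = 0.5),
    remote = list(means = 1, sds = 1, weights = 1))), "weights")
})

test_that("mixture_moments matches a Monte-Carlo evaluation", {
  means <- c(335, 520); sds <- c(75, 80); w <- c(0.8, 0.2)
  mm <- mixture_moments(means, sds, w)
  set.seed(42)
  comp <- sample.int(2, 2e5, replace = TRUE, prob = w)
  x <- rnorm(2e5, means[comp], sds[comp])
  expect_equal(mm[["mean"]], mean(x), tolerance = 0.01)
  expect_equal(mm[["sd"]], sd(x), tolerance = 0.01)
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- tiny_cfg(seed = 7)
  m1 <- gen_endocardial_map(cfg, electrograms = FALSE)
  m2 <- gen_endocardial_map(cfg, electrograms = FALSE)
  expect_identical(m1$ari, m2$ari)
  expect_identical(m1$bipolar_voltage, m2$bipolar_voltage)

  e1 <- gen_electrogram(50, 350, noise_sd = 0.05, seed = 3)
  e2 <- gen_electrogram(50, 350, noise_sd = 0.05, seed = 3)
  expect_identical(e1$samples, e2$samples)

  p1 <- gen_optical_population(cfg, animals = 1)
  p2 <- gen_optical_population(cfg, animals = 1)
  expect_identical(p1$cells$apd90_true, p2$cells$apd90_true)
  expect_identical(p1$traces[[3]]$samples, p2$traces[[3]]$samples)

  d1 <- gen_counts(cfg); d2 <- gen_counts(cfg)
  expect_identical(as.matrix(d1$counts), as.matrix(d2$counts))

  s1 <- gen_lv_slices(cfg, n_slices = 1)[[1]]
  s2 <- gen_lv_slices(cfg, n_slices = 1)[[1]]
  expect_identical(s1$truth$thickness, s2$truth$thickness)
})

test_that("zero spatial noise gives exactly the regional ARI means", {
  cfg <- tiny_cfg(seed = 2, ari_local_sd_by_region = c(infarct = 0,
                                                       bz = 0,
                                                       remote = 0))
  m <- gen_endocardial_map(cfg, electrograms = FALSE)
  expect_equal(m$ari,
               unname(cfg$ari_mean_by_region[m$truth$region]))
})

test_that("degenerate region fractions label every point remote", {
  cfg <- tiny_cfg(seed = 3,
                  region_fractions = c(infarct = 0, bz = 0, remote = 1))
  m <- gen_endocardial_map(cfg, electrograms = FALSE)
  expect_true(all(m$truth$region == "remote"))
})

test_that("voltage thresholding reproduces the generator's region labels", {
  m <- gen_endocardial_map(tiny_cfg(seed = 4), electrograms = FALSE)
  expect_identical(as.character(classify_regions(m$bipolar_voltage)),
                   m$truth$region)
})

test_that("planted local ARI SD is recovered within sampling error", {
  # generator parameterized from the in vivo study values (BZ 3.5 ms,
  # remote 2.0 ms local SD); estimator = mean local SD over region points
  cfg <- synth_config(seed = 5, n_points = 500L)
  m <- gen_endocardial_map(cfg, electrograms = FALSE)
  het <- local_heterogeneity(m, radius = cfg$het_radius)
  rs <- regional_summary(het$local_sd, m$truth$region)$stats
  expect_equal(expect_region_value(rs, "bz", "mean"), 3.5,
               tolerance = 0.10)
  expect_equal(expect_region_value(rs, "remote", "mean"), 2.0,
               tolerance = 0.10)
})

test_that("generator refuses degenerate inputs", {
  expect_error(gen_endocardial_map(tiny_cfg(n_points = 30L)),
               "degenerate")
  expect_error(gen_electrogram(at = 300, rt = 200), "rt > at")
  expect_error(gen_optical_population(tiny_cfg(trace_duration = 5)),
               "average")
  expect_error(gen_counts(tiny_cfg(n_genes = 5L)), "n_genes")
  expect_error(gen_counts(tiny_cfg(
    n_nuclei_by_region = c(bz = 10L, remote = 100L))), "20 nuclei")
})

test_that("electrogram construction places slope extrema at AT and RT", {
  e <- gen_electrogram(at = 50, rt = 350, fs = 1000, noise_sd = 0)
  d <- diff(e$samples) # sample-resolution slope
  expect_equal(which.min(d[1:200]), 50, tolerance = 1)
  expect_equal(200 + which.max(d[201:500]), 350, tolerance = 1)
  expect_equal(attr(e, "truth")$ari, 300)
})

test_that("null count generator plants no effects and NPPB fraction is binomial", {
  cfg <- null_scvar_cfg(seed = 11)
  ds <- gen_counts(cfg)
  expect_false(any(ds$genes$is_hvg))
  expect_false(any(ds$genes$is_deg))

  cfg2 <- tiny_cfg(seed = 12,
                   n_nuclei_by_region = c(bz = 600L, remote = 200L),
                   n_animals_rna = 2L)
  ds2 <- gen_counts(cfg2)
  pos <- ds2$nuclei$nppb_pos[ds2$nuclei$region == "bz"]
  ci <- 1 / 3 + c(-1, 1) * 1.96 * sqrt(1 / 3 * 2 / 3 / length(pos))
  expect_gt(mean(pos), ci[1])
  expect_lt(mean(pos), ci[2])
})

test_that("slice truth obeys the requested regional variance structure", {
  cfg <- tiny_cfg(seed = 13, wall_thickness_variance_by_region =
                    c(core = 1, bz = 4, remote = 1e-12))
  s <- gen_lv_slices(cfg, n_slices = 1)[[1]]
  tr <- s$truth
  v <- tapply(tr$thickness, tr$region, var)
  expect_lt(v[["remote"]], 1e-6)
  expect_gt(v[["bz"]], 1)
  # concentric annulus when all variances are zero
  cfg0 <- tiny_cfg(seed = 14, wall_thickness_mean_by_region =
                     c(core = 10, bz = 10, remote = 10),
                   wall_thickness_variance_by_region =
                     c(core = 0, bz = 0, remote = 0))
  s0 <- gen_lv_slices(cfg0, n_slices = 1)[[1]]
  expect_true(all(abs(s0$truth$thickness - 10) < 1e-9))
})

test_that("noise-free inducibility gives a perfect downstream regression", {
  het <- c(2, 2.5, 3, 3.5, 4, 4.2, 2.8, 3.1)
  ind <- gen_inducibility(het, slope = 0.8, intercept = 0, noise_sd = 0)
  fit <- inducibility_regression(ind)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 0.8, tolerance = 1e-9)
})

test_that("slope-zero inducibility yields near-null R2 across seeds", {
  set.seed(99)
  r2 <- vapply(1:100, function(s) {
    het <- stats::rnorm(8, 3.5, 1.3)
    ind <- gen_inducibility(het, slope = 0, intercept = 2,
                            noise_sd = 0.5, seed = s)
    inducibility_regression(ind)$r_squared
  }, 0)
  expect_lt(median(r2), 0.2)
})

test_that("MTX round trip preserves counts and metadata", {
  ds <- gen_counts(tiny_cfg(seed = 15))
  dir <- withr::local_tempdir()
  write_counts_mtx(ds, dir)
  back <- read_counts_mtx(dir)
  expect_equal(as.matrix(back$counts), as.matrix(ds$counts))
  expect_equal(back$nuclei$region, ds$nuclei$region)
})
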