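# build an analytic slice: circular endocardium, epicardial radius given
# by a per-angle function, on a pixel grid
analytic_mask <- function(r_endo, r_epi_fun, spacing = 0.5,
                          lge_fun = NULL) {
  half <- ceiling((max(r_epi_fun(seq(0, 2 * pi, 0.01))) + 5) / spacing)
  ax <- (-half:half) * spacing
  nx <- length(ax)
  px <- matrix(rep(ax, nx), nx)
  py <- matrix(rep(ax, each = nx), nx)
  rr <- sqrt(px^2 + py^2)
  th <- atan2(py, px) %% (2 * pi)
  label <- matrix(0L, nx, nx)
  label[rr < r_endo] <- 1L
  label[rr >= r_endo & rr < r_epi_fun(th)] <- 2L
  lge <- if (is.null(lge_fun)) NULL else {
    out <- matrix(0, nx, nx)
    out[label == 2L] <- lge_fun(th[label == 2L])
    out
  }
  list(label = label, lge = lge, spacing = spacing)
}

test_that("an annulus measures constant thickness R - r", {
  mask <- analytic_mask(20, function(th) rep(30, length(th)),
                        spacing = 1)
  prof <- wall_thickness(mask)
  expect_false(anyNA(prof$thickness))
  expect_true(all(abs(prof$thickness - 10) <= 1))
  wv <- wall_variance(prof, rep("all", nrow(prof)))
  expect_lt(wv$variance, 0.1)
})

test_that("elliptical epicardium matches the analytic radial chord", {
  a <- 32; b <- 27
  repi <- function(th) a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  mask <- analytic_mask(20, repi, spacing = 0.5)
  prof <- wall_thickness(mask)
  truth <- repi(prof$angle * pi / 180) - 20
  expect_lt(max(abs(prof$thickness - truth), na.rm = TRUE), 0.6)
})

test_that("rotating the mask circularly shifts the profile", {
  cfg <- tiny_cfg(seed = 71)
  s <- gen_lv_slices(cfg, n_slices = 1)[[1]]
  prof <- wall_thickness(s)
  rot <- s
  # 90-degree rotation of the image grid
  rot$label <- t(s$label)[ncol(s$label):1, ]
  rot$lge <- t(s$lge)[ncol(s$lge):1, ]
  prof_rot <- wall_thickness(rot)
  shift <- 90
  expect_equal(prof_rot$thickness[((prof_rot$angle + shift) %% 360) + 1],
               prof$thickness[prof$angle + 1], tolerance = 0.8)
})

test_that("non-annular myocardium raises a topology error", {
  mask <- analytic_mask(20, function(th) ifelse(th < pi, 30, 20),
                        spacing = 1)  # wall missing on half the slice
  expect_error(wall_thickness(mask), "annulus")
})

test_that("LGE classification applies the 20/70% bands with a robust max", {
  mask <- analytic_mask(
    20, function(th) rep(30, length(th)), spacing = 0.5,
    lge_fun = function(th) ifelse(th < pi / 2, 0.9,
                                  ifelse(th < pi, 0.5, 0.1)))
  lab <- lge_classify(mask)
  expect_equal(lab$region[lab$angle == 45], "core")
  expect_equal(lab$region[lab$angle == 135], "bz")
  expect_equal(lab$region[lab$angle == 270], "remote")
  # exactly 0.7 x max falls in the BZ band (upper-closed convention)
  mask2 <- analytic_mask(20, function(th) rep(30, length(th)),
                         spacing = 0.5,
                         lge_fun = function(th) ifelse(th < pi, 1, 0.7))
  lab2 <- lge_classify(mask2)
  expect_equal(lab2$region[lab2$angle == 270], "bz")
  # uniform zero intensity: everything remote
  mask0 <- analytic_mask(20, function(th) rep(30, length(th)),
                         spacing = 0.5,
                         lge_fun = function(th) rep(0, length(th)))
  expect_true(all(lge_classify(mask0)$region == "remote"))
  mask_na <- mask; mask_na$lge <- NULL
  expect_error(lge_classify(mask_na), "LGE")
})

test_that("wall variance equals brute force and has closed forms", {
  prof <- data.frame(angle = 0:359,
                     thickness = rep(c(8, 12), 180), r_endo = 20)
  class(prof) <- c("wall_profile", "data.frame")
  wv <- wall_variance(prof, rep("x", 360))
  expect_equal(wv$variance, (8 - 12)^2 / 4)

  set.seed(72)
  prof$thickness <- rnorm(360, 10, 2)
  wv2 <- wall_variance(prof, rep("x", 360))
  expect_equal(wv2$variance, mean((prof$thickness -
                                     mean(prof$thickness))^2))
  expect_error(wall_variance(prof[1:2, ], rep("x", 2)), "min_angles")
})

test_that("curvature matches the circle and ellipse closed forms", {
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  circ <- cbind(20 * cos(th), 20 * sin(th))
  expect_equal(contour_curvature(circ), rep(0.05, 240),
               tolerance = 0.02)
  # near-straight contour: huge circle
  big <- cbind(1e5 * cos(th), 1e5 * sin(th))
  expect_lt(max(contour_curvature(big)), 1e-4)

  a <- 30; b <- 20
  ell <- cbind(a * cos(th), b * sin(th))
  k_true <- a * b / (a^2 * sin(th)^2 + b^2 * cos(th)^2)^1.5
  k_est <- contour_curvature(ell)
  expect_lt(max(abs(k_est - k_true) / k_true), 0.05)
})

test_that("thickness is consistent when pixel size halves", {
  repi <- function(th) 30 + 2 * cos(2 * th)
  m1 <- analytic_mask(20, repi, spacing = 1)
  m2 <- analytic_mask(20, repi, spacing = 0.5)
  p1 <- wall_thickness(m1)
  p2 <- wall_thickness(m2)
  rel <- abs(p1$thickness - p2$thickness) / p2$thickness
  expect_lt(mean(rel, na.rm = TRUE), 0.02)
})

test_that("regional thickness variance is recovered within 15%", {
  cfg <- synth_config(seed = 73)
  agg <- NULL
  for (a in 1:2) {
    slices <- gen_lv_slices(cfg, n_slices = 8, seed = a)
    for (s in seq_along(slices)) {
      wv <- wall_variance(wall_thickness(slices[[s]]),
                          lge_classify(slices[[s]])$region)
      agg <- rbind(agg, cbind(animal = a, slice = s, wv))
    }
  }
  ws <- wall_summary(agg)
  tgt <- cfg$wall_thickness_variance_by_region
  for (r in c("bz", "remote"))
    expect_equal(mean(ws$mean_variance[ws$region == r]),
                 unname(tgt[r]), tolerance = 0.15)
  expect_gt(mean(ws$mean_variance[ws$region == "bz"]),
            mean(ws$mean_variance[ws$region == "remote"]))
})

test_that("LGE variability is zero for uniform intensity and finds planted spread", {
  lab_u <- data.frame(slice = rep(1:4, each = 3),
                      region = rep(c("bz", "core", "remote"), 4),
                      lge_mean = 0.5)
  lv <- lge_variability(lab_u)
  expect_true(all(lv$variability$sd_across_slices == 0))

  cfg <- tiny_cfg(seed = 74)
  slices <- gen_lv_slices(cfg, n_slices = 6)
  lg <- NULL
  for (s in seq_along(slices))
    lg <- rbind(lg, cbind(slice = s, lge_classify(slices[[s]])))
  lv2 <- lge_variability(lg)
  expect_true(all(lv2$variability$sd_across_slices >= 0))
  expect_true(all(is.finite(lv2$variability$sd_across_slices)))
})
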