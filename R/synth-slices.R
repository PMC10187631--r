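#' Generate synthetic short-axis LV slices with planted wall properties
#'
#' Per slice: a circular endocardial contour of radius `cfg$endo_radius`
#' and an epicardial contour offset by a per-angle wall thickness
#' (regional mean + i.i.d. angular noise with the regional variance),
#' rasterized to a label image (background 0, blood pool 1, myocardium 2)
#' on `cfg$pixel_spacing` mm pixels, plus an LGE intensity image with
#' core > BZ > remote intensities on angular sectors
#' (`cfg$wall_region_angles`).  Analytic contours and the true per-angle
#' thickness/region tables ship with each slice.
#'
#' @param cfg a [synth_config()].
#' @param n_slices number of slices (default `cfg$n_slices`).
#' @param seed optional override of `cfg$seed`.
#' @param angular_resolution spacing (degrees) of the truth table.
#' @return list of `slice_mask` objects; each has `label` (matrix),
#'   `lge` (matrix), `spacing` (mm), `center_px`, `truth` (data.frame:
#'   angle, thickness, region), `endo_radius`.
#' @export
gen_lv_slices <- function(cfg, n_slices = cfg$n_slices, seed = NULL,
                          angular_resolution = 1) {
  cfg <- validate_synth_config(cfg)
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  angles <- seq(0, 360 - angular_resolution, by = angular_resolution)
  region <- angle_region(angles, cfg$wall_region_angles)
  ksd <- 1.5 / angular_resolution
  corr <- popvar_correction(region, length(angles), ksd)
  with_seed(derive_seed(seed, 29L), {
    lapply(seq_len(n_slices), function(s) {
      mu <- cfg$wall_thickness_mean_by_region[region]
      # band-limited angular noise (circular Gaussian smoothing, unit
      # marginal variance): white per-degree noise would be averaged
      # away inside each ray's pixel footprint and the measured
      # variance would undershoot the planted value.  The noise scale is
      # corrected per region so the *expected population variance over
      # the region's angles* equals the configured value (correlation
      # over a finite sector otherwise biases it low).
      sdv <- sqrt(cfg$wall_thickness_variance_by_region[region]) *
        corr[region]
      th <- mu + sdv * smooth_circular_noise(length(angles), ksd)
      for (tries in 1:20) {                # resample non-physical draws
        bad <- th <= 0.5
        if (!any(bad)) break
        th[bad] <- mu[bad] + sdv[bad] * rnorm(sum(bad))
      }
      if (any(th <= 0)) stop("could not draw positive wall thickness")
      rasterize_slice(th, angles, region, cfg)
    })
  })
}

# Per-region factor 1/sqrt(1 - mean pairwise correlation) such that the
# population variance of the correlated field over each region's angle
# set has the nominal expectation.
popvar_correction <- function(region, n, kernel_sd) {
  half <- max(1L, ceiling(3 * kernel_sd))
  j <- -half:half
  w <- exp(-j^2 / (2 * kernel_sd^2))
  rho_tab <- vapply(0:(n %/% 2), function(l)
    sum(w * exp(-(j + l)^2 / (2 * kernel_sd^2))) / sum(w^2), 0)
  out <- c()
  for (r in unique(region)) {
    ix <- which(region == r)
    d <- abs(outer(ix, ix, "-"))
    d <- pmin(d, n - d)
    m <- mean(rho_tab[d + 1L])
    out[r] <- 1 / sqrt(max(1 - m, 0.1))
  }
  out
}

# Unit-variance correlated noise on a circle: i.i.d. Gaussians smoothed
# with a wrapped Gaussian kernel, renormalized analytically.
smooth_circular_noise <- function(n, kernel_sd) {
  z <- rnorm(n)
  if (kernel_sd <= 0) return(z)
  half <- max(1L, ceiling(3 * kernel_sd))
  w <- exp(-(-half:half)^2 / (2 * kernel_sd^2))
  idx <- outer(seq_len(n), -half:half, function(i, j) (i + j - 1L) %% n + 1L)
  as.vector(matrix(z[idx], n) %*% w) / sqrt(sum(w^2))
}

# Region label for angles (degrees) given half-open sector definitions.
angle_region <- function(angles, sectors) {
  lab <- rep("remote", length(angles))
  in_sector <- function(a, s) a >= s[1] & a < s[2]
  for (nm in names(sectors)) {
    ss <- sectors[[nm]]
    if (!is.list(ss)) ss <- list(ss)
    for (s in ss) lab[in_sector(angles, s)] <- nm
  }
  lab
}

# Rasterize one slice: polar-defined contours onto a pixel grid.
rasterize_slice <- function(th, angles, region, cfg) {
  sp <- cfg$pixel_spacing
  r_endo <- cfg$endo_radius
  half <- ceiling((r_endo + max(th) + 6) / sp)
  ax <- (-half:half) * sp
  nx <- length(ax)
  px <- matrix(rep(ax, nx), nx, nx)              # x varies along rows
  py <- matrix(rep(ax, each = nx), nx, nx)
  rr <- sqrt(px^2 + py^2)
  aa <- (atan2(py, px) * 180 / pi) %% 360
  # per-pixel epicardial radius from the per-angle thickness table
  ia <- findInterval(aa, c(angles, 360), rightmost.closed = TRUE)
  ia[ia > length(angles)] <- length(angles)
  r_epi <- r_endo + th[ia]
  label <- matrix(0L, nx, nx)
  label[rr < r_endo] <- 1L
  label[rr >= r_endo & rr < r_epi] <- 2L
  lge <- matrix(0, nx, nx)
  myo <- label == 2L
  lge[myo] <- cfg$lge_intensity[region[ia[myo]]] +
    rnorm(sum(myo), sd = cfg$lge_noise_sd)
  lge[lge < 0] <- 0
  structure(list(label = label, lge = lge, spacing = sp,
                 center_px = c((nx + 1) / 2, (nx + 1) / 2),
                 endo_radius = r_endo,
                 truth = data.frame(angle = angles, thickness = th,
                                    region = region)),
            class = "slice_mask")
}
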