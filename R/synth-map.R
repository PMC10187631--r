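#' Generate a synthetic endocardial map with planted ARI heterogeneity
#'
#' Builds a half-ellipsoid left-ventricular endocardial surface (apex to
#' base, long axis 80 mm, short axis 50 mm) sampled on a structured
#' ring/angle grid with an explicit triangulation.  Points are split into
#' infarct / border zone (BZ) / remote by surface distance from an
#' antero-apical infarct centre so the requested `region_fractions` are hit
#' exactly on the realized points; bipolar voltages are drawn inside each
#' region's diagnostic band (infarct < 0.5 mV, BZ 0.5-1.5 mV, remote
#' > 1.5 mV) so that voltage thresholding recovers the labels.  Activation
#' times come from a planar wavefront; recovery = activation + a regional
#' ARI field.
#'
#' The ARI field is piecewise-constant regional means plus a spatially
#' correlated Gaussian field (distance-weighted smoothing of i.i.d. noise,
#' correlation length `cfg$ari_corr_length`).  The per-region noise scale is
#' *calibrated* by fixed-point iteration so that the mean within-region
#' local SD at radius `cfg$het_radius` equals `cfg$ari_local_sd_by_region`
#' — i.e. the generator plants the heterogeneity statistic itself, not just
#' a marginal SD (spatial correlation and regional mean steps would
#' otherwise bias the planted value).  With a zero SD target the field is
#' exactly the regional mean.
#'
#' @param cfg a [synth_config()].
#' @param electrograms logical; also synthesize one unipolar electrogram
#'   per point via [gen_electrogram()] (slower).
#' @param seed optional override of `cfg$seed`.
#' @return list of class `endocardial_map` with `points` (n x 3 mm),
#'   `triangles` (m x 3 indices), `bipolar_voltage` (mV), `ari` (ms, the
#'   true field), `apex_index`, `base_axis`, `egms` (list or NULL), and
#'   `truth` (data.frame: point, at, rt, ari, region, voltage).
#' @examples
#' m <- gen_endocardial_map(synth_config(seed = 1, n_points = 120),
#'                          electrograms = FALSE)
#' table(m$truth$region)
#' @export
gen_endocardial_map <- function(cfg, electrograms = TRUE, seed = NULL) {
  cfg <- validate_synth_config(cfg)
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  if (cfg$n_points < 50) stop("n_points < 50: mesh would be degenerate")
  geo <- ellipsoid_mesh(cfg$n_points)
  n <- nrow(geo$points)

  with_seed(seed, {
    # --- regions: contiguous patches by surface distance from infarct core
    centre <- geo$points[which.min(
      rowSums(sweep(geo$points, 2, ellipsoid_xyz(0.35, 0), "-")^2)), ]
    d_centre <- sqrt(rowSums(sweep(geo$points, 2, centre, "-")^2))
    ord <- order(d_centre)
    n_inf <- round(cfg$region_fractions[["infarct"]] * n)
    n_bz <- min(round(cfg$region_fractions[["bz"]] * n), n - n_inf)
    region <- rep("remote", n)
    region[ord[seq_len(n_inf)]] <- "infarct"
    region[ord[n_inf + seq_len(n_bz)]] <- "bz"

    # voltages drawn inside each diagnostic band, margins off the cutoffs
    voltage <- numeric(n)
    voltage[region == "infarct"] <- runif(sum(region == "infarct"), 0.05, 0.45)
    voltage[region == "bz"] <- runif(sum(region == "bz"), 0.55, 1.45)
    voltage[region == "remote"] <- runif(sum(region == "remote"), 1.55, 5.0)

    # --- activation: planar wavefront at 1 mm/ms
    dir <- c(0.5, 0.3, 0.8); dir <- dir / sqrt(sum(dir^2))
    proj <- as.vector(geo$points %*% dir)
    at <- 20 + (proj - min(proj)) / 1.0

    # --- ARI field: regional means + calibrated correlated noise
    m_field <- unname(cfg$ari_mean_by_region[region])
    s_unit <- smoothed_unit_field(geo$points, cfg$ari_corr_length)
    cal <- calibrate_local_sd(geo$points, m_field, s_unit, region,
                              targets = cfg$ari_local_sd_by_region,
                              radius = cfg$het_radius)
    ari <- unname(m_field + unname(cal[region]) * s_unit)
    rt <- at + ari

    egms <- NULL
    if (electrograms) {
      dur <- max(rt) + 150
      egms <- lapply(seq_len(n), function(i)
        gen_electrogram(at[i], rt[i], fs = cfg$fs_egm,
                        noise_sd = cfg$egm_noise_sd, duration = dur,
                        seed = derive_seed(seed, i)))
    }

    structure(list(
      points = geo$points, triangles = geo$triangles,
      bipolar_voltage = voltage, ari = ari,
      apex_index = geo$apex_index, base_axis = geo$base_axis,
      egms = egms,
      truth = data.frame(point = seq_len(n), at = at, rt = rt, ari = ari,
                         region = region, voltage = voltage)),
      class = "endocardial_map")
  })
}

# Half-ellipsoid of revolution (apex at -L on z, base ring in z = 0 plane)
# sampled on a ring/angle grid and triangulated. Realized point count is
# the closest grid-representable value to n_points.
ellipsoid_mesh <- function(n_points) {
  n_theta <- max(8L, round(sqrt(2 * (n_points - 1))))
  n_u <- max(3L, round((n_points - 1) / n_theta))
  u <- seq_len(n_u) / n_u                        # apex (0) excluded; base = 1
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  grid <- expand.grid(theta = theta, u = u)
  pts <- rbind(ellipsoid_xyz(0, 0), ellipsoid_xyz(grid$u, grid$theta))
  idx <- function(j, k) 1L + (j - 1L) * n_theta + ((k - 1L) %% n_theta) + 1L
  tris <- list()
  for (k in seq_len(n_theta))                     # apex fan
    tris[[length(tris) + 1L]] <- c(1L, idx(1, k), idx(1, k + 1))
  for (j in seq_len(n_u - 1L)) for (k in seq_len(n_theta)) {
    tris[[length(tris) + 1L]] <- c(idx(j, k), idx(j + 1, k), idx(j, k + 1))
    tris[[length(tris) + 1L]] <- c(idx(j, k + 1), idx(j + 1, k),
                                   idx(j + 1, k + 1))
  }
  list(points = pts, triangles = do.call(rbind, tris), apex_index = 1L,
       base_axis = c(0, 0, 1), n_u = n_u, n_theta = n_theta)
}

# Surface point at normalized apex->base coordinate u in [0,1], angle theta.
ellipsoid_xyz <- function(u, theta, long = 40, short = 25) {
  phi <- u * pi / 2
  cbind(short * sin(phi) * cos(theta), short * sin(phi) * sin(theta),
        -long * cos(phi))
}

# Distance-weighted smoothing of i.i.d. N(0,1) noise; weights
# exp(-d^2 / (2 l^2)); normalized so every point has unit marginal
# variance. l = 0 returns the i.i.d. field.
smoothed_unit_field <- function(points, corr_length) {
  z <- rnorm(nrow(points))
  if (corr_length <= 0) return(z)
  d2 <- as.matrix(dist(points))^2
  w <- exp(-d2 / (2 * corr_length^2))
  as.vector(w %*% z) / sqrt(rowSums(w^2))
}

# Fixed-point calibration of per-region noise scales so that the mean
# local SD (radius-ball sample SD of the assembled field) over each
# region's points equals the target. Regions with a zero target get scale
# 0 (field exactly equals the regional mean there).
calibrate_local_sd <- function(points, m_field, s_unit, region, targets,
                               radius, min_n = 5L, iter = 10L) {
  nb <- ball_neighbors(points, radius)
  scales <- targets
  for (it in seq_len(iter)) {
    fld <- m_field + unname(scales[region]) * s_unit
    lsd <- vapply(nb, function(ix)
      if (length(ix) >= min_n) sd(fld[ix]) else NA_real_, 0)
    for (r in names(scales)) {
      if (targets[[r]] <= 0) { scales[r] <- 0; next }
      L <- mean(lsd[region == r], na.rm = TRUE)
      if (is.finite(L) && L > 0)
        scales[r] <- scales[[r]] * targets[[r]] / L
    }
  }
  scales
}

# Indices (including self) within `radius` mm of each point.
ball_neighbors <- function(points, radius) {
  d <- as.matrix(dist(points))
  apply(d <= radius, 1, which, simplify = FALSE)
}

#' Generate per-animal arrhythmia-inducibility indices
#'
#' Emulates the programmed-stimulation inducibility score (0 =
#' non-inducible after three extrastimuli ... `scale_max` = induced with a
#' single extrastimulus) as a linear response to BZ ARI heterogeneity plus
#' Gaussian noise, clipped to the scale range.  The index is kept
#' continuous (not rounded) so the slope-recovery contract of the
#' downstream regression is exact.
#'
#' @param het per-animal BZ heterogeneity values (ms).
#' @param slope,intercept linear model parameters (index per ms; index).
#' @param noise_sd Gaussian noise SD (index units).
#' @param scale_max top of the ordinal scale.
#' @param seed RNG seed.
#' @return data.frame with `animal`, `bz_heterogeneity`, `index`.
#' @export
gen_inducibility <- function(het, slope = 1, intercept = -1,
                             noise_sd = 0.5, scale_max = 4, seed = 1L) {
  idx <- with_seed(seed,
                   intercept + slope * het + rnorm(length(het), sd = noise_sd))
  data.frame(animal = seq_along(het), bz_heterogeneity = het,
             index = pmin(pmax(idx, 0), scale_max))
}
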