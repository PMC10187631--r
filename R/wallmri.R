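#' Radial wall thickness from a short-axis segmentation
#'
#' Casts rays from the blood-pool centroid at each angle and measures the
#' chord length of the ray's intersection with the myocardium label — the
#' wall thickness "in the radial direction".  The myocardium must form a
#' closed annulus around the blood pool: every ray has to leave the blood
#' pool into myocardium before reaching background; violations name the
#' failing angles.
#'
#' @param mask a `slice_mask` (see [gen_lv_slices()]) or list with
#'   `label` (matrix: 0 background, 1 blood pool, 2 myocardium) and
#'   `spacing` (mm/pixel).
#' @param angular_step ray spacing (degrees, default 1).
#' @param step_frac radial sampling step as a fraction of a pixel.
#' @return object of class `wall_profile`: data.frame with `angle`
#'   (degrees), `thickness` (mm; `NA` where the ray misses myocardium),
#'   `r_endo` (mm, first myocardial sample radius); attribute `spacing`.
#' @export
wall_thickness <- function(mask, angular_step = 1, step_frac = 0.25) {
  label <- mask$label
  sp <- mask$spacing
  if (is.null(sp) || sp <= 0) stop("mask needs a positive pixel spacing")
  bp <- which(label == 1L, arr.ind = TRUE)
  if (nrow(bp) == 0) stop("no blood-pool pixels (label 1)")
  ctr <- colMeans(bp)
  angles <- seq(0, 360 - angular_step, by = angular_step)
  rmax <- max(dim(label)) * sp
  step <- step_frac * sp
  rs <- seq(step, rmax, by = step)
  # bilinear interpolation of the myocardium/background indicators gives
  # sub-pixel boundary localization (plain nearest-pixel lookup leaves
  # ~0.7 px jitter per boundary crossing)
  myo_ind <- (label == 2L) * 1
  bg_ind <- (label == 0L) * 1
  thickness <- rep(NA_real_, length(angles))
  r_endo <- rep(NA_real_, length(angles))
  broken <- logical(length(angles))
  for (k in seq_along(angles)) {
    a <- angles[k] * pi / 180
    fx <- ctr[1] + rs * cos(a) / sp
    fy <- ctr[2] + rs * sin(a) / sp
    ok <- fx >= 1 & fx <= nrow(label) & fy >= 1 & fy <= ncol(label)
    myo <- bilinear(myo_ind, fx[ok], fy[ok]) >= 0.5
    bg <- bilinear(bg_ind, fx[ok], fy[ok]) >= 0.5
    hit <- which(myo)
    if (length(hit) == 0) { broken[k] <- TRUE; next }
    # annulus check: no background gap between the pool and the wall
    if (any(bg[seq_len(hit[1] - 1)])) { broken[k] <- TRUE; next }
    thickness[k] <- sum(myo) * step
    r_endo[k] <- rs[ok][hit[1]]
  }
  if (mean(broken) > 0.05)
    stop(sprintf(paste0("myocardium is not a closed annulus: %d/%d rays ",
                        "hit background before or instead of the wall"),
                 sum(broken), length(angles)))
  out <- data.frame(angle = angles, thickness = thickness, r_endo = r_endo)
  attr(out, "spacing") <- sp
  attr(out, "center") <- ctr
  class(out) <- c("wall_profile", "data.frame")
  out
}

# Bilinear interpolation of matrix `m` at fractional indices (fx, fy).
bilinear <- function(m, fx, fy) {
  x0 <- pmin(pmax(floor(fx), 1L), nrow(m) - 1L)
  y0 <- pmin(pmax(floor(fy), 1L), ncol(m) - 1L)
  dx <- fx - x0
  dy <- fy - y0
  m[cbind(x0, y0)] * (1 - dx) * (1 - dy) +
    m[cbind(x0 + 1L, y0)] * dx * (1 - dy) +
    m[cbind(x0, y0 + 1L)] * (1 - dx) * dy +
    m[cbind(x0 + 1L, y0 + 1L)] * dx * dy
}

#' Label myocardium by late-gadolinium-enhancement intensity
#'
#' Normalizes to a robust maximum (99th percentile of myocardial
#' intensity, guarding single-voxel outliers) and applies the diagnostic
#' bands: > 70% core, 20-70% border zone, < 20% remote; the 0.2 and 0.7
#' cut points belong to the BZ (`[0.2, 0.7]` closed, declared).  Per-angle
#' labels are the majority label of myocardial pixels along the centroid
#' ray; per-angle mean LGE intensity is also returned.
#'
#' @param mask a `slice_mask` with an `lge` intensity image.
#' @inheritParams wall_thickness
#' @return data.frame with `angle`, `region` (`core`/`bz`/`remote`),
#'   `lge_mean` (normalized units); attribute `robust_max`.
#' @export
lge_classify <- function(mask, angular_step = 1, step_frac = 0.25) {
  if (is.null(mask$lge)) stop("mask has no LGE intensity channel")
  label <- mask$label
  sp <- mask$spacing
  myo_int <- mask$lge[label == 2L]
  robust_max <- quantile(myo_int, 0.99, names = FALSE)
  if (robust_max <= 0) robust_max <- max(myo_int, 1e-12)
  bp <- which(label == 1L, arr.ind = TRUE)
  ctr <- colMeans(bp)
  angles <- seq(0, 360 - angular_step, by = angular_step)
  step <- step_frac * sp
  rs <- seq(step, max(dim(label)) * sp, by = step)
  pixel_band <- function(x) {
    b <- rep("remote", length(x))
    b[x >= 0.2 & x <= 0.7] <- "bz"
    b[x > 0.7] <- "core"
    b
  }
  region <- character(length(angles))
  lge_mean <- rep(NA_real_, length(angles))
  for (k in seq_along(angles)) {
    a <- angles[k] * pi / 180
    ix <- round(ctr[1] + rs * cos(a) / sp)
    iy <- round(ctr[2] + rs * sin(a) / sp)
    ok <- ix >= 1 & ix <= nrow(label) & iy >= 1 & iy <= ncol(label)
    ij <- cbind(ix[ok], iy[ok])
    myo <- label[ij] == 2L
    if (!any(myo)) { region[k] <- NA_character_; next }
    xn <- mask$lge[ij][myo] / robust_max
    bands <- pixel_band(xn)
    region[k] <- names(sort(table(bands), decreasing = TRUE))[1]
    lge_mean[k] <- mean(xn)
  }
  out <- data.frame(angle = angles, region = region, lge_mean = lge_mean)
  attr(out, "robust_max") <- robust_max
  out
}

#' Regional wall-thickness variance of a slice
#'
#' Population variance (n denominator) of the per-angle thickness within
#' each region of the slice — the local-heterogeneity metric of the
#' imaging stage.
#'
#' @param profile a `wall_profile` (see [wall_thickness()]).
#' @param regions region label per angle (e.g. from [lge_classify()] or
#'   the generator truth).
#' @param min_angles minimum defined angles per region.
#' @return data.frame with `region`, `variance` (mm^2), `mean_thickness`
#'   (mm), `n_angles`.
#' @export
wall_variance <- function(profile, regions, min_angles = 3L) {
  stopifnot(nrow(profile) == length(regions))
  ok <- !is.na(profile$thickness) & !is.na(regions)
  parts <- lapply(split(profile$thickness[ok],
                        as.character(regions)[ok]), function(v) {
    if (length(v) < min_angles)
      stop("region with fewer than min_angles defined angles")
    data.frame(variance = mean((v - mean(v))^2),
               mean_thickness = mean(v), n_angles = length(v))
  })
  out <- do.call(rbind, Map(function(r, p) cbind(region = r, p),
                            names(parts), parts))
  rownames(out) <- NULL
  out
}

#' Per-animal wall-heterogeneity summary across slices
#'
#' Aggregates per-slice regional variances: for each (animal, region),
#' heterogeneity = SD of the per-slice variances (and their mean).
#'
#' @param slice_variances data.frame rbind of [wall_variance()] outputs
#'   with added `slice` and `animal` columns.
#' @return data.frame with `animal`, `region`, `mean_variance`,
#'   `sd_variance`, `n_slices`.
#' @export
wall_summary <- function(slice_variances) {
  stopifnot(all(c("animal", "region", "variance") %in%
                  names(slice_variances)))
  agg <- do.call(rbind, lapply(
    split(slice_variances, slice_variances[c("animal", "region")],
          drop = TRUE), function(g)
            data.frame(animal = g$animal[1], region = g$region[1],
                       mean_variance = mean(g$variance),
                       sd_variance = if (nrow(g) >= 2) sd(g$variance)
                       else NA_real_,
                       n_slices = nrow(g))))
  rownames(agg) <- NULL
  agg
}

#' Discrete curvature of a closed contour
#'
#' Least-squares circle fit (Kasa method) over a sliding angular window;
#' curvature is the reciprocal fitted radius at each contour point.
#'
#' @param xy n x 2 matrix of contour points, ordered, closed implicitly.
#' @param window_deg arc window for each local fit (degrees of contour
#'   index, default 15).
#' @return numeric curvature (1/mm) per contour point.
#' @export
contour_curvature <- function(xy, window_deg = 15) {
  n <- nrow(xy)
  if (n < 8) stop("contour too short for curvature estimation")
  hw <- max(2L, round(window_deg / 360 * n / 2))
  vapply(seq_len(n), function(i) {
    ix <- ((i - hw):(i + hw) - 1L) %% n + 1L
    fit_circle_radius(xy[ix, , drop = FALSE])
  }, 0)
}

# Kasa circle fit; returns curvature 1/R (0 for a collinear window).
fit_circle_radius <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  a <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(a, b), error = function(e) NULL)
  if (is.null(sol)) return(0)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(0)
  1 / sqrt(r2)
}

#' Across-slice variability of regional LGE intensity
#'
#' Per (slice, region) mean LGE intensity, then per-region variability =
#' SD across slices.
#'
#' @param slice_lge data.frame rbind of [lge_classify()] outputs with an
#'   added `slice` column.
#' @return list: `per_slice` (slice, region, mean_intensity) and
#'   `variability` (region, sd_across_slices, n_slices).
#' @export
lge_variability <- function(slice_lge) {
  stopifnot(all(c("slice", "region", "lge_mean") %in% names(slice_lge)))
  ok <- !is.na(slice_lge$region) & !is.na(slice_lge$lge_mean)
  per <- aggregate(lge_mean ~ slice + region, data = slice_lge[ok, ],
                   FUN = mean)
  names(per)[3] <- "mean_intensity"
  vb <- do.call(rbind, lapply(split(per, per$region), function(g)
    data.frame(region = g$region[1],
               sd_across_slices = if (nrow(g) >= 2) sd(g$mean_intensity)
               else NA_real_,
               n_slices = nrow(g))))
  rownames(vb) <- NULL
  list(per_slice = per, variability = vb)
}
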