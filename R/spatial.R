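#' Classify endocardial points into infarct / border zone / remote
#'
#' Applies the bipolar-voltage criteria used for electroanatomical
#' substrate mapping: border zone (BZ) between 0.5 and 1.5 mV, infarct
#' below, remote above.  Boundaries use half-open bins
#' `[0, 0.5)` infarct, `[0.5, 1.5)` BZ, `[1.5, Inf)` remote — a
#' measure-zero convention declared for reproducibility.
#'
#' @param voltage bipolar voltages (mV), finite and non-negative.
#' @return factor with levels `infarct`, `bz`, `remote`.
#' @examples
#' classify_regions(c(0.4, 1.0, 2.0))
#' @export
classify_regions <- function(voltage) {
  if (any(!is.finite(voltage))) stop("voltages must be finite")
  if (any(voltage < 0)) stop("bipolar voltage cannot be negative")
  cut(voltage, breaks = c(0, 0.5, 1.5, Inf), right = FALSE,
      labels = c("infarct", "bz", "remote"), include.lowest = TRUE)
}

#' Local ARI heterogeneity map
#'
#' For every endocardial point, the sample SD (n-1 denominator) of ARI
#' values over all points within `radius` (3D Euclidean ball, centre
#' included) — the local repolarization-heterogeneity statistic.  Points
#' whose neighborhood holds fewer than `min_n` ARI values are flagged
#' (`NA` local SD).
#'
#' @param map an `endocardial_map` (see [gen_endocardial_map()]) or any
#'   list with `points` (n x 3, mm) and `ari` (ms per point; `NA` allowed).
#' @param radius neighborhood radius (mm); default 10 (the 1-cm rule).
#' @param min_n minimum neighborhood size for a defined local SD.
#' @return object of class `heterogeneity_map`: data.frame with
#'   `local_sd` (ms), `n_neighbors`; attributes `radius`, `min_n`.
#' @export
local_heterogeneity <- function(map, radius = 10, min_n = 5L) {
  if (radius <= 0) stop("radius must be positive")
  pts <- map$points
  ari <- map$ari
  stopifnot(nrow(pts) == length(ari))
  if (sum(!is.na(ari)) < min_n)
    stop("ARI defined on fewer than min_n points")
  d <- as.matrix(dist(pts))
  res <- t(vapply(seq_len(nrow(pts)), function(i) {
    v <- ari[d[i, ] <= radius]
    v <- v[!is.na(v)]
    if (length(v) < min_n) c(NA_real_, length(v))
    else c(sd(v), length(v))
  }, numeric(2)))
  out <- data.frame(local_sd = res[, 1], n_neighbors = as.integer(res[, 2]))
  attr(out, "radius") <- radius
  attr(out, "min_n") <- min_n
  class(out) <- c("heterogeneity_map", "data.frame")
  out
}

#' Per-animal regional summary of a scalar measurement
#'
#' The common currency of the cross-scale analyses: per (animal, region)
#' mean, SD and n of any scalar (ARI, local SD, APD, distance, ...), plus
#' within-animal region differences (each region minus `ref_region`)
#' computed *before* any cross-animal aggregation, so heart-rate-like
#' animal offsets cancel.
#'
#' @param values numeric measurements.
#' @param labels region label per value (factor or character).
#' @param animal animal id per value (scalar or vector).
#' @param ref_region region used as the within-animal reference for
#'   differences (default `"remote"`).
#' @return list of class `regional_summary`: `stats` (animal, region,
#'   mean, sd, n; sd is `NA` when n < 2) and `differences` (animal,
#'   region, diff_mean = mean(region) - mean(ref)).
#' @examples
#' regional_summary(c(1, 2, 3), rep("bz", 3), animal = 1)$stats
#' @export
regional_summary <- function(values, labels, animal = 1L,
                             ref_region = "remote") {
  labels <- as.character(labels)
  if (length(animal) == 1L) animal <- rep(animal, length(values))
  stopifnot(length(values) == length(labels),
            length(values) == length(animal))
  keep <- !is.na(values)
  df <- data.frame(animal = animal[keep], region = labels[keep],
                   value = values[keep])
  agg <- do.call(rbind, lapply(split(df, df[c("animal", "region")],
                                     drop = TRUE), function(g)
    data.frame(animal = g$animal[1], region = g$region[1],
               mean = mean(g$value),
               sd = if (nrow(g) >= 2) sd(g$value) else NA_real_,
               n = nrow(g))))
  rownames(agg) <- NULL
  diffs <- NULL
  for (a in unique(agg$animal)) {
    sub <- agg[agg$animal == a, ]
    if (!ref_region %in% sub$region) next
    ref <- sub$mean[sub$region == ref_region]
    oth <- sub[sub$region != ref_region, ]
    if (nrow(oth) > 0)
      diffs <- rbind(diffs, data.frame(animal = a, region = oth$region,
                                       diff_mean = oth$mean - ref))
  }
  structure(list(stats = agg, differences = diffs),
            class = "regional_summary")
}

#' @export
print.regional_summary <- function(x, ...) {
  cat("<regional_summary>\n")
  print(x$stats)
  invisible(x)
}

#' Project an endocardial map to a polar (bullseye) map
#'
#' Maps every surface point to (r, theta): r is the normalized apex-to-base
#' position along the long axis (apex r = 0, mitral annulus r = 1), theta
#' the circumferential angle.  A channel is rasterized onto an (r, theta)
#' grid by nearest point in polar coordinates; region labels can be
#' rasterized the same way so label boundaries trace the infarct/BZ
#' contours.
#'
#' @param map an `endocardial_map` with `apex_index` and `base_axis` set.
#' @param channel numeric per-point values to rasterize (e.g. `map$ari`).
#' @param n_r,n_theta grid resolution.
#' @return list of class `polar_map`: `grid` (n_r x n_theta values),
#'   `point_r`, `point_theta` (per source point), `r_centers`,
#'   `theta_centers`, `nearest_point` (grid index -> source point).
#' @export
project_polar <- function(map, channel, n_r = 24L, n_theta = 48L) {
  if (is.null(map$apex_index) || is.null(map$base_axis))
    stop("map must carry apex_index and base_axis annotations")
  stopifnot(length(channel) == nrow(map$points))
  ax <- map$base_axis / sqrt(sum(map$base_axis^2))
  z <- as.vector(map$points %*% ax)
  z_apex <- z[map$apex_index]
  z_base <- max(z)
  if (abs(z_base - z_apex) < 1e-12) stop("degenerate long axis")
  r <- (z - z_apex) / (z_base - z_apex)
  # circumferential angle in the plane orthogonal to the axis
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2], ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  theta <- atan2(map$points %*% e2, map$points %*% e1) %% (2 * pi)
  r_c <- (seq_len(n_r) - 0.5) / n_r
  th_c <- 2 * pi * (seq_len(n_theta) - 0.5) / n_theta
  grid <- matrix(NA_real_, n_r, n_theta)
  nearest <- matrix(NA_integer_, n_r, n_theta)
  for (i in seq_len(n_r)) for (j in seq_len(n_theta)) {
    dth <- abs(theta - th_c[j])
    dth <- pmin(dth, 2 * pi - dth)
    # polar metric: radial offset + arc length at the cell's radius
    dd <- (r - r_c[i])^2 + (r_c[i] * dth / pi)^2
    k <- which.min(dd)
    nearest[i, j] <- k
    grid[i, j] <- channel[k]
  }
  structure(list(grid = grid, point_r = r, point_theta = as.vector(theta),
                 r_centers = r_c, theta_centers = th_c,
                 nearest_point = nearest),
            class = "polar_map")
}

# Shared ordinary-least-squares fit used by every cross-scale regression.
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0) stop("zero variance in predictor")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # collinear input is legitimate
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]), n = length(x))
}

#' Regression of arrhythmia inducibility on BZ heterogeneity
#'
#' Ordinary least squares of the inducibility index on per-animal BZ ARI
#' heterogeneity, as in the in vivo arrhythmogenicity correlation.
#'
#' @param records data.frame with columns `bz_heterogeneity` (ms) and
#'   `index` (inducibility score); >= 3 rows.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
inducibility_regression <- function(records) {
  stopifnot(all(c("bz_heterogeneity", "index") %in% names(records)))
  ols_fit(records$bz_heterogeneity, records$index)
}
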