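#' Normalize counts and embed nuclei in PC space
#'
#' Depth-normalizes each nucleus to 10^4 counts, log1p-transforms, selects
#' variable genes by residual from a log-log variance-mean loess trend,
#' z-scales genes and runs PCA.  The number of retained components is
#' either fixed or chosen by a permutation significance rule: components
#' whose variance exceeds the 95th percentile of the leading variance of
#' `n_perm` gene-wise permuted matrices (structureless nulls) are kept.
#'
#' @param counts gene x nucleus matrix (dense or `Matrix` sparse), or a
#'   `count_dataset`.
#' @param n_var_genes number of variable genes (capped at genes present).
#' @param n_components `"auto"` (permutation rule) or an integer.
#' @param n_perm permutations for the `"auto"` rule.
#' @param max_components components computed before selection.
#' @param min_cells_frac genes detected in fewer than this fraction of
#'   nuclei are dropped before selection.
#' @param seed RNG seed for the permutations.
#' @return object of class `pc_embedding`: `coordinates` (nucleus x
#'   component), `sdev`, `n_components`, `var_genes`, `perm_threshold`
#'   (NULL when `n_components` is fixed).
#' @export
normalize_and_embed <- function(counts, n_var_genes = 500,
                                n_components = "auto", n_perm = 20L,
                                max_components = 30L,
                                min_cells_frac = 0.01, seed = 1L) {
  if (inherits(counts, "count_dataset")) counts <- counts$counts
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  n_nuc <- ncol(counts)
  if (n_nuc < 20) stop("need >= 20 nuclei")
  if (n_var_genes > nrow(counts))
    stop("n_var_genes exceeds genes present")
  detected <- Matrix::rowMeans(counts > 0) >= min_cells_frac
  counts <- counts[detected, , drop = FALSE]
  depth <- Matrix::colSums(counts)
  if (any(depth == 0)) stop("all-zero nuclei present; filter on load")
  x <- log1p(t(t(as.matrix(counts)) / depth * 1e4))

  gm <- rowMeans(x)
  gv <- apply(x, 1, var)
  use <- gv > 0 & gm > 0
  fit <- loess(log10(gv[use]) ~ log10(gm[use]), span = 0.5,
               degree = 2, family = "symmetric")
  resid <- log10(gv[use]) - predict(fit)
  n_var_genes <- min(n_var_genes, sum(use))
  names(resid) <- rownames(counts)[use]
  vg <- names(sort(resid, decreasing = TRUE))[seq_len(n_var_genes)]

  xs <- t(scale(t(x[vg, , drop = FALSE])))
  xs[!is.finite(xs)] <- 0
  k <- as.integer(min(max_components, n_nuc - 1L, n_var_genes))
  pc <- prcomp(t(xs), center = FALSE, rank. = k)

  perm_threshold <- NULL
  if (identical(n_components, "auto")) {
    lead <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      xp <- t(apply(xs, 1, sample))
      top_singular_value(xp)^2 / (n_nuc - 1)
    }, 0))
    perm_threshold <- unname(quantile(lead, 0.95))
    n_components <- max(1L, sum(pc$sdev[seq_len(k)]^2 > perm_threshold))
  }
  n_components <- as.integer(min(as.integer(n_components), k))
  structure(list(coordinates = pc$x[, seq_len(n_components), drop = FALSE],
                 sdev = pc$sdev, n_components = n_components,
                 var_genes = vg, perm_threshold = perm_threshold),
            class = "pc_embedding")
}

# Leading singular value by power iteration on A^T A (A genes x cells).
top_singular_value <- function(a, iter = 30L) {
  v <- rnorm(ncol(a))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iter)) {
    w <- as.vector(crossprod(a, a %*% v))
    nv <- sqrt(sum(w^2))
    if (nv == 0) return(0)
    v <- w / nv
  }
  sqrt(sum((a %*% v)^2))
}

#' Mean cell-cell Euclidean distance per nucleus within its region
#'
#' For nucleus i in region R: the mean over all other nuclei j in R of the
#' Euclidean distance between their PC coordinates — the cell-cell
#' transcriptomic variability statistic.
#'
#' @param emb a `pc_embedding` (or plain coordinate matrix).
#' @param regions region label per nucleus.
#' @param animals optional animal id per nucleus (carried through for the
#'   nested test).
#' @return object of class `distance_summary`: data.frame with `nucleus`,
#'   `region`, `animal`, `mean_dist`.
#' @export
cell_cell_distance <- function(emb, regions, animals = NULL) {
  xy <- if (inherits(emb, "pc_embedding")) emb$coordinates else emb
  regions <- as.character(regions)
  stopifnot(nrow(xy) == length(regions))
  if (is.null(animals)) animals <- rep(NA_integer_, nrow(xy))
  out <- data.frame(nucleus = seq_len(nrow(xy)), region = regions,
                    animal = animals, mean_dist = NA_real_)
  for (r in unique(regions)) {
    ix <- which(regions == r)
    if (length(ix) < 2) stop("singleton region: ", r)
    d <- as.matrix(dist(xy[ix, , drop = FALSE]))
    out$mean_dist[ix] <- rowSums(d) / (length(ix) - 1)
  }
  class(out) <- c("distance_summary", "data.frame")
  out
}

#' Nested region comparison of cell-cell distances
#'
#' Collapses per-nucleus distances to per-(animal, region) means — the
#' animal is the experimental unit — then compares BZ vs remote with a
#' paired t test when both regions share the same animals (the matched
#' design) or a Welch two-sample t otherwise.  Nucleus-level medians and
#' IQRs per region are reported for box-plot parity.
#'
#' @param dist a `distance_summary` from [cell_cell_distance()] with
#'   animal ids set.
#' @param region_a,region_b the two regions compared (difference is
#'   `region_a - region_b`).
#' @return list: `p_value`, `difference` (mean of per-animal differences),
#'   `paired`, `animal_means` (data.frame), `region_stats` (median, IQR,
#'   n per region).
#' @export
nested_region_test <- function(dist, region_a = "bz",
                               region_b = "remote") {
  d <- dist[dist$region %in% c(region_a, region_b), ]
  if (anyNA(d$animal)) stop("animal ids required for the nested test")
  am <- aggregate(mean_dist ~ animal + region, data = d, FUN = mean)
  a <- am[am$region == region_a, ]
  b <- am[am$region == region_b, ]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("need >= 2 animals per region")
  paired <- setequal(a$animal, b$animal)
  if (paired) {
    b <- b[match(a$animal, b$animal), ]
    tt <- t.test(a$mean_dist, b$mean_dist, paired = TRUE)
  } else {
    tt <- t.test(a$mean_dist, b$mean_dist)
  }
  stats <- do.call(rbind, lapply(split(d$mean_dist, d$region), function(v)
    data.frame(median = median(v), iqr_lo = unname(quantile(v, 0.25)),
               iqr_hi = unname(quantile(v, 0.75)), n = length(v))))
  stats$region <- rownames(stats)
  list(p_value = tt$p.value,
       difference = mean(a$mean_dist) - mean(b$mean_dist),
       paired = paired, animal_means = am, region_stats = stats)
}
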