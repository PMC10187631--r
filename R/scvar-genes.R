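#' Regional overdispersion analysis and highly-variable-gene calling
#'
#' A moment-based stand-in for Bayesian overdispersion inference (the full
#' MCMC machinery is deliberately out of scope; outputs are labelled
#' accordingly).  Per region and gene, the negative-binomial dispersion is
#' estimated by method of moments, `phi = (var - mean) / mean^2`
#' (truncated at 0); a smooth mean-dispersion trend is fitted by log-log
#' loess; *biological* overdispersion is the ratio of observed to trend
#' dispersion.  The BZ/remote fold increase in biological overdispersion
#' is computed per gene, with uncertainty from a nucleus-level bootstrap
#' (trend held fixed across resamples).  Each gene's bootstrap tail
#' probability of a fold >= `fold_threshold` (default 1.5, i.e. a 50%
#' increase) is computed by normal approximation from the bootstrap SE
#' of the log fold.  A gene is called an HVG when that probability
#' exceeds a cutoff tuned so the expected false discovery rate stays
#' below `efdr` (default 0.10); the expectation is estimated from
#' `n_null_perm` internal region-label permutations (how many
#' permuted-data probabilities land above the cutoff, relative to the
#' observed count, plus one expected false call for conservatism), so
#' FDR control rests on a measured null, not on the bootstrap
#' probability being a calibrated posterior.
#'
#' @param counts gene x nucleus matrix or `count_dataset`.
#' @param regions region label per nucleus (`"bz"` / `"remote"`).
#' @param animals optional animal id per nucleus; when given, the
#'   internal permutations are stratified within animals so the null
#'   keeps the observed animal balance.
#' @param n_boot bootstrap resamples (default 200).
#' @param fold_threshold minimum fold increase in biological
#'   overdispersion defining an HVG.
#' @param efdr expected-false-discovery-rate bound for the probability
#'   cutoff search.
#' @param n_null_perm region-label permutations used to estimate the
#'   false-call count at each candidate cutoff.
#' @param min_cells_frac expression filter: genes detected in fewer than
#'   this fraction of nuclei (in either region) are not tested.
#' @param seed RNG seed for bootstrap and permutations (results are
#'   deterministic given it).
#' @return object of class `dispersion_result`: data.frame with `gene`,
#'   `mean_bz`, `mean_remote`, `dispersion_bz`, `dispersion_remote`
#'   (method-of-moments), `bio_bz`, `bio_remote` (trend-relative),
#'   `fold` (bio_bz / bio_remote), `prob_fold` (bootstrap tail
#'   probability), `hvg`; attributes `prob_cutoff`, `efdr_realized`,
#'   `method` (the simplification label).
#' @export
dispersion_analysis <- function(counts, regions, animals = NULL,
                                n_boot = 200L,
                                fold_threshold = 1.5, efdr = 0.10,
                                n_null_perm = 3L,
                                min_cells_frac = 0.01, seed = 1L) {
  if (inherits(counts, "count_dataset")) {
    if (missing(regions)) regions <- counts$nuclei$region
    if (is.null(animals)) animals <- counts$nuclei$animal
    counts <- counts$counts
  }
  regions <- as.character(regions)
  stopifnot(ncol(counts) == length(regions))
  for (r in c("bz", "remote"))
    if (sum(regions == r) < 20) stop("region with < 20 nuclei: ", r)
  cbz <- counts[, regions == "bz", drop = FALSE]
  crm <- counts[, regions == "remote", drop = FALSE]
  keep <- Matrix::rowMeans(cbz > 0) >= min_cells_frac &
    Matrix::rowMeans(crm > 0) >= min_cells_frac
  cbz <- as.matrix(cbz[keep, , drop = FALSE])
  crm <- as.matrix(crm[keep, , drop = FALSE])
  gene <- rownames(cbz) %||% sprintf("g%d", which(keep))

  obs <- fold_statistics(cbz, crm, n_boot, fold_threshold,
                         seed = derive_seed(seed, 1L))

  # cutoff search: estimated FDR(c) = mean permuted count above c /
  # observed count above c, over region-label permutations
  perm_prob <- NULL
  if (n_null_perm > 0) {
    pooled <- cbind(cbz, crm)
    n1 <- ncol(cbz)
    # permute region labels within animal strata so the permuted null
    # keeps the observed animal balance (animal depth effects would
    # otherwise inflate the permuted folds and cost power)
    strata <- if (is.null(animals)) rep(1L, ncol(pooled)) else
      c(animals[regions == "bz"], animals[regions == "remote"])
    in_a <- seq_len(ncol(pooled)) <= n1
    perm_prob <- unlist(lapply(seq_len(n_null_perm), function(k) {
      sel <- with_seed(derive_seed(seed, 50L + k), {
        unlist(lapply(split(seq_len(ncol(pooled)), strata), function(ix)
          sample(ix, sum(in_a[ix]))))
      })
      pk <- fold_statistics(pooled[, sel, drop = FALSE],
                            pooled[, -sel, drop = FALSE],
                            n_boot, fold_threshold,
                            seed = derive_seed(seed, 100L + k))
      pk$prob
    }))
  }
  cuts <- c(seq(0.50, 0.99, by = 0.005), 0.995, 0.999)
  cutoff <- Inf
  fdr_hat <- NA_real_
  for (cc in cuts) {
    n_obs <- sum(obs$prob > cc)
    if (n_obs == 0) next
    est <- if (is.null(perm_prob)) mean(1 - obs$prob[obs$prob > cc])
    else (sum(perm_prob > cc, na.rm = TRUE) / n_null_perm + 1) / n_obs
    if (is.finite(est) && est <= efdr) { cutoff <- cc; fdr_hat <- est; break }
  }
  hvg <- is.finite(cutoff) & obs$prob > cutoff & obs$fold >= fold_threshold

  out <- data.frame(gene = gene, mean_bz = obs$mean_a,
                    mean_remote = obs$mean_b,
                    dispersion_bz = obs$disp_a,
                    dispersion_remote = obs$disp_b, bio_bz = obs$bio_a,
                    bio_remote = obs$bio_b, fold = obs$fold,
                    se_log_fold = obs$se, prob_fold = obs$prob,
                    hvg = hvg)
  attr(out, "prob_cutoff") <- cutoff
  attr(out, "efdr_estimated") <- fdr_hat
  attr(out, "method") <-
    "moment-based NB dispersion + permutation-calibrated EFDR (non-MCMC)"
  class(out) <- c("dispersion_result", "data.frame")
  out
}

# Core fold machinery shared by the observed analysis and the internal
# permutation null: moment dispersions, pooled log-log trend, biological
# overdispersion ratio, bootstrap SE of the log fold, and the EB tail
# probability of fold >= threshold.
fold_statistics <- function(ca, cb, n_boot, fold_threshold, seed) {
  mom <- function(m, v) pmax((v - m) / m^2, 0)
  stat <- function(cm) {
    m <- rowMeans(cm)
    v <- apply(cm, 1, var)
    list(mean = m, disp = mom(m, v))
  }
  s_a <- stat(ca); s_b <- stat(cb)
  tm <- c(s_a$mean, s_b$mean); td <- c(s_a$disp, s_b$disp)
  ok <- td > 0 & tm > 0
  tdf <- data.frame(x = log(tm[ok]), y = log(td[ok]))
  trend_fit <- loess(y ~ x, data = tdf, span = 0.6, degree = 1,
                     family = "symmetric")
  xr <- range(tdf$x)
  trend <- function(m) {
    x <- pmin(pmax(log(pmax(m, 1e-12)), xr[1]), xr[2])
    p <- predict(trend_fit, newdata = data.frame(x = x))
    exp(pmin(pmax(p, -20), 20))
  }
  eps <- 1e-4
  bio_a <- (s_a$disp + eps) / (trend(s_a$mean) + eps)
  bio_b <- (s_b$disp + eps) / (trend(s_b$mean) + eps)
  fold <- bio_a / bio_b
  lf <- log(fold)
  se <- with_seed(seed, {
    boot_bio <- function(cm, B) {
      n <- ncol(cm)
      w <- matrix(0, n, B)
      for (b in seq_len(B)) {
        tab <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
        w[, b] <- tab / n
      }
      m <- cm %*% w
      q <- (cm^2) %*% w
      v <- (q - m^2) * n / (n - 1)
      d <- pmax((v - m) / m^2, 0)
      d[!is.finite(d)] <- 0
      (d + eps) / (trend(as.vector(m)) + eps)
    }
    bb <- boot_bio(ca, n_boot)
    br <- boot_bio(cb, n_boot)
    pmax(apply(log(bb / br), 1, sd), 0.01)
  })
  # normal-approximation bootstrap tail probability; a deterministic
  # function of (log fold, SE) so observed and permuted runs are
  # directly comparable in the cutoff search
  prob <- pnorm((lf - log(fold_threshold)) / se)
  prob[!is.finite(prob)] <- 0
  list(mean_a = s_a$mean, mean_b = s_b$mean, disp_a = s_a$disp,
       disp_b = s_b$disp, bio_a = bio_a, bio_b = bio_b, fold = fold,
       se = se, prob = prob)
}

#' Pseudobulk differential expression between regions
#'
#' A declared simplification of count-model differential testing that
#' keeps the animal as the experimental unit: counts are summed to
#' (animal, region) pseudobulks, normalized by median-of-ratios size
#' factors (robust to one-sided differential blocks), and
#' compared per gene with a pooled-variance t test on log2(CPM + 1) whose
#' variance is moderated toward a mean-variance loess trend (empirical
#' Bayes shrinkage with `prior_df = 10` pseudo-observations; at 2-3
#' animals per group an unmoderated t has essentially no power after
#' multiplicity adjustment).  Benjamini-Hochberg adjustment; genes are
#' flagged as differentially expressed at adjusted p < 0.05 and
#' |log2FC| > 0.25.
#'
#' @inheritParams dispersion_analysis
#' @param animals animal id per nucleus.
#' @param padj_threshold,lfc_threshold the DEG decision thresholds.
#' @return object of class `deg_result`: data.frame with `gene`,
#'   `log2fc` (BZ vs remote, from mean CPM), `p_value`, `padj`, `deg`.
#' @export
differential_expression <- function(counts, regions, animals,
                                    padj_threshold = 0.05,
                                    lfc_threshold = 0.25,
                                    min_cells_frac = 0.01) {
  if (inherits(counts, "count_dataset")) {
    if (missing(regions)) regions <- counts$nuclei$region
    if (missing(animals)) animals <- counts$nuclei$animal
    counts <- counts$counts
  }
  regions <- as.character(regions)
  grp <- interaction(animals, regions, drop = TRUE)
  pb <- vapply(levels(grp), function(g)
    Matrix::rowSums(counts[, grp == g, drop = FALSE]),
    numeric(nrow(counts)))
  pb_region <- sub("^.*\\.", "", levels(grp))
  if (sum(pb_region == "bz") < 2 || sum(pb_region == "remote") < 2)
    stop("need >= 2 animals per region for pseudobulk testing")
  keep <- Matrix::rowMeans(counts > 0) >= min_cells_frac
  pb <- pb[keep, , drop = FALSE]
  # median-of-ratios size factors: total-count scaling would let a
  # one-sided block of true DEGs shift every other gene's fold change
  # (compositional artifact)
  pos <- rowSums(pb > 0) == ncol(pb)
  logref <- rowMeans(log(pb[pos, , drop = FALSE]))
  sf <- apply(log(pb[pos, , drop = FALSE]) - logref, 2,
              function(z) exp(median(z)))
  sf <- sf / exp(mean(log(sf)))
  cpm <- t(t(pb) / (sf * mean(colSums(pb)))) * 1e6
  l <- log2(cpm + 1)
  a <- l[, pb_region == "bz", drop = FALSE]
  b <- l[, pb_region == "remote", drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  # pooled variance, moderated toward a mean-variance loess trend
  # (limma-style shrinkage with prior_df pseudo-observations): a plain t
  # at 2-3 animals per group has essentially no power after BH
  d <- na + nb - 2
  s2 <- (va * (na - 1) + vb * (nb - 1)) / d
  amean <- (ma + mb) / 2
  okv <- s2 > 0
  vdf <- data.frame(x = amean[okv], y = log(s2[okv]))
  vfit <- loess(y ~ x, data = vdf, span = 0.75, degree = 1,
                family = "symmetric")
  s2_0 <- exp(predict(vfit, newdata = data.frame(
    x = pmin(pmax(amean, min(vdf$x)), max(vdf$x)))))
  s2_0[!is.finite(s2_0)] <- exp(mean(log(s2[okv])))
  prior_df <- 10
  s2_mod <- (prior_df * s2_0 + d * s2) / (prior_df + d)
  tstat <- (ma - mb) / sqrt(s2_mod * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tstat), prior_df + d)
  p[!is.finite(p)] <- 1
  lfc <- log2((rowMeans(cpm[, pb_region == "bz", drop = FALSE]) + 1) /
                (rowMeans(cpm[, pb_region == "remote", drop = FALSE]) + 1))
  padj <- p.adjust(p, "BH")
  out <- data.frame(gene = rownames(pb) %||% sprintf("g%d", which(keep)),
                    log2fc = lfc, p_value = p, padj = padj,
                    deg = padj < padj_threshold & abs(lfc) > lfc_threshold)
  attr(out, "method") <-
    "pseudobulk-by-animal moderated t on log2 CPM (BH)"
  class(out) <- c("deg_result", "data.frame")
  out
}

#' Three-way gene-set intersection table
#'
#' Membership of every gene in the HVG set, the DEG set and a supplied
#' excitation-contraction-coupling (ECC) list, with counts for each of
#' the 7 non-empty intersection cells.
#'
#' @param hvg a `dispersion_result` or character vector of HVG names.
#' @param deg a `deg_result` or character vector of DEG names.
#' @param ecc character vector of ECC gene symbols
#'   (default [ecc_genes()]).
#' @return list: `membership` (data.frame gene/hvg/deg/ecc over the union)
#'   and `counts` (named intersection counts, e.g. `hvg_deg`).
#' @export
intersect_gene_sets <- function(hvg, deg, ecc = ecc_genes()) {
  hvg_set <- if (inherits(hvg, "dispersion_result"))
    hvg$gene[hvg$hvg] else as.character(hvg)
  deg_set <- if (inherits(deg, "deg_result"))
    deg$gene[deg$deg] else as.character(deg)
  universe <- sort(unique(c(hvg_set, deg_set, ecc)))
  mem <- data.frame(gene = universe, hvg = universe %in% hvg_set,
                    deg = universe %in% deg_set, ecc = universe %in% ecc)
  cnt <- c(
    hvg = length(hvg_set), deg = length(deg_set), ecc = length(ecc),
    hvg_deg = sum(mem$hvg & mem$deg), hvg_ecc = sum(mem$hvg & mem$ecc),
    deg_ecc = sum(mem$deg & mem$ecc),
    hvg_deg_ecc = sum(mem$hvg & mem$deg & mem$ecc))
  list(membership = mem, counts = cnt)
}

# Wilson 95% CI for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = ctr - hw, upper = ctr + hw)
}

#' Fraction of marker-positive nuclei per region
#'
#' A nucleus is positive when its count for `gene` reaches `threshold`
#' (default >= 1).  Per-region fractions with Wilson 95% CIs and a
#' chi-squared test between regions.
#'
#' @inheritParams dispersion_analysis
#' @param gene gene name (row of the matrix).
#' @param threshold positivity threshold (counts).
#' @return object of class `composition_result`: `table` (region, n,
#'   positive, fraction, ci_lower, ci_upper), `chisq_p`, `gene`.
#' @export
marker_fraction <- function(counts, gene, regions, threshold = 1) {
  if (inherits(counts, "count_dataset")) {
    if (missing(regions)) regions <- counts$nuclei$region
    counts <- counts$counts
  }
  if (!gene %in% rownames(counts)) stop("gene not found: ", gene)
  pos <- as.vector(counts[gene, ] >= threshold)
  regions <- as.character(regions)
  tab <- do.call(rbind, lapply(split(pos, regions), function(v) {
    ci <- wilson_ci(sum(v), length(v))
    data.frame(n = length(v), positive = sum(v),
               fraction = mean(v), ci_lower = ci[["lower"]],
               ci_upper = ci[["upper"]])
  }))
  tab$region <- rownames(tab)
  chisq_p <- if (length(unique(regions)) >= 2 &&
                 length(unique(pos)) == 2)
    suppressWarnings(chisq.test(table(regions, pos))$p.value) else NA_real_
  structure(list(table = tab, chisq_p = chisq_p, gene = gene),
            class = "composition_result")
}

#' Cluster composition by region
#'
#' Per-region cluster fractions (summing to 1 within region) with Wilson
#' 95% CIs, and a per-cluster chi-squared test of region association with
#' a Bonferroni multiplier equal to the number of clusters.
#'
#' @param clusters cluster label per nucleus.
#' @param regions region label per nucleus.
#' @return object of class `composition_result`: `table` (cluster,
#'   region, n, fraction, ci bounds, chisq_p, p_bonferroni).
#' @export
cluster_composition <- function(clusters, regions) {
  clusters <- as.character(clusters)
  regions <- as.character(regions)
  k <- length(unique(clusters))
  rows <- NULL
  for (cl in sort(unique(clusters))) {
    in_cl <- clusters == cl
    p_raw <- if (k >= 2 && length(unique(regions)) >= 2 &&
                 length(unique(in_cl)) == 2)
      suppressWarnings(chisq.test(table(regions, in_cl))$p.value)
    else NA_real_
    for (r in sort(unique(regions))) {
      n_r <- sum(regions == r)
      k_pos <- sum(in_cl & regions == r)
      ci <- wilson_ci(k_pos, n_r)
      rows <- rbind(rows, data.frame(
        cluster = cl, region = r, n = n_r, fraction = k_pos / n_r,
        ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
        chisq_p = p_raw, p_bonferroni = min(p_raw * k, 1)))
    }
  }
  structure(list(table = rows), class = "composition_result")
}

#' Write per-gene variability results as TSV
#'
#' Joins dispersion and differential-expression tables on gene and writes
#' the documented flat format.
#'
#' @param disp a `dispersion_result`.
#' @param deg a `deg_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_results <- function(disp, deg, path) {
  m <- merge(as.data.frame(disp), as.data.frame(deg), by = "gene",
             all = TRUE)
  cols <- c("gene", "mean_bz", "dispersion_bz", "dispersion_remote",
            "fold", "prob_fold", "hvg", "log2fc", "padj", "deg")
  write.table(m[, cols], path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
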