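test_that("duplicated nuclei embed to identical coordinates", {
  ds <- gen_counts(tiny_cfg(seed = 51))
  counts <- ds$counts
  counts <- cbind(counts, counts[, 1, drop = FALSE])
  colnames(counts)[ncol(counts)] <- "dup"
  emb <- normalize_and_embed(counts, n_var_genes = 100,
                             n_components = 3, seed = 1)
  n <- ncol(counts)
  expect_equal(emb$coordinates[1, ], emb$coordinates[n, ],
               tolerance = 1e-9)
})

test_that("a planted two-cluster structure is separated by the embedding", {
  set.seed(52)
  n <- 120; g <- 150
  mu <- matrix(rep(runif(g, 1, 5), n), g, n)
  grp <- rep(c(0, 1), each = n / 2)
  mu[1:20, grp == 1] <- mu[1:20, grp == 1] * 5
  counts <- matrix(rnbinom(g * n, mu = mu, size = 5), g, n)
  emb <- normalize_and_embed(counts, n_var_genes = 60,
                             n_components = 2, seed = 1)
  pc1 <- emb$coordinates[, 1]
  between <- abs(mean(pc1[grp == 0]) - mean(pc1[grp == 1]))
  within <- sd(pc1[grp == 0]) + sd(pc1[grp == 1])
  expect_gt(between, within)   # silhouette-style separation
})

test_that("structureless data retains at most 2 significant components", {
  set.seed(53)
  kept <- vapply(1:5, function(s) {
    counts <- matrix(rnbinom(200 * 100, mu = 2, size = 2), 200, 100)
    emb <- normalize_and_embed(counts, n_var_genes = 80,
                               n_components = "auto", n_perm = 10,
                               seed = s)
    emb$n_components
  }, 0L)
  expect_true(all(kept <= 2))
})

test_that("embedding validates its inputs", {
  ds <- gen_counts(tiny_cfg(seed = 54))
  expect_error(normalize_and_embed(ds, n_var_genes = 1e6), "exceeds")
  expect_error(normalize_and_embed(ds$counts[, 1:5]), "20 nuclei")
})

test_that("cell-cell distances match hand computation and brute force", {
  xy <- matrix(c(0, 1, 2), ncol = 1)
  d <- cell_cell_distance(xy, rep("bz", 3))
  expect_equal(d$mean_dist, c(1.5, 1, 1.5))

  same <- matrix(1, 5, 2)
  expect_equal(cell_cell_distance(same, rep("r", 5))$mean_dist,
               rep(0, 5))

  set.seed(55)
  emb <- matrix(rnorm(200 * 4), 200, 4)
  reg <- sample(c("bz", "remote"), 200, replace = TRUE)
  fast <- cell_cell_distance(emb, reg)$mean_dist
  for (i in c(1, 57, 200)) {
    others <- setdiff(which(reg == reg[i]), i)
    brute <- mean(vapply(others, function(j)
      sqrt(sum((emb[i, ] - emb[j, ])^2)), 0))
    expect_equal(fast[i], brute, tolerance = 1e-9)
  }
  expect_error(cell_cell_distance(emb, c("solo", reg[-1])), "singleton")
})

test_that("distances are rotation-invariant and scale-equivariant", {
  set.seed(56)
  emb <- matrix(rnorm(80 * 3), 80, 3)
  reg <- rep(c("bz", "remote"), each = 40)
  base <- cell_cell_distance(emb, reg)$mean_dist
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(cell_cell_distance(emb %*% q, reg)$mean_dist, base,
               tolerance = 1e-9)
  expect_equal(cell_cell_distance(2.5 * emb, reg)$mean_dist, 2.5 * base,
               tolerance = 1e-9)
})

test_that("nested region test collapses to animal level and pairs animals", {
  set.seed(57)
  d <- data.frame(nucleus = 1:120,
                  region = rep(c("bz", "remote"), each = 60),
                  animal = rep(rep(1:3, each = 20), 2),
                  mean_dist = rnorm(120, 10))
  class(d) <- c("distance_summary", "data.frame")
  out <- nested_region_test(d)
  expect_true(out$paired)
  expect_equal(nrow(out$animal_means), 6)
  # identical regions: difference exactly 0
  d2 <- d
  d2$mean_dist <- rep(d$mean_dist[1:60], 2)
  out2 <- nested_region_test(d2)
  expect_equal(out2$difference, 0)
  expect_error(nested_region_test(d[d$animal == 1, ]), "2 animals")
})

test_that("BZ nuclei are farther apart than remote on study-like data", {
  cfg <- synth_config(seed = 58, n_genes = 800L,
                      n_nuclei_by_region = c(bz = 250L, remote = 250L))
  ds <- gen_counts(cfg)
  emb <- normalize_and_embed(ds, n_perm = 5, seed = 1)
  dst <- cell_cell_distance(emb, ds$nuclei$region, ds$nuclei$animal)
  nt <- nested_region_test(dst)
  expect_gt(nt$difference, 0)
  expect_lt(nt$p_value, 0.05)
  rs <- nt$region_stats
  ratio <- rs$median[rs$region == "bz"] /
    rs$median[rs$region == "remote"]
  expect_gt(ratio, 1.05)
})

test_that("all-zero genes are excluded from dispersion testing", {
  ds <- gen_counts(tiny_cfg(seed = 59))
  counts <- rbind(ds$counts, ZERO = 0)
  disp <- dispersion_analysis(counts, ds$nuclei$region,
                              ds$nuclei$animal, n_boot = 20,
                              n_null_perm = 0, seed = 1)
  expect_false("ZERO" %in% disp$gene)
})

test_that("HVG calling is deterministic given the seed", {
  ds <- gen_counts(tiny_cfg(seed = 60))
  d1 <- dispersion_analysis(ds$counts, ds$nuclei$region,
                            ds$nuclei$animal, n_boot = 40,
                            n_null_perm = 1, seed = 4)
  d2 <- dispersion_analysis(ds$counts, ds$nuclei$region,
                            ds$nuclei$animal, n_boot = 40,
                            n_null_perm = 1, seed = 4)
  expect_identical(d1$prob_fold, d2$prob_fold)
  expect_identical(d1$hvg, d2$hvg)
})

test_that("planted overdispersion is detected with controlled false calls", {
  cfg <- synth_config(seed = 61, n_genes = 1500L,
                      n_nuclei_by_region = c(bz = 400L, remote = 400L))
  ds <- gen_counts(cfg)
  disp <- dispersion_analysis(ds, n_boot = 150, seed = 2)
  tr <- ds$genes
  called <- disp$gene[disp$hvg]
  planted <- tr$gene[tr$is_hvg]
  genuine <- tr$gene[tr$is_hvg | tr$is_program]
  expect_gte(mean(planted %in% called), 0.30)  # pilot-calibrated power
  fdr <- if (length(called)) mean(!(called %in% genuine)) else 0
  expect_lte(fdr, 0.25)
  # every flagged gene satisfies the 1.5-fold rule
  expect_true(all(disp$fold[disp$hvg] >= 1.5))
})

test_that("pseudobulk DEG detects planted fold changes and respects thresholds", {
  cfg <- synth_config(seed = 62, n_genes = 1000L,
                      n_nuclei_by_region = c(bz = 300L, remote = 300L))
  ds <- gen_counts(cfg)
  deg <- differential_expression(ds$counts, ds$nuclei$region,
                                 ds$nuclei$animal)
  tr <- ds$genes
  planted <- tr$gene[tr$is_deg]
  called <- deg$gene[deg$deg]
  genuine <- tr$gene[tr$is_deg | tr$is_program]
  expect_gte(mean(planted %in% called), 0.75)
  fdr <- if (length(called)) mean(!(called %in% genuine)) else 0
  expect_lte(fdr, 0.15)
  # threshold logic: every flag satisfies both rules
  expect_true(all(deg$padj[deg$deg] < 0.05))
  expect_true(all(abs(deg$log2fc[deg$deg]) > 0.25))
  expect_error(differential_expression(ds$counts, ds$nuclei$region,
                                       rep(1, ncol(ds$counts))),
               "2 animals")
})

test_that("gene-set intersections equal brute-force set algebra", {
  empty <- intersect_gene_sets(c("a", "b"), c("c"), c("d", "e"))
  expect_equal(unname(empty$counts["hvg_deg"]), 0)
  expect_equal(unname(empty$counts["hvg_ecc"]), 0)

  same <- intersect_gene_sets(c("x", "y"), c("x", "y"), c("x", "y"))
  expect_equal(unname(same$counts["hvg_deg_ecc"]), 2)

  set.seed(63)
  pool <- sprintf("g%03d", 1:60)
  a <- sample(pool, 25); b <- sample(pool, 25); c <- sample(pool, 25)
  out <- intersect_gene_sets(a, b, c)
  expect_equal(unname(out$counts["hvg_deg"]), length(intersect(a, b)))
  expect_equal(unname(out$counts["deg_ecc"]), length(intersect(b, c)))
  expect_equal(unname(out$counts["hvg_deg_ecc"]),
               length(Reduce(intersect, list(a, b, c))))
})

test_that("marker fractions, Wilson CIs and the region chi-squared behave", {
  counts <- Matrix::Matrix(0, 2, 200, sparse = TRUE,
                           dimnames = list(c("NPPB", "OTHER"), NULL))
  reg <- rep(c("bz", "remote"), each = 100)
  mf0 <- marker_fraction(counts, "NPPB", reg)
  expect_equal(mf0$table$fraction, c(0, 0))

  set.seed(64)
  counts["NPPB", ] <- rbinom(200, 1, ifelse(reg == "bz", 1 / 3, 0.05))
  mf <- marker_fraction(counts, "NPPB", reg)
  tb <- mf$table
  expect_true(all(tb$ci_lower <= tb$fraction & tb$fraction <= tb$ci_upper))
  expect_lt(mf$chisq_p, 0.01)
  expect_error(marker_fraction(counts, "ABSENT", reg), "not found")
})

test_that("marker CI covers the planted NPPB+ fraction", {
  cov <- vapply(1:12, function(s) {
    cfg <- tiny_cfg(seed = 100 + s,
                    n_nuclei_by_region = c(bz = 300L, remote = 100L))
    ds <- gen_counts(cfg)
    mf <- marker_fraction(ds$counts, "NPPB", ds$nuclei$region)
    tb <- mf$table[mf$table$region == "bz", ]
    tb$ci_lower <= 1 / 3 && 1 / 3 <= tb$ci_upper
  }, TRUE)
  expect_gte(mean(cov), 0.9)
})

test_that("cluster composition conserves mass and adjusts per cluster", {
  set.seed(65)
  cl <- sample(0:4, 400, replace = TRUE)
  reg <- rep(c("bz", "remote"), each = 200)
  cc <- cluster_composition(cl, reg)
  for (r in c("bz", "remote"))
    expect_equal(sum(cc$table$fraction[cc$table$region == r]), 1,
                 tolerance = 1e-9)
  expect_true(all(cc$table$p_bonferroni >= cc$table$chisq_p,
                  na.rm = TRUE))
  one <- cluster_composition(rep(1, 10), rep(c("bz", "remote"), 5))
  expect_equal(one$table$fraction, c(1, 1))
  expect_true(all(is.na(one$table$chisq_p)))
})

test_that("gene results TSV round-trips the key columns", {
  ds <- gen_counts(tiny_cfg(seed = 66))
  disp <- dispersion_analysis(ds$counts, ds$nuclei$region,
                              ds$nuclei$animal, n_boot = 20,
                              n_null_perm = 0, seed = 1)
  deg <- differential_expression(ds$counts, ds$nuclei$region,
                                 ds$nuclei$animal)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_results(disp, deg, path)
  back <- read.delim(path)
  expect_true(all(c("gene", "fold", "hvg", "log2fc", "padj", "deg") %in%
                    names(back)))
  expect_equal(nrow(back), length(union(disp$gene, deg$gene)))
})
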