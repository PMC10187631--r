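#' Curated excitation-contraction-coupling gene symbols
#'
#' Small built-in list of ion-channel, transporter and calcium-handling
#' genes used for gene-set intersections; several of them are also given
#' planted roles by [gen_counts()] (e.g. `SCN3B`, `KCNT2`).
#'
#' @return character vector of gene symbols.
#' @export
ecc_genes <- function() {
  c("SCN5A", "SCN3B", "KCNT2", "KCNJ5", "KCNQ1", "KCNH2", "KCND3",
    "CACNA1C", "CACNB2", "RYR2", "ATP2A2", "PLN", "SLC8A1", "CASQ2",
    "TRDN", "CAMK2D")
}

#' Generate a synthetic gene x nucleus count matrix with planted effects
#'
#' Negative-binomial counts emulating cardiomyocyte single-nucleus RNA-seq
#' from border-zone (BZ) and remote tissue of several animals.  Per-gene
#' baseline means follow a lognormal grid; per-gene dispersion follows the
#' declared mean-dispersion trend `phi = asymptote + scale/mu`
#' (variance = mu + phi mu^2).  Planted effects:
#'
#' * **HVGs** — a fraction of genes has dispersion multiplied by
#'   `hvg_inflation_factor` in BZ nuclei only;
#' * **DEGs** — a disjoint fraction has its mean shifted by `deg_log2fc`
#'   in BZ;
#' * **NPPB+ program** — a per-region fraction of nuclei jointly
#'   up-regulates `NPPB`, `SCN3B` and `INPP5F` (the hypertrophic
#'   subpopulation signature); `NPPB` baseline is near zero so the
#'   count >= 1 positivity rule recovers the planted fraction;
#' * **animal effect** — lognormal per-animal depth factor (CV
#'   `animal_effect_cv`) so nested tests are meaningfully exercised.
#'
#' Cardiomyocyte subcluster labels (5 clusters, NPPB+ nuclei concentrated
#' in cluster 2) are included for composition statistics.
#'
#' @param cfg a [synth_config()].
#' @param seed optional override of `cfg$seed`.
#' @return list of class `count_dataset`: `counts` (sparse dgCMatrix,
#'   genes x nuclei), `genes` (data.frame: gene, base_mean, is_hvg,
#'   is_deg, is_program, log2fc_true), `nuclei` (data.frame: barcode,
#'   region, animal, nppb_pos, cluster).  Program genes are genuinely
#'   overdispersed in BZ (subpopulation mixture), so downstream HVG
#'   calls on them are correct, not false positives; `is_program` lets
#'   calibration tests account for that.
#' @export
gen_counts <- function(cfg, seed = NULL) {
  cfg <- validate_synth_config(cfg)
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  G <- cfg$n_genes
  if (G < 10) stop("n_genes < 10")
  if (any(cfg$n_nuclei_by_region < 20))
    stop("every region needs >= 20 nuclei")
  regions <- names(cfg$n_nuclei_by_region)
  with_seed(derive_seed(seed, 13L), {
    genes <- sprintf("GENE%04d", seq_len(G))
    # hypertrophic stress program of the NPPB+ subpopulation (cluster 2):
    # marker plus co-regulated stress/ECC partners, padded with unnamed
    # program genes so the planted subpopulation shifts a realistic-width
    # module.  The other four subclusters each carry their own smaller
    # expression module; cluster proportions differ by region (BZ more
    # evenly mixed), which is what drives the planted cell-cell
    # transcriptomic heterogeneity contrast.
    named_prog <- c("NPPB", "SCN3B", "INPP5F", "XIRP2", "ANKRD1", "ROBO1")
    n_prog_extra <- min(10L, G - 80L)
    named <- unique(c(named_prog, ecc_genes()))
    genes[seq_along(named)] <- named
    program <- c(named_prog,
                 genes[length(named) + seq_len(max(n_prog_extra, 0L))])
    module_size <- min(8L, max((G - 80L) %/% 8L, 0L))
    other_clusters <- c(0L, 1L, 3L, 4L)
    modules <- setNames(lapply(seq_along(other_clusters), function(k)
      genes[length(named) + n_prog_extra + (k - 1L) * module_size +
              seq_len(module_size)]), other_clusters)
    # non-NPPB+ nuclei split over clusters 0/1/3/4, region-specific
    cluster_probs <- cfg$cluster_probs_by_region
    mp <- cfg$nb_mean_params
    mu0 <- pmin(rlnorm(G, mp$meanlog, mp$sdlog), mp$max)
    # program/module genes get solidly detectable baselines so the
    # planted subpopulations are visible after depth normalization; NPPB
    # itself is near-silent so count>=1 positivity is clean
    module_genes <- c(program, unlist(modules))
    mu0[genes %in% module_genes] <- runif(sum(genes %in% module_genes),
                                          1, 8)
    mu0[genes == "NPPB"] <- 0.01
    dp <- cfg$nb_dispersion_params
    phi <- dp$asymptote + dp$scale / mu0
    # module genes keep trend dispersion (their subpopulation mixture then
    # adds clearly *excess* variance); only NPPB is tight so the count>=1
    # positivity rule cleanly separates NPPB+ from NPPB- nuclei
    phi[genes == "NPPB"] <- 0.05

    free <- setdiff(seq_len(G),
                    c(seq_along(named), match(module_genes, genes)))
    n_hvg <- round(cfg$planted_hvg_frac * G)
    n_deg <- round(cfg$planted_deg_frac * G)
    hvg_idx <- if (cfg$hvg_inflation_factor > 1 && n_hvg > 0)
      sample(free, n_hvg) else integer(0)
    deg_pool <- setdiff(free, hvg_idx)
    deg_idx <- if (cfg$deg_log2fc != 0 && n_deg > 0)
      sample(deg_pool, n_deg) else integer(0)

    cv <- cfg$animal_effect_cv
    afac <- rlnorm(cfg$n_animals_rna, -0.5 * log(1 + cv^2),
                   sqrt(log(1 + cv^2)))

    meta <- NULL
    blocks <- list()
    for (a in seq_len(cfg$n_animals_rna)) for (r in regions) {
      n_nuc <- cfg$n_nuclei_by_region[[r]]
      mu <- mu0
      phi_r <- phi
      if (r == "bz") {
        mu[deg_idx] <- mu[deg_idx] * 2^cfg$deg_log2fc
        # DEGs stay on the mean-dispersion trend at their shifted mean,
        # otherwise a pure mean shift also plants trend-relative
        # overdispersion and contaminates the HVG truth table
        phi_r[deg_idx] <- dp$asymptote + dp$scale / mu[deg_idx]
        phi_r[hvg_idx] <- phi_r[hvg_idx] * cfg$hvg_inflation_factor
      }
      pos <- rbinom(n_nuc, 1, cfg$nppb_pos_frac_by_region[[r]]) == 1
      cp <- cluster_probs[[r]] %||% cluster_probs$remote
      cluster <- ifelse(pos, 2L,
                        other_clusters[sample.int(4L, n_nuc, TRUE,
                                                  prob = cp)])
      mu_mat <- matrix(mu * afac[a], G, n_nuc)
      prog_rows <- match(program, genes)
      prog_fac <- c(600, rep(4, length(program) - 1L))
      mu_mat[prog_rows, pos] <- mu_mat[prog_rows, pos] * prog_fac
      # NPPB goes from ~0 to ~6 counts; partners x4
      for (k in names(modules)) {
        sel <- cluster == as.integer(k)
        rows_k <- match(modules[[k]], genes)
        if (any(sel) && length(rows_k))
          mu_mat[rows_k, sel] <- mu_mat[rows_k, sel] * 4
      }
      cnt <- matrix(rnbinom(G * n_nuc, mu = mu_mat,
                            size = 1 / rep(phi_r, n_nuc)), G, n_nuc)
      meta <- rbind(meta, data.frame(
        barcode = sprintf("A%d_%s_%04d", a, r, seq_len(n_nuc)),
        region = r, animal = a, nppb_pos = pos, cluster = cluster))
      blocks[[length(blocks) + 1L]] <- cnt
    }
    counts <- methods::as(Matrix::Matrix(do.call(cbind, blocks),
                                         sparse = TRUE), "CsparseMatrix")
    dimnames(counts) <- list(genes, meta$barcode)
    gtab <- data.frame(gene = genes, base_mean = mu0,
                       is_hvg = seq_len(G) %in% hvg_idx,
                       is_deg = seq_len(G) %in% deg_idx,
                       is_program = genes %in% module_genes,
                       log2fc_true = ifelse(seq_len(G) %in% deg_idx,
                                            cfg$deg_log2fc, 0))
    structure(list(counts = counts, genes = gtab, nuclei = meta),
              class = "count_dataset")
  })
}

#' Write a count dataset as Matrix Market triplets plus metadata
#'
#' Standard 10x-style layout: `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`, and `metadata.csv` (barcode, region, animal, and any
#' truth flags present).
#'
#' @param ds a `count_dataset` (see [gen_counts()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ds$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(ds$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(ds$counts), file.path(dir, "barcodes.tsv"))
  write.csv(ds$nuclei, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a Matrix Market count directory
#'
#' Counterpart of [write_counts_mtx()]; nuclei that are all-zero after
#' load are dropped (with their metadata rows).
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and optionally `metadata.csv`.
#' @return a `count_dataset` (without truth columns unless present in the
#'   metadata file).
#' @export
read_counts_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "metadata.csv")
  meta <- if (file.exists(meta_path)) read.csv(meta_path) else
    data.frame(barcode = colnames(counts))
  keep <- Matrix::colSums(counts) > 0
  structure(list(counts = counts[, keep, drop = FALSE], genes = NULL,
                 nuclei = meta[keep, , drop = FALSE]),
            class = "count_dataset")
}
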