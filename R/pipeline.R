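#' Run the full multi-scale synthetic analysis pipeline
#'
#' Orchestrates the four stages end to end on synthetic data generated
#' from `cfg`, with every stage seeded from `cfg$seed`:
#'
#' 1. **in vivo** — per animal, an endocardial map with unipolar
#'    electrograms; AT/RT detection ([map_ari()]), voltage region
#'    classification, the local ARI heterogeneity map and per-region
#'    summaries; per-animal BZ heterogeneity feeds the inducibility
#'    regression at `n_animals_inducibility` animals.
#' 2. **optical** — a cell population per animal/region, APD measurement
#'    and APD/morphology dispersion summaries.
#' 3. **scvar** — a count matrix; PC embedding, cell-cell distances with
#'    the nested region test, overdispersion/HVG calling, pseudobulk
#'    differential expression, gene-set intersections, NPPB+ fractions
#'    and cluster composition.
#' 4. **wallmri** — LV slices per animal; per-slice wall profiles, LGE
#'    region labels, regional thickness variance and per-animal
#'    summaries.
#'
#' plus the cross-scale regression table.  Counts of accepted/rejected
#' records are carried per stage.
#'
#' @param cfg a [synth_config()].
#' @param stages character subset of
#'   `c("invivo", "optical", "scvar", "wallmri")`.
#' @param n_animals_invivo animals mapped in vivo.
#' @param n_animals_inducibility animals in the inducibility protocol.
#' @param use_detectors logical; measure ARI from the synthetic
#'   electrograms (TRUE) or take the generator's true field (faster).
#' @param inducibility_slope,inducibility_noise_sd parameters passed to
#'   [gen_inducibility()] (index per ms; index units).
#' @param n_boot bootstrap resamples for [dispersion_analysis()].
#' @param n_perm permutations for the PC-selection rule.
#' @param out_dir optional directory: per-stage CSV tables and a
#'   machine-readable `summary.json` are written there.
#' @return list of class `bordermap_report` with elements `invivo`,
#'   `inducibility`, `optical`, `scvar`, `wallmri`, `cross_scale`,
#'   `summary` (flat named list of headline numbers).
#' @export
run_pipeline <- function(cfg,
                         stages = c("invivo", "optical", "scvar",
                                    "wallmri"),
                         n_animals_invivo = 5L,
                         n_animals_inducibility = 8L,
                         use_detectors = TRUE,
                         inducibility_slope = 1,
                         inducibility_noise_sd = 0.5,
                         n_boot = 200L, n_perm = 20L,
                         out_dir = NULL) {
  cfg <- validate_synth_config(cfg)
  stages <- match.arg(stages, several.ok = TRUE)
  rep <- list()
  summary <- list()

  if ("invivo" %in% stages) {
    n_maps <- max(n_animals_invivo, n_animals_inducibility)
    het_stats <- NULL; ari_stats <- NULL; het_diffs <- NULL
    bz_het <- numeric(n_maps)
    n_rejected <- 0L
    for (a in seq_len(n_maps)) {
      # per-animal heterogeneity targets: regional local SD drawn around
      # the population values with the between-animal spread
      cfg_a <- cfg
      cfg_a$ari_local_sd_by_region <- setNames(pmax(with_seed(
        derive_seed(cfg$seed, 500L + a),
        rnorm(length(cfg$ari_local_sd_by_region),
              cfg$ari_local_sd_by_region,
              cfg$ari_local_sd_between_animal_sd)), 0.3),
        names(cfg$ari_local_sd_by_region))
      m <- gen_endocardial_map(cfg_a, electrograms = use_detectors,
                               seed = derive_seed(cfg$seed, 1000L + a))
      if (use_detectors) {
        det <- map_ari(m$egms)
        m$ari <- det$ari
        n_rejected <- n_rejected + sum(!det$accepted)
      }
      labels <- classify_regions(m$bipolar_voltage)
      het <- local_heterogeneity(m, radius = cfg$het_radius)
      rs_het <- regional_summary(het$local_sd, labels, animal = a)
      rs_ari <- regional_summary(m$ari, labels, animal = a)
      bz_het[a] <- rs_het$stats$mean[rs_het$stats$region == "bz"]
      if (a <= n_animals_invivo) {
        het_stats <- rbind(het_stats, rs_het$stats)
        ari_stats <- rbind(ari_stats, rs_ari$stats)
        het_diffs <- rbind(het_diffs, rs_het$differences)
      }
    }
    rep$invivo <- list(het_stats = het_stats, ari_stats = ari_stats,
                       het_differences = het_diffs,
                       n_rejected_egms = n_rejected)
    ind <- gen_inducibility(bz_het[seq_len(n_animals_inducibility)],
                            slope = inducibility_slope,
                            noise_sd = inducibility_noise_sd,
                            seed = derive_seed(cfg$seed, 2L))
    rep$inducibility <- c(list(records = ind),
                          inducibility_regression(ind))
    summary$bz_ari_local_sd <-
      mean(het_stats$mean[het_stats$region == "bz"])
    summary$remote_ari_local_sd <-
      mean(het_stats$mean[het_stats$region == "remote"])
    summary$inducibility_slope <- rep$inducibility$slope
    summary$inducibility_r_squared <- rep$inducibility$r_squared
  }

  if ("optical" %in% stages) {
    pop <- gen_optical_population(cfg,
                                  seed = derive_seed(cfg$seed, 3L))
    apd <- measure_apd(pop)
    disp <- population_dispersion(apd)
    morph <- morphology_dispersion(pop$cells)
    rep$optical <- list(apd = apd, dispersion = disp, morphology = morph,
                        n_cells = nrow(apd),
                        n_accepted = sum(apd$accepted))
    st <- disp$stats
    summary$bz_apd90_sd <- mean(st$sd[st$region == "bz"], na.rm = TRUE)
    summary$remote_apd90_sd <-
      mean(st$sd[st$region == "remote"], na.rm = TRUE)
  }

  if ("scvar" %in% stages) {
    ds <- gen_counts(cfg, seed = derive_seed(cfg$seed, 4L))
    emb <- normalize_and_embed(ds, n_var_genes = min(500L, cfg$n_genes),
                               n_perm = n_perm,
                               seed = derive_seed(cfg$seed, 5L))
    dst <- cell_cell_distance(emb, ds$nuclei$region, ds$nuclei$animal)
    nested <- nested_region_test(dst)
    disp <- dispersion_analysis(ds$counts, ds$nuclei$region,
                                animals = ds$nuclei$animal,
                                n_boot = n_boot,
                                seed = derive_seed(cfg$seed, 6L))
    deg <- differential_expression(ds$counts, ds$nuclei$region,
                                   ds$nuclei$animal)
    inter <- intersect_gene_sets(disp, deg)
    nppb <- marker_fraction(ds$counts, "NPPB", ds$nuclei$region)
    comp <- cluster_composition(ds$nuclei$cluster, ds$nuclei$region)
    rep$scvar <- list(embedding_components = emb$n_components,
                      distances = dst, nested_test = nested,
                      dispersion = disp, deg = deg,
                      intersections = inter$counts, nppb = nppb,
                      cluster_composition = comp, truth = ds$genes)
    stats <- nested$region_stats
    summary$bz_distance_median <-
      stats$median[stats$region == "bz"]
    summary$remote_distance_median <-
      stats$median[stats$region == "remote"]
    summary$nested_test_p <- nested$p_value
    summary$n_hvg <- sum(disp$hvg)
    summary$n_deg <- sum(deg$deg)
    summary$n_hvg_and_deg <- unname(inter$counts["hvg_deg"])
    tb <- nppb$table
    summary$nppb_fraction_bz <- tb$fraction[tb$region == "bz"]
    summary$nppb_fraction_remote <- tb$fraction[tb$region == "remote"]
  }

  if ("wallmri" %in% stages) {
    sv <- NULL; lg <- NULL
    for (a in seq_len(cfg$n_animals_mri)) {
      slices <- gen_lv_slices(cfg, seed = derive_seed(cfg$seed, 3000L + a))
      for (s in seq_along(slices)) {
        prof <- wall_thickness(slices[[s]])
        lab <- lge_classify(slices[[s]])
        wv <- wall_variance(prof, lab$region)
        sv <- rbind(sv, cbind(animal = a, slice = s, wv))
        lg <- rbind(lg, cbind(slice = paste(a, s, sep = "_"), animal = a,
                              lab))
      }
    }
    ws <- wall_summary(sv)
    lv <- lge_variability(lg)
    rep$wallmri <- list(slice_variances = sv, summary = ws,
                        lge = lv$variability)
    summary$bz_wall_variance <-
      mean(ws$mean_variance[ws$region == "bz"])
    summary$remote_wall_variance <-
      mean(ws$mean_variance[ws$region == "remote"])
  }

  rep$cross_scale <- cross_scale_table(rep)
  rep$summary <- summary
  class(rep) <- "bordermap_report"
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

#' Cross-scale regression table
#'
#' Assembles per-animal vectors from a pipeline report and runs the
#' shared OLS on each available pair: inducibility index on BZ ARI
#' heterogeneity, cellular APD SD on in vivo BZ heterogeneity, and
#' cellular mean APD on in vivo mean ARI (animals matched by index up to
#' the shorter vector; at least 3 pairs required).
#'
#' @param rep a partial or full `bordermap_report` list.
#' @return data.frame with `pair`, `n`, `slope`, `r_squared`, `p_value`
#'   (zero rows when fewer than two stages are present).
#' @export
cross_scale_table <- function(rep) {
  out <- NULL
  add <- function(name, x, y) {
    n <- min(length(x), length(y))
    if (n < 3) return(NULL)
    f <- ols_fit(x[seq_len(n)], y[seq_len(n)])
    data.frame(pair = name, n = n, slope = f$slope,
               r_squared = f$r_squared, p_value = f$p_value)
  }
  if (!is.null(rep$inducibility))
    out <- rbind(out, add("inducibility_vs_bz_heterogeneity",
                          rep$inducibility$records$bz_heterogeneity,
                          rep$inducibility$records$index))
  if (!is.null(rep$invivo) && !is.null(rep$optical)) {
    hs <- rep$invivo$het_stats
    as_ <- rep$invivo$ari_stats
    os <- rep$optical$dispersion$stats
    bz_het <- hs$mean[hs$region == "bz"][order(hs$animal[hs$region == "bz"])]
    bz_sd <- os$sd[os$region == "bz"][order(os$animal[os$region == "bz"])]
    out <- rbind(out, add("cellular_apd_sd_vs_invivo_heterogeneity",
                          bz_het, bz_sd))
    bz_ari <- as_$mean[as_$region == "bz"][order(as_$animal[as_$region == "bz"])]
    bz_apd <- os$mean[os$region == "bz"][order(os$animal[os$region == "bz"])]
    out <- rbind(out, add("cellular_apd_mean_vs_invivo_ari", bz_ari,
                          bz_apd))
  }
  if (is.null(out))
    out <- data.frame(pair = character(), n = integer(),
                      slope = numeric(), r_squared = numeric(),
                      p_value = numeric())
  out
}

# Write per-stage tables and the machine-readable summary.
write_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    if (!is.null(df)) write.csv(df, file.path(out_dir, name),
                                row.names = FALSE)
  wr(rep$invivo$het_stats, "invivo_heterogeneity.csv")
  wr(rep$invivo$ari_stats, "invivo_ari.csv")
  wr(rep$inducibility$records, "inducibility.csv")
  wr(rep$optical$dispersion$stats, "optical_dispersion.csv")
  wr(as.data.frame(rep$scvar$dispersion), "gene_dispersion.csv")
  wr(as.data.frame(rep$scvar$deg), "gene_deg.csv")
  wr(rep$wallmri$summary, "wall_summary.csv")
  wr(rep$cross_scale, "cross_scale.csv")
  jsonlite::write_json(rep$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(rep$optical)) {
    grDevices::png(file.path(out_dir, "apd_histograms.png"), 800, 400)
    on.exit(grDevices::dev.off(), add = TRUE)
    apd <- rep$optical$apd[rep$optical$apd$accepted, ]
    graphics::par(mfrow = c(1, 2))
    for (r in c("bz", "remote"))
      graphics::hist(apd$apd90[apd$region == r], breaks = 20,
                     main = paste("APD90,", r), xlab = "APD90 (ms)")
  }
  invisible(out_dir)
}

#' Render a polar map to a PNG file
#'
#' Simple raster rendering (apex at the centre) of a [project_polar()]
#' grid.
#'
#' @param pm a `polar_map`.
#' @param path output `.png` path.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
plot_polar_png <- function(pm, path, main = "polar map") {
  grDevices::png(path, 480, 480)
  on.exit(grDevices::dev.off())
  n <- 201
  xy <- seq(-1, 1, length.out = n)
  gx <- matrix(rep(xy, n), n)
  gy <- matrix(rep(xy, each = n), n)
  rr <- sqrt(gx^2 + gy^2)
  th <- atan2(gy, gx) %% (2 * pi)
  ir <- findInterval(rr, c(0, pm$r_centers[-1] -
                             diff(pm$r_centers)[1] / 2, 1))
  it <- pmin(findInterval(th, seq(0, 2 * pi,
                                  length.out = length(pm$theta_centers) +
                                    1)), length(pm$theta_centers))
  img <- matrix(NA_real_, n, n)
  ok <- rr <= 1 & ir >= 1 & ir <= length(pm$r_centers)
  img[ok] <- pm$grid[cbind(ir[ok], it[ok])]
  graphics::image(xy, xy, img, asp = 1, axes = FALSE, xlab = "",
                  ylab = "", main = main)
  invisible(path)
}

#' @export
print.bordermap_report <- function(x, ...) {
  cat("<bordermap_report>\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-28s %s\n", nm,
                format(x$summary[[nm]], digits = 4)))
  invisible(x)
}
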