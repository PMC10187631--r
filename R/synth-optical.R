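#' Generate a population of optical action-potential traces
#'
#' Emulates voltage-dye (di-8-ANEPPS) recordings of isolated cardiomyocyte
#' populations: per cell, a `trace_duration`-second fluorescence record
#' under `stim_rate` field stimulation.  Each beat is an instantaneous
#' upstroke followed by monoexponential repolarization with time constant
#' `tau = APD90 / ln(10)`, so every APDx has the closed form
#' `tau * log(1/(1 - x))`.  APD90 values are drawn per cell from the
#' region's Gaussian mixture (`cfg$apd_dist_by_region`): the BZ default is
#' right-skewed with a long-APD subpopulation.  Fluorescence follows the
#' dye's polarity (deflection *downward* on depolarization); the analysis
#' side flips it on load.  Cell width/length are drawn per region from
#' `cfg$morph_by_region`.
#'
#' @param cfg a [synth_config()].
#' @param seed optional override of `cfg$seed`.
#' @param animals number of animals (default `cfg$n_animals_optical`);
#'   per-animal APD means get a small lognormal offset (CV
#'   `cfg$animal_effect_cv`) so nested summaries are exercised.
#' @return list of class `optical_population`: `traces` (list of
#'   [optical_trace()]), `cells` (data.frame: cell, region, animal,
#'   apd90_true, apd50_true, apd25_true, width, length).
#' @export
gen_optical_population <- function(cfg, seed = NULL,
                                   animals = cfg$n_animals_optical) {
  cfg <- validate_synth_config(cfg)
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  n_beats <- cfg$trace_duration * cfg$stim_rate
  if (n_beats < 10)
    stop("trace_duration x stim_rate < 10: cannot average last 10 beats")
  regions <- names(cfg$apd_dist_by_region)
  with_seed(derive_seed(seed, 7L), {
    cells <- NULL
    traces <- list()
    cid <- 0L
    for (a in seq_len(animals)) {
      afac <- rlnorm(1, -0.5 * log(1 + cfg$animal_effect_cv^2),
                     sqrt(log(1 + cfg$animal_effect_cv^2)))
      for (r in regions) {
        nc <- cfg$n_cells_by_region[[r]]
        if (is.null(nc) || nc == 0) next
        mx <- cfg$apd_dist_by_region[[r]]
        comp <- sample.int(length(mx$weights), nc, replace = TRUE,
                           prob = mx$weights)
        apd90 <- pmax(rnorm(nc, mx$means[comp] * afac, mx$sds[comp]), 60)
        mo <- cfg$morph_by_region[[r]]
        width <- pmax(rnorm(nc, mo$width_mean, mo$width_sd), 5)
        len <- pmax(rnorm(nc, mo$length_mean, mo$length_sd), 30)
        for (i in seq_len(nc)) {
          cid <- cid + 1L
          traces[[cid]] <- synth_optical_trace(
            apd90[i], cfg, cell_id = cid, region = r, animal = a,
            seed = derive_seed(seed, 100000L + cid))
        }
        tau <- apd90 / log(10)
        cells <- rbind(cells, data.frame(
          cell = cid - nc + seq_len(nc), region = r, animal = a,
          apd90_true = apd90, apd50_true = tau * log(2),
          apd25_true = tau * log(1 / 0.75), width = width, length = len))
      }
    }
    structure(list(traces = traces, cells = cells),
              class = "optical_population")
  })
}

# One synthetic fluorescence record (inverted dye polarity + noise).
synth_optical_trace <- function(apd90, cfg, cell_id, region, animal, seed) {
  fs <- cfg$fs_optical
  nsmp <- round(cfg$trace_duration * fs)
  t <- (seq_len(nsmp) - 1) / fs                   # s
  tau <- apd90 / log(10) / 1000                   # s
  v <- numeric(nsmp)
  # first stimulus 50 ms into the record so every beat, including the
  # first, carries a pre-upstroke baseline window; the potential is
  # clamped to baseline for the final 50 ms of each cycle so no residual
  # carries into the next beat's baseline (keeps APDx = tau*ln(1/(1-x))
  # exact for every cell)
  cyc <- 1 / cfg$stim_rate
  stim <- seq(0.05, by = cyc,
              length.out = cfg$trace_duration * cfg$stim_rate)
  for (s in stim) {
    idx <- t >= s & t < s + cyc - 0.05
    v[idx] <- exp(-(t[idx] - s) / tau)
  }
  # dye fluorescence dips on depolarization; deflection 10% of baseline
  f <- 1 - 0.1 * v
  if (cfg$optical_noise_sd > 0)
    f <- f + with_seed(seed, rnorm(nsmp, sd = 0.1 * cfg$optical_noise_sd))
  optical_trace(f, fs = fs, stim_rate = cfg$stim_rate,
                cell_id = cell_id, region = region, animal = animal,
                polarity = "inverted",
                truth = list(apd90 = apd90, tau_ms = apd90 / log(10)))
}
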