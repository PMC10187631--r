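#' Configuration for the synthetic multi-scale dataset generator
#'
#' Builds a validated configuration object consumed by all generators
#' ([gen_endocardial_map()], [gen_optical_population()], [gen_counts()],
#' [gen_lv_slices()], [gen_inducibility()]).  Defaults encode the study
#' conditions the generators emulate: a reperfused pig infarct mapped at
#' ~1 month, with border-zone (BZ) local ARI SD 3.5 ms versus 2.0 ms remote,
#' cellular APD90 population SD ~106 ms (BZ, right-skewed) versus ~74 ms
#' (remote), an NPPB-positive BZ subpopulation of one third of
#' cardiomyocytes, and inflated BZ wall-thickness variance.
#'
#' @param seed integer; master seed, propagated (derived) to every generator.
#' @param n_points number of endocardial map points.
#' @param region_fractions named proportions for `infarct`, `bz`, `remote`;
#'   must sum to 1.
#' @param ari_mean_by_region named regional ARI means (ms).  BZ longer
#'   than remote; the steps are kept small because balls straddling a
#'   region boundary add the mean step to the local SD, and the planted
#'   local-SD targets must remain attainable.
#' @param ari_local_sd_by_region named regional *local* ARI SD targets (ms):
#'   the SD of ARIs within `het_radius` of a point, the in vivo
#'   heterogeneity statistic.
#' @param ari_local_sd_between_animal_sd named between-animal SD of the
#'   per-animal local-SD targets (ms): each animal's planted regional
#'   local SD is drawn around `ari_local_sd_by_region` with this spread
#'   (BZ 3.5 +/- 1.3 ms across pigs), so cross-animal regressions such as
#'   the inducibility correlation have genuine predictor variance.
#' @param het_radius radius (mm) at which the local SD targets are planted
#'   (and at which [local_heterogeneity()] is evaluated by default).
#' @param ari_corr_length correlation length (mm) of the spatial ARI noise
#'   field.
#' @param fs_egm electrogram sampling rate (samples/s).
#' @param egm_noise_sd additive Gaussian noise SD on electrograms
#'   (a.u.; QRS deflection has unit amplitude).
#' @param n_cells_by_region optical cells per region *per animal*.
#' @param n_animals_optical number of animals for the cellular stage.
#' @param apd_dist_by_region per-region APD90 mixture specs: each a list
#'   with `means` (ms), `sds` (ms), `weights`.  The BZ default is a
#'   right-skewed two-component mixture (long-APD subpopulation) whose
#'   overall SD is ~106 ms; remote is single-component with SD 73.9 ms.
#' @param trace_duration optical record length (s).
#' @param stim_rate field-stimulation rate (Hz).
#' @param fs_optical optical sampling rate (samples/s).
#' @param optical_noise_sd fluorescence noise SD as a fraction of the AP
#'   deflection amplitude.  The monoexponential repolarization template is
#'   shallow near the 90% level, making APD90 far more noise-sensitive
#'   than with a realistic sigmoidal phase 3; the default reflects a
#'   well-averaged high-SNR recording.
#' @param morph_by_region per-region cell-morphology spec: list with
#'   `width_mean`, `width_sd`, `length_mean`, `length_sd` (µm).
#' @param n_genes,n_nuclei_by_region count-matrix dimensions
#'   (nuclei per region *per animal*).
#' @param n_animals_rna number of animals for the single-nucleus stage.
#' @param nb_mean_params lognormal parameters (`meanlog`, `sdlog`, `max`)
#'   for per-gene baseline mean counts.
#' @param nb_dispersion_params mean-dispersion trend parameters
#'   (`asymptote`, `scale`): dispersion phi = asymptote + scale / mean
#'   (variance = mu + phi mu^2).
#' @param planted_hvg_frac,planted_deg_frac fractions of genes receiving a
#'   planted BZ dispersion inflation / mean shift.
#' @param hvg_inflation_factor multiplicative BZ dispersion inflation for
#'   planted HVGs (>= 1).
#' @param deg_log2fc planted BZ log2 fold change for planted DEGs.
#' @param animal_effect_cv coefficient of variation of the per-animal
#'   lognormal depth factor (nested-structure knob).
#' @param nppb_pos_frac_by_region named fraction of NPPB+ nuclei per region.
#' @param cluster_probs_by_region per-region sampling probabilities of the
#'   non-NPPB+ subclusters (0, 1, 3, 4; NPPB+ nuclei form cluster 2).  The
#'   BZ default is more evenly mixed than remote, the planted driver of
#'   the cell-cell distance contrast; give both regions the same vector
#'   for an exchangeable null.
#' @param n_slices short-axis slices per animal.
#' @param n_animals_mri animals for the imaging stage.
#' @param wall_thickness_mean_by_region named regional mean wall thickness
#'   (mm).
#' @param wall_thickness_variance_by_region named regional per-angle
#'   thickness variance (mm^2).
#' @param wall_region_angles named list of angular sectors (degrees,
#'   `c(from, to)` half-open) for `core` and `bz`; the rest is remote.
#' @param endo_radius endocardial radius (mm) of the synthetic slice.
#' @param pixel_spacing slice pixel spacing (mm).
#' @param lge_intensity named LGE intensities (a.u.) for `core`, `bz`,
#'   `remote`; must satisfy core > bz > remote.
#' @param lge_noise_sd additive noise on LGE intensities (a.u.).
#'
#' @return An object of class `synth_config` (a validated named list).
#' @examples
#' cfg <- synth_config(seed = 1, n_points = 200)
#' cfg$ari_local_sd_by_region
#' @export
synth_config <- function(
    seed = 1L,
    n_points = 800L,
    region_fractions = c(infarct = 0.20, bz = 0.30, remote = 0.50),
    ari_mean_by_region = c(infarct = 252, bz = 254, remote = 250),
    ari_local_sd_by_region = c(infarct = 3.0, bz = 3.5, remote = 2.0),
    ari_local_sd_between_animal_sd = c(infarct = 0.5, bz = 1.3,
                                       remote = 0.5),
    het_radius = 10,
    ari_corr_length = 5,
    fs_egm = 1000,
    egm_noise_sd = 0.015,
    n_cells_by_region = c(infarct = 0L, bz = 120L, remote = 120L),
    n_animals_optical = 6L,
    apd_dist_by_region = list(
      bz     = list(means = c(335, 520), sds = c(75, 80),
                    weights = c(0.8, 0.2)),
      remote = list(means = 340, sds = 73.9, weights = 1)
    ),
    trace_duration = 15,
    stim_rate = 1,
    fs_optical = 500,
    optical_noise_sd = 0.005,
    morph_by_region = list(
      bz     = list(width_mean = 30, width_sd = 8,
                    length_mean = 140, length_sd = 18),
      remote = list(width_mean = 25, width_sd = 5,
                    length_mean = 150, length_sd = 25)
    ),
    n_genes = 1000L,
    n_nuclei_by_region = c(bz = 400L, remote = 400L),
    n_animals_rna = 3L,
    nb_mean_params = list(meanlog = -1, sdlog = 1.5, max = 50),
    nb_dispersion_params = list(asymptote = 0.3, scale = 1),
    planted_hvg_frac = 0.05,
    planted_deg_frac = 0.05,
    hvg_inflation_factor = 2,
    deg_log2fc = 1,
    animal_effect_cv = 0.10,
    nppb_pos_frac_by_region = c(bz = 1 / 3, remote = 0.05),
    cluster_probs_by_region = list(
      bz = c("0" = 0.40, "1" = 0.30, "3" = 0.08, "4" = 0.22),
      remote = c("0" = 0.55, "1" = 0.32, "3" = 0.09, "4" = 0.04)),
    n_slices = 10L,
    n_animals_mri = 6L,
    wall_thickness_mean_by_region = c(core = 5, bz = 7, remote = 10),
    wall_thickness_variance_by_region = c(core = 1.0, bz = 2.0,
                                          remote = 0.5),
    wall_region_angles = list(core = c(30, 90), bz = list(c(0, 30),
                                                          c(90, 120))),
    endo_radius = 20,
    pixel_spacing = 0.5,
    lge_intensity = c(core = 1.0, bz = 0.45, remote = 0.10),
    lge_noise_sd = 0.03) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  stopifnot(is.list(cfg))
  fr <- cfg$region_fractions
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9)
    stop("region_fractions must lie in [0,1] and sum to 1")
  if (cfg$hvg_inflation_factor < 1)
    stop("hvg_inflation_factor must be >= 1")
  nonneg <- c(cfg$ari_local_sd_by_region,
              cfg$ari_local_sd_between_animal_sd, cfg$egm_noise_sd,
              cfg$optical_noise_sd, cfg$wall_thickness_variance_by_region,
              cfg$lge_noise_sd, cfg$animal_effect_cv)
  if (any(nonneg < 0)) stop("SDs, variances and noise levels must be >= 0")
  props <- c(cfg$nppb_pos_frac_by_region, cfg$planted_hvg_frac,
             cfg$planted_deg_frac)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (any(c(cfg$fs_egm, cfg$fs_optical, cfg$stim_rate,
            cfg$pixel_spacing) <= 0))
    stop("rates and spacings must be positive")
  for (r in names(cfg$apd_dist_by_region)) {
    mx <- cfg$apd_dist_by_region[[r]]
    stopifnot(length(mx$means) == length(mx$sds),
              length(mx$means) == length(mx$weights))
    if (abs(sum(mx$weights) - 1) > 1e-9)
      stop("mixture weights must sum to 1 (region ", r, ")")
    if (any(mx$sds < 0)) stop("mixture SDs must be >= 0")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Overall mean and SD of a univariate Gaussian mixture
#'
#' Closed-form moments used to parameterize (and to test) the APD mixture
#' specs in [synth_config()].
#'
#' @param means,sds,weights component parameters; weights must sum to 1.
#' @return named numeric vector `c(mean, sd)`.
#' @examples
#' mixture_moments(c(335, 520), c(75, 80), c(0.8, 0.2))
#' @export
mixture_moments <- function(means, sds, weights) {
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  m <- sum(weights * means)
  m2 <- sum(weights * (sds^2 + means^2))
  c(mean = m, sd = sqrt(m2 - m^2))
}
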