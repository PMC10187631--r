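# Small configurations shared across tests.  Sizes are scaled down from
# the package defaults so the whole suite stays fast; the acceptance
# tests use larger, closer-to-default sizes.

tiny_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_points = 150L,
               n_cells_by_region = c(bz = 25L, remote = 25L),
               n_genes = 300L,
               n_nuclei_by_region = c(bz = 120L, remote = 120L),
               n_animals_rna = 2L, n_slices = 2L, n_animals_mri = 2L)
  args <- utils::modifyList(args, list(...))
  do.call(synth_config, args)
}

# exchangeable-null single-nucleus configuration: no planted effects
null_scvar_cfg <- function(seed, n_genes = 400L, n_nuclei = 150L) {
  even <- c("0" = 0.5, "1" = 0.3, "3" = 0.1, "4" = 0.1)
  synth_config(seed = seed, n_genes = n_genes,
               n_nuclei_by_region = c(bz = n_nuclei, remote = n_nuclei),
               n_animals_rna = 3L,
               hvg_inflation_factor = 1, deg_log2fc = 0,
               nppb_pos_frac_by_region = c(bz = 0.15, remote = 0.15),
               cluster_probs_by_region = list(bz = even, remote = even))
}

# analytic monoexponential beat: baseline, instantaneous upstroke, decay
monoexp_beat <- function(tau_ms, fs = 1000, pre_ms = 100,
                         post_ms = 800) {
  c(rep(0, round(pre_ms * fs / 1000)),
    exp(-(0:round(post_ms * fs / 1000)) * 1000 / fs / tau_ms))
}

expect_region_value <- function(stats, region, col) {
  stats[[col]][stats$region == region]
}
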