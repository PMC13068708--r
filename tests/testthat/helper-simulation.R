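# Simulate a cohort of identical-parameter observers through the preset
# constant-stimuli session and return their Spearman-Kaerber Type B effects.
# Each observer gets a freshly shuffled trial sequence from the ambient RNG.
sim_typeb_deltas <- function(observer_factory, n_obs, standard = 80,
                             n_blocks = 20) {
  anc <- if (standard == 80) c(0, 160) else c(200, 800)
  vapply(seq_len(n_obs), function(i) {
    design <- constant_stimuli_design(standard, n_blocks = n_blocks)
    trials <- build_design(design)
    rec <- run_constant_stimuli(trials, observer_factory(), keep_latents = FALSE)
    tab <- aggregate_records(rec)
    tb <- type_b(spearman_karber(tab, "sc", anc[1], anc[2]),
                 spearman_karber(tab, "cs", anc[1], anc[2]))
    tb$delta_dl
  }, numeric(1))
}
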