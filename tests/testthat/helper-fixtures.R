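# Small end-to-end fixture: 20 subjects x 2 trials, HV-weighted so the
# healthy-reference age band has enough training subjects to fit.
fixture_config <- function(out_dir, seed = 42) {
  pipeline_config(
    out_dir = out_dir, n_subjects = 20, n_trials = 2, seed = seed,
    cohort_params = cohort_sim_params(
      group_props = c("HV" = 0.5, "MS-RR" = 0.3, "MS-SP" = 0.2),
      seed = seed),
    outcomes = c("combiwise", "neurex_sway"),
    families = c("ridge", "lasso"))
}
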