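# memoised small pipeline runs shared across test files

.epc_test_cache <- new.env(parent = emptyenv())

toy_sim_config <- function(seed = 7) {
  simulation_config(
    n_bacteria = 8, n_archaea = 6, n_eukaryotes = 4,
    genus_sizes = c(5, 3),
    n_families = c(euk_specific = 2, euk_bact = 8, euk_arch = 6,
                   euk_dual = 2, prok_only = 2),
    seq_length_range = c(80, 120), seed = seed)
}

toy_run <- function(seed = 7, recheck = TRUE, n_replicates = 50) {
  key <- paste("toy", seed, recheck, n_replicates, sep = "_")
  if (is.null(.epc_test_cache[[key]]))
    .epc_test_cache[[key]] <- run_pipeline(
      pipeline_config(sim = toy_sim_config(seed), n_replicates = n_replicates,
                      recheck = recheck, seed = seed))
  .epc_test_cache[[key]]
}

# criterion-scale study conditions: 30 bacteria in 5 skewed genera,
# 12 archaea, 8 eukaryotes, 60 bacteria-linked + 40 archaea-linked families
recovery_sim_config <- function(seed, parasites = character(0)) {
  simulation_config(
    n_bacteria = 30, n_archaea = 12, n_eukaryotes = 8,
    genus_sizes = c(12, 8, 5, 3, 2),
    n_families = c(euk_bact = 60, euk_arch = 40),
    within_domain_identity = 80, interdomain_identity = 45,
    presence_prob = 0.7,
    parasite_ids = parasites,
    seq_length_range = c(120, 200), seed = seed)
}
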