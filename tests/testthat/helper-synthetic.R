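# A scaled-down generator configuration for fast tests: one 1 Mb
# chromosome, 40/20 planted regions, no fragments or genes unless asked.
small_config <- function(seed, n_fragments = 0, n_genes = 0, ...) {
  base <- list(seed = seed, n_chroms = 1, chrom_length = 1e6,
               n_active_regions = 40, n_repressed_regions = 20,
               n_true_peaks = 40, n_decoy_peaks = 20,
               n_fragments = n_fragments, n_genes = n_genes)
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}

toy_truth <- function() {
  # RP = [0,400) on a; RN = [1000,2000) on a
  build_truth_sets(
    peak_set(character(), numeric(), numeric(), label = "K4me1"),
    peak_set("a", 0, 400, label = "K4me3"),
    peak_set("a", 300, 500, label = "K27ac"),
    peak_set("a", 1000, 2000, label = "K27me3"))
}
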