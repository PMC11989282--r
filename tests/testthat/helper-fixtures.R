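# Small in-code fixtures shared across tests.

small_panel <- function() {
  str_panel(data.frame(
    locus_id = c("BATX1", "BATX2", "DINU1"),
    chrom = c("chr1", "chr2", "chr3"),
    start = c(100L, 500L, 900L),
    end = c(116L, 522L, 920L),
    repeat_unit = c("A", "T", "CA"),
    stringsAsFactors = FALSE))
}

# profile with explicit histograms on the small panel
profile_from_counts <- function(counts_by_locus, sample_id = "S1",
                                sample_type = "FFPE") {
  sample_profile(sample_id, sample_type, counts_by_locus)
}

# fast simulation settings for module tests
quick_config <- function(...) {
  sim_config(n_loci = 12, n_reference = 25, depth_per_locus = 800,
             ...)
}
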