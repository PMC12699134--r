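# Shared simulated fixtures, built once per session. `small_sim()` is a
# fast reduced-scale experiment for module tests; `study_sim()` runs the
# full study conditions (200 enhancers, 1M fragments/library) used by the
# acceptance tests, cached so several tests can share it.

.sim_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 11L, ...) {
  args <- utils::modifyList(
    list(
      seed = seed,
      chromosome_length_bp = 60000L,
      n_enhancers = 12L,
      n_genes = 15L,
      n_input_fragments = 60000L,
      n_rna_fragments = 60000L,
      gene_length_range = c(2000L, 3000L)
    ),
    list(...)
  )
  do.call(sim_config, args)
}

small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    .sim_cache$small <- simulate_starrseq(small_config())
  }
  .sim_cache$small
}

study_sim <- function() {
  if (is.null(.sim_cache$study)) {
    .sim_cache$study <- simulate_starrseq(sim_config(seed = 1L),
                                          chromatin = TRUE,
                                          expression = TRUE)
  }
  .sim_cache$study
}

study_windows <- function() {
  if (is.null(.sim_cache$study_ws)) {
    sim <- study_sim()
    .sim_cache$study_ws <- scan_windows(sim$libraries[[1]]$input,
                                        sim$libraries[[1]]$rna,
                                        chrom_sizes(sim$genome))
  }
  .sim_cache$study_ws
}

# match each truth enhancer to its best overlapping peak; returns a tibble
# with one row per matched enhancer
match_peaks_to_truth <- function(peaks, truth) {
  ov <- suppressWarnings(GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(truth$chromosome,
                           IRanges::IRanges(truth$start + 1, truth$end)),
    GenomicRanges::GRanges(peaks$chromosome,
                           IRanges::IRanges(peaks$start + 1, peaks$end))))
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  if (length(q) == 0) return(tibble::tibble())
  pick <- tapply(seq_along(q), q,
                 function(i) i[which.max(peaks$log2_enrichment[s[i]])])
  q1 <- as.integer(names(pick))
  s1 <- s[unlist(pick)]
  tibble::tibble(
    enhancer_id = truth$enhancer_id[q1],
    true_log2_activity = truth$true_log2_activity[q1],
    center = (truth$start[q1] + truth$end[q1]) %/% 2,
    peak_id = peaks$peak_id[s1],
    log2_enrichment = peaks$log2_enrichment[s1],
    summit = peaks$summit[s1]
  )
}
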