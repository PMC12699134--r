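#' Simulation configuration
#'
#' Collects every parameter of the synthetic STARR-seq experiment. Defaults
#' describe the emulated study conditions: a 3-chromosome toy genome (the
#' third named "scaffold_1" to exercise the regular-chromosome whitelist),
#' 200 planted enhancers with log2 activities uniform on \[2.6, 6.9\] (6- to
#' 117-fold RNA:input enrichment), 49% of enhancers accessible, 800 +/- bp
#' fragments, and two replicate libraries of one million fragments each.
#'
#' @param seed Integer seed fixing all draws end to end.
#' @param chromosome_names Chromosome names; names not in
#'   `enhancer_chromosomes` carry fragments and decoy chromatin but no
#'   planted enhancers.
#' @param chromosome_length_bp Length of each chromosome.
#' @param n_enhancers Number of planted enhancers.
#' @param activity_log2_range Range of true log2 activities (low >= 0,
#'   low < high).
#' @param enhancer_length_bp Planted enhancer length.
#' @param accessible_fraction Probability an enhancer is accessible.
#' @param max_yy1_motifs Embedded YY1 instances scale linearly with activity
#'   up to this count: `floor((a - a_min) / (a_max - a_min) * max_yy1_motifs)`.
#' @param fragment_length_mean_bp,fragment_length_sd_bp Fragment length
#'   distribution (normal, clipped to \[100, 1500\]).
#' @param n_input_fragments,n_rna_fragments Library sizes per replicate.
#' @param n_replicates Number of replicate RNA/input library pairs.
#' @param n_genes Genes in the toy gene model.
#' @param gene_length_range Gene length range in bp.
#' @param tss_proximal_fraction_accessible Fraction of accessible enhancers
#'   centered within +/- 500 bp of a TSS.
#' @param enhancer_chromosomes Chromosomes that receive planted enhancers.
#' @param min_enhancer_gap_bp Minimum spacing between planted enhancers, so
#'   fragment-length bleed from a strong enhancer cannot merge adjacent
#'   peaks.
#' @param rna_weight_min_overlap_bp Minimum fragment/enhancer overlap for a
#'   candidate RNA fragment to carry the enhancer's sampling weight
#'   2^activity; matches the >= 1 bp overlap rule used in counting.
#' @param base_probs Background base composition (A, C, G, T).
#' @param tissue_purity Probability the nearest gene's tissue class follows
#'   the accessible -> ubiquitous / masked -> tissue-specific rule.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(seed = 1L,
                       chromosome_names = c("1", "2", "scaffold_1"),
                       chromosome_length_bp = 500000L,
                       n_enhancers = 200L,
                       activity_log2_range = c(2.6, 6.9),
                       enhancer_length_bp = 500L,
                       accessible_fraction = 0.49,
                       max_yy1_motifs = 5L,
                       fragment_length_mean_bp = 800,
                       fragment_length_sd_bp = 50,
                       n_input_fragments = 1000000L,
                       n_rna_fragments = 1000000L,
                       n_replicates = 2L,
                       n_genes = 120L,
                       gene_length_range = c(2000L, 5000L),
                       tss_proximal_fraction_accessible = 0.5,
                       enhancer_chromosomes = c("1", "2"),
                       min_enhancer_gap_bp = 2600L,
                       rna_weight_min_overlap_bp = 1L,
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       tissue_purity = 0.9) {
  cfg <- list(
    seed = as.integer(seed),
    chromosome_names = chromosome_names,
    chromosome_length_bp = as.integer(chromosome_length_bp),
    n_enhancers = as.integer(n_enhancers),
    activity_log2_range = activity_log2_range,
    enhancer_length_bp = as.integer(enhancer_length_bp),
    accessible_fraction = accessible_fraction,
    max_yy1_motifs = as.integer(max_yy1_motifs),
    fragment_length_mean_bp = fragment_length_mean_bp,
    fragment_length_sd_bp = fragment_length_sd_bp,
    n_input_fragments = as.integer(n_input_fragments),
    n_rna_fragments = as.integer(n_rna_fragments),
    n_replicates = as.integer(n_replicates),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    tss_proximal_fraction_accessible = tss_proximal_fraction_accessible,
    enhancer_chromosomes = enhancer_chromosomes,
    min_enhancer_gap_bp = as.integer(min_enhancer_gap_bp),
    rna_weight_min_overlap_bp = as.integer(rna_weight_min_overlap_bp),
    base_probs = base_probs,
    tissue_purity = tissue_purity
  )
  with(cfg, {
    if (activity_log2_range[1] < 0 || activity_log2_range[1] >= activity_log2_range[2]) {
      abort("activity_log2_range must satisfy 0 <= low < high")
    }
    if (accessible_fraction < 0 || accessible_fraction > 1) {
      abort("accessible_fraction must be in [0, 1]")
    }
    if (tissue_purity < 0 || tissue_purity > 1) {
      abort("tissue_purity must be in [0, 1]")
    }
    if (chromosome_length_bp <= 0 || enhancer_length_bp <= 0 ||
        fragment_length_mean_bp <= 0) {
      abort("lengths must be positive")
    }
    if (!all(enhancer_chromosomes %in% chromosome_names)) {
      abort("enhancer_chromosomes must be a subset of chromosome_names")
    }
    if (abs(sum(base_probs) - 1) > 1e-9) abort("base_probs must sum to 1")
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", length(x$chromosome_names), " chromosomes x ",
      x$chromosome_length_bp, " bp; ", x$n_enhancers,
      " enhancers, activity log2 in [",
      x$activity_log2_range[1], ", ", x$activity_log2_range[2], "]; ",
      x$n_input_fragments, " input / ", x$n_rna_fragments,
      " RNA fragments x ", x$n_replicates, " replicates (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}
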