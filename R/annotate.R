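# Chromatin-context and positional annotation of called peaks: accessibility
# (ATAC overlap), histone flags (with optional flanking window), genomic
# feature of the summit, nearest gene / TSS distance, tissue class of the
# nearest gene, and group-wise expression comparisons.

#' Flag peaks overlapping an ATAC-seq track
#'
#' A peak is "accessible" when it overlaps an ATAC-seq peak by at least 1 bp;
#' otherwise it is "masked".
#'
#' @param peaks Peak tibble.
#' @param atac_peaks ATAC-seq interval tibble.
#' @return `peaks` with a logical `accessible` column.
#' @export
annotate_accessibility <- function(peaks, atac_peaks) {
  mutate(as_tibble(peaks),
         accessible = overlap_flag(peaks, atac_peaks, flank_bp = 0))
}

#' Flag peaks near a ChIP-seq track
#'
#' With `flank_bp = 0` the flag requires a >= 1 bp overlap. With a positive
#' flank the ChIP peaks are extended by `flank_bp` on both sides and the
#' boundary is inclusive: a peak ending exactly `flank_bp` before a ChIP peak
#' starts is still flagged positive.
#'
#' @param peaks Peak tibble.
#' @param chip_peaks ChIP-seq interval tibble.
#' @param flank_bp Flank in bp (e.g. 3000 for H3K4me1; 0 for H3K27ac).
#' @param column Name of the added logical column.
#' @return `peaks` with the added flag column.
#' @export
annotate_histone <- function(peaks, chip_peaks, flank_bp = 0L,
                             column = "histone") {
  out <- as_tibble(peaks)
  out[[column]] <- overlap_flag(peaks, chip_peaks, flank_bp)
  out
}

#' @noRd
overlap_flag <- function(peaks, track, flank_bp = 0L) {
  validate_intervals(peaks)
  if (nrow(track) == 0) return(rep(FALSE, nrow(peaks)))
  validate_intervals(track)
  p <- paired_grs(peaks, track)
  if (flank_bp > 0) {
    tr <- GenomicRanges::resize(p$b, GenomicRanges::width(p$b) + 2 * flank_bp,
                                fix = "center")
    # inclusive boundary: book-ended intervals count
    GenomicRanges::countOverlaps(p$a, tr, maxgap = 0L) > 0
  } else {
    GenomicRanges::countOverlaps(p$a, p$b, minoverlap = 1L) > 0
  }
}

#' @noRd
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' @noRd
gene_tts <- function(genes) {
  ifelse(genes$strand == "+", genes$end - 1L, genes$start)
}

#' Annotate genomic feature, nearest gene and TSS distance
#'
#' Classifies each peak by its summit position with precedence
#' promoter_tss > tts > utr5 > utr3 > exon > intron > intergenic. The
#' promoter window spans `promoter_upstream` bp upstream to
#' `promoter_downstream` bp downstream of the TSS in gene orientation
#' (default +/- 1 kb, the conventional annotatePeaks window); the TTS window
#' is defined the same way around the transcription termination site. The nearest gene minimizes |summit - TSS|
#' on the same chromosome, and `tss_distance_bp` is the strand-oriented
#' signed offset (positive = downstream of the TSS in gene orientation).
#'
#' @param peaks Peak tibble with a `summit` column (defaults to the interval
#'   midpoint when absent).
#' @param gene_model Gene model from [simulate_genome()] (or any list with
#'   `genes`, `exons`, `utr5`, `utr3` tibbles).
#' @param promoter_upstream,promoter_downstream,tts_upstream,tts_downstream
#'   Window sizes in bp, oriented by gene strand.
#' @return `peaks` with `genomic_feature` (factor), `nearest_gene_id`,
#'   `tss_distance_bp` columns.
#' @export
annotate_genomic_feature <- function(peaks, gene_model,
                                     promoter_upstream = 1000L,
                                     promoter_downstream = 1000L,
                                     tts_upstream = 1000L,
                                     tts_downstream = 1000L) {
  peaks <- as_tibble(peaks)
  if (!"summit" %in% names(peaks)) {
    peaks$summit <- (peaks$start + peaks$end) %/% 2
  }
  levels <- c("promoter_tss", "tts", "utr5", "utr3", "exon", "intron",
              "intergenic")
  genes <- gene_model$genes
  if (is.null(genes) || nrow(genes) == 0) {
    return(mutate(peaks,
                  genomic_feature = factor("intergenic", levels = levels),
                  nearest_gene_id = NA_character_,
                  tss_distance_bp = NA_integer_))
  }
  tss <- gene_tss(genes)
  tts <- gene_tts(genes)
  plus <- genes$strand == "+"
  feature_windows <- list(
    promoter_tss = tibble(
      chromosome = genes$chromosome,
      start = ifelse(plus, tss - promoter_upstream, tss - promoter_downstream),
      end = ifelse(plus, tss + promoter_downstream, tss + promoter_upstream) + 1L
    ),
    tts = tibble(
      chromosome = genes$chromosome,
      start = ifelse(plus, tts - tts_upstream, tts - tts_downstream),
      end = ifelse(plus, tts + tts_downstream, tts + tts_upstream) + 1L
    ),
    utr5 = gene_model$utr5,
    utr3 = gene_model$utr3,
    exon = gene_model$exons,
    intron = genes
  )
  summits <- tibble(chromosome = peaks$chromosome,
                    start = peaks$summit, end = peaks$summit + 1L)
  feature <- rep("intergenic", nrow(peaks))
  for (nm in rev(names(feature_windows))) {
    fw <- feature_windows[[nm]]
    if (is.null(fw) || nrow(fw) == 0) next
    fw <- mutate(fw, start = pmax(.data$start, 0L))
    hit <- count_overlaps_tbl(summits, fw) > 0
    feature[hit] <- nm
  }
  # nearest TSS on the same chromosome
  nearest_id <- rep(NA_character_, nrow(peaks))
  tss_dist <- rep(NA_integer_, nrow(peaks))
  for (chr in unique(peaks$chromosome)) {
    gi <- which(genes$chromosome == chr)
    pi <- which(peaks$chromosome == chr)
    if (length(gi) == 0 || length(pi) == 0) next
    d <- abs(outer(peaks$summit[pi], tss[gi], "-"))
    best <- apply(d, 1, which.min)
    g <- gi[best]
    nearest_id[pi] <- genes$gene_id[g]
    raw <- peaks$summit[pi] - tss[g]
    tss_dist[pi] <- as.integer(ifelse(genes$strand[g] == "+", raw, -raw))
  }
  mutate(peaks,
         genomic_feature = factor(feature, levels = levels),
         nearest_gene_id = nearest_id,
         tss_distance_bp = tss_dist)
}

#' Classify genes by tissue-specificity category
#'
#' Maps tissue-distribution categories to coarse classes: genes with low
#' tissue specificity are "ubiquitous"; tissue-enhanced, tissue-enriched and
#' group-enriched genes are "tissue_specific". Genes absent from the lookup
#' are "unknown".
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param lookup_table Tibble with `gene_id` and `category` columns.
#' @return Character vector (`ubiquitous` / `tissue_specific` / `unknown`)
#'   aligned with `gene_ids`.
#' @export
classify_tissue <- function(gene_ids, lookup_table) {
  stopifnot(all(c("gene_id", "category") %in% names(lookup_table)))
  norm <- tolower(gsub("[^a-z ]", " ",
                       tolower(enc2utf8(as.character(lookup_table$category)))))
  norm <- trimws(gsub("\\s+", " ", norm))
  map <- c(
    "low tissue specificity" = "ubiquitous",
    "tissue enhanced" = "tissue_specific",
    "tissue enriched" = "tissue_specific",
    "group enriched" = "tissue_specific"
  )
  unknown_cat <- setdiff(unique(norm), names(map))
  if (length(unknown_cat) > 0) {
    abort(paste0("Unrecognized tissue category value(s): ",
                 paste(unknown_cat, collapse = ", ")))
  }
  cls <- unname(map[norm])
  out <- cls[match(gene_ids, lookup_table$gene_id)]
  out[is.na(out)] <- "unknown"
  out
}

#' Compare gene expression across groups
#'
#' Summarises log2(TPM + 1) per group (median and quartiles) and tests for a
#' group effect with one-way ANOVA, plus Bonferroni-adjusted pairwise t-tests.
#'
#' @param expression Tibble with `gene_id` and `tpm`.
#' @param group_assignments Tibble with `gene_id` and `group`.
#' @return An `expression_comparison` object; see [tidy()] and [glance()]
#'   methods.
#' @export
expression_by_group <- function(expression, group_assignments) {
  stopifnot(all(c("gene_id", "tpm") %in% names(expression)),
            all(c("gene_id", "group") %in% names(group_assignments)))
  df <- dplyr::inner_join(as_tibble(expression),
                          as_tibble(group_assignments), by = "gene_id") |>
    mutate(log_tpm = log2(.data$tpm + 1),
           group = factor(.data$group))
  sizes <- table(df$group)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("Need >= 2 groups with >= 2 members each")
  }
  fit <- stats::aov(log_tpm ~ group, data = df)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  pw <- stats::pairwise.t.test(df$log_tpm, df$group,
                               p.adjust.method = "bonferroni")
  pw_tbl <- as.data.frame(as.table(pw$p.value)) |>
    stats::setNames(c("group_a", "group_b", "p_adjusted")) |>
    filter(!is.na(.data$p_adjusted)) |>
    as_tibble()
  summary_tbl <- df |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(),
              median_log_tpm = stats::median(.data$log_tpm),
              q25 = stats::quantile(.data$log_tpm, 0.25),
              q75 = stats::quantile(.data$log_tpm, 0.75),
              .groups = "drop")
  structure(
    list(summary = summary_tbl, anova_p = anova_p, pairwise = pw_tbl,
         data = df),
    class = "expression_comparison"
  )
}

#' @export
print.expression_comparison <- function(x, ...) {
  cat("<expression_comparison> one-way ANOVA p =",
      format(x$anova_p, digits = 3), "\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.expression_comparison <- function(x, ...) x$summary

#' @export
glance.expression_comparison <- function(x, ...) {
  tibble(anova_p = x$anova_p,
         n_groups = nrow(x$summary),
         n = sum(x$summary$n))
}
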