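# Fragment counting and the activity / signal-to-noise / replicate-correlation
# statistics. STARR-seq activity of a target is the fold change between its
# depth-normalized (RPM) fragment counts in the reporter RNA library and the
# plasmid input library.

#' Count fragments overlapping regions
#'
#' A fragment counts toward a region when it overlaps it by at least
#' `min_overlap_bp` (default 1 bp); one fragment may count toward several
#' regions. Coordinates are 0-based half-open, so a fragment ending exactly
#' where a region starts does not overlap it.
#'
#' @param fragments Fragment tibble (`chromosome`, `start`, `end`).
#' @param regions Region tibble (`chromosome`, `start`, `end`).
#' @param min_overlap_bp Minimum overlap in bp for a fragment to count.
#' @param chromosomes Known chromosome names; regions on other chromosomes
#'   raise an error naming the chromosome. Defaults to the chromosomes
#'   present in `fragments`.
#' @return `regions` with an added integer `count` column.
#' @export
count_fragments <- function(fragments, regions, min_overlap_bp = 1L,
                            chromosomes = NULL) {
  validate_intervals(fragments)
  validate_intervals(regions)
  if (is.null(chromosomes)) chromosomes <- unique(fragments$chromosome)
  bad <- setdiff(unique(regions$chromosome), chromosomes)
  if (length(bad) > 0) {
    abort(paste0("Region(s) on unknown chromosome(s): ",
                 paste(bad, collapse = ", ")))
  }
  counts <- count_overlaps_tbl(regions, fragments,
                               minoverlap = min_overlap_bp)
  dplyr::mutate(as_tibble(regions), count = as.integer(counts))
}

#' Reads-per-million normalization
#'
#' @param x A data frame with a `count` column, or a numeric vector of counts.
#' @param library_total Total fragments in the library (> 0).
#' @return `x` with an `rpm` column added (or a numeric vector of RPM values).
#' @export
rpm_normalize <- function(x, library_total) {
  if (library_total <= 0) abort("`library_total` must be > 0")
  if (is.numeric(x)) return(x * 1e6 / library_total)
  stopifnot(is.data.frame(x), "count" %in% names(x))
  dplyr::mutate(as_tibble(x), rpm = .data$count * 1e6 / library_total)
}

#' Reads-per-kilobase-per-million normalization
#'
#' @inheritParams rpm_normalize
#' @param region_bp Region lengths in bp; defaults to `end - start` when `x`
#'   is a data frame with interval columns.
#' @return `x` with an `rpkm` column added (or a numeric vector).
#' @export
rpkm_normalize <- function(x, library_total, region_bp = NULL) {
  rpm <- rpm_normalize(if (is.data.frame(x)) x$count else x, library_total)
  if (is.null(region_bp)) {
    if (!is.data.frame(x) || !all(c("start", "end") %in% names(x))) {
      abort("`region_bp` is required when `x` has no start/end columns")
    }
    region_bp <- x$end - x$start
  }
  rpkm <- rpm / (region_bp / 1000)
  if (is.numeric(x)) return(rpkm)
  dplyr::mutate(as_tibble(x), rpkm = rpkm)
}

#' Targeted STARR-seq activity
#'
#' Computes per-target activity as the fold change between RPM in the RNA and
#' input libraries. When either raw count is zero, 0.5 is added to both raw
#' counts before normalization so log2 activity stays finite. Targets whose
#' input count falls below `min_input_count` are flagged unquantifiable
#' (`quantifiable = FALSE`) rather than dropped.
#'
#' @param counts Tibble with one row per target: a `target_id` column plus
#'   `count_rna` and `count_input` raw fragment counts.
#' @param rna_total,input_total Library totals.
#' @param min_input_count Minimum input count for a quantifiable target.
#' @param pseudocount Added to both raw counts when either is zero.
#' @return Tibble with raw counts, `rpm_rna`, `rpm_input`, `activity_fc`,
#'   `activity_log2`, `quantifiable`.
#' @export
targeted_activity <- function(counts, rna_total, input_total,
                              min_input_count = 10L, pseudocount = 0.5) {
  stopifnot(all(c("target_id", "count_rna", "count_input") %in% names(counts)))
  if (rna_total <= 0 || input_total <= 0) abort("Library totals must be > 0")
  as_tibble(counts) |>
    mutate(
      .pc = ifelse(.data$count_rna == 0 | .data$count_input == 0,
                   pseudocount, 0),
      rpm_rna = (.data$count_rna + .data$.pc) * 1e6 / rna_total,
      rpm_input = (.data$count_input + .data$.pc) * 1e6 / input_total,
      activity_fc = .data$rpm_rna / .data$rpm_input,
      activity_log2 = log2(.data$activity_fc),
      quantifiable = .data$count_input >= min_input_count
    ) |>
    select(-".pc")
}

#' Signal-to-noise ratio of positive regions
#'
#' SNR of each positive region is its activity fold change divided by the
#' mean activity fold change of the negative-control regions.
#'
#' @param activity Activity tibble (from [targeted_activity()]) with
#'   `target_id` and `activity_fc`.
#' @param positive_ids,negative_ids Target identifiers of the positive and
#'   negative-control regions.
#' @return Tibble with `target_id`, `activity_fc`, `snr`.
#' @export
signal_to_noise <- function(activity, positive_ids, negative_ids) {
  stopifnot(all(c("target_id", "activity_fc") %in% names(activity)))
  neg <- activity$activity_fc[activity$target_id %in% negative_ids]
  neg <- neg[is.finite(neg)]
  if (length(neg) == 0) {
    abort("No negative-control regions with finite activity")
  }
  noise <- mean(neg)
  activity |>
    filter(.data$target_id %in% positive_ids) |>
    mutate(snr = .data$activity_fc / noise) |>
    select("target_id", "activity_fc", "snr")
}

#' Replicate correlation of binned fragment coverage
#'
#' Partitions the genome into non-overlapping bins, normalizes per-bin
#' fragment counts of each replicate to RPM, and reports the squared Pearson
#' correlation over bins with a nonzero count in at least one replicate.
#'
#' @param frags_a,frags_b Fragment tibbles for the two replicates.
#' @param sizes Named chromosome lengths.
#' @param bin_bp Bin width (default 500).
#' @return One-row tibble with `r_squared` and `n_windows`.
#' @export
replicate_correlation <- function(frags_a, frags_b, sizes, bin_bp = 500L) {
  bins <- genome_bins(sizes, bin_bp)
  ka <- count_fragments(frags_a, bins, chromosomes = names(sizes))$count
  kb <- count_fragments(frags_b, bins, chromosomes = names(sizes))$count
  keep <- ka > 0 | kb > 0
  if (!any(keep)) abort("No bins with nonzero counts in either replicate")
  rpm_a <- ka[keep] * 1e6 / nrow(frags_a)
  rpm_b <- kb[keep] * 1e6 / nrow(frags_b)
  tibble(r_squared = stats::cor(rpm_a, rpm_b)^2, n_windows = sum(keep))
}

#' Normalize reporter measurements to a reference construct
#'
#' Background-subtracts raw reporter readings and expresses them as a
#' percentage of the (background-subtracted) reference construct, i.e. the
#' percentage of expression relative to a full-length reference vector.
#'
#' @param raw_table Tibble with `construct_id` and `value` (raw readings).
#' @param reference_id,background_id Construct identifiers of the reference
#'   (100%) and background (0%) rows.
#' @return `raw_table` with an added `percent_of_reference` column.
#' @export
reporter_normalize <- function(raw_table, reference_id, background_id) {
  stopifnot(all(c("construct_id", "value") %in% names(raw_table)))
  ref <- raw_table$value[raw_table$construct_id == reference_id]
  bg <- raw_table$value[raw_table$construct_id == background_id]
  if (length(ref) != 1 || length(bg) != 1) {
    abort("Reference and background must each match exactly one row")
  }
  if (ref <= bg) abort("Reference must exceed background (degenerate scale)")
  mutate(as_tibble(raw_table),
         percent_of_reference = 100 * (.data$value - bg) / (ref - bg))
}

#' Correlation between two reporter tables
#'
#' Pearson correlation (two-sided test) over constructs shared by both
#' tables, e.g. GFP versus SEAP normalized expression.
#'
#' @param table_a,table_b Tibbles with `construct_id` and a value column
#'   (`percent_of_reference` if present, else `value`).
#' @return One-row tibble with `estimate`, `p_value`, `n`.
#' @export
reporter_correlation <- function(table_a, table_b) {
  val <- function(x) {
    col <- if ("percent_of_reference" %in% names(x)) {
      "percent_of_reference"
    } else {
      "value"
    }
    x |> select("construct_id", value = all_of(col))
  }
  shared <- dplyr::inner_join(val(table_a), val(table_b), by = "construct_id",
                              suffix = c("_a", "_b"))
  if (nrow(shared) < 3) abort("Need at least 3 shared constructs")
  ct <- stats::cor.test(shared$value_a, shared$value_b, method = "pearson")
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
         n = nrow(shared))
}
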