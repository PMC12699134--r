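# Motif enrichment with shifted genomic backgrounds, YY1 motif dosage
# analysis, and YY1 core mutagenesis design.

#' Shifted background regions for motif enrichment
#'
#' Translates every (unfiltered) peak call 10 kb downstream in genomic
#' coordinates (strand-agnostic) to obtain background regions with a
#' comparable length and chromosome distribution. Shifted regions are removed
#' when they extend past a chromosome end, overlap any region in `avoid`
#' (e.g. the retained peak set), or have poor input coverage (fewer than
#' `min_input` overlapping input fragments).
#'
#' @param peak_calls Interval tibble of (unfiltered) peak calls.
#' @param sizes Named chromosome lengths.
#' @param shift_bp Shift in bp (default 10000).
#' @param avoid Interval tibble of regions the background must not overlap.
#' @param input_frags Input fragment tibble (NULL skips the coverage filter).
#' @param min_input Minimum overlapping input fragments.
#' @return Tibble of retained background intervals with a `source_id` column
#'   naming the originating peak when `peak_id` is present.
#' @export
shift_background <- function(peak_calls, sizes, shift_bp = 10000L,
                             avoid = NULL, input_frags = NULL,
                             min_input = 10L) {
  validate_intervals(peak_calls)
  shifted <- as_tibble(peak_calls) |>
    mutate(source_id = if ("peak_id" %in% names(peak_calls)) {
      .data$peak_id
    } else {
      sprintf("region_%05d", row_number())
    },
    start = .data$start + as.integer(shift_bp),
    end = .data$end + as.integer(shift_bp)) |>
    select("source_id", "chromosome", "start", "end")
  keep <- shifted$end <= sizes[shifted$chromosome]
  shifted <- shifted[keep, ]
  if (!is.null(avoid) && nrow(avoid) > 0 && nrow(shifted) > 0) {
    hit <- count_overlaps_tbl(shifted, avoid) > 0
    shifted <- shifted[!hit, ]
  }
  if (!is.null(input_frags) && nrow(shifted) > 0) {
    cov <- count_overlaps_tbl(shifted, input_frags)
    shifted <- shifted[cov >= min_input, ]
  }
  shifted
}

#' Motif enrichment between target and background sequences
#'
#' A sequence "has" a motif when [scan_pwm()] reports at least one hit below
#' the p-value threshold. Enrichment per motif is the ratio of the percentage
#' of target sequences with the motif to the percentage of background
#' sequences with it (0.5 sequences added to every cell of the 2x2 table
#' when any cell is zero), with a one-sided Fisher's exact test and
#' Benjamini-Hochberg adjustment across motifs. Comparing strong enhancers
#' (targets) against weak enhancers (background) is the same operation with
#' those sequence sets.
#'
#' @param target_seqs,background_seqs Named character vectors (or
#'   DNAStringSets) of sequences.
#' @param pwm_set List of [pwm_model] objects.
#' @param p_threshold Scan p-value threshold (default 1e-4).
#' @return Tibble per motif: `motif_id`, `n_target`, `n_background`,
#'   `pct_target`, `pct_background`, `fold`, `p_value`, `p_adjusted`.
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwm_set,
                             p_threshold = 1e-4) {
  if (inherits(pwm_set, "pwm_model")) pwm_set <- list(pwm_set)
  n_t <- length(target_seqs)
  n_b <- length(background_seqs)
  if (n_t == 0 || n_b == 0) abort("Both sequence sets must be nonempty")
  rows <- purrr::map_dfr(pwm_set, function(pwm) {
    ht <- scan_pwm(target_seqs, pwm, p_threshold)
    hb <- scan_pwm(background_seqs, pwm, p_threshold)
    with_t <- length(unique(ht$sequence_id))
    with_b <- length(unique(hb$sequence_id))
    tab <- matrix(c(with_t, n_t - with_t, with_b, n_b - with_b), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    pc <- if (any(tab == 0)) 0.5 else 0
    fold <- ((with_t + pc) / (n_t + 2 * pc)) /
      ((with_b + pc) / (n_b + 2 * pc))
    tibble(motif_id = pwm$motif_id, n_target = with_t, n_background = with_b,
           pct_target = 100 * with_t / n_t,
           pct_background = 100 * with_b / n_b,
           fold = fold, p_value = p)
  })
  mutate(rows, p_adjusted = stats::p.adjust(.data$p_value, method = "BH"))
}

#' YY1 motif dosage analysis
#'
#' Counts deduplicated YY1 hits per enhancer, bins counts as 0,1,2,3,4,5+
#' and summarises activity per bin, with a one-way ANOVA across bins and a
#' least-squares linear trend of activity on the (capped) motif count.
#'
#' @param enhancers Tibble with `enhancer_id` and `activity_log2`.
#' @param hits Hit tibble from [scan_pwm()] on the enhancer sequences
#'   (sequence ids = enhancer ids).
#' @param motif_width Motif width used for hit deduplication.
#' @param cap Counts at or above this collapse into the top bin (default 5).
#' @return A `yy1_dosage` object; see [tidy()] / [glance()].
#' @export
yy1_dosage <- function(enhancers, hits, motif_width, cap = 5L) {
  stopifnot(all(c("enhancer_id", "activity_log2") %in% names(enhancers)))
  hits <- dedup_hits(hits, motif_width)
  counts <- table(hits$sequence_id)
  df <- as_tibble(enhancers) |>
    mutate(n_motifs = as.integer(counts[.data$enhancer_id]),
           n_motifs = ifelse(is.na(.data$n_motifs), 0L, .data$n_motifs),
           capped = pmin(.data$n_motifs, cap),
           bin = factor(ifelse(.data$n_motifs >= cap,
                               paste0(cap, "+"), .data$n_motifs),
                        levels = c(seq(0, cap - 1), paste0(cap, "+"))))
  per_bin <- df |>
    group_by(.data$bin, .drop = FALSE) |>
    summarise(n = dplyr::n(),
              mean_activity = mean(.data$activity_log2),
              median_activity = stats::median(.data$activity_log2),
              .groups = "drop")
  occupied <- sum(per_bin$n > 0)
  anova_p <- NA_real_
  slope <- NA_real_
  slope_p <- NA_real_
  if (occupied >= 2) {
    fit <- stats::aov(activity_log2 ~ bin, data = droplevels(df))
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    lf <- stats::lm(activity_log2 ~ capped, data = df)
    slope <- unname(coef(lf)[2])
    slope_p <- summary(lf)$coefficients[2, 4]
  }
  structure(
    list(per_bin = per_bin, anova_p = anova_p, slope = slope,
         slope_p = slope_p, data = df),
    class = "yy1_dosage"
  )
}

#' @export
print.yy1_dosage <- function(x, ...) {
  cat("<yy1_dosage> trend slope =", format(x$slope, digits = 3),
      "log2/motif, ANOVA p =", format(x$anova_p, digits = 3), "\n")
  print(x$per_bin)
  invisible(x)
}

#' @export
tidy.yy1_dosage <- function(x, ...) x$per_bin

#' @export
glance.yy1_dosage <- function(x, ...) {
  tibble(slope = x$slope, slope_p = x$slope_p, anova_p = x$anova_p,
         n = nrow(x$data))
}

#' Mutate the YY1 core within motif hits
#'
#' Within each hit window, the conserved plus-strand core `ATGG` is replaced
#' by `CTCG`; for hits on the minus strand the genomic substring `CCAT`
#' (the reverse complement of the core) is replaced by `CGAG`. Sequence
#' length is unchanged. A hit whose window does not contain the oriented
#' core raises an error naming the hit (a PWM/core mismatch).
#'
#' @param sequence Single sequence (character).
#' @param hits Hit tibble (rows of [scan_pwm()] output for this sequence)
#'   with `start` and `strand`; zero rows return the sequence unchanged.
#' @param motif_width Motif width delimiting each hit window.
#' @param core Plus-strand core (default "ATGG").
#' @param replacement Plus-strand replacement (default "CTCG").
#' @return List with `sequence` (mutated) and `edits` (tibble of
#'   `hit_start`, `strand`, `core_start`, `from`, `to`).
#' @export
mutate_yy1 <- function(sequence, hits, motif_width = 10L,
                       core = "ATGG", replacement = "CTCG") {
  stopifnot(length(sequence) == 1, nchar(core) == nchar(replacement))
  chars <- strsplit(sequence, "")[[1]]
  edits <- list()
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]
    window <- substr(sequence, s + 1, min(s + motif_width, nchar(sequence)))
    look <- if (hits$strand[i] == "+") core else revcomp(core)
    put <- if (hits$strand[i] == "+") replacement else revcomp(replacement)
    at <- gregexpr(look, window, fixed = TRUE)[[1]]
    if (at[1] == -1) {
      abort(paste0("Hit at position ", s, " (strand ", hits$strand[i],
                   ") does not contain the core ", look,
                   "; PWM/core mismatch"))
    }
    for (a in at) {
      pos <- s + a - 1  # 0-based core start in full sequence
      idx <- seq(pos + 1, pos + nchar(core))
      edits[[length(edits) + 1]] <- tibble(
        hit_start = s, strand = hits$strand[i], core_start = pos,
        from = paste(chars[idx], collapse = ""), to = put)
      chars[idx] <- strsplit(put, "")[[1]]
    }
  }
  list(sequence = paste(chars, collapse = ""),
       edits = if (length(edits)) bind_rows(edits) else
         tibble(hit_start = integer(), strand = character(),
                core_start = integer(), from = character(), to = character()))
}

#' Design YY1 mutagenesis candidates
#'
#' Filters peaks to those with at least `min_hits` YY1 hits, takes the
#' `top_n` by activity, trims each to the minimal window covering all its
#' hits plus padding, and emits wild-type / fully-mutated sequence pairs.
#' Mutation is iterated with re-scanning (up to three rounds) so the emitted
#' mutant contains no remaining YY1 hit at the scan threshold.
#'
#' @param peaks Peak tibble with `peak_id`, `chromosome`, `start`, `end` and
#'   an activity column (`log2_enrichment` or `activity_log2`).
#' @param genome Genome ([Biostrings::DNAStringSet]).
#' @param pwm YY1 [pwm_model].
#' @param top_n Number of candidates (default 50).
#' @param min_hits Minimum YY1 hits per peak (default 2).
#' @param pad_bp Padding around the hit-covering window (default 20).
#' @param p_threshold Scan p-value threshold (default 1e-4).
#' @return Tibble with `peak_id`, `chromosome`, `start`, `end`, `n_hits`,
#'   `activity`, `wt_sequence`, `mut_sequence`, `n_edits`.
#' @export
select_mutagenesis_candidates <- function(peaks, genome, pwm, top_n = 50L,
                                          min_hits = 2L, pad_bp = 20L,
                                          p_threshold = 1e-4) {
  act_col <- intersect(c("log2_enrichment", "activity_log2"), names(peaks))[1]
  if (is.na(act_col)) abort("`peaks` needs log2_enrichment or activity_log2")
  peaks <- as_tibble(peaks)
  seqs <- stats::setNames(interval_sequences(genome, peaks), peaks$peak_id)
  hits <- dedup_hits(scan_pwm(seqs, pwm, p_threshold), pwm$width)
  counts <- table(hits$sequence_id)
  peaks$n_hits <- as.integer(counts[peaks$peak_id])
  peaks$n_hits[is.na(peaks$n_hits)] <- 0L
  qualifying <- peaks |>
    filter(.data$n_hits >= min_hits) |>
    arrange(dplyr::desc(.data[[act_col]]))
  if (nrow(qualifying) < top_n) {
    warn(sprintf("Only %d peak(s) qualify (requested %d); emitting all",
                 nrow(qualifying), top_n))
  }
  qualifying <- head(qualifying, top_n)
  sizes <- chrom_sizes(genome)
  purrr::map_dfr(seq_len(nrow(qualifying)), function(i) {
    pk <- qualifying[i, ]
    h <- filter(hits, .data$sequence_id == pk$peak_id)
    win_start <- max(0L, pk$start + min(h$start) - pad_bp)
    win_end <- min(sizes[[pk$chromosome]],
                   pk$start + max(h$start) + pwm$width + pad_bp)
    wt <- interval_sequences(genome, tibble(chromosome = pk$chromosome,
                                            start = win_start,
                                            end = win_end))
    mut <- wt
    n_edits <- 0L
    for (round in 1:3) {
      mh <- scan_pwm(stats::setNames(mut, pk$peak_id), pwm, p_threshold)
      if (nrow(mh) == 0) break
      res <- mutate_yy1(mut, mh, motif_width = pwm$width)
      mut <- res$sequence
      n_edits <- n_edits + nrow(res$edits)
    }
    tibble(peak_id = pk$peak_id, chromosome = pk$chromosome,
           start = win_start, end = win_end,
           n_hits = pk$n_hits, activity = pk[[act_col]],
           wt_sequence = wt, mut_sequence = mut, n_edits = n_edits)
  })
}
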