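# PWM construction, exact-p-value scanning, enrichment, dosage, mutagenesis.

random_pwm <- function(width, seed) {
  set.seed(seed)
  m <- matrix(stats::rgamma(4 * width, 1), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  pwm_model(m, motif_id = paste0("rand", width))
}

test_that("PWM validation enforces column sums and width", {
  bad <- matrix(0.3, nrow = 4, ncol = 6)
  expect_error(pwm_model(bad), "sum to 1")
  expect_error(pwm_model(matrix(0.25, 4, 3)), "width")
})

test_that("the DP null distribution matches exhaustive enumeration", {
  for (w in c(4, 6, 8)) {
    pwm <- random_pwm(w, seed = 100 + w)
    dist <- pwm_score_distribution(pwm)
    tail_fun <- oracle_pwm_tail(pwm)
    support <- dist$min_score + which(dist$prob > 0) - 1L
    probe <- unique(c(support, dist$min_score - 5L,
                      max(support) + 5L))
    for (s in probe) {
      dp <- if (s < dist$min_score) 1 else
        if (s > max(support)) 0 else
          dist$p_value[s - dist$min_score + 1]
      expect_lt(abs(dp - tail_fun(s)), 1e-12)
    }
  }
})

test_that("the consensus word scores maximally with minimal p-value", {
  pwm <- builtin_motifs()$YY1
  hits <- scan_pwm(c(s1 = pwm_consensus(pwm)), pwm)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 0L)
  dist <- pwm_score_distribution(pwm)
  max_int <- sum(apply(pwm$int_scores, 2, max))
  expect_equal(hits$score, max_int * pwm$resolution)
  expect_equal(hits$p_value, dist$p_value[max_int - dist$min_score + 1])
})

test_that("reverse-complement instances are reported on the minus strand", {
  pwm <- builtin_motifs()$YY1
  seq <- paste0("ACGTACGTAC",
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(pwm_consensus(pwm)))),
                "CCCCAAAATT")
  hits <- scan_pwm(c(s1 = seq), pwm)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 10L)
})

test_that("scanning is strand-symmetric", {
  pwm <- builtin_motifs()$ETS
  set.seed(41)
  seq <- paste0(
    paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""),
    pwm_consensus(pwm),
    paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  fwd <- scan_pwm(c(s = seq), pwm)
  rev <- scan_pwm(c(s = rc), pwm)
  expect_equal(nrow(fwd), nrow(rev))
  # mirrored coordinates and flipped strands
  expect_setequal(nchar(seq) - pwm$width - rev$start, fwd$start)
  expect_setequal(rev$strand,
                  ifelse(fwd$strand == "+", "-", "+"))
  expect_equal(sort(rev$score), sort(fwd$score))
})

test_that("sequences shorter than the motif and N runs yield no hits", {
  pwm <- builtin_motifs()$YY1
  expect_equal(nrow(scan_pwm(c(tiny = "ACGT"), pwm)), 0L)
  masked <- sub("ATGG", "ATNG", pwm_consensus(pwm))
  expect_equal(nrow(scan_pwm(c(n = masked), pwm)), 0L)
})

test_that("overlapping hit deduplication keeps the best score", {
  hits <- tibble::tibble(
    sequence_id = "s", start = c(0L, 4L, 30L), strand = "+",
    score = c(5, 9, 3), p_value = 1e-5, motif_id = "m")
  kept <- dedup_hits(hits, width = 10L)
  expect_equal(kept$start, c(4L, 30L))
})

test_that("shifted backgrounds follow the +10 kb rule and filters", {
  sizes <- c("1" = 30000L)
  peaks <- tibble::tibble(peak_id = c("a", "b", "c"),
                          chromosome = "1",
                          start = c(1000L, 5000L, 25000L),
                          end = c(1800L, 5600L, 25500L))
  bg <- shift_background(peaks, sizes)
  # region within 10 kb of the chromosome end is removed
  expect_equal(bg$source_id, c("a", "b"))
  expect_equal(bg$start, c(11000L, 15000L))
  expect_equal(bg$end, c(11800L, 15600L))
  # shifted region overlapping a retained peak is removed
  avoid <- tibble::tibble(chromosome = "1", start = 11500L, end = 11700L)
  expect_equal(shift_background(peaks, sizes, avoid = avoid)$source_id, "b")
  # poor input coverage filter
  input <- tibble::tibble(chromosome = "1",
                          start = rep(15100L, 12), end = rep(15500L, 12))
  covered <- shift_background(peaks, sizes, input_frags = input,
                              min_input = 10L)
  expect_equal(covered$source_id, "b")
})

test_that("motif enrichment matches the hypergeometric oracle", {
  pwm <- builtin_motifs()$YY1
  with_motif <- paste0(strrep("A", 10), pwm_consensus(pwm), strrep("A", 10))
  without <- strrep("A", 30)
  targets <- c(rep(with_motif, 20), rep(without, 80))
  names(targets) <- paste0("t", 1:100)
  background <- c(rep(with_motif, 5), rep(without, 95))
  names(background) <- paste0("b", 1:100)
  res <- motif_enrichment(targets, background, list(pwm))
  expect_equal(res$n_target, 20L)
  expect_equal(res$n_background, 5L)
  expect_equal(res$fold, 4.0)
  p_oracle <- sum(stats::dhyper(20:25, 25, 175, 100))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)

  same <- motif_enrichment(targets, targets, list(pwm))
  expect_equal(same$fold, 1.0)
  expect_gte(same$p_value, 0.5)
})

test_that("strong-vs-weak enrichment recovers the planted YY1 gradient", {
  sim <- small_sim()
  seqs <- stats::setNames(
    interval_sequences(sim$genome, sim$truth), sim$truth$enhancer_id)
  strong <- seqs[sim$truth$true_log2_activity >= 4]
  weak <- seqs[sim$truth$true_log2_activity <= 3.3]
  res <- motif_enrichment(strong, weak, sim$pwms["YY1"])
  expect_gt(res$fold, 1)
})

test_that("YY1 dosage bins are labeled 0..4, 5+ and degenerate input is safe", {
  enh <- tibble::tibble(enhancer_id = paste0("e", 1:10),
                        activity_log2 = runif(10, 3, 6))
  empty_hits <- scan_pwm(stats::setNames(strrep("A", 50), "e1"),
                         builtin_motifs()$YY1)
  d0 <- yy1_dosage(enh, empty_hits, motif_width = 10L)
  expect_equal(levels(d0$data$bin), c("0", "1", "2", "3", "4", "5+"))
  expect_true(is.na(d0$slope))
  expect_equal(sum(tidy(d0)$n > 0), 1L)
})

test_that("the YY1 core is mutated on both strands and is idempotent", {
  # plus-strand hit: ATGG -> CTCG
  res <- mutate_yy1("AAAATGGAAA",
                    tibble::tibble(start = 0L, strand = "+"),
                    motif_width = 10L)
  expect_equal(res$sequence, "AAACTCGAAA")
  expect_equal(nchar(res$sequence), 10L)
  # minus-strand hit: genomic CCAT -> CGAG
  res_m <- mutate_yy1("AAACCATAAA",
                      tibble::tibble(start = 0L, strand = "-"),
                      motif_width = 10L)
  expect_equal(res_m$sequence, "AAACGAGAAA")
  # zero hits: identity
  none <- mutate_yy1("ACGTACGT", tibble::tibble(start = integer(),
                                                strand = character()))
  expect_equal(none$sequence, "ACGTACGT")
  # missing core names the hit
  expect_error(mutate_yy1("AAAAAAAAAA",
                          tibble::tibble(start = 0L, strand = "+"),
                          motif_width = 10L),
               "mismatch")
  # idempotence through scan -> mutate -> rescan
  pwm <- builtin_motifs()$YY1
  seq <- paste0("TTTT", pwm_consensus(pwm), "TTTT")
  h1 <- scan_pwm(c(s = seq), pwm)
  m1 <- mutate_yy1(seq, h1, motif_width = pwm$width)$sequence
  h2 <- scan_pwm(c(s = m1), pwm)
  expect_equal(nrow(h2), 0L)
  m2 <- mutate_yy1(m1, h2, motif_width = pwm$width)$sequence
  expect_equal(m2, m1)
})

test_that("mutagenesis designs cover all hits and silence the motif", {
  sim <- small_sim()
  pwm <- sim$pwms$YY1
  truth_peaks <- dplyr::mutate(sim$truth,
                               peak_id = .data$enhancer_id,
                               activity_log2 = .data$true_log2_activity)
  expect_warning(
    designs <- select_mutagenesis_candidates(truth_peaks, sim$genome, pwm,
                                             top_n = 50L, min_hits = 2L),
    "qualify")
  expect_gt(nrow(designs), 0)
  expect_true(all(designs$n_hits >= 2))
  for (i in seq_len(nrow(designs))) {
    rescan <- scan_pwm(stats::setNames(designs$mut_sequence[i], "m"), pwm)
    expect_equal(nrow(rescan), 0L)
    expect_equal(nchar(designs$mut_sequence[i]),
                 nchar(designs$wt_sequence[i]))
    # wild-type window still contains >= min_hits hits
    wt_scan <- dedup_hits(
      scan_pwm(stats::setNames(designs$wt_sequence[i], "w"), pwm), pwm$width)
    expect_gte(nrow(wt_scan), 2L)
  }
})

test_that("peaks with fewer than min_hits scan hits are excluded", {
  pwm <- builtin_motifs()$YY1
  one_hit <- paste0(strrep("T", 20), pwm_consensus(pwm), strrep("T", 20))
  two_hit <- paste0(strrep("T", 10), pwm_consensus(pwm), strrep("T", 10),
                    pwm_consensus(pwm), strrep("T", 10))
  genome <- Biostrings::DNAStringSet(c("1" = paste0(one_hit, two_hit)))
  peaks <- tibble::tibble(
    peak_id = c("one", "two"), chromosome = "1",
    start = c(0L, nchar(one_hit)),
    end = c(nchar(one_hit), nchar(one_hit) + nchar(two_hit)),
    log2_enrichment = c(5, 4))
  expect_warning(
    designs <- select_mutagenesis_candidates(peaks, genome, pwm,
                                             top_n = 50L, min_hits = 2L),
    "qualify")
  expect_equal(designs$peak_id, "two")
  expect_equal(designs$n_hits, 2L)
  # trimmed window contains every hit interval
  wt_hits <- dedup_hits(
    scan_pwm(stats::setNames(designs$wt_sequence, "w"), pwm), pwm$width)
  expect_equal(nrow(wt_hits), 2L)
})
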