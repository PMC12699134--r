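test_that("fragment counting follows the 1 bp half-open overlap rule", {
  frag <- tibble::tibble(chromosome = "1", start = 100L, end = 900L)
  expect_equal(
    count_fragments(frag, tibble::tibble(chromosome = "1", start = 899L,
                                         end = 1400L))$count, 1L)
  expect_equal(
    count_fragments(frag, tibble::tibble(chromosome = "1", start = 900L,
                                         end = 1400L))$count, 0L)
  tiled <- tibble::tibble(chromosome = "1",
                          start = seq(0L, 900L, by = 100L),
                          end = seq(100L, 1000L, by = 100L))
  region <- tibble::tibble(chromosome = "1", start = 0L, end = 500L)
  expect_equal(count_fragments(tiled, region)$count,
               brute_force_counts(tiled, region))
  expect_equal(count_fragments(tiled, region)$count, 5L)
})

test_that("counting equals the brute-force all-pairs oracle", {
  set.seed(42)
  sizes <- c("1" = 10000L, "2" = 8000L)
  for (rep in 1:3) {
    frags <- random_fragments(400, sizes)
    regions <- random_fragments(60, sizes, len_range = c(100L, 600L))
    expect_equal(count_fragments(frags, regions)$count,
                 brute_force_counts(frags, regions))
  }
})

test_that("counting errors on regions from unknown chromosomes", {
  frags <- tibble::tibble(chromosome = "1", start = 0L, end = 100L)
  expect_error(
    count_fragments(frags, tibble::tibble(chromosome = "chrUn", start = 0L,
                                          end = 10L)),
    "chrUn")
})

test_that("RPM and RPKM normalization are exact and scale-invariant", {
  expect_equal(rpm_normalize(50, 1e6), 50)
  expect_equal(rpkm_normalize(50, 1e6, region_bp = 500), 100)
  counts <- c(3, 17, 250)
  expect_equal(rpm_normalize(counts * 7, 1e6 * 7),
               rpm_normalize(counts, 1e6))
  # conservation over a partition: RPM sums to 1e6 x assigned fraction
  sizes <- c("1" = 5000L)
  set.seed(7)
  frags <- random_fragments(200, sizes, len_range = c(1L, 1L))
  bins <- genome_bins(sizes, 500L)
  k <- count_fragments(frags, bins)$count
  expect_equal(sum(rpm_normalize(k, nrow(frags))), 1e6)
})

test_that("targeted activity reproduces hand arithmetic and flags", {
  tbl <- tibble::tibble(target_id = c("A", "B"),
                        count_rna = c(300L, 10L),
                        count_input = c(50L, 50L))
  act <- targeted_activity(tbl, rna_total = 1e6, input_total = 1e6)
  expect_equal(act$activity_fc, c(6.0, 0.2))
  expect_equal(act$activity_log2, log2(c(6.0, 0.2)))
  expect_true(all(act$quantifiable))

  one <- targeted_activity(
    tibble::tibble(target_id = "x", count_rna = 200L, count_input = 50L),
    rna_total = 1e6, input_total = 1e6)
  expect_equal(one$activity_fc, 4.0)
  expect_equal(one$activity_log2, 2.0)

  same <- targeted_activity(
    tibble::tibble(target_id = "x", count_rna = 75L, count_input = 75L),
    rna_total = 1e6, input_total = 1e6)
  expect_equal(same$activity_fc, 1.0)

  low <- targeted_activity(
    tibble::tibble(target_id = c("lo", "zero"),
                   count_rna = c(4L, 0L), count_input = c(4L, 20L)),
    rna_total = 1e5, input_total = 1e5)
  expect_false(any(low$quantifiable[1]))
  expect_true(is.finite(low$activity_log2[2]))  # pseudocount keeps it finite
})

test_that("signal-to-noise divides by the mean of the negative controls", {
  act <- tibble::tibble(target_id = c("p1", "n1", "n2"),
                        activity_fc = c(10, 1.5, 2.5))
  snr <- signal_to_noise(act, "p1", c("n1", "n2"))
  expect_equal(snr$snr, 5.0)

  eq <- signal_to_noise(
    tibble::tibble(target_id = c("p", "n"), activity_fc = c(2, 2)),
    "p", "n")
  expect_equal(eq$snr, 1.0)

  # 14 positives in, 14 SNRs out
  act14 <- tibble::tibble(target_id = c(paste0("p", 1:14), "n1"),
                          activity_fc = c(runif(14, 2, 50), 1.2))
  expect_equal(nrow(signal_to_noise(act14, paste0("p", 1:14), "n1")), 14L)

  expect_error(signal_to_noise(act, "p1", character(0)), "egative")
})

test_that("replicate correlation is 1 for identical sets and order-invariant", {
  set.seed(5)
  sizes <- c("1" = 20000L)
  frags <- random_fragments(500, sizes)
  expect_equal(replicate_correlation(frags, frags, sizes)$r_squared, 1.0)
  rev_frags <- frags[rev(seq_len(nrow(frags))), ]
  expect_equal(replicate_correlation(frags, rev_frags, sizes)$r_squared, 1.0)
})

test_that("independent fragment tracks have near-zero correlation", {
  set.seed(6)
  sizes <- c("1" = 5000000L)
  a <- random_fragments(20000, sizes, len_range = c(100L, 100L))
  b <- random_fragments(20000, sizes, len_range = c(100L, 100L))
  rc <- replicate_correlation(a, b, sizes)
  expect_gte(rc$n_windows, 9000)
  expect_lt(rc$r_squared, 0.05)
})

test_that("reporter normalization anchors background at 0 and reference at 100", {
  raw <- tibble::tibble(construct_id = c("bg", "ref", "e1", "e2", "e3"),
                        value = c(10, 110, 10, 110, 60))
  norm <- reporter_normalize(raw, "ref", "bg")
  expect_equal(norm$percent_of_reference, c(0, 100, 0, 100, 50))
  expect_error(reporter_normalize(
    tibble::tibble(construct_id = c("bg", "ref"), value = c(5, 5)),
    "ref", "bg"), "egenerate")
})

test_that("reporter correlation matches the closed-form Pearson formula", {
  a <- tibble::tibble(construct_id = letters[1:5],
                      value = c(12, 45, 33, 80, 51))
  b <- tibble::tibble(construct_id = letters[1:5],
                      value = c(15, 40, 30, 95, 45))
  res <- reporter_correlation(a, b)
  x <- a$value
  y <- b$value
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, r_hand, tolerance = 1e-12)
  tstat <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(tstat), df = 3),
               tolerance = 1e-12)
  expect_equal(res$n, 5L)
})

test_that("activity estimates are unbiased on reduced-scale synthetic data", {
  sim <- small_sim()
  ws <- scan_windows(sim$libraries[[1]]$input, sim$libraries[[1]]$rna,
                     chrom_sizes(sim$genome))
  peaks <- call_peaks(ws, chrom_whitelist = sim$config$enhancer_chromosomes)
  matched <- match_peaks_to_truth(peaks, sim$truth)
  expect_gte(nrow(matched), 10)
  bias <- mean(matched$log2_enrichment - matched$true_log2_activity)
  expect_lt(abs(bias), 0.15)
})
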