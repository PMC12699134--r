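# Synthetic-experiment generator: determinism, genome statistics, planting
# invariants, fragment conservation, chromatin and expression structure.

test_that("the generator is deterministic given a seed", {
  cfg <- small_config(seed = 77)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$gene_model$genes, b$gene_model$genes)
  pa <- plant_enhancers(a, cfg)
  pb <- plant_enhancers(b, cfg)
  expect_identical(as.character(pa$genome), as.character(pb$genome))
  expect_identical(pa$truth, pb$truth)
  fa <- simulate_fragments(pa$genome, pa$truth, cfg, replicate = 1)
  fb <- simulate_fragments(pb$genome, pb$truth, cfg, replicate = 1)
  expect_identical(fa$input, fb$input)
  expect_identical(fa$rna, fb$rna)
})

test_that("chromosome count, names and lengths match the configuration", {
  cfg <- small_config()
  g <- simulate_genome(cfg)$genome
  expect_length(g, 3L)
  expect_equal(names(g), c("1", "2", "scaffold_1"))
  expect_equal(unname(chrom_sizes(g)), rep(60000L, 3))
})

test_that("uniform base composition holds to binomial precision", {
  cfg <- sim_config(seed = 6, chromosome_names = "1",
                    chromosome_length_bp = 500000L, n_enhancers = 1L,
                    n_genes = 2L, enhancer_chromosomes = "1")
  g <- simulate_genome(cfg)$genome
  freqs <- Biostrings::alphabetFrequency(g[[1]])[c("A", "C", "G", "T")]
  n <- 500000
  sd3 <- 3 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freqs / n - 0.25) < sd3))
})

test_that("planted enhancers never overlap and respect chromosome bounds", {
  sim <- small_sim()
  tr <- sim$truth
  sizes <- chrom_sizes(sim$genome)
  expect_true(all(tr$start >= 0 & tr$end <= sizes[tr$chromosome]))
  expect_true(all(tr$chromosome %in% sim$config$enhancer_chromosomes))
  by_chr <- split(tr, tr$chromosome)
  for (chr_tr in by_chr) {
    s <- chr_tr[order(chr_tr$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
})

test_that("the motif-count rule is linear in activity and recoverable", {
  sim <- small_sim()
  tr <- sim$truth
  rng <- sim$config$activity_log2_range
  expect_equal(tr$n_yy1_motifs,
               as.integer(floor((tr$true_log2_activity - rng[1]) /
                                  (rng[2] - rng[1]) * 5)))
  seqs <- stats::setNames(interval_sequences(sim$genome, tr), tr$enhancer_id)
  hits <- dedup_hits(scan_pwm(seqs, sim$pwms$YY1), sim$pwms$YY1$width)
  found <- table(hits$sequence_id)
  recovered <- as.integer(found[tr$enhancer_id])
  recovered[is.na(recovered)] <- 0L
  expect_true(all(recovered >= tr$n_yy1_motifs))
})

test_that("accessible_fraction = 0 masks every enhancer", {
  cfg <- small_config(seed = 12, accessible_fraction = 0)
  base <- simulate_genome(cfg)
  pl <- plant_enhancers(base, cfg)
  expect_false(any(pl$truth$accessible))
})

test_that("fragment libraries conserve configured sizes and lengths", {
  sim <- small_sim()
  libs <- sim$libraries[[1]]
  expect_equal(nrow(libs$input), sim$config$n_input_fragments)
  expect_equal(nrow(libs$rna), sim$config$n_rna_fragments)
  lens <- libs$input$end - libs$input$start
  expect_true(all(lens >= 100 & lens <= 1500))
  sizes <- chrom_sizes(sim$genome)
  expect_true(all(libs$input$start >= 0 &
                    libs$input$end <= sizes[libs$input$chromosome]))
})

test_that("without enhancers RNA and input coverage are indistinguishable", {
  cfg <- small_config(seed = 13, n_enhancers = 0L)
  base <- simulate_genome(cfg)
  pl <- plant_enhancers(base, cfg)
  expect_equal(nrow(pl$truth), 0L)
  libs <- simulate_fragments(pl$genome, pl$truth, cfg, replicate = 1)
  sizes <- chrom_sizes(pl$genome)
  bins <- genome_bins(sizes, 500L)
  k_in <- count_fragments(libs$input, bins, chromosomes = names(sizes))$count
  k_rna <- count_fragments(libs$rna, bins, chromosomes = names(sizes))$count
  expect_gt(suppressWarnings(stats::wilcox.test(k_in, k_rna)$p.value), 0.01)
})

test_that("accessible enhancers carry matching chromatin, masked ones do not", {
  sim <- small_sim()
  tr <- sim$truth
  acc <- tr[tr$accessible, ]
  msk <- tr[!tr$accessible, ]
  atac_hits <- count_fragments(sim$chromatin$atac, acc)$count
  expect_true(all(atac_hits >= 1))
  msk_hits <- count_fragments(sim$chromatin$atac, msk)$count
  expect_true(all(msk_hits == 0))
  k4 <- annotate_histone(acc, sim$chromatin$h3k4me1, flank_bp = 3000L,
                         column = "k4")
  expect_true(all(k4$k4))
})

test_that("decoy chromatin peaks avoid planted enhancers exactly", {
  cfg <- small_config(seed = 14)
  base <- simulate_genome(cfg)
  pl <- plant_enhancers(base, cfg)
  chrom <- simulate_chromatin(pl$truth, cfg, chrom_sizes(pl$genome),
                              decoy_count = 1000L)
  decoys <- count_fragments(pl$truth, chrom$atac,
                            chromosomes = names(chrom_sizes(pl$genome)))$count == 0
  expect_equal(sum(decoys), 1000L)
})

test_that("tissue purity 1 labels every accessible-enhancer gene ubiquitous", {
  cfg <- small_config(seed = 15, tissue_purity = 1)
  base <- simulate_genome(cfg)
  pl <- plant_enhancers(base, cfg)
  et <- simulate_expression_and_tissue(pl$truth, base$gene_model, cfg)
  acc_genes <- unique(pl$truth$nearest_gene_id[pl$truth$accessible])
  acc_genes <- setdiff(acc_genes,
                       pl$truth$nearest_gene_id[!pl$truth$accessible])
  cats <- et$tissue_lookup$category[match(acc_genes,
                                          et$tissue_lookup$gene_id)]
  expect_true(all(cats == "low tissue specificity"))
})

test_that("a zero expression effect leaves group means equal", {
  cfg <- small_config(seed = 17)
  base <- simulate_genome(cfg)
  pl <- plant_enhancers(base, cfg)
  et <- simulate_expression_and_tissue(pl$truth, base$gene_model, cfg,
                                       effect_per_log2 = 0)
  acc_genes <- stats::na.omit(unique(pl$truth$nearest_gene_id[pl$truth$accessible]))
  log_tpm <- log2(et$expression$tpm + 1)
  in_acc <- et$expression$gene_id %in% acc_genes
  p <- stats::t.test(log_tpm[in_acc], log_tpm[!in_acc])$p.value
  expect_gt(p, 0.01)
})
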