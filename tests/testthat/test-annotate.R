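# Chromatin flags, genomic-feature assignment, tissue classes, expression.

test_that("accessibility needs >= 1 bp overlap; empty tracks mask everything", {
  peaks <- tibble::tibble(chromosome = "1", start = 1000L, end = 1500L)
  atac <- tibble::tibble(chromosome = "1", start = 1499L, end = 2000L)
  expect_true(annotate_accessibility(peaks, atac)$accessible)
  atac2 <- tibble::tibble(chromosome = "1", start = 1500L, end = 2000L)
  expect_false(annotate_accessibility(peaks, atac2)$accessible)
  empty <- tibble::tibble(chromosome = character(), start = integer(),
                          end = integer())
  expect_false(annotate_accessibility(peaks, empty)$accessible)
})

test_that("the histone flank is inclusive at exactly 3 kb", {
  chip <- tibble::tibble(chromosome = "1", start = 5000L, end = 5400L)
  at_boundary <- tibble::tibble(chromosome = "1", start = 1500L, end = 2000L)
  past_boundary <- tibble::tibble(chromosome = "1", start = 1500L,
                                  end = 1999L)
  expect_true(annotate_histone(at_boundary, chip, flank_bp = 3000L,
                               column = "h3k4me1")$h3k4me1)
  expect_false(annotate_histone(past_boundary, chip, flank_bp = 3000L,
                                column = "h3k4me1")$h3k4me1)
})

toy_gene_model <- function() {
  genes <- tibble::tibble(
    gene_id = c("gPlus", "gMinus"),
    chromosome = c("1", "1"),
    start = c(10000L, 40000L),
    end = c(14000L, 44000L),
    strand = c("+", "-")
  )
  exons <- dplyr::bind_rows(
    dplyr::mutate(genes, end = start + 600L, exon_number = 1L),
    dplyr::mutate(genes, start = end - 600L, exon_number = 2L))
  utr5 <- tibble::tibble(
    gene_id = genes$gene_id, chromosome = "1",
    start = c(10000L, 43800L), end = c(10200L, 44000L),
    strand = genes$strand)
  utr3 <- tibble::tibble(
    gene_id = genes$gene_id, chromosome = "1",
    start = c(13800L, 40000L), end = c(14000L, 40200L),
    strand = genes$strand)
  structure(list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3),
            class = "gene_model")
}

test_that("summit feature assignment is strand-aware with fixed precedence", {
  gm <- toy_gene_model()
  peaks <- tibble::tibble(
    chromosome = "1",
    start = c(10100L, 43700L, 25000L, 12000L),
    end = c(10300L, 43900L, 25200L, 12200L),
    summit = c(10200L, 43800L, 25100L, 12100L)
  )
  ann <- annotate_genomic_feature(peaks, gm)
  # +strand TSS at 10000: summit +200 downstream -> promoter, distance +200
  expect_equal(as.character(ann$genomic_feature[1]), "promoter_tss")
  expect_equal(ann$nearest_gene_id[1], "gPlus")
  expect_equal(ann$tss_distance_bp[1], 200L)
  # -strand TSS at 43999: summit 199 genomically left -> downstream +199
  expect_equal(as.character(ann$genomic_feature[2]), "promoter_tss")
  expect_equal(ann$nearest_gene_id[2], "gMinus")
  expect_equal(ann$tss_distance_bp[2], 199L)
  # gene desert -> intergenic
  expect_equal(as.character(ann$genomic_feature[3]), "intergenic")
  # inside gPlus body, outside exons/promoter -> intron
  expect_equal(as.character(ann$genomic_feature[4]), "intron")
})

test_that("gene-record order does not change assignments", {
  gm <- toy_gene_model()
  set.seed(8)
  gm_shuffled <- gm
  ord <- sample(nrow(gm$genes))
  gm_shuffled$genes <- gm$genes[ord, ]
  peaks <- tibble::tibble(chromosome = "1",
                          start = seq(9000L, 45000L, by = 1500L),
                          end = seq(9200L, 45200L, by = 1500L))
  a <- annotate_genomic_feature(peaks, gm)
  b <- annotate_genomic_feature(peaks, gm_shuffled)
  expect_equal(a$genomic_feature, b$genomic_feature)
  expect_equal(a$nearest_gene_id, b$nearest_gene_id)
})

test_that("an empty gene model yields intergenic peaks with null genes", {
  gm <- structure(list(genes = tibble::tibble(), exons = NULL,
                       utr5 = NULL, utr3 = NULL), class = "gene_model")
  ann <- annotate_genomic_feature(
    tibble::tibble(chromosome = "1", start = 0L, end = 100L, summit = 50L),
    gm)
  expect_equal(as.character(ann$genomic_feature), "intergenic")
  expect_true(is.na(ann$nearest_gene_id))
})

test_that("tissue categories map exactly and absent genes are unknown", {
  lookup <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    category = c("low tissue specificity", "tissue enhanced",
                 "tissue enriched", "group enriched"))
  out <- classify_tissue(c("g1", "g4", "g2", "missing"), lookup)
  expect_equal(out, c("ubiquitous", "tissue_specific", "tissue_specific",
                      "unknown"))
  bad <- tibble::tibble(gene_id = "g1", category = "not detected")
  expect_error(classify_tissue("g1", bad), "not detected")
})

test_that("expression comparison handles null and strong-effect cases", {
  set.seed(90)
  vals <- stats::rlnorm(60, log(10), 1)
  same <- expression_by_group(
    tibble::tibble(gene_id = paste0("g", 1:120), tpm = rep(vals, 2)),
    tibble::tibble(gene_id = paste0("g", 1:120),
                   group = rep(c("a", "b"), each = 60)))
  expect_gt(same$anova_p, 0.5)

  set.seed(9)
  tpm <- 2^c(rnorm(50, 0, 1), rnorm(50, 0, 1), rnorm(50, 5, 1))
  strong <- expression_by_group(
    tibble::tibble(gene_id = paste0("g", 1:150), tpm = tpm),
    tibble::tibble(gene_id = paste0("g", 1:150),
                   group = rep(c("a", "b", "c"), each = 50)))
  expect_lt(strong$anova_p, 1e-10)
  expect_equal(nrow(tidy(strong)), 3L)
  expect_equal(glance(strong)$n, 150L)
  pw <- strong$pairwise
  expect_equal(nrow(pw), 3L)

  expect_error(expression_by_group(
    tibble::tibble(gene_id = c("g1", "g2"), tpm = c(1, 2)),
    tibble::tibble(gene_id = c("g1", "g2"), group = c("a", "b"))),
    "2 members")
})

test_that("accessible-enhancer genes are expressed above masked ones", {
  sim <- study_sim()
  groups <- sim$truth |>
    dplyr::filter(!is.na(nearest_gene_id)) |>
    dplyr::mutate(group = ifelse(accessible, "accessible", "masked")) |>
    dplyr::distinct(gene_id = nearest_gene_id, group)
  groups <- groups[!duplicated(groups$gene_id), ]
  cmp <- expression_by_group(sim$expression, groups)
  med <- tidy(cmp)
  expect_gt(med$median_log_tpm[med$group == "accessible"],
            med$median_log_tpm[med$group == "masked"])
})
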