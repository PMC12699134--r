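# Synthetic STARR-seq experiment generator. Produces a toy genome, a gene
# model, planted enhancers with embedded TF motifs, fragment libraries whose
# RNA:input enrichment encodes the planted activities, chromatin tracks and
# expression/tissue tables, so every downstream stage can be tested against
# known ground truth.

#' Bundled synthetic PWMs (YY1, ETS)
#'
#' Minimal synthetic position weight matrices: a YY1-like motif with the
#' conserved ATGG core and an ETS-family representative with the GGAA core.
#' These are constructed stand-ins for curated motif libraries (which are not
#' redistributable), adequate for planting and recovering motif instances in
#' synthetic sequence; users may supply any MEME-format motifs instead.
#'
#' @return Named list of two [pwm_model] objects (`YY1`, `ETS`).
#' @export
builtin_motifs <- function() {
  yy1 <- matrix(c(
    # A     C     G     T        consensus CAAGATGGCG, core ATGG at 5..8
    0.10, 0.70, 0.10, 0.10,
    0.60, 0.14, 0.13, 0.13,
    0.60, 0.13, 0.14, 0.13,
    0.10, 0.10, 0.70, 0.10,
    0.94, 0.02, 0.02, 0.02,
    0.02, 0.02, 0.02, 0.94,
    0.02, 0.02, 0.94, 0.02,
    0.02, 0.02, 0.94, 0.02,
    0.13, 0.60, 0.14, 0.13,
    0.15, 0.15, 0.55, 0.15
  ), nrow = 4)
  ets <- matrix(c(
    # consensus ACCGGAAG, core GGAA at 4..7
    0.60, 0.14, 0.13, 0.13,
    0.10, 0.70, 0.10, 0.10,
    0.12, 0.64, 0.12, 0.12,
    0.02, 0.02, 0.94, 0.02,
    0.02, 0.02, 0.94, 0.02,
    0.94, 0.02, 0.02, 0.02,
    0.94, 0.02, 0.02, 0.02,
    0.13, 0.13, 0.61, 0.13
  ), nrow = 4)
  rownames(yy1) <- rownames(ets) <- c("A", "C", "G", "T")
  list(YY1 = pwm_model(yy1, motif_id = "YY1"),
       ETS = pwm_model(ets, motif_id = "ETS"))
}

# Place k intervals of the given widths in [0, length) with at least
# `min_gap` between them (and to the ends), uniformly at random via spaced
# order statistics. Errors when they cannot fit.
#' @noRd
place_nonoverlapping <- function(length_bp, widths, min_gap = 0L) {
  k <- length(widths)
  if (k == 0) return(integer(0))
  slack <- length_bp - sum(widths) - (k + 1) * min_gap
  if (slack < 0) {
    abort(paste0("Cannot fit ", k, " features (total ", sum(widths),
                 " bp + gaps) in ", length_bp, " bp"))
  }
  u <- sort(runif(k, 0, slack))
  starts <- floor(u) + min_gap * seq_len(k) +
    cumsum(c(0, widths[-k]))
  as.integer(starts)
}

#' @noRd
random_sequence <- function(len, base_probs) {
  paste(sample(names(base_probs), len, replace = TRUE, prob = base_probs),
        collapse = "")
}

#' Simulate a toy genome and gene model
#'
#' Generates random chromosome sequences at the configured background base
#' composition and a non-overlapping gene model on the enhancer chromosomes.
#' Each gene carries terminal exons (600 bp), terminal UTRs (200 bp, inside
#' the exons) and a central intron. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]) and `gene_model`
#'   (class `gene_model`: tibbles `genes`, `exons`, `utr5`, `utr3`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seqs <- vapply(config$chromosome_names, function(chr) {
    random_sequence(config$chromosome_length_bp, config$base_probs)
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- config$chromosome_names

  chroms <- config$enhancer_chromosomes
  per_chrom <- table(factor(
    sample(chroms, config$n_genes, replace = TRUE), levels = chroms))
  genes <- purrr::map_dfr(chroms, function(chr) {
    k <- per_chrom[[chr]]
    if (k == 0) return(tibble())
    widths <- sample(seq(config$gene_length_range[1],
                         config$gene_length_range[2]), k, replace = TRUE)
    starts <- place_nonoverlapping(config$chromosome_length_bp, widths,
                                   min_gap = 200L)
    tibble(chromosome = chr, start = starts, end = starts + widths,
           strand = sample(c("+", "-"), k, replace = TRUE))
  }) |>
    mutate(gene_id = sprintf("gene_%03d", row_number())) |>
    select("gene_id", "chromosome", "start", "end", "strand")

  exon_bp <- 600L
  utr_bp <- 200L
  exons <- bind_rows(
    mutate(genes, end = .data$start + exon_bp, exon_number = 1L),
    mutate(genes, start = .data$end - exon_bp, exon_number = 2L)
  ) |>
    select("gene_id", "chromosome", "start", "end", "strand", "exon_number") |>
    arrange(.data$gene_id, .data$start)
  left_end <- function(g) tibble(gene_id = g$gene_id,
                                 chromosome = g$chromosome,
                                 start = g$start, end = g$start + utr_bp,
                                 strand = g$strand)
  right_end <- function(g) tibble(gene_id = g$gene_id,
                                  chromosome = g$chromosome,
                                  start = g$end - utr_bp, end = g$end,
                                  strand = g$strand)
  plus <- genes$strand == "+"
  utr5 <- bind_rows(left_end(genes[plus, ]), right_end(genes[!plus, ]))
  utr3 <- bind_rows(right_end(genes[plus, ]), left_end(genes[!plus, ]))
  gene_model <- structure(
    list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3),
    class = "gene_model"
  )
  list(genome = genome, gene_model = gene_model)
}

#' Plant enhancers and motif instances into a genome
#'
#' Assigns each enhancer a true log2 activity uniform over the configured
#' range, draws its accessibility flag, places accessible enhancers
#' preferentially near TSSs (`tss_proximal_fraction_accessible` of them
#' centered within +/- 500 bp of a TSS) and masked enhancers away from
#' promoters, and mutates the genome sequence so that each enhancer contains
#' `floor((a - a_min)/(a_max - a_min) * max_yy1_motifs)` YY1 consensus
#' instances (plus 0-2 ETS instances), each embedded on a random strand.
#'
#' @param sim Output of [simulate_genome()].
#' @param config The same [sim_config()].
#' @return List with the modified `genome`, the `truth` tibble (one row per
#'   planted enhancer), and the `pwms` used for planting.
#' @export
plant_enhancers <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  pwms <- builtin_motifs()
  enh_len <- config$enhancer_length_bp
  if (max(vapply(pwms, function(p) p$width, 1L)) > enh_len) {
    abort("Motif longer than enhancer (design error)")
  }
  n <- config$n_enhancers
  rng <- config$activity_log2_range
  if (n == 0) {
    truth <- tibble(enhancer_id = character(), chromosome = character(),
                    start = integer(), end = integer(),
                    true_log2_activity = numeric(),
                    n_yy1_motifs = integer(), n_ets_motifs = integer(),
                    accessible = logical(), tss_proximal = logical(),
                    nearest_gene_id = character(),
                    tissue_class = character())
    return(list(genome = sim$genome, truth = truth, pwms = pwms))
  }
  activity <- runif(n, rng[1], rng[2])
  accessible <- runif(n) < config$accessible_fraction
  genes <- sim$gene_model$genes
  sizes <- chrom_sizes(sim$genome)
  gap <- config$min_enhancer_gap_bp

  placed <- tibble(chromosome = character(), start = integer(),
                   end = integer())
  conflicts <- function(chr, s, e, extra = NULL) {
    ref <- bind_rows(placed, extra)
    any(ref$chromosome == chr & s < ref$end + gap & e > ref$start - gap)
  }
  tss_tbl <- tibble(chromosome = genes$chromosome, pos = gene_tss(genes),
                    gene_id = genes$gene_id)

  # order of placement: TSS-proximal accessible first (anchored on sampled
  # TSSs), then the rest rejection-sampled away from conflicts
  want_proximal <- accessible &
    runif(n) < config$tss_proximal_fraction_accessible
  idx_order <- order(!want_proximal)
  rows <- vector("list", n)
  avoid_promoters <- tibble(
    chromosome = tss_tbl$chromosome,
    start = pmax(tss_tbl$pos - 1000L, 0L),
    end = tss_tbl$pos + 1000L
  )
  for (i in idx_order) {
    ok <- FALSE
    for (attempt in seq_len(500)) {
      if (want_proximal[i]) {
        j <- sample.int(nrow(tss_tbl), 1)
        center <- tss_tbl$pos[j] + sample.int(1001L, 1) - 501L
        chr <- tss_tbl$chromosome[j]
        s <- center - enh_len %/% 2
      } else {
        chr <- sample(config$enhancer_chromosomes, 1)
        s <- sample.int(sizes[[chr]] - enh_len, 1) - 1L
      }
      e <- s + enh_len
      if (s < 0 || e > sizes[[chr]]) next
      if (conflicts(chr, s, e)) next
      # masked enhancers stay out of promoter windows (intergenic/intronic)
      if (!accessible[i] &&
          any(avoid_promoters$chromosome == chr &
              s < avoid_promoters$end & e > avoid_promoters$start)) next
      rows[[i]] <- tibble(chromosome = chr, start = as.integer(s),
                          end = as.integer(e))
      placed <- bind_rows(placed, rows[[i]])
      ok <- TRUE
      break
    }
    if (!ok) {
      abort(paste0("Could not place enhancer ", i,
                   "; genome too small for the requested design"))
    }
  }
  truth <- bind_rows(rows) |>
    mutate(
      enhancer_id = sprintf("enh_%03d", row_number()),
      true_log2_activity = activity,
      accessible = accessible,
      tss_proximal = want_proximal,
      n_yy1_motifs = as.integer(floor(
        (activity - rng[1]) / (rng[2] - rng[1]) * config$max_yy1_motifs)),
      n_ets_motifs = rbinom(n, 2, 0.5)
    )

  # embed motif instances by rewriting genome sequence inside each enhancer
  genome <- sim$genome
  yy1_word <- pwm_consensus(pwms$YY1)
  ets_word <- pwm_consensus(pwms$ETS)
  for (i in seq_len(nrow(truth))) {
    words <- c(rep(yy1_word, truth$n_yy1_motifs[i]),
               rep(ets_word, truth$n_ets_motifs[i]))
    if (length(words) == 0) next
    flip <- runif(length(words)) < 0.5
    words[flip] <- revcomp(words[flip])
    offsets <- place_nonoverlapping(enh_len, nchar(words), min_gap = 5L)
    at <- IRanges::IRanges(truth$start[i] + offsets + 1L,
                           width = nchar(words))
    chr <- truth$chromosome[i]
    genome[[chr]] <- Biostrings::replaceAt(
      genome[[chr]], at, Biostrings::DNAStringSet(words))
  }

  # nearest gene and tissue class of that gene
  ann <- annotate_genomic_feature(
    mutate(truth, summit = (.data$start + .data$end) %/% 2),
    sim$gene_model
  )
  truth$nearest_gene_id <- ann$nearest_gene_id
  follow <- runif(n) < config$tissue_purity
  truth$tissue_class <- ifelse(
    xor(truth$accessible, !follow), "ubiquitous", "tissue_specific")
  truth <- select(truth, "enhancer_id", "chromosome", "start", "end",
                  "true_log2_activity", "n_yy1_motifs", "n_ets_motifs",
                  "accessible", "tss_proximal", "nearest_gene_id",
                  "tissue_class")
  list(genome = genome, truth = truth, pwms = pwms)
}

#' Simulate input and RNA fragment libraries
#'
#' Input fragments start uniformly over the genome with normal lengths
#' (clipped to \[100, 1500\] bp). The RNA library is drawn from the input
#' fragment distribution reweighted so that a candidate fragment overlapping
#' a planted enhancer (by at least `rna_weight_min_overlap_bp`) carries
#' relative weight `2^true_log2_activity`, via importance resampling from a
#' dense candidate pool. Library sizes match the configuration exactly.
#'
#' @param genome The (planted) genome.
#' @param truth Truth tibble from [plant_enhancers()] (may have zero rows).
#' @param config The [sim_config()].
#' @param replicate Replicate index; offsets the seed so replicates differ.
#' @param pool_factor RNA candidate-pool size as a multiple of the RNA
#'   library size.
#' @return List with `input` and `rna` fragment tibbles
#'   (`chromosome`, `start`, `end`, `replicate`).
#' @export
simulate_fragments <- function(genome, truth, config, replicate = 1L,
                               pool_factor = 8) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 10000L * replicate + 2L)
  sizes <- chrom_sizes(genome)

  draw_pool <- function(n) {
    chr <- sample(names(sizes), n, replace = TRUE,
                  prob = sizes / sum(sizes))
    len <- as.integer(round(pmin(pmax(
      rnorm(n, config$fragment_length_mean_bp,
            config$fragment_length_sd_bp), 100), 1500)))
    maxs <- sizes[chr] - len
    start <- as.integer(floor(runif(n) * pmax(maxs + 1, 1)))
    tibble(chromosome = chr, start = start, end = start + len)
  }

  input <- draw_pool(config$n_input_fragments)
  pool <- draw_pool(ceiling(pool_factor * config$n_rna_fragments))
  w <- rep(1, nrow(pool))
  if (nrow(truth) > 0) {
    hits <- find_overlaps_tbl(pool, truth,
                              minoverlap = config$rna_weight_min_overlap_bp)
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      a <- truth$true_log2_activity[S4Vectors::subjectHits(hits)]
      best <- tapply(a, q, max)
      w[as.integer(names(best))] <- 2^as.numeric(best)
    }
  }
  idx <- sample.int(nrow(pool), config$n_rna_fragments, replace = TRUE,
                    prob = w)
  rna <- pool[idx, ]
  input$replicate <- rna$replicate <- as.integer(replicate)
  list(input = input, rna = rna)
}

#' Simulate chromatin tracks matching the planted truth
#'
#' Accessible enhancers receive an overlapping ATAC peak and H3K27ac peak and
#' an H3K4me1 peak within +/- 3 kb; masked enhancers receive none (optionally
#' a weak H3K9me3 peak). Decoy peaks that do not overlap any enhancer (with a
#' 2.5 kb buffer) model chromatin-predicted-but-inactive regions.
#'
#' @param truth Truth tibble.
#' @param config The [sim_config()].
#' @param sizes Named chromosome lengths.
#' @param decoy_count Number of decoy intervals added per track.
#' @param h3k9me3_prob Probability a masked enhancer gets a weak H3K9me3
#'   peak.
#' @return Named list of interval tibbles: `atac`, `h3k27ac`, `h3k4me1`,
#'   `h3k9me3`.
#' @export
simulate_chromatin <- function(truth, config, sizes, decoy_count = 500L,
                               h3k9me3_prob = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  clip <- function(x) {
    mutate(x, start = pmax(.data$start, 0L),
           end = pmin(.data$end, sizes[.data$chromosome])) |>
      filter(.data$start < .data$end)
  }
  acc <- filter(truth, .data$accessible)
  msk <- filter(truth, !.data$accessible)
  jitter_peak <- function(x, pad_lo = 50L, pad_hi = 200L) {
    if (nrow(x) == 0) return(tibble(chromosome = character(),
                                    start = integer(), end = integer()))
    tibble(chromosome = x$chromosome,
           start = as.integer(x$start - sample(pad_lo:pad_hi, nrow(x), TRUE)),
           end = as.integer(x$end + sample(pad_lo:pad_hi, nrow(x), TRUE)))
  }
  atac <- jitter_peak(acc)
  k27 <- jitter_peak(acc, 100L, 400L)
  k4 <- if (nrow(acc) > 0) {
    off <- sample(-2500:2000, nrow(acc), replace = TRUE)
    tibble(chromosome = acc$chromosome,
           start = as.integer(acc$start + off),
           end = as.integer(acc$start + off + 1000L))
  } else {
    tibble(chromosome = character(), start = integer(), end = integer())
  }
  k9 <- if (nrow(msk) > 0) {
    pick <- runif(nrow(msk)) < h3k9me3_prob
    jitter_peak(msk[pick, ], 200L, 800L)
  } else {
    tibble(chromosome = character(), start = integer(), end = integer())
  }

  decoys <- function(width_lo, width_hi) {
    out <- list()
    got <- 0L
    buffer <- 2500L
    avoid <- if (nrow(truth) > 0) {
      mutate(truth, start = .data$start - buffer, end = .data$end + buffer)
    } else {
      NULL
    }
    while (got < decoy_count) {
      m <- 2L * (decoy_count - got)
      chr <- sample(names(sizes), m, replace = TRUE,
                    prob = sizes / sum(sizes))
      wid <- sample(width_lo:width_hi, m, replace = TRUE)
      s <- as.integer(floor(runif(m) * pmax(sizes[chr] - wid, 1)))
      cand <- tibble(chromosome = chr, start = s, end = s + wid)
      if (!is.null(avoid)) {
        bad <- count_overlaps_tbl(cand, clip(avoid)) > 0
        cand <- cand[!bad, ]
      }
      take <- head(cand, decoy_count - got)
      out[[length(out) + 1]] <- take
      got <- got + nrow(take)
    }
    bind_rows(out)
  }
  list(
    atac = clip(bind_rows(atac, decoys(300L, 800L))),
    h3k27ac = clip(bind_rows(k27, decoys(500L, 1500L))),
    h3k4me1 = clip(bind_rows(k4, decoys(500L, 1500L))),
    h3k9me3 = clip(bind_rows(k9, decoys(1000L, 3000L)))
  )
}

#' Simulate gene expression and tissue-specificity tables
#'
#' Genes nearest to accessible enhancers draw TPM from a log-normal with mean
#' increased in proportion to the enhancer's strength; all other genes draw
#' from the baseline distribution. The tissue lookup labels each
#' enhancer-associated gene according to the truth tissue class (accessible
#' -> ubiquitous, masked -> tissue-specific, at the configured purity).
#'
#' @param truth Truth tibble with `nearest_gene_id`.
#' @param gene_model Gene model from [simulate_genome()].
#' @param config The [sim_config()].
#' @param baseline_meanlog,sdlog Baseline log-normal TPM parameters.
#' @param effect_per_log2 Increase in mean log TPM per log2 of activity above
#'   the activity range minimum (0 disables the effect).
#' @return List with `expression` (`gene_id`, `tpm`) and `tissue_lookup`
#'   (`gene_id`, `category`, using tissue-atlas category names).
#' @export
simulate_expression_and_tissue <- function(truth, gene_model, config,
                                           baseline_meanlog = log(10),
                                           sdlog = 1,
                                           effect_per_log2 = 0.4) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  genes <- gene_model$genes
  meanlog <- rep(baseline_meanlog, nrow(genes))
  acc <- filter(truth, .data$accessible, !is.na(.data$nearest_gene_id))
  if (nrow(acc) > 0) {
    boost <- tapply(
      acc$true_log2_activity - config$activity_log2_range[1],
      acc$nearest_gene_id, max)
    j <- match(names(boost), genes$gene_id)
    meanlog[j] <- meanlog[j] + effect_per_log2 * as.numeric(boost)
  }
  expression <- tibble(gene_id = genes$gene_id,
                       tpm = rlnorm(nrow(genes), meanlog, sdlog))

  specific_cats <- c("tissue enhanced", "tissue enriched", "group enriched")
  category <- ifelse(runif(nrow(genes)) < 0.5, "low tissue specificity",
                     sample(specific_cats, nrow(genes), replace = TRUE))
  near <- filter(truth, !is.na(.data$nearest_gene_id))
  if (nrow(near) > 0) {
    cls <- tapply(near$tissue_class, near$nearest_gene_id,
                  function(x) x[1])
    j <- match(names(cls), genes$gene_id)
    category[j] <- ifelse(cls == "ubiquitous", "low tissue specificity",
                          sample(specific_cats, length(cls), replace = TRUE))
  }
  list(expression = expression,
       tissue_lookup = tibble(gene_id = genes$gene_id, category = category))
}

#' Simulate a complete synthetic STARR-seq experiment
#'
#' Convenience wrapper running [simulate_genome()], [plant_enhancers()],
#' [simulate_fragments()] for each replicate, [simulate_chromatin()] and
#' [simulate_expression_and_tissue()].
#'
#' @param config A [sim_config()].
#' @param chromatin,expression Logical toggles for the auxiliary tracks.
#' @return A `starrseq_sim` list: `genome`, `gene_model`, `truth`, `pwms`,
#'   `libraries` (per replicate, each with `input` and `rna`), `chromatin`,
#'   `expression`, `tissue_lookup`, `config`.
#' @export
simulate_starrseq <- function(config = sim_config(), chromatin = TRUE,
                              expression = TRUE) {
  base <- simulate_genome(config)
  planted <- plant_enhancers(base, config)
  libraries <- purrr::map(seq_len(config$n_replicates), function(r) {
    simulate_fragments(planted$genome, planted$truth, config, replicate = r)
  })
  sizes <- chrom_sizes(planted$genome)
  chrom <- if (chromatin) {
    simulate_chromatin(planted$truth, config, sizes)
  }
  expr <- if (expression) {
    simulate_expression_and_tissue(planted$truth, base$gene_model, config)
  }
  structure(
    list(genome = planted$genome, gene_model = base$gene_model,
         truth = planted$truth, pwms = planted$pwms,
         libraries = libraries, chromatin = chrom,
         expression = expr$expression, tissue_lookup = expr$tissue_lookup,
         config = config),
    class = "starrseq_sim"
  )
}

#' @export
print.starrseq_sim <- function(x, ...) {
  cat("<starrseq_sim> ", length(x$genome), " chromosomes, ",
      nrow(x$truth), " planted enhancers, ",
      length(x$libraries), " replicate library pair(s)\n", sep = "")
  invisible(x)
}
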