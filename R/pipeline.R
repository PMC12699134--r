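# End-to-end orchestration: simulate -> quantify -> callpeaks -> classify ->
# annotate -> motifs -> design, with artifacts, a resolved-config snapshot
# and a manifest (versions, seeds, per-stage record counts, file checksums).

PIPELINE_STAGES <- c("simulate", "quantify", "callpeaks", "classify",
                     "annotate", "motifs", "design")

#' Pipeline configuration
#'
#' Stage toggles and all stage parameters with defaults at the published
#' analysis values (peak p < 1e-5, log2 enrichment >= 2.5, strength
#' thresholds 4.0 / 3.1, H3K4me1 flank 3 kb, motif p < 1e-4, background
#' shift 10 kb, 500/200 bp tiles, 249/100 bp windows). Unknown keys are
#' rejected (the argument list is the schema).
#'
#' @param seed Master seed.
#' @param sim A [sim_config()] for the simulate stage.
#' @param stages Stages to run, in pipeline order.
#' @param p_threshold,log2fc_threshold,enrichment_scale Peak-calling
#'   parameters.
#' @param chrom_whitelist Regular-chromosome whitelist.
#' @param strong_lower_log2,weak_upper_log2 Strength thresholds; set
#'   `auto_thresholds = TRUE` to derive them by changepoint analysis instead.
#' @param auto_thresholds Derive thresholds from the ranked activities.
#' @param h3k4me1_flank_bp Flank for the H3K4me1 annotation.
#' @param motif_p_threshold,shift_bp Motif scan threshold and background
#'   shift.
#' @param tile_bp,tile_overlap_bp,window_bp,window_stride_bp Design-stage
#'   geometry.
#' @param top_n_mutagenesis,min_yy1_hits Mutagenesis candidate selection.
#' @param n_background_windows Background windows in the window dataset.
#' @param write_fragments Write the (large) fragment BED files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            stages = PIPELINE_STAGES,
                            p_threshold = 1e-5,
                            log2fc_threshold = 2.5,
                            enrichment_scale = "log2",
                            chrom_whitelist = sim$enhancer_chromosomes,
                            strong_lower_log2 = 4.0,
                            weak_upper_log2 = 3.1,
                            auto_thresholds = FALSE,
                            h3k4me1_flank_bp = 3000L,
                            motif_p_threshold = 1e-4,
                            shift_bp = 10000L,
                            tile_bp = 500L,
                            tile_overlap_bp = 200L,
                            window_bp = 249L,
                            window_stride_bp = 100L,
                            top_n_mutagenesis = 50L,
                            min_yy1_hits = 2L,
                            n_background_windows = 0L,
                            write_fragments = FALSE) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0) {
    abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the STARR-seq analysis pipeline
#'
#' Executes the enabled stages in order on a simulated experiment, writing
#' stage artifacts, a resolved-config snapshot (`config.json`) and a
#' manifest (`manifest.json`) into `outdir`. Later stages require their
#' upstream stage to be enabled and fail with an error naming it otherwise.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_starrseq_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  need <- function(stage, for_stage) {
    if (!stage %in% stages) {
      abort(paste0("Stage '", for_stage, "' requires stage '", stage,
                   "' to be enabled; run it first"))
    }
  }
  manifest <- list(package_version = as.character(utils::packageVersion("starrmap")),
                   seed = config$seed, stages = list())
  written <- character(0)
  emit <- function(x, name) {
    path <- file.path(outdir, name)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  record <- function(stage, counts) {
    manifest$stages[[stage]] <<- counts
  }
  snap <- rapply(unclass(config), function(x) x, how = "replace")
  snap$sim <- unclass(snap$sim)
  jsonlite::write_json(snap, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  written <- c(written, file.path(outdir, "config.json"))

  sim <- peaks <- classified <- NULL
  if ("simulate" %in% stages) {
    sim <- simulate_starrseq(config$sim)
    fa <- file.path(outdir, "genome.fa")
    write_genome_fasta(sim$genome, fa)
    gtf <- file.path(outdir, "genes.gtf")
    write_gene_model_gtf(sim$gene_model, gtf)
    written <- c(written, fa, gtf)
    emit(sim$truth, "truth.tsv")
    emit(sim$expression, "expression.tsv")
    emit(sim$tissue_lookup, "tissue_lookup.tsv")
    for (track in names(sim$chromatin)) {
      p <- file.path(outdir, paste0(track, ".bed"))
      write_bed(sim$chromatin[[track]], p)
      written <- c(written, p)
    }
    if (config$write_fragments) {
      for (r in seq_along(sim$libraries)) {
        for (role in c("input", "rna")) {
          p <- file.path(outdir, sprintf("%s_rep%d.bed", role, r))
          write_bed(sim$libraries[[r]][[role]], p)
          written <- c(written, p)
        }
      }
    }
    record("simulate", list(chromosomes = length(sim$genome),
                            enhancers = nrow(sim$truth),
                            replicates = length(sim$libraries)))
  }
  sizes <- chrom_sizes(sim$genome)
  input_all <- bind_rows(purrr::map(sim$libraries, "input"))
  rna_all <- bind_rows(purrr::map(sim$libraries, "rna"))

  if ("quantify" %in% stages) {
    need("simulate", "quantify")
    rc <- if (length(sim$libraries) >= 2) {
      replicate_correlation(sim$libraries[[1]]$rna, sim$libraries[[2]]$rna,
                            sizes)
    } else {
      tibble(r_squared = NA_real_, n_windows = NA_integer_)
    }
    emit(rc, "replicate_correlation.tsv")
    record("quantify", list(replicate_r_squared = rc$r_squared,
                            input_fragments = nrow(input_all),
                            rna_fragments = nrow(rna_all)))
  }
  if ("callpeaks" %in% stages) {
    need("quantify", "callpeaks")
    ws <- scan_windows(input_all, rna_all, sizes)
    peaks <- call_peaks(ws, p_threshold = config$p_threshold,
                        log2fc_threshold = config$log2fc_threshold,
                        chrom_whitelist = config$chrom_whitelist,
                        enrichment_scale = config$enrichment_scale)
    emit(peaks, "peaks.tsv")
    np <- file.path(outdir, "peaks.narrowPeak")
    write_narrowpeak(peaks, np)
    written <- c(written, np)
    record("callpeaks", list(windows_tested = sum(!ws$low_input),
                             peaks = nrow(peaks)))
  }
  if ("classify" %in% stages) {
    need("callpeaks", "classify")
    thr <- if (config$auto_thresholds) {
      derive_thresholds(peaks$log2_enrichment)
    } else {
      strength_thresholds(config$strong_lower_log2, config$weak_upper_log2)
    }
    classified <- mutate(peaks,
                         strength = classify_strength(.data$log2_enrichment,
                                                      thr))
    emit(classified, "peaks_classified.tsv")
    record("classify", as.list(table(classified$strength)))
  }
  if ("annotate" %in% stages) {
    need("classify", "annotate")
    ann <- classified |>
      annotate_accessibility(sim$chromatin$atac) |>
      annotate_histone(sim$chromatin$h3k27ac, 0L, "h3k27ac") |>
      annotate_histone(sim$chromatin$h3k4me1, config$h3k4me1_flank_bp,
                       "h3k4me1") |>
      annotate_histone(sim$chromatin$h3k9me3, 0L, "h3k9me3") |>
      annotate_genomic_feature(sim$gene_model)
    ann$tissue_class <- classify_tissue(ann$nearest_gene_id,
                                        sim$tissue_lookup)
    classified <- ann
    emit(ann, "peaks_annotated.tsv")
    groups <- ann |>
      filter(!is.na(.data$nearest_gene_id)) |>
      mutate(group = ifelse(.data$accessible, "accessible", "masked")) |>
      select(gene_id = "nearest_gene_id", "group") |>
      dplyr::distinct(.data$gene_id, .keep_all = TRUE)
    if (length(unique(groups$group)) >= 2) {
      cmp <- expression_by_group(sim$expression, groups)
      emit(tidy(cmp), "expression_by_group.tsv")
      record("annotate", list(peaks = nrow(ann),
                              accessible = sum(ann$accessible),
                              expression_anova_p = cmp$anova_p))
    } else {
      record("annotate", list(peaks = nrow(ann),
                              accessible = sum(ann$accessible)))
    }
  }
  if ("motifs" %in% stages) {
    need("annotate", "motifs")
    pwms <- sim$pwms
    bg <- shift_background(classified, sizes, shift_bp = config$shift_bp,
                           avoid = classified, input_frags = input_all)
    target_seqs <- stats::setNames(
      interval_sequences(sim$genome, classified), classified$peak_id)
    bg_seqs <- stats::setNames(interval_sequences(sim$genome, bg),
                               bg$source_id)
    enr <- motif_enrichment(target_seqs, bg_seqs, pwms,
                            p_threshold = config$motif_p_threshold)
    emit(enr, "motif_enrichment.tsv")
    yy1_hits <- scan_pwm(target_seqs, pwms$YY1,
                         p_threshold = config$motif_p_threshold)
    dosage <- yy1_dosage(
      dplyr::rename(classified, enhancer_id = "peak_id",
                    activity_log2 = "log2_enrichment"),
      yy1_hits, motif_width = pwms$YY1$width)
    emit(tidy(dosage), "yy1_dosage.tsv")
    designs <- select_mutagenesis_candidates(
      classified, sim$genome, pwms$YY1, top_n = config$top_n_mutagenesis,
      min_hits = config$min_yy1_hits,
      p_threshold = config$motif_p_threshold)
    emit(designs, "yy1_mutagenesis.tsv")
    record("motifs", list(background_regions = nrow(bg),
                          yy1_hits = nrow(yy1_hits),
                          mutagenesis_candidates = nrow(designs)))
  }
  if ("design" %in% stages) {
    need("callpeaks", "design")
    top <- head(arrange(classified %||% peaks,
                        dplyr::desc(.data$log2_enrichment)), 50)
    tiles <- tile_peak(top, sizes, genome = sim$genome,
                       tile_bp = config$tile_bp,
                       overlap_bp = config$tile_overlap_bp)
    tiles$synthesis_sequence <- add_cloning_arms(tiles$sequence)
    emit(tiles, "tiles.tsv")
    wd <- prepare_window_dataset(peaks, sim$genome, input_all, rna_all,
                                 window_bp = config$window_bp,
                                 stride_bp = config$window_stride_bp,
                                 n_background = config$n_background_windows,
                                 seed = config$seed)
    emit(wd, "window_dataset.tsv")
    record("design", list(tiles = nrow(tiles), windows = nrow(wd)))
  }
  manifest$files <- lapply(stats::setNames(written, basename(written)),
                           function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
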