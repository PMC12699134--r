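#' Read genomic intervals from a BED file
#'
#' @param path Path to a BED3+ file.
#' @return A tibble with `chromosome`, `start`, `end` (0-based half-open) and,
#'   when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- gr_to_tbl(gr)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(md) > 0) out <- dplyr::bind_cols(out, as_tibble(md))
  st <- as.character(BiocGenerics::strand(gr))
  if (!all(st == "*")) out$strand <- st
  out
}

#' Write genomic intervals to a BED file
#'
#' @param x Interval tibble (0-based half-open); optional `name`, `score`,
#'   `strand` columns are carried into the BED fields.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  gr <- as_gr(x)
  if ("name" %in% names(x)) gr$name <- x$name
  if ("score" %in% names(x)) gr$score <- x$score
  if ("strand" %in% names(x)) BiocGenerics::strand(gr) <- x$strand
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a genome to FASTA
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA path.
#' @return Named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a gene model to GTF
#'
#' Emits gene, exon and UTR records (1-based inclusive coordinates, as GTF
#' requires; the in-memory representation stays 0-based half-open).
#'
#' @param gene_model A gene model as produced by [simulate_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gtf <- function(gene_model, path) {
  stopifnot(inherits(gene_model, "gene_model"))
  feat <- function(tb, type) {
    if (is.null(tb) || nrow(tb) == 0) return(NULL)
    gr <- as_gr(tb)
    BiocGenerics::strand(gr) <- tb$strand %||% "*"
    gr$type <- type
    gr$gene_id <- tb$gene_id
    gr$source <- "starrmap"
    gr
  }
  pieces <- list(
    feat(gene_model$genes, "gene"),
    feat(gene_model$exons, "exon"),
    feat(gene_model$utr5, "five_prime_utr"),
    feat(gene_model$utr3, "three_prime_utr")
  )
  gr <- do.call(c, pieces[!vapply(pieces, is.null, logical(1))])
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read PWMs from a MEME-format motif file
#'
#' Parses minimal MEME text format: the `MOTIF` header lines and their
#' `letter-probability matrix` blocks, plus the optional
#' `Background letter frequencies` line.
#'
#' @param path Path to a MEME-format file.
#' @return A named list of [pwm_model] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1 && bg_at < length(lines)) {
    toks <- strsplit(trimws(lines[bg_at + 1]), "\\s+")[[1]]
    if (length(toks) >= 8) {
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      names(vals) <- toupper(toks[seq(1, 7, by = 2)])
      background <- vals[c("A", "C", "G", "T")]
    }
  }
  motif_at <- grep("^MOTIF\\s", lines)
  if (length(motif_at) == 0) abort("No MOTIF records found in MEME file")
  out <- list()
  for (i in motif_at) {
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines[seq(i, length(lines))])[1]
    if (is.na(hdr)) abort(paste0("Motif ", id, " has no probability matrix"))
    hdr <- i + hdr - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[seq(hdr + 1, hdr + w)]
    mat <- t(vapply(strsplit(trimws(rows), "\\s+"),
                    function(x) as.numeric(x[1:4]), numeric(4)))
    probs <- t(mat)  # 4 x w, rows A C G T
    rownames(probs) <- c("A", "C", "G", "T")
    out[[id]] <- pwm_model(probs, motif_id = id, background = background)
  }
  out
}

#' Write PWMs to a MEME-format motif file
#'
#' @param pwms A list of [pwm_model] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm_model")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg["A"], bg["C"], bg["G"], bg["T"]),
    ""
  ), con)
  for (pwm in pwms) {
    writeLines(sprintf("MOTIF %s", pwm$motif_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      pwm$width), con)
    apply(pwm$probs, 2, function(col) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         col[1], col[2], col[3], col[4]), con)
    })
    writeLines("", con)
  }
  invisible(path)
}
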