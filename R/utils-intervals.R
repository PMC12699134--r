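# Genomic intervals travel through the package as tibbles with columns
# chromosome / start / end in BED convention (0-based, half-open). GRanges
# (1-based, closed) is used internally for overlap machinery; these two
# helpers are the only place the conversion happens.

#' Convert an interval tibble to GRanges
#'
#' @param x A data frame with columns `chromosome`, `start`, `end`
#'   (0-based half-open coordinates).
#' @param seqlengths Optional named vector of chromosome lengths.
#' @return A [GenomicRanges::GRanges] object (1-based closed internally).
#' @keywords internal
#' @noRd
as_gr <- function(x, seqlengths = NULL) {
  validate_intervals(x)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(x$chromosome),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  if (!is.null(seqlengths)) {
    bad <- setdiff(unique(as.character(x$chromosome)), names(seqlengths))
    if (length(bad) > 0) {
      abort(paste0("Intervals on unknown chromosome(s): ",
                   paste(bad, collapse = ", ")))
    }
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

# build GRanges for two interval tables on a shared seqlevel set, so overlap
# operations do not warn about disjoint chromosome universes
#' @noRd
paired_grs <- function(a, b) {
  lv <- union(unique(as.character(a$chromosome)),
              unique(as.character(b$chromosome)))
  ga <- as_gr(a)
  gb <- as_gr(b)
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  list(a = ga, b = gb)
}

#' @noRd
count_overlaps_tbl <- function(a, b, ...) {
  p <- paired_grs(a, b)
  GenomicRanges::countOverlaps(p$a, p$b, ...)
}

#' @noRd
find_overlaps_tbl <- function(a, b, ...) {
  p <- paired_grs(a, b)
  GenomicRanges::findOverlaps(p$a, p$b, ...)
}

#' @noRd
gr_to_tbl <- function(gr) {
  tibble(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' @noRd
validate_intervals <- function(x, arg = deparse(substitute(x))) {
  req <- c("chromosome", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    abort(paste0("`", arg, "` must have columns ",
                 paste(req, collapse = ", "), "; missing: ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0 && any(x$start >= x$end)) {
    abort(paste0("`", arg, "` has intervals with start >= end ",
                 "(coordinates are 0-based half-open)"))
  }
  invisible(x)
}

#' Chromosome sizes of a genome
#'
#' @param genome A named [Biostrings::DNAStringSet] (or named character vector
#'   of sequences).
#' @return A named integer vector of sequence lengths.
#' @export
chrom_sizes <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Partition chromosomes into fixed-width bins
#'
#' @param sizes Named vector of chromosome lengths.
#' @param bin_bp Bin width in bp; the trailing partial bin is kept.
#' @return Tibble of 0-based half-open bins.
#' @export
genome_bins <- function(sizes, bin_bp = 500L) {
  stopifnot(bin_bp > 0)
  purrr::map_dfr(names(sizes), function(chr) {
    len <- sizes[[chr]]
    starts <- seq(0L, len - 1L, by = bin_bp)
    tibble(chromosome = chr, start = starts,
           end = pmin(starts + bin_bp, len))
  })
}

#' Sliding windows over chromosomes
#'
#' @param sizes Named vector of chromosome lengths.
#' @param window_bp,stride_bp Window width and stride in bp. Windows that
#'   would extend past the chromosome end are dropped; chromosomes shorter
#'   than one window yield no windows.
#' @return Tibble of 0-based half-open windows.
#' @export
genome_windows <- function(sizes, window_bp = 500L, stride_bp = 100L) {
  stopifnot(window_bp > 0, stride_bp > 0)
  purrr::map_dfr(names(sizes), function(chr) {
    len <- sizes[[chr]]
    if (len < window_bp) return(tibble())
    starts <- seq(0L, len - window_bp, by = stride_bp)
    tibble(chromosome = chr, start = starts, end = starts + window_bp)
  })
}

#' Extract sequences for an interval tibble
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param x Interval tibble (0-based half-open).
#' @return Character vector of sequences, one per row of `x`.
#' @export
interval_sequences <- function(genome, x) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  sizes <- chrom_sizes(genome)
  validate_intervals(x)
  if (nrow(x) == 0) return(character(0))
  bad <- setdiff(unique(x$chromosome), names(sizes))
  if (length(bad) > 0) {
    abort(paste0("Unknown chromosome(s): ", paste(bad, collapse = ", ")))
  }
  out <- character(nrow(x))
  for (chr in unique(x$chromosome)) {
    i <- which(x$chromosome == chr)
    if (any(x$end[i] > sizes[[chr]]) || any(x$start[i] < 0)) {
      abort(paste0("Interval outside chromosome ", chr))
    }
    out[i] <- as.character(Biostrings::extractAt(
      genome[[chr]], IRanges::IRanges(x$start[i] + 1L, x$end[i])
    ))
  }
  out
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
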