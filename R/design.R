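# Screen-design utilities: summit-centered tiling of peaks into overlapping
# fragments for targeted STARR-seq, sequence/activity window datasets for
# training sequence-to-activity models, and assembly of synthesis-ready
# inserts with adapters and vector homology arms.

#' Tile peaks around their summits
#'
#' Fragments each peak into `tile_bp` tiles centered on the summit with
#' `overlap_bp` overlap between adjacent tiles: the summit tile spans
#' `[summit - tile_bp/2, summit + tile_bp/2)` and flanking tiles are offset
#' by `tile_bp - overlap_bp` up to `n_flank` on each side. Tiles extending
#' past a chromosome end are dropped with a warning.
#'
#' @param peaks Peak tibble with `peak_id`, `chromosome`, `summit`.
#' @param sizes Named chromosome lengths.
#' @param genome Optional genome ([Biostrings::DNAStringSet]); when given, a
#'   `sequence` column is added.
#' @param tile_bp,overlap_bp Tile length and inter-tile overlap (defaults
#'   500 / 200); `tile_bp` must exceed `overlap_bp`.
#' @param n_flank Number of flanking tiles on each side (default 3).
#' @return Tibble with `peak_id`, `label` (-n_flank .. "summit" .. +n_flank),
#'   `chromosome`, `start`, `end` (and `sequence`).
#' @export
tile_peak <- function(peaks, sizes, genome = NULL, tile_bp = 500L,
                      overlap_bp = 200L, n_flank = 3L) {
  if (tile_bp <= overlap_bp) abort("`tile_bp` must be greater than `overlap_bp`")
  stopifnot(all(c("peak_id", "chromosome", "summit") %in% names(peaks)))
  stride <- tile_bp - overlap_bp
  offsets <- seq(-n_flank, n_flank)
  tiles <- tidyr::crossing(as_tibble(peaks)[c("peak_id", "chromosome",
                                              "summit")],
                           offset = offsets) |>
    mutate(
      start = as.integer(.data$summit - tile_bp %/% 2 +
                           .data$offset * stride),
      end = .data$start + as.integer(tile_bp),
      label = ifelse(.data$offset == 0, "summit",
                     sprintf("%+d", .data$offset))
    )
  in_bounds <- tiles$start >= 0 & tiles$end <= sizes[tiles$chromosome]
  if (any(!in_bounds)) {
    warn(sprintf("%d tile(s) extend past a chromosome end and were dropped",
                 sum(!in_bounds)))
  }
  tiles <- tiles[in_bounds, ] |>
    select("peak_id", "label", "offset", "chromosome", "start", "end") |>
    arrange(.data$peak_id, .data$offset)
  if (!is.null(genome)) tiles$sequence <- interval_sequences(genome, tiles)
  tiles
}

#' Prepare a sequence/activity window dataset
#'
#' Bins each peak into `window_bp` windows centered on the summit with a
#' `stride_bp` stride: the central window spans
#' `[summit - 124, summit + 125)` for the default 249 bp (odd lengths place
#' the extra base downstream), plus `flank_windows` windows on each side.
#' Per-window activity is the fold change between RNA and input fragment
#' counts overlapping the window (with the standard pseudocount when a count
#' is zero), scaled by the library-size ratio. Optional background windows
#' are drawn uniformly from regions at least 1 kb from any peak. Windows are
#' split into train/validation/test groups; all windows of one peak stay in
#' the same split.
#'
#' @param peaks Peak tibble with `peak_id`, `chromosome`, `summit`.
#' @param genome Genome ([Biostrings::DNAStringSet]).
#' @param input_frags,rna_frags Fragment tibbles.
#' @param window_bp,stride_bp Window length and stride (defaults 249 / 100).
#' @param flank_windows Windows on each side of the central one (default 3).
#' @param split Proportions for train/validation/test (sums to 1).
#' @param n_background Number of background windows (split like peaks, one
#'   pseudo-peak each).
#' @param seed Seed controlling the split and background sampling.
#' @return Tibble with `peak_id`, `offset_index` (-flank..flank, NA for
#'   background), `chromosome`, `start`, `end`, `sequence`,
#'   `activity_log2`, `split`.
#' @export
prepare_window_dataset <- function(peaks, genome, input_frags, rna_frags,
                                   window_bp = 249L, stride_bp = 100L,
                                   flank_windows = 3L,
                                   split = c(0.8, 0.1, 0.1),
                                   n_background = 0L, seed = 1L) {
  stopifnot(all(c("peak_id", "chromosome", "summit") %in% names(peaks)),
            abs(sum(split) - 1) < 1e-9, length(split) == 3)
  set.seed(seed)
  sizes <- chrom_sizes(genome)
  half_lo <- (window_bp - 1L) %/% 2L      # 124 for 249: extra base downstream
  windows <- tidyr::crossing(
    as_tibble(peaks)[c("peak_id", "chromosome", "summit")],
    offset_index = seq(-flank_windows, flank_windows)
  ) |>
    mutate(start = as.integer(.data$summit - half_lo +
                                .data$offset_index * stride_bp),
           end = .data$start + as.integer(window_bp)) |>
    select("peak_id", "offset_index", "chromosome", "start", "end")
  oob <- windows$start < 0 | windows$end > sizes[windows$chromosome]
  if (any(oob)) {
    warn(sprintf("%d window(s) near chromosome edges dropped", sum(oob)))
    windows <- windows[!oob, ]
  }
  if (n_background > 0) {
    avoid <- mutate(as_tibble(peaks),
                    start = pmax(.data$start - 1000L, 0L),
                    end = .data$end + 1000L)
    bg <- list()
    got <- 0L
    while (got < n_background) {
      m <- 2L * (n_background - got)
      chr <- sample(names(sizes), m, replace = TRUE, prob = sizes / sum(sizes))
      s <- as.integer(floor(runif(m) * pmax(sizes[chr] - window_bp, 1)))
      cand <- tibble(chromosome = chr, start = s,
                     end = s + as.integer(window_bp))
      bad <- count_overlaps_tbl(cand, avoid) > 0
      take <- head(cand[!bad, ], n_background - got)
      bg[[length(bg) + 1]] <- take
      got <- got + nrow(take)
    }
    bg <- bind_rows(bg) |>
      mutate(peak_id = sprintf("background_%05d", row_number()),
             offset_index = NA_integer_) |>
      select("peak_id", "offset_index", "chromosome", "start", "end")
    windows <- bind_rows(windows, bg)
  }
  k_in <- count_fragments(input_frags, windows,
                          chromosomes = names(sizes))$count
  k_rna <- count_fragments(rna_frags, windows,
                           chromosomes = names(sizes))$count
  pc <- ifelse(k_in == 0 | k_rna == 0, 0.5, 0)
  fc <- ((k_rna + pc) / nrow(rna_frags)) / ((k_in + pc) / nrow(input_frags))
  windows$sequence <- interval_sequences(genome, windows)
  windows$activity_log2 <- log2(fc)
  ids <- unique(windows$peak_id)
  shuffled <- sample(ids)
  n_train <- round(length(ids) * split[1])
  n_val <- round(length(ids) * split[2])
  assignment <- stats::setNames(
    rep(c("train", "validation", "test"),
        c(n_train, n_val, length(ids) - n_train - n_val)),
    shuffled)
  windows$split <- unname(assignment[windows$peak_id])
  windows
}

# Fixed assembly sequences for synthesis-ready STARR-seq inserts
INSERT_5_HOMOLOGY_ARM <- "TAGAGCATGCACCGG"
INSERT_5_ADAPTER <- "ACACTCTTTCCCTACACGACGCTCTTCCGATCT"
INSERT_3_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
INSERT_3_HOMOLOGY_ARM <- "TCGACGAATTCGGCC"

#' Assemble a synthesis-ready insert
#'
#' Wraps an insert with the fixed flanking adapters and screening-vector
#' homology arms, in order: 5' homology arm, 5' adapter, insert, 3' adapter,
#' 3' homology arm.
#'
#' @param insert_sequence Character vector of inserts over A/C/G/T.
#' @return Character vector of synthesis-ready sequences.
#' @export
add_cloning_arms <- function(insert_sequence) {
  if (any(!nzchar(insert_sequence))) abort("Insert sequence must be nonempty")
  if (any(grepl("[^ACGT]", insert_sequence))) {
    abort("Insert must contain only A, C, G, T")
  }
  paste0(INSERT_5_HOMOLOGY_ARM, INSERT_5_ADAPTER, insert_sequence,
         INSERT_3_ADAPTER, INSERT_3_HOMOLOGY_ARM)
}
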