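#' Position weight matrix model
#'
#' Builds a PWM object carrying the probability matrix, the background base
#' frequencies, and a log-odds scoring matrix discretized to an integer grid.
#' Scores are log2 odds of the (pseudocount-regularized) motif model against a
#' 0-order background. Discretizing the scores makes the null score
#' distribution exactly computable by dynamic programming, so scan p-values
#' are exact for the discretized matrix rather than approximations.
#'
#' @param probs 4 x width numeric matrix of per-position base probabilities;
#'   rows A, C, G, T; columns must sum to 1 (tolerance 1e-9).
#' @param motif_id Motif identifier.
#' @param background Named base frequencies (A, C, G, T); default uniform.
#' @param pseudocount Fraction of background mixed into each column before
#'   taking log-odds, keeping scores finite for zero entries.
#' @param resolution Log-odds discretization step (log2 units).
#' @return An object of class `pwm_model`.
#' @export
pwm_model <- function(probs, motif_id = "motif",
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      pseudocount = 0.01, resolution = 1e-3) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) abort("`probs` must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 4) abort("PWM width must be >= 4")
  csums <- colSums(probs)
  if (any(abs(csums - 1) > 1e-9)) {
    abort("PWM columns must each sum to 1 (tolerance 1e-9)")
  }
  rownames(probs) <- c("A", "C", "G", "T")
  background <- background[c("A", "C", "G", "T")]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-6) {
    abort("`background` must be named frequencies for A, C, G, T summing to 1")
  }
  reg <- (probs + pseudocount * background) / (1 + pseudocount)
  log_odds <- log2(reg / background)
  structure(
    list(
      motif_id = motif_id,
      width = ncol(probs),
      probs = probs,
      background = background,
      pseudocount = pseudocount,
      resolution = resolution,
      log_odds = log_odds,
      int_scores = round(log_odds / resolution)
    ),
    class = "pwm_model"
  )
}

#' @export
print.pwm_model <- function(x, ...) {
  cat("<pwm_model> ", x$motif_id, " (width ", x$width,
      ", consensus ", pwm_consensus(x), ")\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' @param pwm A [pwm_model].
#' @return Character scalar: the highest-probability base at each position.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$probs)[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#'
#' @param pwm A [pwm_model].
#' @return A `pwm_model` scoring the opposite strand.
#' @export
pwm_reverse_complement <- function(pwm) {
  rc <- pwm$probs[c("T", "G", "C", "A"), rev(seq_len(pwm$width)), drop = FALSE]
  rownames(rc) <- c("A", "C", "G", "T")
  # background of the opposite strand: complement frequencies
  bg <- pwm$background[c("T", "G", "C", "A")]
  names(bg) <- c("A", "C", "G", "T")
  pwm_model(rc, motif_id = pwm$motif_id, background = bg,
            pseudocount = pwm$pseudocount, resolution = pwm$resolution)
}

#' Exact null score distribution of a PWM
#'
#' Computes the probability distribution of the integer-discretized log-odds
#' score of a random background word by dynamic programming (convolution over
#' matrix columns).
#'
#' @param pwm A [pwm_model].
#' @return A list with integer `min_score`, numeric vector `prob` (density
#'   over the dense score grid `min_score ... min_score + length(prob) - 1`),
#'   and `p_value` (upper-tail probability at each grid point).
#' @export
pwm_score_distribution <- function(pwm) {
  int <- pwm$int_scores
  bg <- pwm$background
  lo <- sum(apply(int, 2, min))
  hi <- sum(apply(int, 2, max))
  dens <- numeric(hi - lo + 1)
  # running support [cur_lo, cur_lo + length(cur) - 1]
  cur <- 1
  cur_lo <- 0
  for (j in seq_len(pwm$width)) {
    col <- int[, j]
    new_lo <- cur_lo + min(col)
    new_hi <- cur_lo + length(cur) - 1 + max(col)
    new <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      off <- cur_lo + col[b] - new_lo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + bg[b] * cur
    }
    cur <- new
    cur_lo <- new_lo
  }
  stopifnot(cur_lo == lo, length(cur) == hi - lo + 1)
  list(min_score = lo, prob = cur, p_value = rev(cumsum(rev(cur))))
}

#' @noRd
lookup_pvalue <- function(dist, int_score) {
  idx <- int_score - dist$min_score + 1
  idx <- pmin(pmax(idx, 1L), length(dist$p_value))
  out <- dist$p_value[idx]
  out[int_score > dist$min_score + length(dist$p_value) - 1] <- 0
  out
}

#' @noRd
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
}

#' Scan sequences for PWM matches with exact p-values
#'
#' Slides the PWM over both strands of each sequence, scores every position
#' with the discretized log-odds matrix, and assigns each score an exact
#' p-value from the dynamic-programming null distribution over the 0-order
#' background. Positions whose window contains a non-ACGT character are
#' skipped. When both strands match at the same start, only the better-scoring
#' strand is reported.
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet].
#' @param pwm A [pwm_model].
#' @param p_threshold Report hits with p-value strictly below this (default
#'   1e-4).
#' @return Tibble with `sequence_id`, `start` (0-based, on the given strand's
#'   plus coordinates), `strand`, `score` (log2 odds), `p_value`, `motif_id`.
#'   Sequences shorter than the motif yield no hits.
#' @export
scan_pwm <- function(sequences, pwm, p_threshold = 1e-4) {
  stopifnot(inherits(pwm, "pwm_model"))
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  w <- pwm$width
  fwd <- list(mat = pwm$int_scores, dist = pwm_score_distribution(pwm))
  rcp <- pwm_reverse_complement(pwm)
  rev <- list(mat = rcp$int_scores, dist = pwm_score_distribution(rcp))
  res <- purrr::imap(sequences, function(seq, id) {
    n <- nchar(seq)
    if (n < w) return(NULL)
    code <- encode_dna(seq)
    npos <- n - w + 1
    strand_hits <- purrr::map2(list(fwd, rev), c("+", "-"), function(sc, st) {
      scores <- numeric(npos)
      ok <- rep(TRUE, npos)
      for (j in seq_len(w)) {
        b <- code[seq_len(npos) + j - 1]
        ok <- ok & !is.na(b)
        scores <- scores + ifelse(is.na(b), 0, sc$mat[cbind(b, j)])
      }
      pv <- lookup_pvalue(sc$dist, as.integer(round(scores)))
      keep <- ok & pv < p_threshold
      if (!any(keep)) return(NULL)
      tibble(sequence_id = id, start = which(keep) - 1L, strand = st,
             int_score = as.integer(round(scores[keep])),
             p_value = pv[keep])
    })
    dplyr::bind_rows(strand_hits)
  })
  hits <- dplyr::bind_rows(res)
  if (nrow(hits) == 0) {
    return(tibble(sequence_id = character(), start = integer(),
                  strand = character(), score = numeric(),
                  p_value = numeric(), motif_id = character()))
  }
  hits <- hits |>
    group_by(.data$sequence_id, .data$start) |>
    arrange(dplyr::desc(.data$int_score), .data$strand, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    mutate(score = .data$int_score * pwm$resolution,
           motif_id = pwm$motif_id) |>
    select("sequence_id", "start", "strand", "score", "p_value", "motif_id") |>
    arrange(.data$sequence_id, .data$start)
  hits
}

#' Collapse overlapping motif hits
#'
#' Greedy deduplication: hits on the same sequence for the same motif whose
#' windows overlap are collapsed, keeping the best-scoring hit first.
#'
#' @param hits Hit tibble from [scan_pwm()].
#' @param width Motif width used to delimit the hit windows.
#' @return Filtered hit tibble.
#' @export
dedup_hits <- function(hits, width) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    group_by(.data$sequence_id, .data$motif_id) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(-df$score, df$start), ]
      kept <- integer(0)
      for (i in seq_len(nrow(df))) {
        s <- df$start[i]
        if (!any(abs(df$start[kept] - s) < width)) kept <- c(kept, i)
      }
      df[sort(kept), ]
    }) |>
    ungroup() |>
    arrange(.data$sequence_id, .data$start)
}
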