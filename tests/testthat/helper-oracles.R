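# Independent oracles used across tests: brute-force interval counting,
# exhaustive changepoint segmentation, and full-enumeration PWM null
# distributions. These deliberately avoid the package's own code paths.

# all-pairs overlap counting (0-based half-open, >= 1 bp)
brute_force_counts <- function(fragments, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(fragments$chromosome == regions$chromosome[i] &
          fragments$start < regions$end[i] &
          fragments$end > regions$start[i])
  }, integer(1))
}

# Gaussian mean+variance segment cost, matching the model under test but
# computed directly (no shared code)
oracle_seg_cost <- function(x) {
  m <- length(x)
  v <- max(mean(x^2) - mean(x)^2, 1e-8)
  m * (log(2 * pi) + log(v) + 1)
}

# exhaustive search over all segmentations with <= max_cp changepoints and
# min segment length `minseg`; returns best penalized cost and one optimal
# changepoint set (1-based last-element indices)
oracle_best_segmentation <- function(x, penalty, max_cp = 3, minseg = 2) {
  n <- length(x)
  best_cost <- oracle_seg_cost(x)
  best_cps <- integer(0)
  positions <- seq_len(n - 1)
  for (m in seq_len(max_cp)) {
    combos <- utils::combn(positions, m)
    for (j in seq_len(ncol(combos))) {
      cps <- combos[, j]
      bounds <- c(0, cps, n)
      if (any(diff(bounds) < minseg)) next
      cost <- sum(vapply(seq_len(length(bounds) - 1), function(k) {
        oracle_seg_cost(x[(bounds[k] + 1):bounds[k + 1]])
      }, numeric(1))) + penalty * m
      if (cost < best_cost - 1e-12) {
        best_cost <- cost
        best_cps <- cps
      }
    }
  }
  list(cost = best_cost, cps = best_cps)
}

# penalized cost of a given changepoint set (0-based indices as returned by
# detect_changepoints)
oracle_segmentation_cost <- function(x, cps0, penalty) {
  bounds <- c(0, cps0 + 1, length(x))
  sum(vapply(seq_len(length(bounds) - 1), function(k) {
    oracle_seg_cost(x[(bounds[k] + 1):bounds[k + 1]])
  }, numeric(1))) + penalty * length(cps0)
}

# exhaustive null distribution of the integer PWM score over all 4^w words:
# returns function p(score_int) = P(S >= score_int)
oracle_pwm_tail <- function(pwm) {
  w <- pwm$width
  int <- pwm$int_scores
  bg <- pwm$background
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(words))
  probs <- rep(1, nrow(words))
  for (j in seq_len(w)) {
    scores <- scores + int[cbind(words[, j], j)]
    probs <- probs * bg[words[, j]]
  }
  function(s) sum(probs[scores >= s])
}

random_fragments <- function(n, sizes, len_range = c(50L, 200L)) {
  chr <- sample(names(sizes), n, replace = TRUE)
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(sizes[[chr[i]]] - len[i], 1) - 1L
  }, integer(1))
  tibble::tibble(chromosome = chr, start = start, end = start + len)
}
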