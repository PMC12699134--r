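# Enhancer strength classification: ranked STARR-seq activities are segmented
# by changepoints in mean and variance (Gaussian likelihood); the largest
# changepoint value becomes the lower bound of the "strong" class and the
# smallest the upper bound of the "weak" class.

#' @noRd
seg_cost_fun <- function(values, var_floor = 1e-8) {
  cs <- c(0, cumsum(values))
  cs2 <- c(0, cumsum(values^2))
  # cost of segment values[i..j] (1-based, inclusive): twice the Gaussian
  # negative log-likelihood at the MLE mean/variance
  function(i, j) {
    m <- j - i + 1
    s1 <- cs[j + 1] - cs[i]
    s2 <- cs2[j + 1] - cs2[i]
    v <- pmax((s2 - s1^2 / m) / m, var_floor)
    m * (log(2 * pi) + log(v) + 1)
  }
}

#' Detect changepoints in mean and variance
#'
#' Segments an ordered numeric sequence by minimizing the summed Gaussian
#' (mean and variance) negative log-likelihood plus a per-changepoint penalty.
#' With `max_changepoints = Inf` the penalized optimum is found exactly by
#' PELT (or approximately by binary segmentation); with a finite
#' `max_changepoints` an exact constrained dynamic program is used, returning
#' the penalized optimum among segmentations with at most that many
#' changepoints.
#'
#' @param values Numeric vector, ordered (e.g. ranked activities); length >= 4.
#' @param penalty Penalty per changepoint; default `3 * log(n)` (an MBIC-style
#'   default: one parameter each for mean, variance and location).
#' @param method `"pelt"` (exact) or `"binseg"` (greedy binary segmentation).
#' @param max_changepoints Maximum number of changepoints; finite values
#'   switch to the exact constrained dynamic program.
#' @param min_segment_length Minimum points per segment (>= 2 so the variance
#'   is defined).
#' @return Integer vector of 0-based indices of the last element of each
#'   segment except the final one; empty when no changepoint lowers the
#'   penalized cost (e.g. constant input).
#' @export
detect_changepoints <- function(values, penalty = NULL,
                                method = c("pelt", "binseg"),
                                max_changepoints = Inf,
                                min_segment_length = 2L) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 4) abort("Need at least 4 values to detect changepoints")
  if (!all(is.finite(values))) abort("`values` must be finite")
  if (min_segment_length < 2) abort("`min_segment_length` must be >= 2")
  if (is.null(penalty)) penalty <- 3 * log(n)
  cost <- seg_cost_fun(values)
  cps <- if (is.finite(max_changepoints)) {
    cpt_constrained_dp(n, cost, penalty, as.integer(max_changepoints),
                       min_segment_length)
  } else if (method == "pelt") {
    cpt_pelt(n, cost, penalty, min_segment_length)
  } else {
    cpt_binseg(n, cost, penalty, min_segment_length)
  }
  as.integer(sort(cps) - 1L)  # 0-based last-in-segment indices
}

#' @noRd
cpt_pelt <- function(n, cost, penalty, minseg) {
  f <- c(-penalty, rep(Inf, n))
  last <- integer(n)
  cand <- 0L
  for (t in seq_len(n)) {
    ok <- cand[t - cand >= minseg]
    if (length(ok) > 0) {
      vals <- f[ok + 1] + cost(ok + 1, t) + penalty
      b <- which.min(vals)
      f[t + 1] <- vals[b]
      last[t] <- ok[b]
      pruned <- ok[vals - penalty <= f[t + 1]]  # PELT pruning (K = 0)
      cand <- c(pruned, cand[t - cand < minseg])
    }
    cand <- c(cand, t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- last[t]
    if (s > 0) cps <- c(s, cps)
    t <- s
  }
  cps
}

#' @noRd
cpt_constrained_dp <- function(n, cost, penalty, max_cp, minseg) {
  full <- cost(1, n)
  # C[m, t]: best cost of values[1..t] with exactly m segments
  ts <- seq_len(n)
  C <- matrix(Inf, nrow = max_cp + 1, ncol = n)
  back <- matrix(0L, nrow = max_cp + 1, ncol = n)
  C[1, ts >= minseg] <- cost(1, ts[ts >= minseg])
  if (max_cp >= 1) {
    for (m in 2:(max_cp + 1)) {
      for (t in ts[ts >= m * minseg]) {
        s <- seq((m - 1) * minseg, t - minseg)
        vals <- C[m - 1, s] + cost(s + 1, t)
        b <- which.min(vals)
        C[m, t] <- vals[b]
        back[m, t] <- s[b]
      }
    }
  }
  total <- C[, n] + penalty * (seq_len(max_cp + 1) - 1)
  m_best <- which.min(total)
  if (m_best == 1) return(integer(0))
  cps <- integer(0)
  t <- n
  for (m in seq(m_best, 2)) {
    t <- back[m, t]
    cps <- c(t, cps)
  }
  cps
}

#' @noRd
cpt_binseg <- function(n, cost, penalty, minseg) {
  cps <- integer(0)
  repeat {
    bounds <- c(0L, sort(cps), n)
    best <- NULL
    best_gain <- 0
    for (k in seq_len(length(bounds) - 1)) {
      a <- bounds[k] + 1L
      b <- bounds[k + 1]
      if (b - a + 1 < 2 * minseg) next
      s <- seq(a + minseg - 1, b - minseg)
      gains <- cost(a, b) - (cost(a, s) + cost(s + 1, b))
      i <- which.max(gains)
      if (gains[i] - penalty > best_gain) {
        best_gain <- gains[i] - penalty
        best <- s[i]
      }
    }
    if (is.null(best)) break
    cps <- c(cps, best)
  }
  sort(cps)
}

#' Derive strength thresholds from ranked activities
#'
#' Runs changepoint detection on activities ranked in ascending order. The
#' activity value at the changepoint with the largest value becomes the lower
#' threshold of the strong class; the value at the smallest becomes the upper
#' threshold of the weak class. With a single changepoint both thresholds
#' coincide and the intermediate class is empty.
#'
#' By default at most two changepoints are fitted (exact constrained dynamic
#' program): a three-class strength scheme needs at most two thresholds, and
#' on a ranked curve the unconstrained mean+variance optimum degenerates into
#' many short low-variance segments whose extreme values would not be useful
#' thresholds. Raise `max_changepoints` (or set it to `Inf`) to explore
#' richer segmentations.
#'
#' @param activity_log2 Numeric vector of log2 activities (any order; ranked
#'   internally).
#' @inheritParams detect_changepoints
#' @return An object of class `strength_thresholds` with elements
#'   `strong_lower_log2`, `weak_upper_log2`, `changepoint_indices` (0-based,
#'   into the ranked vector), `changepoint_values`, `method`, `penalty`, `n`.
#' @export
derive_thresholds <- function(activity_log2, penalty = NULL,
                              method = c("pelt", "binseg"),
                              max_changepoints = 2L,
                              min_segment_length = 2L) {
  method <- match.arg(method)
  ranked <- sort(activity_log2)
  cps <- detect_changepoints(ranked, penalty = penalty, method = method,
                             max_changepoints = max_changepoints,
                             min_segment_length = min_segment_length)
  if (length(cps) == 0) {
    abort(paste0("No changepoints detected in the ranked activities; ",
                 "supply thresholds manually to classify_strength()"))
  }
  vals <- ranked[cps + 1]
  structure(
    list(
      strong_lower_log2 = max(vals),
      weak_upper_log2 = min(vals),
      changepoint_indices = cps,
      changepoint_values = vals,
      method = method,
      penalty = penalty %||% 3 * log(length(ranked)),
      n = length(ranked)
    ),
    class = "strength_thresholds"
  )
}

#' Manually specified strength thresholds
#'
#' @param strong_lower_log2 Lower bound (log2 activity) of the strong class.
#' @param weak_upper_log2 Upper bound (log2 activity) of the weak class.
#' @return A `strength_thresholds` object.
#' @export
strength_thresholds <- function(strong_lower_log2 = 4.0,
                                weak_upper_log2 = 3.1) {
  if (weak_upper_log2 > strong_lower_log2) {
    abort("`weak_upper_log2` must be <= `strong_lower_log2`")
  }
  structure(
    list(strong_lower_log2 = strong_lower_log2,
         weak_upper_log2 = weak_upper_log2,
         changepoint_indices = integer(0),
         changepoint_values = numeric(0),
         method = "manual", penalty = NA_real_, n = NA_integer_),
    class = "strength_thresholds"
  )
}

#' @export
print.strength_thresholds <- function(x, ...) {
  cat("<strength_thresholds> strong >= ", format(x$strong_lower_log2),
      ", weak <= ", format(x$weak_upper_log2),
      " (", x$method, ", ", length(x$changepoint_indices),
      " changepoint(s))\n", sep = "")
  invisible(x)
}

#' @export
tidy.strength_thresholds <- function(x, ...) {
  tibble(changepoint_index = x$changepoint_indices,
         activity_log2 = x$changepoint_values)
}

#' @export
glance.strength_thresholds <- function(x, ...) {
  tibble(strong_lower_log2 = x$strong_lower_log2,
         weak_upper_log2 = x$weak_upper_log2,
         n_changepoints = length(x$changepoint_indices),
         method = x$method, penalty = x$penalty, n = x$n)
}

#' Classify enhancers into weak / intermediate / strong
#'
#' @param activity_log2 Numeric vector of log2 activities (finite).
#' @param thresholds A `strength_thresholds` object (from
#'   [derive_thresholds()] or [strength_thresholds()]).
#' @param boundary How values exactly at a threshold are assigned: `"outer"`
#'   (default; to the weak/strong class) or `"inner"` (to intermediate).
#' @return Ordered factor with levels weak < intermediate < strong.
#' @export
classify_strength <- function(activity_log2, thresholds,
                              boundary = c("outer", "inner")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(thresholds, "strength_thresholds"))
  if (!all(is.finite(activity_log2))) abort("Activities must be finite")
  lo <- thresholds$weak_upper_log2
  hi <- thresholds$strong_lower_log2
  cls <- if (boundary == "outer") {
    ifelse(activity_log2 >= hi, "strong",
           ifelse(activity_log2 <= lo, "weak", "intermediate"))
  } else {
    ifelse(activity_log2 > hi, "strong",
           ifelse(activity_log2 < lo, "weak", "intermediate"))
  }
  factor(cls, levels = c("weak", "intermediate", "strong"), ordered = TRUE)
}
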