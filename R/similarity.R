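#' Triangular weighting function
#'
#' The correlation window of the similarity measure: `w(r) = max(0, 1 - |r|/l)`,
#' an even triangle whose full width at half maximum equals the neighbouring
#' range parameter `l`.
#'
#' @param r 2-theta offset(s), degrees
#' @param l neighbouring range, degrees (> 0)
#' @return weight(s) in `[0, 1]`
#' @export
weight_triangular <- function(r, l) {
  if (!is.numeric(l) || length(l) != 1L || l <= 0)
    stop("neighbouring range l must be a single positive number")
  pmax(0, 1 - abs(r) / l)
}

#' Discrete cross-correlation profile of two patterns
#'
#' `c12(k * step) = sum_i I1(theta_i) * I2(theta_i + k * step)` for lags
#' `|k * step| <= l`, on the grid of the first pattern (the second is
#' resampled onto it).
#'
#' @param p1,p2 `powder_pattern` objects
#' @param l maximum lag, degrees
#' @return data.frame with columns `lag` (degrees) and `value`
#' @export
cross_correlation <- function(p1, p2, l) {
  stopifnot(inherits(p1, "powder_pattern"), l > 0)
  p2 <- on_common_grid(p1, p2)
  if (all(p2$intensities == 0) && all(p1$intensities == 0))
    stop("empty overlap between patterns")
  K <- floor(l / p1$step)
  v <- cpp_xcorr(p1$intensities, p2$intensities, K)
  data.frame(lag = (-K:K) * p1$step, value = v)
}

#' Generalized similarity of two powder patterns
#'
#' The weighted-cross-correlation similarity: the triangular-weighted sum of
#' the discrete cross-correlation of the two patterns, normalized by the
#' corresponding weighted auto-correlations,
#' \deqn{S_{12} = \frac{\sum_k w_k c_{12,k}}{\sqrt{(\sum_k w_k c_{11,k})(\sum_k w_k c_{22,k})}}}
#' with lags restricted to `|k step| <= l`. It is symmetric, invariant under
#' positive rescaling of either pattern, equals 1 for identical patterns and
#' lies in `[0, 1]` for non-negative patterns. As `l -> 0` it reduces to the
#' pointwise (cosine / Pearson-type) comparison of the intensity vectors.
#'
#' @param p1,p2 `powder_pattern` objects (`p2` is resampled onto `p1`'s grid)
#' @param l neighbouring range, degrees; ignored when `zero_limit = TRUE`
#' @param range_2theta optional `c(lo, hi)` comparison window, degrees
#' @param zero_limit if `TRUE`, compute the pointwise `l -> 0` limit
#' @param centered centre the intensity vectors first (only meaningful with
#'   `zero_limit`; gives the classical Pearson correlation coefficient)
#' @return list with elements `value`, `l`, `range_2theta`, `variant`
#' @export
s12 <- function(p1, p2, l = 1, range_2theta = NULL, zero_limit = FALSE,
                centered = FALSE) {
  stopifnot(inherits(p1, "powder_pattern"))
  p2 <- on_common_grid(p1, p2)
  I1 <- p1$intensities
  I2 <- p2$intensities
  if (!is.null(range_2theta)) {
    tt <- two_theta(p1)
    keep <- tt >= range_2theta[1] & tt <= range_2theta[2]
    if (!any(keep)) stop("patterns do not overlap within range_2theta")
    I1 <- I1[keep]; I2 <- I2[keep]
  }
  if (all(I1 == 0) || all(I2 == 0))
    stop("a pattern is identically zero on the comparison range; ",
         "similarity is undefined")
  if (zero_limit) {
    if (centered) { I1 <- I1 - mean(I1); I2 <- I2 - mean(I2) }
    val <- sum(I1 * I2) / sqrt(sum(I1^2) * sum(I2^2))
  } else {
    if (!is.numeric(l) || l <= 0) stop("l must be > 0 unless zero_limit")
    K <- floor(l / p1$step)
    w <- weight_triangular((0:K) * p1$step, l)
    sums <- cpp_s12_sums(I1, I2, K, w)
    val <- sums[1] / sqrt(sums[2] * sums[3])
  }
  list(value = val, l = if (zero_limit) 0 else l,
       range_2theta = range_2theta %||%
         c(p1$start, p1$start + p1$step * (length(p1$intensities) - 1L)),
       variant = if (zero_limit) "zero_limit" else "raw")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference similarity of a simulated against an experimental pattern
#'
#' The `l -> 0` pointwise similarity over the full measured 2-theta range of
#' the experimental pattern; the scale-independent figure of merit used for
#' ranking, filtering and clustering of structure candidates. The variant tag
#' records whether the experimental pattern was background-corrected.
#'
#' @param exp experimental `powder_pattern` (defines the grid and range)
#' @param sim simulated `powder_pattern`
#' @return list as for [s12()], variant `"reference_S12_bg0"` when `exp` is
#'   background-corrected, `"reference_S12_0"` otherwise
#' @export
reference_similarity <- function(exp, sim) {
  out <- s12(exp, sim, zero_limit = TRUE)
  out$variant <- if (exp$background_corrected) "reference_S12_bg0"
                 else "reference_S12_0"
  out
}

#' Pairwise similarity matrix of a list of patterns
#'
#' @param patterns list of `powder_pattern` objects (>= 2)
#' @param l neighbouring range, degrees
#' @param zero_limit compute the pointwise limit instead
#' @return symmetric numeric matrix with unit diagonal
#' @export
pairwise_matrix <- function(patterns, l = 0.3, zero_limit = FALSE) {
  n <- length(patterns)
  stopifnot(n >= 2L)
  M <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      M[i, j] <- M[j, i] <-
        s12(patterns[[i]], patterns[[j]], l = l, zero_limit = zero_limit)$value
    }
  }
  dimnames(M) <- list(names(patterns), names(patterns))
  M
}

#' Greedy leader clustering of structure candidates
#'
#' Candidates are visited in descending order of reference similarity (ties
#' broken by candidate id). A candidate joins the first existing cluster whose
#' representative simulated pattern matches it with `s12(l_narrow) >=
#' threshold`; otherwise it founds a new cluster. Each cluster keeps only its
#' representative (the member with the highest reference similarity, i.e. the
#' founder), whose integer weight becomes the sum of the members' weights.
#'
#' @param cands a `candidate_set` (see [run_go()]) or plain list of candidates,
#'   each carrying `$pattern`, `$ref_sim`, `$weight` and `$id`
#' @param l_narrow narrow neighbouring range for the pairwise comparison,
#'   degrees (default 0.3)
#' @param threshold similarity above which two candidates are duplicates
#'   (default 0.995)
#' @param fit_check optional function(candidate, representative) -> logical
#'   used as an additional duplicate test before merging (off by default; the
#'   pattern comparison alone is the standard criterion)
#' @return object of the same shape with merged candidates removed and
#'   representative weights accumulated
#' @export
cluster_candidates <- function(cands, l_narrow = 0.3, threshold = 0.995,
                               fit_check = NULL) {
  set <- inherits(cands, "candidate_set")
  lst <- if (set) cands$candidates else cands
  if (length(lst) <= 1L) return(cands)
  ref <- vapply(lst, function(cc) cc$ref_sim, numeric(1))
  ids <- vapply(lst, function(cc) as.character(cc$id %||% ""), character(1))
  ord <- order(-ref, ids)
  reps <- list()
  for (i in ord) {
    cand <- lst[[i]]
    merged <- FALSE
    for (r in seq_along(reps)) {
      sim <- s12(reps[[r]]$pattern, cand$pattern, l = l_narrow)$value
      if (sim >= threshold &&
          (is.null(fit_check) || isTRUE(fit_check(cand, reps[[r]])))) {
        reps[[r]]$weight <- reps[[r]]$weight + cand$weight
        merged <- TRUE
        break
      }
    }
    if (!merged) reps[[length(reps) + 1L]] <- cand
  }
  if (set) { cands$candidates <- reps; cands } else reps
}
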