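#' Split-half reliability of the rating instrument
#'
#' Repeatedly splits the participants into two random halves, computes each
#' half's vector of per-pair mean ratings, and correlates the two vectors
#' (Pearson). The raw reliability is the mean correlation over splits; the
#' Spearman-Brown correction `2r / (1 + r)` extrapolates it to the full
#' sample length. Both are reported. Participants are sorted by id before
#' splitting, so the result depends only on the seed, not on input row
#' order.
#'
#' @param ratings ratings matrix (participants x pairs) or a
#'   [concept_cohort()].
#' @param n_splits number of random splits to average over (default 500).
#' @param seed integer seed for the split stream.
#' @return object of class `reliability_result`: `r_raw`, `r_corrected`,
#'   `n_splits`, `n_participants`, `seed`.
#' @export
split_half_reliability <- function(ratings, n_splits = 500, seed = 1) {
  if (inherits(ratings, "concept_cohort")) ratings <- ratings$ratings
  n <- nrow(ratings)
  if (n < 4) stopf("need at least 4 participants, got %d", n)
  ord <- if (is.null(rownames(ratings))) seq_len(n)
         else order(rownames(ratings))
  ratings <- ratings[ord, , drop = FALSE]
  half <- n %/% 2L
  set.seed(substream_seed(seed, "split_half"))
  rs <- vapply(seq_len(n_splits), function(i) {
    first <- sample.int(n, half)
    stats::cor(colMeans(ratings[first, , drop = FALSE]),
               colMeans(ratings[-first, , drop = FALSE]))
  }, numeric(1))
  r <- mean(rs)
  structure(list(r_raw = r,
                 r_corrected = 2 * r / (1 + r),
                 n_splits = n_splits, n_participants = n, seed = seed),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    "Split-half reliability over %d splits (n = %d): r = %.3f (Spearman-Brown %.3f)\n",
    x$n_splits, x$n_participants, x$r_raw, x$r_corrected))
  invisible(x)
}
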