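#' Shannon entropy of one concept pair
#'
#' Across-participant entropy of the discrete rating distribution,
#' `H = -sum p(x_i) log2 p(x_i)` with the convention 0 log 0 = 0, computed
#' over the 15 nominal rating levels with empirical frequencies (zero-count
#' levels contribute nothing). Bounded by 0 (point mass) and
#' log2(15) ~ 3.9069 (uniform).
#'
#' @param ratings integer ratings in -7..+7 for one pair.
#' @param levels the nominal response levels (default -7..+7).
#' @param miller_madow apply the Miller-Madow small-sample bias correction
#'   (off by default).
#' @return entropy in bits.
#' @export
pair_entropy <- function(ratings, levels = RATING_LEVELS,
                         miller_madow = FALSE) {
  ratings <- ratings[!is.na(ratings)]
  if (!length(ratings)) stopf("need at least one rating")
  if (any(!ratings %in% levels))
    stopf("rating outside the nominal levels")
  p <- tabulate(match(ratings, levels), nbins = length(levels)) /
    length(ratings)
  nz <- p > 0
  H <- -sum(p[nz] * log2(p[nz]))
  if (miller_madow)
    H <- H + (sum(nz) - 1) / (2 * length(ratings) * log(2))
  H
}

#' Per-pair entropy table
#'
#' @param ratings a ratings matrix (participants x pairs) or a
#'   [concept_cohort()].
#' @param pairs pair index (taken from the cohort when one is given).
#' @param miller_madow see [pair_entropy()].
#' @return data frame with one row per pair: `pair`, `concept_a`,
#'   `concept_b`, `entropy`; the 15-level relative-frequency matrix is
#'   attached as attribute `"distribution"`.
#' @export
entropy_table <- function(ratings, pairs = NULL, miller_madow = FALSE) {
  if (inherits(ratings, "concept_cohort")) {
    pairs <- ratings$pairs
    ratings <- ratings$ratings
  }
  if (is.null(pairs)) stopf("pairs index required when passing a raw matrix")
  H <- apply(ratings, 2, pair_entropy, miller_madow = miller_madow)
  dist <- apply(ratings, 2, function(col)
    tabulate(match(col, RATING_LEVELS), nbins = 15) / length(col))
  out <- data.frame(pair = pairs$pair, concept_a = pairs$concept_a,
                    concept_b = pairs$concept_b, entropy = as.numeric(H),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "distribution") <- dist
  out
}

#' Fit an offset sigmoid by nonlinear least squares
#'
#' Fits `y = 1 / (1 + exp(-a (x - b))) + c` with Levenberg-Marquardt least
#' squares and multi-start initialization: the base start takes `a` from
#' 4 / range(x) (the logistic slope whose linear region spans the data),
#' `b` at the x-position of the steepest increase of a moving average of y,
#' and `c` at min(y); further starts jitter these values under a fixed
#' seed and the converged fit with the lowest residual sum of squares wins.
#'
#' @param x predictor (e.g., per-pair entropies); not all equal.
#' @param y response (e.g., absolute news-bias coefficients).
#' @param n_starts number of jittered restarts (default 10).
#' @param seed seed for the jitter stream.
#' @return object of class `sigmoid_fit`: `a`, `b`, `c`, standard errors,
#'   95% confidence intervals, `r_squared`, `converged`, `n`. When no start
#'   converges (or y is constant) the fit is flagged `converged = FALSE`
#'   with `NA` parameters and `r_squared = 0`.
#' @export
fit_offset_sigmoid <- function(x, y, n_starts = 10, seed = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stopf("need at least 4 points")
  if (stats::var(x) == 0) stopf("x values are all equal")
  degenerate <- function() {
    structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                   se = c(a = NA_real_, b = NA_real_, c = NA_real_),
                   ci = NULL, r_squared = 0, converged = FALSE,
                   n = length(x)),
              class = "sigmoid_fit")
  }
  if (stats::var(y) == 0) return(degenerate())

  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  win <- max(3L, length(ys) %/% 10L)
  smooth <- stats::filter(ys, rep(1 / win, win), sides = 2)
  dy <- diff(as.numeric(smooth))
  b0 <- if (all(is.na(dy))) stats::median(xs) else
    xs[which.max(replace(dy, is.na(dy), -Inf))]
  a0 <- 4 / diff(range(x))
  c0 <- min(y)

  set.seed(substream_seed(seed, "sigmoid_fit"))
  starts <- vector("list", n_starts)
  starts[[1]] <- c(a = a0, b = b0, c = c0)
  for (i in seq_len(n_starts - 1)) {
    starts[[i + 1]] <- c(
      a = a0 * exp(stats::rnorm(1, 0, 1.2)) * sample(c(1, -1), 1, prob = c(.9, .1)),
      b = b0 + stats::rnorm(1, 0, stats::sd(x) / 2),
      c = c0 + stats::rnorm(1, 0, max(stats::sd(y) / 5, 1e-3)))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ 1 / (1 + exp(-a * (x - b))) + c,
        start = as.list(st),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(degenerate())
  cf <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                 error = function(e) rep(NA_real_, 3))
  names(se) <- names(cf)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - best$rss / ss_tot
  ci <- cbind(lower = cf - 1.96 * se, upper = cf + 1.96 * se)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["c"]), se = se, ci = ci,
                 r_squared = r2, converged = TRUE, n = length(x)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Offset sigmoid fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Offset sigmoid fit (n = %d): a = %.3f, b = %.3f, c = %.3f, R^2 = %.3f\n",
    x$n, x$a, x$b, x$c, x$r_squared))
  invisible(x)
}

#' Entropy vs news-bias-effect analysis
#'
#' Joins the per-pair rating entropy with the absolute news-bias coefficient
#' from the edgewise screen, fits the offset sigmoid to |beta| as a function
#' of entropy (absolute values are fitted; signed coefficients are reported
#' for plotting only), and labels the extreme pairs at either end of the
#' entropy and effect ranges.
#'
#' @param edge_results an `edgewise_result` containing a `news_bias`
#'   predictor.
#' @param ratings ratings matrix or [concept_cohort()].
#' @param pairs pair index when `ratings` is a raw matrix.
#' @param n_extremes how many pairs to label at each extreme.
#' @param ... passed to [fit_offset_sigmoid()].
#' @return list of class `entropy_effect_analysis` with `table` (pair,
#'   entropy, beta, abs_beta), `fit` (a `sigmoid_fit`), and `extremes`.
#' @export
entropy_effect_analysis <- function(edge_results, ratings, pairs = NULL,
                                    n_extremes = 3, ...) {
  news <- edge_results[edge_results$predictor == "news_bias", , drop = FALSE]
  if (!nrow(news))
    stopf("edge results carry no news_bias coefficients")
  etab <- entropy_table(ratings, pairs)
  tab <- merge(etab, news[, c("pair", "beta", "q", "significant")],
               by = "pair", sort = FALSE)
  tab$abs_beta <- abs(tab$beta)
  tab <- tab[match(etab$pair, tab$pair), , drop = FALSE]
  fit <- fit_offset_sigmoid(tab$entropy, tab$abs_beta, ...)
  ord_h <- order(tab$entropy)
  ord_e <- order(tab$abs_beta)
  extremes <- list(
    lowest_entropy = tab$pair[utils::head(ord_h, n_extremes)],
    highest_entropy = tab$pair[utils::tail(ord_h, n_extremes)],
    smallest_effect = tab$pair[utils::head(ord_e, n_extremes)],
    largest_effect = tab$pair[utils::tail(ord_e, n_extremes)])
  structure(list(table = tab, fit = fit, extremes = extremes),
            class = "entropy_effect_analysis")
}

#' @export
print.entropy_effect_analysis <- function(x, ...) {
  cat(sprintf("Entropy/effect analysis over %d pairs\n", nrow(x$table)))
  print(x$fit)
  invisible(x)
}
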