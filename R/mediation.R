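#' Mediation path coefficients
#'
#' Decomposes the effect of a group indicator x on an edge weight y into a
#' direct path and an indirect path through the mediator m (news bias),
#' using three nested OLS fits sharing the same covariate set:
#' `m ~ x + C` (a path), `y ~ x + C` (total effect c), and
#' `y ~ x + m + C` (direct effect c' and b path). With identical covariates
#' the decomposition `c = c' + a * b` is an exact algebraic identity of OLS.
#'
#' @param x group indicator (e.g., race dummy).
#' @param m mediator (e.g., news-bias score); no missing values.
#' @param y response (edge weight).
#' @param covariates optional numeric matrix/data frame of nuisance
#'   covariates (no intercept column; added internally).
#' @return list with `a`, `se_a`, `b`, `se_b`, `c`, `se_c`, `c_prime`,
#'   `se_c_prime`, `indirect` (= a * b).
#' @export
mediation_paths <- function(x, m, y, covariates = NULL) {
  n <- length(y)
  if (length(x) != n || length(m) != n)
    stopf("x, m, y must have equal length")
  if (anyNA(x) || anyNA(m) || anyNA(y))
    stopf("missing values not allowed; subset to complete cases first")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X1 <- cbind("(Intercept)" = 1, x = x, C)
  X2 <- cbind("(Intercept)" = 1, x = x, m = m, C)
  f_a <- fit_edge_glm(m, X1)
  f_c <- fit_edge_glm(y, X1)
  f_b <- fit_edge_glm(y, X2)
  list(a = unname(f_a$coefficients["x"]), se_a = unname(f_a$se["x"]),
       b = unname(f_b$coefficients["m"]), se_b = unname(f_b$se["m"]),
       c = unname(f_c$coefficients["x"]), se_c = unname(f_c$se["x"]),
       c_prime = unname(f_b$coefficients["x"]),
       se_c_prime = unname(f_b$se["x"]),
       indirect = unname(f_a$coefficients["x"] * f_b$coefficients["m"]))
}

#' Sobel test of an indirect effect
#'
#' Normal-approximation test of the product a * b using the first-order
#' delta-method standard error:
#' `z = a b / sqrt(b^2 se_a^2 + a^2 se_b^2)`, two-sided p from the standard
#' normal. The degenerate case a = b = 0 returns z = 0, p = 1 (limit
#' convention).
#'
#' @param a,se_a mediator-path estimate and standard error (`se_a > 0`).
#' @param b,se_b outcome-path estimate and standard error (`se_b > 0`).
#' @return list with `z` and `p`.
#' @examples
#' sobel_test(0.5, 0.1, 0.4, 0.1) # z ~ 3.1235
#' @export
sobel_test <- function(a, se_a, b, se_b) {
  if (se_a <= 0 || se_b <= 0) stopf("standard errors must be positive")
  denom <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  if (denom == 0) return(list(z = 0, p = 1))
  z <- a * b / denom
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Permutation test of the indirect effect
#'
#' Builds a null for a * b by permuting the mediator across participants and
#' recomputing both paths each time. Under the default `"residual"` scheme
#' the mediator's residuals from its regression on x and the covariates are
#' permuted and added back to the fitted values, so the group-to-mediator
#' path is preserved while the mediator-to-outcome link is broken; this
#' keeps the test calibrated on edges where the group genuinely shifts the
#' mediator but the mediator does not drive the edge weight (b = 0), the
#' null that matters when screening group-differing edges. The `"simple"`
#' scheme permutes the raw mediator, breaking both paths at once; it is
#' calibrated only under the joint null (a = 0 and b = 0) and is
#' anti-conservative whenever the a path is real. Two-sided p with add-one
#' smoothing.
#'
#' @inheritParams mediation_paths
#' @param n_perm permutations (>= 100).
#' @param seed integer seed for this test's permutation stream.
#' @param scheme `"residual"` (default) or `"simple"`.
#' @return list with `indirect` (observed a * b) and `p`.
#' @export
mediation_permutation <- function(x, m, y, covariates = NULL,
                                  n_perm = 10000, seed = 1,
                                  scheme = c("residual", "simple")) {
  scheme <- match.arg(scheme)
  if (n_perm < 100) stopf("n_perm must be >= 100")
  if (stats::var(m) == 0) stopf("mediator is constant")
  n <- length(y)
  Cov <- if (is.null(covariates)) NULL else as.matrix(covariates)
  C1 <- cbind(rep(1, n), x, Cov)
  Q1 <- nuisance_basis(cbind(rep(1, n), Cov))
  rx <- x - Q1 %*% crossprod(Q1, x)   # x residualized on covariates
  Q2 <- nuisance_basis(C1)            # basis spanning (1, x, covariates)
  a_obs <- sum(rx * m) / sum(rx^2)
  rm_obs <- m - Q2 %*% crossprod(Q2, m)
  b_obs <- sum(rm_obs * y) / sum(rm_obs^2)
  ind_obs <- a_obs * b_obs
  perms <- permutation_indices(n, n_perm,
                               substream_seed(seed, "mediation_perm"))
  if (scheme == "simple") {
    Mp <- matrix(m[perms], n, n_perm)
  } else {
    fit_m <- m - rm_obs # fitted values of m ~ x + covariates
    Mp <- matrix(as.numeric(rm_obs)[perms], n, n_perm) + as.numeric(fit_m)
  }
  a_star <- as.numeric(crossprod(rx, Mp)) / sum(rx^2)
  Rm <- Mp - Q2 %*% crossprod(Q2, Mp)
  b_star <- colSums(Rm * y) / colSums(Rm^2)
  ind_star <- a_star * b_star
  thresh <- abs(ind_obs) * (1 - 1e-12)
  p <- (1 + sum(abs(ind_star) >= thresh)) / (n_perm + 1)
  list(indirect = ind_obs, p = p)
}

#' Classify mediation of a group-differing edge
#'
#' Applies the full/partial rule after FDR correction within the
#' race-differing family: an edge is *fully* mediated when the indirect
#' effect stays significant while the direct effect does not survive
#' correction; *partially* mediated when both survive; *unmediated* when
#' the indirect effect does not survive.
#'
#' @param q_indirect,q_direct BH-adjusted p-values of the indirect and
#'   direct effects (vectors recycle).
#' @param race_flag logical: was the edge race-differing to begin with?
#' @param alpha FDR level.
#' @return character vector with levels `not_race_differing`, `full`,
#'   `partial`, `unmediated`.
#' @export
classify_mediation <- function(q_indirect, q_direct, race_flag = TRUE,
                               alpha = 0.05) {
  n <- max(length(q_indirect), length(q_direct), length(race_flag))
  q_indirect <- rep_len(q_indirect, n)
  q_direct <- rep_len(q_direct, n)
  race_flag <- rep_len(race_flag, n)
  out <- rep("unmediated", n)
  out[q_indirect <= alpha & q_direct <= alpha] <- "partial"
  out[q_indirect <= alpha & q_direct > alpha] <- "full"
  out[!race_flag] <- "not_race_differing"
  out
}

#' Mediation screen over race-differing edges
#'
#' For each edge previously flagged race-differing, decomposes the group
#' effect on the edge weight into direct and news-bias-mediated paths,
#' tests the indirect effect with a permutation null (primary inference)
#' and the Sobel test (converging evidence), tests the direct effect with a
#' permutation test of x in the full model, applies BH correction
#' separately to the indirect and direct families over the screened set,
#' and labels each edge full/partial/unmediated.
#'
#' @param cohort a [concept_cohort()].
#' @param race_pairs pair keys to screen: a character vector, integer
#'   column indices, or an `edgewise_result` (its significant race pairs
#'   are used).
#' @param covariates nuisance covariates for all three path regressions
#'   (`NULL` to drop them).
#' @param n_perm permutations per test.
#' @param alpha FDR level.
#' @param seed root seed; per-edge streams are derived by hashing.
#' @param scheme mediator permutation scheme, see [mediation_permutation()].
#' @return data frame of class `mediation_result`, one row per screened
#'   edge: paths `a`, `b`, `c`, `c_prime`, `indirect`, `sobel_z`, `sobel_p`,
#'   `p_indirect`, `p_direct`, `q_indirect`, `q_direct`, `label`.
#' @export
run_mediation_screen <- function(cohort, race_pairs,
                                 covariates = c("gender", "income", "age"),
                                 n_perm = 10000, alpha = 0.05, seed = 1,
                                 scheme = c("residual", "simple")) {
  scheme <- match.arg(scheme)
  if (inherits(race_pairs, "edgewise_result"))
    race_pairs <- significant_pairs(race_pairs, "race")
  if (is.numeric(race_pairs)) race_pairs <- cohort$pairs$pair[race_pairs]
  cols <- c("pair", "concept_a", "concept_b", "a", "se_a", "b", "se_b",
            "c", "c_prime", "se_c_prime", "indirect", "sobel_z", "sobel_p",
            "p_indirect", "p_direct", "q_indirect", "q_direct", "label")
  if (!length(race_pairs)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 3), cols[1:3]))
    for (cc in cols[4:17]) out[[cc]] <- numeric(0)
    out$label <- character(0)
    class(out) <- c("mediation_result", "data.frame")
    return(out)
  }
  idx <- match(race_pairs, cohort$pairs$pair)
  if (anyNA(idx))
    stopf("unknown pair key(s): %s",
          paste(race_pairs[is.na(idx)], collapse = ", "))
  des <- build_design(cohort, "race",
                      covariates = c("news_bias", covariates))
  rows <- des$rows
  x <- cohort$demographics$race[rows]
  m <- cohort$news_bias[rows]
  C <- if (length(covariates)) {
    cm <- des$X[, covariates, drop = FALSE]
    cm
  } else NULL
  W <- edge_weights(cohort)
  res <- lapply(seq_along(idx), function(k) {
    j <- idx[k]
    y <- W[rows, j]
    paths <- mediation_paths(x, m, y, covariates = C)
    sob <- sobel_test(paths$a, paths$se_a, paths$b, paths$se_b)
    perm <- mediation_permutation(
      x, m, y, covariates = C, n_perm = n_perm,
      seed = substream_seed(seed, "mediation", j), scheme = scheme)
    ## direct effect: permutation test of x holding the mediator fixed
    Xfull <- cbind("(Intercept)" = 1, x = x, m = m, C)
    pdir <- permutation_pvalue(
      y, Xfull, "x", n_perm = n_perm,
      seed = substream_seed(seed, "mediation_direct", j))
    data.frame(
      pair = cohort$pairs$pair[j],
      concept_a = cohort$pairs$concept_a[j],
      concept_b = cohort$pairs$concept_b[j],
      a = paths$a, se_a = paths$se_a, b = paths$b, se_b = paths$se_b,
      c = paths$c, c_prime = paths$c_prime, se_c_prime = paths$se_c_prime,
      indirect = paths$indirect,
      sobel_z = sob$z, sobel_p = sob$p,
      p_indirect = perm$p, p_direct = pdir$p,
      stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$q_indirect <- fdr_correct(out$p_indirect, alpha)$q
  out$q_direct <- fdr_correct(out$p_direct, alpha)$q
  out$label <- classify_mediation(out$q_indirect, out$q_direct,
                                  race_flag = TRUE, alpha = alpha)
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "n_used") <- length(rows)
  class(out) <- c("mediation_result", "data.frame")
  out
}
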