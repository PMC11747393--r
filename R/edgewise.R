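#' Ordinary least squares fit for one edge
#'
#' Fits the edge-wise general linear model by QR-decomposed ordinary least
#' squares and returns coefficients with classical standard errors.
#'
#' @param y numeric response (per-participant edge weights for one pair).
#' @param X numeric design matrix, including the intercept column.
#' @return list with `coefficients`, `se`, `sigma`, `df_residual`,
#'   `residuals`, `fitted`.
#' @export
fit_edge_glm <- function(y, X) {
  X <- as.matrix(X)
  if (length(y) != nrow(X))
    stopf("length(y) = %d does not match nrow(X) = %d", length(y), nrow(X))
  qx <- qr(X)
  p <- ncol(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p]] %||%
      qx$pivot[(qx$rank + 1L):p]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - as.numeric(X %*% beta)
  df <- length(y) - p
  sigma2 <- sum(res^2) / df
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  names(se) <- names(beta) <- colnames(X)
  list(coefficients = beta, se = se, sigma = sqrt(sigma2),
       df_residual = df, residuals = res, fitted = y - res)
}

## Orthonormal basis of the column space of C (nuisance block).
nuisance_basis <- function(C) {
  qc <- qr(C)
  qr.Q(qc)[, seq_len(qc$rank), drop = FALSE]
}

## n x n_perm matrix of permutation indices under a local substream.
## The batched Fisher-Yates shuffle is compiled (see src/) with its own
## explicitly seeded generator, because index generation dominates the cost
## of the permutation screens and must not disturb R's global RNG.
permutation_indices <- function(n, n_perm, seed) {
  perm_indices_cpp(n, n_perm, as.double(seed))
}

## Core of the permutation test for one predictor. x is the tested column,
## C the remaining columns (with intercept), y the response. Uses the
## Frisch-Waugh-Lovell identity: the OLS coefficient of x in the full model
## equals r'y / r'r where r is x residualized against C, so each permutation
## costs one projection instead of a full refit.
perm_beta_core <- function(y, x, C, n_perm, seed,
                           scheme = c("simple", "freedman_lane")) {
  scheme <- match.arg(scheme)
  n <- length(y)
  if (stats::var(x) == 0) stopf("tested predictor column is constant")
  Q <- nuisance_basis(C)
  rx <- x - Q %*% crossprod(Q, x)
  beta_obs <- sum(rx * y) / sum(rx^2)
  perms <- permutation_indices(n, n_perm, seed)
  if (scheme == "simple") {
    ## expanded projection: r'y = x'y - (Q'y)'(Q'x) and
    ## r'r = x'x - |Q'x|^2 column-wise, avoiding the n x n_perm residual
    Xp <- matrix(x[perms], n, n_perm)
    A <- crossprod(Q, Xp)
    qy <- crossprod(Q, y)
    beta_star <- (as.numeric(crossprod(y, Xp)) -
                    as.numeric(crossprod(qy, A))) /
      (sum(x^2) - colSums(A^2))
  } else { # Freedman-Lane: permute nuisance-model residuals of y
    fit_y <- Q %*% crossprod(Q, y)
    res_y <- y - fit_y
    Ystar <- matrix(res_y[perms], n, n_perm) + as.numeric(fit_y)
    beta_star <- as.numeric(crossprod(rx, Ystar)) / sum(rx^2)
  }
  ## two-sided with add-one smoothing; ties count against the observed
  ## statistic, with a relative tolerance so p is affine-invariant in y
  thresh <- abs(beta_obs) * (1 - 1e-12)
  p <- (1 + sum(abs(beta_star) >= thresh)) / (n_perm + 1)
  list(beta = beta_obs, p = p, beta_star = beta_star)
}

#' Permutation p-value for one predictor in an edge GLM
#'
#' Builds an empirical null for the OLS coefficient of one predictor by
#' permuting across participants. Under the default `"simple"` scheme the
#' tested predictor column is permuted while the response and the other
#' columns stay fixed (exchangeability of the predictor under the marginal
#' null); the `"freedman_lane"` scheme instead permutes the residuals of the
#' nuisance-only model of y. The two-sided p-value is
#' `(1 + #\{|beta*| >= |beta|\}) / (n_perm + 1)`, so p > 0 always.
#'
#' @param y response vector.
#' @param X design matrix with named columns, including the intercept.
#' @param predictor name (or index) of the tested column.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for this test's permutation stream.
#' @param scheme `"simple"` or `"freedman_lane"`.
#' @return list with `beta` (observed coefficient) and `p`.
#' @export
permutation_pvalue <- function(y, X, predictor, n_perm = 10000, seed = 1,
                               scheme = c("simple", "freedman_lane")) {
  X <- as.matrix(X)
  if (n_perm < 100) stopf("n_perm must be >= 100")
  if (is.character(predictor)) {
    k <- match(predictor, colnames(X))
    if (is.na(k)) stopf("no design column named '%s'", predictor)
  } else k <- predictor
  out <- perm_beta_core(y, X[, k], X[, -k, drop = FALSE], n_perm, seed,
                        match.arg(scheme))
  list(beta = out$beta, p = out$p)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment of a family of p-values, with significance flags at
#' the given level.
#'
#' @param pvals numeric p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (BH-adjusted values) and `significant` flags
#'   (`q <= alpha`).
#' @export
fdr_correct <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stopf("p-values must lie in (0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, significant = q <= alpha)
}

## Design-matrix builder. Columns: intercept, focal predictor, covariates.
## Rows are restricted to participants with complete data on the used
## columns; news_bias is only required when it is actually in the model.
build_design <- function(cohort, focal,
                         covariates = c("gender", "income", "age")) {
  d <- cohort$demographics
  cols <- list(race = d$race, gender = d$gender, income = d$income,
               age = d$age, news_bias = cohort$news_bias)
  used <- c(focal, covariates)
  unknown <- setdiff(used, names(cols))
  if (length(unknown))
    stopf("unknown design column(s): %s", paste(unknown, collapse = ", "))
  M <- do.call(cbind, cols[used])
  colnames(M) <- used
  rows <- which(stats::complete.cases(M))
  X <- cbind("(Intercept)" = 1, M[rows, , drop = FALSE])
  list(X = X, rows = rows)
}

#' Edge-wise permutation GLM screen
#'
#' Fits one general linear model per concept pair and per predictor of
#' interest, with gender, income bracket, and age always included as
#' nuisance covariates, and tests each focal coefficient against a
#' 10,000-iteration (by default) permutation null. Benjamini-Hochberg FDR
#' correction is applied across the pairs separately for each predictor.
#' The response is the per-participant edge weight, so a positive race
#' coefficient means a larger distance (weaker association) for the group
#' coded 1. Each focal predictor is tested in its own model: the race screen
#' estimates the total group effect (the quantity the mediation stage
#' subsequently decomposes into direct and news-mediated paths), while the
#' news-bias model additionally controls for race by default
#' (`control_race_in_news`), so a group effect routed around the mediator is
#' not misattributed to news bias.
#'
#' Rows with missing values on any used column are dropped per model; the
#' news-bias model is therefore restricted to participants with a defined
#' bias score. Per-edge permutation streams are derived from the root seed
#' by hashing (predictor, edge index), so results do not depend on
#' evaluation order.
#'
#' @param cohort a [concept_cohort()].
#' @param predictors focal predictors to screen (default race and news bias).
#' @param covariates nuisance covariates included in every model.
#' @param n_perm permutations per edge (default 10000).
#' @param alpha FDR level.
#' @param seed root seed.
#' @param scheme permutation scheme, see [permutation_pvalue()].
#' @param control_race_in_news include race as an additional covariate in
#'   the news-bias model (default `TRUE`).
#' @return data frame of class `edgewise_result`: one row per pair x
#'   predictor with `beta`, `se`, `p_perm`, `q`, `significant`; attributes
#'   `alpha`, `n_perm`, `seed`, `scheme`, `concepts`, `n_used` (rows per
#'   predictor model).
#' @export
run_edgewise <- function(cohort, predictors = c("race", "news_bias"),
                         covariates = c("gender", "income", "age"),
                         n_perm = 10000, alpha = 0.05, seed = 1,
                         scheme = c("simple", "freedman_lane"),
                         control_race_in_news = TRUE) {
  scheme <- match.arg(scheme)
  W <- edge_weights(cohort)
  pairs <- cohort$pairs
  P <- nrow(pairs)
  n_used <- integer(0)
  res <- vector("list", length(predictors))
  for (k in seq_along(predictors)) {
    focal <- predictors[k]
    covs <- covariates
    if (focal == "news_bias" && control_race_in_news)
      covs <- unique(c(covariates, "race"))
    des <- build_design(cohort, focal, covs)
    n_used[focal] <- length(des$rows)
    x <- des$X[, focal]
    C <- des$X[, setdiff(colnames(des$X), focal), drop = FALSE]
    beta <- se <- p <- numeric(P)
    for (j in seq_len(P)) {
      y <- W[des$rows, j]
      fit <- fit_edge_glm(y, des$X)
      beta[j] <- fit$coefficients[focal]
      se[j] <- fit$se[focal]
      p[j] <- perm_beta_core(
        y, x, C, n_perm,
        seed = substream_seed(seed, "edgewise", focal, j),
        scheme = scheme)$p
    }
    fdr <- fdr_correct(p, alpha)
    res[[k]] <- data.frame(
      pair = pairs$pair, concept_a = pairs$concept_a,
      concept_b = pairs$concept_b, predictor = focal,
      beta = beta, se = se, p_perm = p, q = fdr$q,
      significant = fdr$significant,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, res)
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "scheme") <- scheme
  attr(out, "concepts") <- cohort$concepts
  attr(out, "n_used") <- n_used
  class(out) <- c("edgewise_result", "data.frame")
  out
}

#' Significant pairs of an edgewise screen
#'
#' @param results an `edgewise_result`.
#' @param predictor predictor name.
#' @return character vector of pair keys flagged significant.
#' @export
significant_pairs <- function(results, predictor) {
  tab <- results[results$predictor == predictor & results$significant, ]
  tab$pair
}
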