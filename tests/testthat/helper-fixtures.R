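# Small programmatic fixtures shared across test files.

# A 5-concept cohort written to CSV files in a temp dir; returns paths.
write_tiny_fixture <- function(dir = tempfile("fixture")) {
  dir.create(dir)
  concepts <- c("alpha", "beta", "gamma", "delta", "epsilon")
  pairs <- canonical_pair_index(concepts)
  ids <- c("p1", "p2", "p3")
  set.seed(42)
  ratings <- matrix(sample(-7:7, length(ids) * nrow(pairs), replace = TRUE),
                    nrow = length(ids),
                    dimnames = list(ids, pairs$pair))
  long <- data.frame(
    participant_id = rep(ids, each = nrow(pairs)),
    concept_a = rep(pairs$concept_a, length(ids)),
    concept_b = rep(pairs$concept_b, length(ids)),
    rating = as.integer(t(ratings)))
  demo <- data.frame(
    participant_id = ids,
    race = c("Black/African American", "White", "Black/African American"),
    gender = c("Female", "Male", "Female"),
    income_bracket = c(2, 5, 3),
    age = c(34, 51, 28),
    source1 = c("Outlet Left", "Outlet Right", "YouTube"),
    source2 = c("Outlet Center", "Outlet Right-ish", "Reddit"),
    source3 = c("outlet left", NA, ""))
  bias <- data.frame(
    source = c("Outlet Left", "Outlet Center", "Outlet Right",
               "Outlet Right-ish"),
    bias = c(1, 3, 5, 4))
  paths <- list(
    ratings = file.path(dir, "ratings.csv"),
    demographics = file.path(dir, "demographics.csv"),
    bias = file.path(dir, "bias.csv"),
    concepts = concepts, ratings_matrix = ratings)
  write.csv(long, paths$ratings, row.names = FALSE)
  write.csv(demo, paths$demographics, row.names = FALSE)
  write.csv(bias, paths$bias, row.names = FALSE)
  paths
}

# Random regression instance for OLS oracle checks.
random_glm_instance <- function(n, p, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  beta <- rnorm(p)
  y <- as.numeric(X %*% beta + rnorm(n))
  list(X = X, y = y, beta = beta)
}

# Brute-force normal-equation OLS used as an independent oracle.
ols_oracle <- function(y, X) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- as.numeric(xtx_inv %*% t(X) %*% y)
  res <- y - as.numeric(X %*% beta)
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  list(beta = beta, se = unname(sqrt(diag(xtx_inv) * sigma2)))
}

# Hand-rolled BH step-up used as an independent oracle.
bh_oracle_rejections <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  passed <- which(p[ord] <= seq_len(m) * alpha / m)
  if (!length(passed)) return(integer(0))
  sort(ord[seq_len(max(passed))])
}
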