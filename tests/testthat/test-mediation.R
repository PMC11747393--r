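test_that("path decomposition c = c' + a*b is exact on arbitrary data", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(30:150, 1)
    x <- rbinom(n, 1, 0.5)
    C <- cbind(g = rbinom(n, 1, 0.5), inc = rnorm(n))
    m <- 2 + 0.5 * x + rnorm(n)
    y <- 1 + rnorm(1) * x + rnorm(1) * m + rnorm(n)
    paths <- mediation_paths(x, m, y, covariates = C)
    expect_lt(abs(paths$c - paths$c_prime - paths$a * paths$b), 1e-10)
  }
  # planted b = 0 means indirect exactly 0
  set.seed(99)
  x <- rbinom(60, 1, 0.5)
  m <- 1 + x + rnorm(60)
  y_indep <- rep(3, 60) # constant outcome: all slopes 0
  paths0 <- mediation_paths(x, m, y_indep)
  expect_equal(paths0$b, 0, tolerance = 1e-12)
  expect_equal(paths0$indirect, 0, tolerance = 1e-12)
  expect_error(mediation_paths(x[1:10], m, y_indep), "equal length")
  expect_error(mediation_paths(x, replace(m, 1, NA), y_indep), "missing")
})

test_that("Sobel test matches the delta-method formula", {
  s <- sobel_test(0.5, 0.1, 0.4, 0.1)
  expect_equal(s$z, 0.2 / sqrt(0.0041), tolerance = 1e-10)
  expect_equal(round(s$z, 4), 3.1235)
  expect_equal(s$p, 2 * pnorm(-abs(s$z)))

  expect_equal(sobel_test(0, 0.1, 1, 0.1), list(z = 0, p = 1))
  expect_equal(sobel_test(0, 0.1, 0, 0.1), list(z = 0, p = 1))
  # sign of z follows sign of a*b
  expect_lt(sobel_test(-0.5, 0.1, 0.4, 0.1)$z, 0)
  expect_gt(sobel_test(-0.5, 0.1, -0.4, 0.1)$z, 0)
  expect_error(sobel_test(1, 0, 1, 0.1), "positive")
})

test_that("mediation permutation is seeded and detects strong mediation", {
  set.seed(5)
  n <- 400
  x <- rep(0:1, each = n / 2)
  m <- 2 - 0.5 * x + rnorm(n, sd = 0.5)
  y <- 0.3 - 1.5 * (m - mean(m)) + rnorm(n, sd = 1)
  p1 <- mediation_permutation(x, m, y, n_perm = 300, seed = 7)
  p2 <- mediation_permutation(x, m, y, n_perm = 300, seed = 7)
  expect_identical(p1, p2)
  expect_equal(p1$p, 1 / 301)
  expect_error(mediation_permutation(x, rep(1, n), y, n_perm = 300),
               "constant")
})

test_that("residual-scheme permutation is calibrated when b = 0 despite a != 0", {
  set.seed(17)
  n <- 150
  n_rep <- 150
  rej <- c(residual = 0, simple = 0)
  for (r in seq_len(n_rep)) {
    x <- rep(0:1, each = n / 2)
    m <- 2 - 0.5 * x + rnorm(n, sd = 0.6) # real a path
    y <- 1 + 1.2 * x + rnorm(n)           # direct effect only, b = 0
    for (sc in names(rej)) {
      p <- mediation_permutation(x, m, y, n_perm = 199, seed = r,
                                 scheme = sc)$p
      rej[sc] <- rej[sc] + (p <= 0.05)
    }
  }
  expect_lte(rej[["residual"]] / n_rep, 0.10)
  # the raw-mediator scheme is anti-conservative under this null
  expect_gt(rej[["simple"]], rej[["residual"]])
})

test_that("classification rules map q-values to labels", {
  expect_equal(classify_mediation(0.01, 0.30), "full")
  expect_equal(classify_mediation(0.01, 0.01), "partial")
  expect_equal(classify_mediation(0.30, 0.01), "unmediated")
  expect_equal(classify_mediation(0.01, 0.30, race_flag = FALSE),
               "not_race_differing")
  expect_equal(
    classify_mediation(c(0.01, 0.01, 0.5), c(0.3, 0.01, 0.01)),
    c("full", "partial", "unmediated"))
})

test_that("full mediation is recovered: c' near zero, indirect near planted", {
  co <- simulate_cohort(default_scenarios(seed = 23)$fully_mediated)
  truth <- attr(co, "truth")
  keys <- names(truth$b_path)[truth$b_path != 0]
  med <- run_mediation_screen(co, keys, n_perm = 500, seed = 23)
  # planted indirect on the weight scale: a * b / -14 (weights flip sign)
  planted_ind <- truth$a_path * truth$b_path[med$pair] / -14
  expect_true(all(abs(med$indirect - planted_ind) <
                    3 * sqrt(med$se_a^2 * med$b^2 + med$se_b^2 * med$a^2) +
                    0.2 * abs(planted_ind)))
  # direct effects vanish; most labels are full
  expect_true(all(abs(med$c_prime) < 4 * med$se_c_prime))
  expect_gte(mean(med$label == "full"), 0.8)
  expect_true(all(sign(med$sobel_z) == sign(med$indirect)))
})

test_that("screen handles empty sets and stays order-invariant", {
  co <- simulate_cohort(simulation_config(n_per_group = 30, seed = 3))
  med0 <- run_mediation_screen(co, character(0), n_perm = 200)
  expect_s3_class(med0, "mediation_result")
  expect_equal(nrow(med0), 0)

  keys <- co$pairs$pair[c(5, 17, 40)]
  m1 <- run_mediation_screen(co, keys, n_perm = 200, seed = 11)
  m2 <- run_mediation_screen(co, rev(keys), n_perm = 200, seed = 11)
  m2 <- m2[match(m1$pair, m2$pair), ]
  expect_equal(m1$p_indirect, m2$p_indirect)
  expect_equal(m1$label, m2$label)
  expect_error(run_mediation_screen(co, "nope|nah", n_perm = 200),
               "unknown pair")
})

test_that("strengthening the mediator path never demotes a mediated edge", {
  ranks <- c(unmediated = 0, partial = 1, full = 1)
  labels <- vapply(c(0.8, 1.6, 2.4, 3.2), function(b) {
    cfg <- simulation_config(
      n_per_group = 400, seed = 77,
      direct_effect = c("police|fear" = 1.5),
      b_path = c("police|fear" = -b),
      mediation_label = c("police|fear" = "partial"))
    co <- simulate_cohort(cfg)
    run_mediation_screen(co, "police|fear", n_perm = 300, seed = 77)$label
  }, character(1))
  expect_true(all(diff(ranks[labels]) >= 0))
})
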