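test_that("canonical pair index enumerates unordered pairs deterministically", {
  pairs16 <- canonical_pair_index(default_concepts())
  expect_equal(nrow(pairs16), 120)
  expect_identical(pairs16, canonical_pair_index(default_concepts()))

  expect_equal(nrow(canonical_pair_index(c("a", "b"))), 1)

  pairs5 <- canonical_pair_index(letters[1:5])
  expect_equal(nrow(pairs5), 10)
  expect_equal(pairs5$i[1], 1)
  expect_equal(pairs5$j[1], 2)
  # lexicographic in (i, j), each unordered pair exactly once
  keys <- pairs5$pair
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(pairs5$i < pairs5$j))
  expect_identical(order(pairs5$i, pairs5$j), seq_len(10L))

  expect_error(canonical_pair_index(c("a", "a", "b")), "duplicate")
  expect_error(canonical_pair_index("solo"), "at least 2")
})

test_that("news bias is the mean over scorable sources and NA when unscorable", {
  lk <- bias_lookup(c("Src A", "Src B", "Src C", "Src D"), c(1, 2, 3, 5))
  expect_equal(compute_news_bias(c("Src A", "Src B", "Src C"), lk), 2)
  expect_equal(compute_news_bias(rep("Src D", 3), lk), 5)
  # permutation invariance in the source list
  srcs <- c("Src C", "Src A", "Src D")
  expect_equal(compute_news_bias(srcs, lk),
               compute_news_bias(rev(srcs), lk))
  # case and whitespace normalization, no fuzzy matching
  expect_equal(compute_news_bias(c("  src   a ", "SRC B"), lk), 1.5)
  expect_true(is.na(compute_news_bias(c("YouTube", "Reddit"), lk)))
  expect_true(is.na(compute_news_bias(character(0), lk)))
  # strict policy: any unscorable source voids the score
  expect_true(is.na(compute_news_bias(c("Src A", "YouTube"), lk,
                                      require_all = TRUE)))
  expect_equal(compute_news_bias(c("Src A", "YouTube"), lk), 1)
  expect_error(bias_lookup(c("x", "X "), c(1, 2)), "duplicate")
  expect_error(bias_lookup("x", 6), "\\[1, 5\\]")
})

test_that("load_cohort validates, aligns, and logs exclusions", {
  fx <- write_tiny_fixture()
  co <- load_cohort(fx$ratings, fx$demographics, fx$bias,
                    concepts = fx$concepts)
  expect_s3_class(co, "concept_cohort")
  expect_equal(nrow(co$ratings), 3)
  expect_equal(unname(co$ratings), unname(fx$ratings_matrix))
  expect_equal(co$demographics$race, c(1, 0, 1))
  expect_equal(co$demographics$gender, c(1, 0, 1))
  # p1: mean(1, 3, 1) = 5/3; p2: mean(5, 4); p3 unscorable
  expect_equal(co$news_bias, c(5 / 3, 4.5, NA))
  expect_equal(co$exclusions$participant_id, "p3")

  # out-of-range rating names the row and pair
  raw <- read.csv(fx$ratings)
  raw$rating[raw$participant_id == "p2"][3] <- 9
  bad_path <- tempfile(fileext = ".csv")
  write.csv(raw, bad_path, row.names = FALSE)
  expect_error(load_cohort(bad_path, fx$demographics, fx$bias,
                           concepts = fx$concepts), "p2")

  # unknown concept label
  raw <- read.csv(fx$ratings)
  raw$concept_a[1] <- "zeta"
  write.csv(raw, bad_path, row.names = FALSE)
  expect_error(load_cohort(bad_path, fx$demographics, fx$bias,
                           concepts = fx$concepts), "zeta")

  # missing demographics row
  demo <- read.csv(fx$demographics)[-2, ]
  demo_path <- tempfile(fileext = ".csv")
  write.csv(demo, demo_path, row.names = FALSE)
  expect_error(load_cohort(fx$ratings, demo_path, fx$bias,
                           concepts = fx$concepts), "p2")
})

test_that("cohorts round-trip through the CSV interface bit-identically", {
  fx <- write_tiny_fixture()
  co <- load_cohort(fx$ratings, fx$demographics, fx$bias,
                    concepts = fx$concepts)
  dir2 <- tempfile("roundtrip")
  write_cohort(co, dir2)
  co2 <- load_cohort(file.path(dir2, "ratings.csv"),
                     file.path(dir2, "demographics.csv"),
                     file.path(dir2, "bias.csv"),
                     concepts = fx$concepts)
  expect_identical(co$ratings, co2$ratings)
  expect_equal(co$news_bias, co2$news_bias)
  expect_equal(co$demographics$race, co2$demographics$race)
  expect_equal(co$demographics$income, co2$demographics$income)

  # a simulated cohort survives the round trip too
  cfg <- simulation_config(n_per_group = 10, seed = 11)
  sim <- simulate_cohort(cfg)
  dir3 <- tempfile("roundtrip2")
  write_cohort(sim, dir3)
  sim2 <- load_cohort(file.path(dir3, "ratings.csv"),
                      file.path(dir3, "demographics.csv"),
                      file.path(dir3, "bias.csv"))
  expect_identical(sim$ratings, sim2$ratings)
  expect_equal(sim$news_bias, sim2$news_bias)
})

test_that("cohort constructor enforces invariants", {
  pairs <- canonical_pair_index(letters[1:3])
  ratings <- matrix(c(1L, -7L, 7L, 0L, 3L, -2L), 2, 3,
                    dimnames = list(c("a1", "a2"), pairs$pair))
  demo <- data.frame(participant_id = c("a1", "a2"), race = c(1, 0),
                     gender = c(0, 1), income = c(1, 2), age = c(30, 40))
  co <- concept_cohort(ratings, demo, c(2, NA), concepts = letters[1:3])
  expect_equal(sum(is.finite(co$news_bias)), 1)
  ratings_bad <- ratings; ratings_bad[1, 2] <- 8L
  expect_error(concept_cohort(ratings_bad, demo, c(2, NA),
                              concepts = letters[1:3]), "invalid rating")
  ratings_frac <- ratings; ratings_frac[1, 2] <- 2.5
  expect_error(concept_cohort(ratings_frac, demo, c(2, NA),
                              concepts = letters[1:3]), "invalid rating")
  demo_bad <- demo; demo_bad$race[1] <- 2
  expect_error(concept_cohort(ratings, demo_bad, c(2, NA),
                              concepts = letters[1:3]), "0/1")
})
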