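test_that("rating-to-weight map hits its endpoints and inverts exactly", {
  expect_equal(rating_to_edge_weight(7), 0)
  expect_equal(rating_to_edge_weight(-7), 1)
  expect_equal(rating_to_edge_weight(0), 0.5)
  s <- -7:7
  expect_equal(edge_weight_to_rating(rating_to_edge_weight(s)), s)
  e <- seq(0, 1, by = 0.05)
  expect_equal(rating_to_edge_weight(edge_weight_to_rating(e)), e)
  # strictly decreasing, affine
  w <- rating_to_edge_weight(s)
  expect_true(all(diff(w) < 0))
  expect_equal(unique(round(diff(w), 12)), -1 / 14)
  expect_error(rating_to_edge_weight(8), "out of range")
  expect_error(edge_weight_to_rating(1.2), "out of range")
  # alternative endpoints
  expect_equal(rating_to_edge_weight(3, r_min = 1, r_max = 5), 0.5)
  expect_error(rating_to_edge_weight(1, r_min = 2, r_max = 2), "r_min")
})

test_that("mean graph averages weights and is linear in participant subsets", {
  pairs <- canonical_pair_index(letters[1:4])
  w <- matrix(runif(6 * 6), 6, 6, dimnames = list(NULL, pairs$pair))
  g_all <- mean_graph(w, pairs)
  expect_equal(g_all$edges$weight, unname(colMeans(w)))

  # identical participants: graph equals any individual's weights
  w_same <- matrix(rep(w[1, ], each = 5), 5, 6)
  expect_equal(mean_graph(w_same, pairs)$edges$weight, unname(w[1, ]))

  # two participants at the extremes average to 0.5
  w2 <- rbind(rep(0, 6), rep(1, 6))
  expect_equal(mean_graph(w2, pairs)$edges$weight, rep(0.5, 6))

  # linearity: mean over a union is the size-weighted mean of subset means
  s1 <- 1:2; s2 <- 3:6
  m1 <- mean_graph(w, pairs, subset = s1)$edges$weight
  m2 <- mean_graph(w, pairs, subset = s2)$edges$weight
  expect_equal((2 * m1 + 4 * m2) / 6, g_all$edges$weight)
  expect_error(mean_graph(w, pairs, subset = integer(0)), "empty")
})

test_that("group mean weights differ by planted effect over the scale factor", {
  key <- "police|fear"
  # flat baseline keeps the planted effect away from the scale ends, so
  # rounding/clipping attenuation is negligible at this effect size
  cfg <- simulation_config(n_per_group = 4000, seed = 9, baseline = 0,
                           direct_effect = setNames(-2, key), a_path = 0)
  co <- simulate_cohort(cfg)
  g <- co$demographics$race
  j <- match(key, co$pairs$pair)
  w <- edge_weights(co)
  g1 <- mean_graph(w, co$pairs, subset = which(g == 1))
  g0 <- mean_graph(w, co$pairs, subset = which(g == 0))
  # rating effect -2 maps to +2/14 on the weight scale (weights invert
  # sign); clipping at the scale ends shaves a few percent off
  expect_lt(abs(g1$edges$weight[j] - g0$edges$weight[j] - 2 / 14), 0.01)
})

test_that("subgraph extraction keeps flagged edges with direction tags", {
  pairs <- canonical_pair_index(default_concepts())
  fake <- data.frame(
    pair = pairs$pair, concept_a = pairs$concept_a,
    concept_b = pairs$concept_b, predictor = "race",
    beta = 0, se = 1, p_perm = 1, q = 1, significant = FALSE)
  fake$beta[1:4] <- c(-0.1, 0.2, -0.3, 0.4)
  fake$q[1:4] <- 0.01
  fake$significant[1:4] <- TRUE
  attr(fake, "concepts") <- default_concepts()
  class(fake) <- c("edgewise_result", "data.frame")

  sg <- subgraph_from_flags(fake, "race")
  expect_equal(nrow(sg$edges), 4)
  # negative beta on the weight = stronger association for group 1
  expect_equal(sg$edges$direction, c(1, -1, 1, -1))

  fake$significant[] <- FALSE
  empty <- subgraph_from_flags(fake, "race")
  expect_equal(nrow(empty$edges), 0)
  expect_length(degree_centrality(empty), 0)
  expect_error(subgraph_from_flags(fake, "nope"), "no rows")
})

test_that("degree centrality normalizes by subgraph size and ignores labels", {
  # star-plus construction: node h connected to 9 others in a 15-node subgraph
  nodes <- paste0("n", 1:15)
  edges <- data.frame(
    concept_a = c(rep("n1", 9), "n11", "n13"),
    concept_b = c(nodes[2:10], "n12", "n14"),
    pair = paste(c(rep("n1", 9), "n11", "n13"),
                 c(nodes[2:10], "n12", "n14"), sep = "|"))
  # bring node 15 in with one more edge so all 15 nodes participate
  edges <- rbind(edges, data.frame(concept_a = "n15", concept_b = "n2",
                                   pair = "n15|n2"))
  g <- structure(list(concepts = c(nodes, "n16"), edges = edges,
                      n_participants = NA), class = "concept_graph")
  cent <- degree_centrality(g)
  expect_equal(unname(cent["n1"]), 9 / 14)
  expect_equal(round(cent[["n1"]], 2), 0.64)
  # full-set denominator option: 16 concepts -> 15
  cent_all <- degree_centrality(g, denominator = "all_nodes")
  expect_equal(unname(cent_all["n1"]), 9 / 15)

  # invariance under node relabeling
  perm <- sample(15)
  relabel <- setNames(nodes[perm], nodes)
  edges2 <- edges
  edges2$concept_a <- unname(relabel[edges$concept_a])
  edges2$concept_b <- unname(relabel[edges$concept_b])
  g2 <- structure(list(concepts = c(nodes, "n16"), edges = edges2,
                       n_participants = NA), class = "concept_graph")
  cent2 <- degree_centrality(g2)
  expect_equal(unname(cent2[relabel["n1"]]), unname(cent["n1"]))
  expect_equal(sort(unname(cent2)), sort(unname(cent)))

  # node connected to all others in a 15-node subgraph has centrality 1
  full_star <- data.frame(concept_a = "n1", concept_b = nodes[2:15],
                          pair = paste("n1", nodes[2:15], sep = "|"))
  g3 <- structure(list(concepts = nodes, edges = full_star,
                       n_participants = NA), class = "concept_graph")
  expect_equal(unname(degree_centrality(g3)["n1"]), 1)
})

test_that("graph exports write edge lists and GraphML", {
  pairs <- canonical_pair_index(letters[1:4])
  w <- matrix(runif(12), 2, 6, dimnames = list(NULL, pairs$pair))
  g <- mean_graph(w, pairs)
  csv <- tempfile(fileext = ".csv")
  gml <- tempfile(fileext = ".graphml")
  write_graph_files(g, csv_path = csv, graphml_path = gml)
  back <- read.csv(csv)
  expect_equal(back$weight, g$edges$weight)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(ig), 6)
  expect_equal(igraph::vcount(ig), 4)
})
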