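## Planted edge sets used by the scenario presets. The race-differing set
## contains 31 pairs over 15 of the 16 concepts (firefighter untouched),
## with hub degrees religion 9, conservatives 8, science 7, police 6 --
## the hub structure reported for race-differing subgraphs (centralities
## 9/14, 8/14, 7/14, 6/14 on a 15-node subgraph).
planted_edge_sets <- function() {
  full <- c("political conservatives|healthcare",
            "religion|anger",
            "religion|love")
  partial <- c(
    "political conservatives|religion", "political liberals|religion",
    "religion|science", "police|religion", "healthcare|religion",
    "voting|religion", "religion|trust",
    "political conservatives|political liberals",
    "political conservatives|science", "police|political conservatives",
    "political conservatives|immigration", "political conservatives|trust",
    "political conservatives|anger",
    "political liberals|science", "voting|science", "science|trust",
    "police|fear", "police|trust")
  unmediated <- c(
    "science|fear", "science|joy", "police|anger", "police|sadness",
    "political liberals|trust", "healthcare|voting", "voting|trust",
    "immigration|fear", "political liberals|anger", "your neighbors|trust")
  list(full = full, partial = partial, unmediated = unmediated,
       race = c(full, partial, unmediated))
}

## canonicalize a pair key regardless of the order the two labels were given
canonical_key <- function(keys, pairs) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  vapply(parts, function(p) {
    pos <- pair_position(pairs, p[1], p[2])
    pairs$pair[pos]
  }, character(1))
}

#' Configure a synthetic cohort
#'
#' Defines the generative model of the simulator. Each participant carries a
#' group indicator g (balanced 0/1, coded like racial identity with
#' Black = 1), covariates (gender, income bracket, age), three integer-scored
#' news sources on the 1..5 bias scale, and one latent rating per concept
#' pair:
#'
#'   latent = baseline + direct * g + b_path * (m - mean(m))
#'            + covariate terms + Normal(0, noise_sd)
#'
#' where m is the participant's mean source bias. Latent ratings are rounded
#' to the nearest integer and clipped to -7..+7, producing the discrete
#' 15-level marginal the entropy analysis assumes. The participant's three
#' source scores are integer draws around a latent partisan position
#' mu = mediator_mean + a_path * g, clipped to 1..5, so the mediator written
#' to disk (mean of three integer scores) round-trips exactly through the
#' CSV interface.
#'
#' @param n_per_group participants per group (total n = 2 * n_per_group).
#' @param seed root seed for the generator.
#' @param concepts concept labels.
#' @param direct_effect named numeric: planted direct group effect per pair,
#'   in rating-scale units (names are `"a|b"` pair keys). Unnamed pairs get 0.
#' @param b_path named numeric: mediator-to-rating slope per pair (rating
#'   units per bias unit). Unnamed pairs get 0.
#' @param mediation_label named character giving the planted truth per pair
#'   (`"partial"`, `"full"`, or `"news_only"`); used only for bookkeeping.
#' @param a_path group effect on latent partisan position (bias units;
#'   default -0.48, the Black-vs-white mean difference on the 5-point scale).
#' @param mediator_mean latent partisan position of the g = 0 group
#'   (default 2.52).
#' @param mediator_sd between-participant sd of the latent position
#'   (default 1.1).
#' @param source_sd within-participant sd across the three sources
#'   (default 0.7).
#' @param gender_effect,income_effect,age_effect covariate slopes per pair
#'   (scalar or named; income and age enter standardized; default 0).
#' @param noise_sd residual sd of the latent rating, scalar or named per
#'   pair (default 3).
#' @param baseline mean latent rating per pair; default an even spread from
#'   -3 to +5 across pairs, giving the between-pair dispersion real rating
#'   data show.
#' @param p_unscorable probability that a participant lists only
#'   algorithm-driven (unscorable) sources; their news bias is missing.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = 223, seed = 1,
                              concepts = default_concepts(),
                              direct_effect = NULL, b_path = NULL,
                              mediation_label = NULL,
                              a_path = -0.48, mediator_mean = 2.52,
                              mediator_sd = 1.1, source_sd = 0.7,
                              gender_effect = 0, income_effect = 0,
                              age_effect = 0,
                              noise_sd = 3,
                              baseline = NULL,
                              p_unscorable = 0) {
  pairs <- canonical_pair_index(concepts)
  P <- nrow(pairs)
  expand <- function(x, default = 0) {
    out <- rep(as.numeric(default), P)
    names(out) <- pairs$pair
    if (is.null(x)) return(out)
    if (is.null(names(x))) {
      if (length(x) == 1) return(stats::setNames(rep(x, P), pairs$pair))
      if (length(x) == P) return(stats::setNames(as.numeric(x), pairs$pair))
      stopf("per-pair parameter must be scalar, length-%d, or named", P)
    }
    keys <- canonical_key(names(x), pairs)
    out[keys] <- as.numeric(x)
    out
  }
  cfg <- list(
    n_per_group = as.integer(n_per_group), seed = as.integer(seed),
    concepts = concepts, pairs = pairs,
    direct_effect = expand(direct_effect),
    b_path = expand(b_path),
    mediation_label = {
      lab <- rep("none", P); names(lab) <- pairs$pair
      if (!is.null(mediation_label))
        lab[canonical_key(names(mediation_label), pairs)] <-
          as.character(mediation_label)
      lab
    },
    a_path = a_path, mediator_mean = mediator_mean,
    mediator_sd = mediator_sd, source_sd = source_sd,
    gender_effect = expand(gender_effect),
    income_effect = expand(income_effect),
    age_effect = expand(age_effect),
    noise_sd = expand(noise_sd, default = noise_sd[1]),
    baseline = if (is.null(baseline)) {
      stats::setNames(seq(-3, 5, length.out = P), pairs$pair)
    } else expand(baseline),
    p_unscorable = p_unscorable)
  if (cfg$n_per_group < 2) stopf("n_per_group must be >= 2")
  if (any(cfg$noise_sd <= 0)) stopf("noise_sd must be > 0")
  full <- cfg$mediation_label == "full"
  if (any(full & cfg$direct_effect != 0))
    stopf("fully mediated pairs must have direct effect exactly 0")
  if (any(cfg$mediation_label == "partial" &
            (cfg$direct_effect == 0 | cfg$b_path == 0)))
    stopf("partially mediated pairs need both a direct effect and a b path")
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d x 2 participants, %d pairs, seed %d\n",
    x$n_per_group, nrow(x$pairs), x$seed))
  cat(sprintf("  planted: %d direct, %d mediated (%d partial, %d full), %d news-only\n",
              sum(x$direct_effect != 0),
              sum(x$mediation_label %in% c("partial", "full")),
              sum(x$mediation_label == "partial"),
              sum(x$mediation_label == "full"),
              sum(x$mediation_label == "news_only")))
  invisible(x)
}

## source names used for synthetic data; scores 1..5
synthetic_sources <- function() {
  c("synthetic left outlet", "synthetic left-leaning outlet",
    "synthetic center outlet", "synthetic right-leaning outlet",
    "synthetic right outlet")
}

#' Simulate a cohort
#'
#' Draws a cohort from the generative model described in
#' [simulation_config()]. Reproducible: the same config (including its seed)
#' yields a bit-identical cohort. The planted truth (per-pair direct
#' effects, b paths, and mediation labels) is attached as attribute
#' `"truth"` for parameter-recovery studies.
#'
#' @param config a [simulation_config()].
#' @param seed optional override of `config$seed`.
#' @return a [concept_cohort()].
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- seed %||% config$seed
  if (all(config$direct_effect == 0) && all(config$b_path == 0) &&
        config$a_path == 0)
    message("note: degenerate config with no planted effects (null scenario)")
  set.seed(substream_seed(seed, "simulate"))
  n <- 2L * config$n_per_group
  P <- nrow(config$pairs)
  g <- rep(c(0, 1), each = config$n_per_group)
  ids <- sprintf("S%05d", seq_len(n))

  gender <- stats::rbinom(n, 1, 0.5)
  income <- sample(1:8, n, replace = TRUE,
                   prob = c(1, 2, 3, 3, 2.5, 2, 1.5, 1))
  age <- pmin(pmax(round(stats::rnorm(n, 45, 13)), 18), 90)

  ## three integer-scored sources around a latent partisan position
  latent_pos <- config$mediator_mean + config$a_path * g +
    stats::rnorm(n, 0, config$mediator_sd)
  scores <- matrix(
    pmin(pmax(round(latent_pos + stats::rnorm(3L * n, 0, config$source_sd)),
              1), 5),
    nrow = n, ncol = 3)
  m <- rowMeans(scores)
  unscorable <- stats::runif(n) < config$p_unscorable
  mc <- m - mean(m)
  inc_z <- as.numeric(scale(income))
  age_z <- as.numeric(scale(age))

  latent <- matrix(config$baseline, n, P, byrow = TRUE) +
    outer(g, config$direct_effect) +
    outer(mc, config$b_path) +
    outer(gender, config$gender_effect) +
    outer(inc_z, config$income_effect) +
    outer(age_z, config$age_effect) +
    matrix(stats::rnorm(n * P), n, P) *
      matrix(config$noise_sd, n, P, byrow = TRUE)
  ratings <- pmin(pmax(round(latent), RATING_MIN), RATING_MAX)
  rownames(ratings) <- ids

  src_names <- synthetic_sources()
  sources <- matrix(src_names[scores], n, 3)
  sources[unscorable, ] <- "algorithmic feed"
  news_bias <- m
  news_bias[unscorable] <- NA_real_

  demo <- data.frame(
    participant_id = ids, race = g, gender = gender,
    income = income, age = age,
    source1 = sources[, 1], source2 = sources[, 2], source3 = sources[, 3],
    stringsAsFactors = FALSE)
  excl <- data.frame(
    participant_id = ids[unscorable],
    reason = rep("no scorable news sources", sum(unscorable)),
    stringsAsFactors = FALSE)
  cohort <- concept_cohort(
    ratings, demo, news_bias, concepts = config$concepts,
    bias_table = bias_lookup(src_names, 1:5),
    exclusions = excl)
  attr(cohort, "truth") <- list(
    direct_effect = config$direct_effect, b_path = config$b_path,
    mediation_label = config$mediation_label, a_path = config$a_path)
  cohort
}

#' Scenario presets
#'
#' Named simulation configs covering the study conditions the analysis is
#' exercised under:
#' \describe{
#'   \item{null}{no planted effects anywhere; calibration runs.}
#'   \item{race_only}{direct group effects of 1.5 rating units
#'     (d = 0.5 at noise sd 3) on the 31-pair race set; no mediation.}
#'   \item{fully_mediated}{10 pairs with direct effect 0 and a strong
#'     mediator path (all group signal flows through news bias).}
#'   \item{partially_mediated}{10 pairs carrying both a direct effect and a
#'     mediator path.}
#'   \item{paper_like}{the full planted structure: 446 participants
#'     (223 per group), 31 race-differing pairs of which 18 are partially
#'     and 3 fully mediated, plus 23 news-only pairs (44 news-affected
#'     pairs in total), group-to-mediator path -0.48 bias points.}
#'   \item{entropy_gradient}{no group effects; per-pair noise sd rises from
#'     0.7 to 3.5 across pairs and the news-bias slope rises stepwise with
#'     it, so effect magnitude is an increasing function of planted
#'     response entropy.}
#' }
#'
#' @param n_per_group participants per group (default 223, the analyzed
#'   sample size of 446).
#' @param seed root seed stored in each config.
#' @return named list of [simulation_config()] objects.
#' @export
default_scenarios <- function(n_per_group = 223, seed = 1) {
  sets <- planted_edge_sets()
  pairs <- canonical_pair_index(default_concepts())
  alt <- function(keys, size) # alternating signs, deterministic
    stats::setNames(size * rep_len(c(1, -1), length(keys)), keys)

  direct_paper <- alt(c(sets$partial, sets$unmediated), 1.5)
  b_paper <- c(alt(sets$partial, -1.2), alt(sets$full, -3.0))
  news_only <- setdiff(
    pairs$pair[pairs$concept_a != "firefighter" &
                 pairs$concept_b != "firefighter"],
    sets$race)[1:23]
  b_paper <- c(b_paper, alt(news_only, 0.6))
  label_paper <- c(
    stats::setNames(rep("partial", length(sets$partial)), sets$partial),
    stats::setNames(rep("full", length(sets$full)), sets$full),
    stats::setNames(rep("news_only", length(news_only)), news_only))

  med10 <- sets$partial[1:10]
  quart <- rep(1:4, each = 30)
  ## noise and news slope rise together across pairs; kept inside the range
  ## where discretized-rating entropy is still increasing in total sd
  ## (heavy clipping at the scale ends would otherwise bend it back down)
  noise_grad <- stats::setNames(seq(0.5, 2.2, length.out = 120), pairs$pair)
  b_grad <- stats::setNames(c(0, 0.5, 1.0, 1.5)[quart] *
                              rep_len(c(1, -1), 120), pairs$pair)

  list(
    null = simulation_config(n_per_group = n_per_group, seed = seed,
                             a_path = 0),
    race_only = simulation_config(
      n_per_group = n_per_group, seed = seed,
      direct_effect = alt(sets$race, 1.5)),
    fully_mediated = simulation_config(
      n_per_group = n_per_group, seed = seed,
      b_path = alt(med10, -3.0),
      mediation_label = stats::setNames(rep("full", 10), med10)),
    partially_mediated = simulation_config(
      n_per_group = n_per_group, seed = seed,
      direct_effect = alt(med10, 1.5),
      b_path = alt(med10, -1.2),
      mediation_label = stats::setNames(rep("partial", 10), med10)),
    paper_like = simulation_config(
      n_per_group = n_per_group, seed = seed,
      direct_effect = direct_paper,
      b_path = b_paper,
      mediation_label = label_paper),
    entropy_gradient = simulation_config(
      n_per_group = n_per_group, seed = seed,
      b_path = b_grad, noise_sd = noise_grad,
      mediation_label = stats::setNames(
        rep("news_only", sum(b_grad != 0)), names(b_grad)[b_grad != 0]))
  )
}
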