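#' Default socioenvironmental concept set
#'
#' The sixteen concepts of the pairwise rating task: ten socioenvironmental
#' concepts (police, firefighter, your neighbors, political conservatives,
#' political liberals, healthcare, voting, immigration, religion, science)
#' and six attitude concepts reflecting primitive emotions (anger, fear,
#' joy, love, sadness, trust).
#'
#' @return character vector of 16 concept labels, in canonical order.
#' @export
default_concepts <- function() {
  c("police", "firefighter", "your neighbors", "political conservatives",
    "political liberals", "healthcare", "voting", "immigration",
    "religion", "science", "anger", "fear", "joy", "love", "sadness",
    "trust")
}

validate_concepts <- function(concepts) {
  if (!is.character(concepts) || length(concepts) < 2)
    stopf("need at least 2 concept labels, got %d", length(concepts))
  dup <- concepts[duplicated(concepts)]
  if (length(dup))
    stopf("duplicate concept labels: %s", paste(unique(dup), collapse = ", "))
  concepts
}

#' Canonical concept-pair index
#'
#' Enumerates all unordered concept pairs (i, j) with i < j in lexicographic
#' order over the stated concept order, the ordering used for the columns of
#' every rating and edge-weight matrix. For n concepts there are
#' n(n-1)/2 pairs; the default 16 concepts give 120.
#'
#' @param concepts character vector of unique concept labels.
#' @return a data frame of class `pair_index` with columns `i`, `j`
#'   (1-based concept indices, i < j), `concept_a`, `concept_b`, and `pair`
#'   (the key `"a|b"`); row order is the canonical column order.
#' @examples
#' nrow(canonical_pair_index(default_concepts())) # 120
#' @export
canonical_pair_index <- function(concepts = default_concepts()) {
  concepts <- validate_concepts(concepts)
  n <- length(concepts)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n),
              use.names = FALSE)
  out <- data.frame(
    i = i, j = j,
    concept_a = concepts[i], concept_b = concepts[j],
    pair = paste(concepts[i], concepts[j], sep = "|"),
    stringsAsFactors = FALSE
  )
  attr(out, "concepts") <- concepts
  class(out) <- c("pair_index", "data.frame")
  out
}

#' Position of a pair in the canonical index
#'
#' @param pairs a `pair_index`.
#' @param concept_a,concept_b concept labels (order-insensitive).
#' @return integer column positions.
#' @export
pair_position <- function(pairs, concept_a, concept_b) {
  key1 <- paste(concept_a, concept_b, sep = "|")
  key2 <- paste(concept_b, concept_a, sep = "|")
  pos <- match(key1, pairs$pair)
  pos2 <- match(key2, pairs$pair)
  pos[is.na(pos)] <- pos2[is.na(pos)]
  if (anyNA(pos))
    stopf("unknown concept pair(s): %s",
          paste(key1[is.na(pos)], collapse = ", "))
  pos
}

#' Mean news bias of a participant's sources
#'
#' Each source is scored on the 5-point partisan bias scale (Left = 1,
#' Left-leaning = 2, Center = 3, Right-leaning = 4, Right = 5); a
#' participant's news bias is the arithmetic mean over their listed sources.
#' Sources absent from the lookup (typically algorithm-driven platforms that
#' carry no fixed editorial bias) cannot be scored; a participant with no
#' scorable source gets `NA` and is excluded from news-based analyses.
#'
#' @param sources character vector of source names (NA/empty entries dropped).
#' @param lookup named numeric vector mapping normalized source name to bias
#'   score in 1..5, as returned by [load_bias_lookup()].
#' @param require_all if `TRUE`, participants with any unscorable source are
#'   marked missing instead of averaging the scorable subset.
#' @return mean bias score, or `NA_real_` if unscorable.
#' @examples
#' lk <- c("outlet a" = 1, "outlet b" = 2, "outlet c" = 3)
#' compute_news_bias(c("Outlet A", "outlet b", "OUTLET C"), lk) # 2
#' @export
compute_news_bias <- function(sources, lookup, require_all = FALSE) {
  sources <- sources[!is.na(sources) & nzchar(trimws(sources))]
  if (!length(sources)) return(NA_real_)
  scores <- lookup[normalize_source(sources)]
  if (require_all && anyNA(scores)) return(NA_real_)
  scores <- scores[!is.na(scores)]
  if (!length(scores)) return(NA_real_)
  mean(scores)
}

#' Read a news-bias lookup table
#'
#' @param path CSV with columns `source`, `bias` (bias in 1..5).
#' @return named numeric vector keyed by normalized source name.
#' @export
load_bias_lookup <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source", "bias") %in% names(tab)))
    stopf("bias table must have columns 'source' and 'bias'")
  bias_lookup(tab$source, tab$bias)
}

#' Construct a news-bias lookup
#'
#' @param source character source names.
#' @param bias numeric scores on the 5-point scale.
#' @return named numeric vector keyed by normalized source name.
#' @export
bias_lookup <- function(source, bias) {
  if (any(!is.finite(bias)) || any(bias < 1 | bias > 5))
    stopf("bias scores must lie in [1, 5]")
  nm <- normalize_source(source)
  if (anyDuplicated(nm))
    stopf("duplicate source names after normalization: %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  stats::setNames(as.numeric(bias), nm)
}

validate_ratings <- function(values, where = "ratings") {
  bad <- which(!is.finite(values) | values != round(values) |
                 values < RATING_MIN | values > RATING_MAX)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(values))
    stopf(
      "%s: invalid rating %s for participant '%s', pair '%s' (must be an integer in [%d, %d])",
      where, format(values[bad[1]]),
      rownames(values)[rc[1]] %||% rc[1],
      colnames(values)[rc[2]] %||% rc[2],
      RATING_MIN, RATING_MAX)
  }
  invisible(values)
}

#' Assemble a cohort object
#'
#' A cohort bundles the rating matrix with row-aligned demographics and
#' per-participant news-bias scores. Demographic indicators follow the dummy
#' coding of the analysis: `race` = 1 for Black/African American
#' participants, 0 for white participants; `gender` = 1 for women, 0 for
#' men; `income` is an ordinal bracket rank; `age` in years.
#'
#' @param ratings integer matrix, participants x pairs, values in -7..+7;
#'   row names are participant ids.
#' @param demographics data frame with columns `participant_id`, `race`,
#'   `gender`, `income`, `age` (and optionally `source1..source3`).
#' @param news_bias numeric vector of mean bias scores (NA = unscorable).
#' @param concepts concept labels; `pairs` is derived from them.
#' @param bias_table optional named numeric lookup retained so the cohort
#'   can be written back to disk.
#' @param exclusions optional data frame logging excluded participants and
#'   reasons.
#' @return an object of class `concept_cohort`.
#' @export
concept_cohort <- function(ratings, demographics, news_bias,
                           concepts = default_concepts(),
                           bias_table = NULL, exclusions = NULL) {
  pairs <- canonical_pair_index(concepts)
  ratings <- as.matrix(ratings)
  storage.mode(ratings) <- "double"
  if (ncol(ratings) != nrow(pairs))
    stopf("ratings have %d columns but the concept set implies %d pairs",
          ncol(ratings), nrow(pairs))
  colnames(ratings) <- pairs$pair
  validate_ratings(ratings)
  storage.mode(ratings) <- "integer"
  n <- nrow(ratings)
  if (nrow(demographics) != n)
    stopf("demographics rows (%d) do not match rating rows (%d)",
          nrow(demographics), n)
  if (length(news_bias) != n)
    stopf("news_bias length (%d) does not match rating rows (%d)",
          length(news_bias), n)
  need <- c("participant_id", "race", "gender", "income", "age")
  miss <- setdiff(need, names(demographics))
  if (length(miss))
    stopf("demographics missing column(s): %s", paste(miss, collapse = ", "))
  if (!is.null(rownames(ratings)) &&
      !identical(as.character(demographics$participant_id),
                 rownames(ratings)))
    stopf("participant ids of ratings and demographics are not row-aligned")
  rownames(ratings) <- as.character(demographics$participant_id)
  for (v in c("race", "gender")) {
    x <- demographics[[v]]
    if (any(!is.na(x) & !(x %in% c(0, 1))))
      stopf("demographics$%s must be a 0/1 indicator", v)
  }
  if (any(!is.na(demographics$income) & demographics$income < 0))
    stopf("income bracket rank must be >= 0")
  if (any(!is.na(demographics$age) & demographics$age <= 0))
    stopf("age must be positive")
  ok <- is.finite(news_bias)
  if (any(news_bias[ok] < 1 | news_bias[ok] > 5))
    stopf("news_bias scores must lie in [1, 5]")
  structure(
    list(ratings = ratings,
         demographics = demographics,
         news_bias = as.numeric(news_bias),
         concepts = concepts,
         pairs = pairs,
         bias_table = bias_table,
         exclusions = exclusions %||%
           data.frame(participant_id = character(), reason = character(),
                      stringsAsFactors = FALSE)),
    class = "concept_cohort")
}

#' @export
print.concept_cohort <- function(x, ...) {
  cat(sprintf("Concept cohort: %d participants, %d concepts, %d pairs\n",
              nrow(x$ratings), length(x$concepts), nrow(x$pairs)))
  cat(sprintf("  news bias defined for %d participants (mean %.2f)\n",
              sum(is.finite(x$news_bias)),
              mean(x$news_bias, na.rm = TRUE)))
  if (nrow(x$exclusions))
    cat(sprintf("  %d exclusion notes logged\n", nrow(x$exclusions)))
  invisible(x)
}

## Coerce textual race/gender codes to the analysis dummy coding.
code_indicator <- function(x, one_patterns, what) {
  if (is.numeric(x)) {
    if (any(!is.na(x) & !(x %in% c(0, 1))))
      stopf("numeric %s codes must be 0/1", what)
    return(as.numeric(x))
  }
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(lx))
  out[grepl(one_patterns[1], lx)] <- 1
  out[!is.na(lx) & nzchar(lx) & !grepl(one_patterns[1], lx)] <- 0
  out[lx %in% c("", "na")] <- NA_real_
  out
}

#' Load a cohort from CSV files
#'
#' Reads the three tables of the data model and assembles a validated,
#' row-aligned cohort. Ratings are accepted in long form
#' (`participant_id, concept_a, concept_b, rating`; canonical) or wide form
#' (one `a|b` column per pair). Race accepts 0/1 codes or labels (any label
#' containing "black" codes 1); gender accepts 0/1 or labels ("female"/
#' "woman" codes 1). Participants whose news sources cannot be scored are
#' retained with `NA` news bias and logged in the exclusion table.
#'
#' @param ratings_path,demographics_path,bias_path CSV paths.
#' @param concepts concept labels defining the pair index.
#' @param require_three_sources if `TRUE`, a participant's bias is defined
#'   only when all listed sources are scorable (strict exclusion policy).
#' @return a [concept_cohort()].
#' @export
load_cohort <- function(ratings_path, demographics_path, bias_path,
                        concepts = default_concepts(),
                        require_three_sources = FALSE) {
  pairs <- canonical_pair_index(concepts)
  lookup <- load_bias_lookup(bias_path)
  demo <- utils::read.csv(demographics_path, stringsAsFactors = FALSE)
  need <- c("participant_id", "race", "gender", "income_bracket", "age")
  miss <- setdiff(need, names(demo))
  if (length(miss))
    stopf("demographics file missing column(s): %s",
          paste(miss, collapse = ", "))
  demo$participant_id <- as.character(demo$participant_id)
  if (anyDuplicated(demo$participant_id))
    stopf("duplicate participant_id in demographics: %s",
          demo$participant_id[duplicated(demo$participant_id)][1])

  raw <- utils::read.csv(ratings_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  long <- all(c("participant_id", "concept_a", "concept_b", "rating") %in%
                names(raw))
  if (long) {
    unknown <- setdiff(unique(c(raw$concept_a, raw$concept_b)), concepts)
    if (length(unknown))
      stopf("unknown concept label(s) in ratings: %s",
            paste(unknown, collapse = ", "))
    ids <- unique(as.character(raw$participant_id))
    pos <- pair_position(pairs, raw$concept_a, raw$concept_b)
    rmat <- matrix(NA_real_, length(ids), nrow(pairs),
                   dimnames = list(ids, pairs$pair))
    idx <- cbind(match(as.character(raw$participant_id), ids), pos)
    if (anyDuplicated(idx))
      stopf("duplicate rating rows for participant '%s'",
            ids[idx[duplicated(idx), 1][1]])
    rmat[idx] <- raw$rating
    if (anyNA(rmat)) {
      bad <- which(is.na(rmat), arr.ind = TRUE)[1, ]
      stopf("participant '%s' is missing a rating for pair '%s'",
            ids[bad[1]], pairs$pair[bad[2]])
    }
  } else {
    if (!"participant_id" %in% names(raw))
      stopf("ratings file must be long form or wide form with a participant_id column")
    ids <- as.character(raw$participant_id)
    cols <- setdiff(names(raw), "participant_id")
    missp <- setdiff(pairs$pair, cols)
    if (length(missp))
      stopf("wide ratings file missing pair column(s): %s",
            paste(utils::head(missp, 3), collapse = ", "))
    rmat <- as.matrix(raw[, pairs$pair, drop = FALSE])
    rownames(rmat) <- ids
  }
  validate_ratings(rmat, where = basename(ratings_path))

  missing_ids <- setdiff(rownames(rmat), demo$participant_id)
  if (length(missing_ids))
    stopf("participant '%s' has ratings but no demographics row",
          missing_ids[1])
  demo <- demo[match(rownames(rmat), demo$participant_id), , drop = FALSE]

  src_cols <- grep("^source[0-9]+$", names(demo), value = TRUE)
  news_bias <- vapply(seq_len(nrow(demo)), function(r) {
    compute_news_bias(unlist(demo[r, src_cols], use.names = FALSE), lookup,
                      require_all = require_three_sources)
  }, numeric(1))

  excl <- data.frame(
    participant_id = demo$participant_id[!is.finite(news_bias)],
    reason = rep("no scorable news sources", sum(!is.finite(news_bias))),
    stringsAsFactors = FALSE)
  demo_out <- data.frame(
    participant_id = demo$participant_id,
    race = code_indicator(demo$race, "black", "race"),
    gender = code_indicator(demo$gender, "female|woman", "gender"),
    income = as.numeric(demo$income_bracket),
    age = as.numeric(demo$age),
    stringsAsFactors = FALSE)
  for (sc in src_cols) demo_out[[sc]] <- demo[[sc]]

  concept_cohort(rmat, demo_out, news_bias, concepts = concepts,
                 bias_table = lookup, exclusions = excl)
}

#' Write a cohort back to the three CSV files
#'
#' Inverse of [load_cohort()]: writes `ratings.csv` (long form),
#' `demographics.csv`, and `bias.csv` in deterministic column and row order.
#'
#' @param cohort a [concept_cohort()] with a `bias_table`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- cohort$pairs
  n <- nrow(cohort$ratings)
  long <- data.frame(
    participant_id = rep(rownames(cohort$ratings), each = nrow(pr)),
    concept_a = rep(pr$concept_a, n),
    concept_b = rep(pr$concept_b, n),
    rating = as.integer(t(cohort$ratings)),
    stringsAsFactors = FALSE)
  demo <- cohort$demographics
  names(demo)[names(demo) == "income"] <- "income_bracket"
  paths <- file.path(dir, c("ratings.csv", "demographics.csv", "bias.csv"))
  utils::write.csv(long, paths[1], row.names = FALSE, quote = TRUE)
  utils::write.csv(demo, paths[2], row.names = FALSE, quote = TRUE)
  if (is.null(cohort$bias_table))
    stopf("cohort carries no bias table; cannot write bias.csv")
  utils::write.csv(
    data.frame(source = names(cohort$bias_table),
               bias = as.numeric(cohort$bias_table)),
    paths[3], row.names = FALSE, quote = TRUE)
  invisible(paths)
}
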