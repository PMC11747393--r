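#' Configure a full pipeline run
#'
#' Validates and freezes everything a pipeline run depends on. Input is
#' either a scenario name (simulated cohort) or the three CSV paths of the
#' data model. `n_perm` defaults to 1000, a reduced setting that keeps
#' desk-scale runs in minutes; pass 10000 for full-resolution inference.
#'
#' @param scenario name of a [default_scenarios()] preset, or `NULL` when
#'   loading CSVs.
#' @param ratings_path,demographics_path,bias_path input CSVs (used when
#'   `scenario` is `NULL`).
#' @param out_dir output directory (`NULL` = do not write files).
#' @param n_perm permutations per test.
#' @param alpha FDR level.
#' @param seed root seed; every stage derives its own substream from it.
#' @param scheme permutation scheme for the edgewise screen.
#' @param n_per_group cohort size per group for simulated scenarios.
#' @param n_splits reliability splits.
#' @param stages character subset of
#'   `c("reliability", "edgewise", "entropy", "mediation")`.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, ratings_path = NULL,
                            demographics_path = NULL, bias_path = NULL,
                            out_dir = NULL, n_perm = 1000, alpha = 0.05,
                            seed = 1, scheme = "simple", n_per_group = 223,
                            n_splits = 500,
                            stages = c("reliability", "edgewise", "entropy",
                                       "mediation")) {
  if (is.null(scenario) &&
        (is.null(ratings_path) || is.null(demographics_path) ||
           is.null(bias_path)))
    stopf("provide either a scenario name or all three input CSV paths")
  if (!is.null(scenario) &&
        !scenario %in% names(default_scenarios(n_per_group = 2)))
    stopf("unknown scenario '%s'", scenario)
  bad <- setdiff(stages, c("reliability", "edgewise", "entropy", "mediation"))
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (n_perm < 100) stopf("n_perm must be >= 100")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  structure(list(scenario = scenario, ratings_path = ratings_path,
                 demographics_path = demographics_path,
                 bias_path = bias_path, out_dir = out_dir,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed), scheme = scheme,
                 n_per_group = as.integer(n_per_group),
                 n_splits = as.integer(n_splits), stages = stages),
            class = "pipeline_config")
}

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes load/simulate, split-half reliability, the edgewise permutation
#' GLM screen for race and news bias, subgraph extraction with degree
#' centrality, the entropy/offset-sigmoid analysis of news effects, and the
#' mediation screen over the detected race-differing edges. When
#' `config$out_dir` is set, writes the result tables (TSV/CSV), the
#' significant-race-edge subgraph, a deterministic `summary.json`, and an
#' echo of the configuration. Identical configs (including the seed)
#' produce byte-identical summaries.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `cohort`, `reliability`, `edgewise`,
#'   `race_subgraph`, `centrality`, `entropy`, `mediation`, and `summary`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$scenario)) {
    cfg <- default_scenarios(n_per_group = config$n_per_group,
                             seed = config$seed)[[config$scenario]]
    simulate_cohort(cfg)
  } else {
    load_cohort(config$ratings_path, config$demographics_path,
                config$bias_path)
  }
  message(sprintf("pipeline: cohort of %d participants (%d with news bias)",
                  nrow(cohort$ratings), sum(is.finite(cohort$news_bias))))

  out <- list(cohort = cohort)
  summary <- list(
    n_participants = nrow(cohort$ratings),
    n_with_news_bias = sum(is.finite(cohort$news_bias)),
    seed = config$seed, n_perm = config$n_perm, alpha = config$alpha,
    scheme = config$scheme)

  if ("reliability" %in% config$stages) {
    out$reliability <- split_half_reliability(
      cohort, n_splits = config$n_splits,
      seed = substream_seed(config$seed, "reliability"))
    summary$reliability <- list(
      r_raw = out$reliability$r_raw,
      r_corrected = out$reliability$r_corrected,
      n_splits = out$reliability$n_splits)
  }

  if ("edgewise" %in% config$stages) {
    out$edgewise <- run_edgewise(
      cohort, predictors = c("race", "news_bias"),
      n_perm = config$n_perm, alpha = config$alpha,
      seed = config$seed, scheme = config$scheme)
    full_graph <- mean_graph(cohort)
    out$race_subgraph <- subgraph_from_flags(out$edgewise, "race",
                                             graph = full_graph)
    out$centrality <- degree_centrality(out$race_subgraph)
    summary$significant_edges <- list(
      race = sum(out$edgewise$significant[out$edgewise$predictor == "race"]),
      news_bias = sum(
        out$edgewise$significant[out$edgewise$predictor == "news_bias"]))
    summary$race_subgraph_nodes <- length(
      unique(c(out$race_subgraph$edges$concept_a,
               out$race_subgraph$edges$concept_b)))
    summary$centrality <- as.list(out$centrality)
  }

  if ("entropy" %in% config$stages) {
    if (is.null(out$edgewise))
      stopf("entropy stage requires the edgewise stage")
    out$entropy <- entropy_effect_analysis(
      out$edgewise, cohort,
      seed = substream_seed(config$seed, "sigmoid"))
    summary$sigmoid <- list(
      a = out$entropy$fit$a, b = out$entropy$fit$b, c = out$entropy$fit$c,
      r_squared = out$entropy$fit$r_squared,
      converged = out$entropy$fit$converged)
  }

  if ("mediation" %in% config$stages) {
    if (is.null(out$edgewise))
      stopf("mediation stage requires the edgewise stage")
    out$mediation <- run_mediation_screen(
      cohort, out$edgewise, n_perm = config$n_perm,
      alpha = config$alpha, seed = config$seed)
    labs <- table(factor(out$mediation$label,
                         levels = c("full", "partial", "unmediated")))
    summary$mediation <- list(
      n_screened = nrow(out$mediation),
      full = unname(labs["full"]), partial = unname(labs["partial"]),
      unmediated = unname(labs["unmediated"]))
  }

  out$summary <- summary

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$edgewise))
      write_tsv(out$edgewise, file.path(config$out_dir, "edgewise.tsv"))
    if (!is.null(out$mediation))
      write_tsv(out$mediation, file.path(config$out_dir, "mediation.tsv"))
    if (!is.null(out$entropy))
      write_tsv(out$entropy$table, file.path(config$out_dir, "entropy.tsv"))
    if (!is.null(out$race_subgraph))
      write_graph_files(out$race_subgraph,
                        csv_path = file.path(config$out_dir,
                                             "race_subgraph_edges.csv"))
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_echo <- unclass(config)
    jsonlite::write_json(cfg_echo[!vapply(cfg_echo, is.null, logical(1))],
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message(sprintf("pipeline: wrote outputs to %s", config$out_dir))
  }
  invisible(out)
}
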