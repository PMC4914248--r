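#' End-to-end correlation-cohort survival pipeline
#'
#' Runs the full analysis: read a series-matrix expression file, rank-transform
#' per sample, extract the target gene pair, greedily partition the cohort to
#' maximize the pair's positive correlation, and compare survival between the
#' two cohorts by Kaplan-Meier / log-rank. Writes a per-sample partition
#' report (`partition_report.tsv`), a machine-readable survival summary
#' (`survival_report.json`) and a reproducibility manifest (`manifest.json`)
#' into `output_dir`. All outputs are deterministic for fixed inputs and tie
#' rule: rerunning with the same configuration reproduces them byte for byte.
#'
#' @param expression_path Series-matrix expression file
#'   ([read_series_matrix()]).
#' @param survival_path Survival annotation file ([read_survival_table()]).
#' @param probe_a,probe_b Probe identifiers of the target pair.
#' @param output_dir Output directory; must be empty (or absent) unless
#'   `force = TRUE`.
#' @param min_cohort,tie_rule Passed to [greedy_partition()].
#' @param allow_missing Passed to [compare_partition_survival()].
#' @param force Allow writing into a nonempty `output_dir`.
#' @return Invisibly, a list with `partition` (the
#'   [greedy_partition()] result), `survival` (the
#'   [compare_partition_survival()] report), `pair` (the extracted
#'   [pair_profile()]) and `paths` of the written files.
#' @export
run_correlation_survival_pipeline <- function(expression_path, survival_path,
                                              probe_a, probe_b,
                                              output_dir,
                                              min_cohort = 3L,
                                              tie_rule = "lowest-index",
                                              allow_missing = FALSE,
                                              force = FALSE) {
  prepare_output_dir(output_dir, force)
  expr <- read_series_matrix(expression_path)
  surv <- read_survival_table(survival_path)
  ranks <- rank_transform(expr$matrix)
  pair <- extract_gene_pair(ranks, probe_a, probe_b)
  partition <- greedy_partition(pair, min_cohort = min_cohort,
                                tie_rule = tie_rule)
  comparison <- compare_partition_survival(partition, surv,
                                           allow_missing = allow_missing)

  paths <- list(
    partition_report = file.path(output_dir, "partition_report.tsv"),
    survival_report = file.path(output_dir, "survival_report.json"),
    manifest = file.path(output_dir, "manifest.json")
  )
  run_summary <- write_partition_report(partition, paths$partition_report)
  jsonlite::write_json(
    list(n = as.list(comparison$n),
         events = as.list(comparison$events),
         dropped = as.list(comparison$dropped),
         logrank_chisq = comparison$logrank$statistic,
         logrank_p = comparison$logrank$p_value,
         r_initial = partition$r_initial,
         r_final = partition$r_final,
         note = comparison$note),
    paths$survival_report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(paths$manifest,
                 inputs = list(expression = expression_path,
                               survival = survival_path),
                 parameters = list(probe_a = probe_a, probe_b = probe_b,
                                   min_cohort = min_cohort,
                                   tie_rule = tie_rule,
                                   allow_missing = allow_missing,
                                   samples_dropped_missing_pair = pair$n_dropped))
  invisible(list(partition = partition, survival = comparison, pair = pair,
                 paths = paths))
}

#' Two-group differential-expression pipeline
#'
#' Reads an expression matrix, runs [differential_expression()] between two
#' sample groups, applies [filter_hits()], and — when gene sets are supplied —
#' computes the [enrichment_odds_ratio()] of the hit list against each set
#' over the universe of all tested probes. Writes `de_report.tsv` (all
#' probes), `hits.tsv` (the filtered list), optionally `enrichment.tsv`, and
#' `manifest.json` into `output_dir`.
#'
#' @param expression_path Series-matrix expression file.
#' @param group_a,group_b Disjoint sample identifier vectors.
#' @param output_dir Output directory; must be empty (or absent) unless
#'   `force = TRUE`.
#' @param p_threshold,fc_threshold,use_adjusted Passed to [filter_hits()].
#' @param values Passed to [differential_expression()].
#' @param gene_set_path Optional plain-list or GMT file ([read_gene_sets()]).
#' @param force Allow writing into a nonempty `output_dir`.
#' @return Invisibly, a list with `records`, `hits`, `enrichment` (named list
#'   or `NULL`) and `paths`.
#' @export
run_de_pipeline <- function(expression_path, group_a, group_b, output_dir,
                            p_threshold = 0.05, fc_threshold = 2,
                            use_adjusted = TRUE, values = "log2",
                            gene_set_path = NULL, force = FALSE) {
  prepare_output_dir(output_dir, force)
  expr <- read_series_matrix(expression_path)
  records <- differential_expression(expr$matrix, group_a, group_b,
                                     values = values)
  hits <- filter_hits(records, p_threshold = p_threshold,
                      fc_threshold = fc_threshold,
                      use_adjusted = use_adjusted)
  paths <- list(de_report = file.path(output_dir, "de_report.tsv"),
                hits = file.path(output_dir, "hits.tsv"),
                manifest = file.path(output_dir, "manifest.json"))
  write_tsv_binary(records, paths$de_report)
  write_tsv_binary(hits, paths$hits)

  enrichment <- NULL
  if (!is.null(gene_set_path)) {
    sets <- read_gene_sets(gene_set_path)
    universe <- records$probe_id
    enrichment <- lapply(sets, function(members)
      enrichment_odds_ratio(hits$probe_id, intersect(members, universe),
                            universe))
    enr_df <- data.frame(
      gene_set = names(enrichment),
      set_size = vapply(sets, function(m) length(intersect(m, universe)),
                        numeric(1)),
      hits_in_set = vapply(enrichment, function(e) e$counts["in_set", "hit"],
                           numeric(1)),
      odds_ratio = vapply(enrichment, function(e) e$odds_ratio, numeric(1)),
      p_value = vapply(enrichment, function(e) e$p_value, numeric(1)),
      continuity_corrected = vapply(enrichment,
                                    function(e) e$continuity_corrected,
                                    logical(1)),
      stringsAsFactors = FALSE)
    paths$enrichment <- file.path(output_dir, "enrichment.tsv")
    write_tsv_binary(enr_df, paths$enrichment)
  }
  write_manifest(paths$manifest,
                 inputs = list(expression = expression_path,
                               gene_sets = gene_set_path),
                 parameters = list(group_a = group_a, group_b = group_b,
                                   p_threshold = p_threshold,
                                   fc_threshold = fc_threshold,
                                   use_adjusted = use_adjusted,
                                   values = values))
  invisible(list(records = records, hits = hits, enrichment = enrichment,
                 paths = paths))
}

prepare_output_dir <- function(output_dir, force) {
  if (dir.exists(output_dir)) {
    if (!force && length(list.files(output_dir, all.files = TRUE,
                                    no.. = TRUE)) > 0L)
      stop("output directory '", output_dir,
           "' is not empty; pass force = TRUE to overwrite", call. = FALSE)
  } else {
    dir.create(output_dir, recursive = TRUE)
  }
  invisible(output_dir)
}

# write.table through a binary connection so reports are byte-identical
# across platforms and reruns
write_tsv_binary <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(path, inputs, parameters) {
  jsonlite::write_json(
    list(inputs = inputs,
         parameters = parameters,
         package = list(name = "corcohort",
                        version = as.character(utils::packageVersion("corcohort"))),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
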