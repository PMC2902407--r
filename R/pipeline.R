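#' Configuration for a full pipeline run
#'
#' Collects every analysis toggle with defaults matching the package's
#' standard workflow: simulate (or read) a study, optionally pre-filter
#' all-censored assays, stratify and assess duplicate agreement, count well
#' failures, compute overall and stratified concordance, test
#' stratum-occupancy shifts with migration tables, and analyse sample
#' structure by clustering and PCA.
#'
#' @param simulate A [sim_config()] object describing the synthetic study,
#'   or `NULL` when reading data from files.
#' @param ct_path,metadata_path Input CSVs (long-dialect Ct table and sample
#'   metadata), used when `simulate` is `NULL`.
#' @param cutoffs A [stratum_cutoffs()] object.
#' @param aggregation Count aggregation for shift tests
#'   (see [stratum_counts()]).
#' @param censor_policy Censoring policy for correlations
#'   (see [ct_correlation()]).
#' @param linkage Clustering linkage (see [hierarchical_cluster()]).
#' @param prefilter Drop miR assays censored in every condition first?
#' @param comparisons Character subset of
#'   `c("duplicates", "concentration_series", "ffpe_vs_frozen")`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulate = sim_config(),
                       ct_path = NULL, metadata_path = NULL,
                       cutoffs = stratum_cutoffs(),
                       aggregation = c("per_sample_average", "mean_ct"),
                       censor_policy = c("exclude_any_40", "include"),
                       linkage = c("complete", "average", "single"),
                       prefilter = TRUE,
                       comparisons = c("duplicates", "concentration_series",
                                       "ffpe_vs_frozen")) {
  if (is.null(simulate) && (is.null(ct_path) || is.null(metadata_path))) {
    abort("either a sim_config or both input paths must be given")
  }
  structure(
    list(simulate = simulate, ct_path = ct_path,
         metadata_path = metadata_path, cutoffs = cutoffs,
         aggregation = match.arg(aggregation),
         censor_policy = match.arg(censor_policy),
         linkage = match.arg(linkage), prefilter = prefilter,
         comparisons = if (length(comparisons) == 0) character() else {
           match.arg(comparisons,
                     c("duplicates", "concentration_series",
                       "ffpe_vs_frozen"),
                     several.ok = TRUE)
         }),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Mirrors the arguments of [run_config()]; the `simulate` block, when
#' present, is passed to [sim_config()].
#'
#' @param path Path to a YAML configuration file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cut <- raw$cutoffs %||% list()
  args <- list(
    simulate = if (!is.null(raw$simulate)) do.call(sim_config, raw$simulate),
    ct_path = raw$ct_path, metadata_path = raw$metadata_path,
    cutoffs = stratum_cutoffs(cut$high_below %||% 30, cut$low_above %||% 35),
    prefilter = raw$prefilter %||% TRUE
  )
  for (key in c("aggregation", "censor_policy", "linkage", "comparisons")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  do.call(run_config, args)
}

write_stage <- function(x, out_dir, name, manifest_env) {
  path <- file.path(out_dir, name)
  readr::write_csv(x, path, progress = FALSE)
  manifest_env$files <- c(manifest_env$files, name)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: ingest or simulate, pre-filter, stratum map and
#' duplicate agreement (with the smoothing-spline fit), well-failure
#' summaries, overall and abundance-stratified concordance, shift chi-square
#' tests with migration tables, and hierarchical clustering plus PCA of the
#' clinical block. Each stage writes a CSV into `out_dir`; a `manifest.csv`
#' lists every file written and `run_log.txt` records the package version
#' and seed. The run is deterministic for a fixed config.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of all stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (!inherits(config, "run_config")) abort("'config' must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- new.env()
  manifest$files <- character()
  results <- list()

  # -- ingest or simulate -----------------------------------------------
  if (!is.null(config$simulate)) {
    study <- simulate_study(config$simulate)
    ct <- study$ct
    meta <- study$metadata
    results$study <- study
  } else {
    ct <- read_ct_table(config$ct_path, dialect = "long")
    meta <- read_sample_metadata(config$metadata_path)
    if (!"design" %in% names(meta)) meta$design <- NA_character_
  }
  if (config$prefilter) ct <- prefilter_all_censored(ct)
  results$ct <- ct
  results$metadata <- meta
  write_stage(meta, out_dir, "sample_metadata.csv", manifest)

  # -- stratification ----------------------------------------------------
  strat_map <- add_stratum(ct, config$cutoffs)
  results$stratum_map <- strat_map
  write_stage(strat_map, out_dir, "stratum_map.csv", manifest)

  titration <- meta |> filter(design %in% "titration")
  dup_pairs <- titration |>
    summarise(n_reps = n(), .by = input_rna_conc) |>
    filter(n_reps >= 2)
  if ("duplicates" %in% config$comparisons && nrow(dup_pairs) > 0) {
    agreement <- purrr::map(dup_pairs$input_rna_conc, function(conc) {
      conds <- titration |> filter(input_rna_conc == conc) |>
        pull(condition_id)
      duplicate_agreement(ct, conds[1], conds[2]) |>
        mutate(input_rna_conc = conc, .before = 1)
    }) |> list_rbind()
    results$agreement <- agreement
    if (nrow(agreement) >= 10) {
      spline_fit <- fit_agreement_spline(agreement)
      results$agreement_spline <- spline_fit
      write_stage(tidy(spline_fit), out_dir, "duplicate_agreement.csv",
                  manifest)
    }
    failures <- purrr::map(dup_pairs$input_rna_conc, function(conc) {
      conds <- titration |> filter(input_rna_conc == conc) |>
        pull(condition_id)
      refs <- setdiff(c(titration$condition_id,
                        meta$condition_id[meta$design %in% "control"]),
                      conds)
      summarize_duplicate_failures(ct, conds[1], conds[2], refs) |>
        mutate(input_rna_conc = conc, .before = 1)
    }) |> list_rbind()
    results$failures <- failures
    write_stage(failures, out_dir, "well_failures.csv", manifest)

    dup_conds <- titration |>
      filter(input_rna_conc == max(input_rna_conc)) |> pull(condition_id)
    strat_cor <- stratified_pairwise_correlations(
      ct, dup_conds, config$cutoffs, config$censor_policy)
    results$stratified_correlations <- strat_cor
    write_stage(strat_cor, out_dir, "stratified_correlations.csv", manifest)
  }

  if ("concentration_series" %in% config$comparisons && nrow(titration) > 0) {
    concs <- sort(unique(titration$input_rna_conc))
    lo <- titration |> filter(input_rna_conc == min(concs)) |>
      pull(condition_id)
    hi <- titration |> filter(input_rna_conc == max(concs)) |>
      pull(condition_id)
    shift <- compare_methods_shift(
      ct, setNames(list(lo, hi), paste0(c(min(concs), max(concs)), "ng")),
      config$cutoffs, config$aggregation)
    results$concentration_shift <- shift
    write_stage(shift$counts, out_dir, "concentration_stratum_counts.csv",
                manifest)
    write_stage(shift$test, out_dir, "concentration_shift_test.csv", manifest)
  }

  clinical <- meta |> filter(design %in% "clinical")
  if ("ffpe_vs_frozen" %in% config$comparisons && nrow(clinical) > 0) {
    by_method <- split(clinical$condition_id, clinical$extraction_method)
    shift <- compare_methods_shift(
      ct, by_method[c("TRIzol_Qiagen", "RecoverAll")],
      config$cutoffs, config$aggregation)
    results$ffpe_shift_test <- shift
    write_stage(shift$counts, out_dir, "ffpe_stratum_counts.csv", manifest)
    write_stage(shift$test, out_dir, "ffpe_shift_test.csv", manifest)
    migration <- migration_table(ct, by_method$mirVana, by_method$RecoverAll,
                                 config$cutoffs)
    results$migration <- migration
    write_stage(migration, out_dir, "stratum_migration.csv", manifest)
    summaries <- summarize_ct(ct, by_method)
    results$ct_summaries <- summaries
    write_stage(summaries, out_dir, "ct_summaries.csv", manifest)

    d <- correlation_distance(ct, clinical$condition_id)
    hc <- hierarchical_cluster(d, config$linkage)
    results$clustering <- hc
    results$cluster_groups <- cluster_groups(hc, k = 2)
    write_stage(results$cluster_groups, out_dir, "cluster_groups.csv",
                manifest)
    writeLines(dendrogram_newick(hc), file.path(out_dir, "dendrogram.nwk"))
    manifest$files <- c(manifest$files, "dendrogram.nwk")
    pca <- ct_pca(ct, clinical$condition_id)
    results$pca <- pca
    write_stage(tidy(pca), out_dir, "pca_scores.csv", manifest)
    write_stage(glance(pca), out_dir, "pca_variance.csv", manifest)
  }

  readr::write_csv(tibble(file = manifest$files),
                   file.path(out_dir, "manifest.csv"), progress = FALSE)
  seed_line <- if (!is.null(config$simulate)) {
    sprintf("seed: %d", config$simulate$seed)
  } else "seed: none (file input)"
  writeLines(c(
    sprintf("ctstrata version: %s",
            as.character(utils::packageVersion("ctstrata"))),
    seed_line,
    sprintf("stages written: %d", length(manifest$files))
  ), file.path(out_dir, "run_log.txt"))
  invisible(results)
}
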