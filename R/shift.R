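#' Pearson chi-square test of independence on a stratum count table
#'
#' Tests whether stratum occupancy is independent of the condition group,
#' using the Pearson statistic `sum((O - E)^2 / E)` with
#' `E = row_total * column_total / grand_total`, no continuity correction.
#' Degrees of freedom are `(rows - 1) * (columns - 1)`; the p-value is the
#' upper tail of the chi-square distribution at the statistic. A zero row or
#' column total is a degenerate-table error; expected counts below 5 trigger
#' a warning, not an error.
#'
#' @param counts A numeric matrix of nonnegative counts (strata as rows,
#'   groups as columns), or the long tibble produced by [stratum_counts()].
#' @return One-row tibble: `statistic`, `df`, `p.value`, `n` (grand total).
#' @export
#' @examples
#' chi_square_independence(cbind(a = c(90, 122, 172), b = c(125, 141, 118)))
chi_square_independence <- function(counts) {
  if (is.data.frame(counts) && all(c("group", "stratum", "n") %in% names(counts))) {
    counts <- count_matrix(counts)
  }
  O <- as.matrix(counts)
  if (!is.numeric(O) || any(O < 0) || any(!is.finite(O))) {
    abort("counts must be a nonnegative numeric matrix")
  }
  if (nrow(O) < 2 || ncol(O) < 2) {
    abort("contingency table needs at least 2 rows and 2 columns")
  }
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0)) {
    abort("degenerate table: zero row or column total")
  }
  E <- outer(rs, cs) / sum(O)
  if (any(E < 5)) {
    warn("some expected cell counts are below 5; the chi-square approximation may be poor")
  }
  statistic <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  tibble(
    statistic = statistic,
    df = df,
    p.value = pchisq(statistic, df, lower.tail = FALSE),
    n = sum(O)
  )
}

#' Test for an abundance-stratum shift between two condition groups
#'
#' Builds the 3-by-2 stratum-occupancy table for the two groups via
#' [stratum_counts()] and applies [chi_square_independence()]. This is the
#' analysis that shows, e.g., FFPE samples shifting miRs from the high
#' toward the low abundance stratum relative to fresh-frozen tissue, or the
#' occupancy shift from a 10 to a 200 ng/uL input RNA concentration.
#'
#' @param ct A long Ct tibble.
#' @param groups Named list of exactly two condition-id vectors.
#' @inheritParams stratum_counts
#' @return List with `counts` (long tibble) and `test` (one-row tibble).
#' @export
compare_methods_shift <- function(ct, groups, cutoffs = stratum_cutoffs(),
                                  aggregation = c("per_sample_average",
                                                  "mean_ct"),
                                  censored = c("low", "drop")) {
  if (length(groups) != 2) abort("'groups' must name exactly two groups")
  counts <- stratum_counts(ct, groups, cutoffs,
                           aggregation = match.arg(aggregation),
                           censored = match.arg(censored))
  list(counts = counts, test = chi_square_independence(counts))
}

#' Cross-stratum migration table between two condition groups
#'
#' Cross-tabulates each miR assay's stratum under group A against its
#' stratum under group B (strata assigned to the per-assay mean Ct within
#' each group, censored values entering at 40). Off-diagonal cells quantify
#' abundance migration: e.g. many assays high-abundance under a fresh-frozen
#' extraction but only medium-abundance in FFPE, with few moving the other
#' way.
#'
#' @param ct A long Ct tibble.
#' @param conditions_a,conditions_b Condition ids of the two groups.
#' @param cutoffs A [stratum_cutoffs()] object.
#' @return Tibble covering all 9 cells: `stratum_a`, `stratum_b`, `n`.
#' @export
migration_table <- function(ct, conditions_a, conditions_b,
                            cutoffs = stratum_cutoffs()) {
  ct <- as_ct_table(ct)
  mean_by <- function(conds) {
    ct |>
      filter(role == "mir", condition_id %in% conds) |>
      summarise(mean_ct = mean(ct), .by = assay_id)
  }
  a <- mean_by(conditions_a)
  b <- mean_by(conditions_b)
  merged <- inner_join(a, b, by = "assay_id", suffix = c("_a", "_b"))
  if (nrow(merged) == 0) abort("no shared assays between the two groups")
  merged |>
    mutate(
      stratum_a = assign_stratum(mean_ct_a, cutoffs),
      stratum_b = assign_stratum(mean_ct_b, cutoffs)
    ) |>
    count(stratum_a, stratum_b) |>
    complete(
      stratum_a = factor(stratum_levels, levels = stratum_levels, ordered = TRUE),
      stratum_b = factor(stratum_levels, levels = stratum_levels, ordered = TRUE),
      fill = list(n = 0L)
    ) |>
    mutate(n = as.integer(n))
}
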