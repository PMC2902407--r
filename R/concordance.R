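#' Pearson correlation between paired Ct vectors
#'
#' Standard Pearson correlation on pairwise-complete observations, with a
#' censoring policy: by default pairs where either Ct is 40 are excluded
#' (40 is a detection bound, not a measurement); `"include"` keeps them at
#' face value. The p-value refers `t = r * sqrt((n - 2) / (1 - r^2))` to a
#' t distribution with `n - 2` degrees of freedom (two-sided); `|r| = 1`
#' yields `p = 0`.
#'
#' @param x,y Numeric Ct vectors of equal length (NAs allowed).
#' @param censor_policy `"exclude_any_40"` or `"include"`.
#' @return One-row tibble: `r`, `n`, `n_dropped`, `statistic`, `p.value`.
#' @export
#' @examples
#' ct_correlation(c(1, 2, 3, 4), c(2, 4, 5, 9))
ct_correlation <- function(x, y, censor_policy = c("exclude_any_40", "include")) {
  censor_policy <- match.arg(censor_policy)
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  if (censor_policy == "exclude_any_40") keep <- keep & x < 40 & y < 40
  n_dropped <- length(x) - sum(keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs for a correlation")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance in one of the vectors")
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    statistic <- sign(r) * Inf
    p <- 0
  } else {
    statistic <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(statistic), df = n - 2)
  }
  tibble(r = r, n = n, n_dropped = n_dropped,
         statistic = statistic, p.value = p)
}

#' Correlation between two conditions of a Ct table
#'
#' Pairs the miR assays measured in both conditions and applies
#' [ct_correlation()].
#'
#' @param ct A long Ct tibble.
#' @param condition_a,condition_b Condition ids to correlate.
#' @inheritParams ct_correlation
#' @return One-row tibble with the pair labels and the correlation result.
#' @export
condition_correlation <- function(ct, condition_a, condition_b,
                                  censor_policy = c("exclude_any_40", "include")) {
  ct <- as_ct_table(ct)
  wide <- ct |>
    filter(role == "mir", condition_id %in% c(condition_a, condition_b)) |>
    select(assay_id, condition_id, ct) |>
    pivot_wider(names_from = condition_id, values_from = ct)
  if (!all(c(condition_a, condition_b) %in% names(wide))) {
    abort("both conditions must carry measurements")
  }
  res <- ct_correlation(wide[[condition_a]], wide[[condition_b]],
                        censor_policy)
  bind_cols(tibble(condition_a = condition_a, condition_b = condition_b), res)
}

#' Abundance-stratified pairwise correlations
#'
#' Each miR assay is assigned to exactly ONE stratum by its mean Ct across
#' the listed conditions (censored values entering at 40), so strata
#' partition the assay set. Within each stratum, all pairwise correlations
#' between conditions are computed. Strata retaining fewer than 3 assays are
#' returned with `NA` results and flagged `computable = FALSE`.
#'
#' This is the analysis behind per-stratum correlation heat-maps: duplicate
#' and equivalent-sample concordance is near-perfect for high-abundance miRs
#' and collapses in the low-abundance stratum.
#'
#' @param ct A long Ct tibble.
#' @param conditions Character vector (>= 2) of condition ids.
#' @param cutoffs A [stratum_cutoffs()] object.
#' @inheritParams ct_correlation
#' @return Tibble with `stratum`, `condition_a`, `condition_b`, `r`, `n`,
#'   `n_dropped`, `p.value`, `computable`.
#' @export
stratified_pairwise_correlations <- function(ct, conditions,
                                             cutoffs = stratum_cutoffs(),
                                             censor_policy = c("exclude_any_40",
                                                               "include")) {
  censor_policy <- match.arg(censor_policy)
  if (length(conditions) < 2) abort("need at least two conditions")
  ct <- as_ct_table(ct)
  wide <- ct |>
    filter(role == "mir", condition_id %in% conditions) |>
    select(assay_id, condition_id, ct) |>
    pivot_wider(names_from = condition_id, values_from = ct)
  missing_conds <- setdiff(conditions, names(wide))
  if (length(missing_conds) > 0) {
    abort(paste0("no measurements for condition(s): ",
                 paste(missing_conds, collapse = ", ")))
  }
  mat <- as.matrix(wide[, conditions, drop = FALSE])
  mean_ct <- rowMeans(mat, na.rm = TRUE)
  stratum <- assign_stratum(mean_ct, cutoffs)
  pairs <- crossing(i = seq_along(conditions), j = seq_along(conditions)) |>
    filter(i < j)
  res <- purrr::map(stratum_levels, function(s) {
    idx <- which(stratum == s)
    purrr::map2(pairs$i, pairs$j, function(i, j) {
      base <- tibble(stratum = s, condition_a = conditions[i],
                     condition_b = conditions[j])
      if (length(idx) < 3) {
        return(bind_cols(base, tibble(r = NA_real_, n = length(idx),
                                      n_dropped = NA_integer_,
                                      p.value = NA_real_,
                                      computable = FALSE)))
      }
      out <- tryCatch(
        ct_correlation(mat[idx, i], mat[idx, j], censor_policy),
        error = function(e) NULL)
      if (is.null(out)) {
        bind_cols(base, tibble(r = NA_real_, n = length(idx),
                               n_dropped = NA_integer_, p.value = NA_real_,
                               computable = FALSE))
      } else {
        bind_cols(base, out |> select(r, n, n_dropped, p.value),
                  tibble(computable = TRUE))
      }
    }) |> list_rbind()
  }) |> list_rbind()
  if (any(!res$computable)) {
    warn("some strata retained fewer than 3 computable assays")
  }
  res |> mutate(stratum = factor(stratum, levels = stratum_levels,
                                 ordered = TRUE))
}

#' Per-group Ct summary statistics
#'
#' Mean, standard deviation and range of raw Ct values for each named group
#' of conditions. Censored values enter at 40 by default (`include_censored
#' = FALSE` drops them first).
#'
#' @param ct A long Ct tibble.
#' @param groups Named list mapping group labels to condition-id vectors.
#' @param include_censored Keep Ct-40 values in the summaries?
#' @return Tibble with one row per group: `group`, `n_values`, `mean_ct`,
#'   `sd_ct`, `min_ct`, `max_ct`.
#' @export
summarize_ct <- function(ct, groups, include_censored = TRUE) {
  ct <- as_ct_table(ct)
  purrr::map2(names(groups), groups, function(label, conds) {
    sub <- ct |> filter(role == "mir", condition_id %in% conds)
    if (!include_censored) sub <- sub |> filter(!censored)
    if (nrow(sub) == 0) abort(sprintf("group '%s' is empty", label))
    tibble(group = label, n_values = nrow(sub),
           mean_ct = mean(sub$ct), sd_ct = sd(sub$ct),
           min_ct = min(sub$ct), max_ct = max(sub$ct))
  }) |> list_rbind()
}

#' Paired mean Ct difference between two groups
#'
#' Averages each miR assay's Ct within each group of conditions and applies
#' a two-sided paired t-test to the per-assay means (group B minus group A).
#' With `censor = "exclude"` (default) assays carrying any censored
#' measurement in either group are dropped first, so the estimate is not
#' distorted by the Ct-40 detection ceiling. Used, for example, to estimate
#' the global FFPE-associated Ct shift against matched fresh-frozen samples.
#'
#' @param ct A long Ct tibble.
#' @param conditions_a,conditions_b Condition ids of the two groups.
#' @param censor `"exclude"` or `"include"`.
#' @return One-row tibble: `estimate` (mean of B minus A), `conf.low`,
#'   `conf.high`, `statistic`, `p.value`, `n_assays`.
#' @export
paired_group_difference <- function(ct, conditions_a, conditions_b,
                                    censor = c("exclude", "include")) {
  censor <- match.arg(censor)
  ct <- as_ct_table(ct)
  per_assay <- function(conds) {
    sub <- ct |> filter(role == "mir", condition_id %in% conds)
    sub |>
      summarise(mean_ct = mean(ct), any_cens = any(censored), .by = assay_id)
  }
  a <- per_assay(conditions_a)
  b <- per_assay(conditions_b)
  merged <- inner_join(a, b, by = "assay_id", suffix = c("_a", "_b"))
  if (censor == "exclude") {
    merged <- merged |> filter(!any_cens_a, !any_cens_b)
  }
  if (nrow(merged) < 3) abort("fewer than 3 paired assays after filtering")
  diffs <- merged$mean_ct_b - merged$mean_ct_a
  if (sd(diffs) == 0) {
    # degenerate but legal (e.g. a group compared with itself)
    return(tibble(estimate = mean(diffs), conf.low = NA_real_,
                  conf.high = NA_real_, statistic = NA_real_,
                  p.value = NA_real_, n_assays = nrow(merged)))
  }
  tt <- t.test(merged$mean_ct_b, merged$mean_ct_a, paired = TRUE)
  tibble(
    estimate = unname(tt$estimate),
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2],
    statistic = unname(tt$statistic),
    p.value = tt$p.value,
    n_assays = nrow(merged)
  )
}
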