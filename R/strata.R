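#' Abundance stratum cutoffs
#'
#' Ct space is partitioned into three abundance strata: high (Ct < 30),
#' medium (30 <= Ct <= 35) and low (Ct > 35). Lower Ct means more template,
#' so "high" is the most abundant stratum. The medium stratum is closed on
#' both boundaries; censored measurements (Ct = 40) fall in the low stratum.
#'
#' @param high_below Upper (exclusive) Ct bound of the high stratum.
#' @param low_above Lower (exclusive) Ct bound of the low stratum.
#' @return An object of class `stratum_cutoffs`.
#' @export
stratum_cutoffs <- function(high_below = 30, low_above = 35) {
  if (!(high_below > 0 && high_below < low_above && low_above < 40)) {
    abort("cutoffs must satisfy 0 < high_below < low_above < 40")
  }
  structure(list(high_below = high_below, low_above = low_above),
            class = "stratum_cutoffs")
}

#' @export
print.stratum_cutoffs <- function(x, ...) {
  cat(sprintf(
    "Abundance strata: high (Ct < %g), medium (%g <= Ct <= %g), low (Ct > %g)\n",
    x$high_below, x$high_below, x$low_above, x$low_above))
  invisible(x)
}

stratum_levels <- c("low", "medium", "high")

#' Assign abundance strata to Ct values
#'
#' Vectorised stratum assignment. Returns an ordered factor with levels
#' `low < medium < high` (ordered by abundance), so monotonicity in Ct maps
#' to monotonicity in the factor order.
#'
#' @param ct Numeric vector of Ct values in (0, 40].
#' @param cutoffs A [stratum_cutoffs()] object.
#' @return Ordered factor of strata, same length as `ct`.
#' @export
#' @examples
#' assign_stratum(c(25, 30, 35, 35.01, 40))
assign_stratum <- function(ct, cutoffs = stratum_cutoffs()) {
  if (any(!is.na(ct) & (ct <= 0 | ct > 40))) {
    abort("Ct values must lie in (0, 40]")
  }
  out <- ifelse(ct < cutoffs$high_below, "high",
                ifelse(ct <= cutoffs$low_above, "medium", "low"))
  factor(out, levels = stratum_levels, ordered = TRUE)
}

#' Add a stratum column to a Ct table
#'
#' @param ct A long Ct tibble.
#' @param cutoffs A [stratum_cutoffs()] object.
#' @return The tibble with an added `stratum` column.
#' @export
add_stratum <- function(ct, cutoffs = stratum_cutoffs()) {
  ct <- as_ct_table(ct)
  ct |> mutate(stratum = assign_stratum(ct, cutoffs))
}

#' Duplicate-plate agreement points
#'
#' For each miR assay measured on both plates with both Ct values strictly
#' below 40, returns the duplicate mean and the absolute duplicate
#' difference — the raw material of the agreement-versus-abundance plot.
#' Pairs where either value is censored (exactly 40) or missing are excluded;
#' the number of excluded miR assays is attached as attribute `n_dropped`.
#'
#' @param ct A long Ct tibble.
#' @param condition_a,condition_b The two duplicate condition ids.
#' @return Tibble with columns `assay_id`, `ct_a`, `ct_b`, `mean_ct`,
#'   `abs_diff`; attribute `n_dropped` counts excluded pairs.
#' @export
duplicate_agreement <- function(ct, condition_a, condition_b) {
  ct <- as_ct_table(ct)
  wide <- ct |>
    filter(role == "mir", condition_id %in% c(condition_a, condition_b)) |>
    select(assay_id, condition_id, ct) |>
    pivot_wider(names_from = condition_id, values_from = ct)
  if (!all(c(condition_a, condition_b) %in% names(wide)) || nrow(wide) == 0) {
    warn("no overlapping miR assays between the two conditions")
    return(structure(tibble(assay_id = character(), ct_a = numeric(),
                            ct_b = numeric(), mean_ct = numeric(),
                            abs_diff = numeric()),
                     n_dropped = 0L))
  }
  wide <- wide |> rename(ct_a = all_of(condition_a), ct_b = all_of(condition_b))
  if (!any(!is.na(wide$ct_a) & !is.na(wide$ct_b))) {
    warn("no overlapping miR assays between the two conditions")
  }
  keep <- !is.na(wide$ct_a) & !is.na(wide$ct_b) &
    wide$ct_a < 40 & wide$ct_b < 40
  out <- wide |>
    filter(keep) |>
    mutate(mean_ct = (ct_a + ct_b) / 2, abs_diff = abs(ct_a - ct_b))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Fit the duplicate-agreement smoothing spline
#'
#' Fits a cubic smoothing spline of the absolute duplicate difference on the
#' duplicate mean Ct, the diagnostic curve that motivates the 30/35 stratum
#' cutoffs: agreement is tight below Ct 30 and deteriorates above Ct 35.
#' The smoothing parameter is chosen by generalized cross-validation.
#'
#' @param points Output of [duplicate_agreement()] (needs at least 10 points
#'   spanning more than 2 cycles of `mean_ct`).
#' @return An object of class `agreement_spline` with [predict()],
#'   [tidy()] and [glance()] methods.
#' @export
fit_agreement_spline <- function(points) {
  if (nrow(points) < 10) {
    abort("need at least 10 agreement points to fit a spline")
  }
  if (diff(range(points$mean_ct)) <= 2) {
    abort("agreement points must span more than 2 cycles of mean Ct")
  }
  fit <- smooth.spline(points$mean_ct, points$abs_diff, cv = FALSE)
  fitted <- predict(fit, points$mean_ct)$y
  structure(
    list(
      fit = fit,
      points = points |> mutate(.fitted = fitted, .resid = abs_diff - fitted),
      range = range(points$mean_ct)
    ),
    class = "agreement_spline"
  )
}

#' @export
predict.agreement_spline <- function(object, mean_ct, ...) {
  predict(object$fit, mean_ct)$y
}

#' @export
print.agreement_spline <- function(x, ...) {
  cat(sprintf(
    "Cubic smoothing spline of |dCt| on mean Ct (GCV): %d points, df = %.2f\n",
    nrow(x$points), x$fit$df))
  invisible(x)
}

#' @rdname fit_agreement_spline
#' @param x,object An `agreement_spline` object.
#' @param ... Unused.
#' @method tidy agreement_spline
#' @export
tidy.agreement_spline <- function(x, ...) {
  x$points |> select(assay_id, mean_ct, abs_diff, .fitted, .resid)
}

#' @rdname fit_agreement_spline
#' @method glance agreement_spline
#' @export
glance.agreement_spline <- function(x, ...) {
  tibble(
    n = nrow(x$points),
    df = x$fit$df,
    spar = x$fit$spar,
    lambda = x$fit$lambda,
    sigma = sd(x$points$.resid)
  )
}

round_half_up <- function(x) floor(x + 0.5)

#' Count assays per abundance stratum
#'
#' Builds the stratum-occupancy contingency counts that feed the chi-square
#' shift tests. Two aggregations are available for a group of conditions:
#'
#' * `per_sample_average`: stratify every measurement, count per stratum
#'   within each condition, then average counts across the group's
#'   conditions and round half-up to an integer (contingency tests need
#'   integer counts).
#' * `mean_ct`: average each assay's Ct across the group's conditions
#'   (censored values entering at 40) and stratify the mean.
#'
#' By default censored measurements count toward the low stratum, so column
#' totals equal the number of miR assays measured; set
#' `censored = "drop"` to count detectable assays only.
#'
#' @param ct A long Ct tibble.
#' @param groups Named list mapping a group label to a character vector of
#'   condition ids.
#' @param cutoffs A [stratum_cutoffs()] object.
#' @param aggregation `"per_sample_average"` or `"mean_ct"`.
#' @param censored `"low"` (default: Ct 40 counts as low abundance) or
#'   `"drop"` (censored wells excluded before counting).
#' @return Tibble with columns `group`, `stratum`, `n` covering every
#'   group-by-stratum cell.
#' @export
stratum_counts <- function(ct, groups, cutoffs = stratum_cutoffs(),
                           aggregation = c("per_sample_average", "mean_ct"),
                           censored = c("low", "drop")) {
  aggregation <- match.arg(aggregation)
  censored <- match.arg(censored)
  ct <- as_ct_table(ct)
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    abort("'groups' must be a named list of condition-id vectors")
  }
  one_group <- function(label, conds) {
    sub <- ct |> filter(role == "mir", condition_id %in% conds)
    if (nrow(sub) == 0) {
      abort(sprintf("group '%s' has no measurements", label))
    }
    if (censored == "drop") sub <- sub |> filter(!censored)
    if (aggregation == "per_sample_average") {
      counts <- sub |>
        mutate(stratum = assign_stratum(ct, cutoffs)) |>
        count(condition_id, stratum) |>
        complete(condition_id, stratum = factor(stratum_levels,
                                                levels = stratum_levels,
                                                ordered = TRUE),
                 fill = list(n = 0L)) |>
        summarise(n = round_half_up(mean(n)), .by = stratum)
    } else {
      counts <- sub |>
        summarise(mean_ct = mean(ct), .by = assay_id) |>
        mutate(stratum = assign_stratum(mean_ct, cutoffs)) |>
        count(stratum) |>
        complete(stratum = factor(stratum_levels, levels = stratum_levels,
                                  ordered = TRUE),
                 fill = list(n = 0L))
    }
    counts |> mutate(group = label, .before = 1)
  }
  purrr::map2(names(groups), groups, one_group) |>
    list_rbind() |>
    mutate(n = as.integer(n)) |>
    select(group, stratum, n)
}

#' Pivot stratum counts to a contingency matrix
#'
#' @param counts Output of [stratum_counts()].
#' @return Integer matrix, strata as rows, groups as columns.
#' @export
count_matrix <- function(counts) {
  wide <- counts |>
    pivot_wider(names_from = group, values_from = n)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$stratum)
  m
}
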