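#' Classify a duplicate well pair as failed, not expressed, or ok
#'
#' A well *failure* is an expected-positive well that returned no
#' amplification within 40 cycles. For duplicate plates the rule is:
#'
#' * one value equal to 40 while the duplicate is below 40 — a single
#'   failure (one failed well);
#' * both values equal to 40 while any reference Ct for the same assay
#'   (other concentrations of the same sample, or the Universal RNA
#'   positive control) is below 40 — a double failure (both wells failed);
#' * both values equal to 40 with no reference evidence of expression —
#'   the assay is called not expressed and charged no failure;
#' * both values below 40 — ok.
#'
#' The classification is symmetric in the two duplicate values.
#'
#' @param ct_a,ct_b Duplicate Ct values in (0, 40].
#' @param reference_cts Numeric vector of the same assay's Ct values in
#'   reference conditions (may be empty).
#' @return One-row tibble with `call` and `failure_count`.
#' @export
classify_well_failure <- function(ct_a, ct_b, reference_cts = numeric()) {
  vals <- c(ct_a, ct_b, reference_cts)
  if (any(vals <= 0 | vals > 40)) abort("Ct values must lie in (0, 40]")
  if (ct_a < 40 && ct_b < 40) {
    call <- "ok"; n <- 0L
  } else if (xor(ct_a == 40, ct_b == 40)) {
    call <- "single_failure"; n <- 1L
  } else if (length(reference_cts) > 0 && any(reference_cts < 40)) {
    call <- "double_failure"; n <- 2L
  } else {
    call <- "not_expressed"; n <- 0L
  }
  tibble(call = call, failure_count = n)
}

#' Per-assay failure calls for a duplicate plate pair
#'
#' Applies [classify_well_failure()] to every miR assay measured on both
#' plates. Blank and endogenous-control wells never enter failure counts
#' (blanks are expected 40s; controls have their own QC role).
#'
#' @param ct A long Ct tibble.
#' @param condition_a,condition_b The duplicate condition ids.
#' @param reference_conditions Condition ids supplying reference Cts for the
#'   both-40 lookup (other concentrations of the same sample, Universal RNA).
#' @return Tibble with `assay_id`, `ct_a`, `ct_b`, `call`, `failure_count`
#'   and per-plate indicators `fail_a`, `fail_b`.
#' @export
duplicate_failure_calls <- function(ct, condition_a, condition_b,
                                    reference_conditions = character()) {
  ct <- as_ct_table(ct)
  wide <- ct |>
    filter(role == "mir", condition_id %in% c(condition_a, condition_b)) |>
    select(assay_id, condition_id, ct) |>
    pivot_wider(names_from = condition_id, values_from = ct)
  if (!all(c(condition_a, condition_b) %in% names(wide))) {
    abort("both duplicate conditions must carry measurements")
  }
  wide <- wide |>
    rename(ct_a = all_of(condition_a), ct_b = all_of(condition_b)) |>
    filter(!is.na(ct_a), !is.na(ct_b))
  ref_evidence <- ct |>
    filter(role == "mir", condition_id %in% reference_conditions) |>
    summarise(ref_expressed = any(ct < 40), .by = assay_id)
  wide <- wide |>
    left_join(ref_evidence, by = "assay_id") |>
    mutate(ref_expressed = coalesce(ref_expressed, FALSE))
  wide |>
    mutate(
      call = case_when(
        ct_a < 40 & ct_b < 40 ~ "ok",
        xor(ct_a == 40, ct_b == 40) ~ "single_failure",
        ref_expressed ~ "double_failure",
        .default = "not_expressed"
      ),
      failure_count = c(ok = 0L, single_failure = 1L, double_failure = 2L,
                        not_expressed = 0L)[call],
      fail_a = (ct_a == 40 & call %in% c("single_failure", "double_failure")),
      fail_b = (ct_b == 40 & call %in% c("single_failure", "double_failure"))
    ) |>
    select(assay_id, ct_a, ct_b, call, failure_count, fail_a, fail_b)
}

#' Summarize well failures between duplicate plates
#'
#' Per-plate failure totals are averaged between the duplicates (a double
#' failure contributes one failed well to each plate) and expressed as a
#' percentage of the miR assays with evidence of expression:
#' `percent = average failures / number of miRs expressed * 100`.
#'
#' @inheritParams duplicate_failure_calls
#' @return One-row tibble with plate failure counts, `average_failures`,
#'   `n_expressed` and `percent_failures`.
#' @export
summarize_duplicate_failures <- function(ct, condition_a, condition_b,
                                         reference_conditions = character()) {
  calls <- duplicate_failure_calls(ct, condition_a, condition_b,
                                   reference_conditions)
  n_expressed <- sum(calls$call != "not_expressed")
  if (n_expressed == 0) {
    abort("no expressed miR assays: failure percentage undefined")
  }
  n_a <- sum(calls$fail_a)
  n_b <- sum(calls$fail_b)
  tibble(
    condition_a = condition_a,
    condition_b = condition_b,
    n_failures_plate_a = n_a,
    n_failures_plate_b = n_b,
    average_failures = (n_a + n_b) / 2,
    n_expressed = n_expressed,
    percent_failures = (n_a + n_b) / 2 / n_expressed * 100
  )
}

#' Well failures on a single plate against a known expressed set
#'
#' When only one plate is run per condition (e.g. across a cDNA dilution
#' series), a failure is a Ct of 40 for any miR known to be expressed in
#' that sample from prior duplicate runs or other conditions.
#'
#' @param ct A long Ct tibble.
#' @param condition The single plate's condition id.
#' @param expressed_assays Character vector of assay ids known to be
#'   expressed in the sample.
#' @return One-row tibble with `n_failures`, `n_expressed`,
#'   `percent_failures`.
#' @export
single_plate_failures <- function(ct, condition, expressed_assays) {
  if (length(expressed_assays) == 0) {
    abort("expressed_assays must be non-empty")
  }
  ct <- as_ct_table(ct)
  plate <- ct |>
    filter(role == "mir", condition_id == condition,
           assay_id %in% expressed_assays)
  n_fail <- sum(plate$ct == 40)
  tibble(
    condition = condition,
    n_failures = n_fail,
    n_expressed = length(expressed_assays),
    percent_failures = n_fail / length(expressed_assays) * 100
  )
}
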