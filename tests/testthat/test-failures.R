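test_that("well-failure classification follows the duplicate rule", {
  expect_equal(classify_well_failure(40, 33.5)$call, "single_failure")
  expect_equal(classify_well_failure(40, 33.5)$failure_count, 1L)
  both <- classify_well_failure(40, 40, c(34.2, 40))
  expect_equal(both$call, "double_failure")
  expect_equal(both$failure_count, 2L)
  expect_equal(classify_well_failure(40, 40, c(40, 40))$call, "not_expressed")
  expect_equal(classify_well_failure(40, 40)$call, "not_expressed")
  expect_equal(classify_well_failure(33, 34)$call, "ok")
  # symmetric in the duplicate pair
  expect_equal(classify_well_failure(33.5, 40), classify_well_failure(40, 33.5))
  expect_error(classify_well_failure(41, 33), "0, 40")
})

# Builds duplicate plates with prescribed failure structure: n_a / n_b
# single-plate failures, n_dead assays with no expression evidence.
failure_fixture <- function(n_total = 365, n_a = 10, n_b = 6, n_dead = 45) {
  ids <- sprintf("miR-%03d", seq_len(n_total))
  ct_a <- rep(30, n_total)
  ct_b <- rep(30, n_total)
  ct_a[seq_len(n_a)] <- 40
  ct_b[n_a + seq_len(n_b)] <- 40
  dead <- n_total - n_dead + seq_len(n_dead)
  ct_a[dead] <- 40
  ct_b[dead] <- 40
  as_ct_table(dplyr::bind_rows(
    tibble::tibble(assay_id = ids, condition_id = "p1", ct = ct_a),
    tibble::tibble(assay_id = ids, condition_id = "p2", ct = ct_b),
    tibble::tibble(assay_id = ids, condition_id = "ref", ct = 40)
  ))
}

test_that("duplicate failure percentages follow the printed formula", {
  ct <- failure_fixture()
  s <- summarize_duplicate_failures(ct, "p1", "p2", "ref")
  expect_equal(s$n_failures_plate_a, 10L)
  expect_equal(s$n_failures_plate_b, 6L)
  expect_equal(s$average_failures, 8)
  expect_equal(s$n_expressed, 320L)
  expect_equal(s$percent_failures, 8 / 320 * 100)   # 2.5
})

test_that("a reference below 40 turns both-40 assays into double failures", {
  ct <- failure_fixture(n_total = 20, n_a = 0, n_b = 0, n_dead = 5)
  # give one dead assay reference evidence
  ct$ct[ct$assay_id == "miR-016" & ct$condition_id == "ref"] <- 32
  ct$censored <- ct$ct == 40
  calls <- duplicate_failure_calls(ct, "p1", "p2", "ref")
  expect_equal(calls$call[calls$assay_id == "miR-016"], "double_failure")
  expect_true(calls$fail_a[calls$assay_id == "miR-016"])
  expect_true(calls$fail_b[calls$assay_id == "miR-016"])
  s <- summarize_duplicate_failures(ct, "p1", "p2", "ref")
  expect_equal(s$n_expressed, 16L)
  expect_equal(s$average_failures, 1)   # one failed well on each plate
})

test_that("failure summaries handle clean plates and degenerate input", {
  clean <- duplicate_plates(seq(20, 35, length.out = 30), sigma = 0)
  s <- summarize_duplicate_failures(clean, "p1", "p2")
  expect_equal(s$percent_failures, 0)
  dead <- as_ct_table(tibble::tibble(
    assay_id = rep(c("a", "b"), 2),
    condition_id = rep(c("p1", "p2"), each = 2), ct = 40))
  expect_error(summarize_duplicate_failures(dead, "p1", "p2"), "undefined")
})

test_that("failure percentage ignores assay order and not-expressed assays", {
  ct <- failure_fixture(n_total = 100, n_a = 4, n_b = 2, n_dead = 10)
  base <- summarize_duplicate_failures(ct, "p1", "p2", "ref")
  shuffled <- as_ct_table(ct[sample.int(nrow(ct)), ])
  expect_equal(summarize_duplicate_failures(shuffled, "p1", "p2", "ref"),
               base)
  more_dead <- failure_fixture(n_total = 120, n_a = 4, n_b = 2, n_dead = 30)
  expect_equal(
    summarize_duplicate_failures(more_dead, "p1", "p2", "ref")$percent_failures,
    base$percent_failures)
})

test_that("single-plate failures count only the known-expressed set", {
  ids <- sprintf("miR-%03d", 1:320)
  ct_vals <- rep(28, 320)
  ct_vals[1:12] <- 40          # failures within the expressed set
  ct_vals[301:320] <- 40       # at 40 but outside the expressed set
  ct <- as_ct_table(tibble::tibble(assay_id = ids, condition_id = "p1",
                                   ct = ct_vals))
  s <- single_plate_failures(ct, "p1", ids[1:300])
  expect_equal(s$n_failures, 12L)
  expect_equal(s$percent_failures, 4.0)
  none <- single_plate_failures(ct, "p1", ids[13:300])
  expect_equal(none$percent_failures, 0)
  expect_error(single_plate_failures(ct, "p1", character()), "non-empty")
})

test_that("failure rate falls with concentration and rises with dilution", {
  study <- default_study()
  meta <- study$metadata
  titr <- dplyr::filter(meta, design == "titration")
  pct <- vapply(sort(unique(titr$input_rna_conc)), function(conc) {
    conds <- titr$condition_id[titr$input_rna_conc == conc]
    refs <- setdiff(c(titr$condition_id, "universal"), conds)
    summarize_duplicate_failures(study$ct, conds[1], conds[2],
                                 refs)$percent_failures
  }, numeric(1))
  expect_true(all(diff(pct) <= 0))
  dil <- dplyr::filter(meta, design == "dilution_series",
                       input_rna_conc == 200) |>
    dplyr::arrange(cdna_dilution)
  expressed <- study$ct |>
    dplyr::filter(role == "mir", condition_id %in% titr$condition_id) |>
    dplyr::summarise(e = any(ct < 40), .by = assay_id) |>
    dplyr::filter(e) |>
    dplyr::pull(assay_id)
  pct_dil <- vapply(dil$condition_id, function(cond) {
    single_plate_failures(study$ct, cond, expressed)$percent_failures
  }, numeric(1))
  expect_true(all(diff(pct_dil) >= 0))
})
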