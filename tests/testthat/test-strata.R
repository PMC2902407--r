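test_that("stratum assignment respects the 30/35 boundaries", {
  s <- assign_stratum(c(29.99, 30.0, 35.0, 35.01, 40, 0.5))
  expect_equal(as.character(s),
               c("high", "medium", "medium", "low", "low", "high"))
  expect_s3_class(s, "ordered")
  expect_error(assign_stratum(41), "0, 40")
  expect_error(assign_stratum(-2), "0, 40")
  expect_error(stratum_cutoffs(35, 30), "high_below < low_above")
})

test_that("stratum assignment is monotone in Ct", {
  set.seed(7)
  for (i in 1:20) {
    ct <- sort(stats::runif(50, 0.1, 40))
    s <- as.integer(assign_stratum(ct))   # low=1 < medium=2 < high=3
    expect_true(all(diff(s) <= 0))        # rising Ct never gains abundance
  }
})

test_that("duplicate agreement computes means/differences and drops 40s", {
  pts <- duplicate_agreement(tiny_ct(), "s1", "s2")
  expect_equal(pts$mean_ct[pts$assay_id == "miR-a"], 25.2)
  expect_equal(pts$abs_diff[pts$assay_id == "miR-a"], 0.4)
  # miR-c has one 40, miR-d two 40s: both excluded; controls never enter
  expect_setequal(pts$assay_id, c("miR-a", "miR-b"))
  expect_equal(attr(pts, "n_dropped"), 2L)
  # symmetric in plate order
  rev <- duplicate_agreement(tiny_ct(), "s2", "s1")
  expect_equal(rev$mean_ct, pts$mean_ct)
  expect_equal(rev$abs_diff, pts$abs_diff)
  # identical plates agree perfectly
  same <- duplicate_plates(seq(20, 35, length.out = 20), sigma = 0)
  expect_true(all(duplicate_agreement(same, "p1", "p2")$abs_diff == 0))
  # disjoint assay sets warn and return empty
  ct <- as_ct_table(tibble::tibble(
    assay_id = c("miR-a", "miR-b"), condition_id = c("x", "y"),
    ct = c(25, 26)))
  expect_warning(out <- duplicate_agreement(ct, "x", "y"), "overlap")
  expect_equal(nrow(out), 0)
})

test_that("the agreement spline reproduces smooth truth", {
  mean_ct <- seq(20, 38, length.out = 60)
  # noise-free linear trend
  pts <- tibble::tibble(assay_id = as.character(seq_along(mean_ct)),
                        mean_ct = mean_ct, abs_diff = 0.01 * mean_ct)
  fit <- fit_agreement_spline(pts)
  expect_lt(max(abs(predict(fit, mean_ct) - 0.01 * mean_ct)), 1e-3)
  # constant data give a flat curve
  pts$abs_diff <- 0.7
  flat <- fit_agreement_spline(pts)
  expect_lt(max(abs(predict(flat, mean_ct) - 0.7)), 1e-6)
  expect_error(fit_agreement_spline(pts[1:5, ]), "at least 10")
  expect_error(
    fit_agreement_spline(dplyr::mutate(pts, mean_ct = 25 + mean_ct / 100)),
    "span")
})

test_that("the fitted agreement curve rises with Ct under the noise model", {
  study <- default_study()
  dup <- dplyr::filter(study$metadata, design == "titration",
                       input_rna_conc == 200)
  pts <- duplicate_agreement(study$ct, dup$condition_id[1],
                             dup$condition_id[2])
  fit <- fit_agreement_spline(pts)
  expect_gt(predict(fit, 37), predict(fit, 25))
  expect_gt(nrow(tidy(fit)), 100)
  expect_equal(nrow(glance(fit)), 1)
})

test_that("per-stratum duplicate variability is ordered low > medium > high", {
  study <- default_study()
  dup <- dplyr::filter(study$metadata, design == "titration",
                       input_rna_conc == 200)
  pts <- duplicate_agreement(study$ct, dup$condition_id[1],
                             dup$condition_id[2])
  med <- pts |>
    dplyr::mutate(stratum = assign_stratum(mean_ct)) |>
    dplyr::summarise(m = stats::median(abs_diff), .by = stratum)
  m <- setNames(med$m, as.character(med$stratum))
  expect_gt(m["low"], m["medium"])
  expect_gt(m["medium"], m["high"])
})

test_that("stratum counts partition assays and honour the aggregation rules", {
  ct <- as_ct_table(tibble::tibble(
    assay_id = c("a", "b", "c"), condition_id = "s1",
    ct = c(25, 32, 38)))
  counts <- stratum_counts(ct, list(g = "s1"))
  expect_equal(sort(counts$n), c(1L, 1L, 1L))
  expect_equal(sum(counts$n), 3L)
  # two identical conditions average to the same counts
  ct2 <- dplyr::bind_rows(ct, dplyr::mutate(ct, condition_id = "s2"))
  counts2 <- stratum_counts(as_ct_table(ct2), list(g = c("s1", "s2")))
  expect_equal(counts2$n, counts$n)
  # half counts round half-up: high counts 3 and 4 average to 4
  ct3 <- as_ct_table(tibble::tibble(
    assay_id = rep(c("a", "b", "c", "d"), 2),
    condition_id = rep(c("s1", "s2"), each = 4),
    ct = c(25, 26, 27, 36, 25, 26, 27, 28)))
  counts3 <- stratum_counts(ct3, list(g = c("s1", "s2")))
  expect_equal(counts3$n[counts3$stratum == "high"], 4L)
  # mean-Ct aggregation stratifies the per-assay mean
  counts4 <- stratum_counts(ct3, list(g = c("s1", "s2")),
                            aggregation = "mean_ct")
  expect_equal(sum(counts4$n), 4L)
  expect_equal(counts4$n[counts4$stratum == "low"], 0L)  # mean(36,28)=32
  expect_error(stratum_counts(ct, list(g = "nope")), "no measurements")
})

test_that("censored wells count as low abundance unless dropped", {
  ct <- as_ct_table(tibble::tibble(
    assay_id = c("a", "b"), condition_id = "s1", ct = c(25, 40)))
  with_cens <- stratum_counts(ct, list(g = "s1"))
  expect_equal(with_cens$n[with_cens$stratum == "low"], 1L)
  expect_equal(sum(with_cens$n), 2L)
  dropped <- stratum_counts(ct, list(g = "s1"), censored = "drop")
  expect_equal(sum(dropped$n), 1L)
})

test_that("count_matrix pivots counts with strata as rows", {
  study <- default_study()
  titr <- dplyr::filter(study$metadata, design == "titration")
  counts <- stratum_counts(
    study$ct,
    list(a = titr$condition_id[titr$input_rna_conc == 10],
         b = titr$condition_id[titr$input_rna_conc == 200]))
  m <- count_matrix(counts)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(rownames(m), c("low", "medium", "high"))
  expect_equal(sum(m), sum(counts$n))
})
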