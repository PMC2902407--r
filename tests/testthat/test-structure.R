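test_that("correlation distance hits its exact endpoints", {
  x <- seq(20, 35, length.out = 10)
  ct <- dplyr::bind_rows(
    tibble::tibble(assay_id = sprintf("m%02d", 1:10), condition_id = "a", ct = x),
    tibble::tibble(assay_id = sprintf("m%02d", 1:10), condition_id = "b", ct = x),
    tibble::tibble(assay_id = sprintf("m%02d", 1:10), condition_id = "c",
                   ct = 60 - x)
  ) |> as_ct_table()
  d <- as.matrix(correlation_distance(ct))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
})

test_that("independent conditions sit near distance 1", {
  set.seed(9)
  n <- 2000
  ct <- dplyr::bind_rows(
    tibble::tibble(assay_id = sprintf("m%04d", 1:n), condition_id = "a",
                   ct = stats::runif(n, 20, 39)),
    tibble::tibble(assay_id = sprintf("m%04d", 1:n), condition_id = "b",
                   ct = stats::runif(n, 20, 39))
  ) |> as_ct_table()
  d <- as.matrix(correlation_distance(ct))
  expect_equal(d["a", "b"], 1, tolerance = 0.1)
})

test_that("correlation distance survives affine rescaling of one condition", {
  set.seed(2)
  x <- stats::runif(20, 20, 39)
  make <- function(scale, shift) {
    dplyr::bind_rows(
      tibble::tibble(assay_id = sprintf("m%02d", 1:20), condition_id = "a",
                     ct = x),
      tibble::tibble(assay_id = sprintf("m%02d", 1:20), condition_id = "b",
                     ct = pmin(scale * x + shift, 39.9))
    ) |> as_ct_table()
  }
  base <- as.matrix(correlation_distance(make(1, 0)))["a", "b"]
  rescaled <- as.matrix(correlation_distance(make(0.5, 5)))["a", "b"]
  expect_equal(rescaled, base, tolerance = 1e-10)
})

test_that("clustering recovers two well-separated blobs", {
  set.seed(4)
  n <- 50
  sig_a <- stats::rnorm(n, 30, 3)
  sig_b <- stats::rnorm(n, 30, 3)
  build <- function(cond, sig) {
    tibble::tibble(assay_id = sprintf("m%03d", 1:n), condition_id = cond,
                   ct = pmin(pmax(sig + stats::rnorm(n, 0, 0.2), 15), 39.9))
  }
  ct <- dplyr::bind_rows(
    build("a1", sig_a), build("a2", sig_a), build("a3", sig_a),
    build("b1", sig_b), build("b2", sig_b), build("b3", sig_b)
  ) |> as_ct_table()
  hc <- hierarchical_cluster(correlation_distance(ct))
  groups <- cluster_groups(hc, 2)
  lab <- substr(groups$condition_id, 1, 1)
  expect_equal(length(unique(groups$cluster[lab == "a"])), 1L)
  expect_equal(length(unique(groups$cluster[lab == "b"])), 1L)
  expect_false(groups$cluster[lab == "a"][1] == groups$cluster[lab == "b"][1])
  # deterministic: identical call, identical merge tree
  hc2 <- hierarchical_cluster(correlation_distance(ct))
  expect_identical(hc$merge, hc2$merge)
  expect_equal(hc$height, hc2$height)
  # complete-linkage heights never decrease toward the root
  expect_true(all(diff(hc$height) >= 0))
})

test_that("dendrograms export as parseable Newick text", {
  ct <- duplicate_plates(c(25, 31, 36, 28, 33), sigma = 0.5, seed = 3)
  ct <- dplyr::bind_rows(
    ct, dplyr::mutate(dplyr::filter(ct, condition_id == "p1"),
                      condition_id = "p3",
                      ct = pmin(ct + stats::rnorm(5, 0, 0.3), 39.9),
                      censored = FALSE)
  ) |> as_ct_table()
  hc <- hierarchical_cluster(correlation_distance(ct))
  nwk <- dendrogram_newick(hc)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, c("p1", "p2", "p3"))
})

test_that("PCA isolates a rank-1 group shift on PC1", {
  n <- 40
  base_profile <- seq(20, 38, length.out = n)
  shift <- stats::rnorm(n, 0, 1)
  build <- function(cond, shifted) {
    tibble::tibble(assay_id = sprintf("m%03d", 1:n), condition_id = cond,
                   ct = pmin(base_profile + if (shifted) shift else 0, 39.9))
  }
  ct <- dplyr::bind_rows(build("a1", FALSE), build("a2", FALSE),
                         build("b1", TRUE), build("b2", TRUE)) |>
    as_ct_table()
  pc <- ct_pca(ct)
  expect_gt(pc$var_explained[1], 0.999)
  scores <- tidy(pc)
  expect_equal(scores$PC1[scores$condition_id == "a1"],
               scores$PC1[scores$condition_id == "a2"], tolerance = 1e-8)
  expect_true(
    sign(scores$PC1[scores$condition_id == "a1"]) !=
      sign(scores$PC1[scores$condition_id == "b1"]))
})

test_that("variance fractions are complete at full rank and flat for noise", {
  set.seed(12)
  n <- 500
  conds <- sprintf("c%d", 1:6)
  ct <- purrr::map(conds, function(cc) {
    tibble::tibble(assay_id = sprintf("m%04d", 1:n), condition_id = cc,
                   ct = stats::runif(n, 25, 35))
  }) |> purrr::list_rbind() |> as_ct_table()
  pc <- ct_pca(ct)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-10)
  # isotropic noise: no component dominates
  expect_lt(pc$var_explained[1] / pc$var_explained[5], 2.5)
  expect_error(
    ct_pca(duplicate_plates(rep(30, 5), sigma = 0)), "zero variance")
})

test_that("PCA scores are stable under condition reordering", {
  study <- default_study()
  clin <- dplyr::filter(study$metadata, design == "clinical")
  pc1 <- ct_pca(study$ct, clin$condition_id)
  pc2 <- ct_pca(study$ct, rev(clin$condition_id))
  s1 <- dplyr::arrange(tidy(pc1), condition_id)
  s2 <- dplyr::arrange(tidy(pc2), condition_id)
  expect_equal(abs(s1$PC1), abs(s2$PC1), tolerance = 1e-8)
  expect_equal(abs(s1$PC2), abs(s2$PC2), tolerance = 1e-8)
})
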