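#' One-minus-Pearson correlation distance between conditions
#'
#' Computes `d = 1 - r` between every pair of conditions over the shared miR
#' assays, optionally restricted to one abundance stratum (assigned to each
#' assay's mean Ct across the selected conditions). Correlations use
#' pairwise-complete observations, so partial plates do not abort the
#' analysis. Because Pearson r is invariant under per-condition affine
#' increasing rescaling, so is the distance.
#'
#' @param ct A long Ct tibble.
#' @param conditions Condition ids to include (default: all present).
#' @param stratum Optional stratum name (`"low"`, `"medium"`, `"high"`) to
#'   restrict the assay set.
#' @param cutoffs A [stratum_cutoffs()] object.
#' @return A `dist` object over the conditions (d in [0, 2], zero diagonal).
#' @export
correlation_distance <- function(ct, conditions = NULL, stratum = NULL,
                                 cutoffs = stratum_cutoffs()) {
  ct <- as_ct_table(ct)
  mir <- ct |> filter(role == "mir")
  conditions <- conditions %||% unique(mir$condition_id)
  if (length(conditions) < 2) abort("need at least two conditions")
  wide <- mir |>
    filter(condition_id %in% conditions) |>
    select(assay_id, condition_id, ct) |>
    pivot_wider(names_from = condition_id, values_from = ct)
  mat <- as.matrix(wide[, conditions, drop = FALSE])
  if (!is.null(stratum)) {
    stratum <- match.arg(stratum, stratum_levels)
    keep <- assign_stratum(rowMeans(mat, na.rm = TRUE), cutoffs) == stratum
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(mat) < 3) {
    abort("fewer than 3 shared assays after stratum restriction")
  }
  r <- cor(mat, use = "pairwise.complete.obs")
  if (any(is.na(r))) abort("undefined correlation between some conditions")
  as.dist(1 - r)
}

#' Agglomerative hierarchical clustering of conditions
#'
#' Standard agglomerative clustering (via [stats::hclust()]) on a
#' correlation-distance matrix; complete linkage by default. `hclust`
#' resolves ties deterministically by lowest pair index, so results are
#' reproducible for a fixed input.
#'
#' @param d A `dist` object, e.g. from [correlation_distance()].
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "average",
                                                "single")) {
  linkage <- match.arg(linkage)
  if (!inherits(d, "dist")) abort("'d' must be a dist object")
  hclust(d, method = linkage)
}

#' Cut a dendrogram into k groups
#'
#' @param hc An `hclust` object.
#' @param k Number of groups (default 2).
#' @return Tibble with `condition_id` and integer `cluster`.
#' @export
cluster_groups <- function(hc, k = 2) {
  cl <- cutree(hc, k = k)
  tibble(condition_id = names(cl), cluster = unname(cl))
}

#' Export a dendrogram as Newick text
#'
#' @param hc An `hclust` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Principal component analysis of conditions
#'
#' Treats conditions as observations and miR assays as variables: the assay
#' by condition matrix is transposed, each assay is centred across
#' conditions, and scores come from the singular value decomposition (via
#' [stats::prcomp()], no scaling). Assays with any missing well are dropped
#' (PCA needs a complete matrix). The sign of each component is fixed so
#' that its first nonzero loading is positive, making scores reproducible
#' across runs.
#'
#' @param ct A long Ct tibble.
#' @param conditions Condition ids to include (default: all present).
#' @param n_components Number of components to retain (default: full rank,
#'   at most `#conditions - 1`).
#' @return An object of class `ct_pca` with `scores` (tibble), `var_explained`
#'   (numeric), `rotation`; has [tidy()], [glance()] and [autoplot()] methods.
#' @export
ct_pca <- function(ct, conditions = NULL, n_components = NULL) {
  ct <- as_ct_table(ct)
  mir <- ct |> filter(role == "mir")
  conditions <- conditions %||% unique(mir$condition_id)
  if (length(conditions) < 2) abort("need at least two conditions")
  wide <- mir |>
    filter(condition_id %in% conditions) |>
    select(assay_id, condition_id, ct) |>
    pivot_wider(names_from = condition_id, values_from = ct)
  mat <- as.matrix(wide[, conditions, drop = FALSE])
  rownames(mat) <- wide$assay_id
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 2) abort("fewer than 2 complete assays across conditions")
  obs <- t(mat)                       # conditions as observations
  if (all(apply(obs, 2, sd) == 0)) abort("degenerate input: zero variance")
  max_rank <- min(length(conditions) - 1L, nrow(mat))
  n_components <- min(n_components %||% max_rank, max_rank)
  pc <- prcomp(obs, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rotation <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: first nonzero loading of each component positive
  for (j in seq_len(k)) {
    nz <- which(rotation[, j] != 0)[1]
    if (!is.na(nz) && rotation[nz, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total_var <- sum(pc$sdev^2)
  structure(
    list(
      scores = bind_cols(tibble(condition_id = rownames(scores)),
                         as_tibble(scores)),
      var_explained = pc$sdev[seq_len(k)]^2 / total_var,
      rotation = rotation,
      n_assays = nrow(mat)
    ),
    class = "ct_pca"
  )
}

#' @export
print.ct_pca <- function(x, ...) {
  cat(sprintf("PCA of %d conditions on %d complete assays\n",
              nrow(x$scores), x$n_assays))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname ct_pca
#' @param x,object A `ct_pca` object.
#' @param ... Unused.
#' @method tidy ct_pca
#' @export
tidy.ct_pca <- function(x, ...) x$scores

#' @rdname ct_pca
#' @method glance ct_pca
#' @export
glance.ct_pca <- function(x, ...) {
  tibble(
    component = paste0("PC", seq_along(x$var_explained)),
    var_explained = x$var_explained
  )
}
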