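# Small in-code fixtures shared across test files.

# A tiny long Ct table: 2 conditions x a handful of assays, mixed roles.
tiny_ct <- function() {
  as_ct_table(tibble::tribble(
    ~assay_id, ~condition_id, ~role, ~ct,
    "miR-a", "s1", "mir", 25.0,
    "miR-a", "s2", "mir", 25.4,
    "miR-b", "s1", "mir", 32.0,
    "miR-b", "s2", "mir", 33.0,
    "miR-c", "s1", "mir", 38.0,
    "miR-c", "s2", "mir", 40.0,
    "miR-d", "s1", "mir", 40.0,
    "miR-d", "s2", "mir", 40.0,
    "snoRNA-ctrl-1", "s1", "endogenous_control", 20.0,
    "snoRNA-ctrl-1", "s2", "endogenous_control", 40.0,
    "blank", "s1", "blank", 40.0,
    "blank", "s2", "blank", 40.0
  ))
}

# Random valid Ct table (censored entries and missing wells included).
random_ct <- function(n_assays = 20, n_conditions = 4, seed = 1) {
  set.seed(seed)
  grid <- tidyr::crossing(
    assay_id = sprintf("miR-%02d", seq_len(n_assays)),
    condition_id = sprintf("c%d", seq_len(n_conditions))
  )
  grid <- grid[stats::runif(nrow(grid)) > 0.1, ]   # missing wells
  ct <- stats::runif(nrow(grid), 18, 42)
  ct <- ifelse(ct >= 40, 40, ct)
  as_ct_table(dplyr::mutate(grid, ct = ct))
}

# Duplicate-plate table with a prescribed per-assay Ct vector and noise.
duplicate_plates <- function(true_ct, sigma = 0, seed = 1) {
  set.seed(seed)
  n <- length(true_ct)
  ids <- sprintf("miR-%03d", seq_len(n))
  obs <- function() {
    x <- true_ct + stats::rnorm(n, 0, sigma)
    ifelse(x >= 40, 40, x)
  }
  as_ct_table(dplyr::bind_rows(
    tibble::tibble(assay_id = ids, condition_id = "p1", ct = obs()),
    tibble::tibble(assay_id = ids, condition_id = "p2", ct = obs())
  ))
}

# One default synthetic study per test run, shared where only reading occurs.
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(sim_config(seed = 1L))
    cache
  }
})

# Stratum counts of the packaged extraction-method comparison table
# (365 miR assays plus duplicated controls under three extraction methods).
extraction_counts <- function() {
  path <- system.file("extdata", "extraction_stratum_counts.csv",
                      package = "ctstrata")
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl$stratum
  m
}
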