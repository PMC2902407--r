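#' Default TaqMan-style array layout
#'
#' Models the assay content of a 384-well microfluidic qPCR card as used for
#' microRNA profiling: `n_mirs` individual miR assays (one well each), three
#' endogenous small-nucleolar-RNA control assays spotted in duplicate, and a
#' duplicated negative-control blank well.
#'
#' @param n_mirs Number of individual microRNA assays on the card (default 365).
#'
#' @return A tibble with columns `assay_id`, `role` (one of `"mir"`,
#'   `"endogenous_control"`, `"blank"`) and `n_wells` (wells per assay on one
#'   card).
#' @export
#' @examples
#' default_array_layout()
default_array_layout <- function(n_mirs = 365) {
  tibble(
    assay_id = c(
      sprintf("miR-%03d", seq_len(n_mirs)),
      paste0("snoRNA-ctrl-", 1:3),
      "blank"
    ),
    role = c(rep("mir", n_mirs), rep("endogenous_control", 3), "blank"),
    n_wells = c(rep(1L, n_mirs), rep(2L, 3), 2L)
  )
}

assay_roles <- c("mir", "endogenous_control", "blank")

#' Coerce and validate a long Ct table
#'
#' The package's universal currency is a long tibble of Ct measurements with
#' one row per (assay, condition) well: columns `assay_id`, `condition_id`,
#' `ct` and `censored`, plus an optional `role` column (defaulted to `"mir"`).
#' A Ct of 40 is the instrument's detection ceiling ("Undetermined": no
#' amplification within 40 cycles) and is recorded as `ct = 40` with
#' `censored = TRUE`; censoring and `ct == 40` must agree row by row.
#'
#' @param x A data frame with at least `assay_id`, `condition_id` and `ct`
#'   columns. A missing `censored` column is derived from `ct == 40`.
#'
#' @return A validated tibble with columns `assay_id`, `condition_id`, `role`,
#'   `ct`, `censored`.
#' @export
as_ct_table <- function(x) {
  x <- as_tibble(x)
  needed <- c("assay_id", "condition_id", "ct")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Ct table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"censored" %in% names(x)) x$censored <- x$ct == 40
  if (!"role" %in% names(x)) x$role <- "mir"
  x <- x |>
    mutate(
      assay_id = as.character(assay_id),
      condition_id = as.character(condition_id),
      ct = as.numeric(ct),
      censored = as.logical(censored),
      role = as.character(role)
    ) |>
    select(assay_id, condition_id, role, ct, censored)
  validate_ct_table(x)
  x
}

validate_ct_table <- function(x) {
  if (any(!x$role %in% assay_roles)) {
    abort(paste0("unknown assay role(s): ",
                 paste(unique(setdiff(x$role, assay_roles)), collapse = ", ")))
  }
  bad <- which(!is.finite(x$ct) | x$ct <= 0 | x$ct > 40)
  if (length(bad) > 0) {
    abort(sprintf("Ct values must lie in (0, 40]; offending row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  disagree <- which(x$censored != (x$ct == 40))
  if (length(disagree) > 0) {
    abort(sprintf(
      "censoring flag must hold exactly when ct = 40; offending row(s): %s",
      paste(head(disagree, 5), collapse = ", ")))
  }
  dup <- duplicated(x[c("assay_id", "condition_id")])
  if (any(dup)) {
    d <- x[dup, , drop = FALSE]
    abort(sprintf("duplicate measurement for (%s, %s)",
                  d$assay_id[1], d$condition_id[1]))
  }
  invisible(x)
}

parse_ct_token <- function(token, line) {
  token <- trimws(token)
  if (tolower(token) == "undetermined") {
    return(c(ct = 40, censored = 1))
  }
  value <- suppressWarnings(as.numeric(token))
  if (is.na(value)) {
    abort(sprintf("line %d: cannot parse Ct value '%s'", line, token))
  }
  if (value <= 0 || value > 40) {
    abort(sprintf("line %d: Ct value %s outside (0, 40]", line, token))
  }
  c(ct = value, censored = as.numeric(value == 40))
}

#' Read a Ct table from CSV
#'
#' Two dialects are supported. The *long* dialect (the canonical interchange
#' format) has one row per well: columns `assay_id`, `condition_id`, `ct` and
#' optionally `role`. The *wide* dialect has assays as rows (first column
#' `assay_id`, optional `role` column) and one column per condition; empty
#' cells denote missing wells. In either dialect the token `"Undetermined"`
#' (case-insensitive) and the value `40` both map to a censored Ct of 40;
#' values outside (0, 40] are a range error, never clamped.
#'
#' @param path Path to a CSV file (UTF-8, header row required).
#' @param dialect `"long"` or `"wide"`.
#'
#' @return A validated long Ct tibble (see [as_ct_table()]).
#' @export
read_ct_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (dialect == "long") {
    needed <- c("assay_id", "condition_id", "ct")
    if (!all(needed %in% names(raw))) {
      abort(paste0("long dialect requires columns: ",
                   paste(needed, collapse = ", ")))
    }
    if (nrow(raw) == 0) {
      return(as_ct_table(tibble(assay_id = character(),
                                condition_id = character(),
                                ct = numeric())))
    }
    bad <- which(is.na(raw$assay_id) | is.na(raw$condition_id) | is.na(raw$ct))
    if (length(bad) > 0) {
      abort(sprintf("line %d: malformed row (missing field)", bad[1] + 1L))
    }
    parsed <- vapply(seq_len(nrow(raw)),
                     function(i) parse_ct_token(raw$ct[i], i + 1L),
                     numeric(2))
    out <- tibble(
      assay_id = raw$assay_id,
      condition_id = raw$condition_id,
      ct = parsed["ct", ],
      censored = parsed["censored", ] == 1
    )
    if ("role" %in% names(raw)) out$role <- raw$role
  } else {
    if (names(raw)[1] != "assay_id") {
      abort("wide dialect requires 'assay_id' as the first column")
    }
    cond_cols <- setdiff(names(raw), c("assay_id", "role"))
    long <- raw |>
      pivot_longer(all_of(cond_cols), names_to = "condition_id",
                   values_to = "token") |>
      filter(!is.na(token) & trimws(token) != "")
    if (nrow(long) == 0) {
      return(as_ct_table(tibble(assay_id = character(),
                                condition_id = character(),
                                ct = numeric())))
    }
    parsed <- vapply(seq_len(nrow(long)),
                     function(i) parse_ct_token(long$token[i], NA_integer_),
                     numeric(2))
    out <- long |>
      mutate(ct = parsed["ct", ], censored = parsed["censored", ] == 1) |>
      select(-token)
  }
  as_ct_table(out)
}

format_ct_token <- function(ct, censored) {
  ifelse(censored, "Undetermined", sprintf("%.17g", ct))
}

#' Write a Ct table to CSV
#'
#' Inverse of [read_ct_table()]: censored measurements are emitted as the
#' token `"Undetermined"` in both dialects, so `read(write(x))` reproduces
#' `x` exactly, including censoring flags. Missing wells appear as empty
#' cells in the wide dialect and are simply absent in the long dialect.
#'
#' @param ct A long Ct tibble (see [as_ct_table()]).
#' @param path Output CSV path.
#' @param dialect `"long"` or `"wide"`.
#'
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  ct <- as_ct_table(ct)
  if (dialect == "long") {
    out <- ct |>
      mutate(ct = format_ct_token(ct, censored)) |>
      select(assay_id, condition_id, role, ct)
  } else {
    out <- ct |>
      mutate(token = format_ct_token(ct, censored)) |>
      select(assay_id, role, condition_id, token) |>
      pivot_wider(names_from = condition_id, values_from = token)
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a sample-metadata sheet
#'
#' Metadata are keyed by `condition_id` and describe each run condition:
#' tissue source (`FFPE`, `frozen`, `reference`), RNA extraction method,
#' disease state, input RNA concentration (ng/uL), cDNA fold-dilution and
#' replicate index. A cDNA dilution below 5-fold is rejected: the array
#' chemistry requires at least a 5x dilution to supply the loading volume.
#'
#' @param path Path to a metadata CSV keyed by `condition_id`.
#' @return A tibble, one row per condition.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_metadata(meta)
}

validate_sample_metadata <- function(meta) {
  meta <- as_tibble(meta)
  if (!"condition_id" %in% names(meta)) {
    abort("metadata requires a 'condition_id' column")
  }
  if (anyDuplicated(meta$condition_id)) {
    abort("condition_id must be unique in sample metadata")
  }
  if ("cdna_dilution" %in% names(meta) && any(meta$cdna_dilution < 5)) {
    abort("cdna_dilution must be at least 5 (minimum loading dilution)")
  }
  if ("input_rna_conc" %in% names(meta) && any(meta$input_rna_conc <= 0)) {
    abort("input_rna_conc must be positive")
  }
  meta
}

#' Drop miR assays censored in every condition
#'
#' Pre-filtering rule for downstream analysis: a miR assay whose Ct is 40
#' ("Undetermined") in *all* conditions carries no evidence of expression and
#' is removed; an assay with even one uncensored value in any condition is
#' retained. Endogenous-control and blank assays are tracked, never filtered.
#' The operation is idempotent.
#'
#' @param ct A long Ct tibble.
#' @return The filtered Ct tibble.
#' @export
prefilter_all_censored <- function(ct) {
  ct <- as_ct_table(ct)
  drop <- ct |>
    filter(role == "mir") |>
    summarise(all_cens = all(censored), .by = assay_id) |>
    filter(all_cens) |>
    pull(assay_id)
  ct |> filter(!(assay_id %in% drop))
}

#' Effective template concentration of each condition
#'
#' The amount of template actually loaded per well scales as input RNA
#' concentration divided by the cDNA fold-dilution. Conditions with equal
#' ratios (e.g. 200 ng/uL at 15x, 100 ng/uL at 7.5x, 66.7 ng/uL at 5x) are
#' *equivalent samples* and should yield the same expression profile.
#'
#' @param meta Sample metadata with `input_rna_conc` and `cdna_dilution`.
#' @return `meta` with an added `eff_template_conc` column (ng/uL-equivalent).
#' @export
effective_template_concentration <- function(meta) {
  meta <- as_tibble(meta)
  if (any(meta$input_rna_conc <= 0) || any(meta$cdna_dilution <= 0)) {
    abort("input_rna_conc and cdna_dilution must be positive")
  }
  meta |> mutate(eff_template_conc = input_rna_conc / cdna_dilution)
}

#' Identify equivalent-sample pairs
#'
#' Two conditions are equivalent when their effective template concentrations
#' agree within a relative tolerance (default 1%, generous enough to treat
#' 66.7/5 and 200/15 as equal — they differ by 0.05%).
#'
#' @param meta Sample metadata with `input_rna_conc` and `cdna_dilution`.
#' @param tol Relative tolerance on the concentration ratio.
#' @return A tibble of unordered condition pairs with their ratios and an
#'   `equivalent` flag.
#' @export
equivalent_samples <- function(meta, tol = 0.01) {
  meta <- effective_template_concentration(meta)
  pairs <- crossing(a = seq_len(nrow(meta)), b = seq_len(nrow(meta))) |>
    filter(a < b)
  tibble(
    condition_a = meta$condition_id[pairs$a],
    condition_b = meta$condition_id[pairs$b],
    eff_conc_a = meta$eff_template_conc[pairs$a],
    eff_conc_b = meta$eff_template_conc[pairs$b]
  ) |>
    mutate(equivalent = abs(eff_conc_a - eff_conc_b) <=
             tol * pmax(eff_conc_a, eff_conc_b))
}
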