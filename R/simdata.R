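#' Configuration for a synthetic TaqMan-style array study
#'
#' Defines the generative model for synthetic Ct data emulating a 384-well
#' microfluidic qPCR miR array study of FFPE and fresh-frozen tissue. For
#' assay *i* in condition *c* the pre-censoring true Ct is
#'
#' `true = base_i - efficiency_slope * log2(conc_c / reference_conc)
#'        + dilution_penalty * log2(dilution_c / min(dilutions))
#'        + shift_i * [FFPE] + effect_i * [tumour]`
#'
#' and the observed value is `true + e` with
#' `e ~ Normal(0, sigma0 + sigma1 * max(0, true - knee))` — replicate noise
#' grows once the template becomes scarce (above the knee, default Ct 30).
#' A well independently fails (no amplification) with probability
#' `plogis((true - midpoint_c) * failure_steepness)`, where the midpoint is
#' lowered by `dilution_failure_coupling * log2(dilution_c / min(dilutions))`
#' so that stronger cDNA dilution raises the failure rate without moving the
#' Ct location. Failed wells and observations reaching 40 cycles are
#' recorded as Ct 40, censored. Duplicate plates are independent noise and
#' failure draws around the same true Ct.
#'
#' Baseline Cts are drawn from a three-component normal mixture (defaults
#' centred at 26, 32 and 37 cycles) so that the high/medium/low strata are
#' each well populated at the reference concentration. The per-assay FFPE
#' shift is `Normal(ffpe_shift_mean, ffpe_shift_sd)` (default 1.25 +/- 0.25
#' cycles, the magnitude reported for formalin fixation); `n_de` assays
#' receive a tumour effect of `+/- de_effect` cycles with random sign.
#'
#' @param n_mirs Number of miR assays (default 365).
#' @param baseline_means,baseline_sds,baseline_weights Mixture components
#'   for the baseline Ct distribution at the reference concentration.
#' @param efficiency_slope Cycles gained per twofold loss of input RNA.
#' @param reference_conc Reference input RNA concentration (ng/uL).
#' @param concentrations Titration series (ng/uL).
#' @param dilutions cDNA fold-dilution series.
#' @param ffpe_shift_mean,ffpe_shift_sd Per-assay FFPE Ct shift (cycles).
#' @param noise_sigma0,noise_sigma1,noise_knee Replicate-noise model.
#' @param failure_midpoint,failure_steepness Logistic well-failure model.
#' @param dilution_penalty Cycles per log2 fold-dilution added to true Ct
#'   (default 0: dilution acts through the failure model).
#' @param dilution_failure_coupling Cycles by which one log2 of extra
#'   dilution lowers the failure midpoint.
#' @param n_de,de_effect Number of differentially expressed miRs (default:
#'   about one in six, 60 of 365) and the magnitude (cycles) of their tumour
#'   effect.
#' @param n_tumour,n_normal Paired clinical samples per disease state.
#' @param seed Integer seed recorded in every output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_mirs = 365,
                       baseline_means = c(26, 32, 37),
                       baseline_sds = c(2, 1.5, 1.2),
                       baseline_weights = c(0.35, 0.35, 0.30),
                       efficiency_slope = 1,
                       reference_conc = 200,
                       concentrations = c(10, 25, 50, 100, 200),
                       dilutions = c(5, 15, 30, 62.5),
                       ffpe_shift_mean = 1.25,
                       ffpe_shift_sd = 0.25,
                       noise_sigma0 = 0.15,
                       noise_sigma1 = 0.25,
                       noise_knee = 30,
                       failure_midpoint = 38,
                       failure_steepness = 1,
                       dilution_penalty = 0,
                       dilution_failure_coupling = 0.5,
                       n_de = NULL,
                       de_effect = 2,
                       n_tumour = 3,
                       n_normal = 3,
                       seed = 1L) {
  n_de <- n_de %||% round(n_mirs * 60 / 365)
  config <- list(
    n_mirs = n_mirs, baseline_means = baseline_means,
    baseline_sds = baseline_sds, baseline_weights = baseline_weights,
    efficiency_slope = efficiency_slope, reference_conc = reference_conc,
    concentrations = concentrations, dilutions = dilutions,
    ffpe_shift_mean = ffpe_shift_mean, ffpe_shift_sd = ffpe_shift_sd,
    noise_sigma0 = noise_sigma0, noise_sigma1 = noise_sigma1,
    noise_knee = noise_knee, failure_midpoint = failure_midpoint,
    failure_steepness = failure_steepness,
    dilution_penalty = dilution_penalty,
    dilution_failure_coupling = dilution_failure_coupling,
    n_de = n_de, de_effect = de_effect,
    n_tumour = n_tumour, n_normal = n_normal, seed = as.integer(seed)
  )
  problems <- character()
  if (n_mirs < 1) problems <- c(problems, "n_mirs")
  if (length(baseline_means) != length(baseline_sds) ||
      length(baseline_means) != length(baseline_weights)) {
    problems <- c(problems, "baseline mixture lengths")
  }
  if (any(baseline_sds <= 0) || any(baseline_weights <= 0)) {
    problems <- c(problems, "baseline mixture scales")
  }
  if (any(concentrations <= 0) || any(concentrations > reference_conc)) {
    problems <- c(problems, "concentrations")
  }
  if (any(dilutions < 5)) problems <- c(problems, "dilutions")
  if (any(c(failure_steepness, reference_conc) <= 0) ||
      noise_sigma0 < 0 || noise_sigma1 < 0 || ffpe_shift_sd < 0) {
    problems <- c(problems, "noise/failure scales")
  }
  if (n_de < 0 || n_de > n_mirs || de_effect < 0) {
    problems <- c(problems, "differential-expression settings")
  }
  if (n_tumour < 1 || n_normal < 1) problems <- c(problems, "sample counts")
  if (length(problems) > 0) {
    abort(paste0("invalid sim_config field(s): ",
                 paste(problems, collapse = ", ")))
  }
  structure(config, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic array study: %d miRs, FFPE shift %.2f +/- %.2f Ct, seed %d\n",
    x$n_mirs, x$ffpe_shift_mean, x$ffpe_shift_sd, x$seed))
  invisible(x)
}

#' Default condition design for a synthetic study
#'
#' Builds the sample-metadata sheet the generator simulates: an input-RNA
#' titration with duplicate plates at a fixed 15x dilution, a single-plate
#' cDNA dilution series at 100 and 200 ng/uL, an equivalent-samples trio
#' (200/15x, 100/7.5x, 66.7/5x), paired tumour and normal clinical samples
#' profiled as FFPE (RecoverAll) and fresh-frozen (mirVana and
#' TRIzol-Qiagen) extractions, and one Universal RNA positive control.
#'
#' @param config A [sim_config()] object.
#' @return A metadata tibble with a `design` column naming each block.
#' @export
default_study_conditions <- function(config = sim_config()) {
  titration <- crossing(conc = config$concentrations, rep = 1:2) |>
    mutate(
      condition_id = sprintf("node0_c%03d_r%d", round(conc), rep),
      tissue_source = "FFPE", extraction_method = "RecoverAll",
      disease_state = "normal", input_rna_conc = conc,
      cdna_dilution = 15, replicate_index = rep,
      sample_id = "node0", design = "titration"
    ) |> select(-conc, -rep)
  dilution <- crossing(conc = c(100, 200), dil = config$dilutions) |>
    mutate(
      condition_id = sprintf("node0_c%03d_d%04.1f", round(conc), dil),
      tissue_source = "FFPE", extraction_method = "RecoverAll",
      disease_state = "normal", input_rna_conc = conc,
      cdna_dilution = dil, replicate_index = 1L,
      sample_id = "node0", design = "dilution_series"
    ) |> select(-conc, -dil)
  equivalence <- tibble(
    input_rna_conc = c(200, 100, 66.7),
    cdna_dilution = c(15, 7.5, 5)
  ) |>
    mutate(
      condition_id = sprintf("node0_eq%.0f_d%.1f", input_rna_conc,
                             cdna_dilution),
      tissue_source = "FFPE", extraction_method = "RecoverAll",
      disease_state = "normal", replicate_index = 1L,
      sample_id = "node0", design = "equivalence"
    )
  samples <- tibble(
    sample_id = c(paste0("t", seq_len(config$n_tumour)),
                  paste0("n", seq_len(config$n_normal))),
    disease_state = c(rep("tumour", config$n_tumour),
                      rep("normal", config$n_normal))
  )
  methods <- tibble(
    method = c("ffpe", "mirvana", "trizol"),
    tissue_source = c("FFPE", "frozen", "frozen"),
    extraction_method = c("RecoverAll", "mirVana", "TRIzol_Qiagen")
  )
  clinical <- crossing(samples, methods) |>
    mutate(
      condition_id = paste0(sample_id, "_", method),
      input_rna_conc = 200, cdna_dilution = 15, replicate_index = 1L,
      design = "clinical"
    ) |> select(-method)
  universal <- tibble(
    condition_id = "universal", tissue_source = "reference",
    extraction_method = "other", disease_state = "universal_control",
    input_rna_conc = 200, cdna_dilution = 15, replicate_index = 1L,
    sample_id = "universal", design = "control"
  )
  bind_rows(titration, dilution, equivalence, clinical, universal) |>
    select(condition_id, tissue_source, extraction_method, disease_state,
           input_rna_conc, cdna_dilution, replicate_index, sample_id, design)
}

sigma_at <- function(true_ct, config) {
  config$noise_sigma0 +
    config$noise_sigma1 * pmax(0, true_ct - config$noise_knee)
}

#' Simulate a synthetic array study
#'
#' Draws per-assay ground truth (baseline Ct, FFPE shift, tumour effect),
#' then generates one well per (assay, condition) under the generative model
#' described in [sim_config()]. Blank wells never amplify; endogenous
#' controls are stably expressed near Ct 20 and carry no tumour effect.
#' Identical seeds reproduce identical studies.
#'
#' @param config A [sim_config()] object.
#' @param conditions Optional metadata tibble (see
#'   [default_study_conditions()] for the required columns).
#' @return A list of class `sim_study` with elements `ct` (long Ct tibble),
#'   `metadata`, `truth` (list of `assays` and `wells` tibbles) and `config`.
#' @export
simulate_study <- function(config = sim_config(), conditions = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("'config' must be a sim_config object")
  }
  set.seed(config$seed)
  metadata <- conditions %||% default_study_conditions(config)
  metadata <- validate_sample_metadata(metadata)
  layout <- default_array_layout(config$n_mirs)

  n_mirs <- config$n_mirs
  comp <- sample.int(length(config$baseline_means), n_mirs, replace = TRUE,
                     prob = config$baseline_weights)
  baseline <- rnorm(n_mirs, config$baseline_means[comp],
                    config$baseline_sds[comp])
  baseline <- pmin(pmax(baseline, 15), 39.5)
  ffpe_shift <- rnorm(n_mirs, config$ffpe_shift_mean, config$ffpe_shift_sd)
  de_effect <- numeric(n_mirs)
  if (config$n_de > 0) {
    de_idx <- sample.int(n_mirs, config$n_de)
    de_effect[de_idx] <- sample(c(-1, 1), config$n_de, replace = TRUE) *
      config$de_effect
  }
  ctrl_baseline <- rnorm(3, 20, 0.5)
  assays <- tibble(
    assay_id = layout$assay_id,
    role = layout$role,
    baseline_ct = c(baseline, ctrl_baseline, NA_real_),
    ffpe_shift = c(ffpe_shift, rep(0, 3), NA_real_),
    de_effect = c(de_effect, rep(0, 3), NA_real_)
  )

  min_dil <- min(config$dilutions, metadata$cdna_dilution)
  wells <- crossing(assay_id = layout$assay_id,
                    condition_id = metadata$condition_id) |>
    left_join(assays, by = "assay_id") |>
    left_join(metadata, by = "condition_id") |>
    arrange(condition_id, assay_id)
  wells <- wells |>
    mutate(
      true_ct = baseline_ct -
        config$efficiency_slope * log2(input_rna_conc / config$reference_conc) +
        config$dilution_penalty * log2(cdna_dilution / min_dil) +
        ffpe_shift * (tissue_source == "FFPE") +
        de_effect * (disease_state == "tumour"),
      midpoint = config$failure_midpoint -
        config$dilution_failure_coupling * log2(cdna_dilution / min_dil),
      failure_prob = ifelse(role == "blank", 1,
                            plogis((true_ct - midpoint) *
                                     config$failure_steepness))
    )
  n <- nrow(wells)
  sig <- sigma_at(wells$true_ct, config)
  sig[is.na(sig)] <- 0          # blank wells: no template, no noise draw
  noise <- rnorm(n, 0, sig)
  failed <- stats::runif(n) < wells$failure_prob
  observed <- wells$true_ct + noise
  censored <- failed | is.na(observed) | observed >= 40
  ct_val <- ifelse(censored, 40, pmax(observed, 0.01))

  ct <- tibble(
    assay_id = wells$assay_id,
    condition_id = wells$condition_id,
    role = wells$role,
    ct = ct_val,
    censored = censored
  )
  truth_wells <- tibble(
    assay_id = wells$assay_id,
    condition_id = wells$condition_id,
    true_ct = wells$true_ct,
    failure_prob = wells$failure_prob,
    failed = failed
  )
  structure(
    list(ct = as_ct_table(ct), metadata = metadata,
         truth = list(assays = assays, wells = truth_wells),
         config = config),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic array study: %d assays x %d conditions (%d wells), seed %d\n",
    length(unique(x$ct$assay_id)), nrow(x$metadata), nrow(x$ct),
    x$config$seed))
  invisible(x)
}

#' Recover generative parameters from a simulated study
#'
#' Checks that the analysis pipeline can read back what the generator put
#' in: the FFPE Ct shift (paired mean difference between FFPE and mirVana
#' fresh-frozen conditions of the clinical block), the amplification
#' efficiency slope (within-assay regression of Ct on log2 input
#' concentration across the titration block, complete uncensored assays
#' only), and the replicate noise scale per abundance stratum (from the
#' duplicate plates at the reference concentration, compared with the
#' average generative sigma of the contributing wells).
#'
#' @param study A `sim_study` object from [simulate_study()].
#' @param cutoffs A [stratum_cutoffs()] object for the noise-scale report.
#' @return Tibble with columns `parameter`, `estimate`, `truth`,
#'   `abs_error`.
#' @export
recover_parameters <- function(study, cutoffs = stratum_cutoffs()) {
  if (!inherits(study, "sim_study")) abort("'study' must be a sim_study")
  ct <- study$ct
  meta <- study$metadata
  config <- study$config
  if (!"design" %in% names(meta)) meta$design <- NA_character_
  out <- list()

  clinical <- meta |> filter(design == "clinical")
  if (nrow(clinical) > 0) {
    ffpe_conds <- clinical |> filter(tissue_source == "FFPE") |>
      pull(condition_id)
    frozen_conds <- clinical |> filter(extraction_method == "mirVana") |>
      pull(condition_id)
    shift_est <- paired_group_difference(ct, frozen_conds, ffpe_conds,
                                         censor = "exclude")
    out$ffpe_shift <- tibble(
      parameter = "ffpe_shift", estimate = shift_est$estimate,
      truth = config$ffpe_shift_mean
    )
  }

  titr <- meta |> filter(design == "titration")
  if (nrow(titr) > 0) {
    sub <- ct |>
      filter(role == "mir", condition_id %in% titr$condition_id) |>
      left_join(titr |> select(condition_id, input_rna_conc),
                by = "condition_id")
    complete_assays <- sub |>
      summarise(ok = !any(censored) && n() == nrow(titr), .by = assay_id) |>
      filter(ok) |> pull(assay_id)
    sub <- sub |>
      filter(assay_id %in% complete_assays) |>
      mutate(log2conc = log2(input_rna_conc / config$reference_conc)) |>
      mutate(dct = ct - mean(ct), dlog = log2conc - mean(log2conc),
             .by = assay_id)
    fit <- lm(dct ~ dlog - 1, data = sub)
    out$slope <- tibble(
      parameter = "efficiency_slope", estimate = -unname(coef(fit)["dlog"]),
      truth = config$efficiency_slope
    )
  }

  ref_conc <- config$reference_conc
  dup <- meta |> filter(design == "titration", input_rna_conc == ref_conc)
  if (nrow(dup) >= 2) {
    pts <- duplicate_agreement(ct, dup$condition_id[1], dup$condition_id[2])
    truth_map <- study$truth$wells |>
      filter(condition_id == dup$condition_id[1]) |>
      select(assay_id, true_ct)
    pts <- pts |>
      left_join(truth_map, by = "assay_id") |>
      mutate(stratum = assign_stratum(mean_ct, cutoffs))
    noise <- pts |>
      summarise(
        estimate = sqrt(mean((ct_a - ct_b)^2) / 2),
        truth = mean(sigma_at(true_ct, config)),
        .by = stratum
      ) |>
      mutate(parameter = paste0("noise_sigma_", stratum)) |>
      select(parameter, estimate, truth)
    out$noise <- noise
  }

  list_rbind(unname(out)) |> mutate(abs_error = abs(estimate - truth))
}
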