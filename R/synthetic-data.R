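#' Synthetic multiplex gene panel
#'
#' Builds a panel emulating the design constraints of a real multiplex:
#' distinct amplicon lengths spread over the separable range, one spike-in
#' internal-standard gene, per-gene transcript abundances spanning several
#' orders of magnitude, attenuated reverse-primer stocks in the documented
#' range, and regulation assignments (up / down / constant) with fold
#' changes for mixing and time-series simulations. Per-gene hybridization
#' rates are drawn so that the pseudo-first-order exposure `k' t` spans a
#' moderate range — together with the abundance spread this makes the
#' normalized peak areas cover roughly three orders of magnitude, the
#' regime the primer attenuation is designed for.
#'
#' @param n_genes Number of transcripts (the spike-in is added on top).
#' @param length_range Amplicon length range in nucleotides.
#' @param primer_conc_range Attenuated reverse-primer stock range
#'   (micromolar).
#' @param conc_orders Orders of magnitude spanned by transcript abundance.
#' @param mean_conc Geometric-centre transcript concentration (M).
#' @param prop_up,prop_down Fractions of up-/down-regulated genes.
#' @param fold_range Fold-change range for regulated genes.
#' @param rt_time RT time (s) used when scaling hybridization rates.
#' @param seed Optional integer seed; the generator is fully deterministic
#'   given it.
#' @return A panel tibble with `gene_id`, `expected_length_nt`,
#'   `is_spike_in`, `rt_primer_conc` (uM stock), `primer_conc` (M, final in
#'   reaction), `hybridization_rate` (M^-1 s^-1), `initial_conc` (M at the
#'   undiluted reference), `regulation`, `fold_change`.
#' @export
synthetic_panel <- function(n_genes = 35, length_range = c(114, 357),
                            primer_conc_range = c(0.00025, 0.5),
                            conc_orders = 3, mean_conc = 6.9e-15,
                            prop_up = 0.2, prop_down = 0.2,
                            fold_range = c(2, 16), rt_time = 3600,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_number(n_genes, "n_genes", min = 1, allow_vec = FALSE)
  n_total <- n_genes + 1
  # evenly spaced integer lengths keep every pair separable at tolerance 2
  lengths <- round(seq(length_range[1], length_range[2],
                       length.out = n_total))
  if (anyDuplicated(lengths) || min(diff(sort(lengths))) < 5) {
    abort_config("length range too narrow to separate this many genes")
  }
  gene_ids <- sprintf("g%02d", seq_len(n_genes))
  n_up <- round(prop_up * n_genes)
  n_down <- round(prop_down * n_genes)
  regulation <- sample(c(rep("up", n_up), rep("down", n_down),
                         rep("constant", n_genes - n_up - n_down)))
  stock_um <- 10^runif(n_genes, log10(primer_conc_range[1]),
                       log10(primer_conc_range[2]))
  primer_m <- rt_primer_final_conc(stock_um)
  # draw the dimensionless exposure k' t, then back out k
  exposure <- 10^runif(n_genes, log10(0.1), log10(5))
  k <- exposure / (rt_time * primer_m)
  panel <- tibble(
    gene_id = gene_ids,
    expected_length_nt = lengths[seq_len(n_genes)],
    is_spike_in = FALSE,
    rt_primer_conc = stock_um,
    primer_conc = primer_m,
    hybridization_rate = k,
    initial_conc = 10^runif(n_genes, log10(mean_conc) - conc_orders / 2,
                            log10(mean_conc) + conc_orders / 2),
    regulation = regulation,
    fold_change = ifelse(regulation == "constant", 1,
                         10^runif(n_genes, log10(fold_range[1]),
                                  log10(fold_range[2])))
  )
  spike <- tibble(
    gene_id = "KANr", expected_length_nt = lengths[n_total],
    is_spike_in = TRUE, rt_primer_conc = 0.5,
    primer_conc = rt_primer_final_conc(0.5),
    hybridization_rate = 1 / (rt_time * rt_primer_final_conc(0.5)),
    initial_conc = mean_conc * 10, regulation = "constant", fold_change = 1
  )
  validate_panel(bind_rows(panel, spike))
}

# one run's fragment table from per-gene template concentrations (M)
simulate_run <- function(panel, conc, rt_time, reaction_order, cycles,
                         efficiency, noise_sd, length_jitter_sd, run_scale,
                         area_scale) {
  amount <- amplified_cdna(
    rna0 = conc,
    kprime = pseudo_rate(panel$hybridization_rate, panel$primer_conc),
    t = rt_time, n = reaction_order, cycles = cycles, efficiency = efficiency
  )
  area <- area_scale * run_scale * amount *
    exp(rnorm(nrow(panel), 0, noise_sd))
  tibble(
    fragment_index = seq_len(nrow(panel)),
    length_nt = panel$expected_length_nt +
      rnorm(nrow(panel), 0, length_jitter_sd),
    peak_height = area / 2, # nominal peak shape; height is not used downstream
    peak_area = area
  )
}

#' Simulate a dilution-series experiment
#'
#' Generates fragment tables for a serial dilution of total RNA measured in
#' replicate, with the structure the calibration procedure assumes: every
#' transcript's template scales with the total RNA, peak areas follow the
#' kinetic forward model times a per-run global scale factor and
#' multiplicative lognormal noise, and the spike-in template is held
#' constant per reaction (its area is constant within a run before noise).
#' Ground truth (expected noise-free NPAs and the parameters) is returned
#' alongside.
#'
#' @param panel A panel from [synthetic_panel()] (needs the simulation
#'   columns `initial_conc`, `primer_conc`, `hybridization_rate`).
#' @param dilutions Total RNA per reaction (ng); default 8 two-fold steps
#'   from 100 ng down to 0.78125 ng.
#' @param replicates Independent measurements per dilution.
#' @param reaction_order RT reaction order `n`.
#' @param rt_time RT time (s).
#' @param cycles,efficiency PCR settings.
#' @param noise_sd SD of the multiplicative lognormal noise on peak areas
#'   (natural-log scale).
#' @param length_jitter_sd SD of Gaussian sizing jitter (nt).
#' @param scale_range Range of the uniform per-run global scale factor
#'   (cancels in NPA).
#' @param area_scale Fluorescence units per molar amplified cDNA.
#' @param ref_total_rna Total RNA (ng) at which `initial_conc` applies.
#' @param seed Optional integer seed.
#' @return A list of class `gexp_sim` with `runs` (named list of fragment
#'   tibbles), `manifest` (tibble `run_id`, `sample_id`, `total_rna`,
#'   `replicate`), `truth` (list with the panel, the parameters and the
#'   expected noise-free NPA per gene and dilution).
#' @export
generate_dilution_series <- function(panel, dilutions = 100 / 2^(0:7),
                                     replicates = 2, reaction_order = 1,
                                     rt_time = 3600, cycles = 35,
                                     efficiency = 1, noise_sd = 0.05,
                                     length_jitter_sd = 0.1,
                                     scale_range = c(0.8, 1.25),
                                     area_scale = 1e8,
                                     ref_total_rna = max(dilutions),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- validate_panel(panel)
  check_number(dilutions, "dilutions", min = 0, strict = TRUE)
  if (length(dilutions) < 2) abort_fit("need at least 2 dilution points")
  check_number(replicates, "replicates", min = 1, allow_vec = FALSE)

  manifest <- tidyr::expand_grid(total_rna = as.numeric(dilutions),
                                 replicate = seq_len(replicates)) %>%
    mutate(
      sample_id = sprintf("std_%gng_r%d", .data$total_rna, .data$replicate),
      run_id = sprintf("run%02d", row_number())
    ) %>%
    select("run_id", "sample_id", "total_rna", "replicate")

  runs <- purrr::pmap(manifest, function(run_id, sample_id, total_rna, ...) {
    conc <- ifelse(panel$is_spike_in, panel$initial_conc,
                   panel$initial_conc * total_rna / ref_total_rna)
    simulate_run(panel, conc, rt_time, reaction_order, cycles, efficiency,
                 noise_sd, length_jitter_sd,
                 run_scale = runif(1, scale_range[1], scale_range[2]),
                 area_scale = area_scale)
  })
  names(runs) <- manifest$sample_id

  kprime <- pseudo_rate(panel$hybridization_rate, panel$primer_conc)
  spike_amount <- amplified_cdna(
    panel$initial_conc[panel$is_spike_in], kprime[panel$is_spike_in],
    rt_time, reaction_order, cycles, efficiency)
  true_npa <- tidyr::expand_grid(
    panel[c("gene_id", "is_spike_in")],
    total_rna = as.numeric(dilutions)
  ) %>%
    mutate(
      conc = ifelse(.data$is_spike_in,
                    panel$initial_conc[match(.data$gene_id, panel$gene_id)],
                    panel$initial_conc[match(.data$gene_id, panel$gene_id)] *
                      .data$total_rna / ref_total_rna),
      npa = amplified_cdna(.data$conc,
                           kprime[match(.data$gene_id, panel$gene_id)],
                           rt_time, reaction_order, cycles, efficiency) /
        spike_amount
    ) %>%
    select("gene_id", "total_rna", "npa")

  structure(
    list(
      runs = runs,
      manifest = manifest,
      truth = list(
        panel = panel,
        params = list(reaction_order = reaction_order, rt_time = rt_time,
                      cycles = cycles, efficiency = efficiency,
                      noise_sd = noise_sd, ref_total_rna = ref_total_rna,
                      area_scale = area_scale),
        expected_npa = true_npa
      )
    ),
    class = "gexp_sim"
  )
}

#' Simulate a two-pool mixing experiment
#'
#' Two RNA pools (A and B) share every transcript but regulated genes
#' differ by their panel fold change (up-regulated genes are more abundant
#' in pool B, down-regulated ones in pool A). Mixes at the given fractions
#' of pool A, under constant total RNA, are pushed through the kinetic
#' forward model; with first-order RT kinetics the expected NPA of every
#' gene is exactly linear in the mixing fraction, and the constant
#' spike-in's expected slope is zero.
#'
#' @inheritParams generate_dilution_series
#' @param ratios Fractions of pool A in the mix (in `[0, 1]`, >= 3 values).
#' @return A `gexp_sim` list; `manifest` carries `ratio`, and
#'   `truth$expected_npa` the per-gene linear response.
#' @export
generate_mixing_series <- function(panel, ratios = seq(0, 1, by = 0.25),
                                   reaction_order = 1, rt_time = 3600,
                                   cycles = 35, efficiency = 1,
                                   noise_sd = 0.05, length_jitter_sd = 0.1,
                                   scale_range = c(0.8, 1.25),
                                   area_scale = 1e8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- validate_panel(panel)
  if (length(unique(ratios)) < 3 || any(ratios < 0 | ratios > 1)) {
    abort_param("`ratios` must hold at least 3 distinct values in [0, 1]")
  }
  conc_a <- ifelse(panel$regulation == "down",
                   panel$initial_conc * panel$fold_change,
                   panel$initial_conc)
  conc_b <- ifelse(panel$regulation == "up",
                   panel$initial_conc * panel$fold_change,
                   panel$initial_conc)
  conc_a[panel$is_spike_in] <- panel$initial_conc[panel$is_spike_in]
  conc_b[panel$is_spike_in] <- panel$initial_conc[panel$is_spike_in]

  manifest <- tibble(ratio = as.numeric(sort(unique(ratios)))) %>%
    mutate(sample_id = sprintf("mix_%03d", round(100 * .data$ratio)),
           run_id = sprintf("run%02d", row_number())) %>%
    select("run_id", "sample_id", "ratio")

  runs <- purrr::pmap(manifest, function(run_id, sample_id, ratio) {
    conc <- ratio * conc_a + (1 - ratio) * conc_b
    conc[panel$is_spike_in] <- panel$initial_conc[panel$is_spike_in]
    simulate_run(panel, conc, rt_time, reaction_order, cycles, efficiency,
                 noise_sd, length_jitter_sd,
                 run_scale = runif(1, scale_range[1], scale_range[2]),
                 area_scale = area_scale)
  })
  names(runs) <- manifest$sample_id

  kprime <- pseudo_rate(panel$hybridization_rate, panel$primer_conc)
  spike_amount <- amplified_cdna(
    panel$initial_conc[panel$is_spike_in], kprime[panel$is_spike_in],
    rt_time, reaction_order, cycles, efficiency)
  true_npa <- tidyr::expand_grid(gene_id = panel$gene_id,
                                 ratio = manifest$ratio) %>%
    mutate(
      i = match(.data$gene_id, panel$gene_id),
      conc = ifelse(panel$is_spike_in[.data$i],
                    panel$initial_conc[.data$i],
                    .data$ratio * conc_a[.data$i] +
                      (1 - .data$ratio) * conc_b[.data$i]),
      npa = amplified_cdna(.data$conc, kprime[.data$i], rt_time,
                           reaction_order, cycles, efficiency) / spike_amount
    ) %>%
    select("gene_id", "ratio", "npa")

  structure(
    list(runs = runs, manifest = manifest,
         truth = list(panel = panel, expected_npa = true_npa,
                      conc_a = conc_a, conc_b = conc_b)),
    class = "gexp_sim"
  )
}

#' Simulate paired technical-replicate time series
#'
#' Emulates the replicate design used to assess reproducibility: a cohort
#' of cells sampled at several time points, every sample measured twice by
#' independent RT-PCR, the two measurements sharing one true expression
#' value. Regulated genes follow a monotone temporal profile (up or down by
#' their fold change over the course), constant genes stay flat up to
#' cell-level lognormal variability. Replicate noise is lognormal on the
#' log2 scale. Values at or below `detection_floor` are flagged below
#' limit.
#'
#' @param panel A panel from [synthetic_panel()].
#' @param n_cells Number of cells (time series).
#' @param timepoints Number of samples per cell.
#' @param replicate_sdlog2 SD of each measurement's noise in log2 units
#'   (the log2 replicate ratio then has SD `sqrt(2) * replicate_sdlog2`).
#' @param cell_sdlog Cell-level biological variability (natural-log SD).
#' @param detection_floor Relative-amount floor below which a measurement
#'   is flagged below limit (0 disables).
#' @param seed Optional integer seed.
#' @return A tibble with `cell_id`, `timepoint`, `gene_id`, `true_value`,
#'   `value_1`, `value_2`, `below_limit_1`, `below_limit_2`.
#' @export
generate_replicate_timeseries <- function(panel, n_cells = 26,
                                          timepoints = 5,
                                          replicate_sdlog2 = 0.35,
                                          cell_sdlog = 0.3,
                                          detection_floor = 0,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- validate_panel(panel)
  genes <- panel[!panel$is_spike_in, ]
  grid <- tidyr::expand_grid(
    cell_id = sprintf("P%02d", seq_len(n_cells)),
    timepoint = seq_len(timepoints),
    genes[c("gene_id", "regulation", "fold_change")]
  )
  base <- setNames(genes$initial_conc / min(genes$initial_conc),
                   genes$gene_id)
  grid %>%
    mutate(
      phase = (.data$timepoint - 1) / max(timepoints - 1, 1),
      profile = dplyr::case_when(
        .data$regulation == "up" ~ .data$fold_change^.data$phase,
        .data$regulation == "down" ~ .data$fold_change^(-.data$phase),
        TRUE ~ 1
      ),
      true_value = base[.data$gene_id] * .data$profile *
        exp(rnorm(dplyr::n(), 0, cell_sdlog)),
      value_1 = .data$true_value * 2^rnorm(dplyr::n(), 0, replicate_sdlog2),
      value_2 = .data$true_value * 2^rnorm(dplyr::n(), 0, replicate_sdlog2),
      below_limit_1 = .data$value_1 <= detection_floor,
      below_limit_2 = .data$value_2 <= detection_floor
    ) %>%
    select("cell_id", "timepoint", "gene_id", "true_value", "value_1",
           "value_2", "below_limit_1", "below_limit_2")
}

#' Write a simulated dataset to disk
#'
#' Emits one canonical fragment TSV per run, a `manifest.tsv`, a
#' `panel.tsv` and a `ground_truth.tsv` (expected noise-free NPAs), so a
#' simulated experiment can be processed by the same file-based workflow as
#' a real one.
#'
#' @param sim A `gexp_sim` from [generate_dilution_series()] or
#'   [generate_mixing_series()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "gexp_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- sim$manifest
  manifest$path <- file.path(dir, paste0(manifest$sample_id, ".tsv"))
  purrr::walk2(sim$runs, manifest$path, write_fragment_table)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$panel, file.path(dir, "panel.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$expected_npa, file.path(dir, "ground_truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
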