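#' Pseudo-first-order rate constant for RT-primer hybridization
#'
#' Primer binding to its template RNA is a second-order reaction with rate
#' constant `k` (M^-1 per unit time). Because the gene-specific reverse
#' primer is in large excess over its template, its concentration is
#' effectively constant during reverse transcription and the kinetics
#' collapse to pseudo-first order with rate constant
#' `k' = k * [Primer]`.
#'
#' @param k Second-order hybridization rate constant (M^-1 time^-1).
#' @param primer_conc Primer concentration (M). Must be strictly positive.
#' @return The pseudo-first-order rate constant `k'` (time^-1). Vectorized
#'   over both arguments.
#' @examples
#' pseudo_rate(1e6, 2.5e-11)
#' @export
pseudo_rate <- function(k, primer_conc) {
  check_number(k, "k", min = 0, strict = TRUE)
  check_number(primer_conc, "primer_conc", min = 0, strict = TRUE)
  k * primer_conc
}

#' Template RNA remaining after reverse transcription
#'
#' Integrates the empirical rate law `-d[RNA]/dt = k' [RNA]^n` from 0 to
#' `t`. For reaction order `n = 1` the template decays exponentially,
#' `[RNA] = [RNA]_0 exp(-k' t)`. For `n != 1` the closed form is
#' `[RNA] = (k' t (n - 1) + [RNA]_0^(1 - n))^(1 / (1 - n))`. For `n < 1`
#' this expression reaches zero in finite time (the template is exhausted);
#' past that point the result is clamped at 0 rather than turning complex.
#'
#' @param rna0 Initial template concentration `[RNA]_0` (M), >= 0.
#' @param kprime Pseudo-first-order rate constant `k'` (time^-1), >= 0.
#' @param t Reaction time, in units consistent with `kprime` (only the
#'   product `k' t` matters), >= 0.
#' @param n Empirical reaction order, > 0. Default 1.
#' @return Remaining template concentration, in `[0, rna0]`. Vectorized.
#' @examples
#' remaining_rna(1e-12, 1e-3, log(2) * 1e3) # one half-life -> rna0 / 2
#' @export
remaining_rna <- function(rna0, kprime, t, n = 1) {
  check_number(rna0, "rna0", min = 0)
  check_number(kprime, "kprime", min = 0)
  check_number(t, "t", min = 0)
  check_number(n, "n", min = 0, strict = TRUE, allow_vec = FALSE)
  if (n == 1) {
    return(rna0 * exp(-kprime * t))
  }
  base <- kprime * t * (n - 1) + rna0^(1 - n)
  out <- ifelse(base <= 0, 0, base^(1 / (1 - n)))
  # guard against floating-point overshoot above the initial amount
  pmin(pmax(out, 0), rna0)
}

#' First-strand cDNA synthesized during reverse transcription
#'
#' Mass balance over the RT reaction: every consumed template molecule
#' yields one first-strand cDNA, so
#' `[cDNA_1st] = [RNA]_0 - [RNA](t)`.
#'
#' @inheritParams remaining_rna
#' @return First-strand cDNA concentration in `[0, rna0]`, non-decreasing
#'   in `t` and `kprime`.
#' @export
first_strand_cdna <- function(rna0, kprime, t, n = 1) {
  rna0 - remaining_rna(rna0, kprime, t, n)
}

#' Overall PCR amplification factor
#'
#' The first PCR cycle synthesizes the second strand on each first-strand
#' cDNA, leaving `c - 1` cycles for amplification, so with per-cycle
#' efficiency `e` the overall factor is `alpha = (1 + e)^(c - 1)`;
#' `e = 1` (perfect doubling) gives the upper bound `2^(c - 1)`.
#'
#' @param cycles Number of PCR cycles `c`, integer >= 1.
#' @param efficiency Per-cycle amplification efficiency in (0, 1].
#' @return The amplification factor `alpha`.
#' @export
amplification_factor <- function(cycles, efficiency = 1) {
  check_number(cycles, "cycles", min = 1, allow_vec = FALSE)
  if (cycles != round(cycles)) abort_param("`cycles` must be an integer")
  check_number(efficiency, "efficiency", min = 0, strict = TRUE, allow_vec = FALSE)
  if (efficiency > 1) abort_param("`efficiency` must be <= 1")
  (1 + efficiency)^(cycles - 1)
}

#' Amplified cDNA after reverse transcription and PCR
#'
#' Forward model of the whole assay chemistry for one transcript: the
#' first-strand cDNA produced under the primer-limited rate law is
#' amplified by the universal-primer PCR with overall factor
#' `alpha = (1 + efficiency)^(cycles - 1)`. For `n = 1` the result is
#' `alpha * [RNA]_0 * (1 - exp(-k' t))`, exactly proportional to the
#' initial transcript concentration.
#'
#' @inheritParams remaining_rna
#' @inheritParams amplification_factor
#' @return Amplified cDNA concentration (same unit family as `rna0`).
#' @examples
#' amplified_cdna(1e-12, 1e-3, 3600, n = 1, cycles = 35)
#' @export
amplified_cdna <- function(rna0, kprime, t, n = 1, cycles = 35, efficiency = 1) {
  alpha <- amplification_factor(cycles, efficiency)
  alpha * first_strand_cdna(rna0, kprime, t, n)
}

#' Predicted log-log dilution response of a gene panel
#'
#' Evaluates the forward model for every gene of a panel across a total-RNA
#' dilution series in which every transcript is scaled by the same factor,
#' and returns the predicted amplified-cDNA amounts on both natural and
#' log10 scales. For first-order RT kinetics (`n = 1`) the log-log response
#' has slope exactly 1 for every gene; for a shared `n < 1` the response is
#' a family of near-parallel lines of common slope < 1 whose intercepts
#' differ with transcript abundance and primer concentration.
#'
#' @param panel A data frame with one row per gene: `gene_id`,
#'   `initial_conc` (M, transcript concentration at dilution factor 1),
#'   `primer_conc` (M, final RT-primer concentration) and
#'   `hybridization_rate` (M^-1 time^-1).
#' @param dilutions Numeric vector (>= 2 values, all > 0) of dilution
#'   factors applied to the total RNA (and hence to every transcript).
#' @param rt_time RT reaction time (units consistent with the rate).
#' @param reaction_order Empirical RT reaction order `n`.
#' @inheritParams amplification_factor
#' @return A tibble with columns `gene_id`, `dilution`, `log10_dilution`,
#'   `amount`, `log10_amount` (log10 amount is `NA` where the predicted
#'   amount is 0).
#' @seealso [fit_loglog_slopes()] to regress the predicted lines.
#' @export
predict_dilution_curve <- function(panel, dilutions, rt_time,
                                   reaction_order = 1, cycles = 35,
                                   efficiency = 1) {
  need <- c("gene_id", "initial_conc", "primer_conc", "hybridization_rate")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0) {
    abort_param(paste0("`panel` is missing column(s): ", toString(miss)))
  }
  check_number(dilutions, "dilutions", min = 0, strict = TRUE)
  if (length(dilutions) < 2) {
    abort_fit("at least 2 dilution points are required")
  }
  grid <- tidyr::expand_grid(
    panel[need],
    dilution = as.numeric(dilutions)
  )
  grid %>%
    mutate(
      amount = amplified_cdna(
        rna0 = .data$initial_conc * .data$dilution,
        kprime = pseudo_rate(.data$hybridization_rate, .data$primer_conc),
        t = rt_time, n = reaction_order,
        cycles = cycles, efficiency = efficiency
      ),
      log10_dilution = log10(.data$dilution),
      log10_amount = ifelse(.data$amount > 0, log10(.data$amount), NA_real_)
    ) %>%
    select("gene_id", "dilution", "log10_dilution", "amount", "log10_amount")
}

#' Per-gene slope of a log-log dilution curve
#'
#' Fits, for each gene, an ordinary least-squares line of `log10_amount`
#' (or `log10(npa)`) on `log10_dilution` and reports slope, intercept and
#' R-squared.
#'
#' @param curve A tibble as returned by [predict_dilution_curve()], or any
#'   data frame with `gene_id`, `log10_dilution` and `log10_amount`.
#' @return A tibble with `gene_id`, `slope`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
fit_loglog_slopes <- function(curve) {
  curve %>%
    filter(!is.na(.data$log10_amount)) %>%
    group_by(.data$gene_id) %>%
    summarise(ols_fit(.data$log10_dilution, .data$log10_amount),
              .groups = "drop")
}

#' Final RT-primer concentration in the reaction
#'
#' Converts an attenuated primer stock concentration (the per-gene value
#' adjusted so each fragment's fluorescence falls in the detector's linear
#' range) into the molar concentration in the assembled RT reaction, given
#' the pipetted primer-mix volume and the total reaction volume.
#'
#' @param stock_conc_um Stock concentration of the reverse primer in the
#'   primer mix (micromolar).
#' @param primer_volume_ul Volume of primer mix added (microlitres).
#' @param reaction_volume_ul Total RT reaction volume (microlitres).
#' @return Final primer concentration in the reaction, in molar. Vectorized
#'   over `stock_conc_um`.
#' @examples
#' rt_primer_final_conc(0.00025) # 2.5e-11 M
#' rt_primer_final_conc(0.5)     # 5e-8 M
#' @export
rt_primer_final_conc <- function(stock_conc_um, primer_volume_ul = 1,
                                 reaction_volume_ul = 10) {
  check_number(stock_conc_um, "stock_conc_um", min = 0, strict = TRUE)
  check_number(primer_volume_ul, "primer_volume_ul", min = 0, strict = TRUE,
               allow_vec = FALSE)
  check_number(reaction_volume_ul, "reaction_volume_ul", min = 0,
               strict = TRUE, allow_vec = FALSE)
  stock_conc_um * 1e-6 * primer_volume_ul / reaction_volume_ul
}

#' Average per-gene transcript concentration and copy number
#'
#' Back-of-the-envelope estimate of how much template an RT reaction
#' contains for a typical gene: the mRNA mass is a fixed fraction of the
#' total RNA, split evenly over the expressed genes, and converted to molar
#' concentration through the mean transcript length and the molar mass per
#' nucleotide; the copy number follows via Avogadro's number and the
#' reaction volume.
#'
#' @param total_rna_mass_ng Total RNA input per reaction (ng).
#' @param mrna_fraction Fraction of total RNA that is mRNA (0, 1].
#' @param n_genes Number of expressed genes sharing that mRNA mass.
#' @param mean_mrna_length Mean mature-mRNA length (nucleotides).
#' @param reaction_volume_ul RT reaction volume (microlitres).
#' @param nt_molar_mass Average molar mass per nucleotide of single-stranded
#'   RNA (g/mol). Default 340.
#' @return A one-row tibble with `mrna_mass_ng` (mRNA mass per reaction),
#'   `conc_molar` (average molar concentration of one gene's mRNA) and
#'   `molecules` (average copies of one gene's transcript per reaction).
#' @examples
#' estimate_average_transcript()
#' @export
estimate_average_transcript <- function(total_rna_mass_ng = 20,
                                        mrna_fraction = 0.02,
                                        n_genes = 17000,
                                        mean_mrna_length = 1000,
                                        reaction_volume_ul = 10,
                                        nt_molar_mass = 340) {
  check_number(total_rna_mass_ng, "total_rna_mass_ng", min = 0, strict = TRUE,
               allow_vec = FALSE)
  check_number(mrna_fraction, "mrna_fraction", min = 0, strict = TRUE,
               allow_vec = FALSE)
  if (mrna_fraction > 1) abort_param("`mrna_fraction` must be <= 1")
  check_number(n_genes, "n_genes", min = 0, strict = TRUE, allow_vec = FALSE)
  check_number(mean_mrna_length, "mean_mrna_length", min = 0, strict = TRUE,
               allow_vec = FALSE)
  check_number(reaction_volume_ul, "reaction_volume_ul", min = 0,
               strict = TRUE, allow_vec = FALSE)
  check_number(nt_molar_mass, "nt_molar_mass", min = 0, strict = TRUE,
               allow_vec = FALSE)

  mrna_mass_g <- total_rna_mass_ng * 1e-9 * mrna_fraction
  volume_l <- reaction_volume_ul * 1e-6
  moles_per_gene <- mrna_mass_g / n_genes / (mean_mrna_length * nt_molar_mass)
  conc <- moles_per_gene / volume_l
  tibble(
    mrna_mass_ng = mrna_mass_g * 1e9,
    conc_molar = conc,
    molecules = conc * volume_l * AVOGADRO
  )
}

# shared closed-form OLS used by calibration and slope fits
ols_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2 || length(unique(x)) < 2) {
    abort_fit("need at least 2 distinct abscissa values for a linear fit")
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  slope <- sum(dx * dy) / sum(dx^2)
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum(dy^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  tibble(slope = slope, intercept = intercept,
         r_squared = r2, n_points = length(x))
}
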