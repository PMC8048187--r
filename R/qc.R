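#' Co-amplification linearity over a two-sample mixing series
#'
#' When two RNA pools are mixed at varying ratios under constant total RNA,
#' the normalized peak area of every transcript should be a straight-line
#' function of the mixing fraction (linear axes, unlike the log-log
#' calibration): amplification of each fragment is then proportional to its
#' own template concentration and independent of the co-amplified
#' fragments. The per-gene slope sign reflects which pool carries more of
#' the transcript; a near-zero R-squared flags transcripts with hardly any
#' difference between the pools (non-regulated, including the constant
#' spike-in).
#'
#' @param design A data frame with `gene_id`, `ratio` (fraction of pool A
#'   in the mix, in `[0, 1]`, at least 3 distinct values) and `npa`.
#'   Optional `below_floor` rows are excluded.
#' @return A tibble with `gene_id`, `slope`, `intercept`, `r_squared`,
#'   `n_points`, and `direction` (`"up"`, `"down"` or `"flat"` by slope
#'   sign relative to the pool-A axis). Genes with fewer than 3 usable
#'   points are skipped with a warning.
#' @param flat_tol Relative slope threshold below which a gene is called
#'   `"flat"`: |slope| <= flat_tol * mean NPA of the gene.
#' @export
mixing_linearity <- function(design, flat_tol = 0.05) {
  need <- c("gene_id", "ratio", "npa")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0) {
    abort_param(paste0("`design` is missing column(s): ", toString(miss)))
  }
  design <- as_tibble(design)
  if ("below_floor" %in% names(design)) {
    design <- filter(design, !.data$below_floor %in% TRUE)
  }
  design <- filter(design, is.finite(.data$npa), is.finite(.data$ratio))
  if (any(design$ratio < 0 | design$ratio > 1)) {
    abort_param("mixing `ratio` values must lie in [0, 1]")
  }
  if (n_distinct(design$ratio) < 3) {
    abort_param("a mixing design needs at least 3 distinct ratios")
  }
  usable <- design %>%
    group_by(.data$gene_id) %>%
    filter(dplyr::n() >= 3) %>%
    ungroup()
  skipped <- setdiff(unique(design$gene_id), unique(usable$gene_id))
  if (length(skipped) > 0) {
    warn(paste0("skipped gene(s) with fewer than 3 usable points: ",
                toString(skipped)),
         class = "gexpcal_skipped_genes_warning")
  }
  usable %>%
    group_by(.data$gene_id) %>%
    summarise(
      ols_fit(.data$ratio, .data$npa),
      mean_npa = mean(.data$npa),
      .groups = "drop"
    ) %>%
    mutate(
      direction = dplyr::case_when(
        abs(.data$slope) <= flat_tol * .data$mean_npa ~ "flat",
        .data$slope > 0 ~ "up",
        TRUE ~ "down"
      )
    ) %>%
    select("gene_id", "slope", "intercept", "r_squared", "n_points",
           "direction")
}

#' Technical-replicate concordance histogram
#'
#' For every (sample, gene) measured in two independent RT-PCR experiments,
#' the log2 ratio of the two relative amounts is accumulated into a
#' histogram. Pairs where either value is below its detection limit are
#' excluded (and counted). The distribution is then shifted along the
#' abscissa so the most populated bin is centred at log2 = 0, absorbing any
#' global between-run scale difference; concordance fractions are computed
#' on the shifted values: within two-fold means |log2 ratio| <= 1, beyond
#' four-fold means |log2 ratio| >= 2 (boundaries inclusive). The
#' uncentred (raw) fractions are also reported.
#'
#' @param pairs A data frame with `value_1`, `value_2` (> 0 where usable)
#'   and optionally `below_limit_1`, `below_limit_2`.
#' @param bin_width Histogram bin width in log2 units. Bins are centred on
#'   integer multiples of `bin_width`; modal-bin ties are broken toward the
#'   smaller shift.
#' @return An object of class `gexp_concordance` with the shifted and raw
#'   log2 ratios, the histogram (`bin_center`, `count`), `mode_shift`,
#'   `frac_within_2fold`, `frac_beyond_4fold` (after centring),
#'   `raw_frac_within_2fold`, `raw_frac_beyond_4fold`, `n_used`,
#'   `n_excluded`. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
replicate_concordance <- function(pairs, bin_width = 0.2) {
  need <- c("value_1", "value_2")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0) {
    abort_param(paste0("`pairs` is missing column(s): ", toString(miss)))
  }
  check_number(bin_width, "bin_width", min = 0, strict = TRUE,
               allow_vec = FALSE)
  pairs <- as_tibble(pairs)
  if (!"below_limit_1" %in% names(pairs)) pairs$below_limit_1 <- FALSE
  if (!"below_limit_2" %in% names(pairs)) pairs$below_limit_2 <- FALSE
  usable <- !(pairs$below_limit_1 %in% TRUE) &
    !(pairs$below_limit_2 %in% TRUE) &
    is.finite(pairs$value_1) & is.finite(pairs$value_2) &
    pairs$value_1 > 0 & pairs$value_2 > 0
  n_excluded <- sum(!usable)
  if (!any(usable)) {
    abort("no usable replicate pairs after exclusions",
          class = "gexpcal_empty_summary_error")
  }
  ratios <- log2(pairs$value_1[usable] / pairs$value_2[usable])

  # bins centred at k * bin_width
  bin_idx <- round(ratios / bin_width)
  counts <- table(bin_idx)
  idx_vals <- as.integer(names(counts))
  best <- which(counts == max(counts))
  # ties toward zero shift, deterministically
  best <- best[order(abs(idx_vals[best]), idx_vals[best])][1]
  mode_center <- idx_vals[best] * bin_width
  shifted <- ratios - mode_center

  hist_tbl <- tibble(bin_center = idx_vals * bin_width - mode_center,
                     count = as.integer(counts)) %>%
    arrange(.data$bin_center)

  structure(
    list(
      log2_ratios = ratios,
      shifted_log2_ratios = shifted,
      mode_shift = -mode_center,
      bin_width = bin_width,
      histogram = hist_tbl,
      frac_within_2fold = mean(abs(shifted) <= 1),
      frac_beyond_4fold = mean(abs(shifted) >= 2),
      raw_frac_within_2fold = mean(abs(ratios) <= 1),
      raw_frac_beyond_4fold = mean(abs(ratios) >= 2),
      n_used = length(ratios),
      n_excluded = n_excluded
    ),
    class = "gexp_concordance"
  )
}

#' @export
print.gexp_concordance <- function(x, ...) {
  cat("<gexp_concordance>\n")
  cat(sprintf("  pairs used: %d   excluded (below limit): %d\n",
              x$n_used, x$n_excluded))
  cat(sprintf("  mode shift: %+.2f log2   within 2-fold: %.1f%%   beyond 4-fold: %.1f%%\n",
              x$mode_shift, 100 * x$frac_within_2fold,
              100 * x$frac_beyond_4fold))
  invisible(x)
}

#' @describeIn replicate_concordance histogram table (`bin_center`,
#'   `count`) after mode-centring.
#' @param x,object A `gexp_concordance`.
#' @param ... Unused.
#' @export
tidy.gexp_concordance <- function(x, ...) {
  x$histogram
}

#' @describeIn replicate_concordance one-row summary of the concordance
#'   fractions and counts.
#' @export
glance.gexp_concordance <- function(x, ...) {
  tibble(
    n_used = x$n_used,
    n_excluded = x$n_excluded,
    mode_shift = x$mode_shift,
    frac_within_2fold = x$frac_within_2fold,
    frac_beyond_4fold = x$frac_beyond_4fold,
    raw_frac_within_2fold = x$raw_frac_within_2fold,
    raw_frac_beyond_4fold = x$raw_frac_beyond_4fold
  )
}

#' @describeIn replicate_concordance histogram of centred log2 ratios.
#' @export
autoplot.gexp_concordance <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$bin_center, y = .data$count)) +
    geom_col(width = object$bin_width * 0.95, fill = "grey30") +
    geom_vline(xintercept = c(-1, 1), linetype = "dashed") +
    labs(x = "log2 (replicate 1 / replicate 2), mode-centred",
         y = "count",
         title = sprintf("Replicate concordance (%.0f%% within 2-fold)",
                         100 * object$frac_within_2fold))
}

#' Normalize expression time series to their maximum
#'
#' For comparative display of time courses from different genes and cells,
#' each series is divided by its maximal usable value so the maximum maps
#' to 1 and every other point becomes a fraction of it. Below-limit entries
#' are carried through flagged (with `fraction_of_max = NA`), never treated
#' as zeros; a series with no usable positive value is flagged whole and
#' left unnormalized.
#'
#' @param data A data frame with a `value` column and optionally
#'   `below_limit`; series are normalized within groups given by `...`
#'   (default: column `gene_id` if present, else the whole frame is one
#'   series). Row order is preserved.
#' @param ... Unquoted grouping columns identifying one series (e.g.
#'   `cell_id, gene_id`).
#' @return The input with added columns `fraction_of_max` and
#'   `series_flagged`.
#' @export
normalize_timeseries <- function(data, ...) {
  if (!"value" %in% names(data)) {
    abort_param("`data` must have a `value` column")
  }
  data <- as_tibble(data)
  if (!"below_limit" %in% names(data)) data$below_limit <- FALSE
  groups <- rlang::enquos(...)
  if (length(groups) == 0 && "gene_id" %in% names(data)) {
    groups <- rlang::quos(.data$gene_id)
  }
  flagged_any <- FALSE
  out <- data %>%
    group_by(!!!groups) %>%
    mutate(
      .max = {
        ok <- !(.data$below_limit %in% TRUE) & is.finite(.data$value) &
          .data$value > 0
        if (any(ok)) max(.data$value[ok]) else NA_real_
      },
      series_flagged = is.na(.data$.max),
      fraction_of_max = ifelse(
        !.data$series_flagged & !(.data$below_limit %in% TRUE) &
          is.finite(.data$value),
        .data$value / .data$.max,
        NA_real_
      )
    ) %>%
    ungroup() %>%
    select(-".max")
  if (any(out$series_flagged)) {
    warn("one or more series had no usable value above the limit; left unnormalized",
         class = "gexpcal_flagged_series_warning")
  }
  out
}
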