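#' First-regression fit for one gene's dilution response
#'
#' Ordinary least-squares fit of `log10(NPA)` on `log10(total RNA)` for the
#' points of one gene across a dilution series, using the closed-form
#' covariance/variance estimator. Non-positive NPAs cannot enter the log
#' domain and are excluded with a warning.
#'
#' @param points A data frame with columns `total_rna` (> 0, e.g. ng per
#'   reaction) and `npa`.
#' @return A one-row tibble with `slope`, `intercept`, `r_squared`,
#'   `n_points`, `mean_log_rna`, `mean_log_npa`.
#' @export
fit_gene <- function(points) {
  need <- c("total_rna", "npa")
  miss <- setdiff(need, names(points))
  if (length(miss) > 0) {
    abort_param(paste0("`points` is missing column(s): ", toString(miss)))
  }
  bad <- !is.finite(points$npa) | points$npa <= 0
  if (any(bad)) {
    warn(sprintf("excluded %d point(s) with non-positive NPA from the fit",
                 sum(bad)), class = "gexpcal_excluded_points_warning")
    points <- points[!bad, ]
  }
  x <- log10(points$total_rna)
  y <- log10(points$npa)
  fit <- ols_fit(x, y)
  fit$mean_log_rna <- mean(x)
  fit$mean_log_npa <- mean(y)
  fit
}

#' Build a shared-slope calibration model from a dilution series
#'
#' Two-stage calibration over a log-log dilution series. Stage one fits,
#' for every gene, `log10 F_i = a_i * log10 [RNA]_tot + b_i` by ordinary
#' least squares, where `F_i` is the spike-in-normalized peak area (NPA).
#' Stage two averages the per-gene slopes into the common slope `a_bar`
#' (the kinetic model predicts parallel lines, so a single slope is shared
#' by the whole panel) and refits each gene's intercept at that slope:
#' `b_i = mean(log10 F_i) - a_bar * mean(log10 [RNA]_tot)`, which is the
#' least-squares-optimal intercept for the fixed slope. Fit diagnostics of
#' both stages are retained for quality control.
#'
#' @param series A data frame with one row per measured point: `gene_id`,
#'   `total_rna` (> 0), `npa`, and optionally `below_floor` (rows flagged
#'   TRUE are excluded, mirroring the rule that values below the detection
#'   limit do not enter the fits).
#' @param replicate_mode `"points"` fits all individual replicate points;
#'   `"means"` first averages NPA per gene and concentration. Which mode
#'   produced a model is recorded in it.
#' @param min_peak_area Instrument noise floor on raw peak areas, used by
#'   the default detection-limit policy (`floor NPA = min_peak_area /
#'   spike-in area of the run`). Stored with the model.
#' @param floor_npa Alternative fixed-NPA floor policy; when not `NULL` it
#'   overrides `min_peak_area`.
#' @param series_id Free-form identifier stored in the model's provenance.
#' @return An object of class `gexp_calibration` with components
#'   `mean_slope` (`a_bar`), `fits` (per-gene tibble with `slope`,
#'   `intercept`, `r_squared`, `n_points`, `shared_intercept`),
#'   `max_slope_dev` (parallelism diagnostic `max |a_i - a_bar|`),
#'   `replicate_mode` and `provenance`. Supports [tidy()], [glance()],
#'   `print()` and [ggplot2::autoplot()].
#' @export
build_calibration <- function(series, replicate_mode = c("points", "means"),
                              min_peak_area = 0, floor_npa = NULL,
                              series_id = NA_character_) {
  replicate_mode <- match.arg(replicate_mode)
  need <- c("gene_id", "total_rna", "npa")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0) {
    abort_param(paste0("`series` is missing column(s): ", toString(miss)))
  }
  series <- as_tibble(series)
  if ("is_spike_in" %in% names(series)) {
    # the spike-in is the normalizer, not an analyte: its NPA is constant
    # across dilutions by construction and must not enter the slope average
    series <- filter(series, !.data$is_spike_in %in% TRUE)
  }
  if ("below_floor" %in% names(series)) {
    series <- filter(series, !.data$below_floor %in% TRUE)
  }
  series <- filter(series, is.finite(.data$npa), .data$npa > 0)
  if (any(series$total_rna <= 0)) {
    abort_param("all `total_rna` values must be positive")
  }
  if (n_distinct(series$total_rna) < 2) {
    abort_fit("a dilution series needs at least 2 distinct total_rna values")
  }
  if (replicate_mode == "means") {
    series <- series %>%
      group_by(.data$gene_id, .data$total_rna) %>%
      summarise(npa = mean(.data$npa), .groups = "drop")
  }

  fit_safe <- function(df) {
    tryCatch(fit_gene(df), gexpcal_fit_error = function(e) NULL)
  }
  fits <- series %>%
    tidyr::nest(data = -"gene_id") %>%
    mutate(fit = purrr::map(.data$data, fit_safe))
  failed <- fits$gene_id[purrr::map_lgl(fits$fit, is.null)]
  if (length(failed) > 0) {
    abort_fit(paste0("calibration failed for gene(s): ", toString(failed),
                     " (fewer than 2 usable dilution points)"))
  }
  fits <- fits %>%
    select("gene_id", "fit") %>%
    tidyr::unnest("fit")

  mean_slope <- mean(fits$slope)
  fits <- fits %>%
    mutate(shared_intercept = .data$mean_log_npa -
             mean_slope * .data$mean_log_rna)

  structure(
    list(
      mean_slope = mean_slope,
      fits = fits,
      max_slope_dev = max(abs(fits$slope - mean_slope)),
      replicate_mode = replicate_mode,
      floor_policy = if (is.null(floor_npa)) {
        list(type = "min_peak_area", min_peak_area = min_peak_area)
      } else {
        list(type = "fixed_npa", floor_npa = floor_npa)
      },
      provenance = list(
        series_id = series_id,
        n_points_total = nrow(series),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ),
    class = "gexp_calibration"
  )
}

#' @export
print.gexp_calibration <- function(x, ...) {
  cat("<gexp_calibration>\n")
  cat(sprintf("  genes: %d   shared slope a_bar: %.4f   max |a_i - a_bar|: %.4f\n",
              nrow(x$fits), x$mean_slope, x$max_slope_dev))
  cat(sprintf("  replicate mode: %s   floor policy: %s\n",
              x$replicate_mode, x$floor_policy$type))
  invisible(x)
}

#' @describeIn build_calibration per-gene fit table (both regression stages).
#' @param x,object A `gexp_calibration`.
#' @param ... Unused.
#' @export
tidy.gexp_calibration <- function(x, ...) {
  x$fits %>%
    select("gene_id", "slope", "intercept", "r_squared", "n_points",
           "shared_intercept")
}

#' @describeIn build_calibration one-row model summary.
#' @export
glance.gexp_calibration <- function(x, ...) {
  tibble(
    mean_slope = x$mean_slope,
    n_genes = nrow(x$fits),
    max_slope_dev = x$max_slope_dev,
    min_r_squared = min(x$fits$r_squared),
    replicate_mode = x$replicate_mode
  )
}

#' Per-gene detection limits for a separation run
#'
#' Maps a run's NPA floor through each gene's calibration line to the
#' smallest quantifiable relative RNA amount: `limit = 10^((log10 f - b_i)
#' / a_bar)`. The floor `f` is either the model's fixed-NPA policy or the
#' configured minimum peak area divided by the run's spike-in area, so a
#' dimmer spike-in (smaller denominator) raises every limit of that run.
#'
#' @param model A `gexp_calibration`.
#' @param spike_area The run's spike-in peak area (required under the
#'   `min_peak_area` policy).
#' @return A tibble `gene_id`, `floor_npa`, `detection_limit` (relative
#'   RNA amount at the floor).
#' @export
detection_limits <- function(model, spike_area = NULL) {
  stopifnot(inherits(model, "gexp_calibration"))
  f <- run_floor_npa(model, spike_area)
  model$fits %>%
    mutate(
      floor_npa = f,
      detection_limit = if (f > 0) {
        10^((log10(f) - .data$shared_intercept) / model$mean_slope)
      } else {
        0
      }
    ) %>%
    select("gene_id", "floor_npa", "detection_limit")
}

run_floor_npa <- function(model, spike_area) {
  pol <- model$floor_policy
  if (pol$type == "fixed_npa") return(pol$floor_npa)
  if (is.null(spike_area) || !is.finite(spike_area) || spike_area <= 0) {
    if (pol$min_peak_area == 0) return(0)
    abort_param("`spike_area` is required under the min_peak_area floor policy")
  }
  pol$min_peak_area / spike_area
}

#' Quantify relative transcript amounts from normalized peak areas
#'
#' Inverts each gene's shared-slope calibration line: the relative RNA
#' amount is `10^A` with `A = (log10 F_i - b_i) / a_bar`, on the same scale
#' as the `total_rna` axis the model was calibrated on. NPAs at or below
#' the run's floor — and genes whose fragment was not detected — are
#' reported at the detection limit with `below_limit = TRUE` rather than as
#' spurious small amounts.
#'
#' @param npa_rows A data frame with `sample_id`, `gene_id`, `npa`, and
#'   optionally `below_floor` and `spike_area` (per-row spike-in area used
#'   by the `min_peak_area` floor policy).
#' @param model A `gexp_calibration`.
#' @return A tibble with `sample_id`, `gene_id`, `npa`, `rel_amount`,
#'   `detection_limit`, `below_limit`.
#' @export
quantify <- function(npa_rows, model) {
  stopifnot(inherits(model, "gexp_calibration"))
  need <- c("sample_id", "gene_id", "npa")
  miss <- setdiff(need, names(npa_rows))
  if (length(miss) > 0) {
    abort_param(paste0("`npa_rows` is missing column(s): ", toString(miss)))
  }
  if ("is_spike_in" %in% names(npa_rows)) {
    npa_rows <- filter(as_tibble(npa_rows), !.data$is_spike_in %in% TRUE)
  }
  unknown <- setdiff(unique(npa_rows$gene_id), model$fits$gene_id)
  if (length(unknown) > 0) {
    abort(paste0("gene(s) absent from the calibration model: ",
                 toString(unknown)),
          class = "gexpcal_unknown_gene_error")
  }
  rows <- as_tibble(npa_rows)
  if (!"below_floor" %in% names(rows)) rows$below_floor <- FALSE
  if (!"spike_area" %in% names(rows)) rows$spike_area <- NA_real_
  a_bar <- model$mean_slope
  rows %>%
    left_join(select(model$fits, "gene_id", b = "shared_intercept"),
              by = "gene_id") %>%
    mutate(
      floor_npa = purrr::map_dbl(.data$spike_area, function(sa) {
        tryCatch(run_floor_npa(model, sa), gexpcal_parameter_error = function(e) 0)
      }),
      detection_limit = ifelse(
        .data$floor_npa > 0,
        10^((log10(.data$floor_npa) - .data$b) / a_bar),
        0
      ),
      below_limit = .data$below_floor %in% TRUE | !is.finite(.data$npa) |
        .data$npa <= .data$floor_npa,
      rel_amount = ifelse(
        .data$below_limit,
        .data$detection_limit,
        10^((log10(.data$npa) - .data$b) / a_bar)
      )
    ) %>%
    select("sample_id", "gene_id", "npa", "rel_amount", "detection_limit",
           "below_limit")
}

#' Serialize a calibration model to TSV
#'
#' Writes the per-gene fit table preceded by `#`-prefixed header lines
#' carrying the shared slope, replicate mode, floor policy and provenance,
#' so a kit-specific standard curve can be stored and reused.
#'
#' @param model A `gexp_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "gexp_calibration"))
  hdr <- c(
    sprintf("# gexp_calibration v1"),
    sprintf("# mean_slope=%.17g", model$mean_slope),
    sprintf("# replicate_mode=%s", model$replicate_mode),
    sprintf("# floor_type=%s", model$floor_policy$type),
    sprintf("# floor_value=%.17g",
            if (model$floor_policy$type == "fixed_npa") {
              model$floor_policy$floor_npa
            } else {
              model$floor_policy$min_peak_area
            }),
    sprintf("# series_id=%s", model$provenance$series_id),
    sprintf("# timestamp=%s", model$provenance$timestamp)
  )
  writeLines(hdr, path)
  tab <- model$fits %>%
    select("gene_id", "slope", "intercept", "r_squared", "n_points",
           "mean_log_rna", "mean_log_npa", "shared_intercept")
  suppressWarnings(
    readr::write_tsv(format_num_tbl(tab), path, append = TRUE,
                     col_names = TRUE, progress = FALSE)
  )
  invisible(path)
}

format_num_tbl <- function(tab) {
  dplyr::mutate(tab, dplyr::across(dplyr::where(is.numeric),
                                   ~ sprintf("%.17g", .x)))
}

#' Read a serialized calibration model
#'
#' @param path Path written by [write_calibration()].
#' @return A `gexp_calibration`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("model file not found: %s", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ") | startsWith(lines, "#")]
  if (length(hdr) == 0 || !grepl("gexp_calibration", hdr[1])) {
    abort_format(sprintf("%s is not a serialized calibration model", path))
  }
  kv <- hdr[grepl("=", hdr, fixed = TRUE)]
  keys <- sub("^#\\s*([^=]+)=.*$", "\\1", kv)
  vals <- sub("^#\\s*[^=]+=", "", kv)
  meta <- setNames(vals, keys)
  fits <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  floor_type <- meta[["floor_type"]]
  structure(
    list(
      mean_slope = as.numeric(meta[["mean_slope"]]),
      fits = as_tibble(fits),
      max_slope_dev = max(abs(fits$slope - as.numeric(meta[["mean_slope"]]))),
      replicate_mode = meta[["replicate_mode"]],
      floor_policy = if (identical(floor_type, "fixed_npa")) {
        list(type = "fixed_npa", floor_npa = as.numeric(meta[["floor_value"]]))
      } else {
        list(type = "min_peak_area",
             min_peak_area = as.numeric(meta[["floor_value"]]))
      },
      provenance = list(series_id = meta[["series_id"]],
                        timestamp = meta[["timestamp"]])
    ),
    class = "gexp_calibration"
  )
}

#' Plot a calibration model
#'
#' One panel per gene showing the shared-slope line; if the original series
#' is supplied its points are overlaid, mirroring the standard-curve plots
#' used to inspect a new kit's calibration.
#'
#' @param object A `gexp_calibration`.
#' @param series Optional series data frame (as for [build_calibration()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gexp_calibration <- function(object, series = NULL, ...) {
  fits <- object$fits
  p <- ggplot(mapping = aes(x = .data$log_rna, y = .data$log_npa))
  if (!is.null(series)) {
    pts <- series %>%
      filter(is.finite(.data$npa), .data$npa > 0) %>%
      mutate(log_rna = log10(.data$total_rna), log_npa = log10(.data$npa))
    p <- p + geom_point(data = pts, size = 0.8, alpha = 0.7)
  }
  p +
    geom_abline(data = fits,
                aes(slope = object$mean_slope,
                    intercept = .data$shared_intercept),
                colour = "red") +
    facet_wrap(~gene_id, scales = "free_y") +
    labs(x = "log10 total RNA", y = "log10 NPA",
         title = sprintf("Shared-slope calibration (a_bar = %.3f)",
                         object$mean_slope))
}
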