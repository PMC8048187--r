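#' Read a capillary-electrophoresis fragment table
#'
#' Reads the tab-separated per-fragment peak table exported from the
#' fragment-analysis software after a separation run. The canonical dialect
#' has a header row and the columns `fragment_index`, `length_nt`,
#' `peak_height`, `peak_area`; alternative column names can be mapped with
#' `dialect`. Rows whose numeric fields fail to parse or carry a negative
#' peak area or height are dropped with a warning that names the offending
#' line numbers.
#'
#' @param path Path to the TSV file.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(peak_area = "Area", length_nt = "Size")`. Unmapped canonical names
#'   are looked up as-is.
#' @return A tibble with columns `fragment_index` (integer), `length_nt`,
#'   `peak_height`, `peak_area`.
#' @export
read_fragment_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort_format(sprintf("fragment table not found: %s", path))
  }
  raw <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) abort_format(sprintf("cannot parse %s: %s", path,
                                             conditionMessage(e)))
  )
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    abort_format(sprintf("empty fragment table: %s", path))
  }
  cols <- c(fragment_index = "fragment_index", length_nt = "length_nt",
            peak_height = "peak_height", peak_area = "peak_area")
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || !all(names(dialect) %in% names(cols))) {
      abort_config("`dialect` must be a named vector over the canonical column names")
    }
    cols[names(dialect)] <- dialect
  }
  miss <- cols[!cols %in% names(raw)]
  if (length(miss) > 0) {
    abort_format(sprintf("fragment table %s is missing mandatory column(s): %s",
                         path, toString(unname(miss))))
  }
  out <- tibble(
    fragment_index = suppressWarnings(as.integer(raw[[cols["fragment_index"]]])),
    length_nt = suppressWarnings(as.numeric(raw[[cols["length_nt"]]])),
    peak_height = suppressWarnings(as.numeric(raw[[cols["peak_height"]]])),
    peak_area = suppressWarnings(as.numeric(raw[[cols["peak_area"]]]))
  )
  bad <- !stats::complete.cases(out) | out$length_nt <= 0 |
    out$peak_area < 0 | out$peak_height < 0
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    # +1 for the header row so the numbers match the file
    warn(sprintf("%s: dropped %d invalid row(s) at line(s) %s",
                 path, sum(bad), toString(which(bad) + 1)),
         class = "gexpcal_row_warning")
    out <- out[!bad, ]
  }
  if (nrow(out) == 0) {
    abort_format(sprintf("fragment table %s contains no usable rows", path))
  }
  if (anyDuplicated(out$fragment_index)) {
    abort_format(sprintf("duplicate fragment_index values in %s", path))
  }
  out
}

#' Write a fragment table in the canonical dialect
#'
#' @param fragments A data frame with the canonical fragment columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(fragments, path) {
  need <- c("fragment_index", "length_nt", "peak_height", "peak_area")
  miss <- setdiff(need, names(fragments))
  if (length(miss) > 0) {
    abort_param(paste0("`fragments` is missing column(s): ", toString(miss)))
  }
  readr::write_tsv(fragments[need], path, progress = FALSE)
  invisible(path)
}

#' Read a gene-panel definition
#'
#' A panel TSV defines the multiplex: one row per gene with `gene_id`,
#' `expected_length_nt` (the designed amplicon length), `is_spike_in`
#' (logical; exactly one TRUE row — the internal-standard RNA) and
#' `rt_primer_conc` (attenuated reverse-primer stock, micromolar). Extra
#' columns (e.g. simulation ground truth) are carried through.
#'
#' @param path Path to the panel TSV.
#' @return A validated panel tibble.
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("panel file not found: %s", path))
  panel <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_panel(panel)
}

#' Validate a gene panel
#'
#' @param panel A data frame with at least `gene_id`, `expected_length_nt`
#'   and `is_spike_in`.
#' @return The panel as a tibble, invisibly checked.
#' @export
validate_panel <- function(panel) {
  need <- c("gene_id", "expected_length_nt", "is_spike_in")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0) {
    abort_format(paste0("panel is missing column(s): ", toString(miss)))
  }
  panel <- as_tibble(panel)
  panel$is_spike_in <- as.logical(panel$is_spike_in)
  if (anyDuplicated(panel$gene_id)) abort_format("panel gene_id values must be unique")
  if (sum(panel$is_spike_in) != 1) {
    abort_format("panel must contain exactly one spike-in gene")
  }
  if (anyDuplicated(panel$expected_length_nt)) {
    abort_format("panel expected lengths must be pairwise distinct")
  }
  panel
}

#' Assign detected fragments to panel genes by length
#'
#' Each panel gene is matched to the detected fragment whose sized length
#' is nearest to the gene's designed amplicon length, provided the distance
#' is within `tolerance_nt`. Sizing against the ladder is sub-nucleotide
#' accurate but fractional, so exact integer matching would be wrong. A
#' fragment can serve at most one gene; genes with no fragment in tolerance
#' are returned unmatched (transcript absent or below the noise floor).
#' If two fragments are equidistant from an expected length the larger-area
#' one wins (peak-splitting artifact assumption).
#'
#' @param fragments A fragment tibble (see [read_fragment_table()]).
#' @param panel A gene panel (see [read_gene_panel()]).
#' @param tolerance_nt Matching tolerance in nucleotides; must be positive
#'   and smaller than half the minimum spacing between expected lengths,
#'   otherwise assignments could be ambiguous.
#' @return A tibble with one row per panel gene: `gene_id`,
#'   `expected_length_nt`, `is_spike_in`, `fragment_index`, `length_nt`,
#'   `peak_height`, `peak_area` (fragment columns `NA` when unmatched) and
#'   `matched`.
#' @export
assign_fragments <- function(fragments, panel, tolerance_nt = 2) {
  panel <- validate_panel(panel)
  check_number(tolerance_nt, "tolerance_nt", min = 0, strict = TRUE,
               allow_vec = FALSE)
  lens <- sort(panel$expected_length_nt)
  if (length(lens) > 1) {
    min_gap <- min(diff(lens))
    if (tolerance_nt >= min_gap / 2) {
      abort_config(sprintf(
        "tolerance_nt = %g is not below half the minimum expected-length spacing (%g nt)",
        tolerance_nt, min_gap))
    }
  }
  match_one <- function(expected) {
    d <- abs(fragments$length_nt - expected)
    in_tol <- which(d <= tolerance_nt)
    if (length(in_tol) == 0) return(NA_integer_)
    cand <- in_tol[d[in_tol] == min(d[in_tol])]
    if (length(cand) > 1) {
      cand <- cand[order(-fragments$peak_area[cand],
                         fragments$fragment_index[cand])][1]
      message(sprintf(
        "equidistant fragments at expected length %g; kept the larger-area peak",
        expected))
    }
    cand
  }
  idx <- vapply(panel$expected_length_nt, match_one, integer(1))
  hit <- !is.na(idx)
  if (anyDuplicated(idx[hit])) {
    dup <- idx[hit][duplicated(idx[hit])][1]
    genes <- panel$gene_id[which(!is.na(idx) & idx == dup)]
    abort(sprintf("fragment %d claimed by multiple genes: %s",
                  fragments$fragment_index[dup], toString(genes)),
          class = "gexpcal_ambiguity_error")
  }
  out <- panel[c("gene_id", "expected_length_nt", "is_spike_in")]
  frag_cols <- fragments[idx, c("fragment_index", "length_nt",
                                "peak_height", "peak_area")]
  dplyr::bind_cols(out, frag_cols) %>%
    mutate(matched = hit)
}

#' Spike-in-normalized peak areas for one separation run
#'
#' Converts the raw peak areas of one run into normalized peak areas (NPA):
#' each matched gene's area divided by the spike-in fragment's area in the
#' same run. The NPA is the relative fluorescence signal used throughout
#' calibration and quantification; the spike-in's own NPA is 1 by
#' construction. Genes with no matched fragment get `npa = NA` and are
#' flagged `below_floor` (absent or below the run's noise floor) so that
#' log-domain arithmetic downstream never receives a zero.
#'
#' @param fragments A fragment tibble for the run.
#' @param panel A gene panel.
#' @param sample_id Sample identifier recorded in the output.
#' @param tolerance_nt Length-matching tolerance passed to
#'   [assign_fragments()].
#' @return A tibble with `sample_id`, `gene_id`, `is_spike_in`,
#'   `length_nt`, `peak_area`, `npa`, `below_floor`.
#' @export
normalize_run <- function(fragments, panel, sample_id = NA_character_,
                          tolerance_nt = 2) {
  assignment <- assign_fragments(fragments, panel, tolerance_nt)
  spike <- assignment[assignment$is_spike_in, ]
  if (!spike$matched || is.na(spike$peak_area) || spike$peak_area <= 0) {
    abort(sprintf("run %s: spike-in fragment missing or has zero area; run unusable",
                  sample_id),
          class = "gexpcal_normalization_error")
  }
  assignment %>%
    mutate(
      sample_id = sample_id,
      npa = .data$peak_area / spike$peak_area,
      below_floor = !.data$matched
    ) %>%
    select("sample_id", "gene_id", "is_spike_in", "length_nt", "peak_area",
           "npa", "below_floor")
}

#' Normalize a collection of runs
#'
#' Applies [normalize_run()] to a named list of fragment tibbles and binds
#' the results, using each element's name as its `sample_id`.
#'
#' @param runs Named list of fragment tibbles.
#' @inheritParams normalize_run
#' @return A long NPA tibble over all runs.
#' @export
normalize_runs <- function(runs, panel, tolerance_nt = 2) {
  if (is.null(names(runs)) || any(names(runs) == "")) {
    abort_param("`runs` must be a fully named list")
  }
  purrr::imap(runs, function(fr, id) {
    normalize_run(fr, panel, sample_id = id, tolerance_nt = tolerance_nt)
  }) %>%
    bind_rows()
}
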