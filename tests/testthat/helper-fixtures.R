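# Small hand-built fixtures used across test files.

# minimal three-gene panel plus spike-in, lengths well separated
tiny_panel <- function() {
  tibble::tibble(
    gene_id = c("geneA", "geneB", "geneC", "KANr"),
    expected_length_nt = c(150, 200, 250, 300),
    is_spike_in = c(FALSE, FALSE, FALSE, TRUE),
    rt_primer_conc = c(0.5, 0.05, 0.005, 0.5),
    primer_conc = rt_primer_final_conc(c(0.5, 0.05, 0.005, 0.5)),
    hybridization_rate = c(2e6, 5e6, 1e7, 1e6),
    initial_conc = c(1e-13, 5e-14, 2e-15, 1e-13),
    regulation = c("up", "down", "constant", "constant"),
    fold_change = c(4, 3, 1, 1)
  )
}

# fragment table with peaks at the given lengths/areas
frags <- function(length_nt, peak_area, peak_height = peak_area / 2) {
  tibble::tibble(
    fragment_index = seq_along(length_nt),
    length_nt = length_nt,
    peak_height = peak_height,
    peak_area = peak_area
  )
}

# exact (noise-free) NPA dilution series on a known log-log line per gene:
# log10 F = slope * log10 R + intercept
exact_series <- function(slopes, intercepts, total_rna = 100 / 2^(0:7)) {
  purrr::imap_dfr(slopes, function(a, g) {
    tibble::tibble(
      gene_id = g,
      total_rna = total_rna,
      npa = 10^(a * log10(total_rna) + intercepts[[g]])
    )
  })
}
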