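test_that("mixing linearity recovers exact linear responses", {
  ratios <- seq(0, 1, by = 0.25)
  design <- dplyr::bind_rows(
    tibble::tibble(gene_id = "up", ratio = ratios, npa = 0.2 + 0.8 * ratios),
    tibble::tibble(gene_id = "down", ratio = ratios, npa = 1.0 - 0.6 * ratios),
    tibble::tibble(gene_id = "flat", ratio = ratios, npa = 0.5)
  )
  fit <- mixing_linearity(design)
  up <- fit[fit$gene_id == "up", ]
  expect_equal(up$slope, 0.8, tolerance = 1e-12)
  expect_equal(up$intercept, 0.2, tolerance = 1e-12)
  expect_equal(up$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$direction[fit$gene_id == "down"], "down")
  expect_equal(fit$slope[fit$gene_id == "flat"], 0)
  expect_equal(fit$direction[fit$gene_id == "flat"], "flat")
})

test_that("mixing linearity enforces its design preconditions", {
  expect_error(
    mixing_linearity(tibble::tibble(gene_id = "g", ratio = c(0, 1),
                                    npa = c(1, 2))),
    class = "gexpcal_parameter_error")
  design <- tibble::tibble(
    gene_id = c(rep("ok", 3), "sparse", "sparse"),
    ratio = c(0, 0.5, 1, 0, 1),
    npa = c(1, 2, 3, 1, NA))
  expect_warning(fit <- mixing_linearity(design),
                 class = "gexpcal_skipped_genes_warning")
  expect_equal(fit$gene_id, "ok")
})

test_that("simulated two-pool mixes give linear NPA with flat spike-in", {
  panel <- tiny_panel()
  sim <- generate_mixing_series(panel, ratios = seq(0, 1, by = 0.2),
                                noise_sd = 0.02, length_jitter_sd = 0,
                                seed = 31)
  npa <- normalize_runs(sim$runs, panel) |>
    dplyr::left_join(sim$manifest[c("sample_id", "ratio")], by = "sample_id")
  fit <- mixing_linearity(npa)
  # the spike-in NPA is 1 at every ratio up to noise: flat by construction
  expect_equal(fit$direction[fit$gene_id == "KANr"], "flat")
  # geneA is 4x up in pool B; its line endpoints recover that ratio
  fa <- fit[fit$gene_id == "geneA", ]
  endpoint_ratio <- (fa$intercept) / (fa$intercept + fa$slope) # B over A at r=0 vs r=1
  expect_equal(endpoint_ratio, 4, tolerance = 0.2)
  expect_gt(fa$r_squared, 0.95)
  # endpoints of the true response reproduce the pure-pool values
  truth <- sim$truth$expected_npa
  tA <- truth[truth$gene_id == "geneA", ]
  expect_equal(tA$npa[tA$ratio == 0] / tA$npa[tA$ratio == 1], 4,
               tolerance = 1e-9)
})

test_that("identical replicates give perfect concordance", {
  pairs <- tibble::tibble(value_1 = c(1, 5, 20), value_2 = c(1, 5, 20))
  cc <- replicate_concordance(pairs)
  expect_equal(cc$frac_within_2fold, 1)
  expect_equal(cc$frac_beyond_4fold, 0)
  expect_equal(cc$mode_shift, 0)
  expect_equal(cc$n_used, 3L)
})

test_that("the four-fold boundary is inclusive", {
  # a (8, 2) pair has |log2 ratio| = 2 exactly: counts as beyond four-fold
  pairs <- tibble::tibble(value_1 = c(8, 2, 2), value_2 = c(2, 2, 1))
  cc <- replicate_concordance(pairs, bin_width = 0.5)
  expect_equal(cc$mode_shift, 0) # modal bin ties break toward zero shift
  expect_equal(cc$raw_frac_beyond_4fold, 1 / 3)
  # (2,1) is exactly two-fold: inclusive on the within side
  expect_gte(cc$raw_frac_within_2fold, 2 / 3)
})

test_that("below-limit pairs are excluded and counted", {
  pairs <- tibble::tibble(value_1 = c(1, 2, 3), value_2 = c(1, 2, 3),
                          below_limit_1 = c(FALSE, TRUE, FALSE),
                          below_limit_2 = c(FALSE, FALSE, TRUE))
  cc <- replicate_concordance(pairs)
  expect_equal(cc$n_used, 1L)
  expect_equal(cc$n_excluded, 2L)
  expect_error(replicate_concordance(
    tibble::tibble(value_1 = 1, value_2 = 1,
                   below_limit_1 = TRUE, below_limit_2 = FALSE)),
    class = "gexpcal_empty_summary_error")
})

test_that("swapping replicates mirrors the histogram but not the fractions", {
  set.seed(19)
  pairs <- tibble::tibble(value_1 = exp(rnorm(500, 0, 0.5)),
                          value_2 = exp(rnorm(500, 0, 0.5)))
  a <- replicate_concordance(pairs)
  b <- replicate_concordance(dplyr::rename(pairs, value_1 = "value_2",
                                           value_2 = "value_1"))
  expect_equal(sort(b$log2_ratios), sort(-a$log2_ratios))
  expect_equal(b$frac_within_2fold, a$frac_within_2fold)
  expect_equal(b$frac_beyond_4fold, a$frac_beyond_4fold)
})

test_that("a global scale factor on one run moves only the mode shift", {
  set.seed(23)
  pairs <- tibble::tibble(value_1 = exp(rnorm(2000, 0, 0.4)),
                          value_2 = exp(rnorm(2000, 0, 0.4)))
  a <- replicate_concordance(pairs)
  scaled <- pairs
  scaled$value_1 <- scaled$value_1 * 2^1.4 # exactly 7 bins of 0.2
  b <- replicate_concordance(scaled)
  expect_equal(b$mode_shift, a$mode_shift - 1.4, tolerance = 1e-9)
  expect_equal(b$frac_within_2fold, a$frac_within_2fold)
  expect_equal(b$frac_beyond_4fold, a$frac_beyond_4fold)
})

test_that("concordance tidy/glance/autoplot expose the histogram and summary", {
  set.seed(3)
  cc <- replicate_concordance(tibble::tibble(value_1 = exp(rnorm(100)),
                                             value_2 = exp(rnorm(100))))
  expect_named(tidy(cc), c("bin_center", "count"))
  expect_equal(sum(tidy(cc)$count), cc$n_used)
  gl <- glance(cc)
  expect_true(all(c("frac_within_2fold", "raw_frac_within_2fold") %in%
                    names(gl)))
  expect_s3_class(ggplot2::autoplot(cc), "ggplot")
})

test_that("time series normalize to their within-series maximum", {
  d <- tibble::tibble(gene_id = "g", value = c(2, 4, 8, 4, 2))
  out <- normalize_timeseries(d)
  expect_equal(out$fraction_of_max, c(0.25, 0.5, 1, 0.5, 0.25))

  # constant series: all ones
  cst <- normalize_timeseries(tibble::tibble(gene_id = "g", value = rep(3, 4)))
  expect_equal(cst$fraction_of_max, rep(1, 4))

  # a below-limit entry is carried flagged, not treated as zero
  bl <- normalize_timeseries(tibble::tibble(
    gene_id = "g", value = c(2, 0.1, 8), below_limit = c(FALSE, TRUE, FALSE)))
  expect_true(is.na(bl$fraction_of_max[2]))
  expect_equal(bl$fraction_of_max[3], 1)
  expect_false(any(bl$series_flagged))

  # an all-below-limit series is flagged, not normalized
  expect_warning(
    fl <- normalize_timeseries(tibble::tibble(
      gene_id = "g", value = c(1, 2), below_limit = c(TRUE, TRUE))),
    class = "gexpcal_flagged_series_warning")
  expect_true(all(fl$series_flagged))
  expect_true(all(is.na(fl$fraction_of_max)))

  # grouping by multiple keys normalizes each series independently
  two <- tibble::tibble(cell = rep(c("c1", "c2"), each = 2),
                        gene_id = "g", value = c(1, 2, 10, 40))
  o2 <- normalize_timeseries(two, cell, gene_id)
  expect_equal(o2$fraction_of_max, c(0.5, 1, 0.25, 1))
})
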