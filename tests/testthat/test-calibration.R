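test_that("fit_gene recovers an exact log-log line and matches lm on noisy data", {
  r <- 100 / 2^(0:7)
  pts <- tibble::tibble(total_rna = r, npa = 10^(0.8 * log10(r) + 1.2))
  fit <- fit_gene(pts)
  expect_equal(fit$slope, 0.8, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # two points: exact interpolation
  fit2 <- fit_gene(tibble::tibble(total_rna = c(1, 10), npa = c(2, 9)))
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit2$n_points, 2L)

  # independent route: same estimates from lm on the same 8-point noisy series
  set.seed(42)
  noisy <- tibble::tibble(total_rna = r,
                          npa = 10^(0.8 * log10(r) + 1.2) * exp(rnorm(8, 0, 0.05)))
  fitn <- fit_gene(noisy)
  ref <- lm(log10(npa) ~ log10(total_rna), data = noisy)
  expect_equal(fitn$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fitn$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fitn$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  # within 3 SE of the generating slope
  se <- summary(ref)$coefficients[2, 2]
  expect_lt(abs(fitn$slope - 0.8), 3 * se)

  expect_error(fit_gene(tibble::tibble(total_rna = c(5, 5), npa = c(1, 2))),
               class = "gexpcal_fit_error")
  expect_warning(fit_gene(tibble::tibble(total_rna = r,
                                         npa = c(-1, 0, 10^(1:6)))),
                 class = "gexpcal_excluded_points_warning")
})

test_that("the shared slope is the unweighted mean of the per-gene slopes", {
  series <- exact_series(list(geneA = 0.7, geneB = 0.9),
                         list(geneA = 0, geneB = -1))
  m <- build_calibration(series)
  expect_equal(m$mean_slope, 0.8)
  expect_equal(m$max_slope_dev, 0.1, tolerance = 1e-12)

  # identical slopes: the second regression reproduces each gene's own intercept
  same <- exact_series(list(geneA = 0.8, geneB = 0.8),
                       list(geneA = 0.3, geneB = -0.6))
  ms <- build_calibration(same)
  td <- tidy(ms)
  expect_equal(ms$mean_slope, 0.8, tolerance = 1e-12)
  expect_equal(td$shared_intercept, td$intercept, tolerance = 1e-12)

  # single gene: reduces exactly to the first regression
  one <- exact_series(list(geneA = 0.75), list(geneA = 0.1))
  m1 <- build_calibration(one)
  f1 <- fit_gene(one[c("total_rna", "npa")])
  expect_equal(m1$mean_slope, f1$slope)
  expect_equal(tidy(m1)$shared_intercept, f1$intercept, tolerance = 1e-12)
})

test_that("shared-slope intercepts are least-squares optimal at the fixed slope", {
  set.seed(7)
  r <- 100 / 2^(0:7)
  series <- purrr::map_dfr(c(geneA = 0.7, geneB = 0.85, geneC = 1.0),
    function(a) tibble::tibble(
      total_rna = rep(r, 2),
      npa = 10^(a * log10(rep(r, 2)) + runif(1, -1, 1)) *
        exp(rnorm(16, 0, 0.1))),
    .id = "gene_id")
  m <- build_calibration(series)
  a_bar <- m$mean_slope
  for (g in unique(series$gene_id)) {
    pts <- series[series$gene_id == g, ]
    b_star <- tidy(m)$shared_intercept[tidy(m)$gene_id == g]
    ssr <- function(b) sum((log10(pts$npa) - a_bar * log10(pts$total_rna) - b)^2)
    grid <- b_star + seq(-0.5, 0.5, by = 0.001)
    expect_equal(grid[which.min(vapply(grid, ssr, numeric(1)))], b_star,
                 tolerance = 2e-3)
    # and the closed form equals mean(logF) - a_bar * mean(logR)
    expect_equal(b_star,
                 mean(log10(pts$npa)) - a_bar * mean(log10(pts$total_rna)),
                 tolerance = 1e-12)
  }
})

test_that("replicate handling modes agree on balanced noise-free data", {
  series <- exact_series(list(geneA = 0.8), list(geneA = 0.5))
  dup <- dplyr::bind_rows(series, series)
  mp <- build_calibration(dup, replicate_mode = "points")
  mm <- build_calibration(dup, replicate_mode = "means")
  expect_equal(mp$mean_slope, mm$mean_slope, tolerance = 1e-12)
  expect_equal(mp$replicate_mode, "points")
  expect_equal(mm$replicate_mode, "means")
  expect_equal(tidy(mp)$n_points, 16L)
  expect_equal(tidy(mm)$n_points, 8L)
})

test_that("quantification inverts the calibration line", {
  series <- exact_series(list(geneA = 0.8, geneB = 0.8),
                         list(geneA = 0.5, geneB = -0.9))
  m <- build_calibration(series)
  b <- tidy(m)$shared_intercept[tidy(m)$gene_id == "geneA"]

  # F = 10^b inverts to unit total RNA
  q1 <- quantify(tibble::tibble(sample_id = "s", gene_id = "geneA",
                                npa = 10^b), m)
  expect_equal(q1$rel_amount, 1, tolerance = 1e-12)

  # round trip at an arbitrary abscissa
  x <- 1.7
  qf <- quantify(tibble::tibble(sample_id = "s", gene_id = "geneA",
                                npa = 10^(m$mean_slope * x + b)), m)
  expect_equal(qf$rel_amount, 10^x, tolerance = 1e-12)

  expect_error(quantify(tibble::tibble(sample_id = "s", gene_id = "nope",
                                       npa = 1), m),
               class = "gexpcal_unknown_gene_error")
})

test_that("below-floor measurements are reported at the detection limit", {
  series <- exact_series(list(geneA = 0.8), list(geneA = 0.5))
  m <- build_calibration(series, floor_npa = 0.01)
  lim <- detection_limits(m)
  expect_equal(lim$detection_limit,
               10^((log10(0.01) - tidy(m)$shared_intercept) / m$mean_slope))

  q <- quantify(tibble::tibble(sample_id = "s", gene_id = "geneA",
                               npa = c(0.001, 0.5),
                               below_floor = c(FALSE, FALSE)), m)
  expect_true(q$below_limit[1])
  expect_equal(q$rel_amount[1], lim$detection_limit)
  expect_false(q$below_limit[2])

  # an unmatched fragment is below-limit regardless of its NPA value
  qa <- quantify(tibble::tibble(sample_id = "s", gene_id = "geneA",
                                npa = NA_real_, below_floor = TRUE), m)
  expect_true(qa$below_limit)
})

test_that("detection limits scale as the floor through the calibration line", {
  series <- exact_series(list(geneA = 0.8), list(geneA = 0.5))
  m1 <- build_calibration(series, floor_npa = 0.01)
  m2 <- build_calibration(series, floor_npa = 0.02)
  l1 <- detection_limits(m1)$detection_limit
  l2 <- detection_limits(m2)$detection_limit
  # doubling the floor multiplies the limit by 2^(1/a_bar)
  expect_equal(l2 / l1, 2^(1 / m1$mean_slope), tolerance = 1e-12)

  # under the min-area policy, halving the spike-in area doubles the floor
  ma <- build_calibration(series, min_peak_area = 50)
  la <- detection_limits(ma, spike_area = 1000)
  lb <- detection_limits(ma, spike_area = 500)
  expect_equal(lb$floor_npa / la$floor_npa, 2)
  expect_equal(lb$detection_limit / la$detection_limit,
               2^(1 / ma$mean_slope), tolerance = 1e-12)
})

test_that("calibration models survive TSV serialization", {
  series <- exact_series(list(geneA = 0.72, geneB = 0.91),
                         list(geneA = 0.4, geneB = -0.3))
  m <- build_calibration(series, floor_npa = 0.005, series_id = "kit-7")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calibration(m, path)
  back <- read_calibration(path)
  expect_s3_class(back, "gexp_calibration")
  expect_equal(back$mean_slope, m$mean_slope)
  expect_equal(back$fits$slope, m$fits$slope)
  expect_equal(back$fits$shared_intercept, m$fits$shared_intercept)
  expect_equal(back$floor_policy, m$floor_policy)
  # quantification through the reloaded model is identical
  row <- tibble::tibble(sample_id = "s", gene_id = "geneA", npa = 0.3)
  expect_equal(quantify(row, back)$rel_amount, quantify(row, m)$rel_amount)
})

test_that("degenerate series are rejected with the offending genes named", {
  bad <- tibble::tibble(gene_id = c("geneA", "geneA", "geneB", "geneB"),
                        total_rna = c(10, 5, 10, 10),
                        npa = c(1, 0.5, 2, 2.1))
  expect_error(build_calibration(bad), class = "gexpcal_fit_error",
               regexp = "geneB")
  expect_error(build_calibration(bad[bad$gene_id == "geneB", ]),
               class = "gexpcal_fit_error")
})

test_that("tidy and glance expose both regression stages", {
  series <- exact_series(list(geneA = 0.7, geneB = 0.9),
                         list(geneA = 0, geneB = 1))
  m <- build_calibration(series)
  td <- tidy(m)
  expect_named(td, c("gene_id", "slope", "intercept", "r_squared",
                     "n_points", "shared_intercept"))
  gl <- glance(m)
  expect_equal(gl$mean_slope, 0.8)
  expect_equal(gl$n_genes, 2L)
  p <- ggplot2::autoplot(m, series = series)
  expect_s3_class(p, "ggplot")
})
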