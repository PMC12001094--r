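analytic_curve <- function(f, lower, upper, n = 200L) {
  grid <- seq(lower, upper, length.out = n)
  structure(list(dose = grid, response = f(grid), kind = "analytic"),
            class = "pathway_curve")
}

test_that("compute_bmd interpolates the band crossing and flags direction", {
  cv <- analytic_curve(function(x) 8 + 0.5 * x, 0, 4)
  bmd <- compute_bmd(cv, y0 = 8, sd = 0.4, z = 1)
  expect_equal(bmd$dose, 0.8, tolerance = 4 / 199)
  expect_equal(bmd$direction, "up")

  down <- compute_bmd(analytic_curve(function(x) 8 - x, 0, 4), 8, 0.5, z = 2)
  expect_equal(down$dose, 1, tolerance = 4 / 199)
  expect_equal(down$direction, "down")

  # never exits the band
  expect_null(compute_bmd(analytic_curve(function(x) 8 + 0.1 * sin(x), 0, 4),
                          8, 1, z = 1))
  # unsorted grid is rejected
  bad <- analytic_curve(function(x) x, 0, 4)
  bad$dose <- rev(bad$dose)
  expect_error(compute_bmd(bad, 0, 1), "sorted")
})

test_that("compute_tcds finds constructed extrema and inflections exactly", {
  # p(x) = x^3 - 1.5 x^2 + 0.6 x + 1 as a cubic Bezier spline on [0, 1]:
  # maximum at (3 - sqrt(1.8)) / 6, minimum at (3 + sqrt(1.8)) / 6,
  # inflection at 0.5.
  p <- function(x) x^3 - 1.5 * x^2 + 0.6 * x + 1
  dp <- function(x) 3 * x^2 - 3 * x + 0.6
  basis <- build_spline_basis(c(0, 1), manual_knots = numeric(0))
  p0 <- p(0); p1 <- p0 + dp(0) / 3; p2 <- p(1) - dp(1) / 3; p3 <- p(1)
  cand <- structure(list(kind = "nonlinear_fixed", available = TRUE,
                         beta0 = p0, fixed_dose_params = c(p1, p2, p3) - p0,
                         spline_V = NULL, spline_coef = NULL, basis = basis),
                    class = "candidate_model")
  cv <- curve_grid(cand)
  expect_equal(cv$response, p(cv$dose), tolerance = 1e-10)
  tcds <- compute_tcds(cv)
  expect_length(tcds, 3L)
  types <- vapply(tcds, `[[`, "", "tcd_type")
  doses <- vapply(tcds, `[[`, numeric(1), "dose")
  step <- 1 / 199
  expect_equal(types, c("maximum", "inflection", "minimum"))
  expect_equal(doses, c((3 - sqrt(1.8)) / 6, 0.5, (3 + sqrt(1.8)) / 6),
               tolerance = step)
  expect_true(!is.unsorted(doses))
})

test_that("linear and null curves yield no TCDs", {
  lin <- structure(list(kind = "linear_mixed", available = TRUE, beta0 = 2,
                        fixed_dose_params = c(dose = 0.7), basis = NULL),
                   class = "candidate_model")
  expect_length(compute_tcds(curve_grid(lin, 0, 4)), 0L)
  nul <- structure(list(kind = "null", available = TRUE, beta0 = 2,
                        basis = NULL), class = "candidate_model")
  expect_length(compute_tcds(curve_grid(nul, 0, 4)), 0L)
})

test_that("stratified subsample keeps every dose level without replacement", {
  doses <- rep(c(0.1, 1, 10, 100), each = 6)
  set.seed(9)
  for (i in 1:20) {
    idx <- pathbmd:::stratified_subsample(doses, 0.6)
    expect_length(idx, ceiling(0.6 * length(doses)))
    expect_false(any(duplicated(idx)))
    expect_setequal(unique(doses[idx]), unique(doses))
  }
  # tiny fraction still keeps one sample per level
  idx <- pathbmd:::stratified_subsample(doses, 0.05)
  expect_length(idx, 4L)
  expect_setequal(unique(doses[idx]), unique(doses))
})

test_that("bootstrap is reproducible and honors requested settings", {
  td <- tiny_tdata(n_genes = 5L, n_flat = 0L, slope = 1, sigma = 0.3,
                   seed = 8L)
  fit <- fit_pathway(td, gene_set("resp", sprintf("resp_%d", 1:5)))
  expect_true(fit$significant)
  b1 <- bootstrap_thresholds(fit, td, n_boot = 40L, seed = 123L)
  b2 <- bootstrap_thresholds(fit, td, n_boot = 40L, seed = 123L)
  expect_identical(b1$bmd$ci_low, b2$bmd$ci_low)
  expect_identical(b1$bmd$ci_high, b2$bmd$ci_high)
  expect_equal(b1$bmd$n_boot, 40L)
  expect_equal(b1$bmd$boot_fraction, 0.6)
  expect_true(b1$bmd$ci_low <= b1$bmd$dose && b1$bmd$dose <= b1$bmd$ci_high)
  b3 <- bootstrap_thresholds(fit, td, n_boot = 40L, seed = 124L)
  expect_false(identical(b1$bmd$ci_low, b3$bmd$ci_low))
})

test_that("dose back-transform inverts the log10 modeling scale", {
  expect_equal(back_transform_dose(c(-1, 0, 2), "log10"), c(0.1, 1, 100))
  expect_equal(back_transform_dose(c(-1, 0, 2), "natural"), c(-1, 0, 2))
})

test_that("threshold summaries cover only significant pathways", {
  res <- data.frame(significant = c(TRUE, TRUE, FALSE, TRUE),
                    bmd = c(1, 3, 99, NA), tcd1 = c(0.5, NA, 99, 2))
  s <- summarize_thresholds(res)
  expect_equal(s$bmd$values, c(1, 3))
  expect_equal(s$bmd$median, 2)
  expect_equal(s$tcd1$values, c(0.5, 2))
  expect_equal(s$bmd$cdf(1), 0.5)
  empty <- summarize_thresholds(res[res$significant == FALSE, , drop = FALSE])
  expect_length(empty$bmd$values, 0L)
  expect_true(is.na(empty$bmd$median))
})
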