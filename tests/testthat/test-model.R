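test_that("spline basis has K + d + 1 functions and sums to one", {
  doses <- log10(c(0.1, 1, 10, 100, 1000))
  b <- build_spline_basis(doses)
  expect_equal(b$n_basis, 3L + 3L + 1L)      # K = 3 interior knots, d = 3
  expect_equal(b$interior, doses[2:4])
  x <- seq(min(doses), max(doses), length.out = 50)
  expect_equal(rowSums(eval_spline_basis(b, x)), rep(1, 50))
  # evaluation clips to the boundary
  expect_equal(eval_spline_basis(b, min(doses) - 5),
               eval_spline_basis(b, min(doses)))

  expect_error(build_spline_basis(c(1, 2, 3)), "at least 4 distinct dose levels")
  expect_error(build_spline_basis(c(1, 2, 3, 4), manual_knots = 4.5),
               "strictly inside")
  nk <- build_spline_basis(c(0, 1), manual_knots = numeric(0))
  expect_equal(nk$n_basis, 4L)               # plain cubic on [0, 1]
})

test_that("smooth_spline_coef interpolates exactly and does not ring", {
  doses <- seq(-3.5, 1, length.out = 8)
  basis <- build_spline_basis(doses)
  vals <- c(8, 8, 8, 8.6, 9.4, 9.85, 9.97, 9.98)   # flat tail then rise
  cf <- pathbmd:::smooth_spline_coef(basis, doses, vals)
  expect_equal(as.vector(eval_spline_basis(basis, doses) %*% cf), vals,
               tolerance = 1e-8)
  # no overshoot in the flat region: the curve stays close to 8 there
  # (the minimum-norm representative deviates by ~0.25 on these values)
  x <- seq(doses[1], doses[3], length.out = 100)
  curve <- as.vector(eval_spline_basis(basis, x) %*% cf)
  expect_lt(max(abs(curve - 8)), 0.05)
  # and is the roughness-minimal interpolant: any perturbation within the
  # interpolation null space increases the penalty
  Om <- pathbmd:::roughness_matrix(basis)
  B_u <- eval_spline_basis(basis, doses)
  N <- svd(B_u, nv = ncol(B_u))$v[, (qr(B_u)$rank + 1):ncol(B_u), drop = FALSE]
  base_pen <- drop(t(cf) %*% Om %*% cf)
  set.seed(1)
  for (i in 1:5) {
    cf2 <- cf + N %*% rnorm(ncol(N), 0, 0.1)
    expect_gt(drop(t(cf2) %*% Om %*% cf2), base_pen)
  }
})

test_that("fitted candidates expose likelihood, AIC and identifiable curves", {
  td <- tiny_tdata(n_genes = 5L, n_flat = 0L, slope = 0.8, seed = 2L)
  set <- gene_set("resp", sprintf("resp_%d", 1:5))
  null <- fit_candidate(td, set, "null")
  lin <- fit_candidate(td, set, "linear_mixed")
  expect_s3_class(null, "candidate_model")
  expect_true(null$available && lin$available)
  expect_equal(lin$aic, 2 * lin$n_params - 2 * lin$log_likelihood)
  expect_gt(lin$log_likelihood, null$log_likelihood)
  expect_equal(nrow(lin$ranef), 5L)
  # fixed slope close to the simulated one
  expect_equal(unname(lin$fixed_dose_params), 0.8, tolerance = 0.2)

  basis <- build_spline_basis(unname(td$doses))
  nlf <- fit_candidate(td, set, "nonlinear_fixed", basis)
  expect_true(nlf$available)
  # fitted spline curve reproduces the model's dose-level values
  ud <- sort(unique(unname(td$doses)))
  v1 <- pathbmd:::pathway_curve_values(nlf, ud)
  expect_equal(as.vector(eval_spline_basis(basis, ud) %*%
                           pathbmd:::full_spline_coef(nlf)), v1)
  expect_error(fit_candidate(td, set, "nonlinear_mixed"), "basis required")
})

test_that("LRT requires a common dataset and clips at zero", {
  td <- tiny_tdata(n_genes = 4L, n_flat = 0L, seed = 3L)
  td2 <- tiny_tdata(n_genes = 4L, n_flat = 0L, seed = 4L)
  set <- gene_set("resp", sprintf("resp_%d", 1:4))
  null <- fit_candidate(td, set, "null")
  lin2 <- fit_candidate(td2, set, "linear_mixed")
  expect_error(lrt_against_null(lin2, null), "different data")
  lin <- fit_candidate(td, set, "linear_mixed")
  p <- lrt_against_null(lin, null)
  expect_true(p >= 0 && p <= 1)
  # degenerate df: candidate no richer than null
  expect_equal(lrt_against_null(null, null), 1)
})

test_that("select_best filters by alpha then takes minimum AIC", {
  mk <- function(kind, aic, n_params, p_target, available = TRUE,
                 converged = TRUE) {
    structure(list(kind = kind, available = available, converged = converged,
                   aic = aic, n_params = n_params,
                   log_likelihood = (2 * n_params - aic) / 2,
                   data_fingerprint = c(n = 1, sum_y = 0, sum_d = 0),
                   p_override = p_target),
              class = "candidate_model")
  }
  # craft log-likelihoods so the LRT p-values come out as intended
  null <- mk("null", aic = 100, n_params = 3, p_target = NA)
  ll_for_p <- function(p, df) null$log_likelihood + qchisq(1 - p, df) / 2
  lin <- mk("linear_mixed", aic = 90, n_params = 5, p_target = 0.001)
  lin$log_likelihood <- ll_for_p(0.001, 2)
  lin$aic <- 2 * 5 - 2 * lin$log_likelihood
  # spline beats the null on AIC (qchisq(0.90, 2)/2 > 2) yet fails the gate
  spl <- mk("nonlinear_mixed", aic = 80, n_params = 5, p_target = 0.10)
  spl$log_likelihood <- ll_for_p(0.10, 2)
  spl$aic <- 2 * 5 - 2 * spl$log_likelihood

  sel <- select_best(list(null = null, linear_mixed = lin,
                          nonlinear_mixed = spl), alpha = 0.05)
  expect_lt(spl$aic, null$aic)
  expect_equal(sel$best_kind, "linear_mixed")
  # without the linear candidate the gate still protects the null
  sel_gate <- select_best(list(null = null, nonlinear_mixed = spl),
                          alpha = 0.05)
  expect_equal(sel_gate$best_kind, "null")

  # nothing passes: null selected
  lin2 <- lin; lin2$log_likelihood <- ll_for_p(0.5, 2)
  lin2$aic <- 2 * 5 - 2 * lin2$log_likelihood
  sel2 <- select_best(list(null = null, linear_mixed = lin2), alpha = 0.05)
  expect_equal(sel2$best_kind, "null")

  # equal AIC tie goes to fewer parameters
  a <- mk("linear_mixed", aic = 0, n_params = 5, p_target = NA)
  a$log_likelihood <- ll_for_p(0.001, 2); a$aic <- 50
  b <- mk("nonlinear_fixed", aic = 0, n_params = 10, p_target = NA)
  b$log_likelihood <- ll_for_p(0.001, 7); b$aic <- 50; b$n_genes <- 2L
  sel3 <- select_best(list(null = null, linear_mixed = a, nonlinear_fixed = b),
                      alpha = 0.05)
  expect_equal(sel3$best_kind, "linear_mixed")
})

test_that("BH adjustment matches p.adjust and validates input", {
  p <- c(0.001, 0.01, 0.04, 0.2, NA)
  expect_equal(adjust_pvalues(p), p.adjust(p, "BH"))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "is not TRUE")
})

test_that("fit_pathway skips splines below 4 dose levels and reports p", {
  ds <- tiny_dataset(doses = c(0.1, 1, 10), n_genes = 4L, n_flat = 0L,
                     slope = 1, seed = 5L)
  td <- transform_counts(ds, dose_scale_log10 = TRUE)
  fit <- fit_pathway(td, gene_set("resp", sprintf("resp_%d", 1:4)))
  expect_match(fit$spline_skipped, "4 needed")
  expect_false("nonlinear_fixed" %in% names(fit$candidates))
  expect_true(fit$significant)
  expect_equal(fit$best_kind, "linear_mixed")
  expect_true(fit$lrt_p < 0.05)
  expect_equal(fit$y0, fit$pathway_curve$response[1])
  expect_equal(dim(fit$gene_curves), c(4L, 200L))
})

test_that("noiseless linear data are fitted essentially exactly", {
  ds <- tiny_dataset(n_genes = 4L, n_flat = 0L, slope = 0.7, sigma = 0,
                     seed = 6L)
  td <- transform_counts(ds, dose_scale_log10 = TRUE)
  fit <- fit_pathway(td, gene_set("resp", sprintf("resp_%d", 1:4)))
  expect_lt(fit$rmse, 1e-6)
  # with zero noise the spline candidates also interpolate exactly, so the
  # winning kind is degenerate; the recovered curve must be the true line
  pc <- fit$pathway_curve   # dose column is on the modeling (log10) scale
  co <- coef(lm(pc$response ~ pc$dose))
  expect_equal(unname(co[2]), 0.7, tolerance = 1e-4)
  expect_lt(max(abs(pc$response - (co[1] + co[2] * pc$dose))), 1e-4)
})
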