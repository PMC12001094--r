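test_that("dose transform maps zeros to a recorded pseudo-dose", {
  out <- transform_doses(c(0, 0.1, 1, 10), use_log10 = TRUE)
  expect_equal(out$pseudo_dose, 0.01)
  expect_equal(out$doses, log10(c(0.01, 0.1, 1, 10)))
  expect_equal(out$dose_scale, "log10")

  nat <- transform_doses(c(0, 1, 2))
  expect_equal(nat$doses, c(0, 1, 2))
  expect_true(is.na(nat$pseudo_dose))

  expect_error(transform_doses(c(0, 0), use_log10 = TRUE), "all doses are zero")
  expect_error(transform_doses(c(-1, 2)), "non-negative")
})

test_that("dispersion estimator recovers a known NB dispersion", {
  set.seed(42)
  phi_true <- 0.15
  mu <- rep(2^runif(300, 4, 10), 40)
  counts <- matrix(rnbinom(300 * 40, mu = mu, size = 1 / phi_true), 300, 40,
                   dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:40)))
  phi <- estimate_dispersion(counts)
  expect_true(all(phi >= 0))
  expect_equal(unname(median(phi)), phi_true, tolerance = 0.25)
})

test_that("dispersion estimate agrees with edgeR's tagwise estimates", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  mu <- rep(2^runif(200, 5, 11), 24)
  counts <- matrix(rnbinom(200 * 24, mu = mu, size = 1 / 0.1), 200, 24,
                   dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:24)))
  phi <- estimate_dispersion(counts)
  dge <- edgeR::estimateDisp(edgeR::DGEList(counts))
  # same overall dispersion level and positively associated per-gene
  expect_equal(unname(median(phi)), median(dge$tagwise.dispersion),
               tolerance = 0.5)
  expect_gt(cor(phi, dge$tagwise.dispersion, method = "spearman"), 0.3)
})

test_that("count transform produces log2-CPM values and finite weights", {
  set.seed(3)
  counts <- matrix(rnbinom(40 * 12, mu = 200, size = 10), 40, 12,
                   dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:12)))
  ds <- align_dataset(counts, stats::setNames(rep(c(1, 3, 10, 30), each = 3L),
                                              colnames(counts)),
                      omics_type = "counts")
  td <- transform_counts(ds, dose_scale_log10 = TRUE)
  lib <- colSums(ds$expression)
  expect_equal(td$values, log2(sweep(ds$expression, 2, lib, "/") * 1e6 + 0.5))
  expect_true(all(is.finite(td$weights)) && all(td$weights > 0))
  expect_equal(td$dose_scale, "log10")
  expect_equal(unname(td$natural_doses), rep(c(1, 3, 10, 30), each = 3L))
  # higher-count genes get higher precision under the same dispersion
  disp <- stats::setNames(rep(0.1, 2), c("lo", "hi"))
  cm <- rbind(lo = rep(10L, 12), hi = rep(1000L, 12))
  colnames(cm) <- colnames(counts)
  ds2 <- align_dataset(cm, ds$doses, omics_type = "counts")
  td2 <- transform_counts(ds2, dispersion = disp)
  expect_true(all(td2$weights["hi", ] > td2$weights["lo", ]))
})

test_that("log-intensity input passes through with unit weights", {
  ds <- tiny_dataset()
  td <- transform_counts(ds)
  expect_identical(td$values, ds$expression)
  expect_true(all(td$weights == 1))
  expect_equal(td$dose_scale, "natural")
})

test_that("invariant filter drops low-variance sets and keeps responsive ones", {
  set.seed(11)
  n_s <- 24
  bg <- matrix(rnorm(90 * n_s, sd = 1), 90, n_s)
  quiet <- matrix(rnorm(10 * n_s, sd = 1e-3), 10, n_s)
  m <- rbind(bg, quiet)
  dimnames(m) <- list(c(sprintf("bg%02d", 1:90), sprintf("q%02d", 1:10)),
                      sprintf("s%02d", seq_len(n_s)))
  ds <- align_dataset(m, stats::setNames(rep(c(1, 2, 4, 8), each = 6), colnames(m)),
                      omics_type = "log_intensity")
  td <- transform_counts(ds)
  res <- filter_invariant(td, gene_set("quiet", sprintf("q%02d", 1:10)))
  expect_false(res$keep)
  expect_equal(res$reason, "invariant_genes")
  expect_equal(res$fraction, 1)
  ok <- filter_invariant(td, gene_set("bg", sprintf("bg%02d", 1:10)))
  expect_true(ok$keep)
})

test_that("antagonism and PC1 filters use strict thresholds", {
  set.seed(12)
  n_s <- 24
  s <- rnorm(n_s)
  m <- rbind(up1 = s + rnorm(n_s, 0, 0.01), up2 = s + rnorm(n_s, 0, 0.01),
             dn1 = -s + rnorm(n_s, 0, 0.01), dn2 = -s + rnorm(n_s, 0, 0.01),
             noise1 = rnorm(n_s), noise2 = rnorm(n_s))
  colnames(m) <- sprintf("s%02d", seq_len(n_s))
  ds <- align_dataset(m, stats::setNames(rep(c(1, 2, 4, 8), each = 6), colnames(m)),
                      omics_type = "log_intensity")
  td <- transform_counts(ds)
  ant <- filter_antagonistic(td, gene_set("a", c("up1", "up2", "dn1", "dn2")))
  expect_false(ant$keep)          # 4 of 6 pairs negative > 0.5
  expect_equal(ant$fraction, 4 / 6)
  ok <- filter_antagonistic(td, gene_set("b", c("up1", "up2", "noise1")))
  expect_true(ok$keep)

  pc <- filter_pc1(td, gene_set("c", c("up1", "up2")))
  expect_false(pc$keep)           # near rank-1 pair
  expect_equal(pc$reason, "pc1_dominant")
  okpc <- filter_pc1(td, gene_set("d", c("up1", "noise1", "noise2")))
  expect_true(okpc$keep)
})

test_that("apply_set_filters gates size first and reports the failing filter", {
  td <- tiny_tdata()
  cfg <- filter_config(min_set_size = 2L, max_set_size = 3L)
  small <- apply_set_filters(td, gene_set("one", "resp_1"), cfg)
  expect_false(small$keep); expect_equal(small$reason, "too_small")
  big <- apply_set_filters(td, gene_set("big", rownames(td$values)), cfg)
  expect_false(big$keep); expect_equal(big$reason, "too_large")
  off <- apply_set_filters(td, gene_set("resp", c("resp_1", "resp_2")),
                           filter_config(), use_invariant = FALSE,
                           use_antagonistic = FALSE, use_pc1 = FALSE)
  expect_true(off$keep)
})
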