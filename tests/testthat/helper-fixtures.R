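# Shared helpers for building small in-memory datasets and file fixtures.

# A tiny deterministic log-intensity dataset: `n_genes` responsive genes with
# linear dose trends plus `n_flat` flat genes, on `doses` with `reps`
# replicates each.
tiny_dataset <- function(n_genes = 4L, n_flat = 2L,
                         doses = c(0.1, 1, 10, 100), reps = 3L,
                         slope = 1, sigma = 0.1, seed = 1L) {
  set.seed(seed)
  d <- rep(doses, each = reps)
  samples <- sprintf("S%02d", seq_along(d))
  x <- log10(d)
  genes <- c(sprintf("resp_%d", seq_len(n_genes)),
             if (n_flat > 0L) sprintf("flat_%d", seq_len(n_flat)))
  m <- matrix(NA_real_, length(genes), length(d),
              dimnames = list(genes, samples))
  for (i in seq_len(n_genes)) {
    m[i, ] <- 8 + rnorm(1) + slope * x + rnorm(length(d), 0, sigma)
  }
  if (n_flat > 0L) {
    for (i in seq_len(n_flat)) {
      m[n_genes + i, ] <- 8 + rnorm(1) + rnorm(length(d), 0, sigma)
    }
  }
  align_dataset(m, stats::setNames(d, samples), omics_type = "log_intensity")
}

tiny_tdata <- function(...) {
  transform_counts(tiny_dataset(...), dose_scale_log10 = TRUE)
}

# Write matrix / metadata / GMT fixture files into a fresh temp directory.
write_fixture_files <- function(dataset, genesets, dir = withr_tempdir()) {
  paths <- list(matrix = file.path(dir, "expr.tsv"),
                metadata = file.path(dir, "meta.tsv"),
                gmt = file.path(dir, "sets.gmt"))
  write_expression_matrix(dataset$expression, paths$matrix)
  write_metadata(dataset$doses, paths$metadata)
  write_gmt(genesets, paths$gmt)
  paths
}

withr_tempdir <- function() {
  d <- tempfile("fix")
  dir.create(d)
  d
}
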