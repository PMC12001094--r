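#' Transform doses to the modeling scale
#'
#' With `use_log10 = TRUE`, doses are log10-transformed; zero (control) doses
#' are first replaced by a pseudo-dose of one tenth of the smallest positive
#' dose so they remain finite, and that pseudo-dose is recorded.
#'
#' @param doses Non-negative numeric vector (original units).
#' @param use_log10 Log10-transform? Recommended when doses span several
#'   orders of magnitude.
#' @return A list with `doses` (modeling scale), `dose_scale`
#'   (`"natural"`/`"log10"`) and `pseudo_dose` (`NA` unless zeros were mapped).
#' @export
transform_doses <- function(doses, use_log10 = FALSE) {
  if (any(doses < 0)) stop("doses must be non-negative")
  if (!use_log10) {
    return(list(doses = doses, dose_scale = "natural", pseudo_dose = NA_real_))
  }
  pseudo <- NA_real_
  d <- doses
  if (any(d == 0)) {
    pos <- d[d > 0]
    if (!length(pos)) stop("all doses are zero; log10 transform undefined")
    pseudo <- min(pos) / 10
    d[d == 0] <- pseudo
  }
  list(doses = log10(d), dose_scale = "log10", pseudo_dose = pseudo)
}

#' Estimate per-feature negative-binomial dispersion
#'
#' Two-step estimator for the NB variance model \eqn{Var = \mu + \phi\mu^2}:
#' a per-feature method-of-moments estimate on library-size-scaled counts,
#' followed by empirical-Bayes shrinkage toward a lowess mean-dispersion
#' trend. Features whose moments are sub-Poisson get \eqn{\phi = 0}.
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @param prior_n Shrinkage strength: equivalent number of prior samples
#'   pulling the raw estimate toward the trend.
#' @return Named non-negative numeric vector, one dispersion per feature.
#' @export
estimate_dispersion <- function(counts, prior_n = 10) {
  if (ncol(counts) < 2L) stop("dispersion estimation needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size for sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  # scale to the geometric-mean library so moments are comparable
  sf <- lib / exp(mean(log(lib)))
  scaled <- sweep(counts, 2L, sf, "/")
  m <- rowMeans(scaled)
  v <- apply(scaled, 1L, var)
  phi_raw <- ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
  # trend on log-mean for expressed features, constant fallback otherwise
  ok <- m > 0
  trend <- rep(0, length(m))
  if (sum(ok) >= 10L) {
    lo <- lowess(log(m[ok]), phi_raw[ok], f = 0.5)
    trend[ok] <- pmax(0, approx(lo$x, lo$y, xout = log(m[ok]), rule = 2L)$y)
  } else if (any(ok)) {
    trend[ok] <- median(phi_raw[ok])
  }
  n <- ncol(counts)
  w <- n / (n + prior_n)
  phi <- pmax(0, w * phi_raw + (1 - w) * trend)
  phi[v == 0] <- 0
  setNames(phi, rownames(counts))
}

#' Transform counts (or log-intensities) to the modeling scale
#'
#' Counts become `log2(CPM + 0.5)` on library-size-normalized counts, with
#' precision weights equal to the inverse delta-method variance of the
#' log2-count under the NB variance model with each feature's dispersion
#' (so high-dispersion or low-count observations are down-weighted in the
#' mixed-model fits). Log-intensity input passes through with unit weights.
#'
#' @param dataset A `dose_response_dataset`.
#' @param dispersion Per-feature dispersion from [estimate_dispersion()];
#'   estimated automatically when `NULL` and the data are counts.
#' @param dose_scale_log10 Log10-transform the doses (see [transform_doses()]).
#' @return A `transformed_dataset`: `values`, `weights`, `doses` (modeling
#'   scale), `natural_doses`, `dose_scale`, `pseudo_dose`, `dispersion`,
#'   `omics_type`.
#' @export
transform_counts <- function(dataset, dispersion = NULL, dose_scale_log10 = FALSE) {
  stopifnot(inherits(dataset, "dose_response_dataset"))
  dt <- transform_doses(unname(dataset$doses), use_log10 = dose_scale_log10)
  if (dataset$omics_type == "log_intensity") {
    out <- list(values = dataset$expression,
                weights = matrix(1, nrow(dataset$expression), ncol(dataset$expression),
                                 dimnames = dimnames(dataset$expression)),
                doses = setNames(dt$doses, names(dataset$doses)),
                natural_doses = dataset$doses,
                dose_scale = dt$dose_scale, pseudo_dose = dt$pseudo_dose,
                dispersion = NULL, omics_type = "log_intensity")
    return(structure(out, class = "transformed_dataset"))
  }
  counts <- dataset$expression
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size for sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts)
  dispersion <- dispersion[rownames(counts)]
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  values <- log2(cpm + 0.5)
  # expected count per cell from the feature's mean CPM and the library size
  mu <- outer(rowMeans(cpm), lib / 1e6)
  mu <- pmax(mu, 0.25)                       # guard against zero means
  var_log2 <- (1 / mu + dispersion) / log(2)^2
  weights <- 1 / var_log2
  dimnames(values) <- dimnames(weights) <- dimnames(counts)
  structure(list(values = values, weights = weights,
                 doses = setNames(dt$doses, names(dataset$doses)),
                 natural_doses = dataset$doses,
                 dose_scale = dt$dose_scale, pseudo_dose = dt$pseudo_dose,
                 dispersion = dispersion, omics_type = "counts"),
            class = "transformed_dataset")
}

#' @export
print.transformed_dataset <- function(x, ...) {
  cat("<transformed_dataset> ", nrow(x$values), " features x ", ncol(x$values),
      " samples, dose scale ", x$dose_scale, "\n", sep = "")
  invisible(x)
}

#' Pathway pre-filter configuration
#'
#' Default thresholds: a set is dropped when more than 50% of its genes fall
#' in the lowest-10% variance quantile of all genes (invariant filter), when
#' more than 50% of its gene pairs are negatively correlated (antagonism
#' filter), or when its first principal component explains more than 70% of
#' the within-set variance (PC1 filter). All comparisons are strict.
#'
#' @param invariant_gene_fraction,low_variance_quantile,negative_correlation_fraction,pc1_variance_fraction
#'   Filter thresholds, each in (0, 1].
#' @param min_set_size,max_set_size Matched-gene count limits for a set to be
#'   analyzed.
#' @return A `filter_config` list.
#' @export
filter_config <- function(invariant_gene_fraction = 0.5,
                          low_variance_quantile = 0.10,
                          negative_correlation_fraction = 0.5,
                          pc1_variance_fraction = 0.70,
                          min_set_size = 2L,
                          max_set_size = 500L) {
  stopifnot(invariant_gene_fraction > 0, invariant_gene_fraction <= 1,
            low_variance_quantile > 0, low_variance_quantile <= 1,
            negative_correlation_fraction > 0, negative_correlation_fraction <= 1,
            pc1_variance_fraction > 0, pc1_variance_fraction <= 1,
            min_set_size <= max_set_size)
  structure(list(invariant_gene_fraction = invariant_gene_fraction,
                 low_variance_quantile = low_variance_quantile,
                 negative_correlation_fraction = negative_correlation_fraction,
                 pc1_variance_fraction = pc1_variance_fraction,
                 min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size)),
            class = "filter_config")
}

match_set_features <- function(tdata, set) {
  intersect(set$members, rownames(tdata$values))
}

#' Invariant-gene filter
#'
#' Drops a set when the fraction of member genes whose variance lies within
#' the lowest `low_variance_quantile` quantile of all-gene variances exceeds
#' `invariant_gene_fraction` (strict).
#'
#' @param tdata A `transformed_dataset`.
#' @param set A `gene_set`.
#' @param cfg A [filter_config()].
#' @return A list: `keep` (logical), `reason`, and diagnostic `fraction`.
#' @export
filter_invariant <- function(tdata, set, cfg = filter_config()) {
  genes <- match_set_features(tdata, set)
  if (length(genes) < cfg$min_set_size) {
    return(list(keep = FALSE, reason = "too_small", fraction = NA_real_))
  }
  all_var <- apply(tdata$values, 1L, var)
  q <- quantile(all_var, cfg$low_variance_quantile, names = FALSE, type = 7)
  frac <- mean(all_var[genes] <= q)
  keep <- !(frac > cfg$invariant_gene_fraction)
  list(keep = keep, reason = if (keep) NA_character_ else "invariant_genes",
       fraction = frac)
}

#' Antagonistic-profile filter
#'
#' Drops a set when the fraction of gene pairs with negative Pearson
#' correlation (on the modeling scale) exceeds
#' `negative_correlation_fraction` (strict). Zero-variance genes contribute
#' no pairs.
#'
#' @inheritParams filter_invariant
#' @return A list: `keep`, `reason`, `fraction`, `n_pairs`,
#'   `excluded_genes` (zero-variance members).
#' @export
filter_antagonistic <- function(tdata, set, cfg = filter_config()) {
  genes <- match_set_features(tdata, set)
  if (length(genes) < cfg$min_set_size) {
    return(list(keep = FALSE, reason = "too_small", fraction = NA_real_, n_pairs = 0L))
  }
  sub <- tdata$values[genes, , drop = FALSE]
  vv <- apply(sub, 1L, var)
  excluded <- genes[vv == 0]
  sub <- sub[vv > 0, , drop = FALSE]
  if (nrow(sub) < 2L) {
    return(list(keep = TRUE, reason = NA_character_, fraction = NA_real_,
                n_pairs = 0L, excluded_genes = excluded))
  }
  cc <- cor(t(sub))
  lower <- cc[lower.tri(cc)]
  frac <- mean(lower < 0)
  keep <- !(frac > cfg$negative_correlation_fraction)
  list(keep = keep, reason = if (keep) NA_character_ else "antagonistic_profiles",
       fraction = frac, n_pairs = length(lower), excluded_genes = excluded)
}

#' First-principal-component filter
#'
#' PCA on the member-gene submatrix (samples as observations, genes as
#' centered variables); drops the set when PC1's explained-variance fraction
#' exceeds `pc1_variance_fraction` (strict).
#'
#' @inheritParams filter_invariant
#' @return A list: `keep`, `reason`, and diagnostic `fraction`.
#' @export
filter_pc1 <- function(tdata, set, cfg = filter_config()) {
  genes <- match_set_features(tdata, set)
  if (length(genes) < 2L || length(genes) < cfg$min_set_size) {
    return(list(keep = FALSE, reason = "too_small", fraction = NA_real_))
  }
  sub <- t(tdata$values[genes, , drop = FALSE])   # samples x genes
  sub <- scale(sub, center = TRUE, scale = FALSE)
  if (all(abs(sub) < .Machine$double.eps^0.5)) {
    return(list(keep = FALSE, reason = "rank_zero", fraction = NA_real_))
  }
  pc <- prcomp(sub, center = FALSE, scale. = FALSE)
  frac <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  keep <- !(frac > cfg$pc1_variance_fraction)
  list(keep = keep, reason = if (keep) NA_character_ else "pc1_dominant",
       fraction = frac)
}

#' Apply the pathway pre-filters to one gene set
#'
#' Runs the size check and the enabled filters as disjunctive gates: the set
#' is kept only if every enabled filter keeps it.
#'
#' @inheritParams filter_invariant
#' @param use_invariant,use_antagonistic,use_pc1 Enable/disable each filter.
#' @return A list: `keep`, `reason` (first failing gate), and per-filter
#'   diagnostics.
#' @export
apply_set_filters <- function(tdata, set, cfg = filter_config(),
                              use_invariant = TRUE, use_antagonistic = TRUE,
                              use_pc1 = TRUE) {
  genes <- match_set_features(tdata, set)
  if (length(genes) < cfg$min_set_size) {
    return(list(keep = FALSE, reason = "too_small", n_matched = length(genes)))
  }
  if (length(genes) > cfg$max_set_size) {
    return(list(keep = FALSE, reason = "too_large", n_matched = length(genes)))
  }
  diags <- list(n_matched = length(genes))
  for (f in c(if (use_invariant) "invariant",
              if (use_antagonistic) "antagonistic",
              if (use_pc1) "pc1")) {
    res <- switch(f,
                  invariant = filter_invariant(tdata, set, cfg),
                  antagonistic = filter_antagonistic(tdata, set, cfg),
                  pc1 = filter_pc1(tdata, set, cfg))
    diags[[f]] <- res
    if (!res$keep) {
      return(c(list(keep = FALSE, reason = res$reason), diags))
    }
  }
  c(list(keep = TRUE, reason = NA_character_), diags)
}
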