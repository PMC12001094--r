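#' Cluster genes of a pathway by their dose-response coefficients
#'
#' Groups the genes of a fitted pathway by k-means on their empirical-Bayes
#' random-effect coefficients (the random intercept concatenated with the
#' random dose/spline coefficients, each dimension standardized). The number
#' of clusters is chosen as the k in `2..k_max` maximizing the mean
#' silhouette width (Euclidean distance); when the best silhouette is below
#' `silhouette_floor` the genes are treated as one homogeneous group
#' (`k = 1`). Deterministic given `seed` (fixed number of k-means restarts).
#'
#' @param fit A `fitted_pathway_model` (its best model supplies the
#'   coefficients), or a numeric gene x feature matrix.
#' @param k_max Largest k to consider (capped at `n_genes - 1`).
#' @param seed Integer seed.
#' @param silhouette_floor Minimum mean silhouette to accept substructure.
#' @param n_restarts k-means restarts per k.
#' @return A `cluster_assignment`: `labels` (named integer vector), `k`,
#'   `silhouette_by_k`, `dominant_cluster` (label of the largest cluster).
#' @export
cluster_genes <- function(fit, k_max = 6L, seed = 1L, silhouette_floor = 0.25,
                          n_restarts = 25L) {
  feats <- if (is.matrix(fit)) fit else gene_coefficients(fit)
  genes <- rownames(feats)
  if (length(genes) < 3L) stop("clustering needs at least 3 genes")
  k_max <- min(as.integer(k_max), nrow(feats) - 1L)
  # standardize informative dimensions; constant ones carry no signal
  keep <- apply(feats, 2L, sd) > 0
  if (!any(keep) || nrow(unique(feats)) == 1L) {
    return(one_cluster(genes))
  }
  x <- scale(feats[, keep, drop = FALSE])
  sil <- setNames(rep(NA_real_, k_max - 1L), as.character(2:k_max))
  fits <- vector("list", k_max - 1L)
  d <- dist(x)
  for (k in 2:k_max) {
    if (nrow(unique(x)) < k) break
    set.seed(as.integer(seed) + k)
    km <- kmeans(x, centers = k, nstart = n_restarts, iter.max = 50L)
    fits[[k - 1L]] <- km
    sw <- cluster::silhouette(km$cluster, d)
    sil[as.character(k)] <- mean(sw[, "sil_width"])
  }
  if (all(is.na(sil)) || max(sil, na.rm = TRUE) < silhouette_floor) {
    out <- one_cluster(genes)
    out$silhouette_by_k <- sil
    return(out)
  }
  k_best <- as.integer(names(sil)[which.max(sil)])
  labels <- fits[[k_best - 1L]]$cluster
  # relabel so cluster 1 is the largest (the dominant cluster)
  sizes <- sort(table(labels), decreasing = TRUE)
  remap <- setNames(seq_along(sizes), names(sizes))
  labels <- setNames(as.integer(remap[as.character(labels)]), genes)
  structure(list(labels = labels, k = k_best, silhouette_by_k = sil,
                 dominant_cluster = 1L),
            class = "cluster_assignment")
}

one_cluster <- function(genes) {
  structure(list(labels = setNames(rep(1L, length(genes)), genes), k = 1L,
                 silhouette_by_k = NULL, dominant_cluster = 1L),
            class = "cluster_assignment")
}

# Per-gene coefficient matrix: random intercept plus random dose terms of the
# selected model (genes with no dose random effects get the intercept only).
gene_coefficients <- function(fit) {
  re <- fit$best$ranef
  if (is.null(re)) stop("fitted model carries no random effects")
  as.matrix(re)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> k = ", x$k, " over ", length(x$labels), " genes",
      "; dominant cluster size ", sum(x$labels == x$dominant_cluster), "\n", sep = "")
  invisible(x)
}

#' Split a gene set according to a cluster assignment
#'
#' Emits one derived gene set per cluster, named `<parent>__cluster<i>`,
#' partitioning the assigned members of the parent. Each derived set can be
#' refitted independently downstream.
#'
#' @param set The parent `gene_set`.
#' @param assignment A `cluster_assignment` covering the set.
#' @return A list of `gene_set`s (length `k`).
#' @export
split_geneset <- function(set, assignment) {
  labels <- assignment$labels
  if (!all(names(labels) %in% set$members)) {
    stop("cluster assignment contains genes not in set '", set$name, "'")
  }
  lapply(sort(unique(labels)), function(k) {
    gene_set(name = paste0(set$name, "__cluster", k),
             members = names(labels)[labels == k],
             description = paste0("cluster ", k, " of ", set$name))
  })
}
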