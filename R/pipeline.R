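#' Pipeline run configuration
#'
#' Collects all inputs and tuning parameters of an end-to-end run. Inputs
#' may be given as file paths (`matrix`, `metadata`, `gmt`) or as in-memory
#' objects (`dataset`, `genesets`). Defaults: LRT significance gate
#' `alpha = 0.05`, benchmark response multiplier `z = 1`, `n_boot = 1000`
#' bootstrap replicates on `boot_fraction = 0.6` of the samples.
#'
#' @param matrix,metadata,gmt Input file paths (or `NULL` when in-memory
#'   objects are supplied).
#' @param dataset A `dose_response_dataset` (alternative to paths).
#' @param genesets A `gene_set_collection` (alternative to `gmt`).
#' @param omics_type `"counts"` or `"log_intensity"`.
#' @param filters A [filter_config()].
#' @param use_filters Apply the pathway pre-filters? Off by default: the
#'   filters are an opt-in screening step, and the PC1 gate in particular
#'   removes highly coherent (strongly responding) sets.
#' @param alpha LRT significance gate.
#' @param z Benchmark response multiplier.
#' @param n_boot Bootstrap replicates for threshold CIs.
#' @param boot_fraction Bootstrap subsample fraction.
#' @param log10_dose Model on the log10 dose scale?
#' @param clustering Cluster divergent gene subgroups within each
#'   significant pathway (and refit each cluster)?
#' @param seed Global seed; per-pathway seeds are derived from it and the
#'   pathway name, so results do not depend on worker scheduling.
#' @param n_workers Parallel workers (forked; 1 = serial).
#' @param grid_size Curve grid size.
#' @return A `run_config` list.
#' @export
run_config <- function(matrix = NULL, metadata = NULL, gmt = NULL,
                       dataset = NULL, genesets = NULL,
                       omics_type = c("counts", "log_intensity"),
                       filters = filter_config(), use_filters = FALSE,
                       alpha = 0.05, z = 1, n_boot = 1000L, boot_fraction = 0.6,
                       log10_dose = FALSE, clustering = FALSE,
                       seed = 42L, n_workers = 1L, grid_size = 200L) {
  omics_type <- match.arg(omics_type)
  structure(list(matrix = matrix, metadata = metadata, gmt = gmt,
                 dataset = dataset, genesets = genesets,
                 omics_type = omics_type, filters = filters,
                 use_filters = isTRUE(use_filters),
                 alpha = alpha, z = z, n_boot = as.integer(n_boot),
                 boot_fraction = boot_fraction,
                 log10_dose = isTRUE(log10_dose), clustering = isTRUE(clustering),
                 seed = as.integer(seed), n_workers = as.integer(n_workers),
                 grid_size = as.integer(grid_size)),
            class = "run_config")
}

# Deterministic per-pathway seed from the global seed and the pathway name,
# independent of pathway order and worker scheduling.
pathway_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 100000L
  as.integer((as.numeric(seed) * 100003 + h) %% 2147483647)
}

#' Run the full pathway dose-response pipeline
#'
#' For every gene set: size check and optional pre-filters, candidate model
#' fitting and AIC/LRT selection, then — for significant pathways — BMD and
#' TCD estimation with bootstrap confidence intervals, and optional
#' clustering of divergent gene subgroups with per-cluster refits.
#' Benjamini-Hochberg adjustment is applied across all pathways that reached
#' fitting. Deterministic for a fixed seed regardless of `n_workers`.
#'
#' @param config A [run_config()].
#' @return A `pathbmd_results` object: `table` (one row per pathway, doses
#'   in natural units), `pathways` (per-pathway detail), `config`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  if (is.null(config$dataset)) {
    expr <- read_expression_matrix(config$matrix, config$omics_type)
    doses <- read_metadata(config$metadata)
    dataset <- align_dataset(expr, doses, omics_type = config$omics_type)
  } else dataset <- config$dataset
  genesets <- if (is.null(config$genesets)) read_gmt(config$gmt) else config$genesets
  for (side in names(dataset$dropped_samples %||% list())) {
    dr <- dataset$dropped_samples[[side]]
    if (length(dr)) note("dropped ", side, " samples: ", paste(dr, collapse = ", "))
  }
  for (w in dataset$warnings) note("dataset warning: ", w)

  tdata <- transform_counts(dataset, dose_scale_log10 = config$log10_dose)

  worker <- function(set) {
    res <- list(name = set$name, id = set$id %||% NA_character_,
                n_genes = length(match_set_features(tdata, set)))
    if (config$use_filters) {
      fl <- apply_set_filters(tdata, set, config$filters)
    } else {
      n <- res$n_genes
      fl <- if (n < config$filters$min_set_size) {
        list(keep = FALSE, reason = "too_small")
      } else list(keep = TRUE, reason = NA_character_)
    }
    res$filter <- fl
    if (!fl$keep) {
      res$status <- "filtered"
      return(res)
    }
    fit <- tryCatch(fit_pathway(tdata, set, alpha = config$alpha,
                                grid_size = config$grid_size),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      res$status <- "unfit"; res$error <- conditionMessage(fit)
      return(res)
    }
    res$status <- "fitted"
    res$fit <- fit
    if (fit$significant) {
      sd_seed <- pathway_seed(config$seed, set$name)
      res$thresholds <- bootstrap_thresholds(fit, tdata,
                                             n_boot = config$n_boot,
                                             fraction = config$boot_fraction,
                                             seed = sd_seed, z = config$z,
                                             grid_size = config$grid_size)
      if (config$clustering && fit$best_kind != "null" &&
          nrow(fit$best$ranef) >= 3L) {
        res$clusters <- cluster_genes(fit, seed = sd_seed)
        if (res$clusters$k > 1L) {
          derived <- split_geneset(
            gene_set(set$name, names(res$clusters$labels), set$description),
            res$clusters)
          res$cluster_fits <- lapply(derived, function(ds) {
            f <- tryCatch(fit_pathway(tdata, ds, alpha = config$alpha,
                                      grid_size = config$grid_size),
                          error = function(e) NULL)
            if (is.null(f)) NULL else {
              list(name = ds$name, n_genes = length(ds$members),
                   best_kind = f$best_kind, lrt_p = f$lrt_p, rmse = f$rmse)
            }
          })
        }
      }
    }
    res
  }

  sets <- unname(as.list(genesets))
  details <- if (config$n_workers > 1L) {
    parallel::mclapply(sets, worker, mc.cores = config$n_workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(sets, worker)
  }
  names(details) <- vapply(details, `[[`, "", "name")

  for (d in details) {
    if (d$status == "filtered") note("set '", d$name, "' filtered: ", d$filter$reason)
    if (d$status == "unfit") note("set '", d$name, "' unfit: ", d$error)
  }
  if (!any(vapply(details, function(d) d$status == "fitted", logical(1)))) {
    stop("no pathway passed the size/pre-filters and reached fitting")
  }

  table <- results_table(details, tdata, config)
  structure(list(table = table, pathways = details, config = config,
                 log = log_lines, dose_scale = tdata$dose_scale),
            class = "pathbmd_results")
}

results_table <- function(details, tdata, config) {
  bt <- function(x) back_transform_dose(x, tdata$dose_scale)
  rows <- lapply(details, function(d) {
    base <- data.frame(
      geneset = d$name, id = d$id, n_genes = d$n_genes,
      status = d$status,
      filter_reason = if (d$status == "filtered") d$filter$reason else NA_character_,
      best_model = NA_character_, p = NA_real_, adj_p = NA_real_,
      aic = NA_real_, rmse = NA_real_, significant = NA,
      bmd = NA_real_, bmd_lo = NA_real_, bmd_hi = NA_real_,
      tcd1 = NA_real_, tcd1_lo = NA_real_, tcd1_hi = NA_real_,
      n_tcds = NA_integer_, tcd_types = NA_character_,
      k_clusters = NA_integer_, stringsAsFactors = FALSE)
    if (d$status != "fitted") return(base)
    f <- d$fit
    base$best_model <- f$best_kind
    base$p <- f$lrt_p
    base$aic <- f$best$aic
    base$rmse <- f$rmse
    base$significant <- f$significant
    th <- d$thresholds
    if (!is.null(th)) {
      if (!is.null(th$bmd)) {
        base$bmd <- bt(th$bmd$dose)
        base$bmd_lo <- bt(th$bmd$ci_low); base$bmd_hi <- bt(th$bmd$ci_high)
      }
      base$n_tcds <- length(th$tcds)
      if (length(th$tcds)) {
        base$tcd1 <- bt(th$tcds[[1L]]$dose)
        base$tcd1_lo <- bt(th$tcds[[1L]]$ci_low)
        base$tcd1_hi <- bt(th$tcds[[1L]]$ci_high)
        base$tcd_types <- paste(vapply(th$tcds, `[[`, "", "tcd_type"), collapse = ";")
      }
    }
    if (!is.null(d$clusters)) base$k_clusters <- d$clusters$k
    base
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab$adj_p <- adjust_pvalues(tab$p)
  tab[order(tab$p, tab$geneset, na.last = TRUE), , drop = FALSE]
}

#' @export
print.pathbmd_results <- function(x, ...) {
  tab <- x$table
  cat("<pathbmd_results> ", nrow(tab), " pathways; ",
      sum(tab$significant %in% TRUE), " significant\n", sep = "")
  print(head(tab[, c("geneset", "best_model", "p", "adj_p", "bmd", "tcd1")], 10L))
  invisible(x)
}

#' Write pipeline results to an output directory
#'
#' Writes `results.tsv` and `results.csv` (identical content), a JSON
#' sidecar per fitted pathway (curve, thresholds, cluster labels),
#' `run_config.json`, and `run.log`.
#'
#' @param results A `pathbmd_results` object.
#' @param out_dir Output directory (created if needed; must be writable).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("", probe); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop("output directory not writable: ", out_dir)
  unlink(probe)
  tab <- results$table
  write.table(tab, file.path(out_dir, "results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  write.table(tab, file.path(out_dir, "results.csv"), sep = ",",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  for (d in results$pathways) {
    if (d$status != "fitted") next
    side <- list(
      geneset = d$name, best_model = d$fit$best_kind,
      significant = d$fit$significant, lrt_p = d$fit$lrt_p,
      rmse = d$fit$rmse,
      curve = list(dose = d$fit$pathway_curve$dose,
                   response = d$fit$pathway_curve$response),
      bmd = threshold_json(d$thresholds$bmd, results$dose_scale),
      tcds = lapply(d$thresholds$tcds, threshold_json, results$dose_scale),
      cluster_labels = if (!is.null(d$clusters)) as.list(d$clusters$labels))
    jsonlite::write_json(
      side, file.path(out_dir, paste0("pathway_", sanitize_name(d$name), ".json")),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  cfg <- unclass(results$config)
  cfg$dataset <- NULL; cfg$genesets <- NULL
  cfg$filters <- unclass(cfg$filters)
  jsonlite::write_json(cfg, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(results$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

threshold_json <- function(th, dose_scale) {
  if (is.null(th)) return(NULL)
  list(kind = th$kind, tcd_type = th$tcd_type %||% NULL,
       dose = back_transform_dose(th$dose, dose_scale),
       ci_low = back_transform_dose(th$ci_low, dose_scale),
       ci_high = back_transform_dose(th$ci_high, dose_scale),
       n_defined = th$n_defined %||% NULL)
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)
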