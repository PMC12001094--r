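#' Specification for a synthetic dose-response experiment
#'
#' Defines the design and effect structure of a simulated pathway
#' dose-response study. The defaults mirror a typical in-vitro
#' concentration-response design: 8 concentrations spaced evenly on the
#' log10 scale over more than four orders of magnitude, 3 replicates per
#' concentration, and pathway trends modeled on the log10 dose scale.
#'
#' Each entry of `genesets` is a list with `name`, `n_genes`,
#' `shape` (one of `"flat"`, `"linear"`, `"sigmoid"`, `"bell"`, `"u_shape"`,
#' `"antagonistic"`) and `effect_size` (response-scale amplitude of the
#' pathway trend). The simulated response for gene `j` in sample `i` is
#' `beta0 + b0j + effect_size * (1 + s_j) * g_j * shape(x_i) + e_ij` with
#' `b0j ~ N(0, sd_gene_intercept^2)` (gene baseline), `s_j ~ N(0,
#' sd_gene_slope^2)` (gene-specific effect scaling), `g_j = 1` except for
#' antagonistic sets where half the genes get `g_j = -1`, and
#' `x` the dose position rescaled to `[0, 1]` on the log10 scale. In counts
#' mode the latent value is treated as log2 mean expression and counts are
#' drawn from a negative binomial with the requested dispersion.
#'
#' @param doses Dose levels in natural units (all positive).
#' @param reps_per_dose Replicates per dose level.
#' @param genesets List of gene-set specs (see Details).
#' @param beta0 Global baseline (log2 scale).
#' @param sd_gene_intercept SD of the gene random intercepts.
#' @param sd_gene_slope SD of the gene-specific multiplicative effect
#'   perturbation.
#' @param sigma Residual SD.
#' @param omics_type `"log_intensity"` or `"counts"`.
#' @param nb_dispersion NB dispersion for counts mode (`Var = mu + phi mu^2`).
#' @param lib_sd SD of the log-normal library-size factors in counts mode
#'   (0 gives equal library sizes).
#' @param n_background_genes Unassigned flat genes added to the matrix (they
#'   provide the all-gene variance background for the filters).
#' @param seed Integer seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(doses = signif(10^seq(log10(0.0005), log10(10), length.out = 8), 3),
                            reps_per_dose = 3L,
                            genesets = list(list(name = "sigmoid_up", n_genes = 15L,
                                                 shape = "sigmoid", effect_size = 2)),
                            beta0 = 8,
                            sd_gene_intercept = 1,
                            sd_gene_slope = 0.2,
                            sigma = 0.5,
                            omics_type = c("log_intensity", "counts"),
                            nb_dispersion = 0.1,
                            lib_sd = 0.1,
                            n_background_genes = 0L,
                            seed = 1L) {
  omics_type <- match.arg(omics_type)
  stopifnot(all(doses > 0), reps_per_dose >= 1L, sigma >= 0,
            sd_gene_intercept >= 0, sd_gene_slope >= 0, nb_dispersion >= 0,
            lib_sd >= 0)
  shapes <- vapply(genesets, `[[`, "", "shape")
  stopifnot(all(shapes %in% c("flat", "linear", "sigmoid", "bell", "u_shape",
                              "antagonistic")))
  structure(list(doses = sort(doses), reps_per_dose = as.integer(reps_per_dose),
                 genesets = genesets, beta0 = beta0,
                 sd_gene_intercept = sd_gene_intercept,
                 sd_gene_slope = sd_gene_slope, sigma = sigma,
                 omics_type = omics_type, nb_dispersion = nb_dispersion,
                 lib_sd = lib_sd,
                 n_background_genes = as.integer(n_background_genes),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Shape library on the normalized log10-dose position x in [0, 1].
# sigmoid: 4-parameter-logistic rise centered at x0 = 0.5;
# bell / u_shape: Gaussian bump (or dip) centered at 0.5 with width 0.15.
shape_params <- list(sigmoid = list(k = 12, x0 = 0.5),
                     bell = list(center = 0.5, width = 0.15))

shape_value <- function(shape, x) {
  switch(shape,
    flat = rep(0, length(x)),
    linear = ,
    antagonistic = x,
    sigmoid = 1 / (1 + exp(-shape_params$sigmoid$k * (x - shape_params$sigmoid$x0))),
    bell = exp(-(x - shape_params$bell$center)^2 / (2 * shape_params$bell$width^2)),
    u_shape = -exp(-(x - shape_params$bell$center)^2 / (2 * shape_params$bell$width^2)),
    stop("unknown shape: ", shape))
}

#' Simulate a pathway dose-response dataset with known ground truth
#'
#' @param spec A [simulation_spec()].
#' @return A list: `dataset` (a `dose_response_dataset`), `genesets` (a
#'   `gene_set_collection`), `truth` (per-set shape, effect, per-gene
#'   directions and scalings, plus the log10 dose range used for the shape
#'   coordinate and recorded true trend-change positions).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  doses <- rep(spec$doses, each = spec$reps_per_dose)
  n_s <- length(doses)
  samples <- sprintf("S%02d", seq_len(n_s))
  lr <- range(log10(spec$doses))
  x <- (log10(doses) - lr[1L]) / diff(lr)
  rows <- list(); truth_sets <- list(); sets <- list()
  for (gs in spec$genesets) {
    ng <- gs$n_genes
    genes <- paste0(gs$name, "_g", seq_len(ng))
    b0 <- rnorm(ng, 0, spec$sd_gene_intercept)
    s_j <- rnorm(ng, 0, spec$sd_gene_slope)
    g_j <- rep(1, ng)
    if (gs$shape == "antagonistic") g_j[seq_len(floor(ng / 2))] <- -1
    sh <- shape_value(gs$shape, x)
    m <- matrix(NA_real_, nrow = ng, ncol = n_s, dimnames = list(genes, samples))
    for (j in seq_len(ng)) {
      m[j, ] <- spec$beta0 + b0[j] +
        gs$effect_size * (1 + s_j[j]) * g_j[j] * sh +
        rnorm(n_s, 0, spec$sigma)
    }
    rows[[gs$name]] <- m
    sets[[gs$name]] <- gene_set(gs$name, genes,
                                description = paste0("simulated ", gs$shape))
    truth_sets[[gs$name]] <- list(
      shape = gs$shape, effect_size = gs$effect_size,
      beta0 = spec$beta0, gene_intercepts = setNames(b0, genes),
      gene_scalings = setNames(s_j, genes), gene_directions = setNames(g_j, genes),
      true_tcds_x = true_tcds_x(gs$shape))
  }
  if (spec$n_background_genes > 0L) {
    genes <- paste0("bg_g", seq_len(spec$n_background_genes))
    m <- matrix(spec$beta0 + rnorm(spec$n_background_genes, 0, spec$sd_gene_intercept) +
                  rnorm(spec$n_background_genes * n_s, 0, max(spec$sigma, 0.1)),
                nrow = spec$n_background_genes, dimnames = list(genes, samples))
    rows[["__background__"]] <- m
  }
  latent <- do.call(rbind, rows)
  if (spec$omics_type == "counts") {
    mu <- 2^latent
    libfac <- exp(rnorm(n_s, 0, spec$lib_sd %||% 0.1))
    mu <- sweep(mu, 2L, libfac, "*")
    expr <- matrix(
      if (spec$nb_dispersion > 0) {
        rnbinom(length(mu), mu = mu, size = 1 / spec$nb_dispersion)
      } else {
        stats::rpois(length(mu), lambda = mu)
      }, nrow = nrow(mu), dimnames = dimnames(latent))
  } else {
    expr <- latent
  }
  ds <- align_dataset(expr, setNames(doses, samples), omics_type = spec$omics_type,
                      feature_id_kind = "simulated_gene")
  list(dataset = ds,
       genesets = structure(sets, class = "gene_set_collection"),
       truth = list(sets = truth_sets, log10_range = lr,
                    sigma = spec$sigma, spec = spec))
}

# Analytic trend-change positions of each shape on the x in [0, 1] scale.
true_tcds_x <- function(shape) {
  switch(shape,
    sigmoid = list(inflection = shape_params$sigmoid$x0),
    bell = list(maximum = shape_params$bell$center,
                inflection = shape_params$bell$center +
                  c(-1, 1) * shape_params$bell$width),
    u_shape = list(minimum = shape_params$bell$center,
                   inflection = shape_params$bell$center +
                     c(-1, 1) * shape_params$bell$width),
    list())
}

#' Closed-form true benchmark dose for simulated pathways
#'
#' Independent analytic oracle: solves `|effect * shape(x) - effect *
#' shape(0)| = z * sd` exactly for the `linear` and `sigmoid` shapes and
#' returns the corresponding dose on the modeling (log10) scale. Returns
#' `NA` if the band is never exited or the shape has no closed form here.
#'
#' @param truth The `truth` record from [simulate_dataset()].
#' @param set_name Name of the simulated gene set.
#' @param z Band multiplier.
#' @param sd Band standard deviation.
#' @return The true BMD on the log10 dose scale, or `NA`.
#' @export
true_bmd_log10 <- function(truth, set_name, z, sd) {
  ts <- truth$sets[[set_name]]
  eff <- abs(ts$effect_size)
  lr <- truth$log10_range
  x_star <- switch(ts$shape,
    linear = {
      if (z * sd / eff > 1) NA_real_ else z * sd / eff
    },
    sigmoid = {
      k <- shape_params$sigmoid$k; x0 <- shape_params$sigmoid$x0
      s0 <- 1 / (1 + exp(-k * (0 - x0)))
      p <- s0 + z * sd / eff
      if (p >= 1) NA_real_ else {
        xs <- x0 + log(p / (1 - p)) / k
        if (xs > 1) NA_real_ else xs
      }
    },
    NA_real_)
  if (is.na(x_star)) return(NA_real_)
  lr[1L] + x_star * diff(lr)
}

#' Simulate a suite of null (flat) pathways
#'
#' All pathways are flat in dose with gene-level random intercepts only;
#' intended for type-I error studies of the pathway likelihood-ratio test.
#'
#' @param n_pathways Number of flat gene sets.
#' @param n_genes Genes per set.
#' @param spec_template A [simulation_spec()] whose design fields (doses,
#'   replicates, SDs, sigma, omics type) are reused.
#' @param seed Integer seed.
#' @param gmt_path Optional path; when given the gene sets are also written
#'   as a GMT file.
#' @return As [simulate_dataset()].
#' @export
simulate_null_suite <- function(n_pathways, n_genes = 10L,
                                spec_template = simulation_spec(), seed = 1L,
                                gmt_path = NULL) {
  stopifnot(n_pathways >= 1L)
  spec <- spec_template
  spec$genesets <- lapply(seq_len(n_pathways), function(i) {
    list(name = sprintf("null_%03d", i), n_genes = as.integer(n_genes),
         shape = "flat", effect_size = 0)
  })
  spec$seed <- as.integer(seed)
  out <- simulate_dataset(spec)
  if (!is.null(gmt_path)) write_gmt(out$genesets, gmt_path)
  out
}

#' Write a simulated dataset to disk
#'
#' Writes the expression matrix, metadata, gene sets (GMT) and ground truth
#' (JSON) under a common file prefix.
#'
#' @param sim Result of [simulate_dataset()].
#' @param prefix Output path prefix.
#' @return Named character vector of the four written paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- c(matrix = paste0(prefix, "_matrix.tsv"),
             metadata = paste0(prefix, "_metadata.tsv"),
             gmt = paste0(prefix, "_sets.gmt"),
             truth = paste0(prefix, "_truth.json"))
  write_expression_matrix(sim$dataset$expression, paths["matrix"])
  write_metadata(sim$dataset$doses, paths["metadata"])
  write_gmt(sim$genesets, paths["gmt"])
  truth <- sim$truth
  truth$spec <- NULL                         # closures-free, numbers only
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
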