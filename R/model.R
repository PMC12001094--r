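#' Build a cubic B-spline basis over the dose range
#'
#' By default the interior knots are placed at the unique modeling-scale
#' doses excluding the two boundary doses, so the spline flexes at every
#' tested concentration; knots can also be supplied manually. The basis has
#' `K + d + 1` functions for `K` interior knots and degree `d`, clamped at
#' the boundary (each boundary knot repeated `d + 1` times), and forms a
#' partition of unity on the dose range.
#'
#' @param doses Numeric modeling-scale doses (replicates allowed).
#' @param degree Spline degree (3 = cubic).
#' @param manual_knots Optional interior knots; must lie strictly inside the
#'   dose range. `numeric(0)` gives a knot-free polynomial basis.
#' @return A `spline_basis`: `degree`, `interior`, `boundary`, `knots` (full
#'   clamped vector), `n_basis`.
#' @export
build_spline_basis <- function(doses, degree = 3L, manual_knots = NULL) {
  ud <- sort(unique(doses))
  if (length(ud) < 2L) stop("need at least 2 distinct doses for a spline basis")
  boundary <- range(ud)
  if (is.null(manual_knots)) {
    if (length(ud) < 4L) {
      stop("need at least 4 distinct dose levels for default cubic spline knots, got ",
           length(ud))
    }
    interior <- ud[-c(1L, length(ud))]
  } else {
    interior <- sort(manual_knots)
    if (length(interior) && (any(interior <= boundary[1L]) || any(interior >= boundary[2L]))) {
      stop("manual knots must lie strictly inside the dose range [",
           boundary[1L], ", ", boundary[2L], "]")
    }
  }
  knots <- c(rep(boundary[1L], degree + 1L), interior, rep(boundary[2L], degree + 1L))
  structure(list(degree = as.integer(degree), interior = interior,
                 boundary = boundary, knots = knots,
                 n_basis = length(interior) + degree + 1L),
            class = "spline_basis")
}

#' Evaluate a spline basis (or its derivatives)
#'
#' @param basis A [build_spline_basis()] object.
#' @param x Evaluation points, clipped to the basis boundary.
#' @param deriv Derivative order (0 = the basis functions themselves).
#' @return Matrix `length(x)` x `n_basis`.
#' @export
eval_spline_basis <- function(basis, x, deriv = 0L) {
  x <- pmin(pmax(x, basis$boundary[1L]), basis$boundary[2L])
  splines::splineDesign(basis$knots, x, ord = basis$degree + 1L,
                        derivs = rep(as.integer(deriv), length(x)))
}

basis_colnames <- function(basis) paste0("N", seq_len(basis$n_basis))

# Identifiable spline directions. With knots at every interior dose the
# basis dimension K+d+1 exceeds the number of distinct doses, so the raw
# coefficients are not identifiable (the likelihood only constrains the
# curve at the observed doses). We regress on an orthonormal basis of the
# identifiable subspace: the right singular vectors of the dose-level basis
# matrix after centering out the constant direction (the model intercept).
# Curves are reconstructed afterwards via smooth_spline_coef().
spline_directions <- function(basis, doses) {
  ud <- sort(unique(doses))
  B_u <- eval_spline_basis(basis, ud)
  Bc <- scale(B_u, center = TRUE, scale = FALSE)
  sv <- svd(Bc)
  r <- sum(sv$d > max(sv$d) * 1e-9)
  sv$v[, seq_len(r), drop = FALSE]
}

# Roughness penalty matrix: integral of B_i'' B_j'' over the dose range.
# For cubic splines the second derivatives are piecewise linear, so 2-point
# Gauss-Legendre per knot interval integrates the quadratic products exactly.
roughness_matrix <- function(basis) {
  n <- basis$n_basis
  if (basis$degree < 2L) return(matrix(0, n, n))
  kn <- unique(basis$knots)
  Om <- matrix(0, n, n)
  for (i in seq_len(length(kn) - 1L)) {
    a <- kn[i]; b <- kn[i + 1L]
    if (b <= a) next
    for (g in c(-1, 1) / sqrt(3)) {
      x <- (a + b) / 2 + g * (b - a) / 2
      d2 <- eval_spline_basis(basis, x, deriv = 2L)
      Om <- Om + (b - a) / 2 * crossprod(d2)
    }
  }
  Om
}

# Smoothest spline coefficients reproducing given values at the distinct
# doses: the likelihood only pins the curve at the observed dose levels, so
# among the equal-likelihood members of the (over-complete) spline family we
# report the one minimizing the integrated squared second derivative. A tiny
# ridge handles the penalty's null space (affine functions).
smooth_spline_coef <- function(basis, ud, values) {
  values <- as.matrix(values)
  B_u <- eval_spline_basis(basis, ud)
  n <- basis$n_basis
  sv <- svd(B_u, nu = min(dim(B_u)), nv = n)
  r <- sum(sv$d > max(sv$d) * 1e-9)
  Ur <- sv$u[, seq_len(r), drop = FALSE]
  Vr <- sv$v[, seq_len(r), drop = FALSE]
  cf <- Vr %*% (crossprod(Ur, values) / sv$d[seq_len(r)])
  if (r < n) {
    # move along the interpolation null space to minimize roughness
    N <- sv$v[, (r + 1L):n, drop = FALSE]
    Om <- roughness_matrix(basis)
    eps <- 1e-8 * max(mean(diag(Om)), 1)
    P <- Om + diag(eps, n)
    cf <- cf - N %*% solve(crossprod(N, P %*% N), crossprod(N, P %*% cf))
  }
  cf
}

# Long-format stacking of a gene set: one row per (gene, sample), with
# modeling-scale dose, response and precision weight.
stack_set_data <- function(tdata, set) {
  genes <- match_set_features(tdata, set)
  if (length(genes) < 2L) {
    stop("gene set '", set$name, "' has fewer than 2 matched genes; ",
         "random effects need replication across genes")
  }
  ns <- ncol(tdata$values)
  data.frame(
    gene = factor(rep(genes, each = ns), levels = genes),
    sample = rep(colnames(tdata$values), times = length(genes)),
    dose = rep(unname(tdata$doses), times = length(genes)),
    y = as.vector(t(tdata$values[genes, , drop = FALSE])),
    w = if (is.null(tdata$weights)) 1 else as.vector(t(tdata$weights[genes, , drop = FALSE])),
    stringsAsFactors = FALSE
  )
}

candidate_formula <- function(kind, n_directions = 0L, cov_structure = "diagonal") {
  switch(kind,
    null = y ~ 1 + (1 | gene),
    linear_mixed = if (cov_structure == "full") {
      y ~ dose + (1 + dose | gene)
    } else {
      y ~ dose + (1 | gene) + (0 + dose | gene)
    },
    nonlinear_fixed = ,
    nonlinear_mixed = {
      fe <- paste(paste0("Z", seq_len(n_directions)), collapse = " + ")
      re <- if (kind != "nonlinear_mixed") "" else if (cov_structure == "full") {
        NULL  # placeholder, handled below
      } else {
        paste0(" + (0 + ", fe, " || gene)")
      }
      if (kind == "nonlinear_mixed" && cov_structure == "full") {
        stats::as.formula(paste0("y ~ ", fe, " + (1 + ", fe, " | gene)"))
      } else {
        stats::as.formula(paste0("y ~ ", fe, " + (1 | gene)", re))
      }
    },
    stop("unknown model kind: ", kind))
}

#' Fit one candidate dose-response model for a gene set
#'
#' All candidates share the structure `Y_ij = beta0 + b0j + f_j(D_i) + e_ij`
#' with a gene-specific random intercept `b0j`:
#' `null` has no dose term; `linear_mixed` has a shared slope plus a
#' gene-specific random slope; `nonlinear_fixed` has a shared cubic-spline
#' trend; `nonlinear_mixed` adds gene-specific random deviations in each
#' spline coefficient (diagonal covariance). All fits use maximum likelihood
#' (not REML) so that AIC and likelihood-ratio tests are comparable across
#' fixed-effect structures; precision weights are applied when present.
#'
#' @param tdata A `transformed_dataset`.
#' @param set A `gene_set` with at least 2 matched genes.
#' @param kind One of `"null"`, `"linear_mixed"`, `"nonlinear_fixed"`,
#'   `"nonlinear_mixed"`.
#' @param basis A `spline_basis` (required for the nonlinear kinds).
#' @param cov_structure Random-effects covariance: `"diagonal"` (independent
#'   intercept and dose coefficients; the stable default at small gene
#'   counts) or `"full"` (unstructured).
#' @return A `candidate_model`: `kind`, `fit` (the `lmerMod`), `beta0`,
#'   `fixed_dose_params` (zero for spline columns dropped as redundant),
#'   `ranef` (per-gene empirical-Bayes random effects), `sigma_resid`,
#'   `log_likelihood`, `aic`, `n_params`, `converged`, `singular`, `basis`,
#'   `messages`. On total fitting failure, a candidate with
#'   `available = FALSE`.
#' @export
fit_candidate <- function(tdata, set, kind = c("null", "linear_mixed",
                                               "nonlinear_fixed", "nonlinear_mixed"),
                          basis = NULL,
                          cov_structure = c("diagonal", "full")) {
  cov_structure <- match.arg(cov_structure)
  kind <- match.arg(kind)
  if (kind %in% c("nonlinear_fixed", "nonlinear_mixed") && is.null(basis)) {
    stop("spline basis required for ", kind)
  }
  df <- stack_set_data(tdata, set)
  V <- NULL
  if (kind %in% c("nonlinear_fixed", "nonlinear_mixed")) {
    V <- spline_directions(basis, df$dose)
    Z <- eval_spline_basis(basis, df$dose) %*% V
    colnames(Z) <- paste0("Z", seq_len(ncol(V)))
    df <- cbind(df, Z)
  }
  form <- candidate_formula(kind, n_directions = if (is.null(V)) 0L else ncol(V),
                            cov_structure = cov_structure)
  msgs <- character()
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- tryCatch(
    withCallingHandlers(
      lme4::lmer(form, data = df, weights = w, REML = FALSE, control = ctrl),
      message = function(m) { msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage") },
      warning = function(w) { msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning") }
    ),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(kind = kind, available = FALSE,
                          messages = conditionMessage(fit), basis = basis),
                     class = "candidate_model"))
  }
  converged <- !any(grepl("failed to converge", msgs, fixed = TRUE))
  ll <- logLik(fit)
  fe <- lme4::fixef(fit)
  beta0 <- unname(fe["(Intercept)"])
  dose_par <- switch(kind,
    null = numeric(0),
    linear_mixed = unname(fe["dose"]),
    {
      nm <- paste0("Z", seq_len(ncol(V)))
      out <- setNames(numeric(length(nm)), nm)
      got <- intersect(nm, names(fe))
      out[got] <- fe[got]
      out
    })
  re_list <- lme4::ranef(fit)
  re <- do.call(cbind, unname(re_list[names(re_list) == "gene"]))
  re <- re[levels(df$gene), , drop = FALSE]
  ud <- sort(unique(df$dose))
  spline_coef <- NULL
  if (!is.null(V)) {
    # The likelihood identifies the curve only at the observed dose levels;
    # report the smoothest equal-likelihood representative (see
    # smooth_spline_coef) to avoid spurious oscillation between doses.
    v_hat <- beta0 + as.vector(eval_spline_basis(basis, ud) %*% V %*% dose_par)
    spline_coef <- as.vector(smooth_spline_coef(basis, ud, v_hat))
  }
  structure(list(
    kind = kind, available = TRUE, fit = fit,
    beta0 = beta0, fixed_dose_params = dose_par,
    ranef = re, sigma_resid = sigma(fit),
    log_likelihood = as.numeric(ll), aic = AIC(fit),
    n_params = attr(ll, "df"),
    converged = converged, singular = lme4::isSingular(fit),
    basis = basis, spline_V = V, spline_coef = spline_coef,
    dose_levels = ud, n_genes = nlevels(df$gene),
    data_fingerprint = data_fingerprint(df),
    messages = msgs), class = "candidate_model")
}

data_fingerprint <- function(df) {
  c(n = nrow(df), sum_y = sum(df$y), sum_d = sum(df$dose))
}

#' @export
print.candidate_model <- function(x, ...) {
  if (!isTRUE(x$available)) {
    cat("<candidate_model> ", x$kind, " (unavailable)\n", sep = "")
    return(invisible(x))
  }
  cat("<candidate_model> ", x$kind, ": logLik ", signif(x$log_likelihood, 6),
      ", AIC ", signif(x$aic, 6), ", params ", x$n_params,
      if (!x$converged) " [non-converged]" else "", "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio test of a candidate against the null model
#'
#' The statistic `2 * (logLik(candidate) - logLik(null))` is clipped at zero.
#' For candidates that add variance components (the mixed candidates) it is
#' referred to a chi-squared distribution with degrees of freedom equal to
#' the difference in parameter count; because added variances sit on the
#' boundary of their parameter space this reference is conservative. For
#' `nonlinear_fixed`, which adds only fixed-effect spline coefficients, the
#' statistic is referred to its exact finite-sample distribution for
#' Gaussian fixed-effect additions: the monotone F transformation
#' `F = (exp(stat/n) - 1) * df2 / q` with `q` added coefficients and
#' residual degrees of freedom `df2` counting the gene baselines — the plain
#' chi-squared reference is anti-conservative at these sample sizes.
#'
#' @param candidate,null `candidate_model` objects fitted by ML on the same
#'   data.
#' @return The p-value.
#' @export
lrt_against_null <- function(candidate, null) {
  if (!isTRUE(candidate$available) || !isTRUE(null$available)) {
    return(NA_real_)
  }
  if (!isTRUE(all.equal(candidate$data_fingerprint, null$data_fingerprint))) {
    stop("candidate and null models were fitted on different data")
  }
  stat <- max(0, 2 * (candidate$log_likelihood - null$log_likelihood))
  df <- candidate$n_params - null$n_params
  if (df <= 0) return(1)
  if (identical(candidate$kind, "nonlinear_fixed")) {
    n <- unname(candidate$data_fingerprint["n"])
    # mean-structure params of the larger model: intercept + spline
    # coefficients + one baseline per gene (the random intercepts)
    p1 <- df + 1L + candidate$n_genes
    df2 <- n - p1
    if (df2 > 0) {
      f_stat <- (exp(stat / n) - 1) * df2 / df
      return(pf(f_stat, df1 = df, df2 = df2, lower.tail = FALSE))
    }
  }
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' Select the best candidate model
#'
#' Among converged non-null candidates whose LRT p-value against the null is
#' below `alpha`, returns the one with the lowest AIC; ties go to the model
#' with fewer parameters. If none passes, the null model is selected (the
#' pathway shows no significant dose response).
#'
#' @param candidates Named list of `candidate_model`s including `"null"`.
#' @param alpha Significance gate for the LRT (default 0.05).
#' @return A list: `best_kind`, `best`, `lrt_p` (per candidate), `trace`
#'   (decision data.frame).
#' @export
select_best <- function(candidates, alpha = 0.05) {
  stopifnot("null" %in% names(candidates))
  null <- candidates[["null"]]
  if (!isTRUE(null$available)) stop("null model unavailable; pathway cannot be assessed")
  others <- candidates[setdiff(names(candidates), "null")]
  p <- vapply(others, lrt_against_null, numeric(1), null = null)
  ok <- vapply(others, function(m) isTRUE(m$available) && isTRUE(m$converged), logical(1))
  trace <- data.frame(
    kind = names(others),
    available = vapply(others, function(m) isTRUE(m$available), logical(1)),
    converged = ok,
    aic = vapply(others, function(m) if (isTRUE(m$available)) m$aic else NA_real_, numeric(1)),
    n_params = vapply(others, function(m) if (isTRUE(m$available)) as.numeric(m$n_params) else NA_real_, numeric(1)),
    lrt_p = p, row.names = NULL, stringsAsFactors = FALSE)
  pass <- which(ok & !is.na(p) & p < alpha)
  if (!length(pass)) {
    return(list(best_kind = "null", best = null, lrt_p = p, trace = trace))
  }
  sub <- trace[pass, ]
  sub <- sub[order(sub$aic, sub$n_params), ]
  best_kind <- sub$kind[1L]
  list(best_kind = best_kind, best = candidates[[best_kind]], lrt_p = p, trace = trace)
}

#' Benjamini-Hochberg adjustment of pathway p-values
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted p-values (monotone, each at least the raw p).
#' @export
adjust_pvalues <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

# Full spline coefficient vector on the partition-of-unity basis. Fitted
# candidates carry the cached smoothest equal-likelihood representative
# (spline_coef). Candidates assembled directly with per-basis coefficients
# (spline_V = NULL, e.g. analytic test curves) use beta0 +
# fixed_dose_params on columns 2..n_basis.
full_spline_coef <- function(candidate) {
  if (!is.null(candidate$spline_coef)) return(candidate$spline_coef)
  if (is.null(candidate$spline_V)) {
    return(c(candidate$beta0, candidate$beta0 + unname(candidate$fixed_dose_params)))
  }
  candidate$beta0 +
    as.vector(candidate$spline_V %*% unname(candidate$fixed_dose_params))
}

#' Evaluate the fixed-effect pathway curve of a fitted candidate
#'
#' @param candidate A `candidate_model`.
#' @param x Modeling-scale doses.
#' @param deriv Derivative order (0, 1 or 2); analytic for spline models.
#' @return Numeric vector of curve (or derivative) values.
#' @export
pathway_curve_values <- function(candidate, x, deriv = 0L) {
  switch(candidate$kind,
    null = if (deriv == 0L) rep(candidate$beta0, length(x)) else rep(0, length(x)),
    linear_mixed = switch(as.character(deriv),
      "0" = candidate$beta0 + candidate$fixed_dose_params * x,
      "1" = rep(unname(candidate$fixed_dose_params), length(x)),
      rep(0, length(x))),
    {
      B <- eval_spline_basis(candidate$basis, x, deriv = deriv)
      as.vector(B %*% full_spline_coef(candidate))
    })
}

# Per-gene curve: fixed part plus the gene's empirical-Bayes random effects.
gene_curve_values <- function(candidate, gene, x) {
  base <- pathway_curve_values(candidate, x)
  re <- candidate$ranef
  if (is.null(re) || !(gene %in% rownames(re))) return(base)
  v <- base
  if ("(Intercept)" %in% colnames(re)) v <- v + re[gene, "(Intercept)"]
  if (candidate$kind == "linear_mixed" && "dose" %in% colnames(re)) {
    v <- v + re[gene, "dose"] * x
  }
  if (candidate$kind == "nonlinear_mixed" && !is.null(candidate$spline_V)) {
    nm <- grep("^Z[0-9]+$", colnames(re), value = TRUE)
    if (length(nm)) {
      idx <- as.integer(sub("^Z", "", nm))
      ud <- candidate$dose_levels
      dev_u <- as.vector(eval_spline_basis(candidate$basis, ud) %*%
                           candidate$spline_V[, idx, drop = FALSE] %*%
                           as.numeric(re[gene, nm]))
      cf <- smooth_spline_coef(candidate$basis, ud, dev_u)
      v <- v + as.vector(eval_spline_basis(candidate$basis, x) %*% cf)
    }
  }
  v
}

#' Predicted pathway and gene dose-response curves
#'
#' The pathway curve is the fixed-effect part of the selected model on a
#' dense uniform grid over the modeling dose range; gene curves add each
#' gene's empirical-Bayes random effects. RMSE is computed between observed
#' values and the model's fitted values (including random effects) at the
#' observed doses.
#'
#' @param candidate The selected `candidate_model`.
#' @param tdata The `transformed_dataset` it was fitted on.
#' @param set The `gene_set`.
#' @param grid_size Number of grid points (at least 100).
#' @return A list: `pathway_curve` (a `pathway_curve` object with `dose` and
#'   `response`), `gene_curves` (genes x grid matrix), `rmse`.
#' @export
predict_curves <- function(candidate, tdata, set, grid_size = 200L) {
  stopifnot(grid_size >= 100L)
  grid <- seq(min(tdata$doses), max(tdata$doses), length.out = grid_size)
  resp <- pathway_curve_values(candidate, grid)
  pc <- structure(list(dose = grid, response = resp, kind = candidate$kind,
                       candidate = candidate, dose_scale = tdata$dose_scale),
                  class = "pathway_curve")
  genes <- rownames(candidate$ranef) %||% match_set_features(tdata, set)
  gc <- t(vapply(genes, function(g) gene_curve_values(candidate, g, grid),
                 numeric(length(grid))))
  obs <- stack_set_data(tdata, set)
  fitv <- fitted(candidate$fit)
  rmse <- sqrt(mean((obs$y - fitv)^2))
  list(pathway_curve = pc, gene_curves = gc, rmse = rmse)
}

#' Fit all candidate models for one gene set and select the best
#'
#' Fits the null and linear mixed models always, and the spline models when
#' the data have at least 4 distinct dose levels (otherwise they are skipped
#' with a recorded reason), then applies [select_best()] and
#' [predict_curves()].
#'
#' @param tdata A `transformed_dataset`.
#' @param set A `gene_set`.
#' @param alpha LRT significance gate.
#' @param degree Spline degree.
#' @param manual_knots Optional interior knots for the spline basis.
#' @param grid_size Curve grid size.
#' @return A `fitted_pathway_model`: `geneset`, `candidates`, `best_kind`,
#'   `best`, `significant`, `lrt_p` (p-value reported for the pathway),
#'   `pathway_curve`, `gene_curves`, `rmse`, `y0`, `sigma_resid`,
#'   `spline_skipped` (reason or `NA`), `selection` trace.
#' @export
fit_pathway <- function(tdata, set, alpha = 0.05, degree = 3L,
                        manual_knots = NULL, grid_size = 200L) {
  candidates <- list(null = fit_candidate(tdata, set, "null"))
  candidates$linear_mixed <- fit_candidate(tdata, set, "linear_mixed")
  spline_skipped <- NA_character_
  n_levels <- length(unique(unname(tdata$doses)))
  if (n_levels >= 4L || !is.null(manual_knots)) {
    basis <- build_spline_basis(unname(tdata$doses), degree = degree,
                                manual_knots = manual_knots)
    candidates$nonlinear_fixed <- fit_candidate(tdata, set, "nonlinear_fixed", basis)
    candidates$nonlinear_mixed <- fit_candidate(tdata, set, "nonlinear_mixed", basis)
  } else {
    spline_skipped <- sprintf("only %d distinct dose levels (4 needed for cubic splines)",
                              n_levels)
  }
  sel <- select_best(candidates, alpha = alpha)
  significant <- sel$best_kind != "null"
  # pathway p-value: LRT p of the selected model; if nothing passed the gate,
  # the p of the minimum-AIC converged candidate (descriptive)
  p_report <- if (significant) {
    sel$lrt_p[[sel$best_kind]]
  } else {
    tr <- sel$trace[sel$trace$converged & !is.na(sel$trace$lrt_p), ]
    if (nrow(tr)) tr$lrt_p[which.min(tr$aic)] else NA_real_
  }
  curves <- predict_curves(sel$best, tdata, set, grid_size = grid_size)
  structure(list(
    geneset = set, candidates = candidates,
    best_kind = sel$best_kind, best = sel$best,
    significant = significant, lrt_p = p_report, all_lrt_p = sel$lrt_p,
    pathway_curve = curves$pathway_curve, gene_curves = curves$gene_curves,
    rmse = curves$rmse,
    y0 = curves$pathway_curve$response[1L],
    sigma_resid = sel$best$sigma_resid,
    spline_skipped = spline_skipped, selection = sel$trace,
    dose_scale = tdata$dose_scale, pseudo_dose = tdata$pseudo_dose,
    alpha = alpha), class = "fitted_pathway_model")
}

#' @export
print.fitted_pathway_model <- function(x, ...) {
  cat("<fitted_pathway_model> ", x$geneset$name, "\n", sep = "")
  cat("  best model: ", x$best_kind,
      if (x$significant) sprintf(" (LRT p = %.3g)", x$lrt_p) else " (not significant)",
      "\n", sep = "")
  cat("  RMSE: ", signif(x$rmse, 4), "\n", sep = "")
  invisible(x)
}
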