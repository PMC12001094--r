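#' Construct a dense pathway curve from a fitted candidate model
#'
#' Convenience constructor evaluating a candidate's fixed-effect curve on a
#' uniform grid; used by the threshold routines and useful for plotting or
#' for analyzing analytically constructed spline curves.
#'
#' @param candidate A `candidate_model` (fitted, or assembled with known
#'   coefficients and a `spline_basis`).
#' @param lower,upper Dose range (modeling scale); defaults to the basis
#'   boundary when available.
#' @param grid_size Number of grid points (at least 100).
#' @return A `pathway_curve` with `dose`, `response`, `kind`, `candidate`.
#' @export
curve_grid <- function(candidate, lower = NULL, upper = NULL, grid_size = 200L) {
  stopifnot(grid_size >= 100L)
  if (is.null(lower) || is.null(upper)) {
    if (is.null(candidate$basis)) stop("dose range required for models without a spline basis")
    lower <- candidate$basis$boundary[1L]
    upper <- candidate$basis$boundary[2L]
  }
  grid <- seq(lower, upper, length.out = grid_size)
  structure(list(dose = grid, response = pathway_curve_values(candidate, grid),
                 kind = candidate$kind, candidate = candidate),
            class = "pathway_curve")
}

#' Benchmark dose from a fitted pathway curve
#'
#' Scans the curve from the lowest dose upward and returns the first dose at
#' which the response leaves the band `y0 +/- z * sd`, locating the crossing
#' by linear interpolation between grid points. The first-crossing rule
#' covers biphasic curves (the lowest dose reaching the benchmark response
#' is reported even if the curve later returns into the band). `y0` is the
#' modeled control level (the curve at the lowest dose) and `sd` the
#' residual standard deviation of the selected model; `z` is the benchmark
#' response multiplier (default 1).
#'
#' @param curve A `pathway_curve` (sorted, dense grid).
#' @param y0 Control-level response.
#' @param sd Residual standard deviation of the fit (> 0).
#' @param z Band width in residual standard deviations.
#' @return A `threshold_estimate` (`kind = "BMD"`, `dose`, `direction`, `z`)
#'   or `NULL` when the band is never exited.
#' @export
compute_bmd <- function(curve, y0, sd, z = 1) {
  d <- curve$dose; r <- curve$response
  if (is.unsorted(d)) stop("curve grid must be sorted by dose")
  stopifnot(sd > 0, z > 0)
  dev <- r - y0
  out <- which(abs(dev) >= z * sd)
  if (!length(out)) return(NULL)
  i <- out[1L]
  direction <- if (dev[i] >= 0) "up" else "down"
  if (i == 1L) {
    dose <- d[1L]
  } else {
    # linear interpolation on the segment [i-1, i] to |dev| = z*sd
    target <- if (direction == "up") z * sd else -z * sd
    frac <- (target - dev[i - 1L]) / (dev[i] - dev[i - 1L])
    dose <- d[i - 1L] + frac * (d[i] - d[i - 1L])
  }
  structure(list(kind = "BMD", dose = dose, direction = direction, z = z,
                 y0 = y0, sd = sd, ci_low = NA_real_, ci_high = NA_real_),
            class = "threshold_estimate")
}

#' Trend-change doses of a fitted pathway curve
#'
#' Locates maxima and minima (sign changes of the first derivative) and
#' inflection points (sign changes of the second derivative) of the
#' fixed-effect curve. For spline models the derivatives are evaluated
#' analytically from the spline coefficients; a linear (or null) best model
#' has constant first derivative and zero second derivative, so its TCD list
#' is empty. Boundary doses are excluded; results are sorted ascending, the
#' first element being TCD1.
#'
#' @param curve A `pathway_curve` carrying its `candidate_model`.
#' @return A list of `threshold_estimate`s (`kind = "TCD"`, `tcd_type` one of
#'   `"maximum"`, `"minimum"`, `"inflection"`), sorted by dose; may be empty.
#' @export
compute_tcds <- function(curve) {
  d <- curve$dose
  if (is.unsorted(d)) stop("curve grid must be sorted by dose")
  if (length(d) < 100L) stop("TCD detection needs a grid of at least 100 points")
  cand <- curve$candidate
  if (is.null(cand) || cand$kind %in% c("null", "linear_mixed")) return(list())
  d1 <- pathway_curve_values(cand, d, deriv = 1L)
  d2 <- pathway_curve_values(cand, d, deriv = 2L)
  extrema <- sign_change_roots(d, d1)
  inflections <- sign_change_roots(d, d2)
  tcds <- c(
    lapply(seq_along(extrema$root), function(i) {
      structure(list(kind = "TCD",
                     tcd_type = if (extrema$falling[i]) "maximum" else "minimum",
                     dose = extrema$root[i], ci_low = NA_real_, ci_high = NA_real_),
                class = "threshold_estimate")
    }),
    lapply(seq_along(inflections$root), function(i) {
      structure(list(kind = "TCD", tcd_type = "inflection",
                     dose = inflections$root[i], ci_low = NA_real_, ci_high = NA_real_),
                class = "threshold_estimate")
    }))
  if (!length(tcds)) return(list())
  tcds[order(vapply(tcds, `[[`, numeric(1), "dose"))]
}

# Roots of f on grid d from strict sign changes, by linear interpolation;
# boundary grid points are never reported as roots.
sign_change_roots <- function(d, f) {
  s <- sign(f)
  idx <- which(s[-length(s)] * s[-1L] < 0)
  root <- d[idx] - f[idx] * (d[idx + 1L] - d[idx]) / (f[idx + 1L] - f[idx])
  keep <- root > d[1L] & root < d[length(d)]
  list(root = root[keep], falling = (f[idx] > 0)[keep])
}

#' @export
print.threshold_estimate <- function(x, ...) {
  lab <- if (x$kind == "BMD") "BMD" else paste0("TCD (", x$tcd_type, ")")
  ci <- if (!is.na(x$ci_low)) sprintf(" [%.4g, %.4g]", x$ci_low, x$ci_high) else ""
  cat("<threshold_estimate> ", lab, ": ", signif(x$dose, 4), ci, "\n", sep = "")
  invisible(x)
}

# Subset a transformed dataset to a set of sample indices (dose order kept).
subset_samples <- function(tdata, idx) {
  out <- tdata
  out$values <- tdata$values[, idx, drop = FALSE]
  if (!is.null(tdata$weights)) out$weights <- tdata$weights[, idx, drop = FALSE]
  out$doses <- tdata$doses[idx]
  out$natural_doses <- tdata$natural_doses[idx]
  out
}

# Dose-stratified subsample without replacement: ceil(fraction * n) samples
# in total, at least one per dose level, the remainder apportioned by
# largest remainder with random tie-breaking from the active RNG stream.
stratified_subsample <- function(doses, fraction) {
  n <- length(doses)
  m <- ceiling(fraction * n)
  levels_ <- split(seq_len(n), doses)
  m <- max(m, length(levels_))
  quota <- vapply(levels_, length, integer(1)) * m / n
  take <- pmax(1L, floor(quota))
  rem <- m - sum(take)
  if (rem > 0) {
    frac <- quota - floor(quota)
    room <- vapply(levels_, length, integer(1)) - take
    ord <- order(-frac, runif(length(quota)))
    for (j in ord) {
      if (rem == 0) break
      add <- min(room[j], rem)
      if (add > 0) { take[j] <- take[j] + add; rem <- rem - add }
    }
  }
  idx <- unlist(lapply(seq_along(levels_), function(j) {
    pool <- levels_[[j]]
    if (length(pool) == take[j]) pool else sort(sample(pool, take[j]))
  }), use.names = FALSE)
  sort(idx)
}

#' Bootstrap confidence intervals for pathway BMD and TCDs
#'
#' Each replicate draws a dose-stratified subsample of the samples without
#' replacement (default 60% of samples, at least one per dose level), refits
#' the originally selected model kind, and recomputes the BMD and TCDs. The
#' 95% confidence interval is the 2.5/97.5 percentile range of the replicate
#' estimates. Replicate TCDs are matched to the original TCDs by type and
#' nearest dose. Replicates where a threshold is undefined are dropped and
#' counted; when more than half of the replicates fail for a threshold its
#' CI is reported as unavailable. Fully reproducible given `seed`.
#'
#' @param fit A `fitted_pathway_model`.
#' @param tdata The `transformed_dataset` it was fitted on.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param fraction Subsample fraction (default 0.6).
#' @param seed Integer seed.
#' @param z Benchmark response multiplier passed to [compute_bmd()].
#' @param grid_size Curve grid size.
#' @return A list: `bmd` (a `threshold_estimate` with CI, or `NULL`), `tcds`
#'   (list of `threshold_estimate`s with CIs), `n_boot`, `fraction`,
#'   `n_failed_fit`, plus per-threshold defined-replicate counts.
#' @export
bootstrap_thresholds <- function(fit, tdata, n_boot = 1000L, fraction = 0.6,
                                 seed = 1L, z = 1, grid_size = 200L) {
  stopifnot(n_boot >= 1L, fraction > 0, fraction <= 1)
  set <- fit$geneset
  kind <- fit$best_kind
  basis <- fit$best$basis
  bmd0 <- compute_bmd(fit$pathway_curve, y0 = fit$y0, sd = fit$sigma_resid, z = z)
  tcds0 <- compute_tcds(fit$pathway_curve)
  grid_range <- range(fit$pathway_curve$dose)
  set.seed(as.integer(seed))
  bmd_rep <- rep(NA_real_, n_boot)
  tcd_rep <- matrix(NA_real_, nrow = n_boot, ncol = length(tcds0))
  n_failed_fit <- 0L
  for (b in seq_len(n_boot)) {
    idx <- stratified_subsample(unname(tdata$doses), fraction)
    sub <- subset_samples(tdata, idx)
    cand <- tryCatch(fit_candidate(sub, set, kind, basis = basis),
                     error = function(e) NULL)
    if (is.null(cand) || !isTRUE(cand$available)) {
      n_failed_fit <- n_failed_fit + 1L
      next
    }
    cv <- curve_grid(cand, grid_range[1L], grid_range[2L], grid_size = grid_size)
    b_bmd <- compute_bmd(cv, y0 = cv$response[1L], sd = cand$sigma_resid, z = z)
    if (!is.null(b_bmd)) bmd_rep[b] <- b_bmd$dose
    if (length(tcds0)) {
      b_tcds <- compute_tcds(cv)
      for (k in seq_along(tcds0)) {
        same <- Filter(function(t) t$tcd_type == tcds0[[k]]$tcd_type, b_tcds)
        if (length(same)) {
          dd <- vapply(same, `[[`, numeric(1), "dose")
          tcd_rep[b, k] <- dd[which.min(abs(dd - tcds0[[k]]$dose))]
        }
      }
    }
  }
  attach_ci <- function(est, reps) {
    if (is.null(est)) return(NULL)
    ok <- reps[!is.na(reps)]
    est$n_boot <- n_boot; est$boot_fraction <- fraction
    est$n_defined <- length(ok)
    if (length(ok) >= n_boot / 2) {
      q <- quantile(ok, c(0.025, 0.975), names = FALSE, type = 7)
      est$ci_low <- q[1L]; est$ci_high <- q[2L]
    } else {
      est$ci_low <- NA_real_; est$ci_high <- NA_real_
      est$ci_unavailable <- TRUE
    }
    est
  }
  list(bmd = attach_ci(bmd0, bmd_rep),
       tcds = lapply(seq_along(tcds0), function(k) attach_ci(tcds0[[k]], tcd_rep[, k])),
       n_boot = n_boot, fraction = fraction, n_failed_fit = n_failed_fit)
}

#' Back-transform a modeling-scale dose to natural units
#'
#' @param x Modeling-scale dose(s).
#' @param dose_scale `"natural"` or `"log10"`.
#' @return Dose(s) in original units.
#' @export
back_transform_dose <- function(x, dose_scale) {
  if (identical(dose_scale, "log10")) 10^x else x
}

#' Cumulative distributions of pathway BMDs and first trend-change doses
#'
#' @param results A results data.frame (see [run_pipeline()]) with columns
#'   `significant`, `bmd` and `tcd1` in natural dose units.
#' @return A list with components `bmd` and `tcd1`, each holding the sorted
#'   `values`, the empirical CDF function `cdf`, and the `median`; empty
#'   components when no significant pathway defines the threshold.
#' @export
summarize_thresholds <- function(results) {
  sig <- results[results$significant %in% TRUE, , drop = FALSE]
  one <- function(v) {
    v <- sort(v[!is.na(v)])
    if (!length(v)) return(list(values = numeric(0), cdf = NULL, median = NA_real_))
    list(values = v, cdf = ecdf(v), median = median(v))
  }
  list(bmd = one(sig$bmd), tcd1 = one(sig$tcd1))
}
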