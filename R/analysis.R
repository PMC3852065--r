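#' Sum of squared log residuals between simulated and observed series
#'
#' `SS_log = sum over points of [ln(simulated / observed)]^2`, the
#' goodness-of-fit statistic used to rank virtual samples against observed
#' cumulative accumulation time-profiles.  Zero if and only if simulated
#' equals observed at every scored point.  Simulated amounts are floored at
#' `floor_sim` before taking the ratio (a cumulative amount can be exactly
#' zero early on while the observation is positive); floored points are
#' counted in the `n_floored` attribute.
#'
#' @param simulated,observed numeric vectors or matrices of matched shape;
#'   `observed` must be strictly positive.
#' @param floor_sim lower floor applied to simulated amounts (default
#'   1e-12).
#' @return scalar SS_log with attribute `n_floored`.
#' @export
ss_log <- function(simulated, observed, floor_sim = 1e-12) {
  if (length(simulated) != length(observed))
    stop("simulated and observed series have different lengths (",
         length(simulated), " vs ", length(observed), ")")
  observed <- as.numeric(observed); simulated <- as.numeric(simulated)
  if (any(!is.finite(observed) | observed <= 0))
    stop("observed amounts must be finite and strictly positive")
  floored <- simulated < floor_sim
  r <- log(pmax(simulated, floor_sim) / observed)
  structure(sum(r^2), n_floored = sum(floored))
}

#' Score every sample of a fitted cluster against observed time-profiles
#'
#' Re-simulates each virtual sample of a cluster and evaluates [ss_log()]
#' on the total-radioactivity accumulation series of each output route
#' (urine, feces and -- for BDC -- the biliary T-tube), summed over routes.
#' Per-compound scoring is available as an option.
#'
#' @param cluster a `cnm_cluster` of PBPK parameter sets.
#' @param observed named list with elements `times` (min) and per-route
#'   observed total amounts `urine`, `feces` and optionally `ttube`
#'   (vectors over `times`, strictly positive).
#' @param settings a [pbpk_settings()].
#' @param per_compound score per-compound series instead of route totals.
#' @return data frame with columns `sample_id`, `ss_log`, `rank` (1 =
#'   best), `failed`.
#' @export
score_cluster <- function(cluster, observed, settings, per_compound = FALSE) {
  stopifnot(is.list(observed), !is.null(observed$times))
  routes <- intersect(c("urine", "feces", "ttube"), names(observed))
  if (length(routes) == 0L) stop("no observed routes supplied")
  P <- cluster_params(cluster)
  scores <- rep(NA_real_, nrow(P))
  for (j in seq_len(nrow(P))) {
    prof <- tryCatch(
      suppressWarnings(simulate_pbpk(P[j, ], settings, times = observed$times)),
      error = function(e) NULL)
    if (is.null(prof)) next
    s <- 0
    for (rt in routes) {
      sim <- if (per_compound) prof[[rt]] else prof[[paste0(rt, "_total")]]
      s <- s + as.numeric(ss_log(sim, observed[[rt]]))
    }
    scores[j] <- s
  }
  df <- data.frame(sample_id = rownames(P), ss_log = scores,
                   failed = !is.finite(scores), stringsAsFactors = FALSE)
  df$rank <- rank(df$ss_log, ties.method = "first", na.last = "keep")
  df
}

#' Select the k best-fitting samples
#'
#' @param scores data frame with columns `sample_id` and `ss_log` (as from
#'   [score_cluster()]).
#' @param k number of samples to keep (e.g. 3 or 10 for profile plots).
#' @return character vector of the `k` sample ids with smallest `ss_log`;
#'   ties broken deterministically by sample id.
#' @export
select_best <- function(scores, k) {
  stopifnot(is.data.frame(scores), all(c("sample_id", "ss_log") %in% names(scores)))
  ok <- scores[is.finite(scores$ss_log), , drop = FALSE]
  if (k > nrow(ok))
    stop("k = ", k, " exceeds the number of scored samples (", nrow(ok), ")")
  ok <- ok[order(ok$ss_log, ok$sample_id), , drop = FALSE]
  ok$sample_id[seq_len(k)]
}

#' Geometric summary of a cluster
#'
#' Per-parameter geometric mean `exp(mean(ln p))` and geometric SD
#' `exp(sd(ln p))`, the natural location/spread pair for log-sampled
#' parameters: "geometric mean -- geometric SD" is read multiplicatively,
#' i.e. a 1-SD band is `gm / gsd` to `gm * gsd`.  The plain mean and SD of
#' the ln-values are reported alongside.
#'
#' @param cluster a `cnm_cluster` (or plain ln-scale matrix).
#' @return data frame with columns `name`, `geo_mean`, `geo_sd`, `ln_mean`,
#'   `ln_sd`.
#' @export
geometric_summary <- function(cluster) {
  X <- unclass(cluster)
  stopifnot(nrow(X) >= 1)
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  if (nrow(X) == 1L) sd_ <- rep(0, ncol(X))
  data.frame(name = colnames(X), geo_mean = exp(mu), geo_sd = exp(sd_),
             ln_mean = mu, ln_sd = sd_, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pairwise correlations of fitted parameters
#'
#' Pearson correlations of the ln-parameters across the cluster, with the
#' screening rule used to pick parameters worth displaying: keep a
#' parameter if it has `r^2` above the threshold (default 0.64, i.e.
#' `|r| > 0.8`) with at least one other parameter.  Signs are reported so
#' inverse-proportional relationships (e.g. a drainage split ratio versus
#' the downstream clearances it starves) are readable.  Parameters with
#' zero variance (fixed, or fully collapsed) have undefined correlations
#' and are excluded from the report rather than imputed.
#'
#' @param cluster a `cnm_cluster`.
#' @param threshold screening threshold on `r^2` (default 0.64).
#' @return An object of class `cnm_correlations`: list with `pairs` (data
#'   frame: `p1`, `p2`, `r`, `r2`, `screened`), `screened` (parameter
#'   names passing the rule), `dropped` (zero-variance parameters),
#'   `threshold`.
#' @export
parameter_correlations <- function(cluster, threshold = 0.64) {
  X <- unclass(cluster)
  if (nrow(X) < 3L) stop("need at least 3 samples for correlations")
  v <- apply(X, 2L, stats::var)
  dropped <- colnames(X)[!is.finite(v) | v == 0]
  keep <- setdiff(colnames(X), dropped)
  Xk <- X[, keep, drop = FALSE]
  R <- stats::cor(Xk)
  idx <- which(upper.tri(R), arr.ind = TRUE)
  pairs <- data.frame(p1 = keep[idx[, 1]], p2 = keep[idx[, 2]],
                      r = R[idx], r2 = R[idx]^2, stringsAsFactors = FALSE)
  pairs$screened <- pairs$r2 > threshold
  screened <- sort(unique(c(pairs$p1[pairs$screened], pairs$p2[pairs$screened])))
  structure(list(pairs = pairs[order(-pairs$r2), , drop = FALSE],
                 screened = screened, dropped = dropped,
                 threshold = threshold),
            class = "cnm_correlations")
}

#' @export
print.cnm_correlations <- function(x, ...) {
  cat("Parameter correlations: ", nrow(x$pairs), " pairs, ",
      sum(x$pairs$screened), " with r^2 > ", x$threshold, "\n", sep = "")
  if (length(x$screened))
    cat("  screened in:", paste(x$screened, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  zero-variance (excluded):", paste(x$dropped, collapse = ", "), "\n")
  print(utils::head(x$pairs[x$pairs$screened, , drop = FALSE], 15),
        row.names = FALSE)
  invisible(x)
}

#' Sweep the diversity parameter dS
#'
#' Runs the full Cluster Newton fit once per requested dS value, with a
#' shared master seed so runs differ only through dS, and reports per run:
#' whether the fit converged (final median absolute log-residual below
#' `converged_tol`), the divergence iteration if the divergence detector
#' fired, final residual quantiles, and the final cluster diversity
#' (median per-free-parameter log-range).  Individual run failures are
#' recorded and the sweep continues.
#'
#' @param model,space,spec as in [run_cnm()].
#' @param base_config a [cnm_config()]; its `dS` entry is overridden.
#' @param ds_values numeric vector of dS values in `[0, 1)`.
#' @param converged_tol threshold on the final median `|log-residual|`
#'   defining the `converged` flag (default 0.1, i.e. about 10% deviation).
#' @param verbose print one line per run.
#' @return data frame, one row per dS: `dS`, `converged`, `diverged`,
#'   `diverged_at`, `median_logres`, `q95_logres`, `diversity`, `error`.
#' @export
ds_sweep <- function(model, space, spec, base_config, ds_values,
                     converged_tol = 0.1, verbose = FALSE) {
  rows <- lapply(ds_values, function(ds) {
    cfg <- base_config
    cfg$dS <- ds
    fit <- tryCatch(
      run_cnm(model, space, spec, cfg, keep_history = FALSE),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(dS = ds, converged = FALSE, diverged = TRUE,
                        diverged_at = NA_integer_, median_logres = NA_real_,
                        q95_logres = NA_real_, diversity = NA_real_,
                        error = conditionMessage(fit),
                        stringsAsFactors = FALSE))
    last <- fit$summary[nrow(fit$summary), ]
    free <- !space$fixed_mask
    Xf <- unclass(fit$final_cluster)[, free, drop = FALSE]
    div <- stats::median(apply(Xf, 2L, function(z) diff(range(z))))
    if (verbose)
      message(sprintf("dS = %.2f  median|logres| %.4g  diversity %.3g%s",
                      ds, last$median, div,
                      if (fit$diagnostics$diverged) "  [diverged]" else ""))
    data.frame(dS = ds, converged = last$median < converged_tol,
               diverged = fit$diagnostics$diverged,
               diverged_at = fit$diagnostics$diverged_at,
               median_logres = last$median, q95_logres = last$q95,
               diversity = div, error = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
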