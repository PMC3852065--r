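#' Evaluate a forward model over a cluster
#'
#' Runs the forward model on every virtual sample (row) of the cluster and
#' collects the objective values.  A sample whose evaluation raises an error
#' or returns non-finite / wrong-length output is flagged as failed rather
#' than dropped, so downstream steps can apply the configured failure
#' policy.  Evaluation is row-independent: the result never depends on the
#' order in which samples are visited.
#'
#' @param model a [forward_model()].
#' @param cluster a `cnm_cluster` (ln-scale parameters).
#' @param max_failure_frac abort (with a diagnostic error) when more than
#'   this fraction of samples fail; default 0.5.
#' @return Numeric matrix `n_samples x n_objectives` with attribute
#'   `failed` (logical per-sample flag).  Failed rows are `NA`.
#' @export
evaluate_cluster <- function(model, cluster, max_failure_frac = 0.5) {
  stopifnot(inherits(model, "forward_model"))
  P <- cluster_params(cluster)
  n <- nrow(P); m <- model$n_objectives
  Y <- matrix(NA_real_, n, m, dimnames = list(rownames(P), model$objective_names))
  failed <- logical(n)
  for (j in seq_len(n)) {
    y <- tryCatch(model$fun(P[j, ]), error = function(e) NULL)
    if (is.null(y) || length(y) != m || any(!is.finite(y))) {
      failed[j] <- TRUE
    } else {
      Y[j, ] <- as.numeric(y)
    }
  }
  if (mean(failed) > max_failure_frac)
    stop(sprintf(
      "forward-model evaluation failed for %d of %d samples (> %.0f%%); %s",
      sum(failed), n, 100 * max_failure_frac,
      "check parameter ranges and model configuration"))
  attr(Y, "failed") <- failed
  Y
}

#' Fit the affine surrogate of the parameter-to-objective map
#'
#' Ordinary least squares of (by default) `ln(objective)` on `ln(parameter)`
#' with intercept, over all successfully evaluated samples.  Fixed
#' parameters carry no information and are excluded from the design; their
#' slope entries are zero.  A rank-deficient design (collinear or constant
#' columns, or fewer samples than free parameters) is handled by the
#' minimum-norm least-squares solution with a warning.
#'
#' @param cluster a `cnm_cluster`.
#' @param objectives objective matrix from [evaluate_cluster()].
#' @param log_objectives fit `ln(objective)` (default) or raw objectives.
#' @return An object of class `cnm_surrogate`: list with `slope`
#'   (`n_objectives x n_params`, zero columns for fixed parameters),
#'   `offset`, `pinv` (Moore--Penrose pseudoinverse of the free-column
#'   slope, computed once and reused by both the Newton update and the dS
#'   replication step), `free` mask, fit diagnostics.
#' @export
fit_affine_surrogate <- function(cluster, objectives, log_objectives = TRUE) {
  X <- unclass(cluster)
  failed <- attr(objectives, "failed")
  if (is.null(failed)) failed <- rep(FALSE, nrow(objectives))
  fixed <- attr(cluster, "fixed_mask")
  if (is.null(fixed)) fixed <- rep(FALSE, ncol(X))
  free <- !fixed
  ok <- !failed & apply(is.finite(objectives), 1L, all)
  if (log_objectives) ok <- ok & apply(objectives > 0, 1L, all)
  if (sum(ok) < sum(free) + 1L)
    warning("fewer evaluated samples (", sum(ok), ") than free parameters + 1 (",
            sum(free) + 1L, "); surrogate is underdetermined")

  Xf <- X[ok, free, drop = FALSE]
  Yf <- objectives[ok, , drop = FALSE]
  if (log_objectives) Yf <- log(Yf)

  D <- cbind(`(intercept)` = 1, Xf)
  sv <- svd(D)
  tol <- max(dim(D)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r < ncol(D))
    warning("rank-deficient surrogate design (rank ", r, " of ", ncol(D),
            "); using minimum-norm least squares")
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  coef <- sv$v %*% (dinv * (t(sv$u) %*% Yf))     # (p_free+1) x m, min-norm LS

  offset <- coef[1L, ]
  slope_free <- t(coef[-1L, , drop = FALSE])     # m x p_free
  slope <- matrix(0, nrow(slope_free), ncol(X),
                  dimnames = list(colnames(objectives), colnames(X)))
  slope[, free] <- slope_free

  fit_res <- Yf - D %*% coef
  structure(list(slope = slope, offset = offset,
                 pinv = MASS::ginv(slope_free), free = free,
                 log_objectives = log_objectives,
                 design_rank = r, n_fit = sum(ok),
                 fit_rms = sqrt(mean(fit_res^2))),
            class = "cnm_surrogate")
}

#' @export
print.cnm_surrogate <- function(x, ...) {
  cat("Affine surrogate: ", nrow(x$slope), " objectives x ", sum(x$free),
      " free parameters (rank ", x$design_rank, ", fit RMS ",
      signif(x$fit_rms, 3), ", n = ", x$n_fit, ")\n", sep = "")
  invisible(x)
}

# Targets on the surrogate's objective scale, one row per sample
# (per-sample perturbed copies of the observations).
surrogate_targets <- function(spec, n, perturb_log = NULL, log_objectives = TRUE) {
  Ylog <- matrix(log(spec$observed), n, length(spec$observed), byrow = TRUE)
  if (!is.null(perturb_log)) Ylog <- Ylog + perturb_log
  if (log_objectives) Ylog else exp(Ylog)
}

# Minimum-norm Newton step toward per-sample targets, applied to every row
# of X (ln-scale).  Shared by newton_update() and ds_replicate(): the same
# pseudoinverse drives both.  `observed` (objectives on the surrogate's
# scale, NA rows allowed) switches the residual from surrogate prediction
# to actually evaluated values wherever those are available.
apply_newton_step <- function(X, surrogate, targets, weights = NULL,
                              observed = NULL) {
  free <- surrogate$free
  # restrict to free columns: fixed parameters have zero slope but may sit
  # at ln(0) = -Inf (parameters fixed at zero), and 0 * Inf is NaN
  pred <- X[, free, drop = FALSE] %*% t(surrogate$slope[, free, drop = FALSE]) +
    matrix(surrogate$offset, nrow(X), length(surrogate$offset), byrow = TRUE)
  resid <- targets - pred
  if (!is.null(observed)) {
    have <- apply(is.finite(observed), 1L, all)
    resid[have, ] <- targets[have, , drop = FALSE] -
      observed[have, , drop = FALSE]
  }
  pinv <- surrogate$pinv
  if (!is.null(weights) && any(weights != 1)) {
    # min-norm solve of the row-weighted system W A dx = W r
    resid <- sweep(resid, 2L, weights, `*`)
    pinv <- MASS::ginv(sweep(surrogate$slope[, free, drop = FALSE],
                             1L, weights, `*`))
  }
  Xn <- X
  Xn[, free] <- X[, free, drop = FALSE] + resid %*% t(pinv)
  Xn
}

#' One Newton update of the whole cluster
#'
#' For every sample `j` a minimum-norm step `dx` toward that sample's
#' (optionally perturbed) copy of the observed targets is applied: the
#' smallest correction, under the iteration's linearisation of the forward
#' map, that closes the gap between where the sample is and where the
#' observations say it should be.  When the sample's own evaluated
#' objectives are supplied the gap is the genuine residual
#' `y*_j - y(x_j)` (the classic cluster-Newton update); otherwise the
#' surrogate's prediction stands in.  On an affine forward model either
#' choice lands every sample exactly on the solution manifold in one step;
#' on a nonlinear model this is one Newton-like iteration against the
#' cluster-wide linearisation.  Fixed parameters are never touched.
#'
#' @param cluster the "before" cluster `X_b`.
#' @param surrogate a `cnm_surrogate` fitted on this iteration's evaluation.
#' @param spec an [objective_spec()].
#' @param targets optional precomputed per-sample target matrix (ln scale if
#'   the surrogate is log-scale); defaults to the unperturbed observations.
#' @param objectives optional objective matrix from [evaluate_cluster()]
#'   (natural scale); rows evaluated successfully drive the step through
#'   their actual residuals.
#' @param failure_policy `"resample"` or `"carry_over"` for samples whose
#'   step is non-finite.
#' @return The "after" cluster `X_a` (same shape, iteration advanced).
#' @export
newton_update <- function(cluster, surrogate, spec, targets = NULL,
                          objectives = NULL,
                          failure_policy = c("resample", "carry_over")) {
  failure_policy <- match.arg(failure_policy)
  X <- unclass(cluster)
  if (is.null(targets))
    targets <- surrogate_targets(spec, nrow(X),
                                 log_objectives = surrogate$log_objectives)
  observed <- NULL
  if (!is.null(objectives)) {
    observed <- unclass(objectives)
    if (surrogate$log_objectives) {
      observed[observed <= 0] <- NA_real_
      observed <- log(observed)
    }
  }
  Xa <- apply_newton_step(X, surrogate, targets, spec$weights, observed)
  bad <- !apply(is.finite(Xa[, surrogate$free, drop = FALSE]), 1L, all)
  if (any(bad)) {
    if (failure_policy == "carry_over") {
      Xa[bad, ] <- X[bad, , drop = FALSE]
    } else {
      good <- which(!bad)
      if (length(good) == 0L) stop("Newton step non-finite for every sample")
      Xa[bad, ] <- Xa[sample(good, sum(bad), replace = TRUE), , drop = FALSE]
    }
  }
  out <- new_cluster(Xa, fixed_mask = attr(cluster, "fixed_mask"),
                     iteration = attr(cluster, "iteration") + 1L)
  attr(out, "step_failed") <- bad
  out
}

#' Diversity-maintaining replication (the dS rule)
#'
#' A full Newton step can overshoot badly on a stiff nonlinear model:
#' samples are thrown far outside the sampled region, their evaluations
#' fail, and within two or three iterations the ensemble degenerates.  The
#' dS rule counteracts this while keeping the ensemble spread.  For each
#' sample the internally dividing point `X_i = (1 - dS) X_b + dS X_a`
#' between its pre- and post-update positions is formed (ratio
#' `dS : (1 - dS)`, so `dS = 0` leaves `X_b`), and the *same* pseudoinverse
#' that produced `X_a` is applied from `X_i` -- by default against freshly
#' evaluated residuals at `X_i` -- to give an alternative solution `X_a'`,
#' a damped re-solve launched from a point that remembers where the sample
#' used to be.  Each sample of the next cluster is then `X_a[j]` or
#' `X_a'[j]` with probability 1/2, independently.
#'
#' Re-evaluation at `X_i` is what gives the rule its effect: if the
#' surrogate's own prediction is used instead (`reevaluate = FALSE`, or
#' rows where the `X_i` evaluation fails), the re-solved point coincides
#' with `X_a` up to rounding, because the linearised update map is affine
#' and idempotent -- see the methods vignette for the two-line proof.
#'
#' With `dS = 0`, `X_i = X_b` and the re-solve reproduces the unmodified
#' update, so `X_a` is returned directly and no random-selection stream is
#' consumed: `dS = 0` runs are identical to runs with replication disabled.
#'
#' @param X_b cluster before the Newton update.
#' @param X_a cluster after the Newton update (same samples, same order).
#' @param surrogate the `cnm_surrogate` used to produce `X_a`.
#' @param spec an [objective_spec()].
#' @param dS diversity parameter in `[0, 1)`.
#' @param targets optional per-sample target matrix, as in [newton_update()].
#' @param model the [forward_model()], required when `reevaluate = TRUE`.
#' @param reevaluate evaluate the model at `X_i` (default when a model is
#'   supplied) or fall back to surrogate predictions.
#' @param toward_before orientation of the ratio: `TRUE` (default) puts
#'   `X_i` a fraction `dS` of the way from `X_b` toward `X_a`.
#' @return The next iteration's cluster.
#' @export
ds_replicate <- function(X_b, X_a, surrogate, spec, dS, targets = NULL,
                         model = NULL, reevaluate = !is.null(model),
                         toward_before = TRUE) {
  if (dS < 0 || dS >= 1) stop("dS must lie in [0, 1); got ", dS)
  stopifnot(identical(rownames(X_b), rownames(X_a)))
  if (reevaluate && is.null(model))
    stop("reevaluate = TRUE needs the forward model")
  Xb <- unclass(X_b); Xa <- unclass(X_a)
  if (is.null(targets))
    targets <- surrogate_targets(spec, nrow(Xb),
                                 log_objectives = surrogate$log_objectives)
  w <- if (toward_before) dS else 1 - dS
  if (w == 0) {
    out <- new_cluster(Xa, fixed_mask = attr(X_b, "fixed_mask"),
                       iteration = attr(X_a, "iteration"))
    attr(out, "step_failed") <- attr(X_a, "step_failed")
    return(out)
  }
  Xi <- (1 - w) * Xb + w * Xa
  Xi[, !surrogate$free] <- Xb[, !surrogate$free]  # fixed entries untouched
  observed <- NULL
  if (reevaluate) {
    Yi <- evaluate_cluster(
      model, new_cluster(Xi, attr(X_b, "fixed_mask")), max_failure_frac = 1)
    observed <- unclass(Yi)
    if (surrogate$log_objectives) {
      observed[observed <= 0] <- NA_real_
      observed <- log(observed)
    }
  }
  Xap <- apply_newton_step(Xi, surrogate, targets, spec$weights, observed)
  bad <- !apply(is.finite(Xap[, surrogate$free, drop = FALSE]), 1L, all)
  Xap[bad, ] <- Xa[bad, , drop = FALSE]
  take_a <- stats::runif(nrow(Xa)) < 0.5
  sel <- Xap
  sel[take_a, ] <- Xa[take_a, , drop = FALSE]
  out <- new_cluster(sel, fixed_mask = attr(X_b, "fixed_mask"),
                     iteration = attr(X_a, "iteration"))
  attr(out, "step_failed") <- attr(X_a, "step_failed")
  out
}

residual_summary <- function(objectives, spec) {
  failed <- attr(objectives, "failed")
  ok <- if (is.null(failed)) rep(TRUE, nrow(objectives)) else !failed
  R <- abs(sweep(log(pmax(objectives[ok, , drop = FALSE], 1e-300)),
                 2L, log(spec$observed), `-`))
  q <- stats::quantile(R, c(0.05, 0.25, 0.5, 0.75, 0.95), na.rm = TRUE)
  c(median = unname(q[3L]), q05 = unname(q[1L]), q25 = unname(q[2L]),
    q75 = unname(q[4L]), q95 = unname(q[5L]),
    n_failed = if (is.null(failed)) 0 else sum(failed))
}

#' Run the Cluster Newton Method
#'
#' Orchestrates the full ensemble fit: draw the initial cluster by
#' log-uniform sampling of the parameter box, then iterate
#' evaluate -> fit affine surrogate -> Newton update -> dS replication.
#' Per-iteration residual summaries (quantiles of `|ln(simulated/observed)|`
#' over all samples and objectives) and failure counts are recorded, and a
#' divergence flag is raised when an iteration's failure fraction or median
#' residual exceeds the configured thresholds.  The whole run is
#' deterministic given `config$seed`.
#'
#' @param model a [forward_model()].
#' @param space a [parameter_space()].
#' @param spec an [objective_spec()]; its names must match the model's
#'   objectives.
#' @param config a [cnm_config()].
#' @param keep_history keep a snapshot of the cluster and objective matrix
#'   at every iteration (memory permitting); summaries are always kept.
#' @param verbose print one line per iteration.
#' @return An object of class `cnm_fit`: list with `final_cluster`,
#'   `objectives` (final evaluation), `residuals` (per-sample per-objective
#'   log-residuals at the final iteration), `summary` (per-iteration
#'   residual quantiles, data frame), `history` (list of snapshots, length
#'   `n_iterations + 1`), `diagnostics`, `config`, `space`, `spec`.
#' @export
run_cnm <- function(model, space, spec, config = cnm_config(),
                    keep_history = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "forward_model"), inherits(space, "parameter_space"),
            inherits(spec, "objective_spec"), inherits(config, "cnm_config"))
  if (length(spec$names) != model$n_objectives)
    stop("objective spec has ", length(spec$names), " values but the model ",
         "returns ", model$n_objectives)

  n <- config$n_samples
  cluster <- sample_initial_cluster(space, n, seed = stage_seed(config$seed, 1L))

  # Per-sample target perturbation, drawn once and chased throughout.
  perturb <- NULL
  if (config$target_perturbation > 0) {
    set.seed(stage_seed(config$seed, 2L))
    perturb <- matrix(stats::rnorm(n * length(spec$observed),
                                   sd = config$target_perturbation),
                      n, length(spec$observed))
  }
  targets <- surrogate_targets(spec, n, perturb, config$log_objectives)

  history <- vector("list", config$n_iterations + 1L)
  summaries <- list()
  diverged_at <- NA_integer_
  out_of_box_counts <- integer(0)

  for (k in seq_len(config$n_iterations)) {
    objectives <- evaluate_cluster(model, cluster, config$max_failure_frac)
    s <- residual_summary(objectives, spec)
    summaries[[k]] <- s
    if (keep_history)
      history[[k]] <- list(cluster = cluster, objectives = objectives)
    if (verbose)
      message(sprintf("iter %2d  median|logres| %.4g  [q25 %.3g q75 %.3g]  failed %d",
                      k - 1L, s["median"], s["q25"], s["q75"], s["n_failed"]))
    if (is.na(diverged_at) && k > 1L) {
      if (s["n_failed"] / n > config$divergence_failure_frac ||
          (is.finite(summaries[[1L]]["median"]) &&
           s["median"] > config$divergence_residual_factor * summaries[[1L]]["median"]))
        diverged_at <- k - 1L
    }

    surrogate <- fit_affine_surrogate(cluster, objectives, config$log_objectives)

    # evaluation failures feed the failure policy: resampled rows are
    # redrawn from the surviving samples before the update
    failed <- attr(objectives, "failed")
    if (any(failed) && config$failure_policy == "resample") {
      set.seed(stage_seed(config$seed, 2L * k + 2L))
      good <- which(!failed)
      repl <- sample(good, sum(failed), replace = TRUE)
      X <- unclass(cluster)
      X[failed, ] <- X[repl, , drop = FALSE]
      cluster <- new_cluster(X, attr(cluster, "fixed_mask"),
                             attr(cluster, "iteration"))
      targets[failed, ] <- targets[repl, , drop = FALSE]
      if (!is.null(perturb)) perturb[failed, ] <- perturb[repl, , drop = FALSE]
      fl <- attr(objectives, "failed")
      objectives[failed, ] <- objectives[repl, , drop = FALSE]
      fl[failed] <- FALSE
      attr(objectives, "failed") <- fl
    }

    set.seed(stage_seed(config$seed, 2L * k + 1L))
    X_a <- newton_update(cluster, surrogate, spec, targets,
                         objectives = if (config$residual == "observed")
                           objectives,
                         failure_policy = config$failure_policy)
    cluster <- if (config$replication) {
      ds_replicate(cluster, X_a, surrogate, spec, config$dS, targets,
                   model = if (config$ds_reevaluate) model,
                   reevaluate = config$ds_reevaluate,
                   toward_before = config$ds_toward_before)
    } else X_a
    out_of_box_counts[k] <- sum(out_of_box(cluster, space))
  }

  objectives <- evaluate_cluster(model, cluster, config$max_failure_frac)
  s <- residual_summary(objectives, spec)
  summaries[[config$n_iterations + 1L]] <- s
  if (keep_history)
    history[[config$n_iterations + 1L]] <-
      list(cluster = cluster, objectives = objectives)
  if (verbose)
    message(sprintf("iter %2d  median|logres| %.4g  failed %d (final)",
                    config$n_iterations, s["median"], s["n_failed"]))

  summary_df <- cbind(iteration = seq_along(summaries) - 1L,
                      as.data.frame(do.call(rbind, summaries)))
  residuals <- sweep(log(pmax(objectives, 1e-300)), 2L, log(spec$observed), `-`)

  structure(list(final_cluster = cluster, objectives = objectives,
                 residuals = residuals, summary = summary_df,
                 history = if (keep_history) history else NULL,
                 diagnostics = list(
                   diverged = !is.na(diverged_at),
                   diverged_at = diverged_at,
                   out_of_box = out_of_box_counts,
                   final_failed = sum(attr(objectives, "failed"))),
                 config = config, space = space, spec = spec),
            class = "cnm_fit")
}

#' @export
print.cnm_fit <- function(x, ...) {
  cat("Cluster Newton fit: ", nrow(x$final_cluster), " samples, ",
      x$config$n_iterations, " iterations, dS = ", x$config$dS, "\n", sep = "")
  cat("  median |log-residual|: ",
      signif(x$summary$median[1L], 3), " (start) -> ",
      signif(x$summary$median[nrow(x$summary)], 3), " (final)\n", sep = "")
  if (x$diagnostics$diverged)
    cat("  DIVERGED at iteration", x$diagnostics$diverged_at, "\n")
  invisible(x)
}

#' Export a fit as tidy tables
#'
#' @param fit a `cnm_fit`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written: `parameters.csv` (one row per
#'   iteration x sample x parameter, natural scale), `summary.csv`, and
#'   `manifest.json` (config echo, seed, diagnostics).
#' @export
export_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  snaps <- if (!is.null(fit$history)) {
    lapply(seq_along(fit$history), function(k) {
      X <- cluster_params(fit$history[[k]]$cluster)
      data.frame(iteration = k - 1L,
                 sample_id = rep(rownames(X), times = ncol(X)),
                 name = rep(colnames(X), each = nrow(X)),
                 value = as.vector(X), stringsAsFactors = FALSE)
    })
  } else {
    X <- cluster_params(fit$final_cluster)
    list(data.frame(iteration = fit$config$n_iterations,
                    sample_id = rep(rownames(X), times = ncol(X)),
                    name = rep(colnames(X), each = nrow(X)),
                    value = as.vector(X), stringsAsFactors = FALSE))
  }
  p_params <- file.path(dir, "parameters.csv")
  utils::write.csv(do.call(rbind, snaps), p_params, row.names = FALSE)
  p_sum <- file.path(dir, "summary.csv")
  utils::write.csv(fit$summary, p_sum, row.names = FALSE)
  p_man <- file.path(dir, "manifest.json")
  manifest <- list(package = "cnmpk",
                   version = as.character(utils::packageVersion("cnmpk")),
                   config = unclass(fit$config),
                   diagnostics = fit$diagnostics,
                   summary = fit$summary)
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(p_params, p_sum, p_man))
}
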