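#' Forward-model contract
#'
#' A forward model maps one parameter vector (natural scale, named as in the
#' parameter space) to one vector of strictly positive objective values.  The
#' Cluster Newton engine only ever calls `fun` row by row, so any simulator
#' -- an ODE system, an analytic map, an external code -- can be wrapped.
#' Evaluation failures are signalled by returning non-finite values or by
#' raising an error; the engine flags the sample instead of crashing.
#'
#' @param fun `function(params)` returning a numeric vector of length
#'   `n_objectives` (positive; the engine fits log-objectives by default).
#' @param n_objectives number of objective values the model returns.
#' @param objective_names optional identifiers for the objectives.
#' @param name short label used in logs and manifests.
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(fun, n_objectives, objective_names = NULL,
                          name = "model") {
  stopifnot(is.function(fun), n_objectives >= 1)
  if (is.null(objective_names))
    objective_names <- sprintf("obj%d", seq_len(n_objectives))
  stopifnot(length(objective_names) == n_objectives)
  structure(list(fun = fun, n_objectives = as.integer(n_objectives),
                 objective_names = objective_names, name = name),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat("Forward model '", x$name, "': ", x$n_objectives, " objectives\n",
      sep = "")
  invisible(x)
}

#' Observed objective values to fit
#'
#' @param names objective identifiers (must match the forward model's).
#' @param observed strictly positive observed values, in the units the model
#'   outputs; positivity is required because residuals are taken on the log
#'   scale.
#' @param weights optional per-objective weights (default 1); applied to the
#'   log-residuals in the Newton step.
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(names, observed, weights = NULL) {
  names <- as.character(names)
  m <- length(names)
  stopifnot(length(observed) == m)
  observed <- as.numeric(observed)
  if (any(!is.finite(observed) | observed <= 0))
    stop("observed objective values must be finite and strictly positive ",
         "(log-residuals are undefined otherwise); offending: ",
         paste(names[!is.finite(observed) | observed <= 0], collapse = ", "))
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m, all(weights > 0))
  structure(list(names = names, observed = observed, weights = as.numeric(weights)),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat("Objective spec:", length(x$names), "observed values\n")
  print(data.frame(name = x$names, observed = x$observed, weight = x$weights),
        row.names = FALSE)
  invisible(x)
}

#' Cluster Newton run configuration
#'
#' @param n_samples ensemble size (virtual samples); 3000 by default.
#' @param n_iterations number of Newton iterations; 9 by default.
#' @param dS diversity parameter in `[0, 1)`.  After each Newton update the
#'   engine forms the internally dividing point
#'   `X_i = (1 - dS) X_b + dS X_a` between the pre-update (`X_b`) and
#'   post-update (`X_a`) positions, re-solves from `X_i` with the same
#'   pseudoinverse to get `X_a'`, and keeps `X_a` or `X_a'` with equal
#'   probability per sample.  `dS = 0` reproduces the unmodified algorithm.
#' @param target_perturbation relative scale of the per-sample multiplicative
#'   log-normal perturbation of the target objectives (0 disables).  Each
#'   sample chases its own jittered copy of the observations, drawn once at
#'   initialisation, which spreads the ensemble across the feasible set
#'   rather than collapsing it onto a single point.
#' @param seed master RNG seed.  Independent sub-streams are derived from it
#'   for initial sampling, target perturbation, and each iteration's random
#'   selection / resampling, so shortening or lengthening a run never
#'   perturbs earlier iterations.
#' @param failure_policy what to do with samples whose evaluation or update
#'   fails: `"resample"` replaces them with a draw from the surviving
#'   samples' empirical distribution, `"carry_over"` leaves them unchanged.
#' @param residual residual driving the Newton step: `"observed"` (default)
#'   uses each sample's actually evaluated objectives, the classic
#'   cluster-Newton update; `"surrogate"` uses the surrogate's prediction
#'   at the sample instead (always available, e.g. for failed rows).
#' @param ds_reevaluate when `TRUE` (default) the replication step
#'   re-evaluates the forward model at the dividing point `X_i` so the
#'   re-solve uses fresh residuals.  With `FALSE` the surrogate's own
#'   prediction at `X_i` is used, which costs nothing but makes the
#'   re-solve coincide with `X_a` up to rounding (see the methods
#'   vignette); it is retained for experimentation.
#' @param log_objectives fit the affine surrogate in `ln(parameter) ->
#'   ln(objective)` coordinates (default) or, when `FALSE`, with objectives
#'   on their natural scale.
#' @param ds_toward_before orientation of the dividing-point ratio.  The
#'   default (`TRUE`) places `X_i` a fraction `dS` of the way from `X_b`
#'   toward `X_a`, so `dS = 0` leaves the "before" point; `FALSE` flips it.
#' @param replication set `FALSE` to skip the replication step altogether
#'   (plain Newton updates only); a `dS = 0` run produces identical iterates.
#' @param max_failure_frac abort an iteration when more than this fraction of
#'   samples fail to evaluate.
#' @param divergence_residual_factor,divergence_failure_frac thresholds for
#'   the per-iteration divergence flag: median absolute log-residual above
#'   `factor` times its iteration-0 value, or more than `frac` failed
#'   samples.
#' @return An object of class `cnm_config`.
#' @export
cnm_config <- function(n_samples = 3000, n_iterations = 9, dS = 0.5,
                       target_perturbation = 0.1, seed = 1L,
                       failure_policy = c("resample", "carry_over"),
                       residual = c("observed", "surrogate"),
                       ds_reevaluate = TRUE,
                       log_objectives = TRUE, ds_toward_before = TRUE,
                       replication = TRUE,
                       max_failure_frac = 0.5,
                       divergence_residual_factor = 2,
                       divergence_failure_frac = 0.1) {
  failure_policy <- match.arg(failure_policy)
  residual <- match.arg(residual)
  if (!is.numeric(dS) || length(dS) != 1L || dS < 0 || dS >= 1)
    stop("dS must lie in [0, 1); got ", dS)
  stopifnot(n_samples >= 1, n_iterations >= 1, target_perturbation >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_iterations = as.integer(n_iterations),
                 dS = dS, target_perturbation = target_perturbation,
                 seed = as.integer(seed), failure_policy = failure_policy,
                 residual = residual, ds_reevaluate = isTRUE(ds_reevaluate),
                 log_objectives = isTRUE(log_objectives),
                 ds_toward_before = isTRUE(ds_toward_before),
                 replication = isTRUE(replication),
                 max_failure_frac = max_failure_frac,
                 divergence_residual_factor = divergence_residual_factor,
                 divergence_failure_frac = divergence_failure_frac),
            class = "cnm_config")
}

# Deterministic per-stage seeds derived from the master seed.  Stage indices:
# 1 initial sampling, 2 target perturbation, 2k+1 / 2k+2 selection and
# resampling of iteration k.  Arithmetic (not RNG-consuming) so the stream of
# iteration k never depends on how many iterations follow it.
stage_seed <- function(seed, stage) {
  x <- as.double(seed) %% 2147483647
  x <- (x * 16807 + as.double(stage)) %% 2147483647
  x <- (x * 48271 + 12345) %% 2147483647
  as.integer(x) + 1L
}
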