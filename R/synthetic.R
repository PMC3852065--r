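#' Synthetic affine inverse problem with known solution manifold
#'
#' Builds a forward model that is exactly affine in the coordinates the
#' engine fits (`ln(parameter) -> ln(objective)`): `ln y = A ln p + b` with
#' a slope matrix of prescribed rank.  The solution set of `A x + b =
#' ln(y*)` is then an affine subspace known in closed form (particular
#' solution plus the null space of `A`), which makes every Cluster Newton
#' property checkable against linear-algebra oracles: one-step exactness,
#' manifold membership, and null-space diversity.
#'
#' @param n_params number of parameters.
#' @param n_objectives number of objectives.
#' @param rank rank of the slope matrix; `rank <= min(n_params,
#'   n_objectives)`.
#' @param seed RNG seed; regeneration with the same seed is bitwise
#'   reproducible.
#' @param noise_sigma multiplicative log-normal noise on the generated
#'   targets (sd of `ln`); 0 (default) gives a consistent, noiseless
#'   problem.
#' @return An object of class `synthetic_problem`: list with `model`
#'   ([forward_model()]), `space` ([parameter_space()]), `spec`
#'   ([objective_spec()]), `A`, `b`, `x_true` (ln-scale generating point),
#'   `null_basis` (orthonormal basis of the null space of `A`), `seed`.
#' @export
make_affine_problem <- function(n_params, n_objectives, rank = NULL,
                                seed = 1L, noise_sigma = 0) {
  if (is.null(rank)) rank <- min(n_params, n_objectives)
  if (rank > min(n_params, n_objectives) || rank < 1)
    stop("rank must lie in [1, min(n_params, n_objectives)]; got ", rank)
  set.seed(seed)
  U <- qr.Q(qr(matrix(stats::rnorm(n_objectives * rank), n_objectives, rank)))
  V <- qr.Q(qr(matrix(stats::rnorm(n_params * rank), n_params, rank)))
  s <- sort(stats::runif(rank, 0.5, 2), decreasing = TRUE)
  A <- U %*% (s * t(V))
  b <- stats::rnorm(n_objectives, sd = 0.5)
  x_true <- stats::rnorm(n_params, sd = 0.5)          # ln-scale, inside e^[-2,2]-ish
  y_log <- drop(A %*% x_true + b)
  if (noise_sigma > 0) y_log <- y_log + stats::rnorm(n_objectives, sd = noise_sigma)

  pn <- sprintf("p%02d", seq_len(n_params))
  on <- sprintf("y%02d", seq_len(n_objectives))
  space <- parameter_space(pn, lower = rep(exp(-3), n_params),
                           upper = rep(exp(3), n_params))
  fun <- function(params) exp(drop(A %*% log(params) + b))
  model <- forward_model(fun, n_objectives, on, name = "affine")
  spec <- objective_spec(on, exp(y_log))

  nb <- if (rank < n_params) {
    sv <- svd(A, nv = n_params)
    sv$v[, (rank + 1L):n_params, drop = FALSE]
  } else matrix(0, n_params, 0)
  structure(list(model = model, space = space, spec = spec, A = A, b = b,
                 x_true = x_true, null_basis = nb, noise_sigma = noise_sigma,
                 seed = seed),
            class = "synthetic_problem")
}

#' Variance of a cluster along the null space of a slope matrix
#'
#' Projects the free-parameter block of a cluster onto an orthonormal null
#' space basis and returns the total variance of the projections -- the
#' spread the Newton step cannot see, and the quantity the dS replication
#' rule is designed to preserve.
#'
#' @param cluster a `cnm_cluster`.
#' @param null_basis orthonormal basis (columns) of the null space, over
#'   the free parameters.
#' @return scalar total variance.
#' @export
null_space_variance <- function(cluster, null_basis) {
  X <- unclass(cluster)
  fixed <- attr(cluster, "fixed_mask")
  if (!is.null(fixed)) X <- X[, !fixed, drop = FALSE]
  if (ncol(null_basis) == 0L) return(0)
  P <- X %*% null_basis
  sum(apply(P, 2L, stats::var))
}

#' Synthetic PBPK inverse problem with known ground truth
#'
#' Simulates the packaged irinotecan PBPK model at a chosen "true"
#' parameter vector and uses the resulting accumulation objectives --
#' optionally degraded by multiplicative log-normal noise -- as the fitting
#' targets.  Recovery experiments ("does the final cluster bracket the
#' generating values?") then have an exact answer.  By default the truth is
#' placed at the geometric midpoint of every sampling range, a neutral
#' choice that is well inside the box.
#'
#' @param group `"OC"` or `"BDC"`.
#' @param true_params optional named 56-parameter vector inside the
#'   sampling ranges; default geometric midpoints.
#' @param noise_sigma sd of the ln-scale target noise (default 0.1, a
#'   realistic 10% assay-level scatter); 0 gives noiseless targets.
#' @param seed RNG seed for the noise draw.
#' @param settings optional [pbpk_settings()].
#' @return A `synthetic_problem`: list with `model`, `space`, `spec`,
#'   `true_params`, `true_objectives`, `noise_sigma`, `seed`.
#' @export
make_pbpk_problem <- function(group = c("OC", "BDC"), true_params = NULL,
                              noise_sigma = 0.1, seed = 1L, settings = NULL) {
  group <- match.arg(group)
  space <- pbpk_parameter_space(group)
  if (is.null(true_params)) {
    v <- exp((log(space$lower) + log(space$upper)) / 2)
    v[space$fixed_mask] <- space$fixed_values[space$fixed_mask]
    true_params <- stats::setNames(v, space$names)
  } else {
    stopifnot(!is.null(names(true_params)))
    true_params <- true_params[space$names]
    free <- !space$fixed_mask
    if (any(true_params[free] < space$lower[free] |
            true_params[free] > space$upper[free]))
      stop("true_params must lie inside the sampling ranges")
  }
  if (is.null(settings)) settings <- pbpk_settings(group)
  model <- pbpk_model(group, settings)
  y <- tryCatch(model$fun(true_params), error = function(e)
    stop("simulation failed at the chosen true parameters: ",
         conditionMessage(e)))
  set.seed(seed)
  y_obs <- y * exp(stats::rnorm(length(y), sd = noise_sigma))
  structure(list(model = model, space = space,
                 spec = objective_spec(model$objective_names, y_obs),
                 true_params = true_params, true_objectives = y,
                 noise_sigma = noise_sigma, seed = seed),
            class = "synthetic_problem")
}

#' @export
print.synthetic_problem <- function(x, ...) {
  cat("Synthetic problem '", x$model$name, "': ",
      length(x$space$names), " parameters -> ",
      length(x$spec$names), " objectives (noise sigma = ",
      x$noise_sigma, ", seed = ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Synthetic observed accumulation time-profiles
#'
#' The published objective values are terminal accumulations only; the
#' intermediate time points of the underlying clinical profiles are not
#' tabulated.  For profile-level scoring demonstrations this helper builds
#' SYNTHETIC observed series: route totals rising to the group's terminal
#' total along a first-order saturation curve `A(t) = A_end (1 -
#' exp(-t/tau))` (normalised so the horizon value matches exactly).  These
#' series are stand-ins for the unavailable clinical time courses and are
#' suitable for exercising [ss_log()] and [score_cluster()], not for
#' clinical inference.
#'
#' @param group `"OC"` or `"BDC"`.
#' @param times sampling times (min), strictly positive.
#' @param tau saturation time constant (min), default 1440 (1 day).
#' @return list with `times` and per-route totals `urine`, `feces` and
#'   (BDC) `ttube`, as consumed by [score_cluster()].
#' @export
synthetic_observed_profiles <- function(group = c("OC", "BDC"),
                                        times = seq(720, 7200, by = 720),
                                        tau = 1440) {
  group <- match.arg(group)
  stopifnot(all(times > 0))
  obj <- pbpk_objectives(group)
  terminal <- function(prefix) sum(obj$observed[startsWith(obj$names, prefix)])
  shape <- (1 - exp(-times / tau)) / (1 - exp(-max(times) / tau))
  out <- list(times = times,
              urine = terminal("urine") * shape,
              feces = terminal("feces") * shape)
  if (group == "BDC") out$ttube <- terminal("bile") * shape
  out
}
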