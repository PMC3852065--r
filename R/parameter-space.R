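#' Bounded, partially fixed parameter-space definition
#'
#' A parameter space names every parameter of a forward model, gives a
#' strictly positive lower and upper bound for each free parameter, and pins
#' fixed parameters to constant values.  All sampling and linear algebra in
#' the Cluster Newton engine act on `ln(parameter)`, so the bounds define a
#' box in log-space; working in the log guarantees parameters stay positive
#' throughout optimisation.
#'
#' @param names character vector of unique parameter identifiers.
#' @param lower,upper numeric bounds on the original (natural) scale.  For a
#'   free parameter `0 < lower < upper` is required.  Ignored (may be `NA`)
#'   for fixed parameters.
#' @param units optional character vector of unit strings (default `""`).
#' @param fixed logical mask; `TRUE` entries never change across iterations.
#' @param values numeric fixed values; only entries where `fixed` is `TRUE`
#'   are used.  Fixed values may be zero (e.g. a drainage route that is
#'   absent in one patient group) but not negative.
#' @return An object of class `parameter_space`.
#' @examples
#' sp <- parameter_space(c("CL", "V"), lower = c(1, 10), upper = c(100, 1000),
#'                       units = c("ml/min/kg", "ml/kg"))
#' n_free(sp)
#' @export
parameter_space <- function(names, lower, upper, units = NULL,
                            fixed = NULL, values = NULL) {
  names <- as.character(names)
  p <- length(names)
  if (p == 0L) stop("parameter space must contain at least one parameter")
  if (anyDuplicated(names)) stop("duplicated parameter names: ",
                                 paste(unique(names[duplicated(names)]), collapse = ", "))
  if (is.null(units)) units <- rep("", p)
  if (is.null(fixed)) fixed <- rep(FALSE, p)
  if (is.null(values)) values <- rep(NA_real_, p)
  stopifnot(length(lower) == p, length(upper) == p,
            length(units) == p, length(fixed) == p, length(values) == p)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  fixed <- as.logical(fixed); values <- as.numeric(values)

  for (i in which(!fixed)) {
    if (!is.finite(lower[i]) || !is.finite(upper[i]))
      stop("non-finite bounds for free parameter '", names[i], "'")
    if (lower[i] <= 0)
      stop("lower bound must be strictly positive for free parameter '",
           names[i], "' (log-space sampling); got ", lower[i])
    if (lower[i] >= upper[i])
      stop("lower bound must be below upper bound for parameter '",
           names[i], "': [", lower[i], ", ", upper[i], "]")
  }
  for (i in which(fixed)) {
    if (!is.finite(values[i]) || values[i] < 0)
      stop("fixed parameter '", names[i], "' needs a finite non-negative value")
  }
  structure(
    list(names = names, units = units, lower = lower, upper = upper,
         fixed_mask = fixed, fixed_values = values),
    class = "parameter_space")
}

#' @rdname parameter_space
#' @param space a `parameter_space`.
#' @export
n_free <- function(space) sum(!space$fixed_mask)

#' @export
length.parameter_space <- function(x) length(x$names)

#' @export
print.parameter_space <- function(x, ...) {
  cat("Parameter space:", length(x$names), "parameters (",
      n_free(x), "free,", sum(x$fixed_mask), "fixed )\n")
  df <- as.data.frame(x)
  print(utils::head(df, 20), row.names = FALSE)
  if (nrow(df) > 20) cat("  ...", nrow(df) - 20, "more\n")
  invisible(x)
}

#' @export
as.data.frame.parameter_space <- function(x, ...) {
  data.frame(name = x$names, unit = x$units, min = x$lower, max = x$upper,
             fixed = x$fixed_mask, value = x$fixed_values,
             stringsAsFactors = FALSE)
}

#' Draw the initial virtual-sample cluster
#'
#' Each free parameter is drawn independently and uniformly in log-space over
#' `[ln lower, ln upper]`; a log-uniform draw spreads samples evenly across
#' the orders of magnitude the bounds allow, which is how broad prior ranges
#' such as 1--100 ml/min/kg are meant to be read.  Fixed parameters are set
#' to their fixed values in every sample.
#'
#' @param space a [parameter_space()].
#' @param n_samples number of virtual samples (rows).
#' @param seed optional integer seed; when supplied the draw is reproducible.
#' @return A `cnm_cluster`: a numeric matrix of shape `n_samples x n_params`
#'   holding `ln(parameter)` values (`-Inf` for parameters fixed at zero),
#'   with attributes `fixed_mask`, `iteration` and rownames giving stable
#'   sample identifiers.
#' @export
sample_initial_cluster <- function(space, n_samples, seed = NULL) {
  stopifnot(inherits(space, "parameter_space"), n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- length(space$names)
  if (n_samples < n_free(space))
    warning("fewer samples (", n_samples, ") than free parameters (",
            n_free(space), "); the affine surrogate will be rank-deficient")
  X <- matrix(NA_real_, n_samples, p,
              dimnames = list(sprintf("s%04d", seq_len(n_samples)), space$names))
  for (i in seq_len(p)) {
    if (space$fixed_mask[i]) {
      X[, i] <- log(space$fixed_values[i])  # -Inf when fixed at 0
    } else {
      X[, i] <- stats::runif(n_samples, log(space$lower[i]), log(space$upper[i]))
    }
  }
  new_cluster(X, fixed_mask = space$fixed_mask, iteration = 0L)
}

new_cluster <- function(X, fixed_mask, iteration = 0L) {
  structure(X, fixed_mask = fixed_mask, iteration = as.integer(iteration),
            class = c("cnm_cluster", class(matrix())))
}

#' @export
print.cnm_cluster <- function(x, ...) {
  cat("CNM cluster: ", nrow(x), " samples x ", ncol(x), " parameters",
      " (iteration ", attr(x, "iteration"), ")\n", sep = "")
  invisible(x)
}

#' Natural-scale view of a cluster
#'
#' @param cluster a `cnm_cluster` (ln-scale matrix).
#' @return matrix of the same shape on the original parameter scale.
#' @export
cluster_params <- function(cluster) {
  Y <- exp(unclass(cluster))
  attributes(Y) <- attributes(unclass(cluster))[c("dim", "dimnames")]
  Y
}

#' Flag samples outside the sampling log-box
#'
#' Newton updates are not clipped to the initial box (clipping would collapse
#' ensemble diversity), so later iterates may leave it; this reports which.
#'
#' @param cluster a `cnm_cluster`.
#' @param space the [parameter_space()] the cluster was sampled from.
#' @return logical vector, one entry per sample, `TRUE` if any free
#'   parameter lies outside `[ln lower, ln upper]`.
#' @export
out_of_box <- function(cluster, space) {
  free <- !space$fixed_mask
  lo <- log(space$lower[free]); hi <- log(space$upper[free])
  Xf <- unclass(cluster)[, free, drop = FALSE]
  apply(Xf, 1L, function(r) any(r < lo | r > hi))
}
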