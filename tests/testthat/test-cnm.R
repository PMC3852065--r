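test_that("evaluate_cluster isolates per-sample failures and aborts past 50%", {
  sp <- parameter_space(c("a", "b"), lower = c(0.1, 0.1), upper = c(10, 10))
  cl <- sample_initial_cluster(sp, 20, seed = 1)
  flaky <- forward_model(function(p) {
    if (p[["a"]] > 1) stop("boom")
    c(p[["a"]] + p[["b"]], p[["a"]])
  }, 2)
  P <- cluster_params(cl)
  n_bad <- sum(P[, "a"] > 1)
  if (n_bad / 20 <= 0.5) {
    Y <- evaluate_cluster(flaky, cl)
    expect_equal(sum(attr(Y, "failed")), n_bad)
    expect_true(all(is.na(Y[attr(Y, "failed"), ])))
    expect_true(all(is.finite(Y[!attr(Y, "failed"), ])))
  }
  always_bad <- forward_model(function(p) stop("boom"), 2)
  expect_error(evaluate_cluster(always_bad, cl), "failed for")
})

test_that("affine surrogate recovers exact affine data and flags degeneracy", {
  set.seed(4)
  A <- matrix(rnorm(3 * 5), 3, 5); b <- rnorm(3)
  sp <- parameter_space(sprintf("p%d", 1:5), lower = rep(0.1, 5),
                        upper = rep(10, 5))
  cl <- sample_initial_cluster(sp, 60, seed = 5)
  model <- forward_model(function(p) exp(drop(A %*% log(p) + b)), 3)
  Y <- evaluate_cluster(model, cl)
  sur <- fit_affine_surrogate(cl, Y)
  expect_equal(unname(sur$slope), A, tolerance = 1e-9)
  expect_equal(unname(sur$offset), b, tolerance = 1e-9)
  expect_lt(sur$fit_rms, 1e-10)

  # perfectly collinear parameters: warning + minimum-norm fit, no crash
  X2 <- unclass(cl); X2[, 2] <- X2[, 1]
  cl2 <- cnmpk:::new_cluster(X2, fixed_mask = rep(FALSE, 5))
  Y2 <- evaluate_cluster(model, cl2)
  expect_warning(sur2 <- fit_affine_surrogate(cl2, Y2), "rank-deficient")
  expect_true(all(is.finite(sur2$slope)))
})

test_that("surrogate slope converges to the analytic Jacobian as the cluster shrinks", {
  set.seed(11)
  A <- matrix(rnorm(2 * 3), 2, 3)
  Q <- matrix(rnorm(2 * 3, sd = 0.5), 2, 3)
  model <- quadratic_model(A, Q)
  x0 <- c(0.2, -0.1, 0.3)
  # oracle: central finite-difference Jacobian of ln f at x0
  h <- 1e-6
  J <- vapply(1:3, function(j) {
    e <- replace(numeric(3), j, h)
    (log(model$fun(exp(x0 + e))) - log(model$fun(exp(x0 - e)))) / (2 * h)
  }, numeric(2))
  err <- vapply(c(0.3, 0.03), function(radius) {
    X <- sweep(matrix(rnorm(400 * 3, sd = radius), 400, 3), 2, x0, `+`)
    cl <- cnmpk:::new_cluster(X, fixed_mask = rep(FALSE, 3))
    colnames(cl) <- sprintf("p%d", 1:3)
    sur <- fit_affine_surrogate(cl, evaluate_cluster(model, cl))
    max(abs(unname(sur$slope) - J))
  }, numeric(1))
  expect_lt(err[2], err[1])          # shrinking radius improves the fit
  expect_lt(err[2], 0.02)            # and lands near the local Jacobian
})

test_that("the minimum-norm Newton step matches the explicit least-norm solve", {
  # 1 objective y = x1 + x2 (fitted coordinates), sample at (3,3), target 2:
  # the pseudoinverse splits the residual equally, landing at (1,1)
  A <- matrix(c(1, 1), 1, 2)
  sur <- structure(list(slope = A, offset = 0, pinv = MASS::ginv(A),
                        free = c(TRUE, TRUE), log_objectives = TRUE),
                   class = "cnm_surrogate")
  cl <- cnmpk:::new_cluster(matrix(c(3, 3), 1, 2), fixed_mask = c(FALSE, FALSE))
  spec <- objective_spec("y", exp(2))
  upd <- newton_update(cl, sur, spec)
  expect_equal(unname(unclass(upd))[1, ], c(1, 1), tolerance = 1e-12)
  # oracle: explicit least-norm solution t(A) (A t(A))^-1 r
  r <- 2 - drop(A %*% c(3, 3))
  expect_equal(drop(c(3, 3) + t(A) %*% solve(A %*% t(A), r)), c(1, 1))

  # fixed point: identity surrogate, target equal to the current position
  sur_id <- structure(list(slope = diag(2), offset = c(0, 0),
                           pinv = diag(2), free = c(TRUE, TRUE),
                           log_objectives = TRUE),
                      class = "cnm_surrogate")
  spec2 <- objective_spec(c("y1", "y2"), exp(c(3, 3)))
  upd2 <- newton_update(cl, sur_id, spec2)
  expect_equal(unclass(upd2)[1, ], unclass(cl)[1, ])
})

test_that("one iteration solves consistent affine problems to 1e-8", {
  for (seed in c(1, 2)) {
    prob <- make_affine_problem(6, 4, rank = 4, seed = seed)
    fit <- run_cnm(prob$model, prob$space, prob$spec,
                   cnm_config(n_samples = 80, n_iterations = 1, dS = 0.5,
                              target_perturbation = 0, seed = seed))
    expect_lt(max(abs(exp(fit$residuals) - 1)), 1e-8)
  }
})

test_that("replication at dS = 0 returns X_a and never consumes RNG", {
  prob <- make_affine_problem(5, 3, rank = 3, seed = 3)
  cl <- sample_initial_cluster(prob$space, 40, seed = 1)
  Y <- evaluate_cluster(prob$model, cl)
  sur <- fit_affine_surrogate(cl, Y)
  Xa <- newton_update(cl, sur, prob$spec, objectives = Y)
  set.seed(123); state_before <- .Random.seed
  out <- ds_replicate(cl, Xa, sur, prob$spec, dS = 0, model = prob$model)
  expect_identical(unclass(out), unclass(Xa))
  expect_identical(state_before, .Random.seed)
  expect_error(ds_replicate(cl, Xa, sur, prob$spec, dS = 1), "dS must lie")
  expect_error(ds_replicate(cl, Xa, sur, prob$spec, dS = -0.1), "dS must lie")
})

test_that("on exactly affine models the dS re-solve reproduces X_a (idempotency)", {
  # the linearised update map is affine and idempotent, so with exact
  # affine data X_a' and X_a coincide for every dS -- the replication step
  # is provably inert there (its effect needs nonlinearity)
  prob <- make_affine_problem(6, 3, rank = 3, seed = 8)
  cl <- sample_initial_cluster(prob$space, 50, seed = 2)
  Y <- evaluate_cluster(prob$model, cl)
  sur <- fit_affine_surrogate(cl, Y)
  Xa <- newton_update(cl, sur, prob$spec, objectives = Y)
  for (ds in c(0.3, 0.5, 0.9)) {
    set.seed(1)
    mixed <- ds_replicate(cl, Xa, sur, prob$spec, dS = ds, model = prob$model)
    expect_equal(unclass(mixed), unclass(Xa), tolerance = 1e-9)
  }
  # and the Newton step preserves null-space spread sample by sample
  expect_equal(null_space_variance(Xa, prob$null_basis),
               null_space_variance(cl, prob$null_basis), tolerance = 1e-9)
})

test_that("dS = 0 run is bitwise identical to replication disabled", {
  prob <- make_affine_problem(5, 3, rank = 2, seed = 6)
  base <- list(n_samples = 60, n_iterations = 9, seed = 17)
  f_ds0 <- run_cnm(prob$model, prob$space, prob$spec,
                   do.call(cnm_config, c(base, dS = 0)))
  f_off <- run_cnm(prob$model, prob$space, prob$spec,
                   do.call(cnm_config, c(base, dS = 0, replication = FALSE)))
  for (k in seq_along(f_ds0$history))
    expect_identical(unclass(f_ds0$history[[k]]$cluster),
                     unclass(f_off$history[[k]]$cluster))
})

test_that("run_cnm is deterministic, keeps history, and never touches fixed parameters", {
  sp <- parameter_space(c("a", "b", "c"), lower = c(1, 1, NA),
                        upper = c(10, 10, NA),
                        fixed = c(FALSE, FALSE, TRUE), values = c(NA, NA, 2.5))
  model <- forward_model(function(p) c(p[["a"]] * p[["b"]] * p[["c"]],
                                       p[["a"]] / p[["b"]]), 2)
  spec <- objective_spec(c("y1", "y2"), c(12, 1.7))
  cfg <- cnm_config(n_samples = 30, n_iterations = 4, dS = 0.4, seed = 5)
  f1 <- run_cnm(model, sp, spec, cfg)
  f2 <- run_cnm(model, sp, spec, cfg)
  expect_identical(f1$final_cluster, f2$final_cluster)
  expect_identical(f1$summary, f2$summary)
  expect_length(f1$history, 5L)
  for (h in f1$history)
    expect_true(all(unclass(h$cluster)[, "c"] == log(2.5)))
  # residuals contract on this easy 2-objective problem
  expect_lt(f1$summary$median[5], f1$summary$median[1])
})

test_that("failure policies keep the run alive when some rows fail", {
  sp <- parameter_space(c("a", "b"), lower = c(0.5, 0.5), upper = c(4, 4))
  # model fails in one corner of the box
  model <- forward_model(function(p) {
    if (p[["a"]] > 3.2 && p[["b"]] > 3.2) stop("corner")
    c(p[["a"]] + p[["b"]], p[["a"]] * p[["b"]])
  }, 2)
  spec <- objective_spec(c("s", "m"), c(3, 2))
  for (policy in c("resample", "carry_over")) {
    fit <- run_cnm(model, sp, spec,
                   cnm_config(n_samples = 50, n_iterations = 3, dS = 0.5,
                              seed = 2, failure_policy = policy))
    expect_s3_class(fit, "cnm_fit")
    expect_lt(fit$summary$median[4], fit$summary$median[1])
  }
})
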