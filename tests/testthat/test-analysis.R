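test_that("ss_log matches hand-computed values", {
  expect_equal(as.numeric(ss_log(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(as.numeric(ss_log(exp(1) * 5, 5)), 1)
  # ratios (2, 0.5, 1): 2 (ln 2)^2
  expect_equal(as.numeric(ss_log(c(2, 1, 3), c(1, 2, 3))), 2 * log(2)^2)
  expect_error(ss_log(1:3, 1:2), "different lengths")
  expect_error(ss_log(1, 0), "strictly positive")
  # flooring of zero simulated amounts is counted, not fatal
  s <- ss_log(c(0, 1), c(1, 1))
  expect_equal(attr(s, "n_floored"), 1L)
})

test_that("select_best picks the k smallest with deterministic ties", {
  sc <- data.frame(sample_id = c("s3", "s1", "s2"),
                   ss_log = c(0.3, 0.1, 0.5))
  expect_equal(select_best(sc, 1), "s1")
  expect_equal(select_best(sc, 3), c("s1", "s3", "s2"))
  expect_error(select_best(sc, 4), "exceeds")
  # ties broken by sample_id
  tied <- data.frame(sample_id = c("b", "a"), ss_log = c(0.2, 0.2))
  expect_equal(select_best(tied, 1), "a")
  # nesting: best-k1 always inside best-k2 for k1 <= k2
  set.seed(7)
  big <- data.frame(sample_id = sprintf("s%03d", 1:50),
                    ss_log = round(rexp(50), 2))
  for (k in c(1, 5, 20))
    expect_true(all(select_best(big, k) %in% select_best(big, 30)))
})

test_that("geometric_summary implements geometric mean and SD", {
  X <- matrix(log(c(1, 100, 5, 5)), 2, 2,
              dimnames = list(NULL, c("p", "q")))
  cl <- cnmpk:::new_cluster(X, fixed_mask = c(FALSE, FALSE))
  gs <- geometric_summary(cl)
  expect_equal(gs$geo_mean, c(10, 5))  # sqrt(1*100), sqrt(5*5)
  expect_equal(gs$geo_sd[2], 1)        # degenerate column
  # large-sample limit: ln-normal draws around ln 5.7
  set.seed(1)
  big <- cnmpk:::new_cluster(matrix(rnorm(20000, log(5.7), 0.3),
                                    ncol = 1, dimnames = list(NULL, "cl")),
                             fixed_mask = FALSE)
  expect_equal(geometric_summary(big)$geo_mean, 5.7, tolerance = 0.01)
})

test_that("correlation screening finds collinear pairs and drops degenerate columns", {
  set.seed(3)
  n <- 400
  x <- rnorm(n)
  X <- cbind(a = x, b = -x + rnorm(n, sd = 0.05), c = rnorm(n),
             d = rep(1.5, n))
  cl <- cnmpk:::new_cluster(X, fixed_mask = rep(FALSE, 4))
  rep_ <- parameter_correlations(cl)
  ab <- rep_$pairs[rep_$pairs$p1 == "a" & rep_$pairs$p2 == "b", ]
  expect_gt(ab$r2, 0.64)
  expect_lt(ab$r, 0)                    # anticorrelation sign is reported
  expect_setequal(rep_$screened, c("a", "b"))
  expect_equal(rep_$dropped, "d")       # zero variance: excluded, not 0
  # independent columns screen out
  expect_false("c" %in% rep_$screened)
  # invariance under unit rescaling (multiplicative shift in log space)
  X2 <- X; X2[, "a"] <- X2[, "a"] + log(1000)
  rep2 <- parameter_correlations(cnmpk:::new_cluster(X2, rep(FALSE, 4)))
  expect_equal(rep2$pairs$r, rep_$pairs$r, tolerance = 1e-12)
})

test_that("cluster scoring against profiles ranks good fits first", {
  st <- fast_settings("OC")
  truth <- mid_params("OC")
  obs_times <- seq(720, st$t_end, by = 720)
  prof <- simulate_pbpk(truth, st, times = obs_times)
  observed <- list(times = obs_times,
                   urine = pmax(prof$urine_total, 1e-9),
                   feces = pmax(prof$feces_total, 1e-9))
  # cluster = truth plus two increasingly distorted copies
  P <- rbind(truth, truth, truth)
  P[2, "CL_r_CPT11"] <- truth[["CL_r_CPT11"]] * 3
  P[3, "CL_r_CPT11"] <- truth[["CL_r_CPT11"]] * 10
  cl <- cnmpk:::new_cluster(log(P), fixed_mask = pbpk_parameter_space("OC")$fixed_mask)
  rownames(cl) <- c("s1", "s2", "s3")
  sc <- score_cluster(cl, observed, st)
  expect_equal(sc$ss_log[1], 0, tolerance = 1e-8)
  expect_true(all(diff(sc$ss_log) > 0))
  expect_equal(select_best(sc, 1), "s1")
})

test_that("ds_sweep reports per-dS diagnostics deterministically and survives failures", {
  prob <- make_affine_problem(4, 2, rank = 2, seed = 9)
  cfg <- cnm_config(n_samples = 40, n_iterations = 2, seed = 4)
  r1 <- ds_sweep(prob$model, prob$space, prob$spec, cfg, c(0, 0.5))
  r2 <- ds_sweep(prob$model, prob$space, prob$spec, cfg, c(0, 0.5))
  expect_identical(r1, r2)
  expect_true(all(r1$converged))
  expect_false(any(r1$diverged))
  # a model that always fails is recorded, not fatal
  bad <- forward_model(function(p) stop("no"), 2)
  rb <- ds_sweep(bad, prob$space, prob$spec, cfg, c(0, 0.5))
  expect_equal(nrow(rb), 2L)
  expect_true(all(!is.na(rb$error)))
})

test_that("final-cluster diversity grows with dS on the nonlinear PBPK problem", {
  # scaled-down version of the BDC fit; diversity = median per-parameter
  # log-range of the final cluster
  sc <- pbpk_scenario("BDC")
  sc$settings <- fast_settings("BDC")
  model <- pbpk_model("BDC", sc$settings)
  cfg <- cnm_config(n_samples = 120, n_iterations = 4, seed = 2)
  rep_ <- ds_sweep(model, sc$space, sc$spec, cfg, c(0, 0.8))
  expect_true(all(is.na(rep_$error)))
  expect_gt(rep_$diversity[2], rep_$diversity[1])
})
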