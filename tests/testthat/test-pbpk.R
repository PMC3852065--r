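test_that("rhs is zero for a closed system at rest, and infusion feeds CPT-11 only", {
  p <- mid_params("OC")
  p[] <- 1e-300  # all rates/clearances effectively zero (positivity required)
  p[grep("^Kp_liver|^V_rapid", names(p))] <- 1
  st <- pbpk_settings("OC")
  y0 <- setNames(numeric(45), cnmpk:::pbpk_state_names(1))
  d_post <- pbpk_rhs(100, y0, p, st)[[1]]
  expect_equal(max(abs(d_post)), 0)
  d_inf <- pbpk_rhs(10, y0, p, st)[[1]]
  expect_equal(d_inf[["rapid_CPT11"]], 1500 / 90)
  expect_equal(sum(abs(d_inf)), 1500 / 90)  # nothing else moves
})

test_that("degenerate single-compartment configuration matches the analytic infusion solution", {
  # only renal elimination from the rapid compartment: one-compartment
  # zero-order infusion with k = CL_r / V_rapid
  p <- mid_params("OC")
  p[] <- 1e-300
  p[grep("^Kp_liver", names(p))] <- 1
  p[grep("^V_rapid", names(p))] <- 100   # ml/kg
  p["CL_r_CPT11"] <- 5                   # ml/min/kg -> k = 0.05 /min
  # hepatic blood flow switched off so the liver cannot act as a
  # distribution compartment
  st <- pbpk_settings("OC", t_end = 600, Q_liver = 1e-12)
  times <- c(0, 45, 90, 180, 600)
  prof <- simulate_pbpk(p, st, times = times)
  k <- 5 / 100; R0 <- 1500 / 90; tinf <- 90
  analytic <- ifelse(times <= tinf,
                     R0 / k * (1 - exp(-k * times)),
                     R0 / k * (1 - exp(-k * tinf)) * exp(-k * (times - tinf)))
  expect_equal(unname(prof$state[, "rapid_CPT11"]), analytic, tolerance = 1e-6)
  # everything eliminated goes to urine
  expect_equal(unname(prof$urine[, "CPT11"]),
               pmin(times, tinf) * R0 - analytic, tolerance = 1e-6)
})

test_that("compiled and reference right-hand sides agree", {
  p <- mid_params("BDC")
  st <- fast_settings("BDC")
  a <- simulate_pbpk(p, st, compiled = TRUE)
  b <- simulate_pbpk(p, st, compiled = FALSE)
  expect_equal(a$state, b$state, tolerance = 1e-10)
  # and with a longer bile-transit chain
  st3 <- fast_settings("BDC", n_bile_transit = 3)
  a3 <- simulate_pbpk(p, st3, compiled = TRUE)
  b3 <- simulate_pbpk(p, st3, compiled = FALSE)
  expect_equal(a3$state, b3$state, tolerance = 1e-10)
})

test_that("mass is conserved and excreta are monotone for random draws", {
  sp <- pbpk_parameter_space("BDC")
  st <- fast_settings("BDC")
  cl <- suppressWarnings(sample_initial_cluster(sp, 12, seed = 31))
  P <- cluster_params(cl)
  for (j in seq_len(nrow(P))) {
    prof <- suppressWarnings(simulate_pbpk(P[j, ], st))
    expect_lt(max(abs(prof$mass_balance)), 1e-3)
    for (series in list(prof$urine_total, prof$feces_total, prof$ttube_total))
      expect_true(all(diff(series) > -1e-9))
  }
})

test_that("OC runs have identically zero T-tube output", {
  p <- mid_params("OC")
  prof <- simulate_pbpk(p, fast_settings("OC"))
  expect_equal(max(abs(prof$ttube)), 0)
})

test_that("metabolites stay at zero when no metabolic clearance is active", {
  p <- mid_params("OC")
  p[c("CL_CES_1", "CL_3A4_1", "CL_3A4_2")] <- 1e-300
  prof <- simulate_pbpk(p, fast_settings("OC"))
  met_cols <- grep("SN38$|SN38G$|NPC$|APC$", colnames(prof$state))
  expect_equal(max(abs(prof$state[, met_cols])), 0)
})

test_that("a dominant renal route captures essentially the whole dose", {
  p <- mid_params("OC")
  p[] <- 1e-300
  p[grep("^Kp_liver", names(p))] <- 1
  p[grep("^V_rapid", names(p))] <- 50
  p["CL_r_CPT11"] <- 200
  prof <- simulate_pbpk(p, pbpk_settings("OC", t_end = 7200, Q_liver = 1e-12))
  expect_equal(unname(prof$urine[nrow(prof$urine), "CPT11"]), 1500,
               tolerance = 1e-3)
})

test_that("enterohepatic recirculation diverts drug away from feces", {
  st <- fast_settings("OC")
  lo <- mid_params("OC"); hi <- lo
  lo["k_a_CPT11"] <- 0.002; hi["k_a_CPT11"] <- 0.08
  f_lo <- simulate_pbpk(lo, st)$feces
  f_hi <- simulate_pbpk(hi, st)$feces
  expect_lt(f_hi[nrow(f_hi), "CPT11"], f_lo[nrow(f_lo), "CPT11"])
})

test_that("the T-tube split trades drainage against downstream biliary delivery", {
  st <- fast_settings("BDC")
  r <- c(0.2, 1, 5)
  res <- t(vapply(r, function(rt) {
    p <- mid_params("BDC"); p["r_Ttube"] <- rt
    prof <- simulate_pbpk(p, st)
    n <- length(prof$times)
    c(ttube = prof$ttube_total[n],
      downstream = sum(prof$state[n, grep("^(SI|LI|feces)_", colnames(prof$state))]))
  }, c(ttube = 0, downstream = 0)))
  expect_true(all(diff(res[, "ttube"]) > 0))
  expect_true(all(diff(res[, "downstream"]) < 0))
})

test_that("objective extraction matches the group design and combines fecal SN-38 species", {
  p <- mid_params("BDC")
  prof <- simulate_pbpk(p, fast_settings("BDC"))
  o_bdc <- objectives_from_simulation(prof, "BDC")
  o_oc <- objectives_from_simulation(prof, "OC")
  expect_length(o_bdc, 14L)
  expect_length(o_oc, 9L)
  expect_named(o_oc, pbpk_objectives("OC")$names)
  expect_named(o_bdc, pbpk_objectives("BDC")$names)
  n <- length(prof$times)
  expect_equal(o_bdc[["feces_SN38_SN38G"]],
               unname(prof$feces[n, "SN38"] + prof$feces[n, "SN38G"]))
  # requesting T-tube objectives from an OC profile is a structural error
  prof_oc <- simulate_pbpk(mid_params("OC"), fast_settings("OC"))
  expect_error(objectives_from_simulation(prof_oc, "BDC"), "OC profile")
})

test_that("parameter packing rejects missing or negative parameters", {
  p <- mid_params("OC")
  expect_error(cnmpk:::pack_pbpk_parms(p[-3], pbpk_settings("OC")), "missing")
  p2 <- p; p2[1] <- -1
  expect_error(cnmpk:::pack_pbpk_parms(p2, pbpk_settings("OC")), "non-negative")
})
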