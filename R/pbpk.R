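#' @useDynLib cnmpk
NULL

#' Compounds tracked by the irinotecan PBPK model
#'
#' Irinotecan (CPT-11) and its four modelled metabolites.  The metabolic
#' network is fixed: CPT-11 is converted to SN-38 (by CES2), to APC and NPC
#' (by CYP3A4); NPC is converted to SN-38 (CES2); SN-38 is glucuronidated to
#' SN-38G (UGT1A).  All amounts are carried as parent-mass equivalents
#' (ug/kg), so conversion moves mass 1:1 between pools and the grand total
#' tracks the infused radioactivity.
#' @export
pbpk_compounds <- c("CPT11", "SN38", "SN38G", "NPC", "APC")

#' Canonical parameter names of the irinotecan PBPK model
#'
#' 56 parameters: five disposition blocks per compound (liver partition
#' coefficient, renal clearance, biliary clearance, fecal / absorption /
#' intestinal-transit / bile-transit rate constants, rapid-late exchange
#' clearance and rate, rapid-compartment volume), five metabolic clearances
#' (single edges of the network), and the shared T-tube split ratio
#' `r_Ttube = CL_bile,T-tube / CL_bile,transit` (zero when no biliary
#' drainage tube is placed).
#' @return character vector of length 56, in the canonical order used by
#'   parameter files and clusters.
#' @export
pbpk_parameter_names <- function() {
  cpd <- pbpk_compounds
  c(paste0("Kp_liver_", cpd),
    paste0("CL_r_", cpd),
    paste0("CL_bile_", cpd),
    "CL_CES_1", "CL_CES_2", "CL_3A4_1", "CL_3A4_2", "CL_UGT",
    paste0("k_feces_", cpd),
    paste0("k_a_", cpd),
    paste0("k_LI_", cpd),
    paste0("k_transit_", cpd),
    paste0("CL_12_", cpd),
    paste0("k_21_", cpd),
    paste0("V_rapid_", cpd),
    "r_Ttube")
}

#' Dosing and physiological settings for a PBPK simulation
#'
#' @param group `"OC"` (other-cancer patients, no biliary drainage) or
#'   `"BDC"` (bile-duct-cancer patient with a biliary T-tube).  For OC the
#'   T-tube clearance is structurally zero.
#' @param dose total intravenous dose, ug/kg (default 1500).
#' @param infusion_duration zero-order infusion time, min (default 90).
#' @param Q_liver hepatic blood flow, ml/min/kg (default 20.7).
#' @param V_liver liver volume, ml/kg (default 24.1).
#' @param t_end simulation / objective-evaluation horizon, min.  Default
#'   7200 min (5 days), long enough for cumulative excreta to plateau under
#'   the admitted rate-constant ranges.
#' @param n_bile_transit number of serial bile-transit compartments
#'   (default 1).
#' @param rtol,atol solver tolerances passed to the stiff integrator.
#' @return An object of class `pbpk_settings`.
#' @export
pbpk_settings <- function(group = c("OC", "BDC"), dose = 1500,
                          infusion_duration = 90, Q_liver = 20.7,
                          V_liver = 24.1, t_end = 7200,
                          n_bile_transit = 1L, rtol = 1e-8, atol = 1e-8) {
  group <- match.arg(group)
  stopifnot(dose > 0, infusion_duration > 0, Q_liver > 0, V_liver > 0,
            t_end > infusion_duration, n_bile_transit >= 1)
  structure(list(group = group, dose = dose,
                 infusion_duration = infusion_duration,
                 Q_liver = Q_liver, V_liver = V_liver, t_end = t_end,
                 n_bile_transit = as.integer(n_bile_transit),
                 rtol = rtol, atol = atol),
            class = "pbpk_settings")
}

pbpk_state_names <- function(n_transit = 1L) {
  per <- c("rapid", "late", "liver", paste0("transit", seq_len(n_transit)),
           "SI", "LI", "urine", "feces", "ttube")
  as.vector(vapply(pbpk_compounds, function(cpd) paste0(per, "_", cpd),
                   character(length(per))))
}

# Pack a named 56-parameter vector plus settings into the flat vector the
# compiled right-hand side reads (layout documented in src/pbpk.c).
pack_pbpk_parms <- function(params, settings) {
  nm <- pbpk_parameter_names()
  if (is.null(names(params))) {
    if (length(params) != length(nm))
      stop("unnamed parameter vector must have length ", length(nm))
    names(params) <- nm
  }
  missing <- setdiff(nm, names(params))
  if (length(missing))
    stop("missing PBPK parameters: ", paste(missing, collapse = ", "))
  params <- params[nm]
  if (any(!is.finite(params)) || any(params < 0))
    stop("PBPK parameters must be finite and non-negative")
  r_T <- if (settings$group == "OC") 0 else unname(params["r_Ttube"])
  pv <- numeric(61)
  pv[1] <- settings$Q_liver
  pv[2] <- settings$V_liver
  pv[3] <- settings$dose / settings$infusion_duration
  pv[4] <- settings$infusion_duration
  pv[5] <- settings$n_bile_transit
  pv[6] <- r_T
  pv[7:11] <- params[c("CL_CES_1", "CL_CES_2", "CL_3A4_1", "CL_3A4_2", "CL_UGT")]
  for (c in seq_along(pbpk_compounds)) {
    cpd <- pbpk_compounds[c]
    pv[11 + 10 * (c - 1) + 1:10] <- params[paste0(
      c("Kp_liver_", "CL_r_", "CL_bile_", "k_feces_", "k_a_", "k_LI_",
        "k_transit_", "CL_12_", "k_21_", "V_rapid_"), cpd)]
  }
  pv
}

#' Right-hand side of the irinotecan PBPK system (reference implementation)
#'
#' Pure-R time derivative of the model state; the packaged simulator runs an
#' algebraically identical compiled version, and the two are kept in lock
#' step by tests.  Per compound the state is: a rapid-equilibrium
#' compartment (volume `V_rapid`) receiving the infusion (CPT-11 only) and
#' exchanging with a late-equilibrium compartment via `CL_12`/`k_21`; a
#' well-stirred liver connected to the rapid compartment by hepatic blood
#' flow `Q_H`, whose outflow concentration `A_liver / (V_liver * Kp_liver)`
#' drives biliary excretion and metabolism; a chain of bile-transit
#' compartments emptying into the small intestine (`k_transit`), from which
#' drug is either reabsorbed into the liver (`k_a`, the enterohepatic loop)
#' or passed to the large intestine (`k_LI`) and on to feces (`k_feces`);
#' and cumulative urine (`CL_r` acting on the rapid compartment), feces, and
#' biliary T-tube (clearance `r_Ttube * CL_bile`) outputs.
#'
#' @param t time (min).
#' @param state named state vector, see [pbpk_state_names] via
#'   [simulate_pbpk()]; amounts in ug/kg.
#' @param params named 56-parameter vector (see [pbpk_parameter_names()]).
#' @param settings a [pbpk_settings()].
#' @return list of one numeric vector: the state derivative (deSolve
#'   convention).
#' @export
pbpk_rhs <- function(t, state, params, settings) {
  pv <- pack_pbpk_parms(params, settings)
  d <- pbpk_rhs_packed(t, state, pv)
  names(d) <- if (!is.null(names(state))) names(state) else
    pbpk_state_names(settings$n_bile_transit)
  list(d)
}

pbpk_rhs_packed <- function(t, state, pv) {
  NT <- as.integer(pv[5]); blk <- 8L + NT
  QH <- pv[1]; VH <- pv[2]; krate <- pv[3]; tinf <- pv[4]; rT <- pv[6]
  CLmet <- pv[7:11]  # CES1, CES2, 3A4_1, 3A4_2, UGT
  d <- numeric(length(state))
  Cu <- numeric(5)
  for (c in 1:5) {
    Kp <- pv[11 + 10 * (c - 1) + 1]
    Cu[c] <- state[blk * (c - 1) + 3] / (VH * Kp)
  }
  form <- c(0,
            CLmet[1] * Cu[1] + CLmet[2] * Cu[4],  # SN-38 <- CPT-11, NPC
            CLmet[5] * Cu[2],                     # SN-38G <- SN-38
            CLmet[4] * Cu[1],                     # NPC <- CPT-11
            CLmet[3] * Cu[1])                     # APC <- CPT-11
  met_out <- c(CLmet[1] + CLmet[3] + CLmet[4], CLmet[5], 0, CLmet[2], 0)
  for (c in 1:5) {
    p <- pv[11 + 10 * (c - 1) + 1:10]
    i0 <- blk * (c - 1)
    Cr <- state[i0 + 1] / p[10]
    infus <- if (c == 1 && t < tinf) krate else 0
    d[i0 + 1] <- infus + QH * Cu[c] - QH * Cr - p[2] * Cr - p[8] * Cr +
      p[9] * state[i0 + 2]
    d[i0 + 2] <- p[8] * Cr - p[9] * state[i0 + 2]
    d[i0 + 3] <- QH * Cr - QH * Cu[c] -
      (p[3] * (1 + rT) + met_out[c]) * Cu[c] + form[c] +
      p[5] * state[i0 + 3 + NT + 1]
    d[i0 + 4] <- p[3] * Cu[c] - p[7] * state[i0 + 4]
    if (NT > 1) for (i in 2:NT)
      d[i0 + 3 + i] <- p[7] * (state[i0 + 2 + i] - state[i0 + 3 + i])
    d[i0 + 4 + NT] <- p[7] * state[i0 + 3 + NT] - (p[5] + p[6]) * state[i0 + 4 + NT]
    d[i0 + 5 + NT] <- p[6] * state[i0 + 4 + NT] - p[4] * state[i0 + 5 + NT]
    d[i0 + 6 + NT] <- p[2] * Cr
    d[i0 + 7 + NT] <- p[4] * state[i0 + 5 + NT]
    d[i0 + 8 + NT] <- rT * p[3] * Cu[c]
  }
  d
}

#' Simulate the irinotecan PBPK model
#'
#' Integrates the system with a stiff solver (`deSolve`, lsoda) from an
#' all-zero initial state and returns the accumulation profile: cumulative
#' urinary, fecal and biliary T-tube amounts per compound and in total
#' (total irinotecan radioactivity), plus the full compartment trajectory.
#'
#' @param params named 56-parameter vector (see [pbpk_parameter_names()]).
#' @param settings a [pbpk_settings()].
#' @param times output time grid (min); default 61 evenly spaced points over
#'   `[0, t_end]`.  The infusion stop is always included internally for
#'   solver accuracy.
#' @param compiled use the compiled right-hand side (default) or the pure-R
#'   reference [pbpk_rhs()].
#' @param check_negative flag the run as failed if any amount drops below
#'   `-1e-6 * dose` (solver trouble); default `TRUE`.
#' @return An object of class `accumulation_profile`: list with `times`,
#'   per-route matrices `urine`, `feces`, `ttube` (time x compound),
#'   per-route totals `urine_total`, `feces_total`, `ttube_total`,
#'   `state` (full trajectory), `mass_balance` (relative conservation error
#'   per output time), and `settings`.
#' @export
simulate_pbpk <- function(params, settings, times = NULL, compiled = TRUE,
                          check_negative = TRUE) {
  stopifnot(inherits(settings, "pbpk_settings"))
  if (is.null(times))
    times <- seq(0, settings$t_end, length.out = 61)
  stopifnot(times[1] >= 0, !is.unsorted(times))
  pv <- pack_pbpk_parms(params, settings)
  NT <- settings$n_bile_transit
  snames <- pbpk_state_names(NT)
  y0 <- stats::setNames(numeric(length(snames)), snames)
  # always integrate from t = 0 (zero initial state + infusion start) and
  # force a mesh point at the infusion stop
  t_solver <- sort(unique(c(0, settings$infusion_duration, times)))

  out <- if (compiled) {
    deSolve::ode(y0, t_solver, func = "cnmpk_derivs", parms = pv,
                 dllname = "cnmpk", initfunc = "cnmpk_initmod",
                 method = "lsoda", rtol = settings$rtol, atol = settings$atol,
                 maxsteps = 50000)
  } else {
    deSolve::ode(y0, t_solver,
                 func = function(t, y, p) list(pbpk_rhs_packed(t, y, p)),
                 parms = pv, method = "lsoda",
                 rtol = settings$rtol, atol = settings$atol, maxsteps = 50000)
  }
  if (nrow(out) < length(t_solver) || any(!is.finite(out)))
    stop("PBPK integration failed (solver did not reach the horizon)")
  out <- out[out[, 1] %in% times, , drop = FALSE]
  S <- out[, -1, drop = FALSE]
  if (check_negative && min(S) < -1e-6 * settings$dose)
    stop("PBPK integration produced negative amounts beyond tolerance (min ",
         signif(min(S), 3), " ug/kg)")

  route <- function(what) {
    M <- S[, paste0(what, "_", pbpk_compounds), drop = FALSE]
    colnames(M) <- pbpk_compounds
    M
  }
  urine <- route("urine"); feces <- route("feces"); ttube <- route("ttube")
  infused <- pmin(out[, 1], settings$infusion_duration) *
    settings$dose / settings$infusion_duration
  total <- rowSums(S)
  mb <- ifelse(infused > 0, (total - infused) / settings$dose, 0)

  structure(list(times = out[, 1], urine = urine, feces = feces,
                 ttube = ttube,
                 urine_total = rowSums(urine), feces_total = rowSums(feces),
                 ttube_total = rowSums(ttube),
                 state = S, mass_balance = mb, settings = settings),
            class = "accumulation_profile")
}

#' @export
print.accumulation_profile <- function(x, ...) {
  n <- length(x$times)
  cat("PBPK accumulation profile (", x$settings$group, "): t in [0, ",
      max(x$times), "] min, ", n, " points\n", sep = "")
  cat(sprintf("  terminal urine %.4g, feces %.4g, T-tube %.4g ug/kg; |mass-balance error| <= %.2g%% of dose\n",
              x$urine_total[n], x$feces_total[n], x$ttube_total[n],
              100 * max(abs(x$mass_balance))))
  invisible(x)
}

#' Tidy export of an accumulation profile
#'
#' @param x an `accumulation_profile`.
#' @param ... unused.
#' @return data frame with columns `time`, `compound`, `compartment`,
#'   `amount` (ug/kg, parent equivalents).
#' @export
as.data.frame.accumulation_profile <- function(x, ...) {
  S <- x$state
  parts <- strsplit(colnames(S), "_(?=[A-Z0-9]+$)", perl = TRUE)
  data.frame(time = rep(x$times, times = ncol(S)),
             compound = rep(vapply(parts, `[`, "", 2L), each = nrow(S)),
             compartment = rep(vapply(parts, `[`, "", 1L), each = nrow(S)),
             amount = as.vector(S), stringsAsFactors = FALSE)
}

#' Objective vector from a simulated accumulation profile
#'
#' Reads the cumulative amounts at the evaluation horizon: urinary
#' accumulation of the five compounds, fecal accumulation of CPT-11,
#' SN-38 + SN-38G combined (intestinal beta-glucuronidase interconverts the
#' two in feces, so only their sum is well determined), NPC and APC, and --
#' for the BDC group -- biliary T-tube accumulation of the five compounds.
#'
#' @param profile an [simulate_pbpk()] result.
#' @param group `"OC"` (9 objectives) or `"BDC"` (14).
#' @return named numeric vector of length 9 or 14.
#' @export
objectives_from_simulation <- function(profile, group = c("OC", "BDC")) {
  group <- match.arg(group)
  stopifnot(inherits(profile, "accumulation_profile"))
  if (group == "BDC" && profile$settings$group == "OC")
    stop("T-tube objectives requested from an OC profile (no T-tube is ",
         "modelled for that group)")
  n <- length(profile$times)
  u <- profile$urine[n, ]; f <- profile$feces[n, ]; b <- profile$ttube[n, ]
  out <- c(urine_CPT11 = u[["CPT11"]], urine_SN38 = u[["SN38"]],
           urine_SN38G = u[["SN38G"]], urine_NPC = u[["NPC"]],
           urine_APC = u[["APC"]],
           feces_CPT11 = f[["CPT11"]],
           feces_SN38_SN38G = f[["SN38"]] + f[["SN38G"]],
           feces_NPC = f[["NPC"]], feces_APC = f[["APC"]])
  if (group == "BDC")
    out <- c(out, bile_CPT11 = b[["CPT11"]], bile_SN38 = b[["SN38"]],
             bile_SN38G = b[["SN38G"]], bile_NPC = b[["NPC"]],
             bile_APC = b[["APC"]])
  out
}

#' Forward model wrapping the PBPK simulator
#'
#' Builds the [forward_model()] the Cluster Newton engine consumes: a map
#' from one 56-parameter vector to the group's 9 (OC) or 14 (BDC)
#' accumulation objectives at the horizon.  Objective evaluation only needs
#' the terminal state, so the solver is run with a two-point output grid.
#'
#' @param group `"OC"` or `"BDC"`.
#' @param settings optional [pbpk_settings()] (defaults to the group's).
#' @return a `forward_model` with 9 or 14 objectives.
#' @export
pbpk_model <- function(group = c("OC", "BDC"), settings = NULL) {
  group <- match.arg(group)
  if (is.null(settings)) settings <- pbpk_settings(group)
  stopifnot(settings$group == group)
  times <- c(0, settings$t_end)
  nobj <- if (group == "OC") 9L else 14L
  fun <- function(params) {
    # solver chatter (early returns etc.) is routine during broad ensemble
    # sweeps; hard failures still raise and are flagged by the engine
    profile <- suppressWarnings(simulate_pbpk(params, settings, times = times))
    objectives_from_simulation(profile, group)
  }
  nm <- names(objectives_from_simulation(
    structure(list(times = c(0, 1),
                   urine = matrix(1, 2, 5, dimnames = list(NULL, pbpk_compounds)),
                   feces = matrix(1, 2, 5, dimnames = list(NULL, pbpk_compounds)),
                   ttube = matrix(1, 2, 5, dimnames = list(NULL, pbpk_compounds)),
                   settings = settings),
              class = "accumulation_profile"), group))
  forward_model(fun, nobj, nm, name = paste0("pbpk_irinotecan_", group))
}
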