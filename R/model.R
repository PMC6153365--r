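#' Sigmoidal response function
#'
#' The logistic response `H(w) = 1 / (1 + exp(-sigma * w))` through which
#' every protein's net interaction input sets its production rate. It is
#' strictly increasing in `w`, with `H(0) = 1/2` and asymptotes 0 and 1.
#'
#' @param w Net interaction input (finite numeric, vectorized).
#' @param sigma Steepness parameter (> 0).
#' @return Values in (0, 1).
#' @examples
#' sigmoid_response(0, 4)      # 0.5
#' sigmoid_response(1e3, 4)    # ~1
#' @export
sigmoid_response <- function(w, sigma) {
  if (any(!is.finite(w))) stop("interaction input w must be finite")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be finite and positive")
  1 / (1 + exp(-sigma * w))
}

#' Receptor:cytokine occupancy
#'
#' With cytokine held constant and in excess of receptor, the bound complex
#' follows `[R:L] = L * R_T / (L + Kd)`; occupancy never exceeds the total
#' receptor level and half-saturates at `L = Kd`.
#'
#' @param ligand Cytokine concentration (>= 0).
#' @param receptor_total Total receptor activity in `[0, 1]`.
#' @param kd Dissociation constant (> 0).
#' @return Bound receptor concentration.
#' @examples
#' receptor_occupancy(1, 0.8, 1)   # 0.4: half-saturation at L = Kd
#' @export
receptor_occupancy <- function(ligand, receptor_total, kd) {
  if (any(ligand < 0) || any(!is.finite(ligand)))
    stop("ligand concentration must be finite and non-negative")
  if (any(receptor_total < 0) || any(receptor_total > 1 + 1e-9))
    stop("receptor_total must lie in [0, 1]")
  if (any(kd <= 0)) stop("kd must be positive")
  ligand * receptor_total / (ligand + kd)
}

#' Partition total C/EBP and IRF8 into free forms and the heterodimer
#'
#' C/EBP and IRF8 bind reversibly; with the binding reaction at mass-action
#' equilibrium (`Keq = complex / (free_C * free_I)`) and both totals fixed,
#' the free C/EBP level is the unique non-negative root of a quadratic:
#' `free_C = (-b + sqrt(b^2 + 4 * total_C / Keq)) / 2` with
#' `b = total_I + 1/Keq - total_C`.
#'
#' @param cebp_total,irf8_total Total concentrations (>= 0).
#' @param keq Equilibrium association constant (> 0).
#' @return List of class `cebp_irf8_partition` with components `cebp_free`,
#'   `irf8_free`, `complex` and the quadratic intermediate `b`. Mass balance
#'   (`free + complex = total`) holds to better than 1e-10.
#' @examples
#' partition_cebp_irf8(0.6, 0.4, 80)
#' @export
partition_cebp_irf8 <- function(cebp_total, irf8_total, keq) {
  if (cebp_total < 0 || irf8_total < 0)
    stop("total concentrations must be non-negative")
  if (keq <= 0) stop("keq must be positive")
  b <- irf8_total + 1 / keq - cebp_total
  cebp_free <- 0.5 * (-b + sqrt(b^2 + 4 * cebp_total / keq))
  cebp_free <- min(max(cebp_free, 0), cebp_total)
  cx <- cebp_total - cebp_free
  structure(list(cebp_free = cebp_free,
                 irf8_free = max(irf8_total - cx, 0),
                 complex = cx, b = b),
            class = "cebp_irf8_partition")
}

# Vectorized free-C/EBP solve used on hot paths.
cebp_free_of <- function(cebp_total, irf8_total, keq) {
  b <- irf8_total + 1 / keq - cebp_total
  pmin(pmax(0.5 * (-b + sqrt(b^2 + 4 * cebp_total / keq)), 0), cebp_total)
}

# Reconstruction of total C/EBP from its free form and total IRF8 (the
# inverse of the partition, used by the pseudo-steady-state closure).
cebp_total_of <- function(cebp_free, irf8_total, keq) {
  cebp_free * (1 + keq * irf8_total / (1 + keq * cebp_free))
}

#' Algebraic quantities derived from a protein state
#'
#' Computes the C/EBP:IRF8 partition, the three receptor occupancies and the
#' interaction input `W_i` for every protein, at the given state and dose.
#'
#' @param state Protein state: numeric vector of the eight activities in
#'   order PU1, CEBP (total), GFI1, EGR, IRF8 (total), MCSFR, GCSFR, GMCSFR.
#' @param dose Cytokine dose, see [cytokine_dose()].
#' @param params Model parameters, see [default_parameters()].
#' @return List with components `partition`, `occupancy` (named length-3
#'   vector of bound receptor levels) and `w` (named length-8 vector of
#'   interaction inputs).
#' @export
derived_state <- function(state, dose, params) {
  state <- as_state(state); dose <- as_dose(dose)
  part <- partition_cebp_irf8(state[["CEBP"]], state[["IRF8"]], params$keq)
  occ <- c(
    MCSFR = receptor_occupancy(dose[["MCSF"]], state[["MCSFR"]],
                               params$kd[["MCSF"]]),
    GCSFR = receptor_occupancy(dose[["GCSF"]], state[["GCSFR"]],
                               params$kd[["GCSF"]]),
    GMCSFR = receptor_occupancy(dose[["GMCSF"]], state[["GMCSFR"]],
                                params$kd[["GMCSF"]])
  )
  reg <- regulator_vector(state, part$cebp_free, occ)
  w <- params$omega0 + drop(params$omega %*% reg)
  list(partition = part, occupancy = occ, w = w)
}

# Regulator activity vector in canonical order: free C/EBP replaces total
# C/EBP and receptor occupancies replace receptor totals.
regulator_vector <- function(state, cebp_free, occ) {
  c(state[["PU1"]], cebp_free, state[["GFI1"]], state[["EGR"]],
    state[["IRF8"]], occ[["MCSFR"]], occ[["GCSFR"]], occ[["GMCSFR"]])
}

#' Interaction input for one protein
#'
#' The weighted sum `W_i = omega0_i + sum_j omega_{i,j} * regulator_j`,
#' where the regulators are the free C/EBP form and receptor:ligand
#' occupancies (never totals) as mandated by the network wiring.
#'
#' @param target Protein id, one of `PU1`, `CEBP`, `GFI1`, `EGR`, `IRF8`,
#'   `MCSFR`, `GCSFR`, `GMCSFR`.
#' @inheritParams derived_state
#' @param derived Optional precomputed [derived_state()] result.
#' @return Scalar interaction input.
#' @export
interaction_input <- function(target, state, dose, params, derived = NULL) {
  if (!(target %in% PROTEINS)) stop("unknown target protein: ", target)
  if (is.null(derived)) derived <- derived_state(state, dose, params)
  unname(derived$w[target])
}

#' Right-hand side of the eight-ODE system
#'
#' `dX_i/dt = rho_i * (H(W_i) - X_i)` with `rho_i = rho_TF` for the five
#' transcription factors and `rho_R` for the three receptors. Because
#' `H` maps into (0, 1), the flow always points into the unit box.
#'
#' @inheritParams derived_state
#' @param check Logical; reject state components outside `[0, 1]` (with a
#'   small numerical allowance). Disabled on solver hot paths.
#' @return Named numeric vector of the eight time derivatives.
#' @export
gmp_rhs <- function(state, dose, params, check = TRUE) {
  state <- as_state(state); dose <- as_dose(dose)
  if (check && (any(state < -1e-8) || any(state > 1 + 1e-8)))
    stop("state components must lie in [0, 1]")
  sc <- pmin(pmax(state, 0), 1)
  cf <- cebp_free_of(sc[[2]], sc[[5]], params$keq)
  occ <- dose * sc[6:8] / (dose + params$kd)
  reg <- c(sc[[1]], cf, sc[[3]], sc[[4]], sc[[5]], occ[[1]], occ[[2]], occ[[3]])
  w <- params$omega0 + drop(params$omega %*% reg)
  params$rho * (1 / (1 + exp(-params$sigma * w)) - sc)
}

#' Integrate the model under a constant cytokine dose
#'
#' Solves the eight-ODE system with a stiff-capable solver
#' (\code{deSolve::ode}, lsoda with root-triggered early stopping) from the
#' supplied initial state. Integration stops early once the system has
#' converged to a steady state (`max |dX/dt| <` `ss_tol`). An optional
#' pre-period prepends a cytokine-free baseline before stimulus onset.
#'
#' @param initial Initial protein state in `[0,1]^8`.
#' @param dose Constant cytokine dose.
#' @param params Model parameters.
#' @param t_end Integration horizon in model time units (1 unit ~ 2 h).
#' @param dt Output grid spacing.
#' @param pre_period Length of cytokine-free baseline to simulate before the
#'   stimulus is applied (0 disables; output times then start negative).
#' @param rtol,atol Solver tolerances.
#' @param ss_tol Steady-state stopping criterion on `max |dX/dt|`.
#' @return Object of class `gmp_trajectory`: a data frame with a `time`
#'   column and one column per protein, plus `cebp_free` and the three
#'   occupancies. Attributes: `dose`, `converged`, `final_residual`,
#'   `final_state`.
#' @examples
#' p <- default_parameters()
#' x0 <- naive_steady_state(p)
#' tr <- integrate_model(x0, cytokine_dose(mcsf = 1), p, t_end = 50)
#' tail(as.data.frame(tr), 1)
#' @export
integrate_model <- function(initial, dose, params, t_end = 300, dt = 1,
                            pre_period = 0, rtol = 1e-8, atol = 1e-10,
                            ss_tol = 1e-8) {
  initial <- as_state(initial); dose <- as_dose(dose)
  if (any(initial < -1e-9) || any(initial > 1 + 1e-9))
    stop("initial state must lie in [0, 1]")
  if (t_end <= 0) stop("t_end must be positive")

  run <- function(x0, d, times) {
    fn <- function(t, y, parms) list(unname(gmp_rhs(y, d, params,
                                                    check = FALSE)))
    root <- function(t, y, parms)
      max(abs(gmp_rhs(y, d, params, check = FALSE))) - ss_tol
    out <- deSolve::ode(y = unname(x0), times = times, func = fn,
                        rtol = rtol, atol = atol, method = "lsodar",
                        rootfunc = root)
    if (attr(out, "istate")[1] < 0)
      stop("ODE solver failed (istate = ", attr(out, "istate")[1],
           ") at dose [", paste(signif(d, 4), collapse = ", "), "]")
    out
  }

  segs <- list()
  x0 <- initial
  if (pre_period > 0) {
    pre <- run(x0, cytokine_dose(), seq(-pre_period, 0, by = dt))
    segs$pre <- pre
    x0 <- pmin(pmax(pre[nrow(pre), -1], 0), 1)
  }
  main <- run(x0, dose, seq(0, t_end, by = dt))
  segs$main <- main

  mat <- do.call(rbind, lapply(segs, unclass))
  mat <- mat[!duplicated(mat[, 1]), , drop = FALSE]
  states <- pmin(pmax(mat[, -1, drop = FALSE], 0), 1)
  colnames(states) <- PROTEINS
  cf <- cebp_free_of(states[, "CEBP"], states[, "IRF8"], params$keq)
  occ <- cbind(
    bound_mcsfr = receptor_occupancy(dose[["MCSF"]], states[, "MCSFR"],
                                     params$kd[["MCSF"]]),
    bound_gcsfr = receptor_occupancy(dose[["GCSF"]], states[, "GCSFR"],
                                     params$kd[["GCSF"]]),
    bound_gmcsfr = receptor_occupancy(dose[["GMCSF"]], states[, "GMCSFR"],
                                      params$kd[["GMCSF"]])
  )
  final <- states[nrow(states), ]
  resid <- max(abs(gmp_rhs(final, dose, params, check = FALSE)))
  df <- data.frame(time = mat[, 1], states, cebp_free = cf, occ,
                   row.names = NULL)
  structure(df, class = c("gmp_trajectory", "data.frame"),
            dose = dose, converged = resid < ss_tol * 10,
            final_residual = resid, final_state = final)
}

#' Final state of a trajectory
#' @param trajectory A `gmp_trajectory`.
#' @return Named length-8 state vector at the last time point.
#' @export
final_state <- function(trajectory) {
  stopifnot(inherits(trajectory, "gmp_trajectory"))
  attr(trajectory, "final_state")
}

#' @export
print.gmp_trajectory <- function(x, ...) {
  d <- attr(x, "dose")
  if (is.null(d)) return(NextMethod())
  cat(sprintf(
    "GMP model trajectory: %d time points, t in [%g, %g]\n",
    nrow(x), min(x$time), max(x$time)))
  cat(sprintf("  dose: MCSF = %g, GCSF = %g, GMCSF = %g\n",
              d[["MCSF"]], d[["GCSF"]], d[["GMCSF"]]))
  cat(sprintf("  converged: %s (final max |dX/dt| = %.2e)\n",
              attr(x, "converged"), attr(x, "final_residual")))
  invisible(x)
}

#' Locate the naive (unstimulated) GMP steady state
#'
#' Finds all steady states at zero dose and returns the stable fixed point
#' with the lowest combined PU.1 and total C/EBP activity -- the resting
#' progenitor from which all stimulations and population samples start.
#' With the packaged parameters it sits near (PU.1, C/EBP_T) = (0.15, 0.15).
#'
#' @param params Model parameters.
#' @param tol Residual tolerance demanded of the fixed point.
#' @return Named length-8 state vector.
#' @export
naive_steady_state <- function(params, tol = 1e-9) {
  ss <- find_steady_states(cytokine_dose(), params)
  stab <- ss[ss$stability == "stable", , drop = FALSE]
  if (nrow(stab) == 0)
    stop("no stable steady state at zero dose: parameter set is inconsistent")
  stab <- stab[order(stab$PU1 + stab$CEBP), , drop = FALSE]
  x <- as_state(unlist(stab[1, PROTEINS]))
  if (x[["PU1"]] > 0.5 || x[["CEBP"]] > 0.5)
    stop("no stable low/low (naive) fixed point found: ",
         "parameter set is inconsistent")
  resid <- max(abs(gmp_rhs(x, cytokine_dose(), params)))
  if (resid > tol)
    stop(sprintf("naive state residual %.3e exceeds tolerance %.1e",
                 resid, tol))
  x
}

#' Timing of the GM-CSF signal during differentiation
#'
#' Integrates the naive cell under a constant GM-CSF dose and tracks the
#' incoming signal strength, measured as the receptor:ligand occupancy
#' `[GMCSFR:GMCSF]`. Reports when the signal first crosses halfway between
#' its initial and maximal level, when it peaks, and the initial, peak and
#' final levels -- the signature that separates the early-strong (then
#' declining) granulopoietic signal from the late, switch-like monopoietic
#' signal.
#'
#' @param gmcsf GM-CSF dose.
#' @param params Model parameters.
#' @param t_end Integration horizon.
#' @param dt Sampling interval.
#' @return List with `t_half`, `t_peak`, `signal_start`, `signal_peak`,
#'   `signal_end` and the sampled `signal` time series (data frame).
#' @export
gm_signal_timing <- function(gmcsf, params, t_end = 150, dt = 0.25) {
  naive <- naive_steady_state(params)
  tr <- integrate_model(naive, cytokine_dose(gmcsf = gmcsf), params,
                        t_end = t_end, dt = dt)
  sig <- tr$bound_gmcsfr
  half <- (sig[1] + max(sig)) / 2
  list(t_half = tr$time[which(sig >= half)[1]],
       t_peak = tr$time[which.max(sig)],
       signal_start = sig[1], signal_peak = max(sig),
       signal_end = sig[length(sig)],
       signal = data.frame(time = tr$time, bound_gmcsfr = sig))
}
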