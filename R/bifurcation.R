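# Steady-state location, eigenvalue stability analysis and one-parameter
# continuation with saddle-node (fold) handling.

# Full-system Newton polish of a candidate fixed point. Returns the refined
# state or NULL when Newton fails to reach the residual tolerance.
newton_polish <- function(x0, dose, params, tol = 1e-12, accept = 1e-9,
                          maxit = 60) {
  x <- pmin(pmax(as_state(x0), 0), 1)
  for (it in seq_len(maxit)) {
    f <- gmp_rhs(x, dose, params, check = FALSE)
    if (any(!is.finite(f))) return(NULL)
    if (max(abs(f)) < tol) break
    J <- rhs_jacobian(x, dose, params)
    dx <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) return(NULL)
    x <- pmin(pmax(x + dx, 0), 1)
  }
  if (max(abs(gmp_rhs(x, dose, params, check = FALSE))) < accept) x else NULL
}

# Central finite-difference Jacobian of the full 8-D right-hand side.
rhs_jacobian <- function(state, dose, params, h = 1e-6) {
  J <- matrix(0, 8, 8, dimnames = list(PROTEINS, PROTEINS))
  for (j in seq_len(8)) {
    xp <- state; xm <- state
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    J[, j] <- (gmp_rhs(xp, dose, params, check = FALSE) -
                 gmp_rhs(xm, dose, params, check = FALSE)) / (2 * h)
  }
  J
}

#' Eigenvalue stability analysis of a fixed point
#'
#' Computes the eigenvalues of the finite-difference Jacobian of the full
#' eight-dimensional system at a steady state and classifies it as
#' `stable` (all real parts negative), `saddle` (mixed signs) or
#' `unstable` (all real parts positive).
#'
#' @param state A polished fixed point (residual below `resid_tol`).
#' @param dose Cytokine dose.
#' @param params Model parameters.
#' @param resid_tol Maximum `max |dX/dt|` accepted before analysis.
#' @return List with `eigenvalues` (8 complex values), `stable` (logical)
#'   and `stability` (label).
#' @export
stability <- function(state, dose, params, resid_tol = 1e-8) {
  state <- as_state(state); dose <- as_dose(dose)
  resid <- max(abs(gmp_rhs(state, dose, params, check = FALSE)))
  if (resid > resid_tol)
    stop(sprintf("state is not a fixed point (residual %.3e > %.1e)",
                 resid, resid_tol))
  ev <- eigen(rhs_jacobian(state, dose, params), only.values = TRUE)$values
  re <- Re(ev)
  label <- if (all(re < 0)) "stable" else if (all(re > 0)) "unstable"
  else "saddle"
  list(eigenvalues = ev, stable = label == "stable", stability = label)
}

#' Phenotype label of a state
#'
#' Quadrant convention on (PU.1, total C/EBP): `GMP` = low/low,
#' `GP` = low/high, `MO` = high/low, `MMDSC` = high/high.
#'
#' @param state Protein state vector.
#' @param threshold Activity level separating low from high.
#' @return One of `"GMP"`, `"GP"`, `"MO"`, `"MMDSC"`.
#' @export
phenotype_label <- function(state, threshold = 0.5) {
  state <- as_state(state)
  hi_p <- state[["PU1"]] >= threshold
  hi_c <- state[["CEBP"]] >= threshold
  if (!hi_p && !hi_c) "GMP" else if (!hi_p) "GP"
  else if (!hi_c) "MO" else "MMDSC"
}

#' Locate all steady states at a dose
#'
#' Seeds candidates from a lattice over the (PU.1, free C/EBP) unit square
#' (every Gfi-1 pseudo-steady root at each lattice point, with the six
#' slaved variables at closure), pre-screens them with a derivative-free
#' simplex minimization of the reduced objective
#' `sqrt((d[PU.1]/dt)^2 + (d[C/EBP]/dt)^2)`, polishes survivors with a full
#' eight-dimensional Newton iteration, deduplicates, and classifies each
#' fixed point by eigenvalue analysis.
#'
#' @param dose Cytokine dose.
#' @param params Model parameters.
#' @param n_seed Lattice resolution per axis. The lattice is graded: the
#'   free-C/EBP axis gets extra resolution near 0, where strong IRF8
#'   sequestration concentrates attractors.
#' @param dedup_tol Minimum pairwise distance between distinct fixed points.
#' @return Data frame of class `gmp_steady_states`: one row per fixed point
#'   with the eight state components, `residual`, `max_re` (leading
#'   eigenvalue real part), `stability` and `phenotype`.
#' @export
find_steady_states <- function(dose, params, n_seed = 25, dedup_tol = 1e-4) {
  dose <- as_dose(dose)
  grid_p <- seq(0.005, 0.995, length.out = n_seed)
  # square-law spacing: dense near cebp_free = 0 (titrated regimes)
  grid_c <- seq(sqrt(0.0005), sqrt(0.995), length.out = n_seed)^2
  cands <- list()
  for (p1 in grid_p) {
    for (cf in grid_c) {
      m <- master_rates(p1, cf, dose, params, tol = 1e-6)
      for (i in seq_len(nrow(m)))
        if (max(abs(m[i, c("dpu1", "dcebp")])) < 0.08)
          cands[[length(cands) + 1]] <- c(p1, cf, m[i, "gfi1"])
    }
  }
  fps <- list()
  obj <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    m <- master_rates(u[1], u[2], dose, params, tol = 1e-6)
    min(sqrt(m[, "dpu1"]^2 + m[, "dcebp"]^2))
  }
  for (cand in cands) {
    x0 <- pss_closure(cand[1], cand[2], cand[3], dose, params)$state
    x <- newton_polish(x0, dose, params)
    if (is.null(x)) {
      # fall back to a derivative-free simplex pre-polish of the reduced
      # objective, then retry Newton
      op <- tryCatch(
        stats::optim(cand[1:2], obj, method = "Nelder-Mead",
                     control = list(maxit = 200, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(op)) next
      seed2 <- pmin(pmax(op$par, 0), 1)
      g <- gfi1_pseudo_steady(seed2[1], seed2[2], dose, params, tol = 1e-9)
      g <- g[which.min(abs(g - cand[3]))]
      x0 <- pss_closure(seed2[1], seed2[2], g, dose, params)$state
      x <- newton_polish(x0, dose, params)
      if (is.null(x)) next
    }
    if (any(vapply(fps, function(y) max(abs(x - y)) < dedup_tol, TRUE)))
      next
    fps[[length(fps) + 1]] <- x
  }
  rows <- lapply(fps, function(x) {
    st <- stability(x, dose, params)
    data.frame(t(x),
               residual = max(abs(gmp_rhs(x, dose, params, check = FALSE))),
               max_re = max(Re(st$eigenvalues)),
               stability = st$stability,
               phenotype = phenotype_label(x))
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(matrix(numeric(0), 0, 8,
                         dimnames = list(NULL, PROTEINS)),
                  residual = numeric(0), max_re = numeric(0),
                  stability = character(0), phenotype = character(0))
  out <- out[order(out$PU1, out$CEBP), ]
  rownames(out) <- NULL
  class(out) <- c("gmp_steady_states", "data.frame")
  attr(out, "dose") <- dose
  out
}

#' @export
print.gmp_steady_states <- function(x, ...) {
  d <- attr(x, "dose")
  cols <- c(PROTEINS, "max_re", "stability", "phenotype")
  if (is.null(d) || !all(cols %in% names(x))) return(NextMethod())
  cat(sprintf("Steady states at dose MCSF = %g, GCSF = %g, GMCSF = %g\n",
              d[["MCSF"]], d[["GCSF"]], d[["GMCSF"]]))
  print.data.frame(cbind(round(as.data.frame(x)[, c(PROTEINS, "max_re")], 4),
                         as.data.frame(x)[, c("stability", "phenotype")]))
  invisible(x)
}

# Newton corrector for continuation: either solves the 8 states at fixed
# parameter value, or -- near a fold -- holds PU.1 fixed and solves the
# remaining 7 states plus the parameter value.
solve_fixed_param <- function(x0, lam, parameter, base_dose, params) {
  d <- base_dose; d[parameter] <- lam
  x <- newton_polish(x0, d, params)
  if (is.null(x)) NULL else list(x = x, lam = lam)
}

solve_fixed_comp <- function(x0, lam0, comp, parameter, base_dose, params,
                             tol = 1e-12, maxit = 60) {
  u <- c(x0[-comp], lam0)   # 7 states (one held) + parameter
  held <- x0[[comp]]
  rebuild <- function(u) {
    x <- numeric(8)
    x[-comp] <- u[1:7]; x[comp] <- held
    x
  }
  fval <- function(u) {
    d <- base_dose; d[parameter] <- max(u[8], 0)
    gmp_rhs(rebuild(u), d, params, check = FALSE)
  }
  for (it in seq_len(maxit)) {
    f <- fval(u)
    if (any(!is.finite(f))) return(NULL)
    if (max(abs(f)) < tol) break
    J <- matrix(0, 8, 8)
    h <- 1e-6
    for (j in seq_len(8)) {
      up <- u; um <- u
      up[j] <- up[j] + h; um[j] <- um[j] - h
      J[, j] <- (fval(up) - fval(um)) / (2 * h)
    }
    du <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) return(NULL)
    u[1:7] <- pmin(pmax(u[1:7] + du[1:7], 0), 1)
    u[8] <- u[8] + du[8]
  }
  if (max(abs(fval(u))) > 1e-9 || u[8] < -1e-6) return(NULL)
  list(x = as_state(rebuild(u)), lam = max(u[8], 0))
}

#' Trace a one-parameter branch of steady states
#'
#' Natural-parameter continuation of a fixed-point branch with respect to
#' one cytokine concentration. Each converged solution seeds the next step;
#' near saddle-node bifurcations, where the branch turns and the state
#' derivative with respect to the parameter diverges, the roles swap: the
#' fastest-moving master regulator (PU.1 or total C/EBP) is stepped and the
#' parameter value is solved for, carrying the branch around the fold. Fold
#' locations are recorded where the parameter direction reverses along the
#' branch.
#'
#' @param seed_state A fixed point at `seed_value` of the parameter.
#' @param parameter One of `"MCSF"`, `"GCSF"`, `"GMCSF"`.
#' @param seed_value Parameter value of the seed.
#' @param range Length-2 numeric: parameter interval to cover.
#' @param step Initial continuation step in the parameter.
#' @param base_dose Dose of the other two cytokines (default zero).
#' @param params Model parameters.
#' @param swap_slope Trigger for the role swap: max |d(master)/d(param)|
#'   above this switches to stepping the master regulator.
#' @param state_step Master-regulator step used while in swapped mode.
#' @param max_points Hard cap on branch length.
#' @return Data frame of class `gmp_branch`: columns `param` (parameter
#'   value), the eight state components, `stability`, `phenotype`, `fold`
#'   (logical marker on points where the branch turns). Attribute `folds`
#'   lists the fold parameter values.
#' @export
continue_branch <- function(seed_state, parameter, seed_value, range,
                            step = 0.005, base_dose = cytokine_dose(),
                            params, swap_slope = 20, state_step = 0.01,
                            max_points = 2000) {
  stopifnot(parameter %in% CYTOKINES)
  base_dose <- as_dose(base_dose)
  d0 <- base_dose; d0[parameter] <- seed_value
  x0 <- newton_polish(seed_state, d0, params)
  if (is.null(x0)) stop("seed_state does not polish to a fixed point")

  trace_dir <- function(dir) {
    pts <- list()
    x <- x0; lam <- seed_value
    h <- step * dir
    prev_x <- x; prev_lam <- lam
    mode <- "param"; swap_i <- 1L; swap_dir <- 1
    hs <- state_step
    for (k in seq_len(max_points)) {
      if (mode == "param") {
        lam_try <- lam + h
        if (lam_try < range[1] - 1e-12 || lam_try > range[2] + 1e-12) break
        sol <- solve_fixed_param(x, lam_try, parameter, base_dose, params)
        if (!is.null(sol) && max(abs(sol$x - x)) > 0.15)
          sol <- NULL   # jumped to another branch; treat as failure
        if (is.null(sol)) {
          h <- h / 2
          if (abs(h) < 1e-6) {
            # fold suspected: swap roles and step the faster master
            mode <- "comp"
            dx <- abs(c(x[[1]] - prev_x[[1]], x[[2]] - prev_x[[2]]))
            swap_i <- if (dx[2] > dx[1]) 2L else 1L
            swap_dir <- sign(x[[swap_i]] - prev_x[[swap_i]])
            if (swap_dir == 0) swap_dir <- 1
            h <- step * dir
            hs <- state_step
          }
          next
        }
        slope <- max(abs(sol$x[1:2] - x[1:2])) / abs(h)
        prev_x <- x; prev_lam <- lam
        x <- sol$x; lam <- sol$lam
        pts[[length(pts) + 1]] <- c(lam, x)
        if (slope > swap_slope) {
          mode <- "comp"
          dx <- abs(x[1:2] - prev_x[1:2])
          swap_i <- if (dx[2] > dx[1]) 2L else 1L
          swap_dir <- sign(x[[swap_i]] - prev_x[[swap_i]])
          if (swap_dir == 0) swap_dir <- 1
          hs <- state_step
        } else if (abs(h) < step) h <- h * 2
      } else {
        xt <- x; xt[swap_i] <- x[[swap_i]] + swap_dir * hs
        if (xt[swap_i] < 0 || xt[swap_i] > 1) break
        sol <- solve_fixed_comp(xt, lam, swap_i, parameter, base_dose,
                                params)
        if (!is.null(sol) && max(abs(sol$x - x)) > 0.15) sol <- NULL
        if (is.null(sol)) {
          hs <- hs / 2
          if (hs < 1e-6) break
          next
        }
        prev_x <- x; prev_lam <- lam
        x <- sol$x; lam <- sol$lam
        pts[[length(pts) + 1]] <- c(lam, x)
        if (lam < range[1] - 1e-12 || lam > range[2] + 1e-12) break
        # leave swapped mode when the parameter moves freely again
        if (abs(lam - prev_lam) > 1e-4 &&
            abs(x[[swap_i]] - prev_x[[swap_i]]) / abs(lam - prev_lam) <
              swap_slope / 2) {
          mode <- "param"
          h <- step * sign(lam - prev_lam)
        } else if (hs < state_step) hs <- hs * 2
      }
    }
    pts
  }

  pts <- c(rev(trace_dir(-1)), list(c(seed_value, x0)), trace_dir(1))
  mat <- do.call(rbind, pts)
  colnames(mat) <- c("param", PROTEINS)
  df <- as.data.frame(mat)
  lab <- vapply(seq_len(nrow(df)), function(i) {
    d <- base_dose; d[parameter] <- max(df$param[i], 0)
    st <- tryCatch(stability(as_state(unlist(df[i, PROTEINS])), d, params,
                             resid_tol = 1e-6),
                   error = function(e) NULL)
    if (is.null(st)) NA_character_ else st$stability
  }, "")
  df$stability <- lab
  df$phenotype <- vapply(seq_len(nrow(df)), function(i)
    phenotype_label(as_state(unlist(df[i, PROTEINS]))), "")
  # folds: sign reversals of the parameter direction along the branch
  dp <- diff(df$param)
  fold_idx <- which(sign(dp[-1]) * sign(dp[-length(dp)]) < 0) + 1
  df$fold <- seq_len(nrow(df)) %in% fold_idx
  class(df) <- c("gmp_branch", "data.frame")
  attr(df, "parameter") <- parameter
  attr(df, "folds") <- df$param[df$fold]
  df
}

#' Dose at which an attractor is lost (grid scan)
#'
#' Walks an attractor along a cytokine axis by re-polishing at each dose
#' increment; reports the first dose at which the fixed point ceases to
#' exist as a stable state (Newton failure, a jump to a distant state, or
#' loss of linear stability).
#'
#' @param state Stable fixed point at `from`.
#' @param parameter Cytokine id.
#' @param params Model parameters.
#' @param from,to Scan interval.
#' @param step Scan increment.
#' @param base_dose Other cytokines.
#' @param jump Continuity guard: a polished step moving farther than this
#'   counts as loss of the attractor.
#' @return The loss dose, or `NA` if the attractor persists to `to`.
#' @export
attractor_loss_dose <- function(state, parameter, params, from = 0, to = 1.5,
                                step = 0.01, base_dose = cytokine_dose(),
                                jump = 0.15) {
  stopifnot(parameter %in% CYTOKINES)
  x <- as_state(state)
  for (v in seq(from + step, to, by = step)) {
    d <- as_dose(base_dose); d[parameter] <- v
    xn <- newton_polish(x, d, params)
    if (is.null(xn) || max(abs(xn - x)) > jump) return(v)
    st <- stability(xn, d, params, resid_tol = 1e-6)
    if (!st$stable) return(v)
    x <- xn
  }
  NA_real_
}

#' Hysteresis scan along one cytokine axis
#'
#' Integrates the naive state to convergence at `up_value` of the chosen
#' cytokine, then withdraws the stimulus (parameter back to zero) and
#' integrates again. Reports both endpoints, their phenotypes, and whether
#' the cell returned to the naive state -- the signature of an
#' (ir)reversible commitment switch.
#'
#' @param parameter Cytokine id.
#' @param up_value Stimulation level.
#' @param params Model parameters.
#' @param t_end Integration horizon per leg.
#' @return List with `up` and `back` (trajectory endpoints), `phenotype_up`,
#'   `phenotype_back`, and `reversible` (TRUE when the final state returned
#'   to within 1e-3 of the naive state).
#' @export
hysteresis_scan <- function(parameter, up_value, params, t_end = 300) {
  stopifnot(parameter %in% CYTOKINES)
  naive <- naive_steady_state(params)
  d_up <- cytokine_dose(); d_up[parameter] <- up_value
  tr_up <- integrate_model(naive, d_up, params, t_end = t_end)
  x_up <- final_state(tr_up)
  tr_back <- integrate_model(x_up, cytokine_dose(), params, t_end = t_end)
  x_back <- final_state(tr_back)
  list(up = x_up, back = x_back,
       phenotype_up = phenotype_label(x_up),
       phenotype_back = phenotype_label(x_back),
       reversible = max(abs(x_back - naive)) < 1e-3)
}
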