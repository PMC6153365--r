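# Pseudo-phase-plane machinery: the eight-dimensional system is reduced to
# the (PU.1, C/EBP) plane by putting the other six variables at pseudo-steady
# state. Egr, IRF8 and the three receptors are explicit functions of PU.1,
# free C/EBP and Gfi-1; Gfi-1 itself is closed by a one-dimensional root
# solve on its own rate equation.

#' Pseudo-steady-state closure of the six slaved variables
#'
#' Given PU.1, free C/EBP and Gfi-1 at a fixed dose, sets Egr, IRF8 and the
#' three receptor totals so that their rate equations vanish exactly (they
#' are explicit logistic functions once the dependency order receptor ->
#' occupancy -> IRF8 is respected), and reconstructs total C/EBP from the
#' equilibrium partition.
#'
#' @param pu1,cebp_free,gfi1 Activities in `[0, 1]`.
#' @param dose Cytokine dose.
#' @param params Model parameters.
#' @return List with `state` (full named 8-vector, with `CEBP` the
#'   reconstructed total) and `occupancy` (bound receptor levels).
#' @export
pss_closure <- function(pu1, cebp_free, gfi1, dose, params) {
  dose <- as_dose(dose)
  if (any(c(pu1, cebp_free, gfi1) < -1e-12) ||
      any(c(pu1, gfi1) > 1 + 1e-12))
    stop("closure inputs must lie in [0, 1]")
  om <- params$omega; o0 <- params$omega0; sg <- params$sigma
  H <- function(id, w) 1 / (1 + exp(-sg[[id]] * w))

  egr <- H("EGR", o0[["EGR"]] + om["EGR", "PU1"] * pu1 +
             om["EGR", "GFI1"] * gfi1)
  gmcsfr <- H("GMCSFR", o0[["GMCSFR"]] + om["GMCSFR", "PU1"] * pu1 +
                om["GMCSFR", "CEBP"] * cebp_free)
  gcsfr <- H("GCSFR", o0[["GCSFR"]] + om["GCSFR", "PU1"] * pu1 +
               om["GCSFR", "CEBP"] * cebp_free +
               om["GCSFR", "GFI1"] * gfi1)
  b_gm <- dose[["GMCSF"]] * gmcsfr / (dose[["GMCSF"]] + params$kd[["GMCSF"]])
  b_g <- dose[["GCSF"]] * gcsfr / (dose[["GCSF"]] + params$kd[["GCSF"]])
  irf8 <- H("IRF8", o0[["IRF8"]] + om["IRF8", "PU1"] * pu1 +
              om["IRF8", "GMCSFR"] * b_gm + om["IRF8", "GCSFR"] * b_g)
  mcsfr <- H("MCSFR", o0[["MCSFR"]] + om["MCSFR", "PU1"] * pu1 +
               om["MCSFR", "CEBP"] * cebp_free + om["MCSFR", "EGR"] * egr +
               om["MCSFR", "GFI1"] * gfi1)
  b_m <- dose[["MCSF"]] * mcsfr / (dose[["MCSF"]] + params$kd[["MCSF"]])
  cebp_total <- cebp_total_of(cebp_free, irf8, params$keq)

  state <- c(PU1 = unname(pu1), CEBP = unname(cebp_total),
             GFI1 = unname(gfi1), EGR = unname(egr), IRF8 = unname(irf8),
             MCSFR = unname(mcsfr), GCSFR = unname(gcsfr),
             GMCSFR = unname(gmcsfr))
  list(state = state,
       occupancy = c(MCSFR = unname(b_m), GCSFR = unname(b_g),
                     GMCSFR = unname(b_gm)))
}

# d[Gfi1]/dt at closure; vectorized over gfi1 (only Egr and the bound
# G-CSFR level depend on Gfi-1).
gfi1_rate <- function(gfi1, pu1, cebp_free, dose, params) {
  om <- params$omega; o0 <- params$omega0; sg <- params$sigma
  egr <- 1 / (1 + exp(-sg[["EGR"]] * (o0[["EGR"]] + om["EGR", "PU1"] * pu1 +
                                        om["EGR", "GFI1"] * gfi1)))
  gcsfr <- 1 / (1 + exp(-sg[["GCSFR"]] *
                          (o0[["GCSFR"]] + om["GCSFR", "PU1"] * pu1 +
                             om["GCSFR", "CEBP"] * cebp_free +
                             om["GCSFR", "GFI1"] * gfi1)))
  b_g <- dose[["GCSF"]] * gcsfr / (dose[["GCSF"]] + params$kd[["GCSF"]])
  w <- o0[["GFI1"]] + om["GFI1", "CEBP"] * cebp_free +
    om["GFI1", "EGR"] * egr + om["GFI1", "GCSFR"] * b_g
  1 / (1 + exp(-sg[["GFI1"]] * w)) - gfi1
}

#' Pseudo-steady-state values of Gfi-1
#'
#' Finds every root of `d[Gfi1]/dt = 0` on `[0, 1]` (all other slaved
#' variables at closure) by recursive interval subdivision: the unit
#' interval is split into 100 subintervals, each sign change is refined by
#' splitting into 10 sub-subintervals, and so on until the bracketing
#' interval is shorter than `tol`.
#'
#' @inheritParams pss_closure
#' @param tol Width of the final bracketing interval.
#' @return Numeric vector of one or more roots (possibly three in bistable
#'   regions of the plane).
#' @export
gfi1_pseudo_steady <- function(pu1, cebp_free, dose, params, tol = 1e-9) {
  dose <- as_dose(dose)
  f <- function(g) gfi1_rate(g, pu1, cebp_free, dose, params)
  refine <- function(lo, hi, flo, fhi) {
    while (hi - lo > tol) {
      gs <- seq(lo, hi, length.out = 11)
      fs <- c(flo, f(gs[2:10]), fhi)
      i <- which(fs[-11] * fs[-1] <= 0)[1]
      lo <- gs[i]; hi <- gs[i + 1]; flo <- fs[i]; fhi <- fs[i + 1]
    }
    (lo + hi) / 2
  }
  gs <- seq(0, 1, length.out = 101)
  fs <- f(gs)
  roots <- numeric(0)
  for (i in seq_len(100)) {
    if (fs[i] == 0) roots <- c(roots, gs[i])
    else if (fs[i] * fs[i + 1] < 0)
      roots <- c(roots, refine(gs[i], gs[i + 1], fs[i], fs[i + 1]))
  }
  if (fs[101] == 0) roots <- c(roots, 1)
  if (length(roots) == 0)
    stop("no Gfi-1 pseudo-steady state found; the rate structure ",
         "guarantees at least one root, so this is a numerical fault")
  roots
}

# Rates of the two master regulators with all slaved variables (including
# Gfi-1) at pseudo-steady state. One row per Gfi-1 root, sorted ascending.
master_rates <- function(pu1, cebp_free, dose, params, tol = 1e-9) {
  roots <- sort(gfi1_pseudo_steady(pu1, cebp_free, dose, params, tol = tol))
  out <- lapply(roots, function(g) {
    cl <- pss_closure(pu1, cebp_free, g, dose, params)
    w_p <- params$omega0[["PU1"]] +
      params$omega["PU1", "PU1"] * pu1 +
      params$omega["PU1", "CEBP"] * cebp_free +
      params$omega["PU1", "GFI1"] * g +
      params$omega["PU1", "MCSFR"] * cl$occupancy[["MCSFR"]]
    w_c <- params$omega0[["CEBP"]] +
      params$omega["CEBP", "CEBP"] * cebp_free +
      params$omega["CEBP", "GMCSFR"] * cl$occupancy[["GMCSFR"]] +
      params$omega["CEBP", "GCSFR"] * cl$occupancy[["GCSFR"]]
    c(gfi1 = g,
      dpu1 = 1 / (1 + exp(-params$sigma[["PU1"]] * w_p)) - pu1,
      dcebp = 1 / (1 + exp(-params$sigma[["CEBP"]] * w_c)) -
        cl$state[["CEBP"]],
      cebp_total = cl$state[["CEBP"]])
  })
  do.call(rbind, out)
}

#' Nullclines in the (PU.1, C/EBP) pseudo-phase plane
#'
#' For the PU.1 nullcline, sweeps a grid of free C/EBP values and finds all
#' PU.1 roots of `d[PU.1]/dt = 0`; for the C/EBP nullcline, sweeps PU.1 and
#' finds all free C/EBP roots of `d[C/EBP]/dt = 0`. In both cases Gfi-1 and
#' the five explicit slaved variables sit at pseudo-steady state. When the
#' Gfi-1 closure is multivalued the computation is repeated per Gfi-1 root
#' layer. Root refinement is bisection on sign changes; points are reported
#' in total C/EBP coordinates and strung into branches by nearest-neighbor
#' continuity.
#'
#' @param which `"PU1"` or `"CEBP"`.
#' @param dose Cytokine dose.
#' @param params Model parameters.
#' @param n_grid Number of sweep abscissae on `[0, 1]`.
#' @param n_scan Number of ordinate scan points per abscissa.
#' @param tol Root tolerance on the target rate: defaults to 1e-7 for the
#'   PU.1 nullcline and 1e-8 for the C/EBP nullcline.
#' @param jump Branch-breaking threshold on the distance between consecutive
#'   points in (abscissa, ordinate) space.
#' @return Data frame with columns `which`, `branch`, `pu1`, `cebp_total`,
#'   `cebp_free`, `gfi1`, `residual`.
#' @export
nullcline <- function(which = c("PU1", "CEBP"), dose, params,
                      n_grid = 200, n_scan = 101, tol = NULL, jump = 0.05) {
  which <- match.arg(which)
  dose <- as_dose(dose)
  if (is.null(tol)) tol <- if (which == "PU1") 1e-7 else 1e-8
  comp <- if (which == "PU1") "dpu1" else "dcebp"

  rates_at <- function(absc, ord) {
    if (which == "PU1") master_rates(ord, absc, dose, params)
    else master_rates(absc, ord, dose, params)
  }
  rate_layer <- function(absc, ord, layer) {
    m <- rates_at(absc, ord)
    m[min(layer, nrow(m)), ]
  }

  pts <- list()
  for (absc in seq(0, 1, length.out = n_grid)) {
    if (absc < 0 || absc > 1) stop("grid abscissa outside [0, 1]")
    ords <- seq(0, 1, length.out = n_scan)
    sweep <- lapply(ords, function(o) rates_at(absc, o))
    nlayer <- max(vapply(sweep, nrow, 0L))
    for (layer in seq_len(nlayer)) {
      fs <- vapply(sweep, function(m) m[min(layer, nrow(m)), comp], 0)
      for (i in seq_len(n_scan - 1)) {
        if (fs[i] * fs[i + 1] < 0 || fs[i] == 0) {
          lo <- ords[i]; hi <- ords[i + 1]; flo <- fs[i]
          m <- NULL
          while (hi - lo > 1e-12) {
            mid <- (lo + hi) / 2
            m <- rate_layer(absc, mid, layer)
            fm <- m[[comp]]
            if (abs(fm) < tol) break
            if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
          }
          if (is.null(m)) m <- rate_layer(absc, lo, layer)
          o <- (lo + hi) / 2
          if (abs(m[[comp]]) <= tol) {
            pu1 <- if (which == "PU1") o else absc
            cf <- if (which == "PU1") absc else o
            pts[[length(pts) + 1]] <- data.frame(
              which = which, abscissa = absc, pu1 = pu1,
              cebp_total = m[["cebp_total"]], cebp_free = cf,
              gfi1 = m[["gfi1"]], residual = abs(m[[comp]]))
          }
        }
      }
    }
  }
  if (length(pts) == 0)
    return(data.frame(which = character(0), branch = integer(0),
                      pu1 = numeric(0), cebp_total = numeric(0),
                      cebp_free = numeric(0), gfi1 = numeric(0),
                      residual = numeric(0)))
  df <- unique(do.call(rbind, pts))
  ordv <- if (which == "PU1") df$pu1 else df$cebp_free
  df <- df[order(df$abscissa, ordv), ]
  n <- nrow(df)
  branch <- integer(n)
  used <- rep(FALSE, n)
  bid <- 0
  coords <- cbind(df$abscissa, if (which == "PU1") df$pu1 else df$cebp_free)
  while (any(!used)) {
    bid <- bid + 1
    i <- which(!used)[1]
    branch[i] <- bid; used[i] <- TRUE
    repeat {
      cand <- which(!used)
      if (length(cand) == 0) break
      d2 <- (coords[cand, 1] - coords[i, 1])^2 +
        (coords[cand, 2] - coords[i, 2])^2
      j <- cand[which.min(d2)]
      if (sqrt(min(d2)) > jump) break
      branch[j] <- bid; used[j] <- TRUE; i <- j
    }
  }
  df$branch <- branch
  rownames(df) <- NULL
  df[, c("which", "branch", "pu1", "cebp_total", "cebp_free", "gfi1",
         "residual")]
}
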