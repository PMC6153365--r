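test_that("Gfi-1 pseudo-steady roots satisfy their defining equation", {
  set.seed(3)
  for (i in 1:25) {
    p1 <- runif(1); cf <- runif(1)
    dose <- cytokine_dose(runif(1), runif(1), runif(1))
    roots <- gfi1_pseudo_steady(p1, cf, dose, params)
    expect_gte(length(roots), 1)
    for (g in roots)
      expect_lt(abs(gmpfate:::gfi1_rate(g, p1, cf, dose, params)), 1e-8)
  }
})

test_that("subdivision roots agree with a dense uniform scan plus bisection", {
  # oracle: scan d[Gfi1]/dt at step 1e-5 and bisect every sign change
  dense_roots <- function(p1, cf, dose) {
    g <- seq(0, 1, by = 1e-5)
    f <- gmpfate:::gfi1_rate(g, p1, cf, dose, params)
    out <- numeric(0)
    idx <- which(f[-length(f)] * f[-1] <= 0 & f[-length(f)] != 0)
    for (i in idx) {
      lo <- g[i]; hi <- g[i + 1]
      flo <- f[i]
      while (hi - lo > 1e-12) {
        mid <- (lo + hi) / 2
        fm <- gmpfate:::gfi1_rate(mid, p1, cf, dose, params)
        if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
      }
      out <- c(out, (lo + hi) / 2)
    }
    out
  }
  cases <- list(c(0.15, 0.02), c(0.5, 0.5), c(0.1, 0.85), c(0.9, 0.01))
  for (cs in cases) {
    for (dose in list(zero_dose, cytokine_dose(gcsf = 0.5))) {
      got <- sort(gfi1_pseudo_steady(cs[1], cs[2], dose, params))
      want <- sort(dense_roots(cs[1], cs[2], dose))
      expect_equal(length(got), length(want))
      expect_lt(max(abs(got - want)), 1e-6)
    }
  }
})

test_that("the closure reproduces a full-system fixed point", {
  cf <- partition_cebp_irf8(naive[["CEBP"]], naive[["IRF8"]],
                            params$keq)$cebp_free
  roots <- gfi1_pseudo_steady(naive[["PU1"]], cf, zero_dose, params)
  g <- roots[which.min(abs(roots - naive[["GFI1"]]))]
  expect_equal(g, naive[["GFI1"]], tolerance = 1e-6)
  cl <- pss_closure(naive[["PU1"]], cf, g, zero_dose, params)
  expect_lt(max(abs(cl$state - naive)), 1e-6)
})

test_that("closure zeroes the six slaved rate equations on random inputs", {
  set.seed(5)
  checked <- 0
  while (checked < 500) {
    p1 <- runif(1); cf <- runif(1); g <- runif(1)
    dose <- cytokine_dose(runif(1), runif(1), runif(1))
    cl <- pss_closure(p1, cf, g, dose, params)
    # (cf, IRF8) pairs whose reconstructed total exceeds 1 are outside the
    # state space; the quadrant is unreachable by the dynamics
    if (cl$state[["CEBP"]] > 1) next
    checked <- checked + 1
    r <- gmp_rhs(cl$state, dose, params, check = FALSE)
    slaved <- c("EGR", "IRF8", "MCSFR", "GCSFR", "GMCSFR")
    expect_lt(max(abs(r[slaved])), 1e-8)
  }
})

test_that("every emitted nullcline point satisfies its tolerance", {
  for (w in c("PU1", "CEBP")) {
    nc <- nullcline(w, zero_dose, params, n_grid = 41, n_scan = 51)
    expect_gt(nrow(nc), 20)
    tol <- if (w == "PU1") 1e-7 else 1e-8
    expect_true(all(nc$residual <= tol))
    expect_true(all(nc$pu1 >= 0 & nc$pu1 <= 1))
  }
})

test_that("nullcline intersections at zero dose correspond to the five fixed points", {
  nc_p <- nullcline("PU1", zero_dose, params, n_grid = 61, n_scan = 61)
  nc_c <- nullcline("CEBP", zero_dose, params, n_grid = 61, n_scan = 61)
  ss <- find_steady_states(zero_dose, params)
  expect_equal(nrow(ss), 5)
  # every fixed point lies close to both curves; distances are taken in the
  # sweep coordinates (PU.1, free C/EBP), where the grid is uniform
  for (i in seq_len(nrow(ss))) {
    cf_i <- partition_cebp_irf8(ss$CEBP[i], ss$IRF8[i],
                                params$keq)$cebp_free
    dp <- min(sqrt((nc_p$pu1 - ss$PU1[i])^2 + (nc_p$cebp_free - cf_i)^2))
    dc <- min(sqrt((nc_c$pu1 - ss$PU1[i])^2 + (nc_c$cebp_free - cf_i)^2))
    expect_lt(dp, 0.05)
    expect_lt(dc, 0.05)
  }
})

test_that("projection artifacts under G-CSF are not genuine fixed points", {
  # in the 2-D projection the curves may appear to cross more often than
  # the system has fixed points; polish every apparent crossing in 8-D and
  # count the distinct survivors
  dose <- cytokine_dose(gcsf = 1)
  nc_p <- nullcline("PU1", dose, params, n_grid = 41, n_scan = 51)
  nc_c <- nullcline("CEBP", dose, params, n_grid = 41, n_scan = 51)
  crossings <- list()
  for (i in seq_len(nrow(nc_p))) {
    d2 <- (nc_c$pu1 - nc_p$pu1[i])^2 + (nc_c$cebp_total - nc_p$cebp_total[i])^2
    if (min(d2) < 0.03^2) crossings[[length(crossings) + 1]] <-
        c(nc_p$pu1[i], nc_p$cebp_free[i], nc_p$gfi1[i])
  }
  expect_gt(length(crossings), 0)
  survivors <- list()
  for (cr in crossings) {
    x0 <- pss_closure(cr[1], cr[2], cr[3], dose, params)$state
    x <- gmpfate:::newton_polish(x0, dose, params)
    if (is.null(x)) next
    if (!any(vapply(survivors, function(y) max(abs(x - y)) < 1e-3, TRUE)))
      survivors[[length(survivors) + 1]] <- x
  }
  # the genuine census has exactly five fixed points at this dose
  expect_lte(length(survivors), 5)
  expect_equal(nrow(find_steady_states(dose, params)), 5)
})

test_that("tightening the root tolerance moves points less than the coarse tolerance", {
  nc1 <- nullcline("PU1", zero_dose, params, n_grid = 11, n_scan = 51,
                   tol = 1e-5)
  nc2 <- nullcline("PU1", zero_dose, params, n_grid = 11, n_scan = 51,
                   tol = 1e-9)
  for (i in seq_len(nrow(nc1))) {
    same <- which(abs(nc2$cebp_free - nc1$cebp_free[i]) < 1e-12)
    if (length(same) == 0) next
    expect_lt(min(abs(nc2$pu1[same] - nc1$pu1[i])), 1e-3)
  }
})
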