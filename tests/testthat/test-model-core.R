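test_that("sigmoid response has the logistic shape, symmetry and limits", {
  for (s in c(1, 4, 8)) expect_equal(sigmoid_response(0, s), 0.5)
  expect_equal(sigmoid_response(1e4, 4), 1)
  expect_equal(sigmoid_response(-1e4, 4), 0)
  for (w in c(0.3, 1.7))
    expect_equal(sigmoid_response(-w, 4), 1 - sigmoid_response(w, 4))
  w <- seq(-3, 3, by = 0.1)
  expect_true(all(diff(sigmoid_response(w, 4)) > 0))
  expect_error(sigmoid_response(NaN, 4), "finite")
  expect_error(sigmoid_response(0, -1), "positive")
})

test_that("receptor occupancy follows the binding isotherm", {
  expect_equal(receptor_occupancy(0, 0.7, 1), 0)
  expect_equal(receptor_occupancy(1, 0.8, 1), 0.4)    # half-saturation
  expect_equal(receptor_occupancy(1e9, 0.3, 1), 0.3, tolerance = 1e-8)
  # never exceeds total receptor
  for (L in c(0.1, 1, 10, 100))
    expect_lte(receptor_occupancy(L, 0.6, 0.5), 0.6)
  expect_error(receptor_occupancy(-1, 0.5, 1), "non-negative")
  expect_error(receptor_occupancy(1, 1.5, 1), "0, 1")
})

test_that("C/EBP:IRF8 partition matches a brute-force bisection oracle", {
  cases <- rbind(c(0.6, 0.4), c(0.15, 0.165), c(0.9, 0.05), c(0.3, 0.8))
  for (i in seq_len(nrow(cases))) {
    ct <- cases[i, 1]; it <- cases[i, 2]
    part <- partition_cebp_irf8(ct, it, params$keq)
    oracle <- bisect_cebp_free(ct, it, params$keq)
    expect_equal(part$cebp_free, oracle, tolerance = 1e-9)
  }
})

test_that("partition limits: no binding and complete titration", {
  part0 <- partition_cebp_irf8(0.8, 0.3, 1e-9)
  expect_equal(part0$cebp_free, 0.8, tolerance = 1e-6)
  partInf <- partition_cebp_irf8(0.8, 0.3, 1e9)
  expect_equal(partInf$cebp_free, 0.5, tolerance = 1e-6)   # T - I
})

test_that("partition mass balance and equilibrium law hold on random inputs", {
  set.seed(42)
  for (i in 1:1000) {
    ct <- runif(1); it <- runif(1); keq <- 10^runif(1, -1, 3)
    part <- partition_cebp_irf8(ct, it, keq)
    expect_lt(abs(part$cebp_free + part$complex - ct), 1e-10)
    expect_lt(abs(part$irf8_free + part$complex - it), 1e-10)
    # round-trip through the reconstruction of total C/EBP
    back <- part$cebp_free *
      (1 + keq * it / (1 + keq * part$cebp_free))
    expect_lt(abs(back - ct), 1e-10)
    if (part$complex > 1e-6)
      expect_lt(abs(keq * part$cebp_free * part$irf8_free / part$complex - 1),
                1e-8)
  }
})

test_that("interaction input reduces to the basal weight and is linear", {
  zero_state <- as_state(rep(0, 8))
  for (tg in c("PU1", "CEBP", "EGR", "GMCSFR")) {
    w0 <- interaction_input(tg, zero_state, zero_dose, params)
    expect_equal(w0, unname(params$omega0[tg]))
  }
  # doubling one regulator changes W by exactly omega * delta
  st <- as_state(c(0.2, 0, 0.3, 0.1, 0, 0.1, 0.1, 0.1))
  st2 <- st; st2[["GFI1"]] <- 0.6
  dW <- interaction_input("PU1", st2, zero_dose, params) -
    interaction_input("PU1", st, zero_dose, params)
  expect_equal(dW, unname(params$omega["PU1", "GFI1"] * 0.3))
  expect_error(interaction_input("NOTCH", st, zero_dose, params), "unknown")
})

test_that("the C/EBP input is the hand-expanded weighted sum of free C/EBP and bound receptors", {
  st <- as_state(c(0.3, 0.5, 0.2, 0.1, 0.4, 0.3, 0.6, 0.7))
  dose <- cytokine_dose(gcsf = 0.8, gmcsf = 1.2)
  cf <- partition_cebp_irf8(0.5, 0.4, params$keq)$cebp_free
  b_g <- 0.8 * 0.6 / (0.8 + params$kd[["GCSF"]])
  b_gm <- 1.2 * 0.7 / (1.2 + params$kd[["GMCSF"]])
  by_hand <- params$omega0[["CEBP"]] +
    params$omega["CEBP", "CEBP"] * cf +
    params$omega["CEBP", "GCSFR"] * b_g +
    params$omega["CEBP", "GMCSFR"] * b_gm
  expect_equal(interaction_input("CEBP", st, dose, params), by_hand)
})

test_that("rhs vanishes at fixed points and pushes the flow into the unit box", {
  expect_lt(max(abs(gmp_rhs(naive, zero_dose, params))), 1e-8)
  set.seed(7)
  for (i in 1:50) {
    dose <- cytokine_dose(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2))
    hi <- as_state(rep(1, 8))
    lo <- as_state(rep(0, 8))
    expect_true(all(gmp_rhs(hi, dose, params) < 0))
    expect_true(all(gmp_rhs(lo, dose, params) > 0))
  }
  # rates are bounded by the time-scale constants
  set.seed(8)
  for (i in 1:50) {
    st <- as_state(runif(8))
    r <- gmp_rhs(st, cytokine_dose(runif(1), runif(1), runif(1)), params)
    expect_true(all(abs(r) < params$rho + 1e-12))
  }
  expect_error(gmp_rhs(as_state(rep(2, 8)), zero_dose, params), "0, 1")
})

test_that("M-CSF immediately drives PU.1 production in the naive cell", {
  r <- gmp_rhs(naive, cytokine_dose(mcsf = 1), params)
  expect_gt(r[["PU1"]], 0)
})

test_that("integration respects the unit box from random starts and doses", {
  set.seed(11)
  for (i in 1:1000) {
    x0 <- as_state(runif(8))
    dose <- cytokine_dose(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2))
    tr <- integrate_model(x0, dose, params, t_end = 2, dt = 0.5,
                          rtol = 1e-6, atol = 1e-8)
    vals <- as.matrix(as.data.frame(tr)[, PROTEINS])
    expect_true(all(vals >= -1e-6 & vals <= 1 + 1e-6))
  }
})

test_that("the naive cell stays naive without stimulation", {
  tr <- integrate_model(naive, zero_dose, params, t_end = 200)
  expect_lt(max(abs(final_state(tr) - naive)), 1e-6)
  expect_true(attr(tr, "converged"))
})

test_that("single cytokines polarize the naive cell to the documented fates", {
  tr_m <- integrate_model(naive, cytokine_dose(mcsf = 1), params)
  xm <- final_state(tr_m)
  expect_gt(xm[["PU1"]], 0.5); expect_lt(xm[["CEBP"]], 0.5)  # monocyte
  tr_g <- integrate_model(naive, cytokine_dose(gcsf = 1), params)
  xg <- final_state(tr_g)
  expect_lt(xg[["PU1"]], 0.5); expect_gt(xg[["CEBP"]], 0.5)  # granulocyte
})

test_that("naive steady state matches its documented location and is attracting", {
  expect_equal(naive[["PU1"]], 0.15, tolerance = 0.02)
  expect_equal(naive[["CEBP"]], 0.15, tolerance = 0.02)
  st <- stability(naive, zero_dose, params)
  expect_true(all(Re(st$eigenvalues) < 0))
})

test_that("equal receptor and transcription-factor time scales are accepted", {
  p2 <- params
  p2$rho_r <- p2$rho_tf
  p2$rho[RECEPTORS] <- p2$rho_tf
  st <- naive; st[["MCSFR"]] <- 0.5   # displaced receptor, nonzero rate
  r_fast <- gmp_rhs(st, zero_dose, p2)
  r_slow <- gmp_rhs(st, zero_dose, params)
  expect_true(all(is.finite(r_fast)))
  expect_equal(unname(r_fast["MCSFR"]), 10 * unname(r_slow["MCSFR"]))
})
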