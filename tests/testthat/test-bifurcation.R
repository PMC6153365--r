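test_that("zero-dose census: five steady states, three stable, two saddles", {
  ss <- find_steady_states(zero_dose, params)
  expect_equal(nrow(ss), 5)
  expect_equal(sum(ss$stability == "stable"), 3)
  expect_equal(sum(ss$stability == "saddle"), 2)
  expect_setequal(ss$phenotype[ss$stability == "stable"],
                  c("GMP", "GP", "MO"))
  expect_true(all(ss$residual < 1e-8))
  # deduplication: pairwise distances exceed the tolerance
  if (nrow(ss) > 1) {
    st <- as.matrix(as.data.frame(ss)[, PROTEINS])
    d <- as.matrix(dist(st, method = "maximum"))
    expect_true(all(d[upper.tri(d)] > 1e-4))
  }
})

test_that("G-CSF eliminates the naive state leaving a bistable MO/GP system", {
  ss <- find_steady_states(cytokine_dose(gcsf = 1), params)
  expect_equal(nrow(ss), 5)
  stable <- ss[ss$stability == "stable", ]
  expect_equal(nrow(stable), 2)
  expect_setequal(stable$phenotype, c("MO", "GP"))
})

test_that("M-CSF stimulation removes the low/low naive attractor", {
  ss <- find_steady_states(cytokine_dose(mcsf = 1), params)
  stable <- ss[ss$stability == "stable", ]
  expect_false(any(stable$PU1 < 0.35 & stable$CEBP < 0.35))
})

test_that("stability labels agree with a perturbation-integration oracle", {
  ss <- find_steady_states(zero_dose, params)
  set.seed(19)
  for (i in seq_len(nrow(ss))) {
    x <- as_state(unlist(as.data.frame(ss)[i, PROTEINS]))
    returned <- 0
    for (k in 1:3) {
      x0 <- pmin(pmax(x + runif(8, -1e-3, 1e-3), 0), 1)
      tr <- integrate_model(x0, zero_dose, params, t_end = 200, dt = 200)
      if (max(abs(final_state(tr) - x)) < 1e-4) returned <- returned + 1
    }
    if (ss$stability[i] == "stable") expect_equal(returned, 3)
    else expect_lt(returned, 3)
  }
})

test_that("stability() rejects points that are not fixed points", {
  expect_error(stability(as_state(runif(8)), zero_dose, params),
               "not a fixed point")
})

test_that("the naive branch folds under M-CSF near half-maximal dose", {
  br <- continue_branch(naive, "MCSF", 0, c(0, 1), params = params)
  folds <- attr(br, "folds")
  expect_gte(length(folds), 1)
  expect_gt(max(folds), 0.35)
  expect_lt(max(folds), 0.65)
  # fold location consistent with an independent grid scan of attractor loss
  loss <- attractor_loss_dose(naive, "MCSF", params, step = 0.01, to = 1)
  expect_lt(abs(max(folds) - loss), 0.02)
  # branch smoothness: no jump along the branch exceeds 5x the step scale
  st <- as.matrix(as.data.frame(br)[, PROTEINS])
  expect_lt(max(abs(diff(st))), 0.15)
})

test_that("the naive state is lost at a much lower G-CSF dose than M-CSF dose", {
  loss_g <- attractor_loss_dose(naive, "GCSF", params, step = 0.01, to = 1)
  loss_m <- attractor_loss_dose(naive, "MCSF", params, step = 0.01, to = 1)
  expect_lt(loss_g, 0.35)
  expect_gt(loss_g, 0.1)
  expect_lt(loss_g, loss_m)
})

test_that("the monocyte branch folds into the hybrid state at high GM-CSF", {
  ss <- find_steady_states(zero_dose, params)
  mo <- as_state(unlist(
    as.data.frame(ss)[ss$phenotype == "MO" & ss$stability == "stable",
                      PROTEINS][1, ]))
  br <- continue_branch(mo, "GMCSF", 0, c(0, 1.5), params = params)
  folds <- attr(br, "folds")
  expect_gte(length(folds), 1)
  # the MO -> hybrid fold sits above the GM-CSF dose that destabilizes the
  # naive state, giving the documented MO/M-MDSC dichotomy
  loss_naive <- attractor_loss_dose(naive, "GMCSF", params, step = 0.02,
                                    to = 1.2)
  expect_gt(max(folds), loss_naive)
  expect_gt(max(folds), 0.7)
  expect_lt(max(folds), 1.0)
  # the branch visits both low-C (monocyte) and high-C (hybrid) regimes
  expect_lt(min(br$CEBP), 0.3)
  expect_gt(max(br$CEBP), 0.8)
})

test_that("M-CSF commitment is irreversible, sub-threshold stimulation is not", {
  hy <- hysteresis_scan("MCSF", 1, params)
  expect_equal(hy$phenotype_up, "MO")
  expect_equal(hy$phenotype_back, "MO")
  expect_false(hy$reversible)
  # the monocyte endpoint after withdrawal equals the zero-dose MO attractor
  ss <- find_steady_states(zero_dose, params)
  mo <- unlist(as.data.frame(ss)[ss$phenotype == "MO" &
                                   ss$stability == "stable", PROTEINS][1, ])
  expect_lt(max(abs(hy$back - mo)), 1e-3)

  hy_low <- hysteresis_scan("MCSF", 0.3, params)
  expect_equal(hy_low$phenotype_back, "GMP")
  expect_true(hy_low$reversible)
})

test_that("GM-CSF commitment at high dose lands in the granulocyte basin and stays there", {
  hy <- hysteresis_scan("GMCSF", 1.2, params)
  expect_equal(hy$phenotype_up, "GP")
  expect_equal(hy$phenotype_back, "GP")
  expect_false(hy$reversible)
})
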