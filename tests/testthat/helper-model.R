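# Shared fixtures: parameters and the naive state are expensive enough to
# compute once per test run.
params <- default_parameters()
naive <- naive_steady_state(params)
zero_dose <- cytokine_dose()

# Independent brute-force oracle for the free-C/EBP partition: 1-D bisection
# on the mass-action equilibrium Keq * F * (I_T - (C_T - F)) = C_T - F.
bisect_cebp_free <- function(ct, it, keq, tol = 1e-14) {
  f <- function(cf) keq * cf * (it - (ct - cf)) - (ct - cf)
  lo <- max(ct - it, 0); hi <- ct
  if (f(lo) > 0) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# internal helpers reused across tests
PROTEINS <- gmpfate:::PROTEINS
RECEPTORS <- gmpfate:::RECEPTORS
as_state <- gmpfate:::as_state
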