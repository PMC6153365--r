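# Default parameter set for the eight-protein GMP differentiation model.
#
# This is a synthetic, re-calibrated parameter set: the interaction weights
# were derived by anchoring the three unstimulated attractors (naive GMP,
# monocyte, granulocyte progenitor) at prescribed activity levels and then
# tuning the six cytokine-coupling weights and dissociation constants so the
# model reproduces the documented bifurcation structure and dose-dependent
# fate map (see the package vignette for the calibration procedure).
#
# Conventions:
#   * omega keys read "TARGET<-REGULATOR"; positive = activation,
#     negative = inhibition.
#   * Wherever C/EBP acts as a regulator the FREE (IRF8-unbound) form enters
#     the interaction sum; receptor regulators enter as receptor:ligand
#     occupancies, not receptor totals.
#   * rho.TF applies to the five transcription factors, rho.R to the three
#     receptors (ten-fold slower).
#   * One model time unit corresponds to roughly 2 hours.
omega:
  PU1<-PU1: 0.616735
  PU1<-CEBP: 0.4
  PU1<-GFI1: -0.452486
  PU1<-MCSFR: 0.35
  CEBP<-CEBP: 1.05
  CEBP<-GMCSFR: 1.4
  CEBP<-GCSFR: 0.45
  GFI1<-CEBP: 0.633569
  GFI1<-EGR: -0.267075
  GFI1<-GCSFR: 0.45
  EGR<-PU1: 0.638245
  EGR<-GFI1: -0.159934
  IRF8<-PU1: 0.501297
  IRF8<-GMCSFR: -0.45
  IRF8<-GCSFR: -0.3
  MCSFR<-PU1: 0.220024
  MCSFR<-CEBP: 0.3
  MCSFR<-EGR: 0.5
  MCSFR<-GFI1: -0.184274
  GCSFR<-PU1: 0.283052
  GCSFR<-CEBP: 0.195176
  GCSFR<-GFI1: 0.5
  GMCSFR<-PU1: 0.664215
  GMCSFR<-CEBP: 0.367601
omega0:
  PU1: -0.271749
  CEBP: -0.236938
  GFI1: -0.260081
  EGR: -0.354396
  IRF8: -0.27788
  MCSFR: -0.344976
  GCSFR: -0.370849
  GMCSFR: -0.381327
sigma:
  PU1: 8.0
  CEBP: 8.0
  GFI1: 8.0
  EGR: 8.0
  IRF8: 8.0
  MCSFR: 8.0
  GCSFR: 8.0
  GMCSFR: 8.0
rho:
  TF: 1.0
  R: 0.1
keq: 200.0
kd:
  MCSF: 1.0
  GCSF: 1.0
  GMCSF: 3.0
checksum: "3af9fc5c"
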