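# Demo material card for a glutaraldehyde-fixed bovine pericardium leaflet.
#
# SYNTHETIC PLACEHOLDER VALUES: the fitted S-N and fracture constants used
# for published leaflet life tables come from proprietary ultra-high-cycle
# pulsatile tests and are not public. The numbers below are of plausible
# magnitude for fixed pericardium and exist so demonstrations and tests can
# run end to end; do not use them for absolute durability claims.
#
# Units: stresses MPa, lengths mm, lives in cycles.
# sigma_f and beta must be calibrated on pulsatile (R = 0) tests: the Gerber
# correction maps every counted cycle onto that reference curve.
fatigue:
  su: 10.0            # MPa, nominal ultimate tensile strength
  sigma_f: 7.0        # MPa, single-cycle fatigue strength limit (pulsatile)
  beta: -0.09         # fatigue life exponent (log-log S-N slope), negative
  e_modulus: 2.0      # MPa, elastic modulus of the leaflet tissue
  hardening_exp: 0.3  # cyclic work-hardening exponent
  strength_coeff: 15.0  # MPa, cyclic strength coefficient
  paris_c: 1.0e-7     # mm/cycle per (MPa*sqrt(mm))^m
  paris_m: 3.0        # crack growth exponent
hyperelastic:
  mu0: 0.69           # MPa, initial shear modulus (E / (2 (1 + nu)))
  nu: 0.45            # Poisson's ratio
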