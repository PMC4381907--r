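# Gating-parameter file schema.
#
# VSD transition rate laws (kRI, kIR, kIA, kAI):
#   k0 : rate at 0 mV, 1/s (positive)
#   z  : equivalent valence, elementary charges (signed)
# Pore rates kCO, kOC: 1/s, voltage-independent.
# theta_*: dimensionless per-VSD coupling strengths (> 0); first letter is
#   the VSD conformation (R resting, I intermediate, A activated), second
#   the pore state (C closed, O open).  Values > 1 stabilise that channel
#   state and slow every transition leaving it.
# N: channel count.  g: maximal conductance per ion condition (arbitrary
#   units); E_rev: reversal potential per ion condition, mV.
# f_I, f_A: relative fluorescence of an intermediate / activated VSD.
# constants: F (C/mol), R (J/(mol*K)), T (K).
#
# These baseline values are the package's own KCNQ1-like calibration, not
# published estimates.
kRI: {k0: 60.0, z: 0.6}
kIR: {k0: 5.0, z: -0.8}
kIA: {k0: 0.8, z: 0.4}
kAI: {k0: 2.0, z: -0.5}
kCO: 2.0
kOC: 700.0
theta_RC: 1.0
theta_IC: 1.0
theta_AC: 1.0
theta_RO: 1.0
theta_IO: 3.0
theta_AO: 3.5
N: 1000
g: {K: 0.01, Rb: 0.007, Na: 0.0002}
E_rev: {K: -80.0, Rb: -80.0, Na: -80.0}
f_I: 0.8
f_A: 1.0
constants: {F: 96485.332, R: 8.31446, T: 298.15}
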