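# Default DPD force field for the Janus-NP / DPPC-monolayer model.
#
# Conventions: repulsion a in kBT/Rc, cutoffs R in Rc, friction gamma in
# reduced units; thermal energy kBT is the energy unit. Gas (B) pairs use
# the exponential conservative force with steepness b; all other pairs use
# the linear soft repulsion. Every unordered pair of the declared alphabet
# must appear exactly once: there is no mixing rule.
#
# Calibration (performed with this package's own engine, desk scale):
#   - water W at rho = 3, a_WW = 25 reproduces the reference pressure
#     23.7 kBT/Rc^3;
#   - the fictitious gas B at rho = 3 is matched to the same pressure via
#     a_BB so that the two phases coexist mechanically;
#   - a_BW sets the bare water-gas surface tension (gamma0, recorded below
#     in units.gamma0_reduced);
#   - K is water-like (a_KW < a_WW: net hydrophilic), L is tail-like
#     (a_LW large, a_LC < a_CC: net hydrophobic).
units:
  Rc_nm: 0.646
  rho_w: 3
  T_dpd: 0.65
  T_real: 293
  P_ref: 23.7
  gamma0_mNm: 72.8
  gamma0_reduced: 7.41
types: ["W", "B", "N", "P", "G", "C", "K", "L"]
charges: {"N": 1.0, "P": -1.0}
electrostatics: {enabled: false, coupling: 13.87, beta: 1.6, cutoff: 3.0}
gas: {density: 3.0}
templates:
  dppc: {bond_k: 150.0, bond_r0: 0.55, angle_k: 6.0, angle0_deg: 180.0}
  np: {bond_k: 500.0, spacing: 0.8}
pairs:
  - {i: "W", j: "W", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "N", j: "N", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "P", j: "P", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "G", j: "G", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "C", j: "C", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "K", j: "K", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "L", j: "L", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "N", j: "P", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "N", j: "G", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "P", j: "G", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "N", j: "W", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "P", j: "W", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "G", j: "W", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "C", j: "W", a: 55.0, R: 1.1, gamma: 4.5}
  - {i: "C", j: "N", a: 60.0, R: 1.1, gamma: 4.5}
  - {i: "C", j: "P", a: 60.0, R: 1.1, gamma: 4.5}
  - {i: "C", j: "G", a: 35.0, R: 1.0, gamma: 4.5}
  # Janus NP beads: K water-like, L tail-like
  - {i: "K", j: "W", a: 20.0, R: 1.0, gamma: 4.5}
  - {i: "K", j: "N", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "K", j: "P", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "K", j: "G", a: 25.0, R: 1.0, gamma: 4.5}
  - {i: "K", j: "C", a: 55.0, R: 1.1, gamma: 4.5}
  - {i: "K", j: "L", a: 55.0, R: 1.1, gamma: 4.5}
  - {i: "L", j: "W", a: 55.0, R: 1.1, gamma: 4.5}
  - {i: "L", j: "N", a: 60.0, R: 1.1, gamma: 4.5}
  - {i: "L", j: "P", a: 60.0, R: 1.1, gamma: 4.5}
  - {i: "L", j: "G", a: 35.0, R: 1.0, gamma: 4.5}
  - {i: "L", j: "C", a: 23.0, R: 1.0, gamma: 4.5}
  # fictitious gas phase: exponential (hardcore-like) conservative force
  - {i: "B", j: "B", a: 11.7, R: 1.0, gamma: 4.5, style: exp, b: 3.0}
  - {i: "B", j: "W", a: 38.0, R: 1.1, gamma: 4.5, style: exp, b: 4.0}
  - {i: "B", j: "N", a: 38.0, R: 1.1, gamma: 4.5, style: exp, b: 4.0}
  - {i: "B", j: "P", a: 38.0, R: 1.1, gamma: 4.5, style: exp, b: 4.0}
  - {i: "B", j: "G", a: 38.0, R: 1.1, gamma: 4.5, style: exp, b: 4.0}
  - {i: "B", j: "C", a: 25.0, R: 1.0, gamma: 4.5, style: exp, b: 4.0}
  - {i: "B", j: "K", a: 38.0, R: 1.1, gamma: 4.5, style: exp, b: 4.0}
  - {i: "B", j: "L", a: 25.0, R: 1.0, gamma: 4.5, style: exp, b: 4.0}
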