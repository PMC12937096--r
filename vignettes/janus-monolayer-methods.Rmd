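---
title: "Modelling Janus nanoparticles at DPPC monolayers with dissipative particle dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Janus nanoparticles at DPPC monolayers with dissipative particle dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`janusdpd` simulates amphiphilic Janus nanoparticles (JNPs) interacting
with a dipalmitoylphosphatidylcholine (DPPC) monolayer at the air-water
interface, the standard single-lipid model of the lung-surfactant film.
The dynamics is dissipative particle dynamics (DPD): soft pairwise
conservative forces

\[ F^C_{ij}(r) = a_{ij}\,(1 - r/R_{ij})\,\hat r_{ij}, \qquad r < R_{ij}, \]

plus the pairwise dissipative and random forces

\[ F^D_{ij} = -\gamma\, w^2(r)\,(\mathbf v_{ij}\cdot \hat r_{ij})\,\hat r_{ij},
   \qquad F^R_{ij} = \sigma\, w(r)\, \theta_{ij}\, \hat r_{ij}, \]

with \(w = 1 - r/R_{ij}\) and \(\sigma^2 = 2 k_B T \gamma\)
(fluctuation-dissipation), which together form a momentum-conserving
thermostat. Harmonic bonds and angles hold molecules together, and an
optional smeared-charge Coulomb force (exponentially screened at short
range, truncated in direct sum) is available for the zwitterionic
headgroups.

Standard DPD cannot hold a liquid slab against vacuum - the fluid is
purely repulsive - so the air phase is modelled by *fictitious gas beads*
(type B) at liquid-like density whose conservative interaction is the
exponential law

\[ F^{\exp}_{Bj}(r) = a_{Bj}\,
   \frac{e^{b_{Bj} r/R_{Bj}} - e^{b_{Bj}}}{1 - e^{b_{Bj}}}\,\hat r_{ij}. \]

For \(b > 0\) this places a steep force wall at the entry into the
interaction range (slope about \(b\)-fold the linear law at \(r \to R\))
that saturates at \(a_{Bj}\) toward contact - a hardcore-like barrier.
During development we also evaluated the opposite reading of
"steep at contact" (\(b < 0\), a decaying exponential force): it cannot
sustain any water-gas surface tension at realistic amplitudes, so the
wall-at-range form is the one shipped.

### Units

Lengths are in the water-bead size \(R_c = 0.646\) nm (one bead is three
water molecules, bead density \(\rho = 3/R_c^3\)), energies in thermal
units \(k_BT\), and the reduced temperature is \(T_{DPD} = 0.65\),
mapping to 293 K. Interaction constants in the force-field files are in
\(k_BT/R_c\); the engine multiplies them by \(T_{DPD}\) internally and
converts pressures and tensions back to \(k_BT/R_c^3\) and
\(k_BT/R_c^2\) on output. This convention was fixed by an independent
Monte-Carlo check of the water equation of state: at \(a/k_BT = 25\) and
\(\rho = 3\) the virial pressure is 23.65, matching the reference value
23.7 used as the barostat target, whereas reading \(a = 25\) in absolute
units at \(T = 0.65\) gives 22.8. One reduced tension unit is
\(k_B \cdot 293\,\mathrm{K} / R_c^2 = 9.694\) mN/m.

## Force-field calibration

The published interaction table of the parent parameterization was not
available to this build, so the `default` bundle is calibrated
internally, interface by interface, with the package's own engine
(the `si` bundle is a drop-in template for the published values):

* **Water**: \(a_{WW} = 25\), the textbook DPD water at \(\rho = 3\);
  reduced pressure 23.65-23.7.
* **Gas phase**: B beads at density 3 with \(a_{BB} = 11.7\)
  (\(b = 3\)) reproduce the same bulk pressure, so the two phases
  coexist mechanically at the reference pressure.
* **Water-gas**: \(a_{BW} = 38\) (\(b = 4\), \(R = 1.1\)) gives a bare
  interfacial tension \(\gamma_0 = 7.413\,k_BT/R_c^2 = 71.9\) mN/m
  against the experimental 72.8 mN/m at 293 K. The in-model value is
  stored in the force-field file (`gamma0_reduced`) and is the default
  \(\gamma_0\) in the surface-pressure definition
  \(\Pi = \gamma_0 - \gamma_m\); the experimental value is available via
  `gamma_zero(us, "experimental")`.
* **Lipid tails**: tail-water repulsion \(a_{CW} = 55\) at \(R = 1.1\)
  is matched to an alkane-water slab tension near 50 mN/m, and tail-gas
  \(a_{BC} = 25\) to an alkane-air tension near 25 mN/m. These two
  interfacial tensions are what make the DPPC monolayer at
  \(a_L = 0.6\) nm\(^2\) reduce the bare tension by only a few mN/m
  (\(\Pi \approx 5\text{-}8\) mN/m across desk-scale realisations), as a
  Langmuir film in the
  liquid-expanded/liquid-condensed (LE-LC) coexistence plateau should.
* **Janus NP beads**: K is water-like (\(a_{KW} = 20 < 25\): net
  hydrophilic) and L tail-like (\(a_{LW} = 55\), \(a_{LC} = 23 < 25\)).
  This ordering fixes the sign pattern of the contact energies
  (below): \(\epsilon_{KW} < 0\), \(\epsilon_{LW} > 0\),
  \(\epsilon_{LC} < 0\).

Electrostatics ships disabled in the default bundle: the headgroups are
net-neutral zwitterions, their packing here is dominated by the soft
repulsions, and the direct-sum smeared-charge solver (no mesh) would
slow desk-scale runs considerably. Setting
`electrostatics: enabled: true` in the force-field file activates
\(\pm 1\) charges on the choline and phosphate beads.

## System construction

`build_system()` places everything deterministically (lattice plus
seeded jitter and a short soft-push relaxation) instead of calling an
external packing program - every system is reproducible from its spec
and seed. A double monolayer covers both faces of a central water slab,
tails toward the gas phase, which keeps the box z-symmetric with two
equivalent interfaces; when an NP is requested one copy adheres to each
leaflet so the symmetry is retained. The full-size study system is
1400 lipids per leaflet at \(a_L = 0.6\) nm\(^2\)
(\(L_x = L_y \approx 44.6 R_c\)) with a 12-nm NP;
`scale_system(factor)` divides the lipid count by `factor` and shrinks
the NP radius by \(\sqrt{factor}\), preserving the area per lipid, all
densities, and the NP footprint as a fraction of the interface.

Janus NPs are built on a cubic lattice (spacing 0.8 \(R_c\)) inside a
sphere; all beads above the plane \(z_{local} = R_{NP} - h\) are typed
hydrophobic (L), which makes the surface coverage equal
\(\phi_L = h/D_{NP}\) up to lattice discretisation. Beads are bonded to
their axial nearest neighbours *and* to face-diagonal neighbours: an
axial-only cubic lattice has zero-energy shear modes, and test runs
showed its radius of gyration drifting by >10% in water; with the
diagonal braces \(R_G\) is constant to better than 1% as required of a
rigid particle. The 0.8-\(R_c\) spacing (rather than a sparser
one-bead-per-\(R_c^3\) lattice) keeps the particle impermeable to the
soft DPD solvent.

The DPPC molecule has 14 beads - choline N, phosphate P, two glycerol
G beads, and two tails of five C beads (three to four heavy-atom groups
per bead) - with harmonic bonds (\(k = 150\,k_BT/R_c^2\),
\(r_0 = 0.55 R_c\)) and straight-angle restraints along the tails
(\(k = 6\,k_BT/\mathrm{rad}^2\)), chosen so the pure film at
\(a_L = 0.6\) nm\(^2\) sits in LE-LC coexistence (mean tail order
\(S \approx 0.3\text{-}0.4\), LC fraction 20-30%).

## Dynamics

The integrator is the modified velocity-Verlet scheme standard in DPD,
with \(\lambda = 0.65\) velocity prediction for the dissipative force
and \(\Delta t = 0.01\) reduced time (kinetic temperature accurate to
better than 1% at the default friction \(\gamma = 4.5\)). Pair noise is
*counter-based*: \(\theta_{ij}\) is hashed from (seed, step, bead pair),
which makes \(\theta_{ij} = \theta_{ji}\) exact, trajectories
bit-reproducible for a fixed seed, and restarts independent of history.
Exactly overlapping beads receive a deterministic tie-break direction
hashed from the pair identity.

NPT stages use a Berendsen rescaling barostat (isotropic, semi-isotropic
x=y/z, or z-only; z-only is the default for interfacial systems built at
fixed area) with the target pressure 23.7 \(k_BT/R_c^3\). The staged
protocol mirrors the study design: a short NPT stage with the film and
NP beads made 50-fold heavier (water and gas equilibrate around an
almost immobile film), an NPT stage at actual masses, then NVT
production.

The virial pressure tensor uses conservative (pair, bonded,
electrostatic) forces only; the monolayer tension is
\(\gamma_m = \tfrac{L_z}{2}\big(P_{zz} - \tfrac{P_{xx}+P_{yy}}{2}\big)\)
with the factor \(\frac12\) for the two equivalent interfaces.

## Observables

* **Orientation**: the NP director \(\mathbf u\) points from the
  hydrophobic-cap to the hydrophilic-cap centre of mass;
  \(\Theta_{NP} = \arccos(\mathbf u \cdot \hat n)\) against the
  leaflet's outward normal, so lipophile adhesion (LA) starts near 0 deg
  and an intercalated particle reads 180 deg.
* **Tail order / phases**: per lipid, \(S = \frac12(3\cos^2\theta - 1)\)
  averaged over the two tails (tail vector = first to last tail bead);
  \(S > 0.6\) labels the LC phase, and the LC density is
  \(f_{LC} = n_L(S > 0.6)/A_{res}\) with
  \(A_{res} = L_xL_y - A_I^{NP}\).
* **NP interfacial area**: by default the sphere cross-section at the
  interface plane (the per-leaflet mean phosphate height, recomputed per
  frame), \(\pi(R_{NP}^2 - d^2)\); a bead-projection census (occupied
  lattice-sized grid cells in a one-lattice-plane slab) is available as
  a sensitivity alternative, agreeing with the geometric footprint to
  about 20%.
* **Lipid loss**: the printed quantity \(n_L^w\) has no formula in the
  source narrative, so the package formalises it as a cluster rule: tail
  beads within 1 \(R_c\) connect lipids of a leaflet; a lipid is lost
  when it is outside the largest connected cluster of its leaflet, or
  when all ten tail beads touch NP beads (coated). The threshold is an
  argument.
* **Effective area per lipid**:
  \(a_L^{eff} = (L_xL_y - A_I^{NP})/(n_L - n_L^w)\).

## Contact-energy surface-energy decomposition

The surface energy of the JNP-monolayer system is
\(E_S = E_{NP} + E_{m}'\), with
\(E_m' = \gamma_m (L_xL_y - A_I^{NP})\) and
\(E_{NP} = \sum_j (\epsilon_{Kj} n_{Kj} + \epsilon_{Lj} n_{Lj})\).
The bead-bead contact energies are RDF-weighted averages of the mismatch
potential \(\Delta V_{\alpha j} = V_{\alpha j} - \frac12(V_{\alpha\alpha}
+ V_{jj})\):

\[ \epsilon_{\alpha j} = \frac{\int_0^{R_{\alpha j}} \Delta V_{\alpha j}(r)\,
   g_{\alpha j}(r)\, r^2\, dr}{\int_0^{R_{\alpha j}} g_{\alpha j}(r)\,
   r^2\, dr}, \]

with \(g_{\alpha j}\) estimated from dilute-bead bulk runs (a few tagged
K or L beads, about one per 500 host beads, in a bath of the other
type). With \(g \equiv 1\) and equal cutoffs the quadrature has the
closed form \(\Delta a\, R/20\), which the tests use as an oracle.
Contacts are counted at the pair interaction cutoff \(R_{\alpha j}\)
(the integral's own upper limit) and, by default, only for NP surface
beads (lattice beads with a missing axial neighbour); an all-beads
variant is a switch.

## Problem sizes and what the desk-scale runs show

The package's own study conditions are scaled-down versions of the full
system (which needs roughly half a million beads and millions of steps):
the standard checks use 50-200 lipids per leaflet, a 2.3-4.5 nm NP
(`scale_system` factors 7-28), staged protocols of 1,000 + 2,000-3,000
equilibration steps and 8,000-96,000 production steps, and bulk boxes of
7-10 \(R_c\). At these sizes the three mechanism outcomes - hydrophilic
translocation, hydrophobic coating, and the coat-rotate-intercalate
pathway at \(\phi_L = 0.5\) with its transient tilted configuration -
are reproduced, as are the water reference pressure, the bare air-water
tension, and the few-mN/m monolayer surface pressure of the plateau
region. The flip is a
rotation-limited rare event whose waiting time grows steeply with
particle size (probes at lattice radii 3.5, 2.1 and 1.8 \(R_c\) flipped
at roughly 120,000+, 60,000-95,000 and 16,000-100,000 steps depending on
the realisation), which is why the rotation-pathway demonstration runs
at the smallest scale with an adaptive stop on the orientation angle.

What scaled runs do *not* establish quantitatively: flip timing is
stochastic (different seeds flip at visibly different times, and small
particles rotate more easily than the 12-nm study particle, a size
dependence the full-scale study itself flags); the surface-pressure
elevation by an adsorbed fully hydrophobic particle is exaggerated
relative to the large system because the particle's own interfacial
stress carries a larger relative weight in a small box; and long-time
lipid-loss/reassociation statistics are out of reach. The synthetic
systems also idealise real films: one lipid species, no cholesterol or
surfactant proteins, no charges by default, and a fictitious gas phase
whose only physical content is the pressure and tension it exerts.

## Numerical choices and degenerate inputs

Tie-breaks for exactly overlapping beads are deterministic unit vectors
hashed from the pair identity. Angle forces vanish smoothly at the
colinear equilibrium (the \(1/\sin\theta\) factor is guarded).
Berendsen scale factors are clamped to \(\pm 0.2\%\) per step. The
barostat acts on instantaneous virial pressures; tension averages should
always be taken over the NVT production stage. RDF bins default to
0.02 \(R_c\) and contact-energy quadrature to a 400-point trapezoid
grid (halving either changes \(\epsilon\) by well under 1%). A box
smaller than three cells per direction falls back to an exact all-pairs
search. Uniform particles (\(\phi_L \in \{0, 1\}\)) have no director;
their orientation is reported `NA`, never 0.

## Interfaces

Everything is driven from R: `build_system()`, `run_dpd()` /
`run_protocol()`, the observables, `contact_energy_table()`,
`run_scenario()` and `coverage_scan()` are the package's operational
surface, with `scripts/acceptance.R` as a worked command-line entry
point. Trajectories can be exported and re-read as extended-XYZ text
(`write_xyz()` / `read_xyz()`), and per-frame metrics as tab-separated
tables (`write_metrics()`).
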