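# janusdpd

Dissipative particle dynamics (DPD) of amphiphilic Janus nanoparticles
(JNPs) at DPPC lipid monolayers — the standard single-lipid model of the
lung-surfactant film at the air–water interface.

Inhaled nanoparticles meet the lung surfactant film first. How a particle
with one hydrophilic and one hydrophobic face interacts with that film —
whether it punches through into the water subphase, sits on top coated by
lipids, or wedges itself between the lipids as another amphiphile — depends
on its hydrophobic surface coverage φ_L and on which face touches the film
first. `janusdpd` is a desk-scale simulator and analysis pipeline for
exactly this problem: it builds the systems, runs the dynamics, and
measures the interfacial observables that distinguish the three outcomes.

## The model

DPD beads interact through soft pairwise forces

    F_C(r) = a_ij (1 − r/R_ij) r̂          (conservative)
    F_D(r) = −γ w²(r) (v_ij · r̂) r̂        (dissipative)
    F_R(r) = σ w(r) θ_ij r̂,  σ² = 2 k_B T γ  (random)

with w = 1 − r/R_ij; the last two form a momentum-conserving thermostat.
The air phase is made of fictitious gas beads (B) whose conservative force
is exponential,

    F_exp(r) = a_Bj (e^(b r/R) − e^b) / (1 − e^b) r̂,

a hardcore-like wall at the interaction range that lets DPD hold a
quantitative air–water interface (bare tension γ₀ ≈ 72 mN/m in the shipped
calibration). Lengths are in R_c = 0.646 nm, energies in k_BT, reduced
temperature T_DPD = 0.65 ↔ 293 K; one reduced tension unit is 9.69 mN/m.

Key observables:

* monolayer tension γ_m = (L_z/2)(P_zz − (P_xx+P_yy)/2) from the virial
  pressure tensor, and surface pressure Π = γ₀ − γ_m;
* NP orientation Θ_NP = arccos(u · ẑ), u the unit vector from the
  hydrophobic-cap to the hydrophilic-cap centre of mass;
* lipid tail order S = (3 cos²θ − 1)/2 (two-tail average), the
  liquid-condensed fraction (S > 0.6) and LC density f_LC;
* effective area per lipid a_L^eff = (L_xL_y − A_I^NP)/(n_L − n_L^w);
* the contact-energy surface-energy decomposition E_S = E_NP + E_m′ with
  ε_αj = ∫ΔV g r²dr / ∫g r²dr estimated from dilute-bead RDF runs.

See the methods vignette (`vignettes/janus-monolayer-methods.Rmd`) for the
full account: unit conventions, force-field calibration, builders, the
integrator and barostat, observable definitions, and known desk-scale
limitations.

## Worked example

Build bulk DPD water, run it, and check the equation of state:

```r
library(janusdpd)

ff <- default_forcefield()
st <- build_bulk("W", box = 10, density = 3, seed = 1)
st <- init_velocities(st, T_dpd = 0.65, seed = 1)
r  <- run_dpd(st, ff, nsteps = 20000, engine_config(seed = 1))
mean((r$obs$Pxx + r$obs$Pyy + r$obs$Pzz) / 3)
#> [1] 23.66  # reduced pressure, kBT/Rc^3: the model's reference pressure
```

Run a scaled-down JNP scenario (half-hydrophobic particle, lipophile
adhesion) and read off the summary:

```r
r5 <- run_scenario(phi_L = 0.5, mode = "la", ff = ff, scale = 28, seed = 1,
                   production = 8000, equil1 = 1000, equil2 = 3000,
                   until_oriented = TRUE, max_production = 96000)
r5$summary[c("mechanism", "theta_deg", "apl_eff_nm2")]
#> $mechanism   [1] "intercalation"
#> $theta_deg   [1] 168       # degrees: hydrophilic cap now points at the water
#> $apl_eff_nm2 [1] 0.544     # nm^2: the intercalated NP excludes area
```

The particle first gets coated by the monolayer (Θ_NP ≈ 0–40°), then flips
through a tilted transient and intercalates (Θ_NP → 180°), compressing the
film: the effective area per lipid drops below the nominal 0.6 nm² and the
surface pressure rises above the pure-monolayer value. A purely hydrophilic
particle (`phi_L = 0`) instead translocates into the water subphase, and a
purely hydrophobic one (`phi_L = 1`) stays adsorbed and coated.

`run_pure_monolayer()` gives the reference film (Π ≈ 5–7 mN/m at
a_L = 0.6 nm² in the default calibration, run-to-run), `coverage_scan()` tabulates
Π(φ_L), f_LC(φ_L) and a_L^eff(φ_L), and `contact_energy_table()` computes
the bead–bead contact energies behind the surface-energy decomposition.

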