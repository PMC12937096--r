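# Shared fixtures: tiny force fields and states built in code.

# minimal water-only force field (one pair)
ff_water_only <- function(a = 25, R = 1, gamma = 4.5) {
  forcefield_from_list(list(
    types = list("W"),
    pairs = list(list(i = "W", j = "W", a = a, R = R, gamma = gamma))))
}

# two-type force field with a gas (exponential) cross pair
ff_two_type <- function(a_WW = 25, a_BB = 11.7, a_BW = 38, b = 4, R_BW = 1.1) {
  forcefield_from_list(list(
    types = list("W", "B"),
    pairs = list(
      list(i = "W", j = "W", a = a_WW, R = 1, gamma = 4.5),
      list(i = "B", j = "B", a = a_BB, R = 1, gamma = 4.5,
           style = "exp", b = 3),
      list(i = "B", j = "W", a = a_BW, R = R_BW, gamma = 4.5,
           style = "exp", b = b))))
}

# ideal-gas force field: single type, zero repulsion
ff_ideal <- function() ff_water_only(a = 0)

# two beads at a given separation along x, in a roomy box
state_two_beads <- function(r, types = c("W", "W"), box = 12,
                            charge = c(0, 0)) {
  dpd_state(pos = rbind(c(1, 1, 1), c(1 + r, 1, 1)), type = types,
            box = rep(box, 3), charge = charge)
}

# a lone lipid in a box, positioned from the template
state_one_lipid <- function(ff = default_forcefield(), box = 12) {
  lip <- build_dppc(ff)
  pos <- sweep(lip$pos, 2, c(box / 2, box / 2, 2), "+")
  dpd_state(pos, lip$type, rep(box, 3), charge = lip$charge,
            bonds = lip$bonds, bond_k = lip$bond_k, bond_r0 = lip$bond_r0,
            angles = lip$angles, angle_k = lip$angle_k,
            angle_theta0 = lip$angle_theta0,
            mol_kind = rep("lipid", 14),
            meta = list(lipid_first = 1L, lipid_leaflet = 2L, np = list()))
}

# deterministic pseudo-random positions without touching the global RNG
fixture_positions <- function(n, box, seed = 1) {
  janusdpd:::withr_seed(seed, matrix(runif(3 * n, 0, box), n, 3))
}

# default force field, loaded once per test session
ff_default_cached <- local({
  ff <- NULL
  function() {
    if (is.null(ff)) ff <<- default_forcefield()
    ff
  }
})
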