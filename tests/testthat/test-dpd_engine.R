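# Engine-level force laws, integration and invariants. dpd_forces() returns
# forces in internal units (k_BT values scaled by T_dpd); tests divide by T
# where they compare against the k_BT-unit force laws.

test_that("linear conservative force follows a(1 - r/R) with a sharp cutoff", {
  expect_equal(pair_force(0, 25, 1), 25)
  expect_equal(pair_force(1, 25, 1), 0)
  expect_equal(pair_force(0.5, 25, 1), 12.5)
  expect_equal(pair_force(1.7, 25, 1.5), 0) # beyond cutoff
  # engine agrees with the formula, Newton's third law by construction
  ff <- ff_water_only()
  T <- ff$units$T_dpd
  for (r in c(0.25, 0.5, 0.9)) {
    st <- state_two_beads(r)
    f <- dpd_forces(st, ff)$forces
    expect_equal(f[1, 1] / T, -25 * (1 - r), tolerance = 1e-12)
    expect_equal(f[1, ], -f[2, ])
  }
})

test_that("exponential gas force matches its closed form and decreases", {
  # a = 1, b = 2, r/R = 0.5 -> (e - e^2)/(1 - e^2)
  expect_equal(pair_force(0.5, 1, 1, "exp", b = 2),
               (exp(1) - exp(2)) / (1 - exp(2)), tolerance = 1e-12)
  expect_equal(pair_force(0.5, 1, 1, "exp", b = 2), 0.7310, tolerance = 1e-4)
  expect_equal(pair_force(0, 5, 1.1, "exp", b = 4), 5)  # contact value = a
  expect_equal(pair_force(1.1, 5, 1.1, "exp", b = 4), 0) # cutoff
  r <- seq(0, 0.99, 0.01)
  f <- pair_force(r, 5, 1, "exp", b = 4)
  expect_true(all(diff(f) < 0)) # strictly decreasing for b > 0
  # hardcore-like: entering the interaction range (r -> R from below) the
  # force rises about b-fold steeper than the linear law
  expect_gt(abs(f[100] - f[99]), 2 * abs(diff(pair_force(r[99:100], 5, 1))[1]))
  expect_error(pair_force(0.5, 5, 1, "exp", b = 0), "b != 0")
})

test_that("overlapping beads get a deterministic non-zero push", {
  ff <- ff_water_only()
  st <- state_two_beads(0)
  f1 <- dpd_forces(st, ff)$forces
  f2 <- dpd_forces(st, ff)$forces
  expect_equal(f1, f2)
  expect_equal(sqrt(sum(f1[1, ]^2)) / ff$units$T_dpd, 25, tolerance = 1e-10)
  expect_equal(f1[1, ], -f1[2, ])
})

test_that("dissipative and random forces vanish at the cutoff and conserve momentum", {
  ff <- ff_water_only()
  st <- state_two_beads(1.0) # exactly at R: w = 0
  st$vel <- rbind(c(0.3, 0, 0), c(-0.2, 0.1, 0))
  f <- dpd_forces(st, ff, with_dr = TRUE, step = 3)$forces
  expect_equal(max(abs(f)), 0)
  st2 <- state_two_beads(0.6)
  st2$vel <- st$vel
  f2 <- dpd_forces(st2, ff, with_dr = TRUE, step = 3)$forces
  expect_equal(f2[1, ], -f2[2, ]) # pairwise antisymmetric
  # pair noise is symmetric and reproducible: same seed/step -> same force
  f3 <- dpd_forces(st2, ff, with_dr = TRUE, step = 3)$forces
  expect_identical(f2, f3)
  f4 <- dpd_forces(st2, ff, with_dr = TRUE, step = 4)$forces
  expect_false(identical(f2, f4))
})

test_that("bonded forces are the exact negative gradient of the energy", {
  ff <- ff_default_cached()
  st <- state_one_lipid(ff)
  # bend the template so bonds and angles are strained
  janusdpd:::withr_seed(7, {
    st$pos <- st$pos + matrix(runif(42, -0.12, 0.12), 14, 3)
  })
  ref <- dpd_forces(st, ff)
  etot <- function(s) {
    e <- dpd_forces(s, ff)
    e$e_pair + e$e_bond + e$e_angle + e$e_elec
  }
  h <- 1e-5
  T <- ff$units$T_dpd
  for (i in c(1, 3, 7, 14)) for (d in 1:3) {
    sp <- st; sp$pos[i, d] <- sp$pos[i, d] + h
    sm <- st; sm$pos[i, d] <- sm$pos[i, d] - h
    fnum <- -(etot(sp) - etot(sm)) / (2 * h)
    expect_equal(ref$forces[i, d] / T, fnum,
                 tolerance = 1e-4 * max(1, abs(fnum)))
  }
  # equilibrium template: no bonded forces at all
  st0 <- state_one_lipid(ff)
  f0 <- dpd_forces(st0, ff)
  expect_equal(f0$e_bond, 0, tolerance = 1e-20)
})

test_that("smeared-charge electrostatics is finite at contact and Coulombic far away", {
  ff <- forcefield_from_list(list(
    types = list("N", "P"),
    charges = list("N" = 1, "P" = -1),
    electrostatics = list(enabled = TRUE, coupling = 13.87, beta = 1.6,
                          cutoff = 3.0),
    pairs = list(list(i = "N", j = "N", a = 0, R = 1),
                 list(i = "P", j = "P", a = 0, R = 1),
                 list(i = "N", j = "P", a = 0, R = 1))))
  T <- ff$units$T_dpd
  pref <- 13.87 / (4 * pi) # kBT units
  fx <- function(r, q2 = -1) {
    st <- state_two_beads(r, types = c("N", "P"), charge = c(1, q2))
    dpd_forces(st, ff)$forces[1, 1] / T
  }
  # attraction: force on bead 1 points toward bead 2 (+x)
  expect_gt(fx(0.8), 0)
  # no divergence near contact
  expect_lt(abs(fx(1e-4)), 1)
  # point-Coulomb asymptotics well beyond the smearing length
  r <- 2.9
  expect_equal(abs(fx(r)), pref / r^2, tolerance = 0.01)
  # zero charges -> zero force
  st <- state_two_beads(0.8, types = c("N", "P"), charge = c(0, 0))
  expect_equal(max(abs(dpd_forces(st, ff)$forces)), 0)
  # net charge warns
  st2 <- state_two_beads(0.8, types = c("N", "N"), charge = c(1, 1))
  expect_warning(dpd_forces(st2, ff), "net charge")
})

test_that("cell-list pair search equals brute force with periodic images", {
  box <- c(7, 6, 8)
  brute <- function(pos, box, rc) {
    n <- nrow(pos)
    out <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- minimum_image(pos[i, ] - pos[j, ], box)
      if (sum(d^2) < rc^2) out <- rbind(out, c(i, j))
    }
    out
  }
  key <- function(m) if (is.null(m) || nrow(m) == 0) character(0) else
    paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  for (seed in 1:10) {
    pos <- fixture_positions(150, 6, seed = seed)
    pr <- neighbor_pairs(pos, box, 1.0)
    expect_setequal(key(pr$pairs), key(brute(pos, box, 1.0)))
  }
  # pair straddling the boundary is found
  pos <- rbind(c(0.05, 3, 3), c(6.9, 3, 3))
  pr <- neighbor_pairs(pos, box, 1.0)
  expect_equal(nrow(pr$pairs), 1)
  expect_equal(pr$dist, 0.15, tolerance = 1e-9)
  # empty system -> empty list; cutoff larger than the box errors
  expect_equal(nrow(neighbor_pairs(matrix(numeric(), 0, 3), box, 1)$pairs), 0)
  expect_error(neighbor_pairs(pos, box, 7.5), "cutoff")
})

test_that("with no forces and no velocities the state is invariant", {
  ff <- ff_water_only(a = 0, gamma = 0)
  st <- build_bulk("W", 5, 1, seed = 2)
  r <- run_dpd(st, ff, 50, engine_config(seed = 1, obs_stride = 0L))
  expect_equal(r$state$pos, st$pos)
  expect_equal(max(abs(r$state$vel)), 0)
})

test_that("trajectories are bit-reproducible for a fixed seed", {
  ff <- ff_water_only()
  st <- init_velocities(build_bulk("W", 5, 3, seed = 3), 0.65, 3)
  cfg <- engine_config(seed = 11, obs_stride = 0L)
  r1 <- run_dpd(st, ff, 200, cfg)
  r2 <- run_dpd(st, ff, 200, cfg)
  expect_identical(r1$state$pos, r2$state$pos)
  expect_identical(r1$state$vel, r2$state$vel)
  r3 <- run_dpd(st, ff, 200, engine_config(seed = 12, obs_stride = 0L))
  expect_false(identical(r1$state$pos, r3$state$pos))
})

test_that("thermostat holds the kinetic temperature and conserves momentum", {
  ff <- ff_water_only()
  st <- init_velocities(build_bulk("W", 6, 3, seed = 4), 0.65, 4)
  r <- run_dpd(st, ff, 3000, engine_config(seed = 5, obs_stride = 10L))
  late <- r$obs[r$obs$step > 500, ]
  expect_equal(mean(late$Tkin), 0.65, tolerance = 0.02)
  p <- colSums(r$state$vel * r$state$mass)
  expect_lt(max(abs(p)) / n_beads(st), 1e-10)
})

test_that("the pressure tensor splits into kinetic and virial parts", {
  ff <- ff_water_only()
  st <- state_two_beads(0.5)
  pt <- pressure_tensor(st, ff)
  expect_equal(pt$total, pt$kinetic + pt$virial)
  expect_equal(unname(pt$kinetic), c(0, 0, 0)) # no velocities yet
  # two beads separated along x: virial = F * r / V on xx only
  expect_equal(unname(pt$virial),
               c(25 * 0.5 * 0.5 / prod(st$box), 0, 0), tolerance = 1e-12)
  st <- init_velocities(st, 0.65, 1)
  pt2 <- pressure_tensor(st, ff)
  expect_true(all(pt2$kinetic >= 0))
})

test_that("an ideal gas reproduces P = rho kT on every diagonal component", {
  ff <- ff_ideal()
  st <- init_velocities(build_bulk("W", 6, 3, seed = 5), 0.65, 5)
  r <- run_dpd(st, ff, 1500, engine_config(seed = 6, obs_stride = 10L))
  late <- r$obs[r$obs$step > 300, ]
  # reported pressures are in kBT/Rc^3: ideal value = rho = 3
  for (cmp in c("Pxx", "Pyy", "Pzz"))
    expect_equal(mean(late[[cmp]]), 3, tolerance = 0.03)
})

test_that("the Berendsen barostat drives the pressure toward its target", {
  ff <- ff_water_only()
  st <- init_velocities(build_bulk("W", 6, 3, seed = 6), 0.65, 6)
  cfg <- engine_config(ensemble = "npt", pmode = "iso", ptarget = 20,
                       taup = 1.0, seed = 7, obs_stride = 20L)
  r <- run_dpd(st, ff, 2500, cfg)
  late <- r$obs[r$obs$step > 1500, ]
  expect_equal(mean((late$Pxx + late$Pyy + late$Pzz) / 3), 20,
               tolerance = 0.05)
  expect_gt(r$state$box[1], st$box[1]) # expanded toward lower pressure
})

test_that("heavy (frozen-stage) beads are nearly immobile", {
  ff <- ff_water_only()
  st <- build_bulk("W", 6, 3, seed = 8)
  heavy <- seq_len(n_beads(st)) <= n_beads(st) / 2
  st$mass[heavy] <- 50
  st <- init_velocities(st, 0.65, 8)
  p0 <- st$pos
  r <- run_dpd(st, ff, 500, engine_config(seed = 9, obs_stride = 0L))
  disp <- rowSums(minimum_image(r$state$pos - p0, st$box)^2)
  expect_lt(mean(disp[heavy]) / mean(disp[!heavy]), 0.15)
})

test_that("staged protocols chain stages and restore masses", {
  ff <- ff_default_cached()
  mono <- monolayer_spec(n_lipids = 16, water_thickness = 5,
                         gas_thickness = 6)
  st <- init_velocities(build_system(mono, ff, seed = 2), 0.65, 2)
  prot <- list(list(steps = 50, ensemble = "npt", pmode = "z",
                    mass_scale = 50),
               list(steps = 50, ensemble = "nvt", traj_stride = 25))
  r <- run_protocol(st, ff, prot, engine_config(seed = 2, obs_stride = 25L))
  expect_equal(sort(unique(r$obs$stage)), 1:2)
  expect_equal(r$state$mass, st$mass) # masses restored after the stage
  expect_equal(length(r$frames), 3)   # initial + 2 strided frames
  expect_equal(r$step_end, 100)
})

test_that("a zero-step protocol returns the initial frame only", {
  ff <- ff_water_only()
  st <- init_velocities(build_bulk("W", 5, 3, seed = 9), 0.65, 9)
  r <- run_dpd(st, ff, 0, engine_config(seed = 1, traj_stride = 10L,
                                        obs_stride = 10L))
  expect_equal(length(r$frames), 1)
  expect_equal(r$frames[[1]]$pos, st$pos, tolerance = 1e-12)
})
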