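test_that("DPPC lipids have the 14-bead head/tail architecture", {
  ff <- ff_default_cached()
  lip <- build_dppc(ff)
  expect_length(lip$type, 14)
  expect_equal(sum(lip$type == "C"), 10)
  expect_equal(lip$type[1:4], c("N", "P", "G", "G"))
  expect_equal(nrow(lip$bonds), 13) # a 14-bead tree
  # connected tree: every bead reachable
  comp <- janusdpd:::uf_components(14, lip$bonds)
  expect_equal(length(unique(comp)), 1)
  expect_equal(sum(lip$charge), 0) # zwitterion
})

test_that("cap typing follows the coverage-height relation h = phi * D", {
  spec <- jnp_spec(radius = 3, phi_L = 0.3)
  expect_equal(spec$h, 0.3 * 6)
  expect_equal(spec$phi_L, spec$h / spec$diameter) # exact closure
  expect_error(jnp_spec(3, phi_L = 1.2), "phi_L")
  expect_error(jnp_spec(3, spacing = 0), "spacing")
  expect_error(jnp_spec(1, spacing = 0.8), "radius")
})

test_that("uniform caps give uniform particles", {
  np0 <- build_jnp(jnp_spec(2.4, phi_L = 0))
  expect_true(all(np0$type == "K"))
  np1 <- build_jnp(jnp_spec(2.4, phi_L = 1))
  expect_true(all(np1$type == "L"))
})

test_that("half-covered particles expose about half their surface as hydrophobic", {
  # 12-nm-diameter particle: R = 9.3 Rc at Rc = 0.646 nm
  np <- build_jnp(jnp_spec(9.3, phi_L = 0.5, spacing = 0.8))
  expect_true(all(rowSums(sweep(np$pos, 2, colMeans(np$pos))^2) <= 9.3^2 + 1e-9))
  expect_equal(np$phi_surface, 0.5, tolerance = 0.06) # lattice discretisation
  # surface fraction converges toward phi with finer lattices
  np_fine <- build_jnp(jnp_spec(9.3, phi_L = 0.5, spacing = 0.5))
  expect_lte(abs(np_fine$phi_surface - 0.5), abs(np$phi_surface - 0.5) + 0.01)
  # bond graph connected, bonds between nearest lattice neighbours only
  comp <- janusdpd:::uf_components(nrow(np$pos), np$bonds)
  expect_equal(length(unique(comp)), 1)
  bl <- sqrt(rowSums((np$pos[np$bonds[, 1], ] - np$pos[np$bonds[, 2], ])^2))
  # axial nearest neighbours plus face-diagonal braces
  expect_true(all(abs(bl - 0.8) < 1e-9 | abs(bl - 0.8 * sqrt(2)) < 1e-9))
  expect_equal(bl, np$bond_r0)
})

test_that("nanoparticles stay rigid during dynamics (constant R_G)", {
  ff <- ff_default_cached()
  np <- build_jnp(jnp_spec(2.4, phi_L = 0.5), center = c(4, 4, 4))
  st <- dpd_state(np$pos, np$type, rep(8, 3), bonds = np$bonds,
                  bond_k = np$bond_k, bond_r0 = np$bond_r0,
                  mol_kind = rep("np", nrow(np$pos)))
  # immerse in water
  set.seed(1)
  wat <- janusdpd:::fill_region(8, 8, 0, 8, 3,
                                excl = list(c(4, 4, 4, 2.8)))
  stw <- dpd_state(rbind(st$pos, wat),
                   c(st$type, rep("W", nrow(wat))), rep(8, 3),
                   bonds = np$bonds, bond_k = np$bond_k, bond_r0 = np$bond_r0)
  stw <- init_velocities(stw, 0.65, 1)
  rg <- function(p) {
    d <- sweep(p, 2, colMeans(p))
    sqrt(mean(rowSums(d^2)))
  }
  ids <- seq_len(nrow(np$pos))
  rg0 <- rg(stw$pos[ids, ])
  r <- run_dpd(stw, ff, 1000, engine_config(seed = 1, obs_stride = 0L))
  # centre the particle before unwrapping-free R_G (it stays compact)
  p <- r$state$pos[ids, ]
  p <- p - rep(1, nrow(p)) %o% p[1, ]
  p <- minimum_image(p, stw$box)
  expect_equal(rg(p), rg0, tolerance = 0.01)
})

test_that("monolayer geometry reproduces the lateral box of the study system", {
  us <- unit_system()
  mono <- monolayer_spec(n_lipids = 1400, apl_nm2 = 0.6, us = us)
  expect_equal(mono$Lx, 44.6, tolerance = 0.01) # ~44.6 Rc
  expect_equal(mono$Lx * mono$Ly, 1400 * 0.6 / us$Rc_nm^2)
})

test_that("built systems have the layered geometry and per-leaflet bookkeeping", {
  ff <- ff_default_cached()
  mono <- monolayer_spec(n_lipids = 36, water_thickness = 6,
                         gas_thickness = 8)
  st <- build_system(mono, ff, seed = 3)
  expect_equal(length(st$meta$lipid_first), 72) # both leaflets
  expect_equal(sum(st$meta$lipid_leaflet == 2), 36)
  # tails point at the gas phase: top-leaflet tail ends above the P beads
  lb <- janusdpd:::lipid_beads(st)
  top <- lb$leaflet == 2
  expect_true(all(st$pos[lb$tail1[top, 2], 3] > st$pos[lb$P[top], 3]))
  expect_true(all(st$pos[lb$tail1[!top, 2], 3] < st$pos[lb$P[!top], 3]))
  # water confined to the central slab, gas outside it
  zw <- st$pos[st$mol_kind == "water", 3]
  zg <- st$pos[st$mol_kind == "gas", 3]
  expect_true(max(zw) < max(zg) && min(zw) > min(zg))
  # builder determinism
  st2 <- build_system(mono, ff, seed = 3)
  expect_identical(st$pos, st2$pos)
  st3 <- build_system(mono, ff, seed = 4)
  expect_false(identical(st$pos, st3$pos))
})

test_that("adhesion modes set the initial orientation angle", {
  ff <- ff_default_cached()
  mono <- monolayer_spec(n_lipids = 36, water_thickness = 6,
                         gas_thickness = 10)
  jnp <- jnp_spec(radius = 2, phi_L = 0.5)
  la <- build_system(mono, ff, jnp = jnp, mode = "la", seed = 1)
  expect_lt(orientation(la, "top")$theta_deg, 10)
  expect_lt(orientation(la, "bot")$theta_deg, 10)
  ha <- build_system(mono, ff, jnp = jnp, mode = "ha", seed = 1)
  expect_gt(orientation(ha, "top")$theta_deg, 170)
  # NP too large for the gas slab is a geometric error
  expect_error(build_system(mono, ff, jnp = jnp_spec(radius = 6, phi_L = 0.5),
                            mode = "la", seed = 1), "fit")
})

test_that("without an NP the effective area reduces to the bare area per lipid", {
  ff <- ff_default_cached()
  mono <- monolayer_spec(n_lipids = 36, water_thickness = 6,
                         gas_thickness = 8)
  st <- build_system(mono, ff, seed = 5)
  expect_equal(np_interfacial_area(st, "top"), 0)
  ea <- effective_area(st$box[1] * st$box[2], 0, 36, 0, ff$units)
  expect_equal(ea$apl_eff, st$box[1] * st$box[2] / 36)
  expect_equal(ea$apl_eff_nm2, 0.6, tolerance = 1e-9)
})

test_that("scale_system preserves the area per lipid and shrinks the bead budget", {
  us <- unit_system()
  mono <- monolayer_spec(n_lipids = 1400, apl_nm2 = 0.6, us = us)
  jnp <- jnp_spec(radius = 9.3, phi_L = 0.5)
  id <- scale_system(mono, jnp, factor = 1)
  expect_equal(id$mono$n_lipids, 1400)
  expect_equal(id$jnp$radius, 9.3)
  sc <- scale_system(mono, jnp, factor = 7)
  expect_equal(sc$mono$n_lipids, 200)
  expect_equal(sc$mono$apl_nm2, 0.6)
  expect_equal(sc$jnp$radius, 9.3 / sqrt(7))
  # bead census of the scaled system stays desk-sized
  area <- sc$mono$Lx * sc$mono$Ly
  n_est <- 2 * sc$mono$n_lipids * 14 +
    area * sc$mono$water_thickness * us$rho_w +
    area * sc$mono$gas_thickness * 3 +
    2 * (4 / 3) * pi * sc$jnp$radius^3 / sc$jnp$spacing^3
  expect_lt(n_est, 40000)
  expect_error(scale_system(mono, jnp, factor = 0.5), "factor")
})
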