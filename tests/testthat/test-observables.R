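# synthetic state with one "NP" of two beads (K above L or similar) and
# no lipids, for orientation geometry
state_toy_np <- function(posK, posL, leaflet = 2L) {
  pos <- rbind(posK, posL)
  dpd_state(pos, c("K", "L"), rep(10, 3), mol_kind = rep("np", 2),
            meta = list(np = list(top = list(
              ids = 1:2, surface = c(TRUE, TRUE),
              spec = jnp_spec(2, 0.5), leaflet = leaflet))))
}

test_that("orientation angle spans 0/90/180 degrees for canonical directors", {
  up <- state_toy_np(c(5, 5, 6), c(5, 5, 4))      # u = +z, outward normal +z
  expect_equal(orientation(up, "top")$theta_deg, 0)
  down <- state_toy_np(c(5, 5, 4), c(5, 5, 6))    # u = -z
  expect_equal(orientation(down, "top")$theta_deg, 180)
  side <- state_toy_np(c(4, 5, 5), c(6, 5, 5))    # u in-plane
  expect_equal(orientation(side, "top")$theta_deg, 90)
  # bottom leaflet measures against the outward normal -z
  up_b <- state_toy_np(c(5, 5, 6), c(5, 5, 4), leaflet = 1L)
  expect_equal(orientation(up_b, "top")$theta_deg, 180)
  # compactness across the periodic boundary is handled
  wrap <- state_toy_np(c(5, 5, 0.5), c(5, 5, 9.5))
  expect_equal(orientation(wrap, "top")$theta_deg, 0)
})

test_that("orientation is reported absent for uniform particles", {
  st <- state_toy_np(c(5, 5, 6), c(5, 5, 4))
  st$type <- c("K", "K")
  expect_true(is.na(orientation(st, "top")$theta_deg))
})

test_that("surface tension and pressure follow the tensor identity", {
  us <- unit_system(gamma0_reduced = 7.41)
  iso <- surface_tension(2, 2, 2, Lz = 30, us)
  expect_equal(iso$gamma_m, 0)
  one <- surface_tension(0, 0, 1, Lz = 10, us)
  expect_equal(one$gamma_m, 5)
  # Pi + gamma_m = gamma0 identically, in both unit systems
  g0 <- gamma_zero(us)
  for (pz in c(-1, 0.3, 2)) {
    r <- surface_tension(0.1, 0.4, pz, Lz = 25, us)
    expect_equal(r$Pi + r$gamma_m, g0)
    expect_equal(r$Pi_mNm + r$gamma_m_mNm, convert_tension(g0, us))
  }
})

# build a small monolayer state and overwrite tail positions analytically
oriented_tail_state <- function(direction) {
  ff <- ff_default_cached()
  mono <- monolayer_spec(n_lipids = 16, water_thickness = 5,
                         gas_thickness = 6)
  st <- build_system(mono, ff, seed = 1, minimize = FALSE)
  lb <- janusdpd:::lipid_beads(st)
  for (i in seq_along(lb$first)) {
    for (tails in list(lb$tail1[i, ], lb$tail2[i, ])) {
      base <- st$pos[tails[1], ]
      st$pos[tails[2], ] <- base + 2 * direction
    }
  }
  st
}

test_that("tail order parameter is 1 along the normal and -1/2 in plane", {
  st_up <- oriented_tail_state(c(0, 0, 1))
  expect_equal(tail_order(st_up)$lipids$S, rep(1, 32))
  st_flat <- oriented_tail_state(c(1, 0, 0))
  expect_equal(tail_order(st_flat)$lipids$S, rep(-0.5, 32))
})

test_that("isotropically oriented tails average to S = 0", {
  # Monte-Carlo oracle of <(3 cos^2 theta - 1)/2> over uniform directions
  n <- 10000
  u <- janusdpd:::withr_seed(42, {
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  })
  S <- (3 * u[, 3]^2 - 1) / 2
  expect_equal(mean(S), 0, tolerance = 0.02)
})

test_that("LC density rises as the effective area shrinks at fixed lipid count", {
  st <- oriented_tail_state(c(0, 0, 1)) # all lipids LC
  A <- st$box[1] * st$box[2]
  f0 <- tail_order(st, leaflet = 2L, A_np = 0)$f_lc
  f1 <- tail_order(st, leaflet = 2L, A_np = 0.4 * A)$f_lc
  expect_gt(f1, f0)
  ea0 <- effective_area(A, 0, 16, 0)
  ea1 <- effective_area(A, 0.4 * A, 16, 0)
  expect_lt(ea1$apl_eff, ea0$apl_eff)
})

test_that("NP interfacial area is the sphere cross-section at the plane", {
  ff <- ff_default_cached()
  mono <- monolayer_spec(n_lipids = 36, water_thickness = 6,
                         gas_thickness = 10)
  st <- build_system(mono, ff, jnp = jnp_spec(radius = 2, phi_L = 0.5),
                     mode = "la", seed = 1, minimize = FALSE)
  R <- 2
  ids <- st$meta$np$top$ids
  plane <- janusdpd:::interface_plane(st, 2L)
  move_np_to <- function(zc) {
    p <- st$pos
    cur <- mean(p[ids, 3])
    p[ids, 3] <- p[ids, 3] - cur + zc
    p
  }
  expect_equal(np_interfacial_area(st, "top", pos = move_np_to(plane)),
               pi * R^2, tolerance = 1e-6)
  expect_equal(np_interfacial_area(st, "top", pos = move_np_to(plane + R)), 0)
  expect_equal(np_interfacial_area(st, "top", pos = move_np_to(plane + R / 2)),
               0.75 * pi * R^2, tolerance = 1e-6)
  # bead-projection alternative agrees with the footprint within ~20%
  Ab <- np_interfacial_area(st, "top", pos = move_np_to(plane),
                            method = "beads")
  expect_gt(Ab, 0.6 * pi * R^2)
  expect_lt(Ab, 1.4 * pi * R^2)
})

test_that("lipid-loss census counts detached lipids and micelles", {
  ff <- ff_default_cached()
  mono <- monolayer_spec(n_lipids = 64, water_thickness = 8,
                         gas_thickness = 8)
  st0 <- build_system(mono, ff, seed = 2)
  # relax briefly so tails splay into realistic contact networks
  st0 <- init_velocities(st0, 0.65, 2)
  st <- run_dpd(st0, ff, 400, engine_config(seed = 2, obs_stride = 0L))$state
  expect_equal(lipid_loss(st)$n_lw, 0) # intact monolayer
  # displace one top-leaflet lipid deep into the water slab
  lb <- janusdpd:::lipid_beads(st)
  i <- which(lb$leaflet == 2)[1]
  ids <- lb$first[i]:(lb$first[i] + 13)
  st1 <- st
  st1$pos[ids, 3] <- st1$pos[ids, 3] - 5
  loss <- lipid_loss(st1)
  expect_equal(loss$n_lw, 1)
  expect_true(loss$lipids$detached[i])
  # a compact 20-lipid micelle in the water slab is fully counted
  st2 <- st
  mic <- which(lb$leaflet == 2)[1:20]
  ctr <- c(st2$box[1] / 2, st2$box[2] / 2, st2$box[3] / 2)
  dirs <- janusdpd:::withr_seed(4, {
    u <- matrix(rnorm(60), 20, 3)
    u / sqrt(rowSums(u^2))
  })
  for (k in seq_along(mic)) {
    ids <- lb$first[mic[k]]:(lb$first[mic[k]] + 13)
    # heads out, tails toward the centre
    d <- dirs[k, ]
    st2$pos[ids, ] <- rep(1, 14) %o% (ctr + 2.2 * d) -
      outer(seq(0, 1.8, length.out = 14), d)
  }
  loss2 <- lipid_loss(st2)
  expect_equal(loss2$n_lw, 20)
})

test_that("effective area per lipid follows the residual-area arithmetic", {
  us <- unit_system()
  A <- 840 / us$Rc_nm^2 # 840 nm^2 in Rc^2
  expect_equal(effective_area(A, 0, 1400, 0, us)$apl_eff_nm2, 0.6)
  A_np <- 113 / us$Rc_nm^2 # 12-nm NP equator
  expect_equal(effective_area(A, A_np, 1400, 0, us)$apl_eff_nm2,
               (840 - 113) / 1400)
  expect_equal(effective_area(A, 0, 1400, 100, us)$apl_eff_nm2, 840 / 1300)
  expect_error(effective_area(A, 0, 100, 100, us), "n_res")
})
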