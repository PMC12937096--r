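#' 14-bead DPPC lipid template
#'
#' Coarse-grained DPPC: choline (N), phosphate (P), two glycerol-backbone
#' beads (G) and two tails of five alkyl beads (C) each - an
#' N1-P1-G2-C10 layout with 14 beads and 13 bonds (a tree). Tail angles
#' are restrained straight. Coordinates are a straight-chain template with
#' the head at the origin and the tails extending toward +z; the system
#' builder rotates/translates copies into leaflets.
#'
#' @param ff a `dpd_forcefield` providing the `templates$dppc` constants
#'   (`bond_k`, `bond_r0`, `angle_k`, `angle0_deg`).
#' @return list with `pos` (14 x 3), `type`, `charge`, `bonds`, `bond_k`,
#'   `bond_r0`, `angles`, `angle_k`, `angle_theta0`, and index helpers
#'   `head`, `tail1`, `tail2`.
#' @export
build_dppc <- function(ff = default_forcefield()) {
  tpl <- ff$templates$dppc
  for (nm in c("bond_k", "bond_r0", "angle_k", "angle0_deg"))
    if (is.null(tpl[[nm]])) stop("dppc template is missing constant ", nm)
  r0 <- tpl$bond_r0
  type <- c("N", "P", "G", "G", rep("C", 10))
  # head stack N-P-G3, G4 offset laterally; tails rise from G3 and G4
  pos <- matrix(0, 14, 3)
  pos[1, ] <- c(0, 0, 0)            # N
  pos[2, ] <- c(0, 0, r0)           # P
  pos[3, ] <- c(0, 0, 2 * r0)       # G3
  pos[4, ] <- c(r0, 0, 2 * r0)      # G4
  for (k in 1:5) pos[4 + k, ] <- c(0, 0, (2 + k) * r0)        # tail 1
  for (k in 1:5) pos[9 + k, ] <- c(r0, 0, (2 + k) * r0)      # tail 2
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4),
                 c(3, 5), c(5, 6), c(6, 7), c(7, 8), c(8, 9),
                 c(4, 10), c(10, 11), c(11, 12), c(12, 13), c(13, 14))
  angles <- rbind(c(3, 5, 6), c(5, 6, 7), c(6, 7, 8), c(7, 8, 9),
                  c(4, 10, 11), c(10, 11, 12), c(11, 12, 13), c(12, 13, 14))
  charge <- numeric(14)
  if (ff$elec$enabled) {
    charge[1] <- ff$charge["N"]
    charge[2] <- ff$charge["P"]
  }
  list(pos = pos, type = type, charge = charge,
       bonds = bonds, bond_k = rep(tpl$bond_k, nrow(bonds)),
       bond_r0 = rep(r0, nrow(bonds)),
       angles = angles, angle_k = rep(tpl$angle_k, nrow(angles)),
       angle_theta0 = rep(tpl$angle0_deg * pi / 180, nrow(angles)),
       head = 1:4, tail1 = 5:9, tail2 = 10:14)
}

#' Specification of a cubic-lattice Janus nanoparticle
#'
#' @param radius nanoparticle radius R_NP in Rc.
#' @param phi_L hydrophobic surface coverage in `[0, 1]`; the hydrophobic
#'   spherical cap height is `h = phi_L * 2 * radius`.
#' @param spacing cubic-lattice constant in Rc.
#' @param bond_k nearest-neighbour harmonic bond constant (k_BT/Rc^2);
#'   strong by default so the particle stays rigid (constant radius of
#'   gyration).
#' @return a `jnp_spec` list, including the derived cap height `h` and
#'   diameter.
#' @export
jnp_spec <- function(radius, phi_L = 0.5, spacing = 0.8, bond_k = 500) {
  if (phi_L < 0 || phi_L > 1) stop("phi_L must lie in [0, 1]")
  if (spacing <= 0) stop("lattice spacing must be positive")
  if (radius < 2 * spacing) stop("nanoparticle radius below 2 lattice spacings")
  structure(list(radius = radius, diameter = 2 * radius, phi_L = phi_L,
                 h = phi_L * 2 * radius, spacing = spacing, bond_k = bond_k),
            class = "jnp_spec")
}

#' Build a Janus nanoparticle on a cubic lattice
#'
#' Beads occupy cubic-lattice sites within `radius` of the centre and are
#' bonded to their nearest lattice neighbours with strong harmonic bonds.
#' The hydrophobic cap consists of all beads whose coordinate along the cap
#' axis exceeds `radius - h` (solid-cap typing, so the reported coverage
#' equals `h / D` up to lattice discretisation). Surface beads are lattice
#' beads with fewer than six nearest neighbours.
#'
#' @param spec a [jnp_spec()].
#' @param axis cap axis (unit vector); the hydrophobic (L) cap apex points
#'   along `+axis`.
#' @param center nanoparticle centre.
#' @return list with `pos`, `type` (`"K"`/`"L"`), `bonds`, `bond_k`,
#'   `bond_r0`, `surface` (logical), `spec`, `axis` and the realised
#'   surface hydrophobic fraction `phi_surface`.
#' @export
build_jnp <- function(spec, axis = c(0, 0, 1), center = c(0, 0, 0)) {
  s <- spec$spacing
  R <- spec$radius
  axis <- axis / sqrt(sum(axis^2))
  m <- ceiling(R / s)
  g <- expand.grid(x = -m:m, y = -m:m, z = -m:m)
  # offset by half a spacing so no bead sits exactly at the centre plane
  p <- as.matrix(g) * s
  keep <- rowSums(p^2) <= R^2
  p <- p[keep, , drop = FALSE]
  n <- nrow(p)
  # nearest-neighbour bonds on the lattice
  key <- function(ix) paste(ix[, 1], ix[, 2], ix[, 3])
  idx <- as.matrix(g)[keep, , drop = FALSE]
  lookup <- new.env(hash = TRUE, size = n)
  kk <- key(idx)
  for (i in seq_len(n)) assign(kk[i], i, envir = lookup)
  # axial nearest neighbours plus face-diagonal braces: an axial-only
  # cubic lattice has zero-energy shear modes and would not keep R_G
  # constant under solvent stress
  offsets <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                   c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                   c(0, 1, 1), c(0, 1, -1))
  bi <- integer(0); bj <- integer(0); blen <- numeric(0)
  for (d in seq_len(nrow(offsets))) {
    nb <- sweep(idx, 2, offsets[d, ], "+")
    knb <- key(nb)
    r_off <- s * sqrt(sum(offsets[d, ]^2))
    for (i in seq_len(n)) {
      j <- lookup[[knb[i]]]
      if (!is.null(j)) {
        bi <- c(bi, i); bj <- c(bj, j); blen <- c(blen, r_off)
      }
    }
  }
  bonds <- cbind(bi, bj)
  axial <- abs(blen - s) < 1e-9
  if (n > 1 && nrow(bonds) == 0) stop("degenerate lattice: no bonds")
  # cap typing along the axis
  saxis <- drop(p %*% axis)
  type <- ifelse(saxis >= R - spec$h, "L", "K")
  if (spec$phi_L == 0) type[] <- "K"
  if (spec$phi_L == 1) type[] <- "L"
  # surface beads: at least one missing axial nearest neighbour
  tab <- tabulate(c(bi[axial], bj[axial]), nbins = n)
  surface <- tab < 6L
  pos <- sweep(p, 2, center, "+")
  list(pos = pos, type = type, bonds = bonds,
       bond_k = rep(spec$bond_k, nrow(bonds)),
       bond_r0 = blen,
       surface = surface, spec = spec, axis = axis,
       phi_surface = mean(type[surface] == "L"))
}

#' Specification of a double-monolayer air/water system
#'
#' Two DPPC leaflets cover the two faces of a water slab (heads toward
#' water, tails toward the gas phase); dense fictitious gas beads fill the
#' remaining volume so the whole box sits at the reference bead density.
#' The lateral box satisfies `Lx * Ly = n_lipids * a_L`.
#'
#' @param n_lipids lipids per leaflet.
#' @param apl_nm2 area per lipid in nm^2.
#' @param water_thickness water-slab thickness in Rc.
#' @param gas_thickness total gas thickness (both slabs combined) in Rc.
#' @param us a [unit_system()] (for the nm -> Rc conversion).
#' @export
monolayer_spec <- function(n_lipids = 1400, apl_nm2 = 0.6,
                           water_thickness = 10, gas_thickness = 14,
                           us = unit_system()) {
  apl <- apl_nm2 / us$Rc_nm^2
  L <- sqrt(n_lipids * apl)
  structure(list(n_lipids = n_lipids, apl_nm2 = apl_nm2, apl = apl,
                 Lx = L, Ly = L,
                 water_thickness = water_thickness,
                 gas_thickness = gas_thickness),
            class = "monolayer_spec")
}

#' Scale the study system down for desk-size runs
#'
#' Divides the lipid count by `factor` (area per lipid and all densities
#' preserved; the lateral box shrinks as `1/sqrt(factor)`) and shrinks the
#' nanoparticle radius by `1/sqrt(factor)` so the NP footprint stays in
#' proportion to the interfacial area.
#'
#' @param mono a [monolayer_spec()].
#' @param jnp a [jnp_spec()] or `NULL`.
#' @param factor scale-down factor, >= 1.
#' @return list with elements `mono` and `jnp`.
#' @export
scale_system <- function(mono, jnp = NULL, factor = 1) {
  if (factor < 1) stop("factor must be >= 1")
  m2 <- monolayer_spec(n_lipids = max(1L, round(mono$n_lipids / factor)),
                       apl_nm2 = mono$apl_nm2,
                       water_thickness = mono$water_thickness,
                       gas_thickness = mono$gas_thickness)
  j2 <- NULL
  if (!is.null(jnp))
    j2 <- jnp_spec(radius = jnp$radius / sqrt(factor), phi_L = jnp$phi_L,
                   spacing = jnp$spacing, bond_k = jnp$bond_k)
  list(mono = m2, jnp = j2)
}

# jittered lattice filling a z-range of the box at the given density,
# excluding spheres listed in `excl` (list of c(x,y,z,r))
fill_region <- function(Lx, Ly, z0, z1, density, excl = list()) {
  vol <- Lx * Ly * (z1 - z0)
  ntarget <- round(density * vol)
  if (ntarget <= 0) return(matrix(numeric(), 0, 3))
  sp <- (1 / density)^(1 / 3)
  nx <- max(1L, floor(Lx / sp)); ny <- max(1L, floor(Ly / sp))
  nz <- max(1L, ceiling(ntarget / (nx * ny)))
  g <- expand.grid(x = (seq_len(nx) - 0.5) * Lx / nx,
                   y = (seq_len(ny) - 0.5) * Ly / ny,
                   z = z0 + (seq_len(nz) - 0.5) * (z1 - z0) / nz)
  p <- as.matrix(g)
  p <- p + matrix(runif(length(p), -0.1, 0.1) * sp, nrow(p), 3)
  p[, 3] <- pmin(pmax(p[, 3], z0 + 1e-3), z1 - 1e-3)
  for (e in excl) {
    d2 <- (p[, 1] - e[1])^2 + (p[, 2] - e[2])^2 + (p[, 3] - e[3])^2
    p <- p[d2 > e[4]^2, , drop = FALSE]
  }
  if (nrow(p) > ntarget) p <- p[seq_len(ntarget), , drop = FALSE]
  p
}

#' Build a double-monolayer air/water system, optionally with Janus NPs
#'
#' Deterministic construction (lattice placement plus seeded jitter
#' followed by a short soft-push relaxation): lipids sit on a jittered
#' square lattice at both water surfaces with tails toward the gas phase;
#' water fills the central slab at the reference density; dense fictitious
#' gas beads fill the outer regions. If a nanoparticle is supplied, one
#' copy is placed in the gas phase above each leaflet at the requested
#' adhesion orientation, keeping the system symmetric in z: `"la"`
#' (lipophile adhesion) points the hydrophobic cap at the monolayer
#' (orientation angle near 0 degrees), `"ha"` points the hydrophilic cap
#' at it (near 180 degrees).
#'
#' @param mono a [monolayer_spec()].
#' @param ff a `dpd_forcefield`.
#' @param jnp a [jnp_spec()], or `NULL` for a pure monolayer system.
#' @param mode adhesion mode, `"la"` or `"ha"`.
#' @param seed integer seed for the jitter (builder is deterministic given
#'   the seed).
#' @param gap initial NP-monolayer gap in Rc.
#' @param minimize run a short soft-push relaxation to remove overlaps.
#' @return a [dpd_state()] with lipid/NP bookkeeping in `$meta`.
#' @export
build_system <- function(mono, ff = default_forcefield(), jnp = NULL,
                         mode = c("la", "ha"), seed = 1L, gap = 1.0,
                         minimize = TRUE) {
  mode <- match.arg(mode)
  us <- ff$units
  lip <- build_dppc(ff)
  lip_len <- max(lip$pos[, 3]) # head-to-tail extent of the template
  Lx <- mono$Lx; Ly <- mono$Ly
  tw <- mono$water_thickness
  tg <- mono$gas_thickness
  np <- NULL
  if (!is.null(jnp)) {
    if (jnp$diameter + 2 * gap > tg)
      stop("nanoparticle does not fit in the gas slab")
    np <- jnp
  }
  Lz <- tw + 2 * (lip_len + 0.6) + tg
  zw0 <- (Lz - tw) / 2
  zw1 <- zw0 + tw
  nL <- mono$n_lipids

  withr_seed(seed, {
    # lipid lattice per leaflet
    nxl <- ceiling(sqrt(nL))
    xy <- expand.grid(x = (seq_len(nxl) - 0.5) * Lx / nxl,
                      y = (seq_len(nxl) - 0.5) * Ly / nxl)
    xy <- as.matrix(xy)[seq_len(nL), , drop = FALSE]
    xy <- xy + matrix(runif(2 * nL, -0.15, 0.15), nL, 2)

    place_leaflet <- function(top) {
      # top leaflet: heads near zw1 (water below heads? water *below* tails..)
      dirz <- if (top) 1 else -1
      anchor <- if (top) zw1 - 0.6 else zw0 + 0.6
      plist <- vector("list", nL)
      for (i in seq_len(nL)) {
        p <- lip$pos
        p[, 3] <- p[, 3] * dirz
        p[, 1] <- p[, 1] + xy[i, 1]
        p[, 2] <- p[, 2] + xy[i, 2]
        p[, 3] <- p[, 3] + anchor
        plist[[i]] <- p
      }
      plist
    }
    top_l <- place_leaflet(TRUE)
    bot_l <- place_leaflet(FALSE)

    pos <- NULL; type <- character(); charge <- numeric()
    bonds <- NULL; bond_k <- numeric(); bond_r0 <- numeric()
    angles <- NULL; angle_k <- numeric(); angle_theta0 <- numeric()
    mol_id <- integer(); mol_kind <- character()
    meta <- list(lipid_first = integer(), lipid_leaflet = integer(),
                 np = list())
    mol <- 0L
    add_mol <- function(p, ty, ch, bd, bk, br, an, ak, at, kind) {
      off <- if (is.null(pos)) 0L else nrow(pos)
      mol <<- mol + 1L
      pos <<- rbind(pos, p)
      type <<- c(type, ty); charge <<- c(charge, ch)
      if (!is.null(bd) && nrow(bd) > 0) {
        bonds <<- rbind(bonds, bd + off)
        bond_k <<- c(bond_k, bk); bond_r0 <<- c(bond_r0, br)
      }
      if (!is.null(an) && nrow(an) > 0) {
        angles <<- rbind(angles, an + off)
        angle_k <<- c(angle_k, ak); angle_theta0 <<- c(angle_theta0, at)
      }
      mol_id <<- c(mol_id, rep(mol, nrow(p)))
      mol_kind <<- c(mol_kind, rep(kind, nrow(p)))
      off + 1L
    }
    for (lf in list(list(l = bot_l, id = 1L), list(l = top_l, id = 2L))) {
      for (i in seq_len(nL)) {
        first <- add_mol(lf$l[[i]], lip$type, lip$charge, lip$bonds,
                         lip$bond_k, lip$bond_r0, lip$angles, lip$angle_k,
                         lip$angle_theta0, "lipid")
        meta$lipid_first <- c(meta$lipid_first, first)
        meta$lipid_leaflet <- c(meta$lipid_leaflet, lf$id)
      }
    }

    excl <- list()
    if (!is.null(np)) {
      # top NP above top leaflet, mirrored NP below bottom leaflet
      ztail_top <- zw1 + 0.6 + lip_len
      ztail_bot <- zw0 - 0.6 - lip_len
      centers <- list(top = c(Lx / 2, Ly / 2, ztail_top + gap + np$radius),
                      bot = c(Lx / 2, Ly / 2, ztail_bot - gap - np$radius))
      for (side in c("top", "bot")) {
        facing_down <- (side == "top")
        # LA: hydrophobic cap toward the monolayer
        ax <- if (mode == "la") c(0, 0, ifelse(facing_down, -1, 1))
              else              c(0, 0, ifelse(facing_down, 1, -1))
        bj <- build_jnp(np, axis = ax, center = centers[[side]])
        first <- add_mol(bj$pos, bj$type, numeric(nrow(bj$pos)), bj$bonds,
                         bj$bond_k, bj$bond_r0, NULL, NULL, NULL, "np")
        meta$np[[side]] <- list(ids = first:(first + nrow(bj$pos) - 1L),
                                surface = bj$surface, spec = np,
                                leaflet = if (side == "top") 2L else 1L,
                                axis = ax)
        excl[[length(excl) + 1L]] <- c(centers[[side]], np$radius + 0.6)
      }
    }

    wat <- fill_region(Lx, Ly, zw0, zw1, us$rho_w, excl)
    if (nrow(wat) > 0)
      add_mol(wat, rep("W", nrow(wat)), numeric(nrow(wat)),
              NULL, NULL, NULL, NULL, NULL, NULL, "water")
    gas_lo <- fill_region(Lx, Ly, 0, zw0 - 0.6 - lip_len - 0.3,
                          ff$gas_density, excl)
    gas_hi <- fill_region(Lx, Ly, zw1 + 0.6 + lip_len + 0.3, Lz,
                          ff$gas_density, excl)
    gas <- rbind(gas_lo, gas_hi)
    if (nrow(gas) > 0)
      add_mol(gas, rep("B", nrow(gas)), numeric(nrow(gas)),
              NULL, NULL, NULL, NULL, NULL, NULL, "gas")

    meta$mono <- mono
    meta$mode <- if (is.null(np)) NA_character_ else mode
    meta$seed <- as.integer(seed)
    meta$jnp <- np
    st <- dpd_state(pos, type, c(Lx, Ly, Lz), charge = charge,
                    bonds = bonds, bond_k = bond_k, bond_r0 = bond_r0,
                    angles = angles, angle_k = angle_k,
                    angle_theta0 = angle_theta0,
                    mol_id = mol_id, mol_kind = mol_kind, meta = meta)
    if (minimize) st <- soft_push(st, ff, niter = 60, dmax = 0.05)
    st
  })
}

#' Build a single-phase bulk box
#'
#' Cubic (or orthorhombic) box of one bead species at a given density;
#' optionally a few beads are re-typed as dilute tagged species (used by
#' the RDF-based contact-energy estimator).
#'
#' @param type host bead type label.
#' @param box box lengths (length 1 or 3), Rc.
#' @param density bead number density.
#' @param tag tagged bead type label, or `NULL`.
#' @param n_tag number of tagged beads.
#' @param seed jitter seed.
#' @export
build_bulk <- function(type = "W", box = 10, density = 3, tag = NULL,
                       n_tag = 0, seed = 1L) {
  if (length(box) == 1) box <- rep(box, 3)
  withr_seed(seed, {
    p <- fill_region(box[1], box[2], 0, box[3], density)
    ty <- rep(type, nrow(p))
    if (!is.null(tag) && n_tag > 0) {
      pick <- round(seq(1, nrow(p), length.out = n_tag))
      ty[pick] <- tag
    }
    dpd_state(p, ty, box, mol_kind = rep(if (type == "B") "gas" else "water",
                                         nrow(p)))
  })
}

#' Soft-push overlap relaxation
#'
#' Steepest descent on the conservative forces with a capped per-step
#' displacement; removes builder overlaps without disturbing the layered
#' geometry.
#'
#' @param state a `dpd_state`.
#' @param ff a `dpd_forcefield`.
#' @param niter iterations.
#' @param dmax maximum displacement per iteration (Rc).
#' @export
soft_push <- function(state, ff, niter = 50, dmax = 0.05) {
  tb <- ff_tables(ff)
  ti <- match(state$type, ff$types) - 1L
  if (anyNA(ti)) stop("state contains bead types unknown to the force field")
  out <- cpp_minimize(state$pos, ti, state$box, tb$A, tb$R, tb$G, tb$B,
                      tb$style, state$bonds - 1L, state$bond_k * ff$units$T_dpd,
                      state$bond_r0, state$angles - 1L,
                      state$angle_k * ff$units$T_dpd, state$angle_theta0,
                      as.integer(niter), dmax)
  state$pos <- out$pos
  state
}

# internal-unit interaction tables (a, k scaled by T_dpd)
ff_tables <- function(ff) {
  T <- ff$units$T_dpd
  list(A = ff$A * T, R = ff$R, G = ff$gamma, B = ff$b,
       style = ff$style)
}
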