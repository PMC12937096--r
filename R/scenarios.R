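#' Run one JNP-monolayer scenario end to end
#'
#' Builds a (scaled) double-monolayer system with one Janus NP per leaflet
#' at the requested hydrophobic coverage and adhesion mode, runs the
#' staged protocol (heavy-film NPT, NPT at actual masses, NVT production)
#' and analyses the trajectory. The outcome is classified as
#' `"translocation"` when the NP centre drops below the interface plane by
#' more than R_NP, `"coating"` when the NP stays above the plane with
#' lipid contacts on its hydrophobic beads and essentially no water
#' contacts there, and `"intercalation"` otherwise when the orientation
#' angle exceeds `theta_intercalated` or the NP holds a sustained
#' interfacial position.
#'
#' @param phi_L hydrophobic coverage.
#' @param mode adhesion mode `"la"` or `"ha"`; ignored for uniform
#'   particles.
#' @param ff a `dpd_forcefield`.
#' @param scale scale-down factor applied to the full-size study system
#'   (1400 lipids/leaflet, 12-nm NP).
#' @param seed seed for builder jitter, velocities and pair noise.
#' @param production NVT production steps.
#' @param equil1,equil2 NPT equilibration steps.
#' @param traj_stride production frame stride.
#' @param theta_intercalated orientation-angle threshold (degrees).
#' @param until_oriented extend production in chunks of `production` steps
#'   until the orientation angle exceeds `theta_intercalated` (plus one
#'   further chunk of statistics), the study-style run-to-steady-state
#'   mode for the rotation-limited pathway.
#' @param max_production hard cap on total production steps.
#' @param gamma0 reduced bare tension for the surface-pressure output.
#' @return list with `summary` (final orientation, surface pressure, LC
#'   density, effective area per lipid, lipid loss, mechanism label),
#'   per-frame `metrics`, the tension series, the final `state` and the
#'   production `frames`.
#' @export
run_scenario <- function(phi_L, mode = "la", ff = default_forcefield(),
                         scale = 7, seed = 1L,
                         production = 20000, equil1 = 2000, equil2 = 5000,
                         traj_stride = 1000,
                         theta_intercalated = 150,
                         until_oriented = FALSE, max_production = 120000,
                         gamma0 = gamma_zero(ff$units)) {
  us <- ff$units
  full <- list(mono = monolayer_spec(us = us),
               jnp = jnp_spec(radius = 6 / us$Rc_nm, phi_L = phi_L,
                              spacing = ff$templates$np$spacing %||% 0.8,
                              bond_k = ff$templates$np$bond_k %||% 500))
  sc <- scale_system(full$mono, full$jnp, scale)
  st <- build_system(sc$mono, ff, jnp = sc$jnp, mode = mode, seed = seed)
  st <- init_velocities(st, us$T_dpd, seed)
  # staged equilibration: heavy film NPT, then NPT at actual masses
  prot <- staged_protocol(equil1 = equil1, equil2 = equil2,
                          production = 0, traj_stride = 0)[1:2]
  cfg <- engine_config(seed = seed)
  res <- run_protocol(st, ff, prot, cfg)
  # NVT production, optionally extended until the NP orientation settles
  # (the study design runs until the interfacial state stops evolving)
  cfg$traj_stride <- as.integer(traj_stride)
  state <- res$state
  step0 <- res$step_end
  obs <- res$obs
  frames <- res$frames
  total <- 0
  has_np <- 0 < phi_L && phi_L < 1
  settled <- FALSE
  repeat {
    chunk <- if (until_oriented) min(production, max_production - total)
             else production
    r <- run_dpd(state, ff, chunk, cfg, step0 = step0)
    state <- r$state
    step0 <- r$step_end
    total <- total + chunk
    if (nrow(r$obs) > 0) {
      r$obs$stage <- 3
      obs <- rbind(obs, r$obs)
    }
    frames <- c(frames, r$frames)
    if (!until_oriented || total >= max_production) break
    if (!has_np) break
    if (settled) break # one extra chunk of statistics after orientation
    th <- orientation(state, "top", pos = state$pos)$theta_deg
    settled <- !is.na(th) && th > theta_intercalated
  }
  res <- list(state = state, obs = obs, frames = frames, step_end = step0)
  analyze_scenario(res, ff, gamma0 = gamma0,
                   theta_intercalated = theta_intercalated)
}

# shared analysis of a protocol result for a JNP (or pure) system
analyze_scenario <- function(res, ff, gamma0 = gamma_zero(ff$units),
                             theta_intercalated = 150,
                             equil_frac = 0.5) {
  us <- ff$units
  st <- res$state
  prod <- res$obs[res$obs$stage == max(res$obs$stage), ]
  keep <- prod[prod$step >= stats::quantile(prod$step, equil_frac), ]
  ten <- tension_series(keep, us, gamma0)
  gm <- mean(ten$gamma_m)
  Pi_mNm <- convert_tension(gamma0 - gm, us)
  has_np <- length(st$meta$np) > 0
  theta <- NA_real_
  A_np <- 0
  mech <- NA_character_
  metrics <- NULL
  if (length(res$frames) > 0) {
    metrics <- do.call(rbind, lapply(seq_along(res$frames), function(k) {
      fr <- res$frames[[k]]
      th <- if (has_np) orientation(st, "top", pos = fr$pos)$theta_deg
            else NA_real_
      An <- if (has_np) np_interfacial_area(st, "top", pos = fr$pos) else 0
      data.frame(frame = k, theta_deg = th, A_np = An)
    }))
  }
  n_lw <- 0
  nL <- length(st$meta$lipid_first) / 2
  if (has_np) {
    theta <- orientation(st, "top")$theta_deg
    A_np <- np_interfacial_area(st, "top")
    loss <- lipid_loss(st)
    n_lw <- loss$per_leaflet[["2"]]
    mech <- classify_mechanism(st, ff, theta_intercalated)
  } else {
    loss <- lipid_loss(st)
    n_lw <- loss$per_leaflet[["2"]]
  }
  ord <- tail_order(st, leaflet = 2L, A_np = A_np)
  ea <- effective_area(st$box[1] * st$box[2], A_np, nL, n_lw, us)
  summary <- list(theta_deg = theta, gamma_m = gm, Pi = gamma0 - gm,
                  Pi_mNm = Pi_mNm, f_lc = ord$f_lc, S_mean = ord$S_mean,
                  A_np = A_np, n_lw = n_lw,
                  apl_eff_nm2 = ea$apl_eff_nm2, mechanism = mech)
  list(summary = summary, metrics = metrics, tension = ten, state = st,
       frames = res$frames, obs = res$obs)
}

# mechanism label for the top-leaflet NP
classify_mechanism <- function(state, ff, theta_intercalated = 150) {
  info <- state$meta$np[["top"]]
  R <- info$spec$radius
  ids <- info$ids
  p <- state$pos[ids, , drop = FALSE]
  ref <- p[1, ]
  ctr <- ref + colMeans(minimum_image(sweep(p, 2, ref), state$box))
  plane <- interface_plane(state, 2L)
  below <- ctr[3] < plane - R # top leaflet: water is below the plane
  if (below) return("translocation")
  cc <- count_contacts(state, ff, "top")
  lipid_contacts <- sum(cc["L", c("N", "P", "G", "C")])
  water_on_L <- cc["L", "W"]
  theta <- orientation(state, "top")$theta_deg
  if (!is.na(theta) && theta > theta_intercalated) return("intercalation")
  if (lipid_contacts > 0 && water_on_L < 0.02 * max(1, lipid_contacts))
    return("coating")
  # sustained interfacial position without rotation
  if (abs(ctr[3] - plane) < R) return("intercalation")
  "coating"
}

#' Pure-monolayer reference run
#'
#' Builds and equilibrates a pure DPPC double monolayer at a given area
#' per lipid and returns the analysed result (surface pressure, order,
#' effective area).
#'
#' @param apl_nm2 area per lipid (nm^2).
#' @param n_lipids lipids per leaflet.
#' @param ff a `dpd_forcefield`.
#' @param seed seed.
#' @param production,equil1,equil2 protocol steps.
#' @param water_thickness,gas_thickness slab thicknesses (Rc); thinner
#'   defaults than the NP systems since no particle must fit in the gas.
#' @param gamma0 reduced bare tension.
#' @export
run_pure_monolayer <- function(apl_nm2 = 0.6, n_lipids = 200,
                               ff = default_forcefield(), seed = 1L,
                               production = 15000, equil1 = 2000,
                               equil2 = 4000, water_thickness = 8,
                               gas_thickness = 8,
                               gamma0 = gamma_zero(ff$units)) {
  mono <- monolayer_spec(n_lipids = n_lipids, apl_nm2 = apl_nm2,
                         water_thickness = water_thickness,
                         gas_thickness = gas_thickness, us = ff$units)
  st <- build_system(mono, ff, jnp = NULL, seed = seed)
  st <- init_velocities(st, ff$units$T_dpd, seed)
  prot <- staged_protocol(equil1 = equil1, equil2 = equil2,
                          production = production, traj_stride = 0)
  res <- run_protocol(st, ff, prot, engine_config(seed = seed))
  analyze_scenario(res, ff, gamma0 = gamma0)
}

#' Coverage scan
#'
#' Runs the JNP scenario over a list of hydrophobic coverages and tabulates
#' the equilibrated surface pressure, LC density and effective area per
#' lipid, with block-averaged standard errors for the pressure.
#'
#' @param phis hydrophobic coverages.
#' @param mode adhesion mode.
#' @param ff force field.
#' @param scale scale-down factor.
#' @param seeds one or more seeds per coverage (spread is reported).
#' @param ... passed to [run_scenario()].
#' @return data.frame with one row per (coverage, seed).
#' @export
coverage_scan <- function(phis, mode = "la", ff = default_forcefield(),
                          scale = 7, seeds = 1L, ...) {
  out <- NULL
  for (phi in phis) for (sd in seeds) {
    r <- run_scenario(phi, mode = mode, ff = ff, scale = scale,
                      seed = sd, ...)
    se <- block_se(r$tension$Pi)
    out <- rbind(out, data.frame(
      phi_L = phi, seed = sd, mode = mode,
      config = sprintf("%s-phi%g-scale%g-ff%.0f", mode, phi, scale,
                       sum(ff$A, na.rm = TRUE) * 1000 + sum(ff$R)),
      Pi = r$summary$Pi, Pi_mNm = r$summary$Pi_mNm,
      Pi_se = se * ff$units$tension_to_mNm,
      f_lc = r$summary$f_lc, apl_eff_nm2 = r$summary$apl_eff_nm2,
      n_lw = r$summary$n_lw, mechanism = r$summary$mechanism))
  }
  out
}

#' Block-averaged standard error
#'
#' @param x a (correlated) time series.
#' @param nblock number of blocks.
#' @export
block_se <- function(x, nblock = 5) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2 * nblock) return(stats::sd(x) / sqrt(max(1, n)))
  bl <- split(x, cut(seq_len(n), nblock, labels = FALSE))
  m <- vapply(bl, mean, numeric(1))
  stats::sd(m) / sqrt(nblock)
}
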