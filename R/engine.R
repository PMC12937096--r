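#' Engine configuration
#'
#' @param dt integration timestep (reduced time units).
#' @param lambda velocity-prediction factor of the modified velocity-Verlet
#'   scheme (0.5 recovers plain velocity Verlet).
#' @param ensemble `"nvt"` or `"npt"`.
#' @param pmode barostat coupling mode: `"iso"` (isotropic), `"semi"`
#'   (x = y lateral, z independent) or `"z"` (normal direction only; the
#'   natural choice for interfacial systems built at fixed area).
#' @param ptarget barostat target pressure in k_BT/Rc^3.
#' @param taup Berendsen pressure-coupling time (reduced units).
#' @param seed integer seed of the counter-based pair-noise generator; a
#'   fixed seed gives bit-reproducible trajectories.
#' @param traj_stride store a trajectory frame every this many steps
#'   (0 = never).
#' @param obs_stride record the pressure tensor and kinetic temperature
#'   every this many steps (0 = never).
#' @export
engine_config <- function(dt = 0.01, lambda = 0.65,
                          ensemble = c("nvt", "npt"),
                          pmode = c("z", "semi", "iso"),
                          ptarget = 23.7, taup = 2.0, seed = 1L,
                          traj_stride = 0L, obs_stride = 10L) {
  ensemble <- match.arg(ensemble)
  pmode <- match.arg(pmode)
  if (dt <= 0) stop("timestep must be positive")
  structure(list(dt = dt, lambda = lambda, ensemble = ensemble,
                 pmode = pmode, ptarget = ptarget, taup = taup,
                 seed = as.integer(seed),
                 traj_stride = as.integer(traj_stride),
                 obs_stride = as.integer(obs_stride)),
            class = "engine_config")
}

#' Conservative pair-force law
#'
#' Magnitude of the conservative force along the unit separation vector,
#' in k_BT/Rc: the soft linear repulsion a (1 - r/R) for standard pairs,
#' or the exponential gas-bead law a (e^{b r/R} - e^b) / (1 - e^b) for
#' gas pairs (equal to a at contact, zero at the cutoff, and steeper than
#' linear near contact for b > 0). Both vanish for r >= R.
#'
#' @param r distances (vectorised).
#' @param a repulsion amplitude (k_BT/Rc).
#' @param R cutoff (Rc).
#' @param style `"linear"` or `"exp"`.
#' @param b exponential steepness (non-zero, required for `"exp"`).
#' @export
pair_force <- function(r, a, R, style = c("linear", "exp"), b = NULL) {
  style <- match.arg(style)
  f <- numeric(length(r))
  inside <- r < R
  if (style == "linear") {
    f[inside] <- a * (1 - r[inside] / R)
  } else {
    if (is.null(b) || b == 0) stop("exponential force needs b != 0")
    eb <- exp(b)
    f[inside] <- a * (exp(b * r[inside] / R) - eb) / (1 - eb)
  }
  f
}

engine_args <- function(state, ff) {
  T <- ff$units$T_dpd
  tb <- ff_tables(ff)
  ti <- match(state$type, ff$types) - 1L
  if (anyNA(ti)) stop("state contains bead types unknown to the force field")
  q <- state$charge
  elec_on <- ff$elec$enabled && any(q != 0)
  if (elec_on && abs(sum(q)) > 1e-9)
    warning("system carries a net charge; direct-sum electrostatics will be biased")
  list(ti = ti, tb = tb, q = q, elec_on = elec_on,
       elec_pref = ff$elec$coupling * T / (4 * pi),
       elec_beta = ff$elec$beta, elec_rc = ff$elec$cutoff,
       bonds = state$bonds - 1L, kb = state$bond_k * T, r0 = state$bond_r0,
       angles = state$angles - 1L, ka = state$angle_k * T,
       th0 = state$angle_theta0, T = T)
}

#' Instantaneous forces, virial and potential energy
#'
#' Evaluates all force terms at the current configuration: soft
#' conservative pair forces (linear or exponential by pair style), bonded
#' terms, optional smeared-charge electrostatics and, if `with_dr = TRUE`,
#' the pairwise dissipative and random forces at the given step counter.
#' Energies and the conservative virial are returned in k_BT units.
#'
#' @param state a `dpd_state`.
#' @param ff a `dpd_forcefield`.
#' @param with_dr include dissipative and random forces.
#' @param dt timestep used to scale the random force (1/sqrt(dt)).
#' @param seed,step noise counter inputs.
#' @return list with `forces` (internal units), `virial` (k_BT, diagonal
#'   components), and per-term potential energies in k_BT.
#' @export
dpd_forces <- function(state, ff, with_dr = FALSE, dt = 0.01, seed = 1L,
                       step = 0L) {
  ea <- engine_args(state, ff)
  out <- cpp_forces(state$pos, state$vel, ea$ti, state$box,
                    ea$tb$A, ea$tb$R, ea$tb$G, ea$tb$B, ea$tb$style,
                    ea$bonds, ea$kb, ea$r0, ea$angles, ea$ka, ea$th0,
                    ea$q, ea$elec_on, ea$elec_pref, ea$elec_beta, ea$elec_rc,
                    with_dr, ea$T, dt, as.numeric(seed), as.numeric(step))
  T <- ea$T
  list(forces = out$forces, virial = out$virial / T,
       e_pair = out$e_pair / T, e_bond = out$e_bond / T,
       e_angle = out$e_angle / T, e_elec = out$e_elec / T)
}

#' Periodic neighbour pairs within a cutoff
#'
#' Cell-list pair search over all periodic images (minimum image); falls
#' back to an exact all-pairs scan when the box is smaller than three
#' cells per direction.
#'
#' @param pos N x 3 positions or a `dpd_state`.
#' @param box box lengths (ignored if `pos` is a state).
#' @param cutoff pair cutoff in Rc.
#' @return list with `pairs` (m x 2, 1-based) and `dist`.
#' @export
neighbor_pairs <- function(pos, box = NULL, cutoff = 1.0) {
  if (inherits(pos, "dpd_state")) { box <- pos$box; pos <- pos$pos }
  cpp_pairs(pos, box, cutoff)
}

#' Instantaneous virial pressure tensor
#'
#' Diagonal pressure-tensor components of the current configuration,
#' P_aa = (sum m v_a^2 + sum_pairs F_a r_a) / V, with the kinetic and
#' conservative-virial parts reported separately (k_BT/Rc^3).
#'
#' @param state a `dpd_state`.
#' @param ff a `dpd_forcefield`.
#' @return list with `kinetic`, `virial` and `total`, each a named vector
#'   (xx, yy, zz).
#' @export
pressure_tensor <- function(state, ff) {
  V <- prod(state$box)
  T <- ff$units$T_dpd
  kin <- colSums(state$vel^2 * state$mass) / V / T
  vir <- dpd_forces(state, ff)$virial / V
  names(kin) <- names(vir) <- c("xx", "yy", "zz")
  list(kinetic = kin, virial = vir, total = kin + vir)
}

#' Run DPD dynamics
#'
#' Advances the state with the modified velocity-Verlet integrator (one
#' force evaluation per step, dissipative force evaluated at predicted
#' velocities) under NVT or Berendsen-NPT conditions. Pressures in the
#' observable table are reported in k_BT/Rc^3; kinetic temperature in
#' reduced units.
#'
#' @param state a `dpd_state` (velocities should be initialised, e.g. with
#'   [init_velocities()]).
#' @param ff a `dpd_forcefield`.
#' @param nsteps number of steps.
#' @param config an [engine_config()].
#' @param step0 global step counter offset (keeps pair noise independent
#'   across chained runs).
#' @return list with the advanced `state`, the observable table `obs`
#'   (columns step, Tkin, Pxx, Pyy, Pzz, Lx, Ly, Lz, Epot), trajectory
#'   `frames`, and `step_end`.
#' @export
run_dpd <- function(state, ff, nsteps, config = engine_config(), step0 = 0) {
  ea <- engine_args(state, ff)
  T <- ea$T
  out <- cpp_run(state$pos, state$vel, ea$ti, state$mass, state$box,
                 ea$tb$A, ea$tb$R, ea$tb$G, ea$tb$B, ea$tb$style,
                 ea$bonds, ea$kb, ea$r0, ea$angles, ea$ka, ea$th0,
                 ea$q, ea$elec_on, ea$elec_pref, ea$elec_beta, ea$elec_rc,
                 as.integer(nsteps), config$dt, T, config$lambda,
                 as.numeric(config$seed), as.numeric(step0),
                 if (config$ensemble == "npt") 1L else 0L,
                 match(config$pmode, c("iso", "semi", "z")) - 1L,
                 config$ptarget * T, config$taup,
                 config$traj_stride, config$obs_stride)
  obs <- as.data.frame(out$obs)
  if (nrow(obs) > 0) {
    obs$Pxx <- obs$Pxx / T; obs$Pyy <- obs$Pyy / T; obs$Pzz <- obs$Pzz / T
    obs$Epot <- obs$Epot / T
  }
  state$pos <- out$pos
  state$vel <- out$vel
  state$box <- out$box
  list(state = state, obs = obs, frames = out$frames,
       step_end = out$step_end)
}

#' Staged simulation protocol
#'
#' Runs a list of stages in sequence, following the staged equilibration
#' used for the monolayer systems: a short NPT stage with NP and lipid
#' beads made heavy (about 50-fold mass) so water and gas subphases
#' equilibrate around an immobile film, an NPT stage at actual masses to
#' relax the system at the reference pressure, then an NVT production
#' stage.
#'
#' @param state a `dpd_state`.
#' @param ff a `dpd_forcefield`.
#' @param stages list of stages, each a list with `steps`, `ensemble`,
#'   optional `mass_scale` (factor applied to `"lipid"` and `"np"` beads
#'   for the duration of the stage), and optional engine-config overrides
#'   (`dt`, `pmode`, `ptarget`, `taup`, `traj_stride`, `obs_stride`).
#' @param config base [engine_config()].
#' @param seed noise seed (overrides `config$seed`).
#' @return list with final `state`, concatenated `obs` (with a `stage`
#'   column) and `frames` from all stages.
#' @export
run_protocol <- function(state, ff, stages, config = engine_config(),
                         seed = config$seed) {
  config$seed <- as.integer(seed)
  step0 <- 0
  obs_all <- NULL
  frames <- list()
  for (k in seq_along(stages)) {
    sg <- stages[[k]]
    cfg <- config
    for (nm in intersect(names(sg), c("dt", "pmode", "ptarget", "taup",
                                      "traj_stride", "obs_stride",
                                      "ensemble")))
      cfg[[nm]] <- sg[[nm]]
    mass0 <- state$mass
    if (!is.null(sg$mass_scale) && sg$mass_scale != 1) {
      heavy <- state$mol_kind %in% c("lipid", "np")
      state$mass[heavy] <- state$mass[heavy] * sg$mass_scale
    }
    res <- run_dpd(state, ff, sg$steps, cfg, step0 = step0)
    state <- res$state
    state$mass <- mass0
    step0 <- res$step_end
    if (nrow(res$obs) > 0) {
      res$obs$stage <- k
      obs_all <- rbind(obs_all, res$obs)
    }
    frames <- c(frames, res$frames)
  }
  list(state = state, obs = obs_all, frames = frames, step_end = step0)
}

#' Default staged equilibration + production protocol
#'
#' @param equil1,equil2 steps of the two NPT equilibration stages (heavy
#'   film, then actual masses).
#' @param production NVT production steps.
#' @param mass_scale mass factor of the first stage.
#' @param traj_stride trajectory stride of the production stage.
#' @export
staged_protocol <- function(equil1 = 2000, equil2 = 5000,
                            production = 20000, mass_scale = 50,
                            traj_stride = 500) {
  list(
    list(steps = equil1, ensemble = "npt", pmode = "z",
         mass_scale = mass_scale),
    list(steps = equil2, ensemble = "npt", pmode = "z"),
    list(steps = production, ensemble = "nvt", traj_stride = traj_stride)
  )
}
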