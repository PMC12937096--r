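#' Pairwise conservative potential
#'
#' The potential whose negative gradient is the conservative pair force:
#' V(r) = (a R / 2)(1 - r/R)^2 for standard (linear-force) pairs, and for
#' gas pairs the integral of the exponential force,
#' V(r) = a/(1 - e^b) * ((r - R) e^b + (R/b)(e^b - e^{b r / R})), both
#' zero at the cutoff. Energies in k_BT.
#'
#' @param r distances (vectorised).
#' @param a repulsion (k_BT/Rc).
#' @param R cutoff (Rc).
#' @param style `"linear"` or `"exp"`.
#' @param b exponential steepness (required for `"exp"`).
#' @export
pair_potential <- function(r, a, R, style = c("linear", "exp"), b = NULL) {
  style <- match.arg(style)
  v <- numeric(length(r))
  inside <- r < R
  if (style == "linear") {
    v[inside] <- 0.5 * a * R * (1 - r[inside] / R)^2
  } else {
    if (is.null(b) || b == 0) stop("exponential potential needs b != 0")
    eb <- exp(b)
    ri <- r[inside]
    v[inside] <- a / (1 - eb) * ((ri - R) * eb + (R / b) * (eb - exp(b * ri / R)))
  }
  v
}

# potential for a labelled type pair from the force field
pair_potential_ff <- function(r, ff, i, j) {
  p <- ff_pair(ff, i, j)
  pair_potential(r, p$a, p$R, p$style, p$b)
}

#' Mismatch potential between an NP bead type and another bead type
#'
#' Delta V_aj(r) = V_aj(r) - (V_aa(r) + V_jj(r)) / 2: the excess of the
#' cross interaction over the mean of the self interactions. Identically
#' zero for identical species.
#'
#' @param r distances.
#' @param ff a `dpd_forcefield`.
#' @param alpha NP bead type (`"K"` or `"L"`).
#' @param j other bead type.
#' @export
mismatch_potential <- function(r, ff, alpha, j) {
  pair_potential_ff(r, ff, alpha, j) -
    0.5 * (pair_potential_ff(r, ff, alpha, alpha) +
           pair_potential_ff(r, ff, j, j))
}

#' Radial distribution function from trajectory frames
#'
#' Normalised histogram of cross distances between a tagged bead group and
#' a host group over a set of frames; g(r) tends to 1 at large r for a
#' homogeneous fluid.
#'
#' @param frames list of frames (each with `pos` and `box`), e.g. from
#'   [run_dpd()].
#' @param ids_a tagged bead indices.
#' @param ids_b host bead indices.
#' @param rmax histogram range (Rc).
#' @param bin bin width (Rc).
#' @return data.frame with bin centres `r` and `g`.
#' @export
estimate_rdf <- function(frames, ids_a, ids_b, rmax = 2.0, bin = 0.02) {
  if (length(frames) < 2) warning("very few frames: the RDF will be noisy")
  nb <- ceiling(rmax / bin)
  counts <- numeric(nb)
  volsum <- 0
  for (fr in frames) {
    box <- fr$box
    sub <- c(ids_a, ids_b)
    pr <- cpp_pairs(fr$pos[sub, , drop = FALSE], box, rmax)
    na <- length(ids_a)
    sel <- (pr$pairs[, 1] <= na) != (pr$pairs[, 2] <= na) # cross pairs only
    d <- pr$dist[sel]
    h <- tabulate(pmin(nb, floor(d / bin) + 1L), nbins = nb)
    counts <- counts + h
    volsum <- volsum + prod(box)
  }
  nf <- length(frames)
  vmean <- volsum / nf
  rho_b <- length(ids_b) / vmean
  r_lo <- (seq_len(nb) - 1) * bin
  shell <- 4 / 3 * pi * ((r_lo + bin)^3 - r_lo^3)
  g <- counts / (nf * length(ids_a) * rho_b * shell)
  data.frame(r = r_lo + bin / 2, g = g)
}

#' Dilute-bead bulk simulation for RDF estimation
#'
#' Simulates a few tagged NP beads (K or L) dilute in a bulk bath of a
#' host bead type (about one tagged bead per 500 host beads) and returns
#' trajectory frames plus the tagged/host index sets.
#'
#' @param ff a `dpd_forcefield`.
#' @param alpha tagged type.
#' @param host host type.
#' @param box cubic box length (Rc).
#' @param steps production steps (after `equil` equilibration steps).
#' @param equil equilibration steps.
#' @param stride frame stride.
#' @param seed engine/builder seed.
#' @export
bulk_rdf_sim <- function(ff, alpha, host, box = 8, steps = 6000,
                         equil = 2000, stride = 20, seed = 1L) {
  dens <- if (host == "B") ff$gas_density else ff$units$rho_w
  n_host <- round(dens * box^3)
  st <- build_bulk(host, box, dens, tag = alpha,
                   n_tag = max(1L, round(n_host / 500)), seed = seed)
  st <- init_velocities(st, ff$units$T_dpd, seed)
  cfg <- engine_config(seed = seed, obs_stride = 0L)
  r1 <- run_dpd(st, ff, equil, cfg)
  cfg$traj_stride <- as.integer(stride)
  r2 <- run_dpd(r1$state, ff, steps, cfg, step0 = r1$step_end)
  list(frames = r2$frames, ids_a = which(st$type == alpha),
       ids_b = which(st$type == host), state = r2$state)
}

#' Bead-bead contact energy
#'
#' RDF-weighted average of the mismatch potential over the interaction
#' range: eps_aj = Int_0^R DeltaV(r) g(r) r^2 dr / Int_0^R g(r) r^2 dr,
#' by trapezoidal quadrature on the RDF grid (g interpolated onto a
#' uniform grid over [0, R]). Negative values mark favourable contacts.
#'
#' @param rdf data.frame `r`, `g` from [estimate_rdf()], or `NULL` for
#'   the ideal-bath approximation g = 1.
#' @param ff a `dpd_forcefield`.
#' @param alpha,j bead types.
#' @param ngrid quadrature grid size.
#' @return contact energy in k_BT.
#' @export
contact_energy <- function(rdf, ff, alpha, j, ngrid = 400) {
  R <- ff$R[alpha, j]
  r <- seq(0, R, length.out = ngrid)
  g <- if (is.null(rdf)) rep(1, ngrid)
       else approx(rdf$r, rdf$g, xout = r, rule = 2)$y
  dv <- mismatch_potential(r, ff, alpha, j)
  num <- trapz(r, dv * g * r^2)
  den <- trapz(r, g * r^2)
  if (den == 0) stop("empty quadrature grid")
  num / den
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Contact-energy table from dilute-bead RDF simulations
#'
#' Runs one dilute-bead bulk simulation per (alpha, j) pair and evaluates
#' the contact energies. Pairs of identical species are exactly zero and
#' skipped.
#'
#' @param ff a `dpd_forcefield`.
#' @param alphas NP bead types.
#' @param hosts host bead types.
#' @param seed base seed (one offset per pair).
#' @param ... passed to [bulk_rdf_sim()].
#' @return data.frame with columns `alpha`, `j`, `eps` (k_BT) plus the
#'   ideal-bath value `eps_g1`.
#' @export
contact_energy_table <- function(ff, alphas = c("K", "L"),
                                 hosts = c("N", "P", "G", "C", "W", "B"),
                                 seed = 1L, ...) {
  res <- NULL
  k <- 0L
  for (a in alphas) for (h in hosts) {
    k <- k + 1L
    sim <- bulk_rdf_sim(ff, a, h, seed = seed + k, ...)
    rdf <- estimate_rdf(sim$frames, sim$ids_a, sim$ids_b)
    res <- rbind(res, data.frame(
      alpha = a, j = h,
      eps = contact_energy(rdf, ff, a, h),
      eps_g1 = contact_energy(NULL, ff, a, h)))
  }
  res
}

#' Count beads in contact with the nanoparticle surface
#'
#' A bead of type j is in contact with an NP bead of type alpha when their
#' separation is below the pair interaction cutoff R_aj (the upper limit
#' of the contact-energy integral). By default only NP surface beads
#' (lattice beads with a missing nearest neighbour) are counted.
#'
#' @param state a `dpd_state`.
#' @param np `"top"` or `"bot"`.
#' @param pos optional positions.
#' @param ff a `dpd_forcefield`.
#' @param surface_only count only NP surface beads.
#' @return named count matrix n (rows K, L; columns other types).
#' @export
count_contacts <- function(state, ff, np = "top", pos = NULL,
                           surface_only = TRUE) {
  info <- state$meta$np[[np]]
  if (is.null(info)) stop("state has no nanoparticle labelled ", np)
  if (is.null(pos)) pos <- state$pos
  ids <- info$ids
  if (surface_only) ids <- ids[info$surface]
  others <- setdiff(seq_len(n_beads(state)), unlist(lapply(state$meta$np,
                                                           `[[`, "ids")))
  sub <- c(ids, others)
  rmax <- max(ff$R)
  pr <- cpp_pairs(pos[sub, , drop = FALSE], state$box, rmax)
  nn <- length(ids)
  sel <- (pr$pairs[, 1] <= nn) != (pr$pairs[, 2] <= nn)
  p1 <- pmin(pr$pairs[sel, 1], pr$pairs[sel, 2]) # NP side
  p2 <- pmax(pr$pairs[sel, 1], pr$pairs[sel, 2])
  ta <- state$type[sub[p1]]
  tj <- state$type[sub[p2]]
  d <- pr$dist[sel]
  within <- d < ff$R[cbind(ta, tj)]
  alphas <- c("K", "L")
  hosts <- setdiff(ff$types, c("K", "L"))
  n <- matrix(0L, 2, length(hosts), dimnames = list(alphas, hosts))
  if (any(within)) {
    tb <- table(factor(ta[within], levels = alphas),
                factor(tj[within], levels = hosts))
    n[] <- as.integer(tb)
  }
  n
}

#' Surface-energy decomposition over a trajectory
#'
#' Per frame: the NP adsorption energy E_NP = sum_j (eps_Kj n_Kj +
#' eps_Lj n_Lj) from contact counts and the contact-energy table, the
#' monolayer term E_m' = gamma_m (Lx Ly - A_I^NP), and their sum
#' E_S = E_NP + E_m'. Tension values are matched to frames by step.
#'
#' @param state a `dpd_state` (topology/bookkeeping reference).
#' @param frames list of trajectory frames.
#' @param eps contact-energy table from [contact_energy_table()].
#' @param gamma_m per-frame monolayer tension (recycled if length 1).
#' @param ff a `dpd_forcefield`.
#' @param np `"top"` or `"bot"`.
#' @param surface_only passed to [count_contacts()].
#' @return data.frame with `frame`, `E_np_K`, `E_np_L`, `E_np`, `E_m`,
#'   `E_s`, `A_np` (all energies in k_BT).
#' @export
surface_energy_series <- function(state, frames, eps, gamma_m, ff,
                                  np = "top", surface_only = TRUE) {
  if (length(gamma_m) == 1) gamma_m <- rep(gamma_m, length(frames))
  if (length(gamma_m) != length(frames))
    stop("gamma_m series does not match the frame grid")
  epsm <- matrix(0, 2, length(unique(eps$j)),
                 dimnames = list(c("K", "L"), unique(eps$j)))
  for (i in seq_len(nrow(eps))) epsm[eps$alpha[i], eps$j[i]] <- eps$eps[i]
  out <- NULL
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    n <- count_contacts(state, ff, np, pos = fr$pos,
                        surface_only = surface_only)
    common <- intersect(colnames(epsm), colnames(n))
    eK <- sum(epsm["K", common] * n["K", common])
    eL <- sum(epsm["L", common] * n["L", common])
    A_np <- np_interfacial_area(state, np, pos = fr$pos)
    Em <- gamma_m[k] * (state$box[1] * state$box[2] - A_np)
    out <- rbind(out, data.frame(frame = k, E_np_K = eK, E_np_L = eL,
                                 E_np = eK + eL, E_m = Em,
                                 E_s = eK + eL + Em, A_np = A_np))
  }
  out
}
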