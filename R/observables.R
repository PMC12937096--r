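#' Nanoparticle orientation
#'
#' The NP director u is the unit vector from the hydrophobic-cap centre of
#' mass to the hydrophilic-cap centre of mass; the orientation angle is
#' measured against the outward normal of the leaflet the NP belongs to
#' (so a lipophile-adhesion start reads about 0 degrees and a fully
#' intercalated particle 180 degrees). Undefined for a uniform particle
#' (phi_L of 0 or 1): returns `NA` angle.
#'
#' @param state a `dpd_state` (with NP bookkeeping in `$meta$np`).
#' @param np which NP, `"top"` or `"bot"`.
#' @param pos optional positions to use instead of `state$pos` (e.g. a
#'   trajectory frame).
#' @return list with `u` and `theta_deg`.
#' @export
orientation <- function(state, np = "top", pos = NULL) {
  info <- state$meta$np[[np]]
  if (is.null(info)) stop("state has no nanoparticle labelled ", np)
  if (is.null(pos)) pos <- state$pos
  ids <- info$ids
  ty <- state$type[ids]
  if (!any(ty == "K") || !any(ty == "L"))
    return(list(u = c(NA, NA, NA), theta_deg = NA_real_))
  p <- pos[ids, , drop = FALSE]
  # unwrap about the first bead (the NP is compact)
  ref <- p[1, ]
  d <- minimum_image(sweep(p, 2, ref), state$box)
  comK <- colMeans(d[ty == "K", , drop = FALSE])
  comL <- colMeans(d[ty == "L", , drop = FALSE])
  u <- comK - comL
  u <- u / sqrt(sum(u^2))
  normal <- c(0, 0, if (info$leaflet == 2L) 1 else -1) # outward normal
  ct <- sum(u * normal)
  ct <- min(1, max(-1, ct))
  list(u = u, theta_deg = acos(ct) * 180 / pi)
}

#' Monolayer surface tension and surface pressure from the pressure tensor
#'
#' For a double-interface slab, gamma_m = Lz/2 * (Pzz - (Pxx + Pyy)/2)
#' per interface; the surface pressure is Pi = gamma0 - gamma_m with the
#' configured bare air-water tension. The identity Pi + gamma_m = gamma0
#' holds by construction.
#'
#' @param Pxx,Pyy,Pzz diagonal pressure-tensor components (k_BT/Rc^3);
#'   vectors are accepted.
#' @param Lz box height (Rc).
#' @param us a [unit_system()].
#' @param gamma0 reduced bare tension; default from [gamma_zero()].
#' @return data.frame with `gamma_m`, `Pi` (reduced) and `gamma_m_mNm`,
#'   `Pi_mNm`.
#' @export
surface_tension <- function(Pxx, Pyy, Pzz, Lz, us = unit_system(),
                            gamma0 = gamma_zero(us)) {
  gm <- Lz / 2 * (Pzz - (Pxx + Pyy) / 2)
  data.frame(gamma_m = gm, Pi = gamma0 - gm,
             gamma_m_mNm = convert_tension(gm, us),
             Pi_mNm = convert_tension(gamma0 - gm, us))
}

#' Surface tension series from an engine observable table
#'
#' @param obs the `obs` table returned by [run_dpd()].
#' @param us,gamma0 passed to [surface_tension()].
#' @export
tension_series <- function(obs, us = unit_system(), gamma0 = gamma_zero(us)) {
  cbind(step = obs$step,
        surface_tension(obs$Pxx, obs$Pyy, obs$Pzz, obs$Lz, us, gamma0))
}

# per-lipid bead index helper: lipid layout is N P G G C5..C9 C10..C14
lipid_beads <- function(state) {
  first <- state$meta$lipid_first
  if (is.null(first)) stop("state carries no lipid bookkeeping")
  list(first = first, leaflet = state$meta$lipid_leaflet,
       P = first + 1L, tail1 = cbind(first + 4L, first + 8L),
       tail2 = cbind(first + 9L, first + 13L),
       tails = lapply(first, function(f) f + c(4:13)))
}

#' Lipid tail order parameter and LE/LC phase statistics
#'
#' Per lipid, S = (3 cos^2 theta - 1)/2 averaged over the two tails, with
#' theta the angle between the tail vector (first tail bead to last tail
#' bead) and the monolayer normal (z). Lipids with S > `lc_threshold`
#' are labelled liquid-condensed (LC); the LC density is
#' f_LC = n(S > 0.6) / A_res with A_res the interfacial area not occupied
#' by the NP.
#'
#' @param state a `dpd_state`.
#' @param pos optional positions (trajectory frame).
#' @param leaflet restrict to one leaflet (1 bottom, 2 top) or `NULL`.
#' @param A_np interfacial area occupied by NPs in that leaflet (Rc^2).
#' @param lc_threshold LC classification threshold on S.
#' @return list with per-lipid table `lipids` (S, lc), `S_mean`, `n_lc`,
#'   `A_res`, `f_lc`.
#' @export
tail_order <- function(state, pos = NULL, leaflet = NULL, A_np = 0,
                       lc_threshold = 0.6) {
  if (is.null(pos)) pos <- state$pos
  lb <- lipid_beads(state)
  keep <- if (is.null(leaflet)) seq_along(lb$first)
          else which(lb$leaflet == leaflet)
  S <- vapply(keep, function(i) {
    s2 <- vapply(list(lb$tail1[i, ], lb$tail2[i, ]), function(t) {
      v <- minimum_image(pos[t[2], ] - pos[t[1], ], state$box)
      ct2 <- (v[3] / sqrt(sum(v^2)))^2
      (3 * ct2 - 1) / 2
    }, numeric(1))
    mean(s2)
  }, numeric(1))
  A_box <- state$box[1] * state$box[2]
  A_res <- A_box - A_np
  n_lc <- sum(S > lc_threshold)
  list(lipids = data.frame(lipid = keep, leaflet = lb$leaflet[keep], S = S,
                           lc = S > lc_threshold),
       S_mean = mean(S), n_lc = n_lc, A_res = A_res, f_lc = n_lc / A_res)
}

#' Interface plane of a leaflet
#'
#' Mean z of the phosphate (P) beads of the leaflet, recomputed per frame.
#'
#' @param state a `dpd_state`.
#' @param leaflet 1 (bottom) or 2 (top).
#' @param pos optional positions.
#' @export
interface_plane <- function(state, leaflet = 2L, pos = NULL) {
  if (is.null(pos)) pos <- state$pos
  lb <- lipid_beads(state)
  mean(pos[lb$P[lb$leaflet == leaflet], 3])
}

#' Interfacial area occupied by a nanoparticle
#'
#' Geometric default: the cross-section of the NP sphere at the interface
#' plane, pi (R^2 - d^2) for centre-plane distance d < R, else 0. The
#' bead-projection alternative (`method = "beads"`) counts occupied
#' 0.5-Rc grid cells among NP beads within 0.5 Rc of the plane, as a
#' sensitivity check.
#'
#' @param state a `dpd_state`.
#' @param np `"top"` or `"bot"`.
#' @param pos optional positions.
#' @param plane interface plane z; default from [interface_plane()] of the
#'   NP's leaflet.
#' @param method `"geometric"` or `"beads"`.
#' @return area in Rc^2.
#' @export
np_interfacial_area <- function(state, np = "top", pos = NULL, plane = NULL,
                                method = c("geometric", "beads")) {
  method <- match.arg(method)
  info <- state$meta$np[[np]]
  if (is.null(info)) return(0)
  if (is.null(pos)) pos <- state$pos
  if (is.null(plane)) plane <- interface_plane(state, info$leaflet, pos)
  p <- pos[info$ids, , drop = FALSE]
  ref <- p[1, ]
  d <- minimum_image(sweep(p, 2, ref), state$box)
  ctr <- ref + colMeans(d)
  R <- info$spec$radius
  if (method == "geometric") {
    dz <- abs(ctr[3] - plane)
    if (dz >= R) 0 else pi * (R^2 - dz^2)
  } else {
    # occupied-cell census of NP beads in a one-lattice-plane slab
    cell <- info$spec$spacing
    sl <- abs(p[, 3] - plane) < 0.505 * cell
    if (!any(sl)) return(0)
    ix <- floor(p[sl, 1] / cell)
    iy <- floor(p[sl, 2] / cell)
    length(unique(paste(ix, iy))) * cell^2
  }
}

# union-find over 1..n
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  edges <- matrix(as.integer(edges), ncol = 2)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges) > 0) for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Lipids lost from the monolayer
#'
#' Cluster-based rule: lipids of a leaflet are connected when any of their
#' tail beads lie within `cutoff` of each other; a lipid counts as lost
#' (n_L^w) when it does not belong to the largest connected cluster of its
#' leaflet, or when all of its tail beads are within contact range of NP
#' beads (coated on the particle).
#'
#' @param state a `dpd_state`.
#' @param pos optional positions.
#' @param cutoff tail-bead connectivity distance (Rc).
#' @return list with `n_lw` (total), per-leaflet counts, and the per-lipid
#'   status table.
#' @export
lipid_loss <- function(state, pos = NULL, cutoff = 1.0) {
  if (is.null(pos)) pos <- state$pos
  lb <- lipid_beads(state)
  nlip <- length(lb$first)
  tail_ids <- unlist(lb$tails)
  tail_lipid <- rep(seq_len(nlip), each = 10L)
  np_ids <- unlist(lapply(state$meta$np, `[[`, "ids"))
  sub_ids <- c(tail_ids, np_ids)
  sub_pos <- pos[sub_ids, , drop = FALSE]
  pr <- cpp_pairs(sub_pos, state$box, cutoff)$pairs
  if (nrow(pr) > 0) { # canonical (low, high) order
    pr <- cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
  }
  ntail <- length(tail_ids)
  # lipid-lipid connectivity (same leaflet only)
  ll <- pr[pr[, 1] <= ntail & pr[, 2] <= ntail, , drop = FALSE]
  e1 <- tail_lipid[ll[, 1]]; e2 <- tail_lipid[ll[, 2]]
  same <- lb$leaflet[e1] == lb$leaflet[e2] & e1 != e2
  comp <- uf_components(nlip, cbind(e1[same], e2[same]))
  detached <- logical(nlip)
  for (lf in unique(lb$leaflet)) {
    in_lf <- which(lb$leaflet == lf)
    cs <- table(comp[in_lf])
    main <- as.integer(names(cs)[which.max(cs)])
    detached[in_lf] <- comp[in_lf] != main
  }
  coated <- logical(nlip)
  if (length(np_ids) > 0) {
    tn <- pr[pr[, 1] <= ntail & pr[, 2] > ntail, , drop = FALSE]
    touched <- tabulate(ll_bead <- tn[, 1], nbins = ntail) > 0
    # a lipid is coated when all 10 tail beads touch the NP
    cnt <- tapply(touched, tail_lipid, sum)
    coated[as.integer(names(cnt))] <- cnt == 10
  }
  lost <- detached | coated
  list(n_lw = sum(lost),
       per_leaflet = tapply(lost, lb$leaflet, sum),
       lipids = data.frame(lipid = seq_len(nlip), leaflet = lb$leaflet,
                           detached = detached, coated = coated,
                           lost = lost))
}

#' Effective area per lipid
#'
#' a_L^eff = (Lx Ly - A_I^NP) / (n_L - n_L^w): the interfacial area not
#' occupied by the nanoparticle divided by the lipids still in the
#' monolayer.
#'
#' @param area_xy interfacial area Lx*Ly (Rc^2).
#' @param A_np NP interfacial area (Rc^2).
#' @param n_l lipids in the leaflet.
#' @param n_lw lost/coated lipids.
#' @param us a [unit_system()] (for the nm^2 conversion).
#' @return list with `apl_eff` (Rc^2) and `apl_eff_nm2`.
#' @export
effective_area <- function(area_xy, A_np = 0, n_l, n_lw = 0,
                           us = unit_system()) {
  n_res <- n_l - n_lw
  if (n_res <= 0) stop("no lipids left in the monolayer (n_res = 0)")
  a <- (area_xy - A_np) / n_res
  list(apl_eff = a, apl_eff_nm2 = a * us$Rc_nm^2, n_res = n_res,
       A_res = area_xy - A_np)
}
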