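#' Construct a DPD system state
#'
#' A `dpd_state` bundles positions, velocities, bead types, masses and
#' charges with the bonded topology and the periodic orthorhombic box.
#' Coordinates are wrapped into the box on construction. Bead types are
#' character labels from the force-field alphabet; molecule membership is
#' tracked through `mol_id` and `mol_kind` (one of `"water"`, `"gas"`,
#' `"lipid"`, `"np"`).
#'
#' @param pos N x 3 matrix of positions (Rc).
#' @param type character vector of bead type labels.
#' @param box box lengths c(Lx, Ly, Lz) in Rc.
#' @param vel N x 3 matrix of velocities; zero if omitted.
#' @param mass per-bead masses (reduced); 1 if omitted.
#' @param charge per-bead charges; 0 if omitted.
#' @param bonds m x 2 integer matrix of bonded bead indices.
#' @param bond_k,bond_r0 harmonic bond constants (k_BT/Rc^2) and
#'   equilibrium lengths (Rc), one per bond.
#' @param angles m x 3 integer matrix (i, j, k) with j the central bead.
#' @param angle_k,angle_theta0 harmonic angle constants (k_BT/rad^2) and
#'   equilibrium angles (radians).
#' @param mol_id integer molecule id per bead.
#' @param mol_kind molecule kind per bead.
#' @param meta free-form metadata list (lipid/NP bookkeeping).
#' @return an object of class `dpd_state`.
#' @export
dpd_state <- function(pos, type, box, vel = NULL, mass = NULL, charge = NULL,
                      bonds = NULL, bond_k = NULL, bond_r0 = NULL,
                      angles = NULL, angle_k = NULL, angle_theta0 = NULL,
                      mol_id = NULL, mol_kind = NULL, meta = list()) {
  pos <- as.matrix(pos)
  dimnames(pos) <- NULL
  n <- nrow(pos)
  stopifnot(ncol(pos) == 3, length(type) == n, length(box) == 3,
            all(box > 0))
  if (is.null(vel)) vel <- matrix(0, n, 3)
  if (is.null(mass)) mass <- rep(1, n)
  if (is.null(charge)) charge <- rep(0, n)
  if (any(mass <= 0)) stop("all bead masses must be positive")
  if (is.null(bonds)) {
    bonds <- matrix(integer(), 0, 2); bond_k <- bond_r0 <- numeric()
  }
  if (is.null(angles)) {
    angles <- matrix(integer(), 0, 3); angle_k <- angle_theta0 <- numeric()
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  angles <- matrix(as.integer(angles), ncol = 3)
  if (nrow(bonds) > 0 && (max(bonds) > n || min(bonds) < 1))
    stop("bond references a non-existent bead")
  if (nrow(angles) > 0 && (max(angles) > n || min(angles) < 1))
    stop("angle references a non-existent bead")
  stopifnot(length(bond_k) == nrow(bonds), length(bond_r0) == nrow(bonds),
            length(angle_k) == nrow(angles),
            length(angle_theta0) == nrow(angles))
  if (is.null(mol_id)) mol_id <- rep(1L, n)
  if (is.null(mol_kind)) mol_kind <- rep("water", n)
  for (d in 1:3) pos[, d] <- pos[, d] %% box[d]
  st <- list(pos = pos, vel = as.matrix(vel), type = as.character(type),
             mass = as.numeric(mass), charge = as.numeric(charge),
             box = as.numeric(box),
             bonds = bonds, bond_k = as.numeric(bond_k),
             bond_r0 = as.numeric(bond_r0),
             angles = angles, angle_k = as.numeric(angle_k),
             angle_theta0 = as.numeric(angle_theta0),
             mol_id = as.integer(mol_id), mol_kind = as.character(mol_kind),
             meta = meta)
  class(st) <- "dpd_state"
  st
}

#' Number of beads in a state
#' @param state a `dpd_state`.
#' @export
n_beads <- function(state) nrow(state$pos)

#' Draw Maxwell-Boltzmann velocities
#'
#' Initialises velocities at reduced temperature `T_dpd` (variance T/m per
#' component, in internal units where k_BT = T_dpd) and removes the
#' centre-of-mass drift.
#'
#' @param state a `dpd_state`.
#' @param T_dpd reduced temperature.
#' @param seed integer seed (local RNG, does not touch the global stream).
#' @export
init_velocities <- function(state, T_dpd = 0.65, seed = 1L) {
  n <- n_beads(state)
  v <- withr_seed(seed, matrix(rnorm(3 * n, sd = sqrt(T_dpd)), n, 3))
  v <- v / sqrt(state$mass)
  p <- colSums(v * state$mass)
  v <- sweep(v, 2, p / sum(state$mass))
  state$vel <- v
  state
}

# run expr with a local RNG seed, restoring the global stream afterwards
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Minimum-image displacement vectors
#'
#' @param d matrix (or vector) of raw displacements.
#' @param box box lengths.
#' @export
minimum_image <- function(d, box) {
  if (is.null(dim(d))) d - box * round(d / box)
  else sweep(d, 2, box, function(x, L) x - L * round(x / L))
}

#' @export
print.dpd_state <- function(x, ...) {
  cat(sprintf("DPD state: %d beads in box %.2f x %.2f x %.2f Rc\n",
              n_beads(x), x$box[1], x$box[2], x$box[3]))
  tt <- table(x$type)
  cat("  types: ", paste(sprintf("%s=%d", names(tt), tt), collapse = " "),
      "\n", sep = "")
  cat(sprintf("  %d bonds, %d angles, %d molecules\n", nrow(x$bonds),
              nrow(x$angles), length(unique(x$mol_id))))
  invisible(x)
}
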