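#' Reduced unit system of the model
#'
#' Collects the length, energy and temperature conventions used throughout
#' the package. The DPD unit length is the water bead size `Rc` (default
#' 0.646 nm, one bead representing three water molecules at bead density
#' `rho_w` = 3 beads per Rc^3). Energies, interaction constants and reported
#' pressures/tensions are expressed in thermal units (k_BT), with the
#' reduced temperature `T_dpd` (default 0.65) mapping to the laboratory
#' temperature `T_real` (default 293 K). The reduced pressure of bulk water
#' at this state point, 23.7 k_BT/Rc^3, serves as the reference pressure.
#'
#' The single multiplicative constant converting a reduced surface tension
#' (k_BT/Rc^2) to mN/m is `k_B * T_real / Rc^2`, exposed as
#' `$tension_to_mNm` (about 9.693 mN/m per reduced unit at 293 K).
#'
#' @param Rc_nm DPD unit length in nm.
#' @param rho_w water bead number density in beads/Rc^3.
#' @param T_dpd reduced temperature.
#' @param T_real mapped laboratory temperature in K.
#' @param P_ref reference (bulk water) reduced pressure in k_BT/Rc^3.
#' @param gamma0_mNm bare air-water surface tension in mN/m (experimental
#'   value at `T_real`).
#' @param gamma0_reduced in-model bare air-water surface tension in
#'   k_BT/Rc^2, as measured from a water-gas slab simulation with the
#'   force field in use. If `NULL`, the experimental `gamma0_mNm` converted
#'   to reduced units is used wherever a reduced gamma0 is needed.
#' @return an object of class `unit_system`.
#' @export
unit_system <- function(Rc_nm = 0.646, rho_w = 3, T_dpd = 0.65,
                        T_real = 293, P_ref = 23.7,
                        gamma0_mNm = 72.8, gamma0_reduced = NULL) {
  stopifnot(Rc_nm > 0, rho_w > 0, T_dpd > 0, T_real > 0)
  kB <- 1.380649e-23
  tension_to_mNm <- kB * T_real / (Rc_nm * 1e-9)^2 * 1e3 # N/m -> mN/m
  us <- list(Rc_nm = Rc_nm, rho_w = rho_w, T_dpd = T_dpd, T_real = T_real,
             P_ref = P_ref, gamma0_mNm = gamma0_mNm,
             gamma0_reduced = gamma0_reduced,
             tension_to_mNm = tension_to_mNm)
  class(us) <- "unit_system"
  us
}

#' Convert a reduced surface tension to mN/m (or back)
#'
#' Linear map with constant `us$tension_to_mNm`; the inverse round-trips
#' exactly.
#'
#' @param gamma surface tension, reduced (k_BT/Rc^2) unless
#'   `inverse = TRUE`, in which case mN/m.
#' @param us a [unit_system()].
#' @param inverse convert mN/m back to reduced units.
#' @export
convert_tension <- function(gamma, us = unit_system(), inverse = FALSE) {
  if (inverse) gamma / us$tension_to_mNm else gamma * us$tension_to_mNm
}

#' Bare air-water surface tension in reduced units
#'
#' Returns the reduced gamma0 used in the surface-pressure definition
#' Pi = gamma0 - gamma_m. Two conventions are supported: the in-model
#' tension of the bare water-gas interface (`source = "model"`, requires
#' `us$gamma0_reduced` to be set, typically from the force-field file), or
#' the experimental value converted to reduced units
#' (`source = "experimental"`).
#'
#' @param us a [unit_system()].
#' @param source which gamma0 to use; `"config"` picks the in-model value
#'   when available and falls back to the experimental one.
#' @export
gamma_zero <- function(us = unit_system(),
                       source = c("config", "model", "experimental")) {
  source <- match.arg(source)
  gexp <- convert_tension(us$gamma0_mNm, us, inverse = TRUE)
  if (source == "experimental") return(gexp)
  if (source == "model" && is.null(us$gamma0_reduced))
    stop("no in-model gamma0 recorded in this unit system")
  if (is.null(us$gamma0_reduced)) gexp else us$gamma0_reduced
}

#' @export
print.unit_system <- function(x, ...) {
  cat("DPD unit system\n")
  cat(sprintf("  Rc = %.4g nm, rho_w = %g/Rc^3, T_dpd = %g (-> %g K)\n",
              x$Rc_nm, x$rho_w, x$T_dpd, x$T_real))
  cat(sprintf("  reference pressure  = %g kBT/Rc^3\n", x$P_ref))
  cat(sprintf("  tension conversion  = %.4f mN/m per kBT/Rc^2\n",
              x$tension_to_mNm))
  cat(sprintf("  gamma0 = %.3f kBT/Rc^2 (%s)\n",
              gamma_zero(x),
              if (is.null(x$gamma0_reduced)) "experimental" else "in-model"))
  invisible(x)
}
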