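#' Phase observables record
#'
#' Builds a tidy table of per-phase canonical-simulation observables: mean
#' internal energy per molecule, mean density, optional mean pressure, at a
#' set of temperatures. One row per (T, phase).
#'
#' @param T Temperatures in K.
#' @param phase `"liquid"` or `"vapor"` (recycled).
#' @param u Mean internal energy per molecule in kJ/mol.
#' @param rho Mean density in g/L.
#' @param p Optional mean pressure in bar (`NA` when not measured).
#' @param n_molecules Number of molecules in the simulation.
#' @return A tibble with the validated columns.
#' @export
phase_observables <- function(T, phase, u, rho, p = NA_real_,
                              n_molecules = NA_integer_) {
  phase <- match.arg(phase, c("liquid", "vapor"), several.ok = TRUE)
  out <- tibble(T = T, phase = phase, u = u, rho = rho, p = p,
                n_molecules = n_molecules)
  if (any(out$rho <= 0)) abort("densities must be positive")
  out
}

#' Convert internal energies from kcal/mol to kJ/mol
#'
#' @param u_kcal Energies in kcal/mol.
#' @return Energies in kJ/mol (thermochemical calorie, 4.184 J).
#' @export
kcal_to_kJ <- function(u_kcal) u_kcal * 4.184

#' Saturation vapor pressure from pure-vapor observables
#'
#' Returns the simulation-reported mean pressure when present; otherwise the
#' ideal-gas estimate `p = (rho_v / M) R T` with `M = 18.0153` g/mol and
#' `R = 0.0831446` L bar / (mol K). At the low vapor densities of
#' coexistence below ~550 K the ideal-gas estimate is accurate to a few
#' percent.
#'
#' @param vapor One or more rows of vapor-phase observables (columns `T`,
#'   `phase`, `rho`, optional `p`).
#' @param M Molar mass in g/mol.
#' @return Numeric vector of saturation pressures in bar.
#' @examples
#' saturation_pressure(phase_observables(450, "vapor", u = -5, rho = 7.2))
#' @export
saturation_pressure <- function(vapor, M = 18.0153) {
  if (!all(vapor$phase == "vapor")) {
    abort("saturation_pressure() expects vapor-phase observables")
  }
  ideal <- (vapor$rho / M) * .const$R_Lbar * vapor$T
  p <- if ("p" %in% names(vapor)) vapor$p else rep(NA_real_, nrow(vapor))
  dplyr::if_else(is.na(p), ideal, p)
}

#' Enthalpy of evaporation and its decomposition
#'
#' For each temperature with both a liquid and a vapor row, computes the
#' evaporation internal energy `dU = u_v - u_l`, the volume work
#' `pdV = p_sat (v_v - v_l)` with molar volumes `v = M / rho` (1 L bar =
#' 0.1 kJ), and the enthalpy `dH = dU + pdV`. The saturation pressure comes
#' from [saturation_pressure()] on the vapor row. The identity
#' `dH = dU + pdV` holds exactly by construction; the liquid molar volume is
#' retained (not approximated away).
#'
#' @param observables A phase-observables table ([phase_observables()]) with
#'   matched liquid and vapor rows per temperature.
#' @param M Molar mass in g/mol.
#' @param temp_tol Maximum |T_liquid - T_vapor| treated as the same state
#'   point, in K.
#' @return A tibble with one row per temperature: `T`, `dU`, `pdV`, `dH`
#'   (kJ/mol) and `p_sat` (bar).
#' @export
evaporation_enthalpy <- function(observables, M = 18.0153, temp_tol = 1e-6) {
  liq <- dplyr::arrange(dplyr::filter(observables, .data$phase == "liquid"), .data$T)
  vap <- dplyr::arrange(dplyr::filter(observables, .data$phase == "vapor"), .data$T)
  if (nrow(liq) != nrow(vap)) {
    abort("need one liquid and one vapor row per temperature")
  }
  if (any(abs(liq$T - vap$T) > temp_tol)) {
    abort("liquid and vapor temperatures do not match")
  }
  p_sat <- saturation_pressure(vap, M = M)
  v_v <- M / vap$rho      # L/mol
  v_l <- M / liq$rho
  dU <- vap$u - liq$u
  pdV <- p_sat * (v_v - v_l) * .const$kJ_per_Lbar
  tibble(T = liq$T, dU = dU, pdV = pdV, dH = dU + pdV, p_sat = p_sat)
}
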