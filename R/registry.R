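#' Registry of rigid three-point water models
#'
#' Loads the bundled table of 11 common rigid three-point (TIP3P-type) water
#' models: O-H bond length, H-O-H angle, oxygen Lennard-Jones parameters and
#' hydrogen partial charge, together with the publication year. The implied
#' oxygen charge is `-2 * q_H` (each model is electrically neutral). sTIP3P
#' (the CHARMM adaptation of TIP3P) shares all numeric parameters with TIP3P
#' and differs only by an additional weak repulsive site on the hydrogens,
#' recorded in the `extra_h_site` flag; that site carries no charge and does
#' not affect the electrostatic moments.
#'
#' @param path Optional path to a registry CSV with the bundled column layout;
#'   defaults to the table shipped with the package.
#' @return A tibble with columns `name`, `d_OH` (Angstrom), `phi_HOH`
#'   (degrees), `sigma_O` (Angstrom), `epsilon_O` (kcal/mol), `q_H` (e),
#'   `year`, `extra_h_site`.
#' @examples
#' water_models()
#' @export
water_models <- function(path = NULL) {
  path <- path %||% system.file("extdata", "water_models.csv",
                                package = "aquacoex", mustWork = FALSE)
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    abort("bundled water-model registry not found; installation is corrupted",
          class = "aquacoex_config_error")
  }
  models <- as_tibble(readr::read_csv(path, show_col_types = FALSE))
  required <- c("name", "d_OH", "phi_HOH", "sigma_O", "epsilon_O", "q_H", "year")
  missing <- setdiff(required, names(models))
  if (length(missing) > 0) {
    abort(paste0("registry file is missing columns: ",
                 paste(missing, collapse = ", ")),
          class = "aquacoex_config_error")
  }
  validate_water_models(models)
  models
}

validate_water_models <- function(models) {
  with(models, {
    if (any(d_OH <= 0) || any(sigma_O <= 0) || any(epsilon_O <= 0)) {
      abort("geometry and LJ parameters must be positive",
            class = "aquacoex_config_error")
    }
    if (any(phi_HOH <= 0 | phi_HOH >= 180)) {
      abort("bond angle must lie strictly between 0 and 180 degrees",
            class = "aquacoex_config_error")
    }
    if (any(q_H <= 0 | q_H >= 1)) {
      abort("hydrogen partial charge must lie in (0, 1) e",
            class = "aquacoex_config_error")
    }
  })
  invisible(models)
}

#' Dipole moment of three-point water models
#'
#' For a rigid three-point model with hydrogen charge `q_H` at bond length
#' `d_OH` and angle `phi_HOH`, the gas-phase dipole moment is
#' `mu = 2 q_H d_OH cos(theta)` with the half-angle `theta = phi_HOH / 2`,
#' converted from e*Angstrom to Debye (1 e*Angstrom = 4.80320 D).
#'
#' @param models A data frame with columns `d_OH`, `phi_HOH`, `q_H`
#'   (e.g. from [water_models()]).
#' @return Numeric vector of dipole moments in Debye, one per row.
#' @examples
#' dipole_moment(water_models())
#' @export
dipole_moment <- function(models) {
  theta <- models$phi_HOH * pi / 360
  2 * models$q_H * models$d_OH * cos(theta) * .const$debye_per_eA
}

#' Tetrahedral quadrupole moment of three-point water models
#'
#' The quadrupole moment of water is a tensor, but for three-point models it
#' is conventionally reduced to the single scalar tetrahedral component
#' `Q_T = (3/2) q_H d_OH^2 sin^2(theta)` (half-angle `theta = phi_HOH / 2`),
#' equal to `(Theta_xx - Theta_yy) / 2` of the traceless quadrupole tensor
#' evaluated with the molecule in the xz-plane, dipole along z and origin at
#' the oxygen. Converted from e*Angstrom^2 to D*Angstrom.
#'
#' @inheritParams dipole_moment
#' @return Numeric vector of quadrupole moments in D*Angstrom, one per row.
#' @examples
#' quadrupole_moment(water_models())
#' @export
quadrupole_moment <- function(models) {
  theta <- models$phi_HOH * pi / 360
  1.5 * models$q_H * models$d_OH^2 * sin(theta)^2 * .const$debye_per_eA
}

#' Derived electrostatic moments for a registry of models
#'
#' @inheritParams dipole_moment
#' @return The input tibble restricted to `name` plus columns `theta`
#'   (half-angle, degrees), `mu` (Debye) and `Q_T` (D*Angstrom).
#' @examples
#' water_models() |> derived_moments()
#' @export
derived_moments <- function(models) {
  tibble(
    name  = models$name,
    theta = models$phi_HOH / 2,
    mu    = dipole_moment(models),
    Q_T   = quadrupole_moment(models)
  )
}

#' Explicit point-charge coordinates of a three-point model
#'
#' Places the three charge sites of one model in the conventional frame:
#' oxygen (charge `-2 q_H`) at the origin, hydrogens (charge `+q_H`) in the
#' xz-plane at `(+/- d sin(theta), 0, d cos(theta))`, so the dipole points
#' along +z. Used by [point_charge_moments()] as the geometric route to the
#' moments, independent of the closed-form expressions.
#'
#' @param model A single-row data frame with `d_OH`, `phi_HOH`, `q_H`.
#' @return A tibble with columns `q` (e) and `x`, `y`, `z` (Angstrom).
#' @export
charge_sites <- function(model) {
  stopifnot(nrow(model) == 1)
  theta <- model$phi_HOH * pi / 360
  d <- model$d_OH
  tibble(
    q = c(-2 * model$q_H, model$q_H, model$q_H),
    x = c(0,  d * sin(theta), -d * sin(theta)),
    y = c(0, 0, 0),
    z = c(0,  d * cos(theta),  d * cos(theta))
  )
}

#' Electrostatic moments from explicit point charges
#'
#' Computes the dipole vector `sum(q_i r_i)` and the full traceless
#' quadrupole tensor `Theta = (1/2) sum q (3 r r^T - r^2 I)` by direct
#' summation over the charge sites, then reduces them to the magnitude `mu`
#' and the tetrahedral scalar `Q_T = (Theta_xx - Theta_yy) / 2`. This is the
#' brute-force geometric route; it must agree with [dipole_moment()] and
#' [quadrupole_moment()] to numerical precision.
#'
#' @inheritParams dipole_moment
#' @return A tibble with `name`, `mu` (Debye), `Q_T` (D*Angstrom), and a
#'   list-column `theta_tensor` holding each 3x3 traceless tensor
#'   (e*Angstrom^2).
#' @export
point_charge_moments <- function(models) {
  rows <- purrr::map(seq_len(nrow(models)), function(i) {
    sites <- charge_sites(models[i, ])
    r <- as.matrix(sites[, c("x", "y", "z")])
    q <- sites$q
    dip <- colSums(q * r)
    theta_t <- matrix(0, 3, 3)
    for (k in seq_along(q)) {
      rk <- r[k, ]
      theta_t <- theta_t + 0.5 * q[k] * (3 * tcrossprod(rk) - sum(rk^2) * diag(3))
    }
    list(
      mu = sqrt(sum(dip^2)) * .const$debye_per_eA,
      Q_T = 0.5 * (theta_t[1, 1] - theta_t[2, 2]) * .const$debye_per_eA,
      theta_tensor = theta_t
    )
  })
  tibble(
    name = models$name,
    mu = purrr::map_dbl(rows, "mu"),
    Q_T = purrr::map_dbl(rows, "Q_T"),
    theta_tensor = purrr::map(rows, "theta_tensor")
  )
}
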