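#' Slab configuration container
#'
#' A configuration is a tibble of per-molecule reference coordinates (the
#' oxygen site) in Angstrom with the orthorhombic box, molar mass and an
#' optional temperature label attached as attributes. Coordinates are wrapped
#' into `[0, L)` per axis on construction. For slab analysis the elongated
#' axis is z.
#'
#' @param positions A data frame with numeric columns `x`, `y`, `z` (Angstrom).
#' @param box Numeric length-3 vector `(Lx, Ly, Lz)` in Angstrom.
#' @param mass_per_molecule Molar mass in g/mol (default: water).
#' @param temperature Optional temperature label in K.
#' @return A `slab_config` object (tibble subclass).
#' @export
slab_config <- function(positions, box, mass_per_molecule = 18.0153,
                        temperature = NA_real_) {
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    abort("box must be three positive edge lengths (Lx, Ly, Lz)")
  }
  positions <- as_tibble(positions)[, c("x", "y", "z")]
  if (nrow(positions) == 0) {
    abort("configuration contains no molecules")
  }
  for (i in 1:3) {
    ax <- c("x", "y", "z")[i]
    positions[[ax]] <- positions[[ax]] %% box[i]
  }
  structure(positions,
            box = unname(box),
            mass_per_molecule = mass_per_molecule,
            temperature = temperature,
            class = c("slab_config", class(positions)))
}

box_of <- function(config) attr(config, "box")

#' Center the liquid slab in the box along z
#'
#' Translates (and re-wraps) all z-coordinates so that the periodic mass
#' center of the configuration sits at `Lz / 2`. The periodic center is
#' computed by circular statistics: z is mapped to an angle `2 pi z / Lz`,
#' the resultant of the unit vectors is taken, and its phase is mapped back.
#' This is robust when the slab straddles the periodic boundary, which is the
#' step that becomes critical near the critical temperature. If the resultant
#' length falls below `min_resultant` the density is effectively uniform
#' along z (no slab to center) and the input is returned unchanged.
#'
#' The transformation is a pure periodic translation: the multiset of
#' pairwise periodic z-distances is preserved, and the operation is
#' idempotent.
#'
#' @param config A [slab_config()].
#' @param min_resultant Degeneracy guard on the circular-mean resultant
#'   length (default 0.05).
#' @return A centered `slab_config`.
#' @export
center_slab <- function(config, min_resultant = 0.05) {
  if (!inherits(config, "slab_config")) {
    abort("center_slab() expects a slab_config")
  }
  Lz <- box_of(config)[3]
  ang <- 2 * pi * config$z / Lz
  cbar <- mean(cos(ang))
  sbar <- mean(sin(ang))
  resultant <- sqrt(cbar^2 + sbar^2)
  if (resultant < min_resultant) {
    return(config)
  }
  center_z <- ((atan2(sbar, cbar) / (2 * pi)) * Lz) %% Lz
  shift <- Lz / 2 - center_z
  out <- config
  out$z <- (config$z + shift) %% Lz
  out
}

#' Mean mass-density profile along z
#'
#' Histograms the molecule reference sites of a sequence of configurations
#' into z-bins after centering each frame with [center_slab()], and converts
#' counts to mass density in g/L. By construction the profile conserves mass:
#' `sum(density * bin_width * Lx * Ly)` (converted to litres) equals the
#' total molecular mass per frame.
#'
#' @param configs A `slab_config` or list of them sharing one box.
#' @param bin_width Bin width along z in Angstrom (default 0.5).
#' @param center Center each frame first (default TRUE).
#' @return A `density_profile` tibble with columns `z` (bin centers,
#'   Angstrom) and `density` (g/L), and attributes `box`, `bin_width`,
#'   `n_frames`, `mass_per_molecule`.
#' @export
density_profile <- function(configs, bin_width = 0.5, center = TRUE) {
  if (inherits(configs, "slab_config")) configs <- list(configs)
  if (length(configs) == 0) abort("no configurations supplied")
  box <- box_of(configs[[1]])
  same_box <- purrr::map_lgl(configs, function(cf) {
    isTRUE(all.equal(box_of(cf), box, tolerance = 1e-9))
  })
  if (!all(same_box)) {
    abort("all configurations must share identical box dimensions")
  }
  Lz <- box[3]
  n_bins <- max(1L, round(Lz / bin_width))
  bin_width <- Lz / n_bins  # snap so bins tile the box exactly
  edges <- seq(0, Lz, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  for (cf in configs) {
    if (center) cf <- center_slab(cf)
    idx <- pmin(floor(cf$z / bin_width) + 1L, n_bins)
    counts <- counts + tabulate(idx, nbins = n_bins)
  }
  counts <- counts / length(configs)
  mpm <- attr(configs[[1]], "mass_per_molecule")
  bin_vol_L <- box[1] * box[2] * bin_width * .const$L_per_A3
  dens <- counts * (mpm / .const$N_A) / bin_vol_L
  out <- tibble(z = (edges[-1] + edges[-(n_bins + 1)]) / 2, density = dens)
  structure(out,
            box = box, bin_width = bin_width, n_frames = length(configs),
            mass_per_molecule = mpm,
            temperature = attr(configs[[1]], "temperature"),
            class = c("density_profile", class(out)))
}

# double-tanh slab profile; shared width w for both interfaces
tanh_profile <- function(z, rho_v, rho_l, z_lo, z_hi, w) {
  rho_v + (rho_l - rho_v) / 2 * (tanh((z - z_lo) / w) - tanh((z - z_hi) / w))
}

#' Fit hyperbolic-tangent interfaces to a slab density profile
#'
#' Least-squares fit of the double-tanh slab model
#' `rho(z) = rho_v + (rho_l - rho_v)/2 * [tanh((z - z_lo)/w) - tanh((z - z_hi)/w)]`
#' with a single liquid density, vapor density and interface width shared by
#' the two interfaces. The fit yields the coexistence densities `rho_l` and
#' `rho_v` at the profile's temperature.
#'
#' If the fitted density gap is smaller than `indistinct_se_factor` times its
#' standard error the two phases cannot be distinguished (near-critical
#' profile) and the result is flagged `indistinct`, which excludes the point
#' from critical-point fitting by default.
#'
#' @param profile A [density_profile()] (or tibble with `z`, `density`).
#' @param indistinct_se_factor Flag threshold on `(rho_l - rho_v) / se`
#'   (default 3).
#' @return An `interface_fit` object; see [tidy.interface_fit()].
#' @export
fit_interfaces <- function(profile, indistinct_se_factor = 3) {
  z <- profile$z
  dens <- profile$density
  if (length(z) < 8) abort("profile has too few bins to fit two interfaces")
  # deterministic initial guesses from profile quantiles
  rho_l0 <- stats::quantile(dens, 0.9, names = FALSE)
  rho_v0 <- max(stats::quantile(dens, 0.1, names = FALSE), 0)
  half <- (rho_l0 + rho_v0) / 2
  inside <- dens > half
  if (!any(inside) || all(inside)) {
    return(new_interface_fit(rho_l = max(dens), rho_v = min(dens),
                             z_lo = NA_real_, z_hi = NA_real_, w = NA_real_,
                             rmse = sd(dens), converged = FALSE,
                             indistinct = TRUE, profile = profile))
  }
  z_lo0 <- min(z[inside])
  z_hi0 <- max(z[inside])
  w0 <- max(diff(z)[1] * 2, (z_hi0 - z_lo0) / 20)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      density ~ tanh_profile(z, rho_v, rho_l, z_lo, z_hi, w),
      data = tibble(z = z, density = dens),
      start = list(rho_v = rho_v0, rho_l = rho_l0,
                   z_lo = z_lo0, z_hi = z_hi0, w = w0),
      lower = c(0, 0, min(z), min(z), 1e-6),
      upper = c(Inf, Inf, max(z), max(z), diff(range(z))),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_interface_fit(rho_l = rho_l0, rho_v = rho_v0,
                             z_lo = z_lo0, z_hi = z_hi0, w = w0,
                             rmse = NA_real_, converged = FALSE,
                             indistinct = FALSE, profile = profile,
                             message = conditionMessage(fit)))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 5))
  names(se) <- names(est)
  gap <- est[["rho_l"]] - est[["rho_v"]]
  gap_se <- sqrt(sum(se[c("rho_l", "rho_v")]^2, na.rm = TRUE))
  indistinct <- is.finite(gap_se) && gap_se > 0 &&
    gap < indistinct_se_factor * gap_se
  new_interface_fit(
    rho_l = est[["rho_l"]], rho_v = est[["rho_v"]],
    z_lo = est[["z_lo"]], z_hi = est[["z_hi"]], w = est[["w"]],
    rmse = sqrt(mean(stats::resid(fit)^2)),
    se = se, converged = TRUE, indistinct = indistinct, profile = profile)
}

new_interface_fit <- function(rho_l, rho_v, z_lo, z_hi, w, rmse, converged,
                              indistinct, profile, se = NULL, message = NULL) {
  structure(
    list(rho_l = rho_l, rho_v = rho_v, z_lo = z_lo, z_hi = z_hi, w = w,
         rmse = rmse, se = se, converged = converged, indistinct = indistinct,
         temperature = attr(profile, "temperature") %||% NA_real_,
         profile = as_tibble(profile), message = message),
    class = "interface_fit")
}

#' @export
print.interface_fit <- function(x, ...) {
  cat("<interface_fit>\n")
  cat(sprintf("  rho_l = %.2f g/L, rho_v = %.2f g/L\n", x$rho_l, x$rho_v))
  cat(sprintf("  interfaces at z = %.2f / %.2f A, width %.2f A\n",
              x$z_lo, x$z_hi, x$w))
  cat(sprintf("  rmse %.3g g/L; converged: %s; indistinct phases: %s\n",
              x$rmse, x$converged, x$indistinct))
  invisible(x)
}

#' Tidy an interface fit
#'
#' @param x An `interface_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`.
#' @method tidy interface_fit
#' @export
tidy.interface_fit <- function(x, ...) {
  terms <- c("rho_l", "rho_v", "z_lo", "z_hi", "w")
  tibble(
    term = terms,
    estimate = purrr::map_dbl(terms, ~ x[[.x]]),
    std.error = if (is.null(x$se)) NA_real_ else unname(x$se[terms])
  )
}

#' @rdname tidy.interface_fit
#' @method glance interface_fit
#' @export
glance.interface_fit <- function(x, ...) {
  tibble(rmse = x$rmse, converged = x$converged, indistinct = x$indistinct,
         n_bins = nrow(x$profile))
}

#' Plot a density profile and its interface fit
#'
#' @param object An `interface_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot interface_fit
#' @export
autoplot.interface_fit <- function(object, ...) {
  prof <- object$profile
  zz <- seq(min(prof$z), max(prof$z), length.out = 400)
  curve_df <- tibble(
    z = zz,
    density = tanh_profile(zz, object$rho_v, object$rho_l,
                           object$z_lo, object$z_hi, object$w))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$z, y = .data$density)) +
    ggplot2::geom_point(size = 0.8, colour = "grey40") +
    ggplot2::geom_line(data = curve_df, colour = "#2166ac") +
    ggplot2::labs(x = "z [Å]", y = "density [g/L]",
                  title = "Slab density profile with tanh interface fit") +
    ggplot2::theme_minimal()
}
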