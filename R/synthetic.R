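#' Specification of a synthetic slab system
#'
#' Describes a liquid slab coexisting with vapor in an elongated periodic
#' box, with ground-truth densities and interface geometry. The number of
#' molecules defaults to the one implied by integrating the double-tanh
#' density profile over the box (so the generated configurations really
#' carry the requested densities); an explicit `n_molecules` below the
#' implied mass is rejected as infeasible. Defaults mirror a typical
#' coexistence setup: a 20 x 20 x 100 Angstrom box holding ~512 molecules
#' split between a liquid layer and surrounding vapor.
#'
#' @param rho_l,rho_v Target liquid and vapor densities in g/L.
#' @param z_lo,z_hi Interface positions in Angstrom (`0 < z_lo < z_hi < Lz`).
#' @param w Interface width in Angstrom.
#' @param box Edge lengths `(Lx, Ly, Lz)` in Angstrom.
#' @param n_frames Number of frames to generate.
#' @param drift_per_frame Rigid z-drift per frame in Angstrom (exercises
#'   periodic re-centering downstream).
#' @param n_molecules Molecules per frame; default derived from the density
#'   integral.
#' @param mass_per_molecule Molar mass in g/mol.
#' @return A `slab_spec` list.
#' @export
slab_spec <- function(rho_l = 1000, rho_v = 10, z_lo = 30, z_hi = 70, w = 3,
                      box = c(20, 20, 100), n_frames = 200,
                      drift_per_frame = 0, n_molecules = NULL,
                      mass_per_molecule = 18.0153) {
  if (!(z_lo > 0 && z_lo < z_hi && z_hi < box[3])) {
    abort("interfaces must satisfy 0 < z_lo < z_hi < Lz")
  }
  if (rho_l <= rho_v || rho_v < 0) abort("require rho_l > rho_v >= 0")
  zz <- seq(0, box[3], length.out = 4001)
  dens <- tanh_profile(zz, rho_v, rho_l, z_lo, z_hi, w)
  # mass in the box from the trapezoid integral of the target profile
  mass_g <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(zz)) *
    box[1] * box[2] * .const$L_per_A3
  implied_n <- round(mass_g / (mass_per_molecule / .const$N_A))
  if (is.null(n_molecules)) {
    n_molecules <- implied_n
  } else if (n_molecules < implied_n) {
    abort(sprintf(
      "target profile implies %d molecules but only %d supplied; spec infeasible",
      implied_n, n_molecules))
  }
  structure(
    list(rho_l = rho_l, rho_v = rho_v, z_lo = z_lo, z_hi = z_hi, w = w,
         box = box, n_frames = n_frames, drift_per_frame = drift_per_frame,
         n_molecules = n_molecules, mass_per_molecule = mass_per_molecule),
    class = "slab_spec")
}

#' Generate synthetic slab configurations
#'
#' Draws per-frame molecule positions from the double-tanh slab density of a
#' [slab_spec()]: z by inverse-CDF sampling of the normalised profile, x and
#' y uniform in the box cross-section. Each frame is rigidly translated in z
#' by the cumulative drift (and re-wrapped), so downstream centering across
#' the periodic boundary is exercised. Molecules are independent samples
#' with no excluded volume - adequate for density-profile statistics, not
#' for structural observables. Deterministic for a fixed seed.
#'
#' @param spec A [slab_spec()].
#' @param seed Integer RNG seed.
#' @return List of [slab_config()] frames; the spec is attached as attribute
#'   `ground_truth`.
#' @export
simulate_slab_frames <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "slab_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  Lz <- spec$box[3]
  zz <- seq(0, Lz, length.out = 4001)
  dens <- tanh_profile(zz, spec$rho_v, spec$rho_l, spec$z_lo, spec$z_hi, spec$w)
  cdf <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * diff(zz)))
  cdf <- cdf / cdf[length(cdf)]
  # strictly increasing support for the inverse CDF (flat stretches collapse)
  keep <- c(TRUE, diff(cdf) > 0)
  inv <- stats::approxfun(cdf[keep], zz[keep], rule = 2)
  frames <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    z <- inv(stats::runif(spec$n_molecules))
    z <- (z + spec$drift_per_frame * (f - 1)) %% Lz
    frames[[f]] <- slab_config(
      tibble(x = stats::runif(spec$n_molecules, 0, spec$box[1]),
             y = stats::runif(spec$n_molecules, 0, spec$box[2]),
             z = z),
      box = spec$box, mass_per_molecule = spec$mass_per_molecule)
  }
  attr(frames, "ground_truth") <- spec
  frames
}

#' Generate a synthetic coexistence-density table
#'
#' Inverts the universal scaling law and the law of rectilinear diameters:
#' with diameter `rho_C + B (T_C - T)` and gap `A (1 - T/T_C)^beta`, the
#' liquid and vapor branches are `diameter +/- gap/2`, each multiplied by
#' `(1 + eps)` with `eps ~ Normal(0, noise_frac)`. Round-trips exactly
#' through [fit_critical_point()] at zero noise.
#'
#' @param T Temperature grid in K, all strictly below `T_C`.
#' @param T_C,rho_C True critical temperature (K) and density (g/L).
#' @param A,B True scaling amplitude and diameter slope.
#' @param beta Critical exponent (default 0.326).
#' @param noise_frac Relative Gaussian noise standard deviation (default 0).
#' @param seed Integer RNG seed.
#' @return A coexistence tibble (`T`, `rho_l`, `rho_v`) with the true
#'   parameters attached as attribute `ground_truth`.
#' @export
simulate_coexistence_table <- function(T, T_C = 640, rho_C = 300, A = 750,
                                       B = 0.85, beta = 0.326,
                                       noise_frac = 0, seed = 1) {
  if (any(T >= T_C)) {
    abort("all temperatures must lie strictly below T_C",
          class = "aquacoex_domain_error")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  diam <- rho_C + B * (T_C - T)
  half_gap <- A / 2 * (1 - T / T_C)^beta
  rho_l <- (diam + half_gap) * (1 + stats::rnorm(length(T), 0, noise_frac))
  rho_v <- (diam - half_gap) * (1 + stats::rnorm(length(T), 0, noise_frac))
  out <- tibble(T = T, rho_l = rho_l, rho_v = rho_v)
  attr(out, "ground_truth") <- list(T_C = T_C, rho_C = rho_C, A = A, B = B,
                                    beta = beta, noise_frac = noise_frac)
  out
}

#' Specification of a synthetic NPT heating ladder
#'
#' Ground truth for [simulate_heating_ladder()]: an equilibrium liquid
#' density line `rho_eq(T) = rho_ref - rho_slope (T - T_ref)`, an
#' Ornstein-Uhlenbeck fluctuation model around it, and a true evaporation
#' temperature above which each step collapses to the vapor density after an
#' exponentially distributed waiting time followed by a linear ramp.
#'
#' @param T_start,T_end,dT Ladder grid in K; a grid entirely below
#'   `T_evap_true` yields a ladder that never collapses.
#' @param tau_per_step Simulation time per step in ns.
#' @param dt Sampling interval in ns.
#' @param T_evap_true True spontaneous-evaporation temperature in K.
#' @param rho_ref,T_ref,rho_slope Equilibrium density line (g/L, K, g/L/K).
#' @param ou_tau OU relaxation time in ns.
#' @param ou_sd Stationary density fluctuation in g/L.
#' @param mean_wait Mean exponential waiting time to collapse above
#'   `T_evap_true`, in ns.
#' @param ramp_ns Duration of the collapse ramp in ns.
#' @param rho_vapor Post-collapse vapor density in g/L.
#' @return A `ladder_spec` list.
#' @export
ladder_spec <- function(T_start = 580, T_end = 620, dT = 1, tau_per_step = 5,
                        dt = 0.01, T_evap_true = 600, rho_ref = 960,
                        T_ref = 300, rho_slope = 0.9, ou_tau = 0.05,
                        ou_sd = 15, mean_wait = 1, ramp_ns = 0.3,
                        rho_vapor = 5) {
  # T_evap_true may lie above the grid: such ladders simply never collapse
  if (mean_wait <= 0 || ramp_ns <= 0) abort("waiting and ramp times must be positive")
  structure(
    list(T_start = T_start, T_end = T_end, dT = dT,
         tau_per_step = tau_per_step, dt = dt, T_evap_true = T_evap_true,
         rho_ref = rho_ref, T_ref = T_ref, rho_slope = rho_slope,
         ou_tau = ou_tau, ou_sd = ou_sd, mean_wait = mean_wait,
         ramp_ns = ramp_ns, rho_vapor = rho_vapor),
    class = "ladder_spec")
}

#' Equilibrium liquid density line of a ladder spec
#'
#' @param spec A [ladder_spec()].
#' @return A function of temperature returning the equilibrium liquid
#'   density in g/L.
#' @export
rho_eq_of <- function(spec) {
  force(spec)
  function(T) spec$rho_ref - spec$rho_slope * (T - spec$T_ref)
}

#' Generate a synthetic NPT heating ladder
#'
#' For each ladder step, simulates a discrete Ornstein-Uhlenbeck density
#' trace around the equilibrium line. Steps strictly above the true
#' evaporation temperature draw an exponential waiting time, then ramp
#' linearly down to the vapor density and stay there (explosive box
#' expansion). Deterministic for a fixed seed.
#'
#' @param spec A [ladder_spec()].
#' @param seed Integer RNG seed.
#' @return A `heating_ladder` (see [heating_schedule()]) whose `traces`
#'   element holds one [density_trace()] per step; the spec is attached as
#'   attribute `ground_truth`.
#' @export
simulate_heating_ladder <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "ladder_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  ladder <- heating_schedule(spec$T_start, spec$T_end, spec$dT,
                             spec$tau_per_step)
  rho_eq <- rho_eq_of(spec)
  times <- seq(spec$dt, spec$tau_per_step, by = spec$dt)
  alpha <- exp(-spec$dt / spec$ou_tau)
  innov_sd <- spec$ou_sd * sqrt(1 - alpha^2)
  ladder$traces <- purrr::map(ladder$steps$T, function(Tk) {
    mu <- rho_eq(Tk)
    n <- length(times)
    x <- numeric(n)
    eps <- stats::rnorm(n, 0, innov_sd)
    prev <- mu + stats::rnorm(1, 0, spec$ou_sd)
    for (i in seq_len(n)) {
      prev <- mu + alpha * (prev - mu) + eps[i]
      x[i] <- prev
    }
    if (Tk > spec$T_evap_true) {
      t_wait <- stats::rexp(1, rate = 1 / spec$mean_wait)
      if (t_wait < max(times)) {
        frac <- pmin(pmax((times - t_wait) / spec$ramp_ns, 0), 1)
        x <- x * (1 - frac) + spec$rho_vapor * frac
      }
    }
    density_trace(times, pmax(x, 0.1), T = Tk, barostat = "synthetic")
  })
  attr(ladder, "ground_truth") <- spec
  ladder
}

# save/restore the global RNG so seeded generators do not disturb callers
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
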