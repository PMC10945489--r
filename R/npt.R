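#' Density trace container
#'
#' One isobaric-isothermal (NPT) density time series at fixed temperature
#' and pressure setpoint, as a tibble with metadata attributes. The barostat
#' and pre-equilibration state are carried as labels only; they are not used
#' by the detectors but matter for interpreting results (Berendsen traces
#' evaporate ~20 K higher and Parrinello-Rahman ~10 K lower than stochastic
#' cell rescaling; skipping density pre-equilibration shifts the apparent
#' transition ~5-10 K lower).
#'
#' @param times Sample times in ns, strictly increasing.
#' @param density Densities in g/L, positive.
#' @param T Temperature setpoint in K.
#' @param pressure Pressure setpoint in bar (default 1).
#' @param barostat Label: `"berendsen"`, `"c-rescale"`, `"parrinello-rahman"`
#'   or `"synthetic"`.
#' @param pre_equilibrated Was the density pre-equilibrated at the previous
#'   temperature step?
#' @return A `density_trace` tibble with columns `time`, `density`.
#' @export
density_trace <- function(times, density, T, pressure = 1,
                          barostat = c("synthetic", "berendsen", "c-rescale",
                                       "parrinello-rahman"),
                          pre_equilibrated = TRUE) {
  barostat <- match.arg(barostat)
  if (length(times) != length(density)) abort("times and density lengths differ")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  if (any(density <= 0)) abort("densities must be positive")
  out <- tibble(time = times, density = density)
  structure(out, T = T, pressure = pressure, barostat = barostat,
            pre_equilibrated = pre_equilibrated,
            class = c("density_trace", class(out)))
}

#' Detect spontaneous evaporation in a density trace
#'
#' A superheated liquid that spontaneously evaporates shows an explosive
#' box expansion: the density collapses from liquid-like to vapor-like and
#' never recovers. The trace is classified as evaporated when the mean
#' density over its final `tail_frac` fraction falls below
#' `threshold * rho_liquid_ref`. The onset time is the first time the
#' density drops below `threshold * rho_liquid_ref` without ever recovering
#' above `recover * rho_liquid_ref` afterwards (hysteresis guard against a
#' single transient dip).
#'
#' @param trace A [density_trace()] (columns `time`, `density`).
#' @param rho_liquid_ref Reference liquid density in g/L (> 0).
#' @param threshold Collapse threshold as a fraction of the reference
#'   (default 0.5).
#' @param recover Recovery threshold fraction (default 0.8).
#' @param tail_frac Fraction of the trace tail used for the verdict
#'   (default 0.2).
#' @param min_samples Minimum trace length (default 50).
#' @return A one-row tibble with `evaporated` (logical) and `onset_time`
#'   (ns, `NA` when not evaporated).
#' @export
detect_evaporation <- function(trace, rho_liquid_ref, threshold = 0.5,
                               recover = 0.8, tail_frac = 0.2,
                               min_samples = 50) {
  if (!is.finite(rho_liquid_ref) || rho_liquid_ref <= 0) {
    abort("rho_liquid_ref must be positive")
  }
  n <- nrow(trace)
  if (n < min_samples) {
    abort(sprintf("trace has %d samples; need at least %d", n, min_samples))
  }
  tail_idx <- seq.int(from = n - ceiling(tail_frac * n) + 1L, to = n)
  evaporated <- mean(trace$density[tail_idx]) < threshold * rho_liquid_ref
  onset <- NA_real_
  if (evaporated) {
    below <- trace$density < threshold * rho_liquid_ref
    # suffix maximum: does the density ever exceed the recovery level later?
    recovers_after <- rev(cummax(rev(trace$density))) > recover * rho_liquid_ref
    # shift by one: recovery strictly after the candidate onset sample
    recovers_later <- c(recovers_after[-1], FALSE)
    ok <- which(below & !recovers_later)
    if (length(ok) > 0) onset <- trace$time[ok[1]]
  }
  tibble(evaporated = evaporated, onset_time = onset)
}

#' Heating-ladder skeleton
#'
#' Describes a stepwise heating protocol: NPT simulations at temperatures
#' `T_start, T_start + dT, ...` up to `T_end`, each `tau_per_step` ns long.
#' The effective average heating rate is `dT / tau_per_step` (5 ns per 1 K
#' step, i.e. 0.2 K/ns, is slow enough for a converged transition
#' temperature with ~216 molecules).
#'
#' @param T_start,T_end Ladder range in K (`T_end > T_start`).
#' @param dT Temperature spacing in K (> 0).
#' @param tau_per_step Simulation time per step in ns (> 0).
#' @return A `heating_ladder` list with a `steps` tibble (column `T`),
#'   `dT`, `tau_per_step` and `rate` (K/ns).
#' @examples
#' heating_schedule(580, 620, dT = 1, tau_per_step = 5)$rate  # 0.2 K/ns
#' @export
heating_schedule <- function(T_start, T_end, dT, tau_per_step) {
  if (!all(is.finite(c(T_start, T_end, dT, tau_per_step)))) {
    abort("all schedule parameters must be finite")
  }
  if (T_end <= T_start) abort("T_end must exceed T_start")
  if (dT <= 0 || tau_per_step <= 0) abort("dT and tau_per_step must be positive")
  structure(
    list(steps = tibble(T = seq(T_start, T_end, by = dT)),
         dT = dT, tau_per_step = tau_per_step, rate = dT / tau_per_step,
         traces = NULL),
    class = "heating_ladder")
}

#' Temperature of spontaneous evaporation from a heating ladder
#'
#' Applies [detect_evaporation()] to every step of a heating ladder and
#' reports the lowest step temperature that evaporated. The estimate is
#' `consistent` when every hotter step also evaporated; a liquid step above
#' an evaporated one indicates borderline statistics and triggers a warning.
#'
#' @param ladder A `heating_ladder` with per-step traces (see
#'   [simulate_heating_ladder()]), or a list of [density_trace()]s ordered
#'   by temperature.
#' @param rho_ref_by_T Liquid reference density per step: a numeric vector
#'   (one per step) or a function of temperature.
#' @param ... Passed to [detect_evaporation()].
#' @return A one-row tibble with `T_evap` (K; `NA` when no step evaporated),
#'   `reached` and `consistent` (logicals).
#' @export
estimate_T_evap <- function(ladder, rho_ref_by_T, ...) {
  traces <- if (inherits(ladder, "heating_ladder")) ladder$traces else ladder
  if (is.null(traces) || length(traces) == 0) {
    abort("ladder carries no density traces")
  }
  temps <- purrr::map_dbl(traces, ~ attr(.x, "T"))
  if (is.unsorted(temps, strictly = TRUE)) {
    abort("ladder steps must be strictly increasing in temperature")
  }
  refs <- if (is.function(rho_ref_by_T)) rho_ref_by_T(temps) else rho_ref_by_T
  if (length(refs) == 1) refs <- rep(refs, length(traces))
  if (length(refs) != length(traces)) {
    abort("rho_ref_by_T must give one reference per ladder step")
  }
  dots <- list(...)
  evap <- purrr::map2_lgl(traces, refs, function(tr, ref) {
    do.call(detect_evaporation, c(list(tr, ref), dots))$evaporated
  })
  if (!any(evap)) {
    return(tibble(T_evap = NA_real_, reached = FALSE, consistent = TRUE))
  }
  first <- which(evap)[1]
  consistent <- all(evap[first:length(evap)])
  if (!consistent) {
    warn("a step above the first evaporated temperature stayed liquid; T_evap estimate is borderline")
  }
  tibble(T_evap = temps[first], reached = TRUE, consistent = consistent)
}

#' Temperature of maximum density from an isobaric density curve
#'
#' Fits a weighted quartic polynomial to mean densities versus temperature
#' and locates the maximum analytically from the stationary points of the
#' fitted curve (real roots of the derivative cubic with negative second
#' derivative, restricted to the sampled range). The quartic stands in for
#' the empirical liquid-water density function often used for this
#' interpolation; the fit family is isolated behind this one interface. The
#' quartic nests any parabola, so data generated from a quadratic law is
#' recovered exactly. Parameter uncertainties are propagated to `T_MD` and
#' `rho_MD` by the delta method.
#'
#' @param samples Data frame with columns `T` (K), `rho` (g/L) and optional
#'   `sd` (g/L, used as weights `1/sd^2`).
#' @return A `max_density_fit` with `T_MD`, `rho_MD`, `sd_T_MD`,
#'   `sd_rho_MD`, `poly_coeffs` and the samples.
#' @export
fit_density_maximum <- function(samples) {
  samples <- as_tibble(samples)
  if (nrow(samples) < 5) {
    abort("need at least five temperatures to fit the quartic density curve")
  }
  w <- if ("sd" %in% names(samples) && all(is.finite(samples$sd)) &&
           all(samples$sd > 0)) 1 / samples$sd^2 else rep(1, nrow(samples))
  Ts <- samples$T - mean(samples$T)  # centered for conditioning
  fit <- lm(samples$rho ~ Ts + I(Ts^2) + I(Ts^3) + I(Ts^4), weights = w)
  cf <- coef(fit)
  T_MD_c <- quartic_argmax(cf, range(Ts))
  if (is.na(T_MD_c)) {
    abort("fitted density curve has no interior maximum in the sampled range",
          class = "aquacoex_domain_error")
  }
  T_MD <- T_MD_c + mean(samples$T)
  rho_MD <- quartic_eval(cf, T_MD_c)
  # delta-method uncertainties from the coefficient covariance
  V <- suppressWarnings(vcov(fit))  # noiseless data triggers a spurious perfect-fit warning
  gT <- num_grad(function(b) quartic_argmax(b, range(Ts), fallback = T_MD_c), cf)
  grho <- num_grad(function(b) quartic_eval(b, quartic_argmax(b, range(Ts),
                                                              fallback = T_MD_c)), cf)
  sd_T_MD <- sqrt(drop(t(gT) %*% V %*% gT))
  sd_rho_MD <- sqrt(drop(t(grho) %*% V %*% grho))
  structure(
    list(T_MD = T_MD, rho_MD = rho_MD,
         sd_T_MD = sd_T_MD, sd_rho_MD = sd_rho_MD,
         poly_coeffs = cf, T_center = mean(samples$T), samples = samples),
    class = "max_density_fit")
}

quartic_eval <- function(cf, x) {
  cf[[1]] + cf[[2]] * x + cf[[3]] * x^2 + cf[[4]] * x^3 + cf[[5]] * x^4
}

# argmax of the fitted quartic over [range[1], range[2]]; NA when no interior
# stationary maximum exists
quartic_argmax <- function(cf, range, fallback = NA_real_) {
  dcf <- c(cf[[2]], 2 * cf[[3]], 3 * cf[[4]], 4 * cf[[5]])
  if (all(abs(dcf[-1]) < 1e-300)) return(fallback)
  roots <- polyroot(dcf)
  re <- Re(roots)[abs(Im(roots)) < 1e-6 * (1 + abs(Re(roots)))]
  re <- re[re > range[1] & re < range[2]]
  if (length(re) == 0) return(fallback)
  second <- 2 * cf[[3]] + 6 * cf[[4]] * re + 12 * cf[[5]] * re^2
  re <- re[second < 0]
  if (length(re) == 0) return(fallback)
  re[which.max(quartic_eval(cf, re))]
}

num_grad <- function(f, x, h = 1e-6) {
  purrr::map_dbl(seq_along(x), function(i) {
    hi <- h * max(1, abs(x[[i]]))
    xp <- x; xp[[i]] <- x[[i]] + hi
    xm <- x; xm[[i]] <- x[[i]] - hi
    (f(xp) - f(xm)) / (2 * hi)
  })
}

#' @export
print.max_density_fit <- function(x, ...) {
  cat("<max_density_fit>\n")
  cat(sprintf("  T_MD = %.2f K (sd %.2g), rho_MD = %.2f g/L (sd %.2g)\n",
              x$T_MD, x$sd_T_MD, x$rho_MD, x$sd_rho_MD))
  invisible(x)
}

#' Tidy a density-maximum fit
#'
#' @param x A `max_density_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error` for `T_MD`, `rho_MD`.
#' @method tidy max_density_fit
#' @export
tidy.max_density_fit <- function(x, ...) {
  tibble(term = c("T_MD", "rho_MD"),
         estimate = c(x$T_MD, x$rho_MD),
         std.error = c(x$sd_T_MD, x$sd_rho_MD))
}

#' @rdname tidy.max_density_fit
#' @method glance max_density_fit
#' @export
glance.max_density_fit <- function(x, ...) {
  pred <- quartic_eval(x$poly_coeffs, x$samples$T - x$T_center)
  tibble(T_MD = x$T_MD, rho_MD = x$rho_MD, n = nrow(x$samples),
         rmse = sqrt(mean((x$samples$rho - pred)^2)))
}

#' Plot a density-maximum fit
#'
#' @param object A `max_density_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot max_density_fit
#' @export
autoplot.max_density_fit <- function(object, ...) {
  Tgrid <- seq(min(object$samples$T), max(object$samples$T), length.out = 300)
  curve_df <- tibble(T = Tgrid,
                     rho = quartic_eval(object$poly_coeffs,
                                        Tgrid - object$T_center))
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$T, y = .data$rho)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve_df, colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = object$T_MD, linetype = "dashed") +
    ggplot2::labs(x = "T [K]", y = "density [g/L]",
                  title = "Temperature of maximum density") +
    ggplot2::theme_minimal()
}

#' Block means and block-splitting uncertainty of a density trace
#'
#' Splits a trace into `n_blocks` consecutive equal-time blocks, optionally
#' discards the first (equilibration) block, and reports per-block mean
#' densities plus their standard deviation. The default 6 blocks with the
#' first discarded mirrors a 30 ns production split into six 5 ns pieces of
#' which five are evaluated.
#'
#' @param trace A [density_trace()] (columns `time`, `density`).
#' @param n_blocks Number of consecutive blocks (default 6).
#' @param discard_first Drop the first block before averaging (default TRUE).
#' @return A list with `block_means` tibble (`block`, `mean_density`,
#'   `retained`), `mean` and `sd` over the retained blocks.
#' @export
split_uncertainty <- function(trace, n_blocks = 6, discard_first = TRUE) {
  n_retained <- n_blocks - as.integer(discard_first)
  if (n_retained < 2) abort("need at least two retained blocks")
  edges <- seq(min(trace$time), max(trace$time), length.out = n_blocks + 1)
  block <- pmin(findInterval(trace$time, edges, rightmost.closed = TRUE),
                n_blocks)
  bm <- dplyr::summarise(
    dplyr::group_by(tibble(block = block, density = trace$density), .data$block),
    mean_density = mean(.data$density), .groups = "drop")
  bm$retained <- !(discard_first & bm$block == 1L)
  kept <- bm$mean_density[bm$retained]
  if (length(kept) < 2) abort("fewer than two retained blocks contain data")
  list(block_means = bm, mean = mean(kept), sd = sd(kept))
}
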