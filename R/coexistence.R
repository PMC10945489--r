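#' Critical point from coexistence densities
#'
#' Jointly fits the universal scaling law of the coexistence densities,
#' `rho_l - rho_v = A (1 - T/T_C)^beta`, and the law of rectilinear
#' diameters, `(rho_l + rho_v)/2 = rho_C + B (T_C - T)`, to a table of
#' coexistence points with a shared critical temperature. The critical
#' exponent is held fixed at `beta = 0.326` (3D Ising universality class) by
#' default. Because the two laws share `T_C`, the fitted liquid and vapor
#' branches intersect exactly at `(T_C, rho_C)`.
#'
#' The residual vector stacks the liquid and vapor branch residuals,
#' `rho_l(T) = diam(T) + gap(T)/2` and `rho_v(T) = diam(T) - gap(T)/2`,
#' weighted by `1/sd` when per-point uncertainties are present (unweighted
#' otherwise), and is minimised by Levenberg-Marquardt. Initial guesses are
#' deterministic: `T_C0 = 1.05 max(T)`, `rho_C0` and `B0` from a straight
#' line through the diameter, `A0` from the lowest-temperature gap.
#'
#' @param points Data frame with columns `T`, `rho_l`, `rho_v` and optional
#'   `sd_rho_l`, `sd_rho_v`, `flag` (points flagged e.g. `"indistinct"` are
#'   excluded unless `include_flagged`).
#' @param beta Critical exponent, fixed (default 0.326).
#' @param free_beta Also optimise `beta` (off by default; the fixed exponent
#'   is the recommended mode).
#' @param include_flagged Keep near-critical flagged points (default FALSE).
#' @return A `critical_point_fit` with elements `T_C`, `rho_C`, `A`, `B`,
#'   `beta`, standard errors when available, and the points used.
#' @examples
#' tbl <- simulate_coexistence_table(seq(400, 620, 20), T_C = 640,
#'                                   rho_C = 300, A = 750, B = 0.85)
#' fit_critical_point(tbl)
#' @export
fit_critical_point <- function(points, beta = 0.326, free_beta = FALSE,
                               include_flagged = FALSE) {
  points <- as_tibble(points)
  if (!all(c("T", "rho_l", "rho_v") %in% names(points))) {
    abort("points must have columns T, rho_l, rho_v")
  }
  if ("flag" %in% names(points) && !include_flagged) {
    points <- dplyr::filter(points, is.na(.data$flag) | .data$flag == "")
  }
  n_par <- if (free_beta) 5L else 4L
  if (nrow(points) < max(4L, n_par)) {
    abort("need at least as many unflagged coexistence points as parameters",
          class = "aquacoex_fit_error")
  }
  if (diff(range(points$T)) < 50) {
    warn("coexistence points span less than 50 K; extrapolation to T_C may be unreliable")
  }
  w_l <- if ("sd_rho_l" %in% names(points) && all(is.finite(points$sd_rho_l)) &&
             all(points$sd_rho_l > 0)) 1 / points$sd_rho_l else rep(1, nrow(points))
  w_v <- if ("sd_rho_v" %in% names(points) && all(is.finite(points$sd_rho_v)) &&
             all(points$sd_rho_v > 0)) 1 / points$sd_rho_v else rep(1, nrow(points))

  Tv <- points$T
  diam <- (points$rho_l + points$rho_v) / 2
  gap <- points$rho_l - points$rho_v
  if (any(gap <= 0)) {
    abort(paste0("point(s) with non-positive density gap at T = ",
                 paste(signif(Tv[gap <= 0], 6), collapse = ", "),
                 " K: liquid and vapor have merged, so these temperatures",
                 " lie at or above T_C and are outside the scaling-law domain"),
          class = "aquacoex_domain_error")
  }
  # deterministic initial guesses
  T_C0 <- 1.05 * max(Tv)
  dline <- lm(diam ~ Tv)
  B0 <- max(-coef(dline)[[2]], 1e-4)
  rho_C0 <- coef(dline)[[1]] + coef(dline)[[2]] * T_C0
  A0 <- gap[which.min(Tv)] / (1 - min(Tv) / T_C0)^beta
  par0 <- c(T_C = T_C0, rho_C = rho_C0, A = A0, B = B0)
  if (free_beta) par0 <- c(par0, beta = beta)

  resid_fn <- function(p) {
    bet <- if (free_beta) p[["beta"]] else beta
    red <- 1 - Tv / p[["T_C"]]
    if (any(red <= 0) || (free_beta && bet <= 0)) {
      return(rep(1e6, 2 * length(Tv)))
    }
    rl <- p[["rho_C"]] + p[["B"]] * (p[["T_C"]] - Tv) + p[["A"]] / 2 * red^bet
    rv <- p[["rho_C"]] + p[["B"]] * (p[["T_C"]] - Tv) - p[["A"]] / 2 * red^bet
    c(w_l * (points$rho_l - rl), w_v * (points$rho_v - rv))
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 5, 9)) {
    abort(paste0("critical-point fit did not converge (info = ", fit$info,
                 "); initial guesses were T_C = ", signif(T_C0, 6),
                 ", rho_C = ", signif(rho_C0, 6), ", A = ", signif(A0, 6),
                 ", B = ", signif(B0, 6)),
          class = "aquacoex_fit_error")
  }
  est <- fit$par
  if (max(Tv) >= est[["T_C"]]) {
    abort(paste0("input contains temperatures at or above the fitted T_C (",
                 signif(est[["T_C"]], 6),
                 " K); the scaling law is only defined below T_C"),
          class = "aquacoex_domain_error")
  }
  se <- tryCatch({
    covm <- tryCatch(vcov(fit), error = function(e) NULL)
    if (is.null(covm)) rep(NA_real_, length(est)) else sqrt(diag(covm))
  }, error = function(e) rep(NA_real_, length(est)))
  names(se) <- names(est)
  new_critical_point_fit(
    T_C = est[["T_C"]], rho_C = est[["rho_C"]], A = est[["A"]], B = est[["B"]],
    beta = if (free_beta) est[["beta"]] else beta,
    sd_T_C = unname(se["T_C"]), sd_rho_C = unname(se["rho_C"]),
    points = points, source = "fit")
}

new_critical_point_fit <- function(T_C, rho_C, A, B, beta, sd_T_C, sd_rho_C,
                                   points, source, block_fits = NULL) {
  structure(
    list(T_C = T_C, rho_C = rho_C, A = A, B = B, beta = beta,
         sd_T_C = sd_T_C, sd_rho_C = sd_rho_C,
         n_points_used = nrow(points), points = points,
         source = source, block_fits = block_fits),
    class = "critical_point_fit")
}

#' Fitted coexistence branches of a critical-point fit
#'
#' Evaluates the fitted liquid and vapor branches at temperatures `T`
#' (must not exceed `T_C`).
#'
#' @param object A `critical_point_fit`.
#' @param T Temperatures in K.
#' @return Tibble with `T`, `rho_l`, `rho_v`, `diameter`.
#' @export
coexistence_curve <- function(object, T) {
  stopifnot(inherits(object, "critical_point_fit"))
  if (any(T > object$T_C)) abort("curve is only defined for T <= T_C")
  red <- pmax(1 - T / object$T_C, 0)
  diam <- object$rho_C + object$B * (object$T_C - T)
  half_gap <- object$A / 2 * red^object$beta
  tibble(T = T, rho_l = diam + half_gap, rho_v = diam - half_gap,
         diameter = diam)
}

#' Critical point with block-splitting uncertainty
#'
#' Refits the critical point on each block of a trajectory-split analysis
#' (e.g. 20 ns analysed in four 5 ns splits). The central value is the fit on
#' the pooled data; the quoted uncertainty is the standard deviation of the
#' per-block estimates.
#'
#' @param blocks List of coexistence-point tables, one per block, sharing the
#'   same temperature grid.
#' @inheritParams fit_critical_point
#' @return A `critical_point_fit` with `sd_T_C`, `sd_rho_C` from blocks and a
#'   `block_fits` tibble.
#' @export
block_estimates <- function(blocks, beta = 0.326, include_flagged = FALSE) {
  if (!is.list(blocks) || length(blocks) < 2) {
    abort("need at least two blocks for a block uncertainty estimate")
  }
  grids <- purrr::map(blocks, ~ sort(.x$T))
  same <- purrr::map_lgl(grids, ~ isTRUE(all.equal(.x, grids[[1]])))
  if (!all(same)) {
    abort("all blocks must share the same temperature grid")
  }
  per_block <- purrr::map(blocks, fit_critical_point, beta = beta,
                          include_flagged = include_flagged)
  pooled <- fit_critical_point(dplyr::bind_rows(blocks), beta = beta,
                               include_flagged = include_flagged)
  block_tbl <- purrr::map_dfr(per_block, function(f) {
    tibble(T_C = f$T_C, rho_C = f$rho_C, A = f$A, B = f$B)
  })
  new_critical_point_fit(
    T_C = pooled$T_C, rho_C = pooled$rho_C, A = pooled$A, B = pooled$B,
    beta = beta,
    sd_T_C = sd(block_tbl$T_C), sd_rho_C = sd(block_tbl$rho_C),
    points = pooled$points, source = "block", block_fits = block_tbl)
}

#' @export
print.critical_point_fit <- function(x, ...) {
  cat("<critical_point_fit>\n")
  cat(sprintf("  T_C   = %.2f K%s\n", x$T_C,
              if (is.finite(x$sd_T_C)) sprintf(" (sd %.2f)", x$sd_T_C) else ""))
  cat(sprintf("  rho_C = %.2f g/L%s\n", x$rho_C,
              if (is.finite(x$sd_rho_C)) sprintf(" (sd %.2f)", x$sd_rho_C) else ""))
  cat(sprintf("  A = %.3g, B = %.3g, beta = %.3f (fixed), n = %d points\n",
              x$A, x$B, x$beta, x$n_points_used))
  invisible(x)
}

#' Tidy a critical-point fit
#'
#' @param x A `critical_point_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`.
#' @method tidy critical_point_fit
#' @export
tidy.critical_point_fit <- function(x, ...) {
  tibble(
    term = c("T_C", "rho_C", "A", "B", "beta"),
    estimate = c(x$T_C, x$rho_C, x$A, x$B, x$beta),
    std.error = c(x$sd_T_C, x$sd_rho_C, NA_real_, NA_real_, NA_real_)
  )
}

#' @rdname tidy.critical_point_fit
#' @method glance critical_point_fit
#' @export
glance.critical_point_fit <- function(x, ...) {
  curve <- coexistence_curve(x, x$points$T)
  rss <- sum((x$points$rho_l - curve$rho_l)^2 + (x$points$rho_v - curve$rho_v)^2)
  tibble(T_C = x$T_C, rho_C = x$rho_C, beta = x$beta,
         n_points = x$n_points_used,
         rmse = sqrt(rss / (2 * x$n_points_used)),
         source = x$source)
}

#' Plot a coexistence envelope and its critical-point fit
#'
#' @param object A `critical_point_fit`.
#' @param ... Unused.
#' @return A ggplot of the phase envelope with the fitted critical point.
#' @method autoplot critical_point_fit
#' @export
autoplot.critical_point_fit <- function(object, ...) {
  pts <- tidyr::pivot_longer(object$points[, c("T", "rho_l", "rho_v")],
                             c("rho_l", "rho_v"),
                             names_to = "phase", values_to = "rho")
  Tgrid <- seq(min(object$points$T), object$T_C, length.out = 300)
  curve <- tidyr::pivot_longer(coexistence_curve(object, Tgrid)[, 1:3],
                               c("rho_l", "rho_v"),
                               names_to = "phase", values_to = "rho")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$rho, y = .data$T,
                                    colour = .data$phase)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(data = curve) +
    ggplot2::annotate("point", x = object$rho_C, y = object$T_C,
                      shape = 4, size = 3, colour = "darkgreen") +
    ggplot2::scale_colour_manual(
      values = c(rho_l = "#e08214", rho_v = "#2166ac"),
      labels = c(rho_l = "liquid", rho_v = "vapor")) +
    ggplot2::labs(x = "density [g/L]", y = "T [K]", colour = NULL,
                  title = "Liquid-vapor coexistence envelope") +
    ggplot2::theme_minimal()
}
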