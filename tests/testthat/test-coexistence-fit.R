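truth <- list(T_C = 640, rho_C = 300, A = 750, B = 0.85, beta = 0.326)
grid <- seq(400, 620, by = 20)

test_that("a noiseless scaling-law table is recovered to 1e-6 relative", {
  tbl <- simulate_coexistence_table(grid, T_C = truth$T_C, rho_C = truth$rho_C,
                                    A = truth$A, B = truth$B, noise_frac = 0)
  fit <- fit_critical_point(tbl)
  expect_equal(fit$T_C, truth$T_C, tolerance = 1e-6)
  expect_equal(fit$rho_C, truth$rho_C, tolerance = 1e-6)
  expect_equal(fit$A, truth$A, tolerance = 1e-6)
  expect_equal(fit$B, truth$B, tolerance = 1e-6)
})

test_that("the fitted branches intersect exactly at the critical point", {
  tbl <- simulate_coexistence_table(grid, noise_frac = 0.01, seed = 11)
  fit <- fit_critical_point(tbl)
  at_tc <- coexistence_curve(fit, fit$T_C)
  expect_lt(abs(at_tc$rho_l - fit$rho_C), 1e-9)
  expect_lt(abs(at_tc$rho_v - fit$rho_C), 1e-9)
  # the liquid branch falls monotonically everywhere below T_C
  Tg <- seq(min(grid), fit$T_C - 1e-6, length.out = 200)
  curve <- coexistence_curve(fit, Tg)
  expect_true(all(diff(curve$rho_l) < 0))
  # the vapor branch rises where the scaling term dominates the diameter
  # slope, i.e. above the analytic crossover (2 B T_C / (A beta))^(1/(beta-1))
  red_star <- (2 * fit$B * fit$T_C / (fit$A * fit$beta))^(1 / (fit$beta - 1))
  Tg_hi <- seq(fit$T_C * (1 - 0.9 * red_star), fit$T_C - 1e-6,
               length.out = 100)
  curve_hi <- coexistence_curve(fit, Tg_hi)
  expect_true(all(diff(curve_hi$rho_v) > 0))
})

test_that("noisy tables are recovered on average across seeds", {
  fits <- lapply(1:20, function(s) {
    fit_critical_point(simulate_coexistence_table(grid, noise_frac = 0.01,
                                                  seed = s))
  })
  mean_tc <- mean(vapply(fits, `[[`, numeric(1), "T_C"))
  mean_rc <- mean(vapply(fits, `[[`, numeric(1), "rho_C"))
  expect_lt(abs(mean_tc - truth$T_C) / truth$T_C, 0.01)
  expect_lt(abs(mean_rc - truth$rho_C) / truth$rho_C, 0.03)
})

test_that("temperatures at or above the fitted T_C raise a domain error", {
  tbl <- simulate_coexistence_table(grid, noise_frac = 0)
  above <- tibble::add_row(tbl, T = 650, rho_l = 291.5, rho_v = 291.5)
  expect_error(fit_critical_point(above), class = "aquacoex_domain_error")
})

test_that("underdetermined or flagged-out inputs raise a fit error", {
  tbl <- simulate_coexistence_table(grid[1:3], noise_frac = 0)
  expect_error(fit_critical_point(tbl), class = "aquacoex_fit_error")
  flagged <- simulate_coexistence_table(grid, noise_frac = 0)
  flagged$flag <- "indistinct"
  expect_error(fit_critical_point(flagged), class = "aquacoex_fit_error")
})

test_that("near-critical flagged points are excluded by default but can be kept", {
  tbl <- simulate_coexistence_table(grid, noise_frac = 0)
  tbl$flag <- NA_character_
  # corrupt one point badly and flag it: the default fit must ignore it
  tbl$rho_l[5] <- tbl$rho_l[5] + 300
  tbl$flag[5] <- "indistinct"
  fit <- fit_critical_point(tbl)
  expect_equal(fit$n_points_used, length(grid) - 1)
  expect_equal(fit$T_C, truth$T_C, tolerance = 1e-6)
  fit_all <- fit_critical_point(tbl, include_flagged = TRUE)
  expect_equal(fit_all$n_points_used, length(grid))
  expect_gt(abs(fit_all$T_C - truth$T_C), abs(fit$T_C - truth$T_C))
})

test_that("per-point uncertainties act as weights", {
  tbl <- simulate_coexistence_table(grid, noise_frac = 0)
  tbl$rho_l[2] <- tbl$rho_l[2] + 50      # one bad point ...
  tbl$sd_rho_l <- rep(1, nrow(tbl))
  tbl$sd_rho_l[2] <- 1e4                 # ... with huge uncertainty
  tbl$sd_rho_v <- rep(1, nrow(tbl))
  fit_w <- fit_critical_point(tbl)
  expect_equal(fit_w$T_C, truth$T_C, tolerance = 1e-4)
})

test_that("block splitting yields zero spread for identical blocks and errors for one", {
  tbl <- simulate_coexistence_table(grid, noise_frac = 0)
  est <- block_estimates(list(tbl, tbl, tbl, tbl))
  expect_equal(est$sd_T_C, 0, tolerance = 1e-9)
  expect_equal(est$T_C, truth$T_C, tolerance = 1e-6)
  expect_error(block_estimates(list(tbl)), "at least two")
  shifted <- simulate_coexistence_table(grid + 5, noise_frac = 0)
  expect_error(block_estimates(list(tbl, shifted)), "temperature grid")
})

test_that("block spread on noisy blocks is commensurate with the seed spread", {
  blocks <- lapply(1:4, function(s) {
    simulate_coexistence_table(grid, noise_frac = 0.01, seed = 100 + s)
  })
  est <- block_estimates(blocks)
  single <- vapply(1:20, function(s) {
    fit_critical_point(simulate_coexistence_table(grid, noise_frac = 0.01,
                                                  seed = s))$T_C
  }, numeric(1))
  expect_gt(est$sd_T_C, 0)
  expect_lt(est$sd_T_C, 3 * sd(single))
})

test_that("tidy, glance and autoplot summarise a critical-point fit", {
  fit <- fit_critical_point(simulate_coexistence_table(grid, noise_frac = 0.01,
                                                       seed = 2))
  td <- tidy(fit)
  expect_equal(td$term, c("T_C", "rho_C", "A", "B", "beta"))
  gl <- glance(fit)
  expect_equal(gl$n_points, length(grid))
  expect_s3_class(autoplot(fit), "ggplot")
})
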