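make_trace <- function(density, T = 600, dt = 0.01) {
  density_trace(seq_along(density) * dt, density, T = T)
}

test_that("a stable liquid trace is classified as not evaporated", {
  tr <- make_trace(rep(950, 500))
  res <- detect_evaporation(tr, 1000)
  expect_false(res$evaporated)
  expect_true(is.na(res$onset_time))
})

test_that("a collapsing trace is detected with onset near the true collapse", {
  times <- seq(0.01, 5, by = 0.01)
  set.seed(1)
  dens <- 700 + rnorm(length(times), 0, 10)
  frac <- pmin(pmax((times - 2.0) / 0.3, 0), 1)   # true collapse at t = 2.0 ns
  dens <- dens * (1 - frac) + 5 * frac
  res <- detect_evaporation(density_trace(times, pmax(dens, 0.1), T = 610), 700)
  expect_true(res$evaporated)
  expect_gte(res$onset_time, 1.9)
  expect_lte(res$onset_time, 2.3)
})

test_that("a transient dip with recovery is not evaporation", {
  dens <- rep(950, 500)
  dens[250] <- 450
  res <- detect_evaporation(make_trace(dens), 1000)
  expect_false(res$evaporated)
  expect_true(is.na(res$onset_time))
})

test_that("raising the collapse threshold can only flip verdicts liquid-to-evaporated", {
  set.seed(5)
  traces <- lapply(1:8, function(i) {
    times <- seq(0.01, 5, by = 0.01)
    base <- runif(1, 300, 900)
    dens <- base + rnorm(length(times), 0, 30)
    if (i %% 2 == 0) {
      frac <- pmin(pmax((times - runif(1, 1, 4)) / 0.3, 0), 1)
      dens <- dens * (1 - frac) + 5 * frac
    }
    density_trace(times, pmax(dens, 0.1), T = 600)
  })
  for (tr in traces) {
    verdicts <- vapply(seq(0.2, 0.9, by = 0.1), function(th) {
      detect_evaporation(tr, 1000, threshold = th, recover = 0.95)$evaporated
    }, logical(1))
    expect_true(all(diff(verdicts) >= 0))  # FALSE can become TRUE, never back
  }
})

test_that("short traces and bad references are rejected", {
  expect_error(detect_evaporation(make_trace(rep(900, 10)), 1000), "samples")
  expect_error(detect_evaporation(make_trace(rep(900, 100)), -5), "positive")
})

test_that("heating schedules report their rate and reject degenerate input", {
  lad <- heating_schedule(580, 620, dT = 1, tau_per_step = 5)
  expect_equal(lad$rate, 0.2)
  expect_equal(nrow(lad$steps), 41)
  expect_equal(heating_schedule(500, 600, dT = 2, tau_per_step = 5)$rate, 0.4)
  expect_error(heating_schedule(600, 600, dT = 1, tau_per_step = 5))
  expect_error(heating_schedule(500, 600, dT = -1, tau_per_step = 5))
})

test_that("T_evap is recovered within 3 K (median over seeds) on synthetic ladders", {
  spec <- ladder_spec(T_evap_true = 600, dT = 1, tau_per_step = 5)
  ests <- vapply(1:10, function(s) {
    lad <- simulate_heating_ladder(spec, seed = s)
    suppressWarnings(
      estimate_T_evap(lad, rho_ref_by_T = rho_eq_of(spec))$T_evap)
  }, numeric(1))
  expect_lte(abs(stats::median(ests) - 600), 3)
})

test_that("a ladder that never evaporates reports not-reached instead of erroring", {
  spec <- ladder_spec(T_start = 560, T_end = 580, T_evap_true = 580)
  lad <- simulate_heating_ladder(spec, seed = 2)
  res <- estimate_T_evap(lad, rho_ref_by_T = rho_eq_of(spec))
  expect_false(res$reached)
  expect_true(is.na(res$T_evap))
})

test_that("a liquid step above an evaporated one triggers the consistency warning", {
  mk <- function(T, level) {
    density_trace(seq(0.01, 5, 0.01), rep(level, 500), T = T)
  }
  traces <- list(mk(589, 900), mk(590, 5), mk(591, 900), mk(592, 5))
  expect_warning(res <- estimate_T_evap(traces, 900), "borderline")
  expect_equal(res$T_evap, 590)
  expect_false(res$consistent)
})

test_that("a quadratic density curve yields its exact analytic maximum", {
  Ts <- seq(240, 320, by = 10)
  fit <- fit_density_maximum(tibble::tibble(T = Ts,
                                            rho = 1000 - 0.007 * (Ts - 277)^2))
  expect_equal(fit$T_MD, 277, tolerance = 1e-6)
  expect_equal(fit$rho_MD, 1000, tolerance = 1e-6)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "T_MD"], fit$T_MD)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("noisy density maxima are recovered on average across seeds", {
  Ts <- seq(240, 320, by = 10)
  tmds <- vapply(1:20, function(s) {
    set.seed(s)
    fit_density_maximum(tibble::tibble(
      T = Ts, rho = 1000 - 0.007 * (Ts - 277)^2 + rnorm(length(Ts), 0, 0.2),
      sd = rep(0.2, length(Ts))))$T_MD
  }, numeric(1))
  expect_lte(abs(mean(tmds) - 277), 1.5)
})

test_that("monotonic or short density curves are rejected", {
  Ts <- seq(240, 320, by = 10)
  expect_error(fit_density_maximum(tibble::tibble(T = Ts, rho = 900 + Ts)),
               class = "aquacoex_domain_error")
  expect_error(fit_density_maximum(tibble::tibble(T = Ts[1:4],
                                                  rho = c(1, 2, 2, 1))),
               "five")
})

test_that("trajectory splitting averages blocks and honours the discard rule", {
  tr <- density_trace(seq(0.01, 30, 0.01), rep(1000, 3000), T = 300)
  res <- split_uncertainty(tr)
  expect_equal(res$mean, 1000)
  expect_equal(res$sd, 0)
  expect_equal(sum(res$block_means$retained), 5)

  # first 5 ns biased high: the retained mean must exclude it
  dens <- c(rep(1100, 500), rep(1000, 2500))
  biased <- density_trace(seq(0.01, 30, 0.01), dens, T = 300)
  res2 <- split_uncertainty(biased)
  expect_equal(res2$mean, 1000, tolerance = 1e-6)
  res3 <- split_uncertainty(biased, discard_first = FALSE)
  expect_gt(res3$mean, 1000)
  expect_error(split_uncertainty(tr, n_blocks = 2), "two retained")
})

test_that("block spread of an OU trace is commensurate with the seed spread", {
  spec <- ladder_spec(T_start = 300, T_end = 310, T_evap_true = 305,
                      tau_per_step = 30, dt = 0.01)
  mk <- function(seed) simulate_heating_ladder(spec, seed = seed)$traces[[1]]
  sds <- vapply(1:20, function(s) split_uncertainty(mk(s))$sd, numeric(1))
  cross_seed <- sd(vapply(1:20, function(s) mean(mk(s)$density), numeric(1)))
  expect_lt(stats::median(sds), 3 * cross_seed * sqrt(5))
  expect_true(all(sds > 0))
})
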