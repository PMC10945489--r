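test_that("center_slab is idempotent and preserves periodic pairwise distances", {
  slab <- grid_slab()
  centered <- center_slab(slab)
  twice <- center_slab(centered)
  expect_equal(twice$z, centered$z, tolerance = 1e-9)
  expect_equal(pairwise_periodic_dz(centered), pairwise_periodic_dz(slab),
               tolerance = 1e-9)
})

test_that("a slab straddling the periodic boundary is re-centered contiguously", {
  slab <- grid_slab()              # centered at z = 50 by construction
  split <- translate_z(slab, 50)   # now half near z ~ 0, half near z ~ Lz
  recovered <- center_slab(split)
  expect_equal(sort(recovered$z), sort(center_slab(slab)$z), tolerance = 1e-6)
})

test_that("center_slab is translation-covariant over a grid of shifts", {
  slab <- grid_slab()
  ref <- sort(center_slab(slab)$z)
  for (dz in seq(5, 95, by = 10)) {
    shifted <- center_slab(translate_z(slab, dz))
    expect_equal(sort(shifted$z), ref, tolerance = 1e-6)
  }
})

test_that("a uniform gas has no defined center and passes through unchanged", {
  set.seed(42)
  gas <- slab_config(tibble::tibble(x = runif(2000, 0, 20),
                                    y = runif(2000, 0, 20),
                                    z = runif(2000, 0, 100)),
                     box = c(20, 20, 100))
  expect_equal(center_slab(gas)$z, gas$z)
})

test_that("a delta distribution lands in a single bin with the exact density", {
  n <- 64
  cfg <- slab_config(tibble::tibble(x = rep(10, n), y = rep(10, n),
                                    z = rep(50.1, n)),
                     box = c(20, 20, 100))
  prof <- density_profile(cfg, bin_width = 0.5, center = FALSE)
  # hand conversion: n molecules of 18.0153 g/mol in a 20*20*0.5 A^3 bin
  expected <- n * 18.0153 / 6.02214076e23 / (20 * 20 * 0.5 * 1e-27)
  expect_equal(max(prof$density), expected, tolerance = 1e-12)
  expect_equal(sum(prof$density > 0), 1)
})

test_that("profiles conserve mass and are invariant under rigid z-translation", {
  frames <- shared_slab()[1:50]
  prof <- density_profile(frames)
  box <- attr(prof, "box")
  mass_profile <- sum(prof$density * attr(prof, "bin_width") *
                        box[1] * box[2] * 1e-27)
  mass_true <- nrow(frames[[1]]) * 18.0153 / 6.02214076e23
  expect_equal(mass_profile, mass_true, tolerance = 1e-9)

  shifted <- lapply(frames, translate_z, dz = 13.7)
  expect_equal(density_profile(shifted)$density, prof$density,
               tolerance = 1e-12)
})

test_that("noiseless model profiles are recovered to 1e-6 relative", {
  z <- seq(0.25, 99.75, by = 0.5)
  truth <- list(rho_v = 25, rho_l = 900, z_lo = 30, z_hi = 70, w = 3)
  prof <- tibble::tibble(
    z = z,
    density = truth$rho_v + (truth$rho_l - truth$rho_v) / 2 *
      (tanh((z - truth$z_lo) / truth$w) - tanh((z - truth$z_hi) / truth$w)))
  fit <- fit_interfaces(prof)
  expect_true(fit$converged)
  for (p in names(truth)) {
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-6)
  }
  expect_lt(fit$rmse, 1e-6)
})

test_that("interface fits on synthetic slabs recover the generator densities", {
  frames <- shared_slab()
  truth <- attr(frames, "ground_truth")
  prof <- density_profile(frames)
  # the plateau (well inside the liquid) sits within 2% of the target density
  plateau <- prof$density[prof$z > truth$z_lo + 4 * truth$w &
                            prof$z < truth$z_hi - 4 * truth$w]
  expect_lt(abs(mean(plateau) - truth$rho_l) / truth$rho_l, 0.02)
  # the vapor region sits within 2 g/L absolute
  vapor <- prof$density[prof$z < truth$z_lo - 4 * truth$w |
                          prof$z > truth$z_hi + 4 * truth$w]
  expect_lt(abs(mean(vapor) - truth$rho_v), 2)

  fit <- fit_interfaces(prof)
  expect_true(fit$converged)
  expect_false(fit$indistinct)
  expect_lt(abs(fit$rho_l - truth$rho_l) / truth$rho_l, 0.01)
  expect_lt(abs(fit$rho_v - truth$rho_v), 2)
})

test_that("a flat single-phase profile is flagged as indistinct", {
  z <- seq(0.25, 99.75, by = 0.5)
  flat <- tibble::tibble(z = z, density = rep(500, length(z)))
  fit <- fit_interfaces(flat)
  expect_true(fit$indistinct)
})

test_that("profile construction rejects inconsistent boxes and empty input", {
  a <- grid_slab(box = c(20, 20, 100))
  b <- grid_slab(box = c(20, 20, 90), z_hi = 60)
  expect_error(density_profile(list(a, b)), "box")
  expect_error(slab_config(tibble::tibble(x = numeric(), y = numeric(),
                                          z = numeric()),
                           box = c(20, 20, 100)), "no molecules")
})

test_that("interface-fit accessors expose tidy parameters and diagnostics", {
  fit <- fit_interfaces(density_profile(shared_slab()[1:20]))
  td <- tidy(fit)
  expect_equal(td$term, c("rho_l", "rho_v", "z_lo", "z_hi", "w"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
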