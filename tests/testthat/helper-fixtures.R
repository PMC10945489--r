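# Shared fixture builders. Everything is generated in code; the only numbers
# frozen here are oracle values computed independently of the implementation.

# a slab of molecules placed deterministically on a grid inside [z_lo, z_hi]
grid_slab <- function(n = 200, box = c(20, 20, 100), z_lo = 30, z_hi = 70) {
  z <- seq(z_lo, z_hi, length.out = n)
  slab_config(
    tibble::tibble(
      x = rep(seq(1, box[1] - 1, length.out = 10), length.out = n),
      y = rep(seq(1, box[2] - 1, length.out = 20), length.out = n),
      z = z),
    box = box)
}

# rigid periodic translation of a slab_config along z
translate_z <- function(config, dz) {
  box <- attr(config, "box")
  out <- config
  out$z <- (config$z + dz) %% box[3]
  out
}

# sorted periodic pairwise z-distance multiset (centering invariant)
pairwise_periodic_dz <- function(config) {
  Lz <- attr(config, "box")[3]
  dz <- abs(outer(config$z, config$z, "-"))
  dz <- pmin(dz, Lz - dz)
  sort(dz[upper.tri(dz)])
}

# the 200-frame synthetic slab used by several tests (generated once)
shared_slab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- slab_spec(rho_l = 1000, rho_v = 10, z_lo = 30, z_hi = 70, w = 3,
                        box = c(20, 20, 100), n_frames = 200,
                        drift_per_frame = 0.8)
      cache <<- simulate_slab_frames(spec, seed = 1)
    }
    cache
  }
})

# minimal 3-molecule GRO content; box 2 x 2 x 10 nm; coordinates in nm
mini_gro_lines <- function() {
  c("three waters",
    "    9",
    "    1SOL     OW    1   0.500   0.500   2.000",
    "    1SOL    HW1    2   0.550   0.500   2.060",
    "    1SOL    HW2    3   0.450   0.500   2.060",
    "    2SOL     OW    4   1.000   1.000   5.000",
    "    2SOL    HW1    5   1.050   1.000   5.060",
    "    2SOL    HW2    6   0.950   1.000   5.060",
    "    3SOL     OW    7   1.500   1.500   8.000",
    "    3SOL    HW1    8   1.550   1.500   8.060",
    "    3SOL    HW2    9   1.450   1.500   8.060",
    "   2.00000   2.00000  10.00000")
}

# same oxygen coordinates as mini_gro_lines(), in Angstrom, extended XYZ
mini_xyz_lines <- function() {
  c("3",
    'Lattice="20.0 0.0 0.0 0.0 20.0 0.0 0.0 0.0 100.0" Properties=species:S:1:pos:R:3',
    "O  5.0  5.0  20.0",
    "O 10.0 10.0  50.0",
    "O 15.0 15.0  80.0")
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
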