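# Lattice -> bead mapping, LAMMPS interoperability and the internal
# tensile engine.

test_that("intact chains map to 220 beads and 219 bonds each", {
  lat <- tiny_lattice()  # m=1, 2 chains per column, 10 chains
  b <- lattice_to_beads(lat)
  expect_identical(b$n_beads, lat$n_chains * 220L)
  expect_identical(length(b$bond_from), lat$n_chains * 219L)
  expect_identical(b$n_chains, lat$n_chains)
})

test_that("a cleaved lattice bond removes exactly one bridging MD bond", {
  lat <- tiny_lattice()
  b0 <- lattice_to_beads(lat)
  lat$bond_up[4L] <- TRUE  # bond(4->5) of chain 1
  b1 <- lattice_to_beads(lat)
  expect_identical(b1$n_beads, b0$n_beads)
  expect_identical(length(b1$bond_from), length(b0$bond_from) - 1L)
  missing <- setdiff(b0$bond_from, b1$bond_from)
  expect_identical(missing, 40L)  # bond out of the 40th bead (site 4, bead 10)
})

test_that("a removed site drops 10 beads and its incident bonds", {
  lat <- tiny_lattice()
  b0 <- lattice_to_beads(lat)
  s <- which(lat$site_chain == 1L & lat$site_i == 8L)
  lat$removed[s] <- TRUE
  b1 <- lattice_to_beads(lat)
  expect_identical(b1$n_beads, b0$n_beads - 10L)
  # 9 intra-block bonds + 2 bridging bonds disappear
  expect_identical(length(b1$bond_from), length(b0$bond_from) - 11L)
})

test_that("bead/bond bookkeeping matches a brute-force oracle on random patterns", {
  set.seed(91)
  for (rep in 1:10) {
    lat <- tiny_lattice()
    lat$bond_up[sample(which(lat$site_i < 22L), 6)] <- TRUE
    lat$removed[sample.int(lat$n_sites, 5)] <- TRUE
    b <- lattice_to_beads(lat)
    expect_identical(b$n_beads, 10L * sum(!lat$removed))
    # oracle: count bonds site-by-site
    n_bonds <- 0L
    for (s in which(!lat$removed)) {
      n_bonds <- n_bonds + 9L  # intra-block
      i <- lat$site_i[s]
      if (i < 22L && !lat$bond_up[s] && !lat$removed[s + 1L]) {
        n_bonds <- n_bonds + 1L
      }
    }
    expect_identical(length(b$bond_from), n_bonds)
    # bonds connect consecutive beads of the same chain at sane lengths
    bl <- bond_lengths(b)
    expect_true(all(abs(bl - b$r0) < 1e-9))
  }
})

test_that("LAMMPS data files round-trip and declare correct counts", {
  lat <- build_fibril(fibril_geometry(m = 1L, chains_per_column = 1L))
  lat$bond_up[4L] <- TRUE
  b <- lattice_to_beads(lat)
  path <- tempfile(fileext = ".data")
  write_lammps_data(b, path)
  txt <- readLines(path)
  expect_true(any(grepl(sprintf("^%d atoms$", b$n_beads), txt)))
  expect_true(any(grepl(sprintf("^%d bonds$", length(b$bond_from)), txt)))
  back <- read_lammps_data(path)
  expect_identical(nrow(back$atoms), b$n_beads)
  expect_equal(back$atoms$x, b$x, tolerance = 1e-9)
  expect_equal(back$atoms$z, b$z, tolerance = 1e-9)
  expect_equal(back$atoms$mol, b$chain)
  expect_identical(nrow(back$bonds), length(b$bond_from))
  expect_equal(back$bonds[, 1], b$bond_from)
  expect_equal(back$box$z, c(b$box$zlo, b$box$zhi), tolerance = 1e-6)
  expect_error(write_lammps_data(b, file.path(tempdir(), "no/such/dir/x")),
               "cannot open")
})

test_that("full-scale export declares 925 x 220 atoms", {
  lat <- build_fibril(fibril_geometry())
  b <- lattice_to_beads(lat)
  expect_identical(b$n_beads, 203500L)
  expect_identical(b$n_chains, 925L)
})

test_that("bond potential is piecewise with continuous energy and force", {
  ff <- force_field()
  # equilibrium: zero force
  expect_equal(bond_potential(ff$r0, ff)$force, 0)
  expect_equal(bond_potential(ff$r0, ff)$energy, 0)
  # harmonic restoring force just above r0
  dr <- 0.1
  expect_equal(bond_potential(ff$r0 + dr, ff)$force, -ff$k0 * dr)
  # continuity at the stiffening transition r1
  eps <- 1e-9
  lo <- bond_potential(ff$r1 - eps, ff)
  hi <- bond_potential(ff$r1 + eps, ff)
  expect_equal(lo$energy, hi$energy, tolerance = 1e-6)
  expect_equal(lo$force, hi$force, tolerance = 1e-6)
  # stiffened slope is k1
  f1 <- bond_potential(ff$r1 + 0.5, ff)$force
  f2 <- bond_potential(ff$r1 + 0.6, ff)$force
  expect_equal((f1 - f2) / 0.1, ff$k1, tolerance = 1e-6)
  # broken beyond r_break
  br <- bond_potential(ff$r_break + 0.1, ff)
  expect_true(br$broken)
  expect_identical(br$force, 0)
  expect_error(bond_potential(-1, ff), "positive")
})

test_that("force field parameter file loads with sane invariants", {
  ff <- force_field()
  expect_lt(ff$r0, ff$r1)
  expect_lt(ff$r1, ff$r_break)
  expect_identical(ff$r0, 14.7)
  ff2 <- force_field(r0 = 10)
  expect_identical(ff2$r0, 10)
  expect_error(force_field(r1 = 5))  # violates r0 < r1
})

test_that("virial stress of a force-free static configuration is zero", {
  lat <- single_chain_lattice()
  ff <- force_field(lj_epsilon = 0, angle_k = 0)
  b <- lattice_to_beads(lat, ff = ff)
  b$velocities <- list(vx = numeric(b$n_beads), vy = numeric(b$n_beads),
                       vz = numeric(b$n_beads))
  out <- fibrildeg:::run_md(b, ff, n_steps = 10, thermostat = FALSE,
                            sample_every = 5)
  expect_true(all(abs(out$res$frame_stress) < 1e-8))
})

test_that("NVE total energy drifts < 1% over 1e4 steps on a toy system", {
  # bonded terms only: checks the integrator without the (truncated) LJ
  # force discontinuity at the cutoff
  lat <- tiny_lattice()
  ff <- force_field(lj_epsilon = 0)
  b <- lattice_to_beads(lat, ff = ff)
  set.seed(61)
  b <- equilibrate_beads(b, ff, steps = 500)
  out <- fibrildeg:::run_md(b, ff, n_steps = 1e4, thermostat = FALSE,
                            sample_every = 100)
  kb <- 0.0019872041
  etot <- out$res$frame_pe +
    1.5 * b$n_beads * kb * out$res$frame_temp
  drift <- abs(etot[length(etot)] - etot[1])
  expect_lt(drift / abs(mean(etot)), 0.01)
})

test_that("quasi-static chain modulus matches the spring-chain closed form", {
  # a single chain wrapped across the periodic boundary into a ring, no
  # LJ, no angles, T = 0: under affine stretch every bond is strained by
  # the box strain, so the virial modulus is n_bonds * k0 * r0^2 / V
  lat <- single_chain_lattice()
  ff <- force_field(lj_epsilon = 0, angle_k = 0)
  b <- lattice_to_beads(lat, expansion_factor = 1L, ff = ff)  # 22 beads
  b$extra_bonds <- cbind(b$n_beads, 1L)  # close the ring across the box
  b$velocities <- list(vx = numeric(b$n_beads), vy = numeric(b$n_beads),
                       vz = numeric(b$n_beads))
  prot <- tensile_protocol(strain_rate = 5e8, max_strain = 0.01,
                           equilibration_steps = 0, sample_every = 50,
                           bond_sample_every = 0, seed = 1)
  ffq <- ff
  ffq$langevin_damp_fs <- 0    # no friction
  ffq$max_velocity_factor <- 0 # no cap
  tr <- run_tensile(b, ffq, prot, equilibrate = FALSE)
  cv <- tr$curve
  slope <- coef(lm(stress_mpa ~ strain, cv))[[2]]
  area <- fibrildeg:::lateral_area(b, ffq)
  Lz <- b$box$zhi - b$box$zlo
  n_bonds <- length(b$bond_from) + 1L
  expected <- n_bonds * ff$k0 * ff$r0^2 / (area * Lz) * 6947.695
  expect_equal(slope, expected, tolerance = 0.05)
})

test_that("tensile runs are deterministic under a fixed seed", {
  lat <- tiny_lattice()
  ff <- force_field()
  b <- lattice_to_beads(lat, ff = ff)
  prot <- tensile_protocol(strain_rate = 5e9, max_strain = 0.05,
                           equilibration_steps = 200, sample_every = 50,
                           seed = 123)
  t1 <- run_tensile(b, ff, prot)
  t2 <- run_tensile(b, ff, prot)
  expect_identical(t1$curve, t2$curve)
})

test_that("unloaded runs fluctuate about a constant stress baseline", {
  lat <- tiny_lattice()
  ff <- force_field()
  b <- lattice_to_beads(lat, ff = ff)
  set.seed(63)
  b <- equilibrate_beads(b, ff, steps = 500)
  out <- fibrildeg:::run_md(b, ff, n_steps = 2000, thermostat = TRUE,
                            sample_every = 50)
  s <- out$res$frame_stress
  # no trend: drift over the window is small next to the tensile scale
  fit <- coef(lm(s ~ seq_along(s)))[[2]] * length(s)
  expect_lt(abs(fit), 50)  # MPa, vs hundreds under load
  expect_identical(out$res$frame_strain, rep(0, length(s)))
})
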