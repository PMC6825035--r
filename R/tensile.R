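# Built-in reduced-scale tensile MD driver.

MVV2E <- 2390.0574   # (g/mol)(A/fs)^2 -> kcal/mol
KB_KCAL <- 0.0019872041

thermal_sd <- function(ff) sqrt(KB_KCAL * ff$temperature_K / (ff$mass * MVV2E))

init_velocities <- function(n, ff) {
  sd <- thermal_sd(ff)
  list(vx = rnorm(n, 0, sd), vy = rnorm(n, 0, sd), vz = rnorm(n, 0, sd))
}

lateral_area <- function(beads, ff) {
  (diff(range(beads$x)) + ff$lj_sigma) * (diff(range(beads$y)) + ff$lj_sigma)
}

run_md <- function(beads, ff, n_steps, strain_rate_fs = 0,
                   thermostat = TRUE, sample_every = 50,
                   bond_sample_every = 0, use_angles = TRUE,
                   Lz0 = NULL) {
  if (is.null(beads$velocities)) {
    beads$velocities <- init_velocities(beads$n_beads, ff)
  }
  v <- beads$velocities
  Lz <- beads$box$zhi - beads$box$zlo
  if (is.null(Lz0)) Lz0 <- Lz
  params <- list(mass = ff$mass, k0 = ff$k0, k1 = ff$k1, r0 = ff$r0,
                 r1 = ff$r1, r_break = ff$r_break,
                 lj_epsilon = ff$lj_epsilon, lj_sigma = ff$lj_sigma,
                 lj_cutoff = ff$lj_cutoff, angle_k = ff$angle_k,
                 dt = ff$timestep_fs, damp = ff$langevin_damp_fs,
                 vmax = ff$max_velocity_factor * thermal_sd(ff),
                 temperature = ff$temperature_K,
                 thermostat = isTRUE(thermostat),
                 use_angles = isTRUE(use_angles))
  run <- list(zlo = beads$box$zlo, Lz = Lz, Lz0 = Lz0,
              lateral_area = lateral_area(beads, ff),
              n_steps = as.double(n_steps),
              sample_every = as.integer(sample_every),
              bond_sample_every = as.integer(bond_sample_every),
              strain_rate_fs = strain_rate_fs,
              noise_seed = as.double(sample.int(.Machine$integer.max, 1L)))
  if (!is.null(beads$extra_bonds)) {
    run$wrap_a <- as.integer(beads$extra_bonds[, 1])
    run$wrap_b <- as.integer(beads$extra_bonds[, 2])
  }
  res <- cpp_md_run(beads$x, beads$y, beads$z, v$vx, v$vy, v$vz,
                    beads$chain, beads$bonded_next, params, run)
  beads$x <- res$x; beads$y <- res$y; beads$z <- res$z
  beads$velocities <- list(vx = res$vx, vy = res$vy, vz = res$vz)
  beads$bonded_next <- res$bonded_next
  beads$bond_from <- which(res$bonded_next)
  beads$box$zhi <- beads$box$zlo + res$Lz
  list(beads = beads, res = res)
}

#' Thermalise an unloaded bead model
#'
#' Runs the Langevin-thermostatted engine at zero strain rate to relax the
#' mapped lattice structure before a tensile test.
#'
#' @param beads A [lattice_to_beads()] model.
#' @param ff A [force_field()].
#' @param steps Number of MD steps.
#' @param seed Optional seed.
#' @param use_angles Include the backbone angle potential.
#' @return The updated `bead_model` (positions, velocities, box).
#' @export
equilibrate_beads <- function(beads, ff = force_field(), steps = 2000,
                              seed = NULL, use_angles = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  out <- run_md(beads, ff, n_steps = steps, strain_rate_fs = 0,
                thermostat = TRUE, sample_every = max(steps, 1),
                bond_sample_every = 0, use_angles = use_angles)
  out$beads
}

#' Current bond lengths of a bead model
#'
#' @param beads A `bead_model`.
#' @return Numeric vector of intact bond lengths (Angstrom).
#' @export
bond_lengths <- function(beads) {
  a <- beads$bond_from
  Lz <- beads$box$zhi - beads$box$zlo
  dx <- beads$x[a + 1L] - beads$x[a]
  dy <- beads$y[a + 1L] - beads$y[a]
  dz <- beads$z[a + 1L] - beads$z[a]
  dz <- dz - Lz * round(dz / Lz)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Run a strain-controlled tensile test
#'
#' Velocity-Verlet dynamics with a Langevin thermostat and per-bead speed
#' cap; the axial box length grows at the protocol strain rate with an
#' affine remap of coordinates, and each recorded frame carries the box
#' strain and the virial axial stress (tension positive, MPa, using the
#' nominal lateral area of the undeformed model).
#'
#' @param beads A [lattice_to_beads()] model (ideally pre-equilibrated; if
#'   not, the protocol's equilibration steps are run first).
#' @param ff A [force_field()].
#' @param protocol A [tensile_protocol()].
#' @param use_angles Include the backbone angle potential.
#' @param equilibrate Run the protocol's equilibration stage first.
#' @return An object of class `tensile_result`: `curve` (data frame
#'   `strain`, `stress_mpa`, `time_fs`, `temperature_K`, `pe`),
#'   `bond_frames` (list of bond-length vectors), `bond_frame_strain`,
#'   the final `beads`, and bookkeeping fields.
#' @export
run_tensile <- function(beads, ff = force_field(),
                        protocol = tensile_protocol(), use_angles = TRUE,
                        equilibrate = TRUE) {
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  if (equilibrate && protocol$equilibration_steps > 0) {
    beads <- equilibrate_beads(beads, ff, protocol$equilibration_steps,
                               use_angles = use_angles)
  }
  edot_fs <- protocol$strain_rate * 1e-15
  dt <- ff$timestep_fs
  n_steps <- ceiling(log1p(protocol$max_strain) / log1p(edot_fs * dt))
  out <- run_md(beads, ff, n_steps = n_steps, strain_rate_fs = edot_fs,
                thermostat = TRUE, sample_every = protocol$sample_every,
                bond_sample_every = protocol$bond_sample_every,
                use_angles = use_angles)
  res <- out$res
  curve <- data.frame(strain = res$frame_strain,
                      stress_mpa = res$frame_stress,
                      time_fs = res$frame_time,
                      temperature_K = res$frame_temp,
                      pe = res$frame_pe)
  structure(list(curve = curve,
                 bond_frames = res$bond_frames,
                 bond_frame_strain = res$bond_frame_strain,
                 beads = out$beads,
                 broken_bonds = res$broken_bonds,
                 protocol = protocol, ff = ff),
            class = "tensile_result")
}

#' @export
print.tensile_result <- function(x, ...) {
  cat(sprintf(
    "<tensile_result> %d frames to strain %.3f; peak stress %.1f MPa\n",
    nrow(x$curve), max(x$curve$strain), max(x$curve$stress_mpa)))
  invisible(x)
}
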