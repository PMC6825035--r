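# Mapping from the Monte Carlo lattice to the coarse-grained bead-spring
# structure, plus LAMMPS data-file interoperability.

#' Coarse-grained force field parameters
#'
#' Loads the versioned bead-spring parameter set shipped with the package
#' (two-regime bond potential: harmonic stiffness `k0` up to `r1`, a
#' stiffened branch `k1` up to the rupture length `r_break`; 12-6
#' Lennard-Jones cohesion between non-bonded beads; optional harmonic
#' backbone angle). Any field can be overridden through `...`.
#'
#' @param ... Named overrides of the parameter file values.
#' @param file Alternative JSON parameter file.
#' @return An object of class `force_field`.
#' @export
force_field <- function(..., file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "forcefield_cg_collagen.json",
                        package = "fibrildeg")
  }
  ff <- jsonlite::read_json(file, simplifyVector = TRUE)
  dots <- list(...)
  for (nm in names(dots)) ff[[nm]] <- dots[[nm]]
  stopifnot(ff$r0 > 0, ff$r0 < ff$r1, ff$r1 < ff$r_break,
            ff$k0 >= 0, ff$k1 >= 0)
  class(ff) <- "force_field"
  ff
}

#' Two-regime bond potential
#'
#' Harmonic about `r0` up to `r1`; for `r1 < r <= r_break` the stiffness
#' switches to `k1` with energy and force continuous at `r1`; beyond
#' `r_break` the bond is broken (zero energy and force). Energies use the
#' `E = k (r - r0)^2 / 2` convention; the returned force is `-dE/dr`
#' (negative = restoring for a stretched bond).
#'
#' @param r Bond length(s), Angstrom; must be positive.
#' @param params A [force_field()].
#' @return A data frame with `energy`, `force`, and `broken`.
#' @export
bond_potential <- function(r, params = force_field()) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("bond length r must be positive", call. = FALSE)
  }
  p <- params
  e1 <- 0.5 * p$k0 * (p$r1 - p$r0)^2   # energy at the regime switch
  f1 <- p$k0 * (p$r1 - p$r0)           # force magnitude at the switch
  energy <- ifelse(r <= p$r1,
                   0.5 * p$k0 * (r - p$r0)^2,
                   e1 + f1 * (r - p$r1) + 0.5 * p$k1 * (r - p$r1)^2)
  force <- ifelse(r <= p$r1,
                  -p$k0 * (r - p$r0),
                  -(f1 + p$k1 * (r - p$r1)))
  broken <- r > p$r_break
  energy[broken] <- 0
  force[broken] <- 0
  data.frame(energy = energy, force = force, broken = broken)
}

#' Tensile loading protocol
#'
#' @param strain_rate Engineering strain rate (1/s); the reference value
#'   is 1e7. Reduced desk-scale runs use higher rates; pass them
#'   explicitly.
#' @param max_strain Target axial strain.
#' @param equilibration_steps Thermostatted steps before loading.
#' @param sample_every Steps between recorded frames.
#' @param bond_sample_every Record the full bond-length vector every this
#'   many frames (0 = never).
#' @param seed Optional seed for initial velocities and thermostat noise.
#' @return An object of class `tensile_protocol`.
#' @export
tensile_protocol <- function(strain_rate = 1e7, max_strain = 0.45,
                             equilibration_steps = 2000, sample_every = 50,
                             bond_sample_every = 5, seed = NULL) {
  stopifnot(strain_rate > 0, max_strain > 0)
  structure(list(strain_rate = strain_rate, max_strain = max_strain,
                 equilibration_steps = as.integer(equilibration_steps),
                 sample_every = as.integer(sample_every),
                 bond_sample_every = as.integer(bond_sample_every),
                 seed = seed),
            class = "tensile_protocol")
}

#' Map a (degraded) lattice to a bead-spring model
#'
#' Each intact lattice site becomes `expansion_factor` collinear beads at
#' the equilibrium bond spacing `r0`; a cleaved lattice bond removes the
#' single bead-bead bond bridging the two corresponding blocks; a removed
#' site removes its beads (and the bonds into the block). An intact
#' 22-site molecule maps to 220 beads and 219 bonds.
#'
#' @param lattice A `fibril_lattice` (run the removal cascade first).
#' @param expansion_factor Beads per lattice site (default 10).
#' @param ff A [force_field()] (sets `r0` and the bead mass).
#' @return An object of class `bead_model`.
#' @export
lattice_to_beads <- function(lattice, expansion_factor = 10L,
                             ff = force_field()) {
  xf <- as.integer(expansion_factor)
  stopifnot(xf >= 1L)
  r0 <- ff$r0
  keep <- which(!lattice$removed)
  n_beads <- length(keep) * xf
  site_of_bead <- rep(keep, each = xf)
  sub <- rep(seq_len(xf), times = length(keep))
  x <- lattice$col_x[lattice$site_col[site_of_bead]] * 10  # nm -> Angstrom
  y <- lattice$col_y[lattice$site_col[site_of_bead]] * 10
  z <- ((lattice$site_z[site_of_bead] - 1) * xf + (sub - 0.5)) * r0
  chain <- lattice$site_chain[site_of_bead]
  # bond between consecutive beads: always within a site block; across
  # blocks only when the two sites abut in the same chain with an intact
  # lattice bond
  bond_ok <- logical(n_beads)
  within <- sub < xf
  bond_ok[within] <- TRUE
  at_top <- which(sub == xf)
  site_top <- site_of_bead[at_top]
  i_top <- lattice$site_i[site_top]
  spc <- lattice$geometry$sites_per_chain
  nxt_ok <- i_top < spc & !lattice$bond_up[site_top] &
    !lattice$removed[pmin(site_top + 1L, lattice$n_sites)]
  bond_ok[at_top] <- nxt_ok
  # drop the (impossible) bond out of the very last bead
  if (n_beads > 0L) {
    last_ok <- bond_ok & c(chain[-1] == chain[-n_beads], FALSE) &
      c(site_of_bead[-1] - site_of_bead[-n_beads] <= 1L, FALSE)
    bond_ok <- last_ok
  }
  box_pad <- 50
  beads <- list(
    x = x, y = y, z = z,
    chain = as.integer(chain),
    bond_from = which(bond_ok),
    bonded_next = bond_ok,
    mass = ff$mass,
    r0 = r0,
    expansion_factor = xf,
    box = list(xlo = min(x, 0) - box_pad, xhi = max(x, 0) + box_pad,
               ylo = min(y, 0) - box_pad, yhi = max(y, 0) + box_pad,
               zlo = 0, zhi = lattice$n_z * xf * r0,
               periodic_z = TRUE),
    n_beads = n_beads,
    n_chains = length(unique(chain)),
    velocities = NULL
  )
  class(beads) <- "bead_model"
  beads
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model> %d beads, %d bonds, %d chains\n",
              x$n_beads, length(x$bond_from), x$n_chains))
  invisible(x)
}

bead_angles <- function(beads) {
  ok <- beads$bonded_next
  first <- which(ok & c(ok[-1], FALSE))
  cbind(first, first + 1L, first + 2L)
}

#' Write a LAMMPS data file
#'
#' Molecular-style data file (atoms, bonds, angles, one type each) usable
#' by LAMMPS unmodified. Angles are the consecutive-bond triplets of each
#' chain.
#'
#' @param beads A [lattice_to_beads()] model.
#' @param path Output path.
#' @param include_angles Write the angle section (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(beads, path, include_angles = TRUE) {
  ang <- if (include_angles) bead_angles(beads) else
    matrix(integer(0), ncol = 3)
  n <- beads$n_beads
  nb <- length(beads$bond_from)
  con <- suppressWarnings(try(file(path, "w"), silent = TRUE))
  if (inherits(con, "try-error")) {
    stop("cannot open for writing: ", path, call. = FALSE)
  }
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file: coarse-grained collagen fibril (fibrildeg)")
  w("")
  w("%d atoms", n)
  w("%d bonds", nb)
  w("%d angles", nrow(ang))
  w("1 atom types")
  w("1 bond types")
  if (nrow(ang) > 0) w("1 angle types")
  w("")
  b <- beads$box
  w("%.6f %.6f xlo xhi", b$xlo, b$xhi)
  w("%.6f %.6f ylo yhi", b$ylo, b$yhi)
  w("%.6f %.6f zlo zhi", b$zlo, b$zhi)
  w("")
  w("Masses")
  w("")
  w("1 %.6f", beads$mass)
  w("")
  w("Atoms # molecular")
  w("")
  writeLines(sprintf("%d %d 1 %.10g %.10g %.10g",
                     seq_len(n), beads$chain, beads$x, beads$y, beads$z),
             con)
  w("")
  w("Bonds")
  w("")
  if (nb > 0) {
    writeLines(sprintf("%d 1 %d %d", seq_len(nb), beads$bond_from,
                       beads$bond_from + 1L), con)
  }
  if (nrow(ang) > 0) {
    w("")
    w("Angles")
    w("")
    writeLines(sprintf("%d 1 %d %d %d", seq_len(nrow(ang)),
                       ang[, 1], ang[, 2], ang[, 3]), con)
  }
  invisible(path)
}

#' Read back a LAMMPS data file
#'
#' Minimal reader for the files produced by [write_lammps_data()] (and
#' other molecular-style data files): returns atoms, bonds, angles and box
#' bounds.
#'
#' @param path Path to a LAMMPS data file.
#' @return A list with `atoms` (data frame `id`, `mol`, `x`, `y`, `z`),
#'   `bonds` (two-column matrix), `angles`, and `box`.
#' @export
read_lammps_data <- function(path) {
  lines <- readLines(path)
  strip <- function(s) sub("\\s+#.*$", "", trimws(s))
  header_count <- function(tag) {
    m <- grep(paste0("^\\s*\\d+\\s+", tag, "\\s*$"), lines, value = TRUE)
    if (!length(m)) 0L else as.integer(sub("\\s.*$", "", trimws(m[1])))
  }
  n_atoms <- header_count("atoms")
  n_bonds <- header_count("bonds")
  n_angles <- header_count("angles")
  get_box <- function(tag) {
    m <- grep(paste0(tag, "\\s*$"), lines, value = TRUE)
    as.numeric(strsplit(trimws(m[1]), "\\s+")[[1]][1:2])
  }
  section <- function(name, count, ncol_min) {
    if (count == 0L) return(NULL)
    at <- grep(paste0("^\\s*", name, "\\b"), lines)[1]
    if (is.na(at)) stop("section not found: ", name, call. = FALSE)
    body <- lines[(at + 2):(at + 1 + count)]
    out <- do.call(rbind, lapply(strsplit(vapply(body, strip, ""), "\\s+"),
                                 function(v) as.numeric(v[seq_len(ncol_min)])))
    dimnames(out) <- NULL
    out
  }
  atoms <- section("Atoms", n_atoms, 6L)
  atoms <- data.frame(id = atoms[, 1], mol = atoms[, 2],
                      x = atoms[, 4], y = atoms[, 5], z = atoms[, 6])
  atoms <- atoms[order(atoms$id), ]
  bonds <- section("Bonds", n_bonds, 4L)
  angles <- section("Angles", n_angles, 5L)
  list(atoms = atoms,
       bonds = if (is.null(bonds)) NULL else bonds[, 3:4, drop = FALSE],
       angles = if (is.null(angles)) NULL else angles[, 3:5, drop = FALSE],
       box = list(x = get_box("xlo xhi"), y = get_box("ylo yhi"),
                  z = get_box("zlo zhi")))
}
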