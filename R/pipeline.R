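# End-to-end orchestration: enzyme-count presets, run configuration,
# pipeline driver and canonical toy fixtures.

#' Enzyme-count presets
#'
#' The four standard degradation conditions: system 1 (4 collagenases : 4
#' gelatinases), system 2 (8:8), system 3 (6:2) and system 4 (2:6).
#'
#' @param system Integer 1..4 or `"system1"` .. `"system4"`.
#' @return A list with `n_collagenase`, `n_gelatinase`, `ratio`, `label`.
#' @export
system_preset <- function(system) {
  if (is.character(system)) {
    system <- as.integer(sub("^system", "", system))
  }
  tab <- list(
    list(n_collagenase = 4L, n_gelatinase = 4L),
    list(n_collagenase = 8L, n_gelatinase = 8L),
    list(n_collagenase = 6L, n_gelatinase = 2L),
    list(n_collagenase = 2L, n_gelatinase = 6L)
  )
  if (is.na(system) || system < 1L || system > 4L) {
    stop("unknown system preset; use 1..4", call. = FALSE)
  }
  p <- tab[[system]]
  p$ratio <- p$n_collagenase / p$n_gelatinase
  p$label <- sprintf("system%d", system)
  p
}

#' Assemble a run configuration
#'
#' A plain nested list with the defaults of the reference setup (m = 4
#' fibril, standard energies and kinetics, 1.1% degradation stop, 1e7 1/s
#' strain rate). Any block can be overridden; unknown fields are
#' rejected. Configurations round-trip through JSON
#' ([read_run_config()]).
#'
#' @param geometry,energy,kinetics,enzymes,stop,md Named lists of
#'   overrides for each block.
#' @param seed Integer seed recorded with all outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(geometry = list(), energy = list(),
                       kinetics = list(), enzymes = list(preset = 1L),
                       stop = list(target_pct = 1.1), md = list(),
                       seed = 1L) {
  defaults <- list(
    geometry = formals(fibril_geometry),
    energy = list(e_well = -2, well_index = 5L,
                  e_collagenase_gelatin = 0.5, e_gelatinase_collagen = 0,
                  e_gelatinase_gelatin = -0.5, cleave_mode = "well"),
    kinetics = list(p_vertical = 0.90, p_horizontal = 0.09,
                    p_cleave_attempt = 0.01, cleave_rate = 0.35,
                    diffusion_coefficient = 8e5),
    enzymes = list(preset = NULL, n_collagenase = NULL,
                   n_gelatinase = NULL),
    stop = list(target_pct = 1.1, max_steps = NULL, max_time = NULL),
    md = list(run_tensile = FALSE, export_lammps = NULL,
              expansion_factor = 10L, strain_rate = 1e7,
              max_strain = 0.45, equilibration_steps = 2000)
  )
  merge_block <- function(name, user) {
    base <- lapply(defaults[[name]], function(v) {
      if (is.language(v) || identical(v, quote(expr = ))) NULL else v
    })
    unknown <- setdiff(names(user), names(base))
    if (length(unknown)) {
      stop(sprintf("unknown field(s) in `%s` block: %s", name,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    base[names(user)] <- user
    base
  }
  cfg <- list(
    geometry = merge_block("geometry", geometry),
    energy = merge_block("energy", energy),
    kinetics = merge_block("kinetics", kinetics),
    enzymes = merge_block("enzymes", enzymes),
    stop = merge_block("stop", stop),
    md = merge_block("md", md),
    seed = as.integer(seed)
  )
  pr <- cfg$enzymes$preset
  if (!is.null(pr) && length(pr) == 1L && !is.na(pr)) {
    p <- system_preset(pr)
    cfg$enzymes$n_collagenase <- p$n_collagenase
    cfg$enzymes$n_gelatinase <- p$n_gelatinase
    cfg$enzymes$preset <- p$label
  } else {
    cfg$enzymes$preset <- NULL
  }
  if (is.null(cfg$enzymes$n_collagenase) ||
      is.null(cfg$enzymes$n_gelatinase)) {
    stop("enzymes block needs a preset or explicit counts", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON file with configuration blocks.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[intersect(names(raw),
                                    c("geometry", "energy", "kinetics",
                                      "enzymes", "stop", "md", "seed"))])
}

# small polynomial rolling hash so every artifact can be stamped with its
# provenance (stays within exact double-precision integer range)
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full degradation -> mechanics pipeline
#'
#' Builds the fibril, places the configured enzymes, degrades to the stop
#' condition, computes the degradation statistics, and (optionally) maps
#' to beads for a LAMMPS export and/or an internal reduced-scale tensile
#' test with mechanics post-processing. All artifacts are stamped with the
#' seed and a configuration hash.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @param quiet Suppress progress messages.
#' @return A list bundle with the state, analyses and artifact paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)
  geo <- do.call(fibril_geometry, config$geometry)
  lat <- build_fibril(geo)
  en <- do.call(energy_model, config$energy)
  kin <- do.call(kinetics_config,
                 c(config$kinetics, list(site_length = geo$site_length)))
  st <- place_enzymes(lat, config$enzymes$n_collagenase,
                      config$enzymes$n_gelatinase, energy = en,
                      kinetics = kin)
  say("degrading to stop condition ...")
  st <- run_until(st, target_pct = config$stop$target_pct,
                  max_steps = config$stop$max_steps,
                  max_time = config$stop$max_time,
                  snapshot_every = 1e4)
  bundle <- list(
    config = config,
    config_hash = config_hash(config),
    seed = config$seed,
    state = st,
    percent_degradation = percent_degradation(st$lattice),
    time_course = time_course(st),
    density_cleaved = density_map(st, "cleaved"),
    density_removed = density_map(st, "removed")
  )
  md <- config$md
  if (!is.null(md$export_lammps) || isTRUE(md$run_tensile)) {
    ff <- force_field()
    beads <- lattice_to_beads(st$lattice, md$expansion_factor, ff)
    bundle$beads <- beads
    if (!is.null(md$export_lammps)) {
      say("writing LAMMPS data file ...")
      write_lammps_data(beads, md$export_lammps)
      bundle$lammps_path <- md$export_lammps
    }
    if (isTRUE(md$run_tensile)) {
      say("running internal tensile test ...")
      prot <- tensile_protocol(strain_rate = md$strain_rate,
                               max_strain = md$max_strain,
                               equilibration_steps = md$equilibration_steps,
                               seed = config$seed)
      tr <- run_tensile(beads, ff, prot)
      bundle$tensile <- tr
      bundle$toughness <- toughness(tr)
      bundle$yield <- tryCatch(yield_point(tr), error = function(e) NULL)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- list(config = unclass(config), config_hash = bundle$config_hash,
                  seed = config$seed,
                  percent_degradation = bundle$percent_degradation,
                  n_collagenase = config$enzymes$n_collagenase,
                  n_gelatinase = config$enzymes$n_gelatinase)
    jsonlite::write_json(stamp, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(bundle$time_course, file.path(out_dir, "time_course.csv"),
              row.names = FALSE)
    write.csv(st$events, file.path(out_dir, "events.csv"),
              row.names = FALSE)
    write.csv(bundle$density_cleaved$cells,
              file.path(out_dir, "density_cleaved.csv"), row.names = FALSE)
    write.csv(bundle$density_removed$cells,
              file.path(out_dir, "density_removed.csv"), row.names = FALSE)
    if (!is.null(bundle$tensile)) {
      write.csv(bundle$tensile$curve,
                file.path(out_dir, "stress_strain.csv"), row.names = FALSE)
    }
    bundle$out_dir <- out_dir
  }
  bundle
}

#' Canonical toy fixtures
#'
#' Small documented systems used across the test-suite:
#' `"single-chain"` (one molecule, 22 sites), `"m1-minifibril"` (one
#' microfibril, 5 columns x 2 molecules) and `"m2-reduced"` (7
#' microfibrils, 2 molecules per column - the reduced fibril used for
#' desk-scale tensile tests).
#'
#' @param name Fixture name.
#' @return A list with `lattice` and `config`.
#' @export
make_fixture <- function(name) {
  fixtures <- list(
    "single-chain" = list(geometry = list(m = 1L, chains_per_column = 1L,
                                          single_column = TRUE)),
    "m1-minifibril" = list(geometry = list(m = 1L, chains_per_column = 2L)),
    "m2-reduced" = list(geometry = list(m = 2L, chains_per_column = 2L))
  )
  if (!name %in% names(fixtures)) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(fixtures), collapse = ", ")), call. = FALSE)
  }
  cfg <- run_config(geometry = fixtures[[name]]$geometry,
                    enzymes = list(n_collagenase = 1L, n_gelatinase = 0L))
  list(lattice = build_fibril(do.call(fibril_geometry, cfg$geometry)),
       config = cfg)
}
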