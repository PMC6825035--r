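# Dynamic Metropolis Monte Carlo state and operations.
#
# `mc_step()`/`run_until()` delegate to the compiled engine; the granular
# operations below (interaction_energy, propose_move, attempt_cleave,
# remove_disconnected) expose the same rules one event at a time for
# inspection and testing.

site_flanked <- function(lattice, s) {
  i <- lattice$site_i[s]
  spc <- lattice$geometry$sites_per_chain
  (i < spc & lattice$bond_up[s]) | (i > 1 & lattice$bond_up[pmax(s - 1L, 1L)])
}

#' Interaction energy of an enzyme on a lattice site
#'
#' @param kind `"collagenase"` or `"gelatinase"`.
#' @param site_id Site id (must be intact).
#' @param lattice A `fibril_lattice`.
#' @param energy An [energy_model()].
#' @return Energy in kT; `Inf` marks the forbidden collagenase-on-
#'   cleaved-flank case (rejected before any arithmetic by the engine).
#' @export
interaction_energy <- function(kind = c("collagenase", "gelatinase"),
                               site_id, lattice, energy = energy_model()) {
  kind <- match.arg(kind)
  s <- check_site(lattice, site_id)
  if (lattice$removed[s]) {
    stop("site is removed; enzymes cannot occupy removed sites",
         call. = FALSE)
  }
  if (kind == "collagenase" && site_flanked(lattice, s)) {
    return(Inf)
  }
  gel <- lattice$gelatin[lattice$site_chain[s]]
  if (kind == "collagenase") {
    if (gel) return(energy$e_collagenase_gelatin)
    if (lattice$site_i[s] == energy$well_index) return(energy$e_well)
    return(0)
  }
  if (gel) energy$e_gelatinase_gelatin else energy$e_gelatinase_collagen
}

#' Metropolis acceptance test
#'
#' Accepts with probability `min(1, exp(-delta_e))`. Vectorised over
#' `delta_e`.
#'
#' @param delta_e Energy change(s) in kT; must be finite (forbidden targets
#'   are rejected before this test).
#' @return Logical vector of acceptances.
#' @export
metropolis_accept <- function(delta_e) {
  if (!all(is.finite(delta_e))) {
    stop("delta_e must be finite", call. = FALSE)
  }
  delta_e <= 0 | runif(length(delta_e)) < exp(-delta_e)
}

#' Place enzymes on the fibril surface
#'
#' Enzymes are placed uniformly at random on distinct intact surface sites
#' (collagenases additionally avoid cleaved-flanked sites). Returns the
#' Monte Carlo state that the stepping functions evolve.
#'
#' @param lattice A `fibril_lattice`.
#' @param n_collagenase,n_gelatinase Enzyme counts (see [system_preset()]
#'   for the standard 4:4, 8:8, 6:2 and 2:6 systems).
#' @param energy An [energy_model()].
#' @param kinetics A [kinetics_config()]; defaults to one calibrated for
#'   the lattice's `site_length`.
#' @param seed Optional integer seed (calls [set.seed()]).
#' @return An object of class `mc_state`.
#' @export
place_enzymes <- function(lattice, n_collagenase, n_gelatinase,
                          energy = energy_model(), kinetics = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(kinetics)) {
    kinetics <- kinetics_config(site_length = lattice$geometry$site_length)
  }
  n_c <- as.integer(n_collagenase)
  n_g <- as.integer(n_gelatinase)
  stopifnot(n_c >= 0, n_g >= 0)
  surf <- surface_sites(lattice)
  if (n_c + n_g > length(surf)) {
    stop(sprintf("too many enzymes: %d requested, %d surface sites",
                 n_c + n_g, length(surf)), call. = FALSE)
  }
  kinds <- c(rep(0L, n_c), rep(1L, n_g))
  sites <- integer(0)
  avail <- surf
  avail_c <- surf[!site_flanked(lattice, surf)]
  for (k in kinds) {
    pool <- if (k == 0L) setdiff(avail_c, sites) else setdiff(avail, sites)
    if (length(pool) == 0L) stop("no free surface site for enzyme placement",
                                 call. = FALSE)
    sites <- c(sites, pool[[sample.int(length(pool), 1L)]])
  }
  enz <- data.frame(
    enzyme_id = seq_along(kinds),
    kind = ifelse(kinds == 0L, "collagenase", "gelatinase"),
    site_id = as.integer(sites),
    stringsAsFactors = FALSE
  )
  st <- list(
    lattice = lattice,
    enzymes = enz,
    enzymes0 = enz,
    energy = energy,
    kinetics = kinetics,
    elapsed_time = 0,
    step_count = 0,
    events = empty_event_log(),
    occupancy = matrix(0, nrow = lattice$geometry$sites_per_chain,
                       ncol = nrow(enz)),
    snapshots = NULL,
    snap_z = NULL
  )
  class(st) <- "mc_state"
  st
}

empty_event_log <- function() {
  data.frame(step = numeric(0), time_s = numeric(0),
             event_type = character(0), enzyme_id = integer(0),
             enzyme_kind = character(0), site_id = integer(0),
             i = integer(0), chain_id = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.mc_state <- function(x, ...) {
  cat("<mc_state>\n")
  cat(sprintf("  %d collagenase(s), %d gelatinase(s)\n",
              sum(x$enzymes$kind == "collagenase"),
              sum(x$enzymes$kind == "gelatinase")))
  cat(sprintf("  steps: %g, time: %.4g s, degradation: %.4f%%\n",
              x$step_count, x$elapsed_time, percent_degradation(x$lattice)))
  cat(sprintf("  events logged: %d\n", nrow(x$events)))
  invisible(x)
}

enzyme_kind_code <- function(state) {
  ifelse(state$enzymes$kind == "collagenase", 0L, 1L)
}

#' Advance the Monte Carlo simulation
#'
#' `run_until()` iterates single enzyme selections until a stop condition:
#' a target percent degradation, a maximum number of steps, or a maximum
#' simulated time. `mc_step()` performs exactly one selection (with move
#' recording on).
#'
#' @param state An `mc_state` from [place_enzymes()].
#' @param target_pct Stop when percent degradation reaches this value.
#' @param max_steps Stop after this many enzyme selections.
#' @param max_time Stop when the simulated clock reaches this value (s).
#' @param record_moves Log every accepted move (needed for event-based
#'   trajectories; off by default to bound memory).
#' @param snapshot_every Record time/degradation/enzyme-z snapshots every
#'   this many steps (0 = off).
#' @return The updated `mc_state`.
#' @export
run_until <- function(state, target_pct = NULL, max_steps = NULL,
                      max_time = NULL, record_moves = FALSE,
                      snapshot_every = 0) {
  stopifnot(inherits(state, "mc_state"))
  if (is.null(target_pct) && is.null(max_steps) && is.null(max_time)) {
    stop("provide a stop condition: target_pct, max_steps or max_time",
         call. = FALSE)
  }
  if (!is.null(target_pct) && nrow(state$enzymes) == 0L) {
    stop("target degradation unreachable with zero enzymes", call. = FALSE)
  }
  target_removed <- if (is.null(target_pct)) -1L else {
    as.integer(ceiling(target_pct / 100 * state$lattice$initial_site_count))
  }
  ctrl <- list(
    max_steps = if (is.null(max_steps)) 1e15 else as.double(max_steps),
    target_removed = target_removed,
    max_time = if (is.null(max_time)) -1 else as.double(max_time),
    record_moves = isTRUE(record_moves),
    snapshot_every = as.double(snapshot_every),
    time0 = state$elapsed_time,
    step0 = as.double(state$step_count)
  )
  kin <- state$kinetics
  res <- cpp_mc_run(state$lattice, state$enzymes$site_id,
                    enzyme_kind_code(state), state$energy,
                    list(p_vertical = kin$p_vertical,
                         p_horizontal = kin$p_horizontal,
                         p_cleave_attempt = kin$p_cleave_attempt,
                         p_cleave_success = kin$p_cleave_success,
                         dt_attempt = kin$dt_attempt,
                         cleave_enabled = kin$cleave_enabled),
                    ctrl)
  lat <- state$lattice
  lat$removed <- res$removed
  lat$bond_up <- res$bond_up
  lat$gelatin <- res$gelatin
  lat$is_surface <- res$is_surface
  state$lattice <- lat
  state$enzymes$site_id <- res$enz_site
  state$step_count <- state$step_count + res$steps
  state$elapsed_time <- res$time
  state$occupancy <- state$occupancy + res$occupancy
  if (length(res$event_type)) {
    type_names <- c("move", "cleave", "removal", "relocation")
    ev <- data.frame(
      step = res$event_step, time_s = res$event_time,
      event_type = type_names[res$event_type],
      enzyme_id = ifelse(res$event_enzyme == 0L, NA_integer_,
                         res$event_enzyme),
      enzyme_kind = ifelse(res$event_enzyme == 0L, NA_character_,
                           state$enzymes$kind[pmax(res$event_enzyme, 1L)]),
      site_id = res$event_site,
      i = lat$site_i[res$event_site],
      chain_id = lat$site_chain[res$event_site],
      stringsAsFactors = FALSE
    )
    state$events <- rbind(state$events, ev)
  }
  if (length(res$snap_time)) {
    sn <- data.frame(time_s = res$snap_time, n_removed = res$snap_removed)
    zmat <- matrix(res$snap_z, ncol = nrow(state$enzymes), byrow = TRUE)
    state$snapshots <- rbind(state$snapshots, sn)
    state$snap_z <- rbind(state$snap_z, zmat)
  }
  state$last_counters <- res$counters
  state
}

#' @rdname run_until
#' @export
mc_step <- function(state) {
  run_until(state, max_steps = 1, record_moves = TRUE)
}

#' Propose a single displacement for an enzyme
#'
#' Mirrors the engine's proposal rules: a vertical trial picks +z or -z
#' with equal probability and lands on the nearest occupied position in
#' that direction (crossing gap regions onto the next molecule in the
#' column); a horizontal trial picks one of the six lateral faces uniformly
#' and lands at the same axial coordinate in that column. Proposals onto
#' removed, occupied, non-surface or (for collagenase) cleaved-flanked
#' sites are blocked without energy evaluation.
#'
#' @param state An `mc_state`.
#' @param enzyme_id Row of `state$enzymes`.
#' @param type `"vertical"` or `"horizontal"`; by default drawn according
#'   to the kinetics configuration.
#' @return A list with `type`, `direction`, `target` (site id or `NA`),
#'   `blocked`, and `reason` (`NA` when not blocked).
#' @export
propose_move <- function(state, enzyme_id, type = NULL) {
  lat <- state$lattice
  enz <- state$enzymes[state$enzymes$enzyme_id == enzyme_id, ]
  if (nrow(enz) != 1L) stop("unknown enzyme_id", call. = FALSE)
  kin <- state$kinetics
  if (is.null(type)) {
    pv <- kin$p_vertical / (kin$p_vertical + kin$p_horizontal)
    type <- if (runif(1) < pv) "vertical" else "horizontal"
  }
  s <- enz$site_id
  col <- lat$site_col[s]
  z <- lat$site_z[s]
  target <- NA_integer_
  direction <- NA
  if (type == "vertical") {
    direction <- if (runif(1) < 0.5) +1L else -1L
    for (k in seq_len(lat$geometry$gap_length + 1L)) {
      zz <- z + direction * k
      if (zz < 1L || zz > lat$n_z) break
      t <- lat$site_at[zz, col]
      if (t > 0L) { target <- t; break }
    }
  } else {
    direction <- sample.int(6L, 1L)
    c2 <- lat$dir_nbr[direction, col]
    if (c2 > 0L) {
      t <- lat$site_at[z, c2]
      if (t > 0L) target <- t
    }
  }
  reason <- NA_character_
  blocked <- FALSE
  if (is.na(target)) {
    blocked <- TRUE; reason <- "no site in that direction"
  } else if (lat$removed[target]) {
    blocked <- TRUE; reason <- "target removed"
  } else if (target %in% state$enzymes$site_id) {
    blocked <- TRUE; reason <- "target occupied"
  } else if (!lat$is_surface[target]) {
    blocked <- TRUE; reason <- "target not on surface"
  } else if (enz$kind == "collagenase" && site_flanked(lat, target)) {
    blocked <- TRUE; reason <- "collagenase cannot cross cleaved site"
  }
  list(type = type, direction = direction, target = target,
       blocked = blocked, reason = reason)
}

#' Attempt a cleavage event
#'
#' A collagenase is competent only at its characteristic cleave-site index
#' on a not-yet-cleaved molecule; a gelatinase only on a gelatin molecule
#' with an intact bond above the occupied site. A competent attempt
#' succeeds with the configured per-attempt probability, severs the bond,
#' marks the chain as gelatin, and triggers the removal cascade (displaced
#' enzymes are relocated to random empty surface sites).
#'
#' @param state An `mc_state`.
#' @param enzyme_id Enzyme id.
#' @return A list `(event, state)`; `event` is `NULL` for a failed or
#'   incompetent attempt, otherwise a list with the severed bond, the
#'   removed sites and relocations.
#' @export
attempt_cleave <- function(state, enzyme_id) {
  lat <- state$lattice
  en <- state$energy
  enz <- state$enzymes[state$enzymes$enzyme_id == enzyme_id, ]
  if (nrow(enz) != 1L) stop("unknown enzyme_id", call. = FALSE)
  s <- enz$site_id
  i <- lat$site_i[s]
  chain <- lat$site_chain[s]
  spc <- lat$geometry$sites_per_chain
  competent <- FALSE
  bond_site <- NA_integer_
  if (enz$kind == "collagenase") {
    if (!lat$gelatin[chain] && i == en$cleave_index) {
      if (en$cleave_mode == "well" && i > 1L && !lat$removed[s - 1L] &&
          !lat$bond_up[s - 1L]) {
        competent <- TRUE; bond_site <- s - 1L
      } else if (en$cleave_mode == "site_below" && i < spc &&
                 !lat$removed[s + 1L] && !lat$bond_up[s]) {
        competent <- TRUE; bond_site <- s
      }
    }
  } else {
    if (lat$gelatin[chain] && i < spc && !lat$bond_up[s] &&
        !lat$removed[s + 1L]) {
      competent <- TRUE; bond_site <- s
    }
  }
  if (!competent || runif(1) >= state$kinetics$p_cleave_success) {
    return(list(event = NULL, state = state))
  }
  lat$bond_up[bond_site] <- TRUE
  lat$gelatin[chain] <- TRUE
  res <- cpp_remove_disconnected(lat, as.integer(chain))
  lat$removed <- res$removed
  lat$is_surface <- res$is_surface
  state$lattice <- lat
  relocations <- integer(0)
  if (length(res$removed_now)) {
    displaced <- which(state$enzymes$site_id %in% res$removed_now)
    for (e in displaced) {
      pool <- surface_sites(lat, recompute = FALSE)
      pool <- setdiff(pool, state$enzymes$site_id)
      if (state$enzymes$kind[e] == "collagenase") {
        ok <- pool[!site_flanked(lat, pool)]
        if (length(ok)) pool <- ok
      }
      if (!length(pool)) stop("no surface sites left to relocate enzyme",
                              call. = FALSE)
      state$enzymes$site_id[e] <- pool[[sample.int(length(pool), 1L)]]
      relocations <- c(relocations, state$enzymes$enzyme_id[e])
    }
  }
  list(event = list(enzyme_id = enzyme_id, kind = enz$kind, site_id = s,
                    bond_site = bond_site,
                    removed_sites = as.integer(res$removed_now),
                    relocated_enzymes = relocations),
       state = state)
}

#' Remove disconnected fragments from a lattice
#'
#' Applies the detachment rules until a fixed point: a single site whose
#' flanking positions are both cleaved bonds or chain ends (a gelatinase
#' double-cut) is removed unconditionally; a larger bond-connected
#' fragment is removed only when it is vertically isolated by occupancy
#' (the column positions directly below and above it are vacant or
#' removed) and attached to fewer than two intact beads laterally. A
#' cleaved bond alone never detaches material: the unbonded neighbour
#' still holds the fragment in place, so removal is gelatinase-driven and
#' spreads from double-cut vacancies.
#'
#' @param lattice A `fibril_lattice`.
#' @return A list with the updated `lattice` and the integer vector
#'   `removed_sites`.
#' @export
remove_disconnected <- function(lattice) {
  res <- cpp_remove_disconnected(lattice, integer(0))
  lattice$removed <- res$removed
  lattice$is_surface <- res$is_surface
  list(lattice = lattice, removed_sites = as.integer(res$removed_now))
}

#' Simulate competent-state cleavage waiting times
#'
#' Holds an enzyme in its cleavage-competent position and simulates the
#' per-step attempt/success draws of the engine, returning the waiting time
#' (seconds) before each cleavage event. Useful to verify that the realised
#' rate equals the configured `cleave_rate`.
#'
#' @param n_events Number of waiting times to simulate.
#' @param kinetics A [kinetics_config()].
#' @return Numeric vector of waiting times (s).
#' @export
cleave_waiting_times <- function(n_events, kinetics = kinetics_config()) {
  stopifnot(n_events >= 1)
  cpp_waiting_times(as.integer(n_events), kinetics$p_cleave_attempt,
                    kinetics$p_cleave_success, kinetics$dt_attempt)
}

#' Replay an event log onto a pristine lattice
#'
#' Re-applies the logged cleave and removal events to a fresh copy of the
#' lattice and returns it; the result must equal the live lattice state
#' (replay identity).
#'
#' @param state An `mc_state` whose events should be replayed.
#' @return A `fibril_lattice`.
#' @export
replay_events <- function(state) {
  lat <- build_like(state$lattice)
  ev <- state$events
  en <- state$energy
  for (r in seq_len(nrow(ev))) {
    if (ev$event_type[r] == "cleave") {
      s <- ev$site_id[r]
      bond_site <- if (ev$enzyme_kind[r] == "collagenase" &&
                       en$cleave_mode == "well") s - 1L else s
      lat$bond_up[bond_site] <- TRUE
      lat$gelatin[lat$site_chain[s]] <- TRUE
    } else if (ev$event_type[r] == "removal") {
      lat$removed[ev$site_id[r]] <- TRUE
    }
  }
  lat$is_surface <- cpp_recompute_surface(lat)
  lat
}
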