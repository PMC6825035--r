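# Degradation-pattern statistics: time courses, cross-sectional density
# maps, pause fractions, axial trajectories.  All statistics are pure
# functions of the recorded state/event log.

#' Degradation time course
#'
#' Cumulative removed sites, cleaved bonds and percent degradation sampled
#' at every removal event (plus the initial point and every cleave).
#'
#' @param state An `mc_state` with a populated event log.
#' @return A data frame with columns `time_s`, `percent_degraded`,
#'   `n_cleaved_bonds`, `n_removed_sites`.
#' @export
time_course <- function(state) {
  ev <- state$events
  keep <- ev$event_type %in% c("cleave", "removal")
  ev <- ev[keep, , drop = FALSE]
  init <- state$lattice$initial_site_count
  n_rem <- cumsum(ev$event_type == "removal")
  n_cl <- cumsum(ev$event_type == "cleave")
  out <- data.frame(
    time_s = c(0, ev$time_s),
    percent_degraded = c(0, 100 * n_rem / init),
    n_cleaved_bonds = c(0, n_cl),
    n_removed_sites = c(0, n_rem)
  )
  out
}

#' Cross-sectional density map of cleaved or removed sites
#'
#' Projects the logged events of the requested kind along the fibril axis
#' onto the cross-section. The default resolution uses one cell per
#' microfibril; a numeric resolution bins on a square grid of that cell
#' size (nm). All cells covering the cross-section are returned, including
#' empty ones, so localisation statistics over the cells are well defined.
#'
#' @param state An `mc_state`.
#' @param kind `"cleaved"` or `"removed"`.
#' @param resolution `"microfibril"` or a numeric cell size in nm.
#' @return An object of class `density_map`: list with `cells` (data frame
#'   `x`, `y`, `count`), `kind`, `total`.
#' @export
density_map <- function(state, kind = c("cleaved", "removed"),
                        resolution = "microfibril") {
  kind <- match.arg(kind)
  lat <- state$lattice
  ev <- state$events
  type <- if (kind == "cleaved") "cleave" else "removal"
  sites <- ev$site_id[ev$event_type == type]
  cols <- lat$site_col[sites]
  if (identical(resolution, "microfibril")) {
    mf <- lat$col_mf[cols]
    all_mf <- sort(unique(lat$col_mf))
    cnt <- tabulate(match(mf, all_mf), nbins = length(all_mf))
    cx <- tapply(lat$col_x, lat$col_mf, mean)[as.character(all_mf)]
    cy <- tapply(lat$col_y, lat$col_mf, mean)[as.character(all_mf)]
    cells <- data.frame(x = as.numeric(cx), y = as.numeric(cy), count = cnt)
  } else {
    gs <- as.numeric(resolution)
    stopifnot(is.finite(gs), gs > 0)
    ix_all <- floor(lat$col_x / gs)
    iy_all <- floor(lat$col_y / gs)
    grid <- unique(data.frame(ix = ix_all, iy = iy_all))
    key <- paste(grid$ix, grid$iy)
    hits <- paste(ix_all[cols], iy_all[cols])
    cnt <- tabulate(match(hits, key), nbins = nrow(grid))
    cells <- data.frame(x = (grid$ix + 0.5) * gs, y = (grid$iy + 0.5) * gs,
                        count = cnt)
  }
  structure(list(cells = cells, kind = kind, resolution = resolution,
                 total = length(sites)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %s events: %d over %d cells (Gini %.3f)\n",
              x$kind, x$total, nrow(x$cells),
              gini_coefficient(x$cells$count)))
  invisible(x)
}

#' Gini coefficient
#'
#' Localisation statistic over density-map cell counts: 0 for a perfectly
#' even distribution, approaching 1 when all events concentrate in one
#' cell.
#'
#' @param x Non-negative numeric vector (cell counts).
#' @return The Gini coefficient; `NA` if `sum(x) == 0`.
#' @export
gini_coefficient <- function(x) {
  stopifnot(all(x >= 0))
  n <- length(x)
  if (n == 0L || sum(x) == 0) return(NA_real_)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n * sum(xs))
}

#' Fraction of steps an enzyme spends at an axial index
#'
#' Uses the engine's exact per-step occupancy tally (every step counts each
#' enzyme's current position).
#'
#' @param state An `mc_state` that has been stepped.
#' @param enzyme_id Enzyme id.
#' @param i_index Axial index (1..sites_per_chain) or a vector of indices.
#' @return Fraction of steps in `[0, 1]`.
#' @export
pause_fraction <- function(state, enzyme_id, i_index) {
  if (!enzyme_id %in% state$enzymes$enzyme_id) {
    stop("unknown enzyme_id", call. = FALSE)
  }
  col <- which(state$enzymes$enzyme_id == enzyme_id)
  tot <- sum(state$occupancy[, col])
  if (tot == 0) return(NA_real_)
  sum(state$occupancy[i_index, col]) / tot
}

#' Axial trajectories of enzymes
#'
#' Axial position (nm, `z = 0` at the fibril's C-terminal end) as a
#' function of time for each enzyme, built from the logged accepted moves
#' and relocations (requires a run with `record_moves = TRUE`), or from
#' periodic snapshots when available.
#'
#' @param state An `mc_state`.
#' @param use `"events"` (default when moves were recorded) or
#'   `"snapshots"`.
#' @return A data frame with columns `enzyme_id`, `kind`, `time_s`, `z_nm`.
#' @export
axial_trajectories <- function(state, use = NULL) {
  lat <- state$lattice
  a <- lat$geometry$site_length
  has_moves <- any(state$events$event_type == "move")
  if (is.null(use)) use <- if (has_moves) "events" else "snapshots"
  if (use == "events") {
    ev <- state$events
    ev <- ev[ev$event_type %in% c("move", "relocation"), , drop = FALSE]
    out <- lapply(seq_len(nrow(state$enzymes)), function(e) {
      id <- state$enzymes$enzyme_id[e]
      evi <- ev[!is.na(ev$enzyme_id) & ev$enzyme_id == id, , drop = FALSE]
      z0 <- lat$site_z[state$enzymes0$site_id[e]]
      data.frame(enzyme_id = id, kind = state$enzymes$kind[e],
                 time_s = c(0, evi$time_s),
                 z_nm = (c(z0, lat$site_z[evi$site_id]) - 0.5) * a)
    })
    do.call(rbind, out)
  } else {
    if (is.null(state$snapshots)) {
      stop("no snapshots recorded; rerun with snapshot_every > 0",
           call. = FALSE)
    }
    n_enz <- nrow(state$enzymes)
    out <- lapply(seq_len(n_enz), function(e) {
      data.frame(enzyme_id = state$enzymes$enzyme_id[e],
                 kind = state$enzymes$kind[e],
                 time_s = state$snapshots$time_s,
                 z_nm = (state$snap_z[, e] - 0.5) * a)
    })
    do.call(rbind, out)
  }
}
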