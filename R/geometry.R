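# Fibril lattice construction and queries.
#
# The cross-section is a triangular close packing of tropocollagen columns,
# tiled by 5-column microfibrils (a centre column plus its neighbours at
# +/-a1 and +/-a2; the microfibril centres form the index-5 sublattice of the
# triangular lattice, so the tiling is gapless and every interior column has
# coordination 6).  Each column carries `chains_per_column` molecules of
# `sites_per_chain` sites stacked with `gap_length` vacant positions between
# consecutive molecules; lateral neighbours are staggered by whole D-periods
# (`stagger_offset` sites), which produces the canonical gap/overlap banding.

#' Fibril geometry description
#'
#' Bundles the structural parameters of the coarse-grained fibril lattice.
#' Defaults reproduce the reference structure used throughout: `m = 4`
#' (37 microfibrils, 185 columns) with 5 molecules per column, i.e. 925
#' tropocollagen chains and 20,350 lattice sites.
#'
#' @param m Microfibrils per fibril edge (centred-hexagonal packing with
#'   `3*m*(m-1)+1` microfibrils in the cross-section).
#' @param chains_per_column Tropocollagen molecules stacked end-to-end in
#'   each column.
#' @param sites_per_chain Axial lattice sites per molecule. The axial index
#'   `i` runs 1..`sites_per_chain` from the C terminus.
#' @param site_length Physical length of one site in nm. The default 13.4 nm
#'   makes one D-period equal to `stagger_offset = 5` sites (67 nm) and one
#'   molecule 22 sites (295 nm).
#' @param stagger_offset D-period stagger between adjacent stagger classes,
#'   in sites.
#' @param gap_length Vacant sites between consecutive molecules in a column.
#' @param microfibril_diameter Microfibril diameter in nm; sets the lateral
#'   column spacing (`0.375 * microfibril_diameter`).
#' @param single_column If `TRUE`, build a degenerate one-column lattice
#'   (useful as a minimal fixture); `m` is ignored.
#' @return An object of class `fibril_geometry`.
#' @export
fibril_geometry <- function(m = 4L,
                            chains_per_column = 5L,
                            sites_per_chain = 22L,
                            site_length = 13.4,
                            stagger_offset = 5L,
                            gap_length = 3L,
                            microfibril_diameter = 4.0,
                            single_column = FALSE) {
  g <- list(
    m = as.integer(m),
    chains_per_column = as.integer(chains_per_column),
    sites_per_chain = as.integer(sites_per_chain),
    site_length = as.numeric(site_length),
    stagger_offset = as.integer(stagger_offset),
    gap_length = as.integer(gap_length),
    microfibril_diameter = as.numeric(microfibril_diameter),
    single_column = isTRUE(single_column)
  )
  class(g) <- "fibril_geometry"
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  chk <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid geometry: field `%s` %s", field, why),
                  call. = FALSE)
  }
  chk(length(g$m) == 1 && !is.na(g$m) && g$m >= 1L, "m",
      "must be an integer >= 1")
  chk(g$chains_per_column >= 1L, "chains_per_column", "must be >= 1")
  chk(g$sites_per_chain >= 2L, "sites_per_chain", "must be >= 2")
  chk(is.finite(g$site_length) && g$site_length > 0, "site_length",
      "must be positive")
  chk(g$stagger_offset >= 0L, "stagger_offset", "must be >= 0")
  chk(g$gap_length >= 0L, "gap_length", "must be >= 0")
  chk(g$stagger_offset < g$sites_per_chain + g$gap_length, "stagger_offset",
      "must be smaller than sites_per_chain + gap_length")
  chk(is.finite(g$microfibril_diameter) && g$microfibril_diameter > 0,
      "microfibril_diameter", "must be positive")
  invisible(g)
}

# Axial (hex) lattice directions used for column adjacency, in a1/a2 integer
# coordinates. Order is fixed; the MC engine proposes one of the six faces
# uniformly for horizontal moves.
hex_directions <- function() {
  matrix(c(1L, 0L,
           0L, 1L,
           -1L, 1L,
           -1L, 0L,
           0L, -1L,
           1L, -1L), ncol = 2L, byrow = TRUE)
}

# Microfibril centres: centred-hexagonal set of radius m-1 in the index-5
# sublattice basis b1 = 2*a1 + a2, b2 = -a1 + 2*a2.
microfibril_centers <- function(m) {
  r <- m - 1L
  s <- rep(seq(-r, r), each = 2L * r + 1L)
  t <- rep(seq(-r, r), times = 2L * r + 1L)
  keep <- (abs(s) + abs(t) + abs(s + t)) / 2L <= r
  s <- s[keep]; t <- t[keep]
  u <- 2L * s - t
  v <- s + 2L * t
  # order by ring then angle for a deterministic layout
  ring <- (abs(s) + abs(t) + abs(s + t)) / 2L
  x <- u + v / 2
  y <- v * sqrt(3) / 2
  ang <- atan2(y, x)
  o <- order(ring, ang, s, t)
  cbind(u = u[o], v = v[o])
}

#' Build a fibril lattice
#'
#' Constructs the hierarchical lattice: microfibrils packed
#' centred-hexagonally in the cross-section, five D-staggered columns per
#' microfibril, and D-period gap/overlap banding along the axis. Site states
#' (intact/removed), bond states and the evolving surface flags are carried
#' on the returned object.
#'
#' @param geometry A [fibril_geometry()].
#' @return An object of class `fibril_lattice`.
#' @examples
#' lat <- build_fibril(fibril_geometry(m = 1, chains_per_column = 2))
#' lat$n_chains
#' @export
build_fibril <- function(geometry = fibril_geometry()) {
  validate_geometry(geometry)
  g <- geometry
  spc <- g$sites_per_chain
  cpc <- g$chains_per_column

  if (g$single_column) {
    cols <- cbind(u = 0L, v = 0L)
    col_mf <- 1L
  } else {
    ctr <- microfibril_centers(g$m)
    off <- rbind(c(0L, 0L), hex_directions()[c(1L, 2L, 4L, 5L), ])
    u <- as.vector(outer(off[, 1L], ctr[, "u"], `+`))
    v <- as.vector(outer(off[, 2L], ctr[, "v"], `+`))
    cols <- cbind(u = u, v = v)
    col_mf <- rep(seq_len(nrow(ctr)), each = nrow(off))
  }
  n_col <- nrow(cols)
  d_col <- 0.375 * g$microfibril_diameter
  col_x <- d_col * (cols[, "u"] + cols[, "v"] / 2)
  col_y <- d_col * cols[, "v"] * sqrt(3) / 2
  col_x <- col_x - mean(col_x)
  col_y <- col_y - mean(col_y)
  col_phase <- ((2L * cols[, "u"] + cols[, "v"]) %% 5L)

  keys <- paste(cols[, "u"], cols[, "v"])
  dirs <- hex_directions()
  dir_nbr <- matrix(0L, nrow = 6L, ncol = n_col)
  for (k in seq_len(6L)) {
    hit <- match(paste(cols[, "u"] + dirs[k, 1L], cols[, "v"] + dirs[k, 2L]),
                 keys)
    dir_nbr[k, ] <- ifelse(is.na(hit), 0L, hit)
  }

  period <- spc + g$gap_length
  z0_col <- col_phase * g$stagger_offset          # axial offset per column
  n_z <- max(z0_col) + (cpc - 1L) * period + spc

  n_chains <- n_col * cpc
  chain_col <- rep(seq_len(n_col), each = cpc)
  chain_stack <- rep(seq_len(cpc) - 1L, times = n_col)
  chain_z0 <- z0_col[chain_col] + chain_stack * period  # z of i=1 minus 1

  n_sites <- n_chains * spc
  site_chain <- rep(seq_len(n_chains), each = spc)
  site_i <- rep(seq_len(spc), times = n_chains)
  site_col <- chain_col[site_chain]
  site_z <- chain_z0[site_chain] + site_i

  site_at <- matrix(0L, nrow = n_z, ncol = n_col)
  site_at[cbind(site_z, site_col)] <- seq_len(n_sites)

  lat <- list(
    geometry = g,
    n_columns = n_col, n_z = n_z, n_sites = n_sites, n_chains = n_chains,
    col_u = as.integer(cols[, "u"]), col_v = as.integer(cols[, "v"]),
    col_x = col_x, col_y = col_y,
    col_phase = as.integer(col_phase), col_mf = as.integer(col_mf),
    dir_nbr = dir_nbr,
    site_col = as.integer(site_col), site_z = as.integer(site_z),
    site_i = as.integer(site_i), site_chain = as.integer(site_chain),
    chain_col = as.integer(chain_col), chain_z0 = as.integer(chain_z0),
    removed = rep(FALSE, n_sites),
    bond_up = rep(FALSE, n_sites),     # TRUE = bond to the site above cleaved
    gelatin = rep(FALSE, n_chains),
    site_at = site_at,
    initial_site_count = n_sites
  )
  class(lat) <- "fibril_lattice"
  lat$is_surface <- cpp_recompute_surface(lat)
  lat
}

#' @export
print.fibril_lattice <- function(x, ...) {
  g <- x$geometry
  cat("<fibril_lattice>\n")
  cat(sprintf("  m = %d, %d microfibrils, %d columns, %d chains, %d sites\n",
              g$m, length(unique(x$col_mf)), x$n_columns, x$n_chains,
              x$n_sites))
  cat(sprintf("  removed: %d (%.3f%%), cleaved bonds: %d, gelatin chains: %d\n",
              sum(x$removed), percent_degradation(x), sum(x$bond_up),
              sum(x$gelatin)))
  invisible(x)
}

check_site <- function(lattice, site_id) {
  if (length(site_id) != 1L || is.na(site_id) || site_id < 1L ||
      site_id > lattice$n_sites) {
    stop(sprintf("unknown site_id: %s", paste(site_id, collapse = ",")),
         call. = FALSE)
  }
  as.integer(site_id)
}

#' Surface sites of a lattice
#'
#' A site is on the surface when at least one of its six lateral faces has
#' no intact occupant. A face toward an adjacent column is blocked when that
#' column holds an intact site at the same axial position, or when the
#' position falls inside a gap whose two flanking sites are intact (gaps are
#' grooves, not channels). Missing or removed material leaves the face
#' exposed. Enzymes are confined to this evolving set.
#'
#' @param lattice A `fibril_lattice`.
#' @param recompute If `TRUE` (default), re-scan the lattice; otherwise use
#'   the cached flags.
#' @return Integer vector of site ids.
#' @export
surface_sites <- function(lattice, recompute = TRUE) {
  flags <- if (recompute) cpp_recompute_surface(lattice) else
    lattice$is_surface
  which(flags)
}

#' Axial neighbours of a site
#'
#' Returns the immediately abutting intact sites above and below (axial
#' `z +/- 1` in the same column). Gap positions, fibril ends and removed
#' sites yield `NA`.
#'
#' @param lattice A `fibril_lattice`.
#' @param site_id Site id.
#' @return Named integer vector `c(above = , below = )`, `NA` where absent.
#' @export
vertical_neighbors <- function(lattice, site_id) {
  s <- check_site(lattice, site_id)
  col <- lattice$site_col[s]
  z <- lattice$site_z[s]
  pick <- function(zz) {
    if (zz < 1L || zz > lattice$n_z) return(NA_integer_)
    t <- lattice$site_at[zz, col]
    if (t == 0L || lattice$removed[t]) NA_integer_ else t
  }
  c(above = pick(z + 1L), below = pick(z - 1L))
}

#' Lateral neighbours of a site
#'
#' Intact sites at the same axial coordinate in the (up to six) adjacent
#' columns, within and across microfibrils.
#'
#' @inheritParams vertical_neighbors
#' @return Integer vector of site ids (possibly empty).
#' @export
lateral_neighbors <- function(lattice, site_id) {
  s <- check_site(lattice, site_id)
  col <- lattice$site_col[s]
  z <- lattice$site_z[s]
  nbr_cols <- lattice$dir_nbr[, col]
  nbr_cols <- nbr_cols[nbr_cols > 0L]
  if (length(nbr_cols) == 0L) return(integer(0))
  t <- lattice$site_at[z, nbr_cols]
  t <- t[t > 0L]
  t[!lattice$removed[t]]
}

#' Percent degradation of a lattice
#'
#' Removed sites divided by the initial site count, times 100.
#'
#' @param lattice A `fibril_lattice`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_degradation <- function(lattice) {
  stopifnot(lattice$initial_site_count > 0L)
  100 * sum(lattice$removed) / lattice$initial_site_count
}

#' Serialize a lattice to JSON
#'
#' Writes geometry plus per-site and per-chain state; [read_lattice_json()]
#' rebuilds the full lattice (derived structure is reconstructed from the
#' geometry, then the recorded states are applied).
#'
#' @param lattice A `fibril_lattice`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lattice_json <- function(lattice, path) {
  payload <- list(
    format = "fibrildeg-lattice",
    version = 1L,
    geometry = unclass(lattice$geometry),
    removed = which(lattice$removed),
    cleaved_bond_sites = which(lattice$bond_up),
    gelatin_chains = which(lattice$gelatin)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lattice_json
#' @param path Path to a JSON file written by [write_lattice_json()].
#' @export
read_lattice_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "fibrildeg-lattice")) {
    stop("not a fibrildeg lattice file: ", path, call. = FALSE)
  }
  geo <- payload$geometry
  g <- fibril_geometry(m = geo$m, chains_per_column = geo$chains_per_column,
                       sites_per_chain = geo$sites_per_chain,
                       site_length = geo$site_length,
                       stagger_offset = geo$stagger_offset,
                       gap_length = geo$gap_length,
                       microfibril_diameter = geo$microfibril_diameter,
                       single_column = isTRUE(geo$single_column))
  lat <- build_fibril(g)
  lat$removed[as.integer(payload$removed)] <- TRUE
  lat$bond_up[as.integer(payload$cleaved_bond_sites)] <- TRUE
  lat$gelatin[as.integer(payload$gelatin_chains)] <- TRUE
  lat$is_surface <- cpp_recompute_surface(lat)
  lat
}
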