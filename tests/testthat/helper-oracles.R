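# Independent brute-force oracles used across the suite.  These re-derive
# the stated rules directly from the lattice arrays and deliberately share
# no code with the engine.

# full re-scan surface oracle: a site is surface iff < 6 of its lateral
# faces are blocked; a face is blocked by an intact site at the same z in
# the adjacent column, or by a gap interior whose two flanking sites are
# intact
oracle_surface <- function(lat) {
  gap <- lat$geometry$gap_length
  sapply(seq_len(lat$n_sites), function(s) {
    if (lat$removed[s]) return(FALSE)
    col <- lat$site_col[s]; z <- lat$site_z[s]
    blocked <- 0L
    for (d in 1:6) {
      c2 <- lat$dir_nbr[d, col]
      if (c2 == 0L) next
      t <- lat$site_at[z, c2]
      if (t > 0L) {
        if (!lat$removed[t]) blocked <- blocked + 1L
        next
      }
      below <- 0L; above <- 0L
      for (k in seq_len(gap)) {
        zz <- z - k
        if (below == 0L && zz >= 1L) below <- lat$site_at[zz, c2]
        zz <- z + k
        if (above == 0L && zz <= lat$n_z) above <- lat$site_at[zz, c2]
      }
      if (below > 0L && above > 0L && !lat$removed[below] &&
          !lat$removed[above]) {
        blocked <- blocked + 1L
      }
    }
    blocked < 6L
  })
}

# brute-force removal fixed point implementing the two detachment rules
oracle_remove <- function(lat) {
  spc <- lat$geometry$sites_per_chain
  removed <- lat$removed
  repeat {
    changed <- FALSE
    for (c in seq_len(lat$n_chains)) {
      first <- (c - 1L) * spc + 1L
      i <- 1L
      while (i <= spc) {
        s <- first + i - 1L
        if (removed[s]) { i <- i + 1L; next }
        j <- i
        while (j < spc && !lat$bond_up[first + j - 1L] &&
               !removed[first + j]) {
          j <- j + 1L
        }
        s_i <- first + i - 1L; s_j <- first + j - 1L
        below_free <- (i == 1L) || lat$bond_up[s_i - 1L]
        above_free <- (j == spc) || lat$bond_up[s_j]
        rm <- FALSE
        if (i == j && below_free && above_free) {
          rm <- TRUE
        } else {
          col <- lat$site_col[s_i]
          zb <- lat$site_z[s_i] - 1L; zt <- lat$site_z[s_j] + 1L
          tb <- if (zb >= 1L) lat$site_at[zb, col] else 0L
          tt <- if (zt <= lat$n_z) lat$site_at[zt, col] else 0L
          iso_b <- tb == 0L || removed[tb]
          iso_t <- tt == 0L || removed[tt]
          if (iso_b && iso_t) {
            attach <- 0L
            for (k in i:j) {
              sk <- first + k - 1L
              z <- lat$site_z[sk]
              for (d in 1:6) {
                c2 <- lat$dir_nbr[d, col]
                if (c2 == 0L) next
                t <- lat$site_at[z, c2]
                if (t > 0L && !removed[t]) attach <- attach + 1L
              }
            }
            rm <- attach < 2L
          }
        }
        if (rm) {
          removed[s_i:s_j] <- TRUE
          changed <- TRUE
        }
        i <- j + 1L
      }
    }
    if (!changed) break
  }
  removed
}

tiny_lattice <- function(cpc = 2L) {
  build_fibril(fibril_geometry(m = 1L, chains_per_column = cpc))
}

single_chain_lattice <- function() {
  build_fibril(fibril_geometry(m = 1L, chains_per_column = 1L,
                               single_column = TRUE))
}

# kinetics that never moves the enzyme (cleave attempts only)
pinned_kinetics <- function(cleave_enabled = TRUE) {
  kinetics_config(p_vertical = 0, p_horizontal = 0, p_cleave_attempt = 1,
                  dt_attempt = 1e-4, cleave_enabled = cleave_enabled)
}
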