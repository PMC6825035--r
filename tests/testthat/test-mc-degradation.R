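# Enzyme energetics, Metropolis moves, cleavage and fragment removal.

test_that("interaction energies reproduce the three-regime model", {
  lat <- tiny_lattice()
  well <- which(lat$site_i == 5L & lat$site_chain == 1L)
  off <- which(lat$site_i == 3L & lat$site_chain == 1L)
  expect_identical(interaction_energy("collagenase", well, lat), -2)
  expect_identical(interaction_energy("collagenase", off, lat), 0)
  expect_identical(interaction_energy("gelatinase", off, lat), 0)
  # gelatin chain: collagenase repelled, gelatinase attracted, any i
  lat$gelatin[1L] <- TRUE
  i17 <- which(lat$site_i == 17L & lat$site_chain == 1L)
  expect_identical(interaction_energy("collagenase", i17, lat), 0.5)
  expect_identical(interaction_energy("gelatinase", i17, lat), -0.5)
  expect_identical(interaction_energy("collagenase", well, lat), 0.5)
  # cleaved-flank is forbidden for collagenase only
  lat$bond_up[off] <- TRUE  # bond(3->4) of chain 1
  expect_identical(interaction_energy("collagenase", off, lat), Inf)
  expect_identical(interaction_energy("collagenase", off + 1L, lat), Inf)
  expect_identical(interaction_energy("gelatinase", off, lat), -0.5)
  # removed site is an error for any enzyme
  lat$removed[off] <- TRUE
  expect_error(interaction_energy("gelatinase", off, lat), "removed")
})

test_that("metropolis_accept follows the Boltzmann factor", {
  expect_true(all(metropolis_accept(rep(0, 100))))
  expect_true(all(metropolis_accept(rep(-2, 100))))
  set.seed(1)
  f <- mean(metropolis_accept(rep(0.5, 2e5)))
  expect_equal(f, exp(-0.5), tolerance = 0.01)
  expect_error(metropolis_accept(Inf), "finite")
})

test_that("place_enzymes respects presets, exclusion and determinism", {
  lat <- build_fibril(fibril_geometry(m = 2L, chains_per_column = 2L))
  p <- system_preset(3)
  st <- place_enzymes(lat, p$n_collagenase, p$n_gelatinase, seed = 11)
  expect_identical(sum(st$enzymes$kind == "collagenase"), 6L)
  expect_identical(sum(st$enzymes$kind == "gelatinase"), 2L)
  expect_false(any(duplicated(st$enzymes$site_id)))
  expect_true(all(lat$is_surface[st$enzymes$site_id]))
  st2 <- place_enzymes(lat, 6, 2, seed = 11)
  expect_identical(st$enzymes, st2$enzymes)
  tiny <- single_chain_lattice()
  expect_error(place_enzymes(tiny, 30, 0), "too many enzymes")
  one <- place_enzymes(tiny, 1, 0, seed = 1)
  expect_identical(nrow(one$enzymes), 1L)
})

test_that("propose_move blocks boundaries, occupancy and cleaved flanks", {
  lat <- single_chain_lattice()
  st <- place_enzymes(lat, 1, 0, seed = 2)
  st$enzymes$site_id <- 22L  # topmost site
  set.seed(1)
  res <- replicate(40, {
    pr <- propose_move(st, 1L, type = "vertical")
    c(pr$direction, pr$blocked)
  })
  up <- res[, res[1, ] == 1, drop = FALSE]
  expect_true(all(up[2, ] == 1))  # +z from the top is always blocked
  # horizontal from a single column is always blocked
  pr <- propose_move(st, 1L, type = "horizontal")
  expect_true(pr$blocked)
  # occupied target is blocked
  lat2 <- tiny_lattice()
  st2 <- place_enzymes(lat2, 2, 0, seed = 3)
  st2$enzymes$site_id <- c(5L, 6L)
  set.seed(4)
  blocked_occ <- FALSE
  for (k in 1:50) {
    pr <- propose_move(st2, 1L, type = "vertical")
    if (!is.na(pr$target) && pr$target == 6L) {
      expect_true(pr$blocked)
      expect_match(pr$reason, "occupied")
      blocked_occ <- TRUE
    }
  }
  expect_true(blocked_occ)
  # collagenase may not step onto a cleaved-flanked site
  lat3 <- tiny_lattice()
  lat3$bond_up[4L] <- TRUE
  lat3$gelatin[1L] <- TRUE
  st3 <- place_enzymes(lat3, 1, 0, seed = 5)
  st3$lattice <- lat3
  st3$enzymes$site_id <- 3L
  set.seed(6)
  saw <- FALSE
  for (k in 1:60) {
    pr <- propose_move(st3, 1L, type = "vertical")
    if (!is.na(pr$target) && pr$target == 4L) {
      expect_true(pr$blocked)
      expect_match(pr$reason, "collagenase")
      saw <- TRUE
    }
  }
  expect_true(saw)
})

test_that("attempt_cleave enforces competence and severs bond(4->5)", {
  lat <- tiny_lattice()
  en <- energy_model()  # well mode: competent at i = 5
  kin <- pinned_kinetics()
  kin$p_cleave_success <- 1  # force success for the contract checks
  st <- place_enzymes(lat, 1, 1, energy = en, kinetics = kin, seed = 8)
  # collagenase at the well of chain 1
  st$enzymes$site_id <- c(5L, 40L)
  out <- attempt_cleave(st, 1L)
  expect_false(is.null(out$event))
  expect_identical(out$event$bond_site, 4L)  # bond between i=4 and i=5
  expect_true(out$state$lattice$bond_up[4L])
  expect_true(out$state$lattice$gelatin[1L])
  # no sites are removed by a lone collagenase cut
  expect_length(out$event$removed_sites, 0L)
  # collagenase away from the competent index: no event
  st$enzymes$site_id <- c(9L, 40L)
  expect_null(attempt_cleave(st, 1L)$event)
  # gelatinase on a never-cleaved chain: no event
  expect_null(attempt_cleave(st, 2L)$event)
  # gelatinase on a gelatin chain severs the bond above its site
  st2 <- out$state
  g_site <- which(st2$lattice$site_chain == 1L & st2$lattice$site_i == 12L)
  st2$enzymes$site_id <- c(9L, g_site)
  out2 <- attempt_cleave(st2, 2L)
  expect_identical(out2$event$bond_site, g_site)
  expect_true(out2$state$lattice$bond_up[g_site])
})

test_that("site_below cleave mode implements the literal reading", {
  lat <- tiny_lattice()
  en <- energy_model(cleave_mode = "site_below")
  expect_identical(en$cleave_index, 4L)
  kin <- pinned_kinetics()
  kin$p_cleave_success <- 1
  st <- place_enzymes(lat, 1, 0, energy = en, kinetics = kin, seed = 9)
  st$enzymes$site_id <- 4L
  out <- attempt_cleave(st, 1L)
  expect_identical(out$event$bond_site, 4L)  # same bond(4->5)
  expect_true(out$state$lattice$bond_up[4L])
})

test_that("remove_disconnected applies the double-cut and isolation rules", {
  # fully intact m=1 lattice: nothing to remove
  lat <- tiny_lattice()
  expect_length(remove_disconnected(lat)$removed_sites, 0L)
  # single site with both flanking bonds cleaved is removed immediately
  lat$bond_up[c(7L, 8L)] <- TRUE  # bonds (7->8) and (8->9): site 8 cut out
  lat$gelatin[1L] <- TRUE
  res <- remove_disconnected(lat)
  expect_identical(res$removed_sites, 8L)
  # a bond-bounded multi-site fragment held by intact vertical neighbours
  # and lateral contacts is retained
  lat2 <- tiny_lattice()
  lat2$bond_up[c(10L, 13L)] <- TRUE  # run 11..13 bounded by cleaved bonds
  lat2$gelatin[1L] <- TRUE
  expect_length(remove_disconnected(lat2)$removed_sites, 0L)
})

test_that("remove_disconnected matches the brute-force oracle on random lattices", {
  set.seed(77)
  for (rep in 1:100) {
    lat <- tiny_lattice(cpc = 2L)
    n_cut <- sample(3:25, 1)
    cut <- sample(which(lat$site_i < lat$geometry$sites_per_chain), n_cut)
    lat$bond_up[cut] <- TRUE
    lat$gelatin[unique(lat$site_chain[cut])] <- TRUE
    if (runif(1) < 0.5) {
      lat$removed[sample.int(lat$n_sites, sample(1:8, 1))] <- TRUE
    }
    got <- remove_disconnected(lat)$lattice$removed
    expect_identical(unname(got), unname(oracle_remove(lat)))
  }
})

test_that("run_until obeys stop conditions and stays deterministic", {
  lat <- tiny_lattice(cpc = 2L)
  st <- place_enzymes(lat, 1, 1, seed = 21)
  expect_error(run_until(st), "stop condition")
  # target 0 returns immediately
  st0 <- run_until(st, target_pct = 0)
  expect_identical(st0$step_count, 0)
  # deterministic under the same seed
  r1 <- run_until(place_enzymes(lat, 2, 2, seed = 5), max_steps = 2e4)
  r2 <- run_until(place_enzymes(lat, 2, 2, seed = 5), max_steps = 2e4)
  expect_identical(r1$enzymes, r2$enzymes)
  expect_identical(r1$lattice$removed, r2$lattice$removed)
  expect_identical(r1$events, r2$events)
  # no enzymes: unreachable target errors
  st_none <- st; st_none$enzymes <- st$enzymes[0, ]
  expect_error(run_until(st_none, target_pct = 1), "zero enzymes")
})

test_that("with cleavage disabled only move events are ever logged", {
  lat <- tiny_lattice()
  kin <- kinetics_config(site_length = lat$geometry$site_length,
                         cleave_enabled = FALSE)
  st <- place_enzymes(lat, 1, 0, kinetics = kin, seed = 31)
  st <- run_until(st, max_steps = 2e4, record_moves = TRUE)
  expect_true(all(st$events$event_type == "move"))
})

test_that("event log replays to the final lattice state exactly", {
  lat <- build_fibril(fibril_geometry(m = 2L, chains_per_column = 2L))
  st <- place_enzymes(lat, 4, 4, seed = 13)
  st <- run_until(st, target_pct = 0.6, max_steps = 5e8)
  expect_gt(nrow(st$events), 0L)
  replayed <- replay_events(st)
  expect_identical(replayed$removed, st$lattice$removed)
  expect_identical(replayed$bond_up, st$lattice$bond_up)
  expect_identical(replayed$gelatin, st$lattice$gelatin)
})

test_that("engine invariants: exclusion, flank avoidance, monotone removal", {
  lat <- build_fibril(fibril_geometry(m = 2L, chains_per_column = 2L))
  st <- place_enzymes(lat, 4, 4, seed = 17)
  st <- run_until(st, target_pct = 0.5, max_steps = 5e8,
                  snapshot_every = 5e4)
  # no two enzymes share a site at the end
  expect_false(any(duplicated(st$enzymes$site_id)))
  # collagenases never rest on a cleaved-flanked site they were forbidden
  # to enter (the cleaving enzyme itself is grandfathered on its own cut,
  # so check enzymes that did not produce the flanking cut at their site)
  lat_f <- st$lattice
  colls <- st$enzymes[st$enzymes$kind == "collagenase", ]
  own_cut <- vapply(seq_len(nrow(colls)), function(k) {
    ev <- st$events
    any(ev$event_type == "cleave" & ev$enzyme_id == colls$enzyme_id[k] &
          ev$site_id == colls$site_id[k])
  }, logical(1))
  flanked <- vapply(colls$site_id, function(s)
    fibrildeg:::site_flanked(lat_f, s), logical(1))
  expect_true(all(!flanked | own_cut))
  # removals are monotone in the snapshots
  expect_true(all(diff(st$snapshots$n_removed) >= 0))
})

test_that("zero collagenases implies zero cleavage events ever", {
  lat <- tiny_lattice(cpc = 2L)
  st <- place_enzymes(lat, 0, 4, seed = 23)
  st <- run_until(st, max_steps = 2e5)
  expect_identical(sum(st$events$event_type == "cleave"), 0L)
  expect_identical(percent_degradation(st$lattice), 0)
})

test_that("calibrate_kinetics maps diffusion to step time and validates", {
  dt1 <- calibrate_kinetics(8e5, 13.4, 0.9)
  expect_equal(dt1, 0.9 * 13.4^2 / (2 * 8e5))
  expect_equal(calibrate_kinetics(1.6e6, 13.4, 0.9), dt1 / 2)  # 2x D halves dt
  expect_error(calibrate_kinetics(8e5, 0, 0.9), "site_length")
  expect_error(calibrate_kinetics(-1, 13.4, 0.9), "diffusion_coefficient")
  expect_error(kinetics_config(p_cleave_attempt = 1e-9,
                               p_vertical = 0.91 - 1e-9,
                               p_horizontal = 0.09),
               "raise")
})

test_that("free-enzyme MSD on a flat landscape matches 2 D t within 5%", {
  lat <- build_fibril(fibril_geometry(m = 1L, chains_per_column = 60L,
                                      single_column = TRUE))
  en <- energy_model(e_well = 0)
  kin <- kinetics_config(site_length = lat$geometry$site_length,
                         cleave_enabled = FALSE)
  a <- lat$geometry$site_length
  D <- kin$diffusion_coefficient
  set.seed(55)
  n_walk <- 600L
  lags_msd <- matrix(0, nrow = n_walk, ncol = 10)
  start <- which(lat$site_chain == 30L)[11L]  # mid lattice
  for (w in seq_len(n_walk)) {
    st <- place_enzymes(lat, 1, 0, energy = en, kinetics = kin)
    st$enzymes$site_id <- start
    st <- run_until(st, max_steps = 1e4, snapshot_every = 1e3)
    # site-contour displacement: site ids are contour-ordered in a column
    pos <- lat$site_at[cbind(st$snap_z[, 1], 1L)]
    lags_msd[w, ] <- (pos[2:11] - pos[1])^2
  }
  msd <- colMeans(lags_msd) * a^2
  t_lag <- (1:10) * 1e3 * kin$dt_attempt
  slope <- coef(lm(msd ~ 0 + t_lag))[[1]]
  expect_equal(slope, 2 * D, tolerance = 0.05)
})

test_that("competent-state waiting times recover the configured rate", {
  kin <- kinetics_config()
  set.seed(3)
  wt <- cleave_waiting_times(500, kin)
  expect_equal(1 / mean(wt), kin$cleave_rate, tolerance = 0.12)
})
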