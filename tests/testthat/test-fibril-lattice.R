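# Lattice construction, surface bookkeeping and neighbour queries.

test_that("default m=4 builder reproduces the reference structure counts", {
  lat <- build_fibril(fibril_geometry())
  expect_identical(lat$n_chains, 925L)
  expect_identical(lat$n_sites, 20350L)
  expect_identical(lat$initial_site_count, 925L * 22L)
  expect_identical(length(unique(lat$col_mf)), 37L)  # 3*4*3 + 1
  expect_identical(lat$n_columns, 185L)
})

test_that("microfibril count follows the centred-hexagonal rule", {
  for (m in 1:3) {
    lat <- build_fibril(fibril_geometry(m = m, chains_per_column = 1L))
    expect_identical(length(unique(lat$col_mf)), 3L * m * (m - 1L) + 1L)
  }
})

test_that("invalid geometry is rejected with the offending field named", {
  expect_error(fibril_geometry(m = 0), "m")
  expect_error(fibril_geometry(site_length = -1), "site_length")
  expect_error(fibril_geometry(stagger_offset = 40), "stagger_offset")
  expect_error(fibril_geometry(chains_per_column = 0), "chains_per_column")
})

test_that("every site of an m=1 fibril is on the surface", {
  lat <- tiny_lattice()
  expect_true(all(lat$is_surface))
  expect_setequal(surface_sites(lat), seq_len(lat$n_sites))
})

test_that("m=2 fibril has buried interior sites and matches the re-scan oracle", {
  lat <- build_fibril(fibril_geometry(m = 2L, chains_per_column = 2L))
  expect_lt(sum(lat$is_surface), lat$n_sites)
  expect_identical(unname(lat$is_surface), unname(oracle_surface(lat)))
})

test_that("surface flags equal the oracle after random removal sequences", {
  lat <- build_fibril(fibril_geometry(m = 2L, chains_per_column = 2L))
  set.seed(101)
  for (rep in 1:5) {
    lat$removed[sample.int(lat$n_sites, 60)] <- TRUE
    got <- cpp_recompute_surface(lat)
    expect_identical(unname(got), unname(oracle_surface(lat)))
  }
})

test_that("removing an outer site exposes its lateral neighbour", {
  lat <- build_fibril(fibril_geometry(m = 2L, chains_per_column = 2L))
  buried <- which(!lat$is_surface)
  # find a buried site adjacent to a surface site and remove that neighbour
  found <- FALSE
  for (s in buried) {
    nb <- lateral_neighbors(lat, s)
    nb_surf <- nb[lat$is_surface[nb]]
    if (length(nb_surf)) {
      lat$removed[nb_surf[1]] <- TRUE
      lat$is_surface <- cpp_recompute_surface(lat)
      expect_true(lat$is_surface[s])
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("vertical neighbours span chains only when abutting", {
  lat <- tiny_lattice()
  spc <- lat$geometry$sites_per_chain
  # mid-chain site: plain +/- 1 neighbours within the chain
  s <- which(lat$site_i == 5L)[1]
  vn <- vertical_neighbors(lat, s)
  expect_identical(unname(vn), c(s + 1L, s - 1L))
  # chain top with a gap above -> none
  top <- which(lat$site_i == spc & lat$site_chain == 1L)
  expect_true(is.na(vertical_neighbors(lat, top)["above"]))
  # with gap_length = 0 chains abut: above is the next chain's i=1 site
  lat0 <- build_fibril(fibril_geometry(m = 1L, chains_per_column = 2L,
                                       gap_length = 0L, stagger_offset = 5L))
  top0 <- which(lat0$site_i == lat0$geometry$sites_per_chain &
                  lat0$site_chain == 1L)
  above <- vertical_neighbors(lat0, top0)["above"]
  expect_identical(lat0$site_i[above], 1L)
  expect_identical(lat0$site_chain[above], 2L)
  expect_error(vertical_neighbors(lat, 10 * lat$n_sites), "unknown site_id")
})

test_that("lateral neighbour relation is symmetric and excludes removed sites", {
  lat <- build_fibril(fibril_geometry(m = 2L, chains_per_column = 2L))
  set.seed(7)
  for (s in sample(which(!lat$removed), 50)) {
    for (t in lateral_neighbors(lat, s)) {
      expect_true(s %in% lateral_neighbors(lat, t))
    }
  }
  s <- which(lengths(lapply(seq_len(50), function(i)
    lateral_neighbors(lat, i))) > 0)[1]
  nb <- lateral_neighbors(lat, s)
  lat$removed[nb[1]] <- TRUE
  expect_false(nb[1] %in% lateral_neighbors(lat, s))
})

test_that("vertical neighbours are mutually inverse", {
  lat <- tiny_lattice()
  for (s in sample.int(lat$n_sites, 40)) {
    vn <- vertical_neighbors(lat, s)
    if (!is.na(vn["above"])) {
      expect_identical(unname(vertical_neighbors(lat, vn[["above"]])["below"]), s)
    }
    if (!is.na(vn["below"])) {
      expect_identical(unname(vertical_neighbors(lat, vn[["below"]])["above"]), s)
    }
  }
})

test_that("a single-column configuration has no lateral neighbours", {
  lat <- single_chain_lattice()
  expect_identical(lat$n_chains, 1L)
  expect_identical(lat$n_sites, 22L)
  expect_length(lateral_neighbors(lat, 5L), 0L)
  expect_true(all(lat$is_surface))
})

test_that("rebuilding with the same geometry is bit-identical", {
  a <- build_fibril(fibril_geometry(m = 2L))
  b <- build_fibril(fibril_geometry(m = 2L))
  expect_identical(a, b)
})

test_that("lattice JSON serialization round-trips including state", {
  lat <- tiny_lattice()
  lat$bond_up[4L] <- TRUE   # cleave bond(4->5) of chain 1
  lat$gelatin[1L] <- TRUE
  lat$removed[30L] <- TRUE
  lat$is_surface <- cpp_recompute_surface(lat)
  path <- tempfile(fileext = ".json")
  write_lattice_json(lat, path)
  back <- read_lattice_json(path)
  expect_identical(back$removed, lat$removed)
  expect_identical(back$bond_up, lat$bond_up)
  expect_identical(back$gelatin, lat$gelatin)
  expect_identical(back$geometry, lat$geometry)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(read_lattice_json(bad), "not a fibrildeg lattice")
})
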