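# Pooling design: geometry arithmetic, cube mapping, partitions, pool sizes.

test_that("geometry invariants hold and inconsistencies are rejected", {
  g <- library_geometry()
  expect_equal(g$n_clones, 82944)
  expect_equal(g$cube_rows, 48)
  expect_equal(g$cube_cols, 48)
  expect_equal(g$n_plates, g$layers * g$plates_per_layer)

  expect_error(library_geometry(n_plates = 215), "inconsistent geometry")
  expect_error(library_geometry(n_plates = 180, plates_per_layer = 5), "blocks")
  expect_error(build_design(scaled_geometry(), c("PP", "XX")), "unknown pooling dimension")
  # SA/SB need divisible plate counts
  g9 <- library_geometry(n_plates = 9, plate_rows = 4, plate_cols = 6,
                         layers = 3, plates_per_layer = 3, blocks = c(3, 1))
  expect_error(build_design(g9, c("PP", "SB")), "divisible by 8")
  g6 <- library_geometry(n_plates = 6, plate_rows = 4, plate_cols = 6,
                         layers = 2, plates_per_layer = 3, blocks = c(3, 1))
  expect_error(build_design(g6, "SA"), NA)  # 6 %% 2 == 0: fine
})

test_that("to_cube follows the block formulas and inverts exactly", {
  g <- library_geometry()
  expect_equal(to_cube(0, 0, 0, g), data.table::data.table(r = 0L, c = 0L, L = 0L))
  expect_equal(to_cube(6, 0, 0, g), data.table::data.table(r = 0L, c = 0L, L = 1L))
  # plate 3 (slot 3 of layer 0: row block 1, col block 1), well (2, 5)
  expect_equal(to_cube(3, 2, 5, g), data.table::data.table(r = 18L, c = 29L, L = 0L))
  expect_error(to_cube(216, 0, 0, g), "out of range")
  expect_error(to_cube(0, 16, 0, g), "out of range")

  # exhaustive round-trip on the scaled cube
  gs <- scaled_geometry()
  all_id <- seq_len(gs$n_clones) - 1L
  coords <- bacscreen:::clone_coord(gs, all_id)
  cube <- to_cube(coords$plate, coords$well_row, coords$well_col, gs)
  back <- from_cube(cube$r, cube$c, cube$L, gs)
  expect_identical(back, coords)
  # all cube positions distinct
  expect_equal(nrow(unique(cube)), gs$n_clones)

  # sampled round-trip at paper scale
  set.seed(1)
  id <- sample.int(g$n_clones, 500) - 1L
  coords <- bacscreen:::clone_coord(g, id)
  cube <- to_cube(coords$plate, coords$well_row, coords$well_col, g)
  expect_identical(from_cube(cube$r, cube$c, cube$L, g), coords)
})

test_that("default design reproduces the printed pool counts and sizes", {
  d <- default_design()
  expect_equal(sum(d$pool_counts[c("PP", "RP", "CP", "DP", "SP", "FP")]), 276)
  expect_equal(sum(d$pool_counts[c("PP", "RP", "CP", "DP", "SP", "FP", "SA", "SB")]), 339)
  expect_equal(unname(d$pool_counts[ALL_DIMS]),
               c(36L, 48L, 48L, 48L, 48L, 48L, 36L, 27L, 216L))
  expect_equal(unname(d$pool_sizes[ALL_DIMS]),
               c(2304L, 1728L, 1728L, 1728L, 1728L, 1728L, 2304L, 3072L, 384L))
})

test_that("every dimension partitions the clone set into equal pools", {
  for (d in list(scaled_design(), default_design())) {
    for (dm in d$dimensions) {
      sizes <- tabulate(d$assignment[, dm] + 1L, nbins = d$pool_counts[[dm]])
      expect_equal(sizes, rep(d$pool_sizes[[dm]], d$pool_counts[[dm]]),
                   info = sprintf("dimension %s", dm))
    }
  }
})

test_that("clone_pools matches the per-clone oracle and pool membership", {
  ds <- scaled_design()
  gs <- ds$geometry
  # exhaustive oracle cross-check on the scaled cube
  for (id in seq_len(gs$n_clones) - 1L) {
    co <- bacscreen:::clone_coord(gs, id)
    got <- clone_pools(ds, co$plate, co$well_row, co$well_col)
    expect_equal(got, oracle_clone_pools(gs, co$plate, co$well_row, co$well_col))
  }
  # modular-formula spot values at paper scale
  d <- default_design()
  g <- d$geometry
  co <- from_cube(5, 10, 3, g)
  pools <- clone_pools(d, co$plate, co$well_row, co$well_col)
  expect_equal(pools[["DP"]], 15)
  expect_equal(pools[["SP"]], 8)
  expect_equal(pools[["FP"]], 13)
  co0 <- from_cube(0, 0, 0, g)
  six <- c("PP", "RP", "CP", "DP", "SP", "FP")
  expect_true(all(clone_pools(d, co0$plate, co0$well_row, co0$well_col)[six] == 0))

  # clone_pools agrees with pool_members: sampled clones at paper scale
  set.seed(7)
  for (id in sample.int(g$n_clones, 20) - 1L) {
    co <- bacscreen:::clone_coord(g, id)
    pools <- clone_pools(d, co$plate, co$well_row, co$well_col)
    for (dm in names(pools)) {
      members <- bacscreen:::pool_member_ids(d, dm, pools[[dm]])
      expect_true(id %in% members)
    }
  }
})

test_that("pool_members returns the printed sizes and validates addresses", {
  d <- default_design()
  pp0 <- pool_members(d, "PP", 0)
  expect_equal(nrow(pp0), 2304)
  expect_equal(sort(unique(pp0$plate)), 0:5)  # first layer = plates 0-5
  expect_equal(nrow(pool_members(d, "SB", 0)), 3072)
  expect_equal(nrow(pool_members(d, "SG", 215)), 384)
  expect_error(pool_members(d, "RP", 48), "out of range")
  expect_error(pool_members(build_design(d$geometry, "PP"), "RP", 0), "not enabled")
})

test_that("the (RP, CP, PP) triple identifies clones uniquely", {
  d <- scaled_design()
  triple <- paste(d$assignment[, "RP"], d$assignment[, "CP"], d$assignment[, "PP"])
  expect_equal(anyDuplicated(triple), 0L)
})

test_that("pool ids format and parse round-trip", {
  d <- default_design()
  expect_equal(pool_id(d, "DP", 7), "DP07")
  expect_equal(pool_id(d, "SG", 215), "SG215")
  ids <- c("PP00", "RP47", "SG007")
  parsed <- parse_pool_id(ids)
  expect_equal(parsed$dimension, c("PP", "RP", "SG"))
  expect_equal(parsed$index, c(0L, 47L, 7L))
  expect_error(parse_pool_id("bogus"), "malformed")
})

test_that("pool manifest writer emits one row per pool", {
  d <- scaled_design()
  path <- withr::local_tempfile(fileext = ".tsv")
  members <- withr::local_tempfile(fileext = ".tsv")
  manifest <- write_pool_manifest(d, path, members)
  expect_equal(nrow(manifest), sum(d$pool_counts))
  on_disk <- data.table::fread(path)
  expect_equal(nrow(on_disk), sum(d$pool_counts))
  expect_equal(sum(on_disk$n_clones), length(d$dimensions) * d$geometry$n_clones)
  mem <- data.table::fread(members)
  expect_equal(nrow(mem), length(d$dimensions) * d$geometry$n_clones)
})
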