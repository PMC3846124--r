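# Shared fixtures: a scaled 192-clone cube (8 plates of 4x6 wells, 4 layers
# of 2 plates in a 2x1 block grid) for exhaustive checks, and the default
# paper-scale geometry built once per test run.

scaled_geometry <- function() library_geometry(
  n_plates = 8, plate_rows = 4, plate_cols = 6,
  layers = 4, plates_per_layer = 2, blocks = c(2, 1))

ALL_DIMS <- c("PP", "RP", "CP", "DP", "SP", "FP", "SA", "SB", "SG")

scaled_design <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- build_design(scaled_geometry(), ALL_DIMS)
    d
  }
})

default_design <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- build_design(library_geometry(), ALL_DIMS)
    d
  }
})

# Independent per-clone pool computation: scalar arithmetic from first
# principles, used as an oracle against the vectorized assignment matrix.
oracle_clone_pools <- function(geometry, plate, row, col) {
  L <- plate %/% geometry$plates_per_layer
  q <- plate %% geometry$plates_per_layer
  r <- geometry$plate_rows * (q %/% geometry$blocks_c) + row
  cc <- geometry$plate_cols * (q %% geometry$blocks_c) + col
  c(PP = L, RP = r, CP = cc,
    DP = (r + cc) %% geometry$cube_rows,
    SP = (r + L) %% geometry$cube_rows,
    FP = (cc + L) %% geometry$cube_cols,
    SA = plate %% geometry$layers,
    SB = plate %% (geometry$n_plates %/% 8L),
    SG = plate)
}

# Brute-force deconvolution over every clone of the library.
brute_force_candidates <- function(design, positive, dimensions) {
  keep <- rep(TRUE, design$geometry$n_clones)
  for (d in dimensions)
    keep <- keep & (design$assignment[, d] %in% positive[[d]])
  which(keep) - 1L
}

# A small intergenomic screen on the scaled cube.
scaled_screen <- function(copy_a = 3, copy_c = 4, params = noise_free_params(),
                          seed = 11) {
  d <- scaled_design()
  set.seed(seed)
  la <- place_locus(d, "locA", "A", copy_a)
  lc <- place_locus(d, "locC", "C", copy_c)
  assay <- assay_definition("assay1", "intergenomic",
                            allele1_loci = "locA", allele2_loci = "locC")
  sim <- simulate_screen(d, list(la, lc), list(assay), params, seed = seed)
  list(design = d, la = la, lc = lc, assay = assay, sim = sim)
}
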