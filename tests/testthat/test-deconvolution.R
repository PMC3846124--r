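# Deconvolution: positive-pool intersection vs the brute-force oracle.

test_that("empty and singleton cases behave as the intersection requires", {
  sc <- scaled_screen()
  d <- sc$design
  # all pools negative -> empty candidate set
  neg <- data.table::copy(sc$sim$records)
  neg[, norm_r := 0.01]
  calls <- score_table(neg)
  cs <- candidates(d, calls, "assay1", "snp1", screening_dimensions("six_dim"))
  expect_length(cs$clone_ids, 0)

  # one planted clone with perfect calls -> exactly that clone
  set.seed(5)
  la <- place_locus(d, "solo", "A", 1)
  assay <- assay_definition("solo_assay", "intragenomic", allele1_loci = "solo")
  sim <- simulate_screen(d, list(la), list(assay), noise_free_params(), seed = 5)
  calls <- score_table(sim$records)
  cs <- candidates(d, calls, "solo_assay", "snp1", screening_dimensions("six_dim"))
  expect_identical(cs$clone_ids, la$clones)
})

test_that("optimized intersection equals brute force, exhaustively on the scaled cube", {
  d <- scaled_design()
  dims <- screening_dimensions("opa1_8dim")
  set.seed(31)
  for (rep in 1:20) {
    la <- place_locus(d, "A", "A", sample(1:6, 1))
    lc <- place_locus(d, "C", "C", sample(1:6, 1))
    assay <- assay_definition("x", "intergenomic", "A", "C")
    sim <- simulate_screen(d, list(la, lc), list(assay),
                           signal_params(theta_sd = 0.05, dropout_prob = 0.1))
    calls <- score_table(sim$records)
    for (allele in c("snp1", "snp2")) {
      pos <- bacscreen:::positive_pools(d, calls, "x", allele, dims)
      expect_identical(candidates(d, calls, "x", allele, dims)$clone_ids,
                       brute_force_candidates(d, pos, dims))
    }
  }
})

test_that("optimized intersection equals brute force on random screens at full scale", {
  d <- default_design()
  dims <- screening_dimensions("opa1_8dim")
  set.seed(17)
  for (rep in 1:10) {
    # random positive pools per dimension, bypassing the simulator entirely
    pos <- lapply(dims, function(dm)
      sort(sample(0:(d$pool_counts[[dm]] - 1L),
                  sample(1:4, 1))))
    names(pos) <- dims
    calls <- data.table::rbindlist(lapply(dims, function(dm)
      data.table::data.table(
        sample_id = pool_id(d, dm, 0:(d$pool_counts[[dm]] - 1L)),
        assay_id = "r",
        call = ifelse(0:(d$pool_counts[[dm]] - 1L) %in% pos[[dm]],
                      sample(c("snp1", "both"), d$pool_counts[[dm]], TRUE),
                      "none"))))
    cs <- candidates(d, calls, "r", "snp1", dims)
    expect_identical(cs$clone_ids, brute_force_candidates(d, pos, dims))
  }
})

test_that("perfect screens recover all planted clones; a lost pool record loses the clone", {
  d <- default_design()
  set.seed(12)
  la <- place_locus(d, "A", "A", 10)
  lc <- place_locus(d, "C", "C", 15)
  assay <- assay_definition("pair", "intergenomic", "A", "C")
  sim <- simulate_screen(d, list(la, lc), list(assay), noise_free_params(),
                         seed = 12)
  calls <- score_table(sim$records)
  for (mode in c("opa1_8dim", "opa2_7dim")) {
    cands <- deconvolve_all(d, calls, list(assay), mode = mode)
    expect_true(all(la$clones %in% cands[["pair:snp1"]]$clone_ids), info = mode)
    expect_true(all(lc$clones %in% cands[["pair:snp2"]]$clone_ids), info = mode)
  }
  # delete one dimension's record for one planted clone -> clone lost
  victim <- la$clones[1]
  co <- bacscreen:::clone_coord(d$geometry, victim)
  pools <- clone_pools(d, co$plate, co$well_row, co$well_col)
  lost_id <- pool_id(d, "RP", pools[["RP"]])
  crippled <- calls[sample_id != lost_id]
  expect_warning(
    cs <- candidates(d, crippled, "pair", "snp1", screening_dimensions("opa1_8dim")),
    "no record")
  expect_false(victim %in% cs$clone_ids)
  # unless one missing dimension is tolerated
  expect_warning(
    cs_tol <- candidates(d, crippled, "pair", "snp1",
                         screening_dimensions("opa1_8dim"), max_missing_dims = 1),
    "no record")
  expect_true(victim %in% cs_tol$clone_ids)
})

test_that("adding screening dimensions never enlarges the candidate set", {
  set.seed(23)
  for (rep in 1:5) {
    sc <- scaled_screen(copy_a = sample(2:5, 1), copy_c = sample(2:5, 1),
                        params = signal_params(), seed = 100 + rep)
    calls <- score_table(sc$sim$records)
    six <- candidates(sc$design, calls, "assay1", "snp1",
                      screening_dimensions("six_dim"))
    eight <- candidates(sc$design, calls, "assay1", "snp1",
                        screening_dimensions("opa1_8dim"))
    seven <- candidates(sc$design, calls, "assay1", "snp1",
                        screening_dimensions("opa2_7dim"))
    expect_true(all(eight$clone_ids %in% six$clone_ids))
    expect_true(all(seven$clone_ids %in% six$clone_ids))
  }
})

test_that("soundness and shadow completeness hold on noisy screens", {
  sc <- scaled_screen(params = signal_params(theta_sd = 0.05), seed = 77)
  calls <- score_table(sc$sim$records)
  dims <- screening_dimensions("six_dim")
  pos <- bacscreen:::positive_pools(sc$design, calls, "assay1", "snp1", dims)
  cs <- candidates(sc$design, calls, "assay1", "snp1", dims)
  # every planted clone whose pools are all positive is returned
  for (id in sc$la$clones) {
    all_pos <- all(vapply(dims, function(dm)
      sc$design$assignment[id + 1L, dm] %in% pos[[dm]], TRUE))
    if (all_pos) expect_true(id %in% cs$clone_ids)
  }
  # every returned coordinate has all pools positive
  for (id in cs$clone_ids)
    for (dm in dims)
      expect_true(sc$design$assignment[id + 1L, dm] %in% pos[[dm]])
})

test_that("unknown dimensions and assay structure are validated", {
  sc <- scaled_screen()
  calls <- score_table(sc$sim$records)
  d6 <- build_design(scaled_geometry(), screening_dimensions("six_dim"))
  expect_error(candidates(d6, calls, "assay1", "snp1", c("PP", "SG")),
               "not in design")
  # intragenomic assay deconvolves to a single allele
  intra <- assay_definition("assay1", "intragenomic", allele1_loci = "locA")
  out <- deconvolve_all(sc$design, calls, intra, mode = "six_dim")
  expect_named(out, "assay1:snp1")
})
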