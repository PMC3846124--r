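#' Signal model parameters for pooled GoldenGate-style assays
#'
#' Pooled SNP genotyping reports, per (sample, assay), a normalized
#' fluorescence intensity ("normalized R") and a normalized allele-frequency
#' coordinate ("normalized Theta" in \[0, 1\]).  The simulator models a pool
#' carrying `a` clones of the Theta~0 allele and `b` clones of the Theta~1
#' allele as
#' `R = r_max * (1 - exp(-kappa * (a + b))) + noise` and
#' `Theta = b / (a + b) + noise`, clamped to \[0, 1\].  Pools with no
#' carriers show only residual intensity (mean `r_residual_mean`, below the
#' 0.2 scoring threshold) and an uninformative uniform Theta.
#'
#' Two failure mechanisms are modelled.  `dropout_prob` is a per-clone,
#' per-assay representation failure (a clone underrepresented in the pooled
#' DNA contributes to none of its pools for that assay); clones listed in
#' `weak_clones` fail with the higher `weak_dropout_prob`, emulating
#' poorly growing clones.  `pool_fail_prob` is an independent per-pool,
#' per-assay failure (the whole reaction yields only residual signal),
#' useful for injecting a controlled per-carrier-pool miss rate.
#'
#' @param r_residual_mean,r_residual_sd residual intensity of empty pools
#'   (also the intensity noise scale of non-empty pools).
#' @param r_max saturation intensity.
#' @param kappa intensity rate per carrier clone.
#' @param theta_sd Gaussian noise on Theta.
#' @param dropout_prob per-clone per-assay representation-failure
#'   probability.
#' @param weak_clones integer vector of clone indices with elevated dropout.
#' @param weak_dropout_prob dropout probability for `weak_clones`.
#' @param pool_fail_prob per-(pool, assay) whole-reaction failure
#'   probability.
#' @return An object of class `signal_params`.
#' @export
signal_params <- function(r_residual_mean = 0.05, r_residual_sd = 0.02,
                          r_max = 1.0, kappa = 1.0, theta_sd = 0.02,
                          dropout_prob = 0.03, weak_clones = integer(0),
                          weak_dropout_prob = 0.5, pool_fail_prob = 0) {
  probs <- c(dropout_prob, weak_dropout_prob, pool_fail_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(c(r_residual_sd, theta_sd) < 0) || r_max <= 0 || kappa <= 0)
    stop("noise scales must be non-negative and r_max, kappa positive",
         call. = FALSE)
  if (r_residual_mean < 0 || r_residual_mean >= 0.2)
    stop("r_residual_mean must be in [0, 0.2) so empty pools stay below the scoring threshold",
         call. = FALSE)
  p <- list(r_residual_mean = r_residual_mean, r_residual_sd = r_residual_sd,
            r_max = r_max, kappa = kappa, theta_sd = theta_sd,
            dropout_prob = dropout_prob,
            weak_clones = as.integer(weak_clones),
            weak_dropout_prob = weak_dropout_prob,
            pool_fail_prob = pool_fail_prob)
  class(p) <- "signal_params"
  p
}

#' Noise-free signal parameters
#'
#' Convenience wrapper: all noise scales, dropout and pool-failure
#' probabilities set to zero.  Under these parameters every carrier pool
#' exceeds the R threshold and Theta equals `b / (a + b)` exactly.
#'
#' @param ... overrides passed to [signal_params()].
#' @export
noise_free_params <- function(...) {
  args <- list(r_residual_sd = 0, theta_sd = 0, dropout_prob = 0,
               weak_dropout_prob = 0, pool_fail_prob = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(signal_params, args)
}

#' Place a locus on random clones of the library
#'
#' Emulates the representation of a locus in the library: `copy_number`
#' distinct clones drawn uniformly.  The studied library represented its
#' loci 10.6 times on average (about 10-fold genome coverage), so a Poisson
#' draw with mean 10.6 (zero-truncated) is a realistic default copy number.
#'
#' @param design a [build_design()] result (or a `bac_geometry`).
#' @param locus_id locus name.
#' @param genome_class `"A"` or `"C"` progenitor genome of the locus.
#' @param copy_number number of carrier clones; `NULL` draws
#'   zero-truncated Poisson(10.6).
#' @param seed optional integer seed for reproducible placement.
#' @return An object of class `locus_placement` with fields `locus_id`,
#'   `genome_class`, `clones` (sorted clone indices), `copy_number`.
#' @export
place_locus <- function(design, locus_id, genome_class = "A",
                        copy_number = NULL, seed = NULL) {
  geometry <- if (inherits(design, "pooling_design")) design$geometry else design
  stopifnot(inherits(geometry, "bac_geometry"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(copy_number)) {
    copy_number <- 0L
    while (copy_number == 0L) copy_number <- stats::rpois(1L, 10.6)
  }
  copy_number <- as.integer(copy_number)
  if (is.na(copy_number) || copy_number < 0L)
    stop("copy_number must be a non-negative integer", call. = FALSE)
  if (copy_number > geometry$n_clones)
    stop("copy_number exceeds the library size", call. = FALSE)
  clones <- if (copy_number == 0L) integer(0) else
    sort(sample.int(geometry$n_clones, copy_number) - 1L)
  structure(list(locus_id = as.character(locus_id),
                 genome_class = match.arg(genome_class, c("A", "C")),
                 clones = clones, copy_number = copy_number),
            class = "locus_placement")
}

#' Define a SNP assay over placed loci
#'
#' Intergenomic assays discriminate a homoeologous locus pair: the locus of
#' one genome drives Theta towards 0 (`allele1`), the other towards 1
#' (`allele2`).  Intragenomic assays detect a single gene (one allele class
#' populated).  Non-discriminating assays detect homoeologs that share one
#' allele class.  Off-target loci add spurious carriers to either allele,
#' emulating assays that cross-react with homologous sequences.
#'
#' @param assay_id assay name.
#' @param assay_type one of `"intergenomic"`, `"intragenomic"`,
#'   `"non_discriminating"`.
#' @param allele1_loci,allele2_loci locus ids whose carriers pull Theta
#'   towards 0 resp. 1.
#' @param off_target_allele1,off_target_allele2 locus ids contributing
#'   spurious carriers to either allele.
#' @return An object of class `assay_definition`.
#' @export
assay_definition <- function(assay_id,
                             assay_type = c("intergenomic", "intragenomic",
                                            "non_discriminating"),
                             allele1_loci = character(0),
                             allele2_loci = character(0),
                             off_target_allele1 = character(0),
                             off_target_allele2 = character(0)) {
  assay_type <- match.arg(assay_type)
  if (assay_type == "intergenomic" &&
      (length(allele1_loci) != 1L || length(allele2_loci) != 1L))
    stop("an intergenomic assay has exactly one homoeolog per allele",
         call. = FALSE)
  if (assay_type == "intragenomic" &&
      !xor(length(allele1_loci) > 0L, length(allele2_loci) > 0L))
    stop("an intragenomic assay detects a single gene: exactly one allele class may carry loci",
         call. = FALSE)
  if (assay_type == "non_discriminating" &&
      !xor(length(allele1_loci) > 0L, length(allele2_loci) > 0L))
    stop("a non-discriminating assay places all homoeologs in one allele class",
         call. = FALSE)
  structure(list(assay_id = as.character(assay_id), assay_type = assay_type,
                 allele1_loci = as.character(allele1_loci),
                 allele2_loci = as.character(allele2_loci),
                 off_target_allele1 = as.character(off_target_allele1),
                 off_target_allele2 = as.character(off_target_allele2)),
            class = "assay_definition")
}

## Signal generation from effective carrier counts (dropout already applied).
## Vectorized over (a, b).
signal_from_counts <- function(a, b, params) {
  n <- length(a)
  stopifnot(length(b) == n)
  total <- a + b
  empty <- total == 0
  norm_r <- numeric(n); norm_theta <- numeric(n)
  if (any(empty)) {
    norm_r[empty] <- pmax(0, stats::rnorm(sum(empty), params$r_residual_mean,
                                          params$r_residual_sd))
    norm_theta[empty] <- stats::runif(sum(empty))
  }
  if (any(!empty)) {
    k <- sum(!empty)
    norm_r[!empty] <- pmax(0, params$r_max * (1 - exp(-params$kappa * total[!empty])) +
                              stats::rnorm(k, 0, params$r_residual_sd))
    norm_theta[!empty] <- pmin(1, pmax(0, b[!empty] / total[!empty] +
                                          stats::rnorm(k, 0, params$theta_sd)))
  }
  data.table::data.table(norm_r = norm_r, norm_theta = norm_theta)
}

#' Simulate the signal of one pool from raw carrier counts
#'
#' Applies per-clone dropout (`dropout_prob`) to the raw counts, then
#' generates `(norm_r, norm_theta)` from the effective counts.  With noise
#' and dropout off this is deterministic: an empty pool yields
#' `r_residual_mean` and a carrier pool yields
#' `r_max * (1 - exp(-kappa * (a + b)))` and `Theta = b / (a + b)`.
#'
#' @param a,b raw carrier counts of allele 1 (Theta ~ 0) and allele 2
#'   (Theta ~ 1); vectorized.
#' @param params a [signal_params()].
#' @param seed optional integer seed.
#' @return A `data.table` with columns `norm_r`, `norm_theta`.
#' @export
simulate_pool_signal <- function(a, b, params = signal_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  a <- as.integer(a); b <- as.integer(b)
  if (anyNA(a) || anyNA(b) || any(a < 0L) || any(b < 0L))
    stop("carrier counts must be non-negative", call. = FALSE)
  a_eff <- if (params$dropout_prob > 0) stats::rbinom(length(a), a, 1 - params$dropout_prob) else a
  b_eff <- if (params$dropout_prob > 0) stats::rbinom(length(b), b, 1 - params$dropout_prob) else b
  signal_from_counts(a_eff, b_eff, params)
}

## Per-pool carrier counts of a clone set: counts clones falling in each pool
## of each enabled dimension.  Returns a data.table (dimension, index, count)
## for pools with count > 0 only.
count_carriers <- function(design, clones) {
  if (!length(clones))
    return(data.table::data.table(dimension = character(0), index = integer(0),
                                  count = integer(0)))
  sub <- design$assignment[clones + 1L, , drop = FALSE]
  data.table::rbindlist(lapply(design$dimensions, function(d) {
    tab <- tabulate(sub[, d] + 1L, nbins = design$pool_counts[[d]])
    pos <- which(tab > 0L)
    data.table::data.table(dimension = d, index = pos - 1L, count = tab[pos])
  }))
}

#' Simulate a full pooled screen
#'
#' Generates one signal record per (enabled pool, assay).  For each assay,
#' per-clone dropout is realized once (a dropped clone is missing from all
#' of its pools for that assay), off-target carriers are added to their
#' allele class, per-pool failures are applied, and signals are drawn from
#' the effective counts.
#'
#' @param design a [build_design()] result.
#' @param placements list of [place_locus()] results.
#' @param assays list of [assay_definition()]s referencing placed loci.
#' @param params a [signal_params()].
#' @param seed optional integer seed; the same seed reproduces the same
#'   table exactly.
#' @return An object of class `bac_screen_sim`: a list with
#'   `records` (the signal table: `sample_id`, `assay_id`, `norm_r`,
#'   `norm_theta`), `truth` (per (pool, assay): raw and effective carrier
#'   counts, the expected call from raw counts, and whether the pool
#'   reaction failed), `dropped` (per assay, the dropped clone indices),
#'   `placements`, `assays`, `params`.
#' @export
simulate_screen <- function(design, placements, assays,
                            params = signal_params(), seed = NULL) {
  stopifnot(inherits(design, "pooling_design"))
  if (inherits(placements, "locus_placement")) placements <- list(placements)
  if (inherits(assays, "assay_definition")) assays <- list(assays)
  if (!is.null(seed)) set.seed(as.integer(seed))
  locus_map <- stats::setNames(placements,
                               vapply(placements, `[[`, "", "locus_id"))
  all_pools <- data.table::rbindlist(lapply(design$dimensions, function(d)
    data.table::data.table(dimension = d,
                           index = seq_len(design$pool_counts[[d]]) - 1L)))
  all_pools[, sample_id := pool_id(design, dimension, index)]

  records <- list(); truths <- list(); dropped <- list()
  for (assay in assays) {
    ids <- c(assay$allele1_loci, assay$allele2_loci,
             assay$off_target_allele1, assay$off_target_allele2)
    missing <- setdiff(ids, names(locus_map))
    if (length(missing))
      stop(sprintf("assay %s references unplaced locus/loci: %s",
                   assay$assay_id, paste(missing, collapse = ", ")),
           call. = FALSE)
    carriers1 <- sort(unique(unlist(lapply(
      c(assay$allele1_loci, assay$off_target_allele1),
      function(l) locus_map[[l]]$clones))))
    carriers2 <- sort(unique(unlist(lapply(
      c(assay$allele2_loci, assay$off_target_allele2),
      function(l) locus_map[[l]]$clones))))
    carriers <- sort(unique(c(carriers1, carriers2)))
    p_drop <- rep(params$dropout_prob, length(carriers))
    p_drop[carriers %in% params$weak_clones] <- params$weak_dropout_prob
    drop_mask <- stats::runif(length(carriers)) < p_drop
    dropped_clones <- carriers[drop_mask]
    dropped[[assay$assay_id]] <- dropped_clones

    raw1 <- count_carriers(design, carriers1)
    raw2 <- count_carriers(design, carriers2)
    eff1 <- count_carriers(design, setdiff(carriers1, dropped_clones))
    eff2 <- count_carriers(design, setdiff(carriers2, dropped_clones))
    truth <- data.table::copy(all_pools)
    merge_count <- function(dt, cnt, col) {
      dt[cnt, (col) := i.count, on = c("dimension", "index")]
      dt[is.na(get(col)), (col) := 0L]
    }
    truth[, c("a_raw", "b_raw", "a_eff", "b_eff") := 0L]
    merge_count(truth, raw1, "a_raw"); merge_count(truth, raw2, "b_raw")
    merge_count(truth, eff1, "a_eff"); merge_count(truth, eff2, "b_eff")
    truth[, assay_id := assay$assay_id]
    truth[, expected := data.table::fcase(
      a_raw > 0L & b_raw == 0L, "snp1",
      a_raw == 0L & b_raw > 0L, "snp2",
      a_raw > 0L & b_raw > 0L, "both",
      default = "none")]
    truth[, pool_failed := a_eff + b_eff > 0L &
            stats::runif(.N) < params$pool_fail_prob]
    a_sig <- truth$a_eff; b_sig <- truth$b_eff
    a_sig[truth$pool_failed] <- 0L; b_sig[truth$pool_failed] <- 0L
    sig <- signal_from_counts(a_sig, b_sig, params)
    records[[assay$assay_id]] <- data.table::data.table(
      sample_id = truth$sample_id, assay_id = assay$assay_id,
      norm_r = sig$norm_r, norm_theta = sig$norm_theta)
    truths[[assay$assay_id]] <- truth
  }
  structure(list(records = data.table::rbindlist(records),
                 truth = data.table::rbindlist(truths),
                 dropped = dropped, placements = placements, assays = assays,
                 params = params, design_dimensions = design$dimensions),
            class = "bac_screen_sim")
}

#' Simulate a plant reference sample
#'
#' Plant DNA samples behave like pools with balanced template: homozygous
#' genotypes give Theta near 0 or 1, heterozygous (or amphidiploid samples
#' carrying both homoeologs) near 0.5, and null genotypes (locus absent,
#' e.g. the wrong progenitor species for a genome-specific assay) only
#' residual intensity.
#'
#' @param genotype one of `"allele1_homozygous"`, `"allele2_homozygous"`,
#'   `"heterozygous_or_both"`, `"null"`.
#' @param params a [signal_params()].
#' @param sample_id,assay_id names for the output record.
#' @param seed optional integer seed.
#' @return A one-row signal `data.table`.
#' @export
simulate_plant_sample <- function(genotype = c("allele1_homozygous",
                                               "allele2_homozygous",
                                               "heterozygous_or_both", "null"),
                                  params = signal_params(),
                                  sample_id = "plant", assay_id = "assay",
                                  seed = NULL) {
  genotype <- match.arg(genotype)
  if (!is.null(seed)) set.seed(as.integer(seed))
  counts <- switch(genotype,
                   allele1_homozygous = c(2L, 0L),
                   allele2_homozygous = c(0L, 2L),
                   heterozygous_or_both = c(1L, 1L),
                   null = c(0L, 0L))
  sig <- signal_from_counts(counts[1], counts[2], params)
  data.table::data.table(sample_id = sample_id, assay_id = assay_id,
                         norm_r = sig$norm_r, norm_theta = sig$norm_theta)
}
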