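#' Threshold rule for scoring BAC pools
#'
#' The optimized BAC-pool scoring rule classifies each (pool, assay) record
#' from its normalized R intensity and normalized Theta: records with
#' `norm_r < r_min` are not scored (`none`); otherwise
#' `Theta <= theta_low` is a `snp1` call, `Theta >= theta_high` a `snp2`
#' call, and anything strictly between the bounds is `both` (the pool
#' carries clones of both alleles/homoeologs).  Note the boundary
#' semantics: Theta exactly at a bound is a single-SNP call, never `both`.
#'
#' @param r_min intensity threshold (default 0.2).
#' @param theta_low,theta_high Theta bounds (defaults 0.05 and 0.95).
#' @return An object of class `scoring_thresholds`.
#' @export
scoring_thresholds <- function(r_min = 0.2, theta_low = 0.05, theta_high = 0.95) {
  if (!(r_min > 0)) stop("r_min must be positive", call. = FALSE)
  if (!(theta_low >= 0 && theta_low < theta_high && theta_high <= 1))
    stop("need 0 <= theta_low < theta_high <= 1", call. = FALSE)
  structure(list(r_min = r_min, theta_low = theta_low, theta_high = theta_high),
            class = "scoring_thresholds")
}

CALL_LEVELS <- c("none", "snp1", "snp2", "both")

validate_signal_values <- function(norm_r, norm_theta) {
  if (anyNA(norm_r) || anyNA(norm_theta))
    stop("missing signal values", call. = FALSE)
  if (any(norm_r < 0))
    stop("normalized R must be non-negative", call. = FALSE)
  if (any(norm_theta < 0 | norm_theta > 1))
    stop("normalized Theta must lie in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Score one signal record
#'
#' @param norm_r,norm_theta signal values (scalar).
#' @param thresholds a [scoring_thresholds()].
#' @return One of `"none"`, `"snp1"`, `"snp2"`, `"both"`.
#' @export
score_record <- function(norm_r, norm_theta, thresholds = scoring_thresholds()) {
  stopifnot(length(norm_r) == 1L, length(norm_theta) == 1L)
  validate_signal_values(norm_r, norm_theta)
  if (norm_r < thresholds$r_min) return("none")
  if (norm_theta <= thresholds$theta_low) return("snp1")
  if (norm_theta >= thresholds$theta_high) return("snp2")
  "both"
}

#' Score a signal table
#'
#' Vectorized application of [score_record()]; the input table must carry
#' columns `sample_id`, `assay_id`, `norm_r`, `norm_theta`.
#'
#' @param records signal table (`data.frame`/`data.table`).
#' @param thresholds a [scoring_thresholds()].
#' @return A `data.table` with the input columns plus `call`.
#' @export
score_table <- function(records, thresholds = scoring_thresholds()) {
  records <- as_signal_table(records)
  validate_signal_values(records$norm_r, records$norm_theta)
  out <- data.table::copy(records)
  out[, call := data.table::fcase(
    norm_r < thresholds$r_min, "none",
    norm_theta <= thresholds$theta_low, "snp1",
    norm_theta >= thresholds$theta_high, "snp2",
    default = "both")]
  out[]
}

#' Fold Theta about 0.5
#'
#' Diagnostic transform `0.5 - |0.5 - Theta|`, mapping \[0, 1\] onto
#' \[0, 0.5\] so the two single-allele tails can be summarised together
#' (e.g. when assessing how many R-passing pools of single-gene assays fall
#' inside the "both" window).
#'
#' @param theta numeric vector in \[0, 1\].
#' @return Folded values in \[0, 0.5\].
#' @export
fold_theta <- function(theta) {
  if (anyNA(theta) || any(theta < 0 | theta > 1))
    stop("theta must lie in [0, 1]", call. = FALSE)
  0.5 - abs(0.5 - theta)
}

#' Clustering baseline for pool calls
#'
#' A declared stand-in for cluster-based genotype calling: records passing
#' the `r_min` intensity threshold are partitioned by 1-D k-means on Theta
#' into up to `n_components` clusters, which are mapped to calls by cluster
#' mean ordering (lowest -> `snp1`, middle -> `both`, highest -> `snp2`).
#' Records below `r_min` are `none`.  If fewer passing records than
#' components exist (or the clustering degenerates), the function falls
#' back to the threshold rule with a warning.  This baseline is intended as
#' a comparator only: when Theta values of both-allele pools intermingle
#' with the single-allele clusters it misassigns them, which is exactly the
#' failure mode the threshold rule addresses.
#'
#' @param records signal table.
#' @param thresholds a [scoring_thresholds()] (supplies `r_min` and the
#'   fallback rule).
#' @param n_components maximum number of Theta clusters (default 3).
#' @param seed integer seed for k-means initialisation.
#' @return A `data.table` like [score_table()]'s output.
#' @export
cluster_baseline <- function(records, thresholds = scoring_thresholds(),
                             n_components = 3L, seed = 1L) {
  records <- as_signal_table(records)
  validate_signal_values(records$norm_r, records$norm_theta)
  out <- data.table::copy(records)
  out[, call := "none"]
  pass <- which(records$norm_r >= thresholds$r_min)
  if (!length(pass)) return(out[])
  theta <- records$norm_theta[pass]
  k <- min(n_components, length(unique(theta)))
  if (length(pass) < n_components || k < 2L) {
    warning("too few R-passing records for clustering; falling back to the threshold rule",
            call. = FALSE)
    return(score_table(records, thresholds))
  }
  set.seed(as.integer(seed))
  centers <- stats::quantile(theta, probs = seq(0.05, 0.95, length.out = k),
                             names = FALSE)
  centers <- centers + seq_len(k) * 1e-9  # break exact ties deterministically
  km <- tryCatch(stats::kmeans(theta, centers = matrix(centers, ncol = 1)),
                 error = function(e) NULL)
  if (is.null(km)) {
    warning("clustering degenerated; falling back to the threshold rule",
            call. = FALSE)
    return(score_table(records, thresholds))
  }
  ord <- order(km$centers[, 1])
  labels <- if (k == 3L) c("snp1", "both", "snp2")
            else if (k == 2L) c("snp1", "snp2")
            else if (km$centers[ord[1], 1] <= 0.5) "snp1" else "snp2"
  map <- character(k); map[ord] <- labels
  out[pass, call := map[km$cluster]]
  out[]
}

#' Sweep the Theta scoring window
#'
#' Re-scores the signal table for each candidate `(theta_low, theta_high)`
#' window, deconvolves the resulting calls, and reports how many pools are
#' assigned to the both-allele class and how many putative clone
#' coordinates result.  Widening the window (nested windows) can only grow
#' the both-class count; for non-nested windows no monotonicity is
#' guaranteed.
#'
#' @param records signal table.
#' @param windows list of numeric pairs `c(theta_low, theta_high)`.
#' @param design a [build_design()] result.
#' @param assays list of [assay_definition()]s (locus placements are not
#'   needed; only allele structure).
#' @param dimensions screening dimensions to deconvolve over.
#' @param r_min intensity threshold held fixed across the sweep.
#' @return A `data.table` with columns `theta_low`, `theta_high`,
#'   `n_both_pools`, `n_putative_coordinates`.
#' @export
threshold_sweep <- function(records, windows, design, assays,
                            dimensions = design$dimensions, r_min = 0.2) {
  records <- as_signal_table(records)
  data.table::rbindlist(lapply(windows, function(w) {
    if (length(w) != 2L)
      stop("each window must be c(theta_low, theta_high)", call. = FALSE)
    th <- scoring_thresholds(r_min = r_min, theta_low = w[1], theta_high = w[2])
    calls <- score_table(records, th)
    cands <- deconvolve_all(design, calls, assays, mode = "custom",
                            dimensions = dimensions)
    data.table::data.table(
      theta_low = w[1], theta_high = w[2],
      n_both_pools = sum(calls$call == "both"),
      n_putative_coordinates = sum(vapply(cands, function(cs)
        length(cs$clone_ids), integer(1))))
  }))
}
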