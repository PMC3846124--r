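## Evaluation layer: confirmation statistics against known clone
## coordinates, per-pool audit categories, and the two-step plate filter
## used to prune putative coordinates before clone-level confirmation.

#' Confirmation statistics for a candidate set
#'
#' Compares putative clone coordinates with the clones known to carry the
#' locus.  `n_confirmed` is the size of the intersection; percentages are
#' reported to one decimal, as in standard screening summaries, and are
#' `NA` when the denominator is zero.
#'
#' @param candidate_set a [candidates()] result (or an integer vector of
#'   clone indices).
#' @param known integer vector of known carrier clone indices (e.g. a
#'   [place_locus()] `$clones`).
#' @return A one-row `data.table`: `assay_id`, `allele`, `n_known`,
#'   `n_confirmed`, `pct_of_known`, `n_putative`, `pct_of_putative`.
#' @export
confirm <- function(candidate_set, known) {
  if (inherits(candidate_set, "candidate_set")) {
    ids <- candidate_set$clone_ids
    assay_id <- candidate_set$assay_id; allele <- candidate_set$allele
  } else {
    ids <- as.integer(candidate_set); assay_id <- NA_character_
    allele <- NA_character_
  }
  known <- unique(as.integer(known))
  n_known <- length(known); n_putative <- length(ids)
  n_confirmed <- length(intersect(ids, known))
  pct <- function(num, den) if (den == 0L) NA_real_ else round(100 * num / den, 1)
  data.table::data.table(
    assay_id = assay_id, allele = allele,
    n_known = n_known, n_confirmed = n_confirmed,
    pct_of_known = pct(n_confirmed, n_known),
    n_putative = n_putative, pct_of_putative = pct(n_confirmed, n_putative))
}

#' Expected pool calls from known clone coordinates
#'
#' For each pool of the requested dimensions, counts the known carriers of
#' the assay's allele-1 and allele-2 loci and derives the call that a
#' perfect screen would report: `snp1` if only allele-1 carriers, `snp2` if
#' only allele-2, `both` if both, `none` if empty.
#'
#' @param design a [build_design()] result.
#' @param known named list: locus id -> integer vector of carrier clone
#'   indices (e.g. from [read_known_coordinates()] or placements).
#' @param assay an [assay_definition()]; all its loci must appear in
#'   `known`.
#' @param dimensions dimensions to tabulate (default: all enabled).
#' @return A `data.table`: `sample_id`, `assay_id`, `a`, `b`, `expected`.
#' @export
expected_calls <- function(design, known, assay, dimensions = design$dimensions) {
  dimensions <- match_dimensions(dimensions)
  loci <- c(assay$allele1_loci, assay$allele2_loci)
  missing <- setdiff(loci, names(known))
  if (length(missing))
    stop(sprintf("assay %s references unknown locus/loci: %s", assay$assay_id,
                 paste(missing, collapse = ", ")), call. = FALSE)
  carriers1 <- sort(unique(unlist(known[assay$allele1_loci])))
  carriers2 <- sort(unique(unlist(known[assay$allele2_loci])))
  out <- data.table::rbindlist(lapply(dimensions, function(d)
    data.table::data.table(dimension = d,
                           index = seq_len(design$pool_counts[[d]]) - 1L)))
  cnt1 <- count_carriers(design, carriers1)
  cnt2 <- count_carriers(design, carriers2)
  out[, c("a", "b") := 0L]
  out[cnt1, a := i.count, on = c("dimension", "index")]
  out[cnt2, b := i.count, on = c("dimension", "index")]
  out[, sample_id := pool_id(design, dimension, index)]
  out[, assay_id := assay$assay_id]
  out[, expected := data.table::fcase(
    a > 0L & b == 0L, "snp1",
    a == 0L & b > 0L, "snp2",
    a > 0L & b > 0L, "both",
    default = "none")]
  out[, .(sample_id, assay_id, a, b, expected)]
}

AUDIT_LEVELS <- c("consistent", "both_for_single", "conflicting",
                  "unexpected_positive", "below_threshold")

#' Audit observed pool calls against expectations
#'
#' Classifies every audited (pool, assay) pair into one of five categories:
#' \describe{
#'   \item{consistent}{observed call equals the expected call.}
#'   \item{below_threshold}{a carrier pool was not scored because its
#'     normalized R stayed below `r_min` (observed `none`).}
#'   \item{both_for_single}{scored `both` where a single allele was
#'     expected; this does not lose any known coordinate, it can only
#'     inflate the putative list.}
#'   \item{conflicting}{a call that removes a known coordinate from
#'     candidacy: a single-allele call where the other single allele or
#'     `both` was expected.}
#'   \item{unexpected_positive}{a positive call in a pool with no known
#'     carrier (a false-positive pool score).}
#' }
#' The categories partition the audited pairs.
#'
#' @param observed a scored table from [score_table()] (columns
#'   `sample_id`, `assay_id`, `call`, and `norm_r` unless `records` is
#'   given).
#' @param expected an [expected_calls()] table.
#' @param records optional signal table supplying `norm_r` when `observed`
#'   lacks it.
#' @param r_min intensity threshold used in the below-threshold check.
#' @return A list with `audit` (per-pair table with `category`) and
#'   `summary` (per-assay category counts, wide).
#' @export
audit_pools <- function(observed, expected, records = NULL, r_min = 0.2) {
  obs <- data.table::as.data.table(observed)
  if (!"norm_r" %in% names(obs)) {
    if (is.null(records))
      stop("`observed` lacks norm_r; supply `records`", call. = FALSE)
    obs <- merge(obs, data.table::as.data.table(records)[
      , .(sample_id, assay_id, norm_r)], by = c("sample_id", "assay_id"))
  }
  exp_dt <- data.table::as.data.table(expected)[, .(sample_id, assay_id, expected)]
  key_obs <- paste(obs$sample_id, obs$assay_id)
  key_exp <- paste(exp_dt$sample_id, exp_dt$assay_id)
  if (!setequal(key_obs, key_exp) || anyDuplicated(key_obs) || anyDuplicated(key_exp))
    stop("observed and expected tables must index the same (pool, assay) pairs exactly once",
         call. = FALSE)
  audit <- merge(obs[, .(sample_id, assay_id, norm_r, observed = call)],
                 exp_dt, by = c("sample_id", "assay_id"))
  audit[, category := data.table::fcase(
    expected != "none" & observed == "none" & norm_r < r_min, "below_threshold",
    observed == expected, "consistent",
    observed == "both" & expected %in% c("snp1", "snp2"), "both_for_single",
    expected == "none" & observed != "none", "unexpected_positive",
    default = "conflicting")]
  counts <- audit[, .N, by = .(assay_id, category)]
  summary <- data.table::dcast(counts, assay_id ~ factor(category, AUDIT_LEVELS),
                               value.var = "N", fill = 0L, drop = FALSE)
  for (lev in setdiff(AUDIT_LEVELS, names(summary))) summary[, (lev) := 0L]
  data.table::setcolorder(summary, c("assay_id", AUDIT_LEVELS))
  list(audit = audit[], summary = summary[])
}

#' Two-step plate filter of putative coordinates
#'
#' Screening validation first identifies the plates that truly contain a
#' locus (by PCR on single-plate DNA) and only tests putative clones on
#' those plates individually.  This filter retains candidates whose plate
#' is in `positive_plates`.
#'
#' @param candidate_set a [candidates()] result.
#' @param positive_plates integer vector of 0-based plate numbers.
#' @param geometry the library geometry (defaults to the set's coordinates'
#'   source design geometry via its clone ids; required here explicitly).
#' @return A filtered `candidate_set`.
#' @export
plate_filter <- function(candidate_set, positive_plates, geometry) {
  stopifnot(inherits(candidate_set, "candidate_set"))
  keep <- candidate_set$coordinates$plate %in% as.integer(positive_plates)
  new_candidate_set(list(geometry = geometry), candidate_set$assay_id,
                    candidate_set$allele, candidate_set$dimensions,
                    candidate_set$clone_ids[keep])
}
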