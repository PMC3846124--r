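## Deconvolution: from per-pool calls to putative clone coordinates.
## A coordinate is putative for an allele iff its containing pool is
## positive for that allele in EVERY screened dimension; a "both" call is
## positive for either allele.

SCREEN_MODES <- c("six_dim", "opa1_8dim", "opa2_7dim", "custom")

#' Dimension sets of the screening modes
#'
#' `six_dim` screens the six cube dimensions; `opa1_8dim` adds the SA and
#' SB superpools (eight dimensions, the OPA1 layout); `opa2_7dim` adds the
#' single-plate pools instead (seven dimensions, the OPA2 layout).
#'
#' @param mode one of `"six_dim"`, `"opa1_8dim"`, `"opa2_7dim"`,
#'   `"custom"`.
#' @param dimensions explicit dimension set, required for `"custom"`.
#' @return Character vector of dimension codes.
#' @export
screening_dimensions <- function(mode = SCREEN_MODES, dimensions = NULL) {
  mode <- match.arg(mode)
  switch(mode,
         six_dim = SIX_DIM,
         opa1_8dim = c(SIX_DIM, "SA", "SB"),
         opa2_7dim = c(SIX_DIM, "SG"),
         custom = {
           if (is.null(dimensions))
             stop("mode 'custom' needs an explicit `dimensions` set", call. = FALSE)
           match_dimensions(dimensions)
         })
}

## Positive pool indices per dimension for one (assay, allele), from a call
## table.  Pools without a record are treated as negative; a warning reports
## how many were missing.
positive_pools <- function(design, calls, assay_id, allele, dimensions) {
  stopifnot(allele %in% c("snp1", "snp2"))
  sub <- calls[calls$assay_id == assay_id, ]
  parsed <- parse_pool_id(sub$sample_id)
  sub <- cbind(sub, parsed)
  res <- list()
  n_missing <- 0L
  for (d in dimensions) {
    dsub <- sub[sub$dimension == d, ]
    n_pools <- design$pool_counts[[d]]
    covered <- unique(dsub$index)
    n_missing <- n_missing + (n_pools - length(covered))
    pos <- dsub$index[dsub$call %in% c(allele, "both")]
    res[[d]] <- sort(unique(pos))
  }
  if (n_missing > 0L)
    warning(sprintf(
      "assay %s: %d pool(s) of the requested dimensions have no record; treated as negative",
      assay_id, n_missing), call. = FALSE)
  res
}

#' Deconvolve calls into putative clone coordinates for one allele
#'
#' A clone coordinate is returned iff, for every requested dimension, the
#' pool containing it is positive for the allele (its call is the allele's
#' single-SNP class or `both`).  The search starts from the dimension with
#' the smallest positive-pool membership and filters by the remaining
#' dimensions; the result is identical to brute-force filtering over all
#' coordinates.  Optionally up to `max_missing_dims` failing dimensions may
#' be tolerated (off by default: the screening protocol requires a score in
#' every dimension).
#'
#' @param design a [build_design()] result.
#' @param calls a scored table from [score_table()].
#' @param assay_id assay to deconvolve.
#' @param allele `"snp1"` or `"snp2"`.
#' @param dimensions screening dimensions (must be enabled in the design).
#' @param max_missing_dims number of non-positive dimensions tolerated per
#'   coordinate (default 0).
#' @return An object of class `candidate_set`: list with `assay_id`,
#'   `allele`, `dimensions`, `clone_ids` (sorted 0-based clone indices) and
#'   `coordinates` (a `data.table` of `plate`, `well_row`, `well_col`).
#' @export
candidates <- function(design, calls, assay_id, allele,
                       dimensions = design$dimensions, max_missing_dims = 0L) {
  stopifnot(inherits(design, "pooling_design"))
  dimensions <- match_dimensions(dimensions)
  missing_dims <- setdiff(dimensions, design$dimensions)
  if (length(missing_dims))
    stop(sprintf("dimension(s) not in design: %s",
                 paste(missing_dims, collapse = ", ")), call. = FALSE)
  pos <- positive_pools(design, calls, assay_id, allele, dimensions)
  ids <- candidate_ids(design, pos, dimensions, max_missing_dims)
  new_candidate_set(design, assay_id, allele, dimensions, ids)
}

candidate_ids <- function(design, pos, dimensions, max_missing_dims = 0L) {
  max_missing_dims <- as.integer(max_missing_dims)
  if (max_missing_dims == 0L) {
    sizes <- vapply(dimensions, function(d)
      length(pos[[d]]) * design$pool_sizes[[d]], numeric(1))
    if (any(sizes == 0)) return(integer(0))
    start <- dimensions[which.min(sizes)]
    ids <- which(design$assignment[, start] %in% pos[[start]]) - 1L
    for (d in setdiff(dimensions, start)) {
      if (!length(ids)) break
      ids <- ids[design$assignment[ids + 1L, d] %in% pos[[d]]]
    }
    sort(ids)
  } else {
    hits <- rep(0L, design$geometry$n_clones)
    for (d in dimensions)
      hits <- hits + (design$assignment[, d] %in% pos[[d]])
    sort(which(hits >= length(dimensions) - max_missing_dims) - 1L)
  }
}

new_candidate_set <- function(design, assay_id, allele, dimensions, ids) {
  structure(list(assay_id = assay_id, allele = allele,
                 dimensions = dimensions, clone_ids = ids,
                 coordinates = clone_coord(design$geometry, ids)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set: assay %s, allele %s, %d putative clone(s) over %s\n",
              x$assay_id, x$allele, length(x$clone_ids),
              paste(x$dimensions, collapse = "+")))
  invisible(x)
}

#' Deconvolve every (assay, allele) of a scored screen
#'
#' Intergenomic assays yield two candidate sets (one per homoeolog);
#' intragenomic and non-discriminating assays yield one, for whichever
#' allele class carries loci.
#'
#' @param design a [build_design()] result.
#' @param calls a scored table from [score_table()].
#' @param assays list of [assay_definition()]s.
#' @param mode screening mode, see [screening_dimensions()].
#' @param dimensions explicit dimensions for `mode = "custom"`.
#' @param max_missing_dims see [candidates()].
#' @return Named list of `candidate_set`s (names `"<assay>:<allele>"`).
#' @export
deconvolve_all <- function(design, calls, assays, mode = "six_dim",
                           dimensions = NULL, max_missing_dims = 0L) {
  if (inherits(assays, "assay_definition")) assays <- list(assays)
  dims <- screening_dimensions(mode, dimensions)
  out <- list()
  for (assay in assays) {
    alleles <- if (assay$assay_type == "intergenomic") c("snp1", "snp2")
               else if (length(assay$allele1_loci)) "snp1" else "snp2"
    for (al in alleles)
      out[[paste(assay$assay_id, al, sep = ":")]] <-
        candidates(design, calls, assay$assay_id, al, dims, max_missing_dims)
  }
  out
}

#' Write candidate sets to TSV
#'
#' Columns `assay_id`, `allele`, `plate` (1-based at the file boundary) and
#' `well_label`.
#'
#' @param candidate_sets list of `candidate_set`s (or a single one).
#' @param path output path.
#' @param geometry the library geometry (for well labels).
#' @return Invisibly, the written `data.table`.
#' @export
write_candidates <- function(candidate_sets, path, geometry = library_geometry()) {
  if (inherits(candidate_sets, "candidate_set"))
    candidate_sets <- list(candidate_sets)
  tab <- data.table::rbindlist(lapply(candidate_sets, function(cs) {
    if (!nrow(cs$coordinates))
      return(data.table::data.table(assay_id = character(0),
                                    allele = character(0), plate = integer(0),
                                    well_label = character(0)))
    data.table::data.table(
      assay_id = cs$assay_id, allele = cs$allele,
      plate = cs$coordinates$plate + 1L,
      well_label = well_label(cs$coordinates$well_row, cs$coordinates$well_col,
                              geometry))
  }))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(tab)
}
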