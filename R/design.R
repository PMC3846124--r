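## Pooling dimensions.  Six cube axes (PP plate/layer, RP row, CP column,
## DP diagonal, SP side, FP face) plus three plate-group dimensions:
## SA (stride groups of n_plates/layers plates), SB (stride groups of eight
## plates) and SG (single-plate pools).

DIMENSIONS <- c("PP", "RP", "CP", "DP", "SP", "FP", "SA", "SB", "SG")
SIX_DIM <- c("PP", "RP", "CP", "DP", "SP", "FP")

#' Number of pools of each dimension for a geometry
#'
#' @param geometry a [library_geometry()].
#' @param dimensions character vector of dimension codes.
#' @return Named integer vector of pool counts.
#' @export
dim_pool_counts <- function(geometry, dimensions = DIMENSIONS) {
  dimensions <- match_dimensions(dimensions)
  counts <- vapply(dimensions, function(d) switch(
    d,
    PP = geometry$layers,
    RP = geometry$cube_rows,
    CP = geometry$cube_cols,
    DP = geometry$cube_rows,
    SP = geometry$cube_rows,
    FP = geometry$cube_cols,
    SA = geometry$layers,
    SB = geometry$n_plates %/% 8L,
    SG = geometry$n_plates
  ), integer(1))
  names(counts) <- dimensions
  counts
}

match_dimensions <- function(dimensions) {
  dimensions <- toupper(as.character(dimensions))
  bad <- setdiff(dimensions, DIMENSIONS)
  if (length(bad))
    stop(sprintf("unknown pooling dimension(s): %s (known: %s)",
                 paste(bad, collapse = ", "), paste(DIMENSIONS, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(dimensions))
    stop("duplicated pooling dimensions", call. = FALSE)
  dimensions
}

## Pool index of every clone for one dimension, from cube/plate coordinates.
## Each formula is a partition of the clone set by construction: for fixed
## values of the other coordinates the formula is a bijection onto the pool
## index range.
pool_index_formula <- function(dimension, plate, r, c, L, geometry) {
  switch(dimension,
         PP = L,
         RP = r,
         CP = c,
         DP = (r + c) %% geometry$cube_rows,
         SP = (r + L) %% geometry$cube_rows,
         FP = (c + L) %% geometry$cube_cols,
         SA = plate %% geometry$layers,
         SB = plate %% (geometry$n_plates %/% 8L),
         SG = plate)
}

validate_dimension_config <- function(geometry, dimensions) {
  if ("SA" %in% dimensions && geometry$n_plates %% geometry$layers != 0L)
    stop(sprintf("SA pools need n_plates (%d) divisible by layers (%d)",
                 geometry$n_plates, geometry$layers), call. = FALSE)
  if ("SB" %in% dimensions && geometry$n_plates %% 8L != 0L)
    stop(sprintf("SB pools need n_plates (%d) divisible by 8", geometry$n_plates),
         call. = FALSE)
  invisible(TRUE)
}

#' Build a multidimensional pooling design
#'
#' Computes, for every clone of the library and every enabled dimension, the
#' index of the (single) pool of that dimension containing the clone.  The
#' six cube dimensions use the clone's cube position `(r, c, L)`:
#' `PP = L`, `RP = r`, `CP = c`, `DP = (r + c) mod cube_rows`,
#' `SP = (r + L) mod cube_rows`, `FP = (c + L) mod cube_cols`.  The plate
#' group dimensions use the plate number: `SA = plate mod layers`,
#' `SB = plate mod (n_plates / 8)`, `SG = plate`.  Every dimension
#' partitions the clone set into equally sized pools, and the `(RP, CP, PP)`
#' triple identifies a clone uniquely.
#'
#' At the default geometry this yields the classic screening layout:
#' 36 plate pools of 2304 clones, 48 each of row/column/diagonal/side/face
#' pools of 1728 clones (276 six-dimensional pools in total, 339 with the
#' SA and SB superpools), 36 SA pools of 2304, 27 SB pools of 3072, and
#' 216 single-plate pools of 384 clones.
#'
#' @param geometry a [library_geometry()].
#' @param dimensions dimension codes to enable, a subset of
#'   `c("PP","RP","CP","DP","SP","FP","SA","SB","SG")`.
#' @return An object of class `pooling_design` with elements `geometry`,
#'   `dimensions`, `pool_counts`, `pool_sizes` and `assignment` (an
#'   `n_clones x length(dimensions)` integer matrix of 0-based pool
#'   indices, rows in clone-index order).
#' @export
build_design <- function(geometry = library_geometry(), dimensions = SIX_DIM) {
  stopifnot(inherits(geometry, "bac_geometry"))
  dimensions <- match_dimensions(dimensions)
  validate_dimension_config(geometry, dimensions)
  id <- seq_len(geometry$n_clones) - 1L
  coord <- clone_coord(geometry, id)
  cube <- to_cube(coord$plate, coord$well_row, coord$well_col, geometry)
  assignment <- vapply(dimensions, function(d)
    as.integer(pool_index_formula(d, coord$plate, cube$r, cube$c, cube$L, geometry)),
    integer(geometry$n_clones))
  dim(assignment) <- c(geometry$n_clones, length(dimensions))
  colnames(assignment) <- dimensions
  counts <- dim_pool_counts(geometry, dimensions)
  design <- list(
    geometry = geometry,
    dimensions = dimensions,
    pool_counts = counts,
    pool_sizes = geometry$n_clones %/% counts,
    assignment = assignment
  )
  class(design) <- "pooling_design"
  design
}

#' @export
print.pooling_design <- function(x, ...) {
  cat(sprintf("Pooling design: %d dimensions, %d pools over %s clones\n",
              length(x$dimensions), sum(x$pool_counts),
              format(x$geometry$n_clones, big.mark = ",")))
  for (d in x$dimensions)
    cat(sprintf("  %s: %3d pools x %d clones\n", d, x$pool_counts[[d]],
                x$pool_sizes[[d]]))
  invisible(x)
}

#' Pools containing a clone
#'
#' @param design a [build_design()] result.
#' @param plate,well_row,well_col 0-based clone coordinates (vectorized).
#' @return For a single clone, a named integer vector (dimension -> pool
#'   index); for several clones, a `data.table` with one column per enabled
#'   dimension.
#' @export
clone_pools <- function(design, plate, well_row, well_col) {
  stopifnot(inherits(design, "pooling_design"))
  id <- clone_index(design$geometry, plate, well_row, well_col)
  sub <- design$assignment[id + 1L, , drop = FALSE]
  if (nrow(sub) == 1L) {
    out <- as.integer(sub[1L, ])
    names(out) <- design$dimensions
    out
  } else {
    data.table::as.data.table(sub)
  }
}

#' Format and parse pool identifiers
#'
#' Pool identifiers combine the dimension code with a zero-padded index,
#' e.g. `"DP07"` or `"SG215"`; the pad width is the number of digits of the
#' largest pool index of that dimension (at least 2).
#'
#' @param design a [build_design()] result.
#' @param dimension dimension code(s).
#' @param index pool index (0-based).
#' @return `pool_id()` a character vector; `parse_pool_id()` a `data.table`
#'   with columns `dimension` and `index`.
#' @export
pool_id <- function(design, dimension, index) {
  dimension <- toupper(as.character(dimension))
  bad <- setdiff(dimension, DIMENSIONS)
  if (length(bad))
    stop(sprintf("unknown pooling dimension(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  counts <- design$pool_counts[dimension]
  width <- pmax(2L, nchar(counts - 1L))
  sprintf("%s%0*d", dimension, width, as.integer(index))
}

#' @rdname pool_id
#' @param id character vector of pool identifiers.
#' @export
parse_pool_id <- function(id) {
  m <- regmatches(id, regexec("^([A-Z]{2})([0-9]+)$", id))
  ok <- vapply(m, length, 0L) == 3L
  if (any(!ok))
    stop(sprintf("malformed pool id: '%s'", id[!ok][1]), call. = FALSE)
  data.table::data.table(
    dimension = vapply(m, `[`, "", 2L),
    index = as.integer(vapply(m, `[`, "", 3L))
  )
}

#' Clones making up one pool
#'
#' @param design a [build_design()] result.
#' @param dimension dimension code.
#' @param index 0-based pool index within the dimension.
#' @return A `data.table` of clone coordinates (`plate`, `well_row`,
#'   `well_col`), in clone-index order.
#' @export
pool_members <- function(design, dimension, index) {
  stopifnot(inherits(design, "pooling_design"))
  dimension <- match_dimensions(dimension)
  stopifnot(length(dimension) == 1L, length(index) == 1L)
  if (!dimension %in% design$dimensions)
    stop(sprintf("dimension %s not enabled in this design", dimension),
         call. = FALSE)
  index <- as.integer(index)
  if (is.na(index) || index < 0L || index >= design$pool_counts[[dimension]])
    stop(sprintf("pool index %d out of range for dimension %s (%d pools)",
                 index, dimension, design$pool_counts[[dimension]]),
         call. = FALSE)
  ids <- which(design$assignment[, dimension] == index) - 1L
  clone_coord(design$geometry, ids)
}

pool_member_ids <- function(design, dimension, index) {
  which(design$assignment[, dimension] == index) - 1L
}

#' Write a pool manifest
#'
#' Writes a TSV with one row per pool (`dimension`, `pool_index`, `pool_id`,
#' `n_clones`) and optionally a full membership table (`pool_id`, `plate`,
#' `well_label`; plates written 1-based, the bench convention).
#'
#' @param design a [build_design()] result.
#' @param path output path for the manifest TSV.
#' @param members_path optional output path for the membership TSV.
#' @return Invisibly, the manifest `data.table`.
#' @export
write_pool_manifest <- function(design, path, members_path = NULL) {
  manifest <- data.table::rbindlist(lapply(design$dimensions, function(d) {
    idx <- seq_len(design$pool_counts[[d]]) - 1L
    data.table::data.table(dimension = d, pool_index = idx,
                           pool_id = pool_id(design, d, idx),
                           n_clones = design$pool_sizes[[d]])
  }))
  data.table::fwrite(manifest, path, sep = "\t")
  if (!is.null(members_path)) {
    g <- design$geometry
    members <- data.table::rbindlist(lapply(design$dimensions, function(d) {
      coords <- clone_coord(g, seq_len(g$n_clones) - 1L)
      data.table::data.table(
        pool_id = pool_id(design, d, design$assignment[, d]),
        plate = coords$plate + 1L,
        well_label = well_label(coords$well_row, coords$well_col, g)
      )
    }))
    data.table::fwrite(members[order(pool_id)], members_path, sep = "\t")
  }
  invisible(manifest)
}
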