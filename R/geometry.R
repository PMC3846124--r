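#' Library geometry: plates, wells and the conceptual clone cube
#'
#' A BAC library stored in microtiter plates is conceptually arranged in a
#' cube of `layers` layers, each layer consisting of `plates_per_layer`
#' plates laid out in a `blocks[1] x blocks[2]` grid.  The cube then has
#' `plate_rows * blocks[1]` rows and `plate_cols * blocks[2]` columns, and
#' every clone has a unique cube position `(r, c, L)`.  The defaults describe
#' a 216-plate library of 384-well plates (16 rows A-P, 24 columns), arranged
#' in 36 layers of six plates each (3 x 2 block grid), i.e. a 48 x 48 x 36
#' cube holding 82,944 clones.
#'
#' All indices are 0-based and half-open internally; well labels such as
#' "A1" are converted only at the file boundary.
#'
#' @param n_plates number of microtiter plates.
#' @param plate_rows,plate_cols wells per plate along each axis.
#' @param layers number of cube layers.
#' @param plates_per_layer plates making up one layer.
#' @param blocks integer(2): layout of the plates within a layer as
#'   (row blocks, column blocks); `prod(blocks)` must equal
#'   `plates_per_layer`.
#' @return An object of class `bac_geometry`.
#' @examples
#' g <- library_geometry()
#' g$n_clones   # 82944
#' @export
library_geometry <- function(n_plates = 216L, plate_rows = 16L, plate_cols = 24L,
                             layers = 36L, plates_per_layer = 6L,
                             blocks = c(3L, 2L)) {
  n_plates <- as.integer(n_plates); plate_rows <- as.integer(plate_rows)
  plate_cols <- as.integer(plate_cols); layers <- as.integer(layers)
  plates_per_layer <- as.integer(plates_per_layer); blocks <- as.integer(blocks)
  if (length(blocks) != 2L || any(blocks < 1L))
    stop("`blocks` must be two positive integers (row blocks, column blocks)",
         call. = FALSE)
  if (any(c(n_plates, plate_rows, plate_cols, layers, plates_per_layer) < 1L))
    stop("all geometry counts must be positive", call. = FALSE)
  if (n_plates != layers * plates_per_layer)
    stop(sprintf("inconsistent geometry: n_plates (%d) != layers (%d) x plates_per_layer (%d)",
                 n_plates, layers, plates_per_layer), call. = FALSE)
  if (prod(blocks) != plates_per_layer)
    stop(sprintf("inconsistent geometry: blocks %dx%d do not hold %d plates per layer",
                 blocks[1], blocks[2], plates_per_layer), call. = FALSE)
  g <- list(
    n_plates = n_plates, plate_rows = plate_rows, plate_cols = plate_cols,
    layers = layers, plates_per_layer = plates_per_layer,
    blocks_r = blocks[1], blocks_c = blocks[2],
    cube_rows = plate_rows * blocks[1], cube_cols = plate_cols * blocks[2],
    wells_per_plate = plate_rows * plate_cols,
    n_clones = n_plates * plate_rows * plate_cols
  )
  class(g) <- "bac_geometry"
  g
}

#' @export
print.bac_geometry <- function(x, ...) {
  cat(sprintf("BAC library geometry: %d plates of %d x %d wells (%s clones)\n",
              x$n_plates, x$plate_rows, x$plate_cols,
              format(x$n_clones, big.mark = ",")))
  cat(sprintf("  cube: %d rows x %d cols x %d layers (%d plates/layer, %dx%d blocks)\n",
              x$cube_rows, x$cube_cols, x$layers, x$plates_per_layer,
              x$blocks_r, x$blocks_c))
  invisible(x)
}

stop_coord <- function(msg) stop(msg, call. = FALSE)

check_coord <- function(geometry, plate, well_row, well_col) {
  if (length(plate) != length(well_row) || length(plate) != length(well_col))
    stop_coord("plate, well_row and well_col must have equal length")
  bad <- plate < 0L | plate >= geometry$n_plates |
    well_row < 0L | well_row >= geometry$plate_rows |
    well_col < 0L | well_col >= geometry$plate_cols
  if (anyNA(bad) || any(bad))
    stop_coord(sprintf("coordinate out of range for geometry (first bad entry: plate=%s row=%s col=%s)",
                       plate[which(bad | is.na(bad))[1]],
                       well_row[which(bad | is.na(bad))[1]],
                       well_col[which(bad | is.na(bad))[1]]))
  invisible(TRUE)
}

#' Map plate/well coordinates to cube positions
#'
#' The layer is `plate %/% plates_per_layer`; the within-layer slot
#' `plate %% plates_per_layer` is placed row-major into the block grid, so
#' that r is `plate_rows * (slot %/% blocks_c) + well_row` and c is
#' `plate_cols * (slot %% blocks_c) + well_col`.  The mapping is a
#' bijection between clone coordinates and cube positions; [from_cube()]
#' inverts it.
#'
#' @param plate,well_row,well_col 0-based clone coordinates (vectorized).
#' @param geometry a [library_geometry()].
#' @return A `data.table` with columns `r`, `c`, `L`.
#' @export
to_cube <- function(plate, well_row, well_col, geometry) {
  plate <- as.integer(plate); well_row <- as.integer(well_row)
  well_col <- as.integer(well_col)
  check_coord(geometry, plate, well_row, well_col)
  q <- plate %% geometry$plates_per_layer
  data.table::data.table(
    r = geometry$plate_rows * (q %/% geometry$blocks_c) + well_row,
    c = geometry$plate_cols * (q %% geometry$blocks_c) + well_col,
    L = plate %/% geometry$plates_per_layer
  )
}

#' Map cube positions back to plate/well coordinates
#'
#' @param r,c,L 0-based cube row, column and layer (vectorized).
#' @inheritParams to_cube
#' @return A `data.table` with columns `plate`, `well_row`, `well_col`.
#' @export
from_cube <- function(r, c, L, geometry) {
  r <- as.integer(r); c <- as.integer(c); L <- as.integer(L)
  bad <- r < 0L | r >= geometry$cube_rows | c < 0L | c >= geometry$cube_cols |
    L < 0L | L >= geometry$layers
  if (anyNA(bad) || any(bad)) stop_coord("cube position out of range for geometry")
  q <- geometry$blocks_c * (r %/% geometry$plate_rows) + (c %/% geometry$plate_cols)
  data.table::data.table(
    plate = L * geometry$plates_per_layer + q,
    well_row = r %% geometry$plate_rows,
    well_col = c %% geometry$plate_cols
  )
}

## Dense clone index <-> coordinates.  Clones are numbered 0..n_clones-1,
## plate-major then row-major within the plate.
clone_index <- function(geometry, plate, well_row, well_col) {
  check_coord(geometry, plate, well_row, well_col)
  as.integer(plate) * geometry$wells_per_plate +
    as.integer(well_row) * geometry$plate_cols + as.integer(well_col)
}

clone_coord <- function(geometry, id) {
  id <- as.integer(id)
  if (anyNA(id) || any(id < 0L | id >= geometry$n_clones))
    stop_coord("clone index out of range for geometry")
  rem <- id %% geometry$wells_per_plate
  data.table::data.table(
    plate = id %/% geometry$wells_per_plate,
    well_row = rem %/% geometry$plate_cols,
    well_col = rem %% geometry$plate_cols
  )
}

#' Convert between well labels ("A1".."P24") and 0-based row/column indices
#'
#' Rows are letters (A = row 0); columns are 1-based numbers.  Labels are
#' used only at the I/O boundary.
#'
#' @param well_row,well_col 0-based indices.
#' @param geometry a [library_geometry()]; used for range validation.
#' @return `well_label()` returns character labels; `parse_well_label()`
#'   returns a `data.table` with `well_row`, `well_col`.
#' @export
well_label <- function(well_row, well_col, geometry = library_geometry()) {
  well_row <- as.integer(well_row); well_col <- as.integer(well_col)
  if (any(well_row < 0L | well_row >= geometry$plate_rows |
          well_col < 0L | well_col >= geometry$plate_cols))
    stop_coord("well indices out of range for geometry")
  paste0(LETTERS[well_row + 1L], well_col + 1L)
}

#' @rdname well_label
#' @param label character vector of labels such as "A1".
#' @export
parse_well_label <- function(label, geometry = library_geometry()) {
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)$", label))
  ok <- vapply(m, length, 0L) == 3L
  if (any(!ok))
    stop_coord(sprintf("malformed well label: '%s'", label[!ok][1]))
  row <- match(toupper(vapply(m, `[`, "", 2L)), LETTERS) - 1L
  col <- as.integer(vapply(m, `[`, "", 3L)) - 1L
  if (any(is.na(row)) || any(row >= geometry$plate_rows) ||
      any(col < 0L | col >= geometry$plate_cols))
    stop_coord(sprintf(
      "well label out of range for %d x %d plates: '%s'",
      geometry$plate_rows, geometry$plate_cols,
      label[which(is.na(row) | row >= geometry$plate_rows |
                    col < 0L | col >= geometry$plate_cols)[1]]))
  data.table::data.table(well_row = row, well_col = col)
}
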