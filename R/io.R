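## File formats.  Signal tables are CSV (matching genotyping-export
## habits); everything else is TSV.  Readers sniff the delimiter and
## accept extra columns.  Plates are 1-based and wells "A1"-style at the
## file boundary; everything is 0-based internally.

as_signal_table <- function(records) {
  records <- data.table::as.data.table(records)
  needed <- c("sample_id", "assay_id", "norm_r", "norm_theta")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop(sprintf("signal table lacks required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  records
}

#' Read a signal table
#'
#' Expects columns `sample_id`, `assay_id`, `norm_r`, `norm_theta`
#' (delimiter sniffed, extra columns ignored).  Rows with non-numeric
#' signal values abort with their line numbers unless `skip_bad = TRUE`,
#' in which case they are dropped with a warning.
#'
#' @param path input CSV/TSV path.
#' @param skip_bad drop malformed rows instead of failing.
#' @return A signal `data.table`.
#' @export
read_signal_table <- function(path, skip_bad = FALSE) {
  raw <- data.table::fread(path, showProgress = FALSE)
  needed <- c("sample_id", "assay_id", "norm_r", "norm_theta")
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  raw <- raw[, ..needed]
  raw[, sample_id := as.character(sample_id)]
  raw[, assay_id := as.character(assay_id)]
  r <- suppressWarnings(as.numeric(raw$norm_r))
  th <- suppressWarnings(as.numeric(raw$norm_theta))
  bad <- which(is.na(r) | is.na(th))
  if (length(bad)) {
    msg <- sprintf("%s: non-numeric signal value(s) at data row(s) %s", path,
                   paste(utils::head(bad, 5), collapse = ", "))
    if (!skip_bad) stop(msg, call. = FALSE)
    warning(paste(msg, "- dropped"), call. = FALSE)
  }
  raw[, norm_r := r]
  raw[, norm_theta := th]
  if (length(bad)) raw <- raw[-bad]
  raw[]
}

#' @rdname read_signal_table
#' @param records signal table to write.
#' @export
write_signal_table <- function(records, path) {
  records <- as_signal_table(records)
  data.table::fwrite(records[, .(sample_id, assay_id, norm_r, norm_theta)],
                     path, sep = ",")
  invisible(path)
}

#' Read known clone coordinates
#'
#' TSV with columns `locus_id`, `plate` (1-based, bench convention) and
#' either `well` ("A1"-style label) or numeric `well_row`/`well_col`
#' (0-based).  Duplicated rows are deduplicated with a warning;
#' out-of-range coordinates abort with row context.
#'
#' @param path input path.
#' @param geometry a [library_geometry()] used for validation.
#' @return Named list: locus id -> sorted integer vector of clone indices.
#' @export
read_known_coordinates <- function(path, geometry = library_geometry()) {
  tab <- data.table::fread(path, showProgress = FALSE)
  if (!all(c("locus_id", "plate") %in% names(tab)))
    stop(sprintf("%s: need columns locus_id and plate", path), call. = FALSE)
  if ("well" %in% names(tab)) {
    wells <- parse_well_label(as.character(tab$well), geometry)
  } else if (all(c("well_row", "well_col") %in% names(tab))) {
    wells <- tab[, .(well_row, well_col)]
  } else {
    stop(sprintf("%s: need a well label column or well_row/well_col", path),
         call. = FALSE)
  }
  plate0 <- as.integer(tab$plate) - 1L
  if (anyNA(plate0) || any(plate0 < 0L | plate0 >= geometry$n_plates))
    stop(sprintf("%s: plate out of range at data row %d", path,
                 which(is.na(plate0) | plate0 < 0L |
                         plate0 >= geometry$n_plates)[1]), call. = FALSE)
  ids <- clone_index(geometry, plate0, wells$well_row, wells$well_col)
  key <- paste(tab$locus_id, ids)
  if (anyDuplicated(key)) {
    warning(sprintf("%s: %d duplicated coordinate row(s) dropped", path,
                    sum(duplicated(key))), call. = FALSE)
    keep <- !duplicated(key)
    tab <- tab[keep]; ids <- ids[keep]
  }
  lapply(split(ids, tab$locus_id), function(x) sort(unique(x)))
}

#' @rdname read_known_coordinates
#' @param known named list locus id -> clone indices.
#' @export
write_known_coordinates <- function(known, path, geometry = library_geometry()) {
  tab <- data.table::rbindlist(lapply(names(known), function(l) {
    coords <- clone_coord(geometry, known[[l]])
    data.table::data.table(locus_id = l, plate = coords$plate + 1L,
                           well = well_label(coords$well_row, coords$well_col,
                                             geometry))
  }))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
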