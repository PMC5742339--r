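# Plain-TSV readers/writers shared by all pipeline stages.

write_tsv_matrix <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(colnames(mat)))
  invisible(path)
}

read_tsv_matrix <- function(path, header = TRUE) {
  as.matrix(utils::read.table(path, sep = "\t", header = header,
                              check.names = FALSE))
}

#' Write a tabular stage output as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a parcel time-series TSV as written by [write_dataset()]
#'
#' @param path TSV with one column per parcel, header row of parcel IDs.
#' @param tr_seconds Sampling interval to attach.
#' @return A [parcel_timeseries()] object (no provenance stages set).
#' @export
read_timeseries_tsv <- function(path, tr_seconds) {
  m <- read_tsv_matrix(path)
  parcel_timeseries(m, parcel_ids = colnames(m), tr_seconds = tr_seconds)
}

#' Read a 6-column motion-parameter TSV
#'
#' @param path TSV with columns tx, ty, tz (mm), rx, ry, rz (degrees).
#' @return Numeric matrix with those six columns.
#' @export
read_motion_tsv <- function(path) {
  m <- read_tsv_matrix(path)
  if (ncol(m) != 6) stop("motion table must have exactly 6 columns")
  m
}

#' Write one Fisher-Z connectivity matrix as TSV
#'
#' Parcel IDs form both the header and the first column.
#'
#' @param conn A `gfc_connectivity` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectivity_tsv <- function(conn, path) {
  stopifnot(inherits(conn, "gfc_connectivity"))
  z <- conn$z
  df <- data.frame(parcel = conn$parcel_ids, z, check.names = FALSE)
  colnames(df) <- c("parcel", conn$parcel_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Fisher-Z connectivity matrix written by [write_connectivity_tsv()]
#'
#' @param path TSV path.
#' @param subject,session Identifiers to attach.
#' @return A `gfc_connectivity` object.
#' @export
read_connectivity_tsv <- function(path, subject = NA_character_,
                                  session = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  z <- as.matrix(df[, -1, drop = FALSE])
  rownames(z) <- ids
  new_connectivity(z, parcel_ids = ids, subject = subject, session = session)
}
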