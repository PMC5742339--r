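#' Pearson correlation matrix of parcel signals
#'
#' Full pairwise Pearson correlation of the columns of a cleaned parcel
#' time series. Zero-variance parcels make the correlation undefined and
#' raise an error naming the offending parcels.
#'
#' @param ts A `parcel_timeseries` or timepoints x parcels matrix.
#' @return Symmetric parcels x parcels correlation matrix with unit
#'   diagonal.
#' @export
correlation_matrix <- function(ts) {
  m <- if (inherits(ts, "parcel_timeseries")) ts$data else as.matrix(ts)
  if (nrow(m) < 3) stop("need at least 3 timepoints for a correlation matrix")
  flat <- flag_degenerate_parcels(m)
  if (length(flat)) {
    stop(sprintf("zero-variance parcel(s): %s", paste(flat, collapse = ", ")))
  }
  r <- cor(m)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

new_connectivity <- function(z, parcel_ids, subject, session) {
  diag(z) <- NA_real_
  rownames(z) <- colnames(z) <- parcel_ids
  structure(list(z = z, parcel_ids = as.character(parcel_ids),
                 subject = subject, session = session),
            class = "gfc_connectivity")
}

#' Fisher-Z transform of a correlation matrix
#'
#' Applies `z = atanh(r)` to every off-diagonal entry. Correlations with
#' `|r| >= 1 - 1e-7` are clamped to `sign(r) * (1 - 1e-7)` (z about 8.1)
#' so the transform stays finite; the number of clamped entries is
#' reported via a warning attribute. The diagonal (self-connection) is
#' invalid after the transform and stored as `NA`.
#'
#' @param r_matrix Symmetric correlation matrix.
#' @param subject,session Identifiers carried on the result.
#' @return An object of class `gfc_connectivity` with fields `z`
#'   (symmetric matrix, `NA` diagonal), `parcel_ids`, `subject`,
#'   `session`, and attribute `n_clamped`.
#' @export
fisher_z <- function(r_matrix, subject = NA_character_, session = NA_character_) {
  r <- as.matrix(r_matrix)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| > 1 in correlation matrix")
  lim <- 1 - 1e-7
  off <- row(r) != col(r)
  n_clamped <- sum(abs(r[off]) >= lim, na.rm = TRUE)
  r <- pmin(pmax(r, -lim), lim)
  z <- atanh(r)
  ids <- colnames(r_matrix) %||% sprintf("p%03d", seq_len(ncol(r)))
  out <- new_connectivity(z, parcel_ids = ids, subject = subject, session = session)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' @export
print.gfc_connectivity <- function(x, ...) {
  cat(sprintf("<gfc_connectivity> %d parcels, subject %s, session %s\n",
              length(x$parcel_ids), x$subject, x$session))
  invisible(x)
}

#' Stack per-subject, per-session connectivity matrices
#'
#' Collects Fisher-Z matrices for all subjects and both sessions into
#' two parcels x parcels x subjects arrays, the layout every group-level
#' operation in the package works on. Parcel order must be identical
#' across all inputs.
#'
#' @param conn_list Nested list: `conn_list[[subject]][[session]]` is a
#'   `gfc_connectivity`, sessions named `rest1` and `rest2`.
#' @return An object of class `gfc_conn_stack`: list with `rest1`,
#'   `rest2` (3D arrays, diagonal `NA`), `parcel_ids`, `subjects`.
#' @export
conn_stack <- function(conn_list) {
  subjects <- names(conn_list)
  stopifnot(length(subjects) >= 1)
  ids <- conn_list[[1]]$rest1$parcel_ids
  P <- length(ids)
  arr <- function(session) {
    a <- array(NA_real_, c(P, P, length(subjects)),
               dimnames = list(ids, ids, subjects))
    for (k in seq_along(subjects)) {
      cm <- conn_list[[k]][[session]]
      if (!identical(cm$parcel_ids, ids)) {
        stop(sprintf("parcel order mismatch for subject %s, %s", subjects[k], session))
      }
      a[, , k] <- cm$z
    }
    a
  }
  structure(list(rest1 = arr("rest1"), rest2 = arr("rest2"),
                 parcel_ids = ids, subjects = subjects),
            class = "gfc_conn_stack")
}

#' Compute Fisher-Z connectivity for a whole dataset
#'
#' Convenience wrapper: trims lead volumes, optionally cleans, and maps
#' every subject-session time series to a Fisher-Z connectivity matrix.
#' Intended for simulation studies where the nuisance amplitude is zero
#' and the full cleaning chain is unnecessary; the pipeline runner
#' applies the full chain instead.
#'
#' @param dataset A `gfc_dataset` from [generate_dataset()].
#' @param trim Number of lead volumes to drop (defaults to the spec's
#'   `n_lead_volumes`).
#' @return A `gfc_conn_stack`.
#' @export
dataset_connectivity <- function(dataset, trim = NULL) {
  stopifnot(inherits(dataset, "gfc_dataset"))
  if (is.null(trim)) trim <- dataset$spec$n_lead_volumes
  ids <- dataset$parcel_ids
  conn <- lapply(names(dataset$subjects), function(subj) {
    lapply(stats::setNames(c("rest1", "rest2"), c("rest1", "rest2")), function(sess) {
      m <- trim_volumes(dataset$subjects[[subj]][[sess]]$ts, trim)
      fisher_z(correlation_matrix(m), subject = subj, session = sess)
    })
  })
  names(conn) <- names(dataset$subjects)
  conn_stack(conn)
}
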