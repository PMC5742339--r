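#' Screen parcels for session changes in the gFC measures
#'
#' Runs a one-sample t-test on the per-subject session deltas of each
#' parcel for each of the three gFC measures and controls the FDR with a
#' step-up procedure. By default each measure forms its own correction
#' family (family size = parcel count); a single pooled family across
#' all three measures is available as an option.
#'
#' @param deltas Data frame from [stack_delta_gfc()] / [delta_gfc()].
#' @param q FDR level.
#' @param method `"BY"` (default) or `"BH"`.
#' @param family `"per_measure"` (default) or `"pooled"`.
#' @return List with `results` (per parcel x measure: `mean`, `sd`, `n`,
#'   `t`, `df`, `p`, `q_adj`, `significant`) and `detected` (the
#'   significant subset).
#' @export
gfc_change_screen <- function(deltas, q = 0.05, method = c("BY", "BH"),
                              family = c("per_measure", "pooled")) {
  method <- match.arg(method)
  family <- match.arg(family)
  subjects <- unique(deltas$subject)
  parcels <- unique(deltas$parcel)
  if (length(subjects) < 3) stop("need at least 3 subjects")
  if (nrow(deltas) != length(subjects) * length(parcels)) {
    stop("deltas must contain one row per subject x parcel")
  }
  measures <- c(d_gfc = "gfc", d_gfc_pos = "gfc_pos", d_gfc_neg = "gfc_neg")
  res <- list()
  for (mcol in names(measures)) {
    D <- matrix(deltas[[mcol]][order(match(deltas$parcel, parcels),
                                     match(deltas$subject, subjects))],
                nrow = length(subjects), ncol = length(parcels))
    st <- col_one_sample_t(D)
    p <- st$p
    p[!is.finite(st$t)] <- NA_real_
    res[[mcol]] <- data.frame(
      parcel = parcels, measure = measures[[mcol]],
      mean = st$mean, sd = st$sd, n = st$n, t = st$t, df = st$df, p = p,
      row.names = NULL)
  }
  out <- do.call(rbind, res)
  if (family == "per_measure") {
    out$q_adj <- NA_real_
    out$significant <- FALSE
    for (ms in unique(out$measure)) {
      idx <- out$measure == ms
      f <- fdr_adjust(out$p[idx], q = q, method = method)
      out$q_adj[idx] <- f$adjusted
      out$significant[idx] <- f$reject
    }
  } else {
    f <- fdr_adjust(out$p, q = q, method = method)
    out$q_adj <- f$adjusted
    out$significant <- f$reject
  }
  rownames(out) <- NULL
  list(results = out, detected = out[out$significant, , drop = FALSE])
}

seed_index <- function(stack, seed) {
  if (is.character(seed)) {
    idx <- match(seed, stack$parcel_ids)
    if (is.na(idx)) stop(sprintf("seed parcel '%s' not found", seed))
    idx
  } else {
    seed <- as.integer(seed)
    if (seed < 1 || seed > length(stack$parcel_ids)) stop("seed index out of range")
    seed
  }
}

#' Fixed set of parcels with significant positive seed connectivity
#'
#' Selects the parcels whose Fisher-Z connectivity with the seed is both
#' significantly non-zero (two-tailed one-sample t across subjects,
#' uncorrected `p < alpha`) and positive in mean, in BOTH sessions. The
#' resulting set is fixed across subjects and sessions, removing the
#' variable-support problem of the positive-sum gFC measure.
#'
#' @param stack A `gfc_conn_stack`.
#' @param seed Seed parcel ID or index.
#' @param alpha Selection level (two-tailed, uncorrected).
#' @return Object of class `gfc_fixed_set`: `seed`, `members` (parcel
#'   IDs), `stats` (per parcel x session: `mean_z`, `t`, `p`), `alpha`.
#' @export
fixed_positive_set <- function(stack, seed, alpha = 0.05) {
  stopifnot(inherits(stack, "gfc_conn_stack"))
  si <- seed_index(stack, seed)
  others <- setdiff(seq_along(stack$parcel_ids), si)
  stats_rows <- list()
  ok <- matrix(NA, length(others), 2,
               dimnames = list(NULL, c("rest1", "rest2")))
  for (sess in c("rest1", "rest2")) {
    D <- t(stack[[sess]][si, others, , drop = TRUE])  # subjects x others
    if (is.null(dim(D))) D <- matrix(D, ncol = length(others))
    st <- col_one_sample_t(D)
    ok[, sess] <- st$p < alpha & st$mean > 0
    stats_rows[[sess]] <- data.frame(
      parcel = stack$parcel_ids[others], session = sess,
      mean_z = st$mean, t = st$t, p = st$p, row.names = NULL)
  }
  members <- stack$parcel_ids[others][ok[, "rest1"] & ok[, "rest2"]]
  structure(list(seed = stack$parcel_ids[si], members = members,
                 stats = do.call(rbind, stats_rows), alpha = alpha),
            class = "gfc_fixed_set")
}

#' @export
print.gfc_fixed_set <- function(x, ...) {
  cat(sprintf("<gfc_fixed_set> seed %s: %d members (alpha %g, both sessions)\n",
              x$seed, length(x$members), x$alpha))
  invisible(x)
}

#' Seed gFC+ restricted to a fixed member set
#'
#' Per subject and session, sums the seed's Fisher-Z values over the
#' fixed member connections (every member edge counts, whatever its
#' per-subject sign), then tests the session delta with a one-sample
#' t-test.
#'
#' @param stack A `gfc_conn_stack`.
#' @param seed Seed parcel ID or index.
#' @param members Character vector of member parcel IDs (e.g. from
#'   [fixed_positive_set()]).
#' @return List: `per_subject` (data.frame `subject`, `rest1`, `rest2`,
#'   `delta`), `test` (as [one_sample_t()] on the deltas), and the
#'   session means.
#' @export
restricted_delta_gfc <- function(stack, seed, members) {
  stopifnot(inherits(stack, "gfc_conn_stack"))
  if (!length(members)) stop("member set is empty")
  si <- seed_index(stack, seed)
  mi <- match(members, stack$parcel_ids)
  if (any(is.na(mi))) stop("unknown member parcel ID")
  if (si %in% mi) stop("seed cannot be a member of its own set")
  sums <- sapply(c("rest1", "rest2"), function(sess) {
    a <- stack[[sess]][si, mi, , drop = FALSE]
    colSums(matrix(a, nrow = length(mi)))
  })
  per_subject <- data.frame(subject = stack$subjects,
                            rest1 = sums[, "rest1"], rest2 = sums[, "rest2"],
                            delta = sums[, "rest2"] - sums[, "rest1"],
                            row.names = NULL)
  list(per_subject = per_subject,
       mean_rest1 = mean(per_subject$rest1),
       mean_rest2 = mean(per_subject$rest2),
       test = one_sample_t(per_subject$delta))
}
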