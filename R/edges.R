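#' Per-connection session change test
#'
#' For every edge in scope, computes the per-subject Fisher-Z session
#' delta `z_rest2 - z_rest1`, tests it against zero with a one-sample
#' t-test across subjects, and FDR-corrects over the in-scope family:
#' all `P(P-1)/2` edges for the whole-brain screen, or the `P-1` edges
#' incident to a seed parcel for the seed-restricted follow-up.
#'
#' @param stack A `gfc_conn_stack`.
#' @param scope `"whole_brain"` or `"seed_restricted"`.
#' @param seed Seed parcel ID or index; required for the seed scope.
#' @param q FDR level.
#' @param method `"BY"` (default) or `"BH"`.
#' @return Data frame, one row per edge: `i`, `j` (parcel IDs, `i < j`
#'   by index), `mean_dz`, `sd`, `n`, `t`, `df`, `p`, `q_adj`,
#'   `significant`, plus attributes `scope` and `seed`.
#' @export
edge_change_test <- function(stack, scope = c("whole_brain", "seed_restricted"),
                             seed = NULL, q = 0.05, method = c("BY", "BH")) {
  stopifnot(inherits(stack, "gfc_conn_stack"))
  scope <- match.arg(scope)
  method <- match.arg(method)
  P <- length(stack$parcel_ids)
  N <- length(stack$subjects)
  dz <- stack$rest2 - stack$rest1
  if (scope == "seed_restricted") {
    if (is.null(seed)) stop("seed is required for the seed-restricted scope")
    si <- seed_index(stack, seed)
    others <- setdiff(seq_len(P), si)
    D <- t(matrix(dz[si, others, ], nrow = length(others)))  # subjects x edges
    ii <- pmin(si, others)
    jj <- pmax(si, others)
  } else {
    ut <- which(upper.tri(matrix(0, P, P)))
    D <- t(apply(dz, 3, function(m) m[ut]))
    if (N == 1) D <- matrix(D, nrow = 1)
    ii <- row(matrix(0, P, P))[ut]
    jj <- col(matrix(0, P, P))[ut]
  }
  st <- col_one_sample_t(D)
  p <- st$p
  p[!is.finite(st$t)] <- NA_real_
  f <- fdr_adjust(p, q = q, method = method)
  out <- data.frame(i = stack$parcel_ids[ii], j = stack$parcel_ids[jj],
                    mean_dz = st$mean, sd = st$sd, n = st$n, t = st$t,
                    df = st$df, p = p, q_adj = f$adjusted,
                    significant = f$reject, row.names = NULL)
  attr(out, "scope") <- scope
  attr(out, "seed") <- if (scope == "seed_restricted") stack$parcel_ids[si] else NA_character_
  out
}

#' Count seed connections that strengthened between sessions
#'
#' Reproduces the scatter-plot construction in which every seed edge is
#' placed at its per-session group t statistic (one-sample t of the
#' across-subject Fisher-Z values against zero): an edge counts as
#' increased when its rest2 t exceeds its rest1 t.
#'
#' @param stack A `gfc_conn_stack`.
#' @param seed Seed parcel ID or index.
#' @return List: `n_increased`, `n_edges`, and `per_edge` (data.frame
#'   with `parcel`, `t_rest1`, `t_rest2`, `increased`).
#' @export
count_increased_edges <- function(stack, seed) {
  stopifnot(inherits(stack, "gfc_conn_stack"))
  si <- seed_index(stack, seed)
  others <- setdiff(seq_along(stack$parcel_ids), si)
  tstat <- sapply(c("rest1", "rest2"), function(sess) {
    D <- t(matrix(stack[[sess]][si, others, ], nrow = length(others)))
    col_one_sample_t(D)$t
  })
  inc <- tstat[, "rest2"] > tstat[, "rest1"]
  list(n_increased = sum(inc), n_edges = length(others),
       per_edge = data.frame(parcel = stack$parcel_ids[others],
                             t_rest1 = tstat[, "rest1"],
                             t_rest2 = tstat[, "rest2"],
                             increased = inc, row.names = NULL))
}
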