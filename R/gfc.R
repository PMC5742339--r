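#' Per-parcel global connectivity (gFC, gFC+, gFC-)
#'
#' For each parcel, sums its Fisher-Z correlations with every other
#' parcel: `gfc_pos` over strictly positive entries, `gfc_neg` over
#' strictly negative entries (zeros contribute to neither), and
#' `gfc = gfc_pos + gfc_neg`, so the decomposition holds exactly in
#' floating point.
#'
#' @param conn A `gfc_connectivity`, or a symmetric Fisher-Z matrix with
#'   an ignorable diagonal.
#' @return Data frame with columns `parcel`, `gfc`, `gfc_pos`, `gfc_neg`.
#' @export
gfc_values <- function(conn) {
  z <- if (inherits(conn, "gfc_connectivity")) conn$z else as.matrix(conn)
  ids <- colnames(z) %||% as.character(seq_len(ncol(z)))
  diag(z) <- 0
  if (any(!is.finite(z))) stop("non-finite off-diagonal Fisher-Z entries")
  pos <- rowSums(pmax(z, 0))
  neg <- rowSums(pmin(z, 0))
  data.frame(parcel = ids, gfc = pos + neg, gfc_pos = pos, gfc_neg = neg,
             row.names = NULL)
}

#' Long gFC table for a connectivity stack
#'
#' @param stack A `gfc_conn_stack`.
#' @return Data frame: `subject`, `session`, `parcel`, `gfc`, `gfc_pos`,
#'   `gfc_neg`.
#' @export
gfc_table <- function(stack) {
  stopifnot(inherits(stack, "gfc_conn_stack"))
  rows <- list()
  for (sess in c("rest1", "rest2")) {
    a <- stack[[sess]]
    for (k in seq_along(stack$subjects)) {
      g <- gfc_values(a[, , k])
      g$subject <- stack$subjects[k]
      g$session <- sess
      rows[[length(rows) + 1]] <- g
    }
  }
  out <- do.call(rbind, rows)
  out[, c("subject", "session", "parcel", "gfc", "gfc_pos", "gfc_neg")]
}

#' Session deltas of the gFC measures
#'
#' Subtracts rest1 values from rest2 values per subject and parcel for
#' all three measures. Subjects and parcels must match between sessions.
#'
#' @param gfc_rest1,gfc_rest2 Data frames as one session's slice of
#'   [gfc_table()] (columns `subject`, `parcel`, `gfc`, `gfc_pos`,
#'   `gfc_neg`).
#' @return Data frame: `subject`, `parcel`, `d_gfc`, `d_gfc_pos`,
#'   `d_gfc_neg` (rest2 - rest1).
#' @export
delta_gfc <- function(gfc_rest1, gfc_rest2) {
  k1 <- paste(gfc_rest1$subject, gfc_rest1$parcel)
  k2 <- paste(gfc_rest2$subject, gfc_rest2$parcel)
  if (!identical(sort(k1), sort(k2))) {
    stop("subject/parcel sets differ between sessions")
  }
  gfc_rest2 <- gfc_rest2[match(k1, k2), ]
  data.frame(subject = gfc_rest1$subject, parcel = gfc_rest1$parcel,
             d_gfc = gfc_rest2$gfc - gfc_rest1$gfc,
             d_gfc_pos = gfc_rest2$gfc_pos - gfc_rest1$gfc_pos,
             d_gfc_neg = gfc_rest2$gfc_neg - gfc_rest1$gfc_neg,
             row.names = NULL)
}

#' Deltas straight from a connectivity stack
#'
#' @param stack A `gfc_conn_stack`.
#' @return As [delta_gfc()].
#' @export
stack_delta_gfc <- function(stack) {
  g <- gfc_table(stack)
  delta_gfc(g[g$session == "rest1", ], g[g$session == "rest2", ])
}

#' One-sample t-test against zero
#'
#' `t = mean / (sd / sqrt(n))` with `df = n - 1` and a two-tailed p-value
#' from the central t distribution.
#'
#' @param values Numeric vector of per-subject values.
#' @return List: `mean`, `sd`, `n`, `t`, `df`, `p`.
#' @export
one_sample_t <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("one_sample_t needs at least 3 values")
  s <- sd(values)
  if (s == 0) stop("one_sample_t is degenerate: zero standard deviation")
  m <- mean(values)
  t <- m / (s / sqrt(n))
  list(mean = m, sd = s, n = n, t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Vectorized one-sample t over the columns of a subjects x units matrix.
col_one_sample_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(mean = m, sd = s, n = n, t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

#' Two-tailed critical value of the central t distribution
#'
#' @param df Degrees of freedom.
#' @param alpha Two-tailed significance level.
#' @return The positive critical value; reject when `|t|` exceeds it.
#' @export
critical_t <- function(df, alpha = 0.05) {
  stopifnot(df >= 1, alpha > 0, alpha < 1)
  qt(1 - alpha / 2, df)
}

#' FDR adjustment (Benjamini-Yekutieli / Benjamini-Hochberg)
#'
#' Step-up FDR control. The default Benjamini-Yekutieli procedure is
#' valid under arbitrary dependence: reject the `k` smallest p-values
#' where `k` is the largest index with `p_(i) <= i q / (m c(m))`,
#' `c(m) = sum_{j<=m} 1/j`. Benjamini-Hochberg (`c(m) = 1`) is available
#' as an option. Adjusted values come from [stats::p.adjust()]; the
#' rejection set `adjusted <= q` is identical to the step-up rule.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target FDR level.
#' @param method `"BY"` (default) or `"BH"`.
#' @return List: `adjusted`, `reject` (logical), `q`, `method`.
#' @export
fdr_adjust <- function(p_values, q = 0.05, method = c("BY", "BH")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(p_values, method = method)
  list(adjusted = adj, reject = !is.na(adj) & adj <= q, q = q, method = method)
}
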