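#' Trait-anger sum score
#'
#' Sum of the 10 trait-anger items, each rated on a 1-4 frequency scale,
#' giving a score in 10..40.
#'
#' @param items Numeric vector of 10 responses in 1..4.
#' @return Integer sum score.
#' @export
score_trait_anger <- function(items) {
  if (length(items) != 10) stop("trait-anger requires exactly 10 items")
  if (any(is.na(items)) || any(items < 1 | items > 4)) {
    stop("trait-anger items must lie in 1..4")
  }
  as.integer(sum(items))
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum var(item) / var(total))` over the item
#' columns of a subjects x items response matrix.
#'
#' @param item_matrix Numeric matrix, subjects x items.
#' @return Alpha coefficient.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  k <- ncol(m)
  if (k < 2 || nrow(m) < 3) stop("need >= 2 items and >= 3 subjects")
  v <- apply(m, 2, var)
  if (any(v <= 0)) stop("zero-variance item(s) make alpha undefined")
  k / (k - 1) * (1 - sum(v) / var(rowSums(m)))
}

#' Stress-symptom checklist score with hyperarousal items removed
#'
#' Sum of the 17 symptom items (1-5 frequency scale) after removing the
#' items that overlap with anger concomitants; by default items 5, 14,
#' 16 and 17 (1-based), leaving a 13-item score in 13..65.
#'
#' @param items Numeric vector of 17 responses in 1..5.
#' @param removed_items Integer indices (1-based) to drop before summing.
#' @return Integer sum over the retained items.
#' @export
score_pcl <- function(items, removed_items = c(5L, 14L, 16L, 17L)) {
  if (length(items) != 17) stop("the checklist has exactly 17 items")
  if (any(is.na(items)) || any(items < 1 | items > 5)) {
    stop("checklist items must lie in 1..5")
  }
  removed_items <- as.integer(removed_items)
  if (any(removed_items < 1L | removed_items > 17L)) stop("removed_items out of range")
  keep <- setdiff(seq_len(17L), removed_items)
  as.integer(sum(items[keep]))
}

#' Mean anger-cluster emotion rating
#'
#' Arithmetic mean over all available anger-cluster ratings (0-6
#' intensity scale) across rounds and periods; missing cells are
#' excluded from both numerator and denominator.
#'
#' @param ratings Numeric vector, matrix or data frame of ratings in
#'   0..6 (NA allowed).
#' @return Mean rating.
#' @export
score_anger_cluster <- function(ratings) {
  x <- as.numeric(as.matrix(ratings))
  x <- x[!is.na(x)]
  if (!length(x)) stop("no non-missing ratings")
  if (any(x < 0 | x > 6)) stop("ratings must lie in 0..6")
  mean(x)
}

#' Intracranial-volume-adjusted regional volume
#'
#' @param region_mm3 Regional gray-matter volume, cubic mm.
#' @param icv_mm3 Intracranial volume, cubic mm.
#' @return The dimensionless ratio `region / icv`.
#' @export
adjusted_volume <- function(region_mm3, icv_mm3) {
  if (any(!is.finite(region_mm3)) || any(!is.finite(icv_mm3)) ||
      any(region_mm3 <= 0) || any(icv_mm3 <= 0)) {
    stop("volumes must be positive and finite")
  }
  region_mm3 / icv_mm3
}

#' Spearman rank association with a two-tailed test
#'
#' Rank correlation with average ranks for ties; the two-tailed p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with
#' `n - 2` degrees of freedom, the standard choice for moderate samples.
#' Pairs with a missing value in either variable are dropped
#' (pairwise-complete), and the n actually used is always reported.
#'
#' @param x,y Paired numeric vectors.
#' @param pair_name Label for the reported pair.
#' @param family Correction-family label (used by
#'   [adjust_association_family()]).
#' @return One-row data.frame: `pair`, `family`, `n`, `rho`, `p`.
#' @export
spearman_assoc <- function(x, y, pair_name = "x~y", family = "default") {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), n - 2)
  }
  data.frame(pair = pair_name, family = family, n = n, rho = rho, p = p,
             row.names = NULL)
}

#' FDR-adjust an association table within declared families
#'
#' Applies [fdr_adjust()] separately inside each `family` label of a
#' table of [spearman_assoc()] rows, appending `q_adj` and `significant`.
#' Raw p-values are kept so results can be read both corrected and
#' uncorrected.
#'
#' @param assoc Data frame with columns `family` and `p`.
#' @param q FDR level.
#' @param method `"BY"` (default) or `"BH"`.
#' @return The table with `q_adj` and `significant` columns added.
#' @export
adjust_association_family <- function(assoc, q = 0.05, method = c("BY", "BH")) {
  method <- match.arg(method)
  assoc$q_adj <- NA_real_
  assoc$significant <- FALSE
  for (fam in unique(assoc$family)) {
    idx <- assoc$family == fam
    f <- fdr_adjust(assoc$p[idx], q = q, method = method)
    assoc$q_adj[idx] <- f$adjusted
    assoc$significant[idx] <- f$reject
  }
  assoc
}

#' Welch two-sample group comparison
#'
#' @param values Numeric vector.
#' @param group_labels Factor-like vector with exactly two levels, each
#'   with at least two observations.
#' @return List: `t`, `df`, `p` (two-tailed), `group_means`.
#' @export
group_compare <- function(values, group_labels) {
  keep <- complete.cases(values, group_labels)
  values <- values[keep]
  g <- factor(group_labels[keep])
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("each group needs at least 2 observations")
  if (all(tapply(values, g, sd) == 0)) {
    m <- tapply(values, g, mean)
    if (m[1] == m[2]) {
      return(list(t = 0, df = sum(table(g)) - 2, p = 1, group_means = m))
    }
  }
  ht <- t.test(values ~ g)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, group_means = tapply(values, g, mean))
}
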