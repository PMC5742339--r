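# Independent brute-force oracles and fixture builders. These stay
# deliberately naive (double loops, direct formulas) so they cannot share
# a bug with the vectorized implementation paths they check.

naive_pearson <- function(m) {
  P <- ncol(m)
  out <- matrix(1, P, P)
  for (i in seq_len(P)) for (j in seq_len(P)) {
    x <- m[, i]; y <- m[, j]
    out[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  out
}

naive_gfc <- function(z) {
  P <- ncol(z)
  out <- data.frame(gfc = numeric(P), gfc_pos = numeric(P), gfc_neg = numeric(P))
  for (i in seq_len(P)) {
    pos <- 0; neg <- 0
    for (j in seq_len(P)) {
      if (i == j) next
      v <- z[i, j]
      if (v > 0) pos <- pos + v else if (v < 0) neg <- neg + v
    }
    out$gfc_pos[i] <- pos; out$gfc_neg[i] <- neg; out$gfc[i] <- pos + neg
  }
  out
}

naive_one_sample_t <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(mean = m, sd = s, t = t, p = 2 * stats::pt(-abs(t), n - 1))
}

# Hand step-up BY/BH rejection set (returns logical in input order).
naive_fdr_reject <- function(p, q, method = "BY") {
  m <- length(p)
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  o <- order(p)
  ps <- p[o]
  thr <- seq_len(m) * q / (m * cm)
  k <- suppressWarnings(max(which(ps <= thr)))
  rej <- rep(FALSE, m)
  if (is.finite(k)) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Random symmetric Fisher-Z matrix with NA diagonal.
random_z_matrix <- function(P, sd = 0.3, ids = sprintf("p%03d", seq_len(P))) {
  z <- matrix(rnorm(P * P, sd = sd), P, P)
  z <- (z + t(z)) / 2
  diag(z) <- NA_real_
  rownames(z) <- colnames(z) <- ids
  z
}

# Build a gfc_conn_stack from two lists of symmetric z matrices.
stack_from_z <- function(z1_list, z2_list) {
  ids <- colnames(z1_list[[1]])
  subs <- sprintf("S%03d", seq_along(z1_list))
  conn <- lapply(seq_along(z1_list), function(k) {
    list(
      rest1 = gfconn:::new_connectivity(z1_list[[k]], ids, subs[k], "rest1"),
      rest2 = gfconn:::new_connectivity(z2_list[[k]], ids, subs[k], "rest2")
    )
  })
  names(conn) <- subs
  conn_stack(conn)
}

# Random stack: session-2 matrices equal session 1 plus symmetric noise
# and an optional shift on edge (i, j).
random_stack <- function(N, P, noise_sd = 0.1, shift = 0, edge = c(1, 2)) {
  z1 <- lapply(seq_len(N), function(k) random_z_matrix(P))
  z2 <- lapply(z1, function(z) {
    d <- matrix(rnorm(P * P, sd = noise_sd), P, P)
    d <- (d + t(d)) / 2
    out <- z + d
    out[edge[1], edge[2]] <- out[edge[1], edge[2]] + shift
    out[edge[2], edge[1]] <- out[edge[1], edge[2]]
    diag(out) <- NA_real_
    out
  })
  stack_from_z(z1, z2)
}
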