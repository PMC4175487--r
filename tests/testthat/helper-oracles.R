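# Independent oracles used to cross-check the package's graph statistics,
# ANOVA sums of squares, and BH step-up rule. All are deliberately naive
# (brute-force loops, closed-form identities) and share no code with the
# implementation they verify.

# O(n^3) triple loop over ordered (j, k) pairs, exactly as the weighted
# local clustering formula is written; global = mean over defined nodes.
oracle_clustering <- function(w) {
  n <- nrow(w)
  local <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    num <- 0
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (j != i && k != i && k != j) {
          num <- num + w[i, j] * w[j, k] * w[k, i]
        }
      }
    }
    den <- sum(w[i, -i])^2 - sum(w[i, -i]^2)
    if (den > 1e-12) local[i] <- num / den
  }
  mean(local, na.rm = TRUE)
}

# assortativity as the Pearson correlation of endpoint weighted degrees
# over the doubled (symmetrized) edge list — a known identity for the
# M-edge moment formula
oracle_assortativity <- function(w, tau = 0) {
  k <- rowSums(w)
  idx <- which(upper.tri(w) & w > tau, arr.ind = TRUE)
  je <- k[idx[, 1]]
  ke <- k[idx[, 2]]
  suppressWarnings(stats::cor(c(je, ke), c(ke, je)))
}

random_weight_matrix <- function(n) {
  m <- matrix(stats::runif(n * n), n)
  w <- (m + t(m)) / 2
  diag(w) <- 0
  w
}

# literal step-up rule: largest k with p_(k) <= fdr * k / m
oracle_bh_reject <- function(p, fdr, m) {
  o <- order(p)
  sorted <- p[o]
  kstar <- 0
  for (k in seq_along(sorted)) {
    if (sorted[k] <= fdr * k / m) kstar <- k
  }
  reject <- logical(length(p))
  if (kstar > 0) reject[o[seq_len(kstar)]] <- TRUE
  reject
}

# textbook balanced 2x2x2 factorial sums of squares from marginal means
oracle_threeway_F <- function(value, a, b, c) {
  stopifnot(length(unique(table(a, b, c))) == 1) # balanced only
  n_cell <- unname(table(a, b, c)[1])
  grand <- mean(value)
  m1 <- function(f) tapply(value, f, mean) - grand
  m_a <- m1(a); m_b <- m1(b); m_c <- m1(c)
  m2 <- function(f1, f2, e1, e2) {
    cm <- tapply(value, list(f1, f2), mean)
    sweep(sweep(cm - grand, 1, e1), 2, e2)
  }
  m_ab <- m2(a, b, m_a, m_b)
  m_ac <- m2(a, c, m_a, m_c)
  m_bc <- m2(b, c, m_b, m_c)
  cell <- tapply(value, list(a, b, c), mean)
  m_abc <- cell - grand
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    m_abc[i, j, k] <- m_abc[i, j, k] - m_a[i] - m_b[j] - m_c[k] -
      m_ab[i, j] - m_ac[i, k] - m_bc[j, k]
  }
  ss <- c(
    A = 4 * n_cell * sum(m_a^2),
    B = 4 * n_cell * sum(m_b^2),
    C = 4 * n_cell * sum(m_c^2),
    AB = 2 * n_cell * sum(m_ab^2),
    AC = 2 * n_cell * sum(m_ac^2),
    BC = 2 * n_cell * sum(m_bc^2),
    ABC = n_cell * sum(m_abc^2)
  )
  fitted_cell <- cell[cbind(
    match(a, dimnames(cell)[[1]]),
    match(b, dimnames(cell)[[2]]),
    match(c, dimnames(cell)[[3]])
  )]
  sse <- sum((value - fitted_cell)^2)
  df_err <- length(value) - 8
  ss / (sse / df_err)
}

# small fully-specified study used across tests
tiny_config <- function(...) {
  simulation_config(n_per_group = 4, ...)
}

# wide expression tibble straight from a samples x genes matrix
expr_tibble <- function(x, ids = sprintf("s%02d", seq_len(nrow(x)))) {
  out <- tibble::as_tibble(x, .name_repair = "minimal")
  names(out) <- colnames(x) %||% paste0("g", seq_len(ncol(x)))
  dplyr::mutate(out, sample_id = ids, .before = 1)
}

`%||%` <- rlang::`%||%`
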