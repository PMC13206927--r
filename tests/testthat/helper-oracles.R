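# Independent oracles: brute-force / closed-form references kept separate
# from the implementation paths they check.

# Upper-tail overlap probability by exhaustive enumeration: draw every
# subset of size n_b from universe 1:N with successes 1:n_a, count those
# sharing >= k elements with the success set.
oracle_hyper_upper <- function(k, n_a, n_b, N) {
  if (n_b == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n_b)
  overlaps <- colSums(subsets <= n_a)
  mean(overlaps >= k)
}

# Full overlap distribution by enumeration (for vectorized tail checks).
oracle_overlap_counts <- function(n_a, n_b, N) {
  if (n_b == 0) return(table(factor(0, levels = 0:min(n_a, n_b))))
  subsets <- utils::combn(N, n_b)
  table(factor(colSums(subsets <= n_a), levels = 0:min(n_a, n_b)))
}

# Literal Benjamini-Hochberg step-up: q_(i) = min over j >= i (sorted
# order) of p_(j) * m / j, clipped at 1, via explicit loops.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, ps[j] * m / j)
    qs[i] <- min(1, cand)
  }
  q <- numeric(m)
  q[o] <- qs
  q
}

# Shoelace area of the radar polygon: Cartesian vertices at angle
# 2*pi*(i-1)/k, radius S_i.
oracle_star_shoelace <- function(S) {
  k <- length(S)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  x <- S * cos(ang)
  y <- S * sin(ang)
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Step-by-step IBR chain with explicit loops: mean/SD standardization,
# direction sign flip, per-biomarker min shift, shoelace area.
oracle_ibr <- function(X, directions, sd_mode = "sample") {
  G <- nrow(X); B <- ncol(X)
  Y <- matrix(0, G, B, dimnames = dimnames(X))
  for (b in seq_len(B)) {
    m <- sum(X[, b]) / G
    s2 <- sum((X[, b] - m)^2) / if (sd_mode == "sample") (G - 1) else G
    s <- sqrt(s2)
    if (s > 0) for (g in seq_len(G)) Y[g, b] <- (X[g, b] - m) / s
  }
  Z <- Y
  for (b in seq_len(B)) if (directions[colnames(X)[b]] == "down") Z[, b] <- -Y[, b]
  S <- Z
  for (b in seq_len(B)) S[, b] <- Z[, b] + abs(min(Z[, b]))
  idx <- vapply(seq_len(G), function(g) oracle_star_shoelace(S[g, ]),
                numeric(1))
  names(idx) <- rownames(X)
  list(Y = Y, Z = Z, S = S, ibr_index = idx)
}

# Random panel builder for property tests.
random_panel <- function(n_groups, n_biomarkers, seed) {
  set.seed(seed)
  X <- matrix(stats::runif(n_groups * n_biomarkers, 0.2, 5),
              nrow = n_groups,
              dimnames = list(paste0("g", seq_len(n_groups)),
                              paste0("b", seq_len(n_biomarkers))))
  dirs <- stats::setNames(sample(c("up", "down"), n_biomarkers, TRUE),
                          colnames(X))
  list(panel = panel_from_means(X, dirs), X = X, directions = dirs)
}
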