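# Independent brute-force implementations used as oracles. Deliberately
# naive (double loops, no vectorization) and kept separate from the
# package's own code paths.

brute_bmu <- function(weights, v) {
  best <- 1L
  bd <- Inf
  for (m in seq_len(nrow(weights))) {
    d <- sqrt(sum((weights[m, ] - v)^2))
    if (d < bd) {
      bd <- d
      best <- m
    }
  }
  best
}

brute_pairwise_mean <- function(pts) {
  n <- nrow(pts)
  tot <- 0
  cnt <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      tot <- tot + sqrt(sum((pts[i, ] - pts[j, ])^2))
      cnt <- cnt + 1L
    }
  }
  tot / cnt
}

brute_sem_ellipse <- function(xs, ys) {
  n <- length(xs)
  semx <- sqrt(sum((xs - mean(xs))^2) / (n - 1)) / sqrt(n)
  semy <- sqrt(sum((ys - mean(ys))^2) / (n - 1)) / sqrt(n)
  c(h = semx, v = semy, area = pi * semx * semy)
}

# kNN vote for one test point, same tie rule as the package (vote tie ->
# nearest neighbour's label).
brute_knn_vote <- function(train, labels, v, k) {
  d <- apply(train, 1L, function(r) sqrt(sum((r - v)^2)))
  ord <- order(d)
  nb <- as.character(labels[ord[seq_len(k)]])
  tab <- table(nb)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) winners else as.character(labels[ord[1L]])
}

# Exact two-sided Mann-Whitney p by direct enumeration over combinations,
# written independently of the package internals.
brute_mw_exact_p <- function(a, b) {
  na <- length(a)
  pooled <- rank(c(a, b))
  u_obs <- sum(pooled[seq_len(na)]) - na * (na + 1) / 2
  sel <- utils::combn(length(pooled), na)
  us <- apply(sel, 2L, function(idx) sum(pooled[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}
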