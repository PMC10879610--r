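# Independent brute-force reference implementations used to cross-check the
# package. Deliberately written as plain loops over first-principles
# definitions, sharing no code path with the package internals.

# mid-ranks by pairwise comparison
midrank_oracle <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- 1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2
  }
  r
}

spearman_oracle <- function(x, y) {
  rx <- midrank_oracle(x)
  ry <- midrank_oracle(y)
  n <- length(x)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  rho <- num / den
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (k in seq_len(n)) q[k] <- p[ord[k]] * n / k
  # step-up: enforce monotonicity from the largest rank down
  for (k in rev(seq_len(max(0, n - 1)))) {
    if (q[k] > q[k + 1]) q[k] <- q[k + 1]
  }
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

pdist_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  bases <- c("A", "C", "G", "T")
  used <- 0; diff <- 0
  for (i in seq_along(av)) {
    if (av[i] %in% bases && bv[i] %in% bases) {
      used <- used + 1
      if (av[i] != bv[i]) diff <- diff + 1
    }
  }
  if (used == 0) return(NA_real_)
  diff / used
}

shannon_oracle <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  h <- 0
  for (pi in p) h <- h - pi * log(pi)
  h
}

simpson_oracle <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  1 - sum(p * p)
}

chao1_oracle <- function(counts) {
  s <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

# Shortest-path betweenness on an unweighted undirected graph by explicit
# path counting (BFS distances + DP path counts), normalised by
# (n-1)(n-2)/2. Nodes are 1..n; edges a 2-column matrix of node indices.
betweenness_oracle <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  bfs <- function(s) {
    dist <- rep(Inf, n); cnt <- rep(0, n)
    dist[s] <- 0; cnt[s] <- 1
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) cnt[w] <- cnt[w] + cnt[v]
      }
    }
    list(dist = dist, cnt = cnt)
  }
  res <- lapply(seq_len(n), bfs)
  btw <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      if (is.infinite(res[[s]]$dist[t])) next
      total <- res[[s]]$cnt[t]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (res[[s]]$dist[v] + res[[t]]$dist[v] == res[[s]]$dist[t]) {
          btw[v] <- btw[v] + res[[s]]$cnt[v] * res[[t]]$cnt[v] / total
        }
      }
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else rep(0, n)
}
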