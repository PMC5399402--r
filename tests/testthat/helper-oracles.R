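# Independent reference implementations used as test oracles. These stay
# deliberately naive (loops, enumeration, textbook algorithms) and share no
# code with the package internals they check.

# Textbook NIPALS PLS2 with score deflation; returns per-component X-weights
# and scores.
oracle_pls2 <- function(X, Y, A, tol = 1e-12, max_iter = 1000) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  W <- matrix(0, ncol(X), A)
  Tm <- matrix(0, nrow(X), A)
  for (a in seq_len(A)) {
    u <- Y[, which.max(apply(Y, 2, function(y) sum(y^2)))]
    t_old <- rep(0, nrow(X))
    repeat {
      w <- drop(t(X) %*% u); w <- w / sqrt(sum(w^2))
      t <- drop(X %*% w)
      q <- drop(t(Y) %*% t); q <- q / sqrt(sum(q^2))
      u <- drop(Y %*% q)
      if (sqrt(sum((t - t_old)^2)) < tol) break
      t_old <- t
    }
    p <- drop(t(X) %*% t) / sum(t^2)
    c_reg <- drop(t(Y) %*% t) / sum(t^2)
    X <- X - outer(t, p)
    Y <- Y - outer(t, c_reg)
    W[, a] <- w; Tm[, a] <- t
  }
  list(weights = W, scores = Tm)
}

# Brute-force node metrics from a 0/1 adjacency matrix.
oracle_metrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  nc <- numeric(n); cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    nc[i] <- if (length(nb) == 0) 0 else mean(deg[nb])
    if (length(nb) < 2) {
      cc[i] <- 0
    } else {
      e <- 0
      for (a in seq_along(nb))
        for (b in seq_along(nb))
          if (a < b && adj[nb[a], nb[b]] == 1) e <- e + 1
      cc[i] <- e / choose(length(nb), 2)
    }
  }
  list(degree = deg, nc = nc, cc = cc)
}

# Exact hypergeometric tails by direct pmf summation (log factorials).
oracle_hyper_tails <- function(k, K, N, n) {
  lpmf <- function(i)
    lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  support <- max(0, n - (N - K)):min(n, K)
  p_over <- sum(exp(lpmf(support[support >= k])))
  p_under <- sum(exp(lpmf(support[support <= k])))
  list(p_over = p_over, p_under = p_under)
}

# Minimal within-cluster SSE over every 2-partition of the rows of X.
oracle_best_2partition <- function(X) {
  n <- nrow(X)
  best <- Inf; best_assign <- NULL
  for (code in 1:(2^(n - 1) - 1)) {   # fix point 1 in group 1; skip empty
    assign <- c(1, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    sse <- 0
    for (g in 1:2) {
      rows <- X[assign == g, , drop = FALSE]
      ctr <- colMeans(rows)
      sse <- sse + sum(sweep(rows, 2, ctr)^2)
    }
    if (sse < best) { best <- sse; best_assign <- assign }
  }
  list(sse = best, assignment = best_assign)
}

# Agreement of a clustering with truth labels via majority mapping: the
# fraction of the focal genes whose cluster's majority truth label matches
# their own. Over-partitioning (splitting one signal across clusters) is not
# penalized; mixing different signals in one cluster is.
cluster_majority_agreement <- function(assignment, truth, focal) {
  maj <- tapply(truth[names(assignment)], assignment, function(lbl)
    names(sort(table(lbl), decreasing = TRUE))[1])
  mean(maj[as.character(assignment[focal])] == truth[focal])
}
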