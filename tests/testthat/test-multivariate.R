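test_that("PCA handles rank-1 input, reconstructs fully, matches eigen", {
  u <- c(1, 2, 3, 4); v <- c(2, -1, 0.5)
  X <- outer(u, v)
  m <- fit_pca(X, 1)
  expect_equal(m$explained_variance[1], 1, tolerance = 1e-12)
  # completeness: all components reconstruct the input
  set.seed(2)
  X2 <- matrix(rnorm(8 * 5), 8, 5)
  m2 <- fit_pca(X2, min(nrow(X2) - 1, ncol(X2)))
  rec <- m2$scores %*% t(m2$loadings) + rep(1, 8) %o% m2$center
  expect_equal(unname(rec), X2, tolerance = 1e-8)
  # loadings orthonormal
  expect_equal(crossprod(m2$loadings), diag(ncol(m2$loadings)),
               ignore_attr = TRUE, tolerance = 1e-10)
  # eigen-decomposition oracle on a 3x3 worked matrix
  X3 <- matrix(c(1, 2, 4, 2, 6, 3, 5, 1, 2), 3, 3)
  m3 <- fit_pca(X3, 2)
  ev <- eigen(crossprod(sweep(X3, 2, colMeans(X3))))$values
  expect_equal(m3$explained_variance[1], ev[1] / sum(ev), tolerance = 1e-10)
  expect_error(fit_pca(X3, 3), "A must lie in")
})

test_that("single-block MB-PLS equals textbook NIPALS PLS2 up to sign", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 12; p <- 7; r <- 2; A <- 3
    X <- scale(matrix(rnorm(n * p), n, p))
    colnames(X) <- paste0("v", 1:p)
    Y <- scale(matrix(rnorm(n * r), n, r))
    colnames(Y) <- c("y1", "y2")
    m <- fit_mbpls(list(one = X), Y, A = A)
    o <- oracle_pls2(X / sqrt(p), Y, A)   # same block scaling convention
    for (a in 1:A) {
      w1 <- m$block_weights$one[, a]; w2 <- o$weights[, a]
      s <- sign(sum(w1 * w2))
      expect_equal(w1, s * w2, tolerance = 1e-6, ignore_attr = TRUE)
      t1 <- m$super_scores[, a]; t2 <- o$scores[, a]
      s <- sign(sum(t1 * t2))
      expect_equal(t1, s * t2, tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("MB-PLS structural invariants hold on random fits", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 15
    X1 <- scale(matrix(rnorm(n * 6), n, 6))
    colnames(X1) <- paste0("a", 1:6)
    X2 <- scale(matrix(rnorm(n * 11), n, 11))
    colnames(X2) <- paste0("b", 1:11)
    Y <- scale(cbind(y = rnorm(n)))
    m <- fit_mbpls(list(A = X1, B = X2), Y, A = 3)
    # unit-norm block weights and super weights per component
    for (b in 1:2)
      expect_equal(colSums(m$block_weights[[b]]^2), rep(1, 3),
                   tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(colSums(m$super_weights^2), rep(1, 3),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # super scores mutually orthogonal
    g <- crossprod(m$super_scores)
    expect_lt(max(abs(g[upper.tri(g)])), 1e-8 * max(diag(g)))
    # SSY non-negative
    expect_true(all(m$ssy >= 0))
    # raw VIP conservation per block
    v <- compute_vip(m, "y")
    expect_equal(as.numeric(tapply(v$raw_vip^2, v$block, sum)[c("A", "B")]),
                 c(6, 11), tolerance = 1e-6 * 11)
    expect_equal(mean(v$vip), 1, tolerance = 1e-9)
  }
})

test_that("two identical blocks get equal super weights", {
  set.seed(5)
  X <- scale(matrix(rnorm(10 * 4), 10, 4))
  colnames(X) <- paste0("v", 1:4)
  Y <- scale(cbind(y = rnorm(10)))
  m <- fit_mbpls(list(L = X, R = X), Y, A = 2)
  expect_equal(m$super_weights["L", ], m$super_weights["R", ],
               tolerance = 1e-8)
})

test_that("fit_mbpls rejects misaligned samples and excessive A", {
  set.seed(6)
  X <- scale(matrix(rnorm(8 * 3), 8, 3))
  colnames(X) <- paste0("v", 1:3)
  Y <- scale(cbind(y = rnorm(8)))
  expect_error(fit_mbpls(list(a = X[1:7, ]), Y, A = 1), "samples")
  expect_error(fit_mbpls(list(a = X), Y, A = 5), "rank")
})

test_that("VIP of a single-variable block is forced to 1 (raw scale)", {
  set.seed(7)
  n <- 10
  X1 <- scale(cbind(solo = rnorm(n)))
  X2 <- scale(matrix(rnorm(n * 5), n, 5))
  colnames(X2) <- paste0("v", 1:5)
  Y <- scale(cbind(y = rnorm(n)))
  m <- fit_mbpls(list(narrow = X1, wide = X2), Y, A = 2)
  v <- compute_vip(m, "y")
  expect_equal(v$raw_vip[v$block == "narrow"], 1, tolerance = 1e-8)
  # block rescaling gives equal block sums: P_total/B = 3 each
  expect_equal(as.numeric(tapply(v$vip, v$block, sum)), c(3, 3),
               tolerance = 1e-8)
})

test_that("block-mean rescaled VIP ratio is the inverse block-size ratio", {
  set.seed(8)
  n <- 20; p1 <- 6; p2 <- 45
  X1 <- scale(matrix(rnorm(n * p1), n, p1)); colnames(X1) <- paste0("m", 1:p1)
  X2 <- scale(matrix(rnorm(n * p2), n, p2)); colnames(X2) <- paste0("t", 1:p2)
  Y <- scale(cbind(y = rnorm(n)))
  v <- compute_vip(fit_mbpls(list(met = X1, trans = X2), Y, A = 3), "y")
  bm <- tapply(v$vip, v$block, mean)
  expect_equal(unname(bm["met"] / bm["trans"]), p2 / p1, tolerance = 1e-8)
})

test_that("VIP selection applies the normal upper-tail rule per block", {
  v <- structure(
    data.frame(variable = c("a", "b", "c"), block = "one",
               raw_vip = c(0.5, 1.0, 1.5), vip = c(0.5, 1.0, 1.5),
               selected = NA, sign = NA_character_,
               stringsAsFactors = FALSE),
    class = c("vip_table", "data.frame"))
  out <- select_vips(v, p = 0.33)
  # threshold = 1.0 + 0.4399 * 0.5 = 1.2200; only 1.5 exceeds it
  expect_equal(out$selected, c(FALSE, FALSE, TRUE))
  expect_equal(qnorm(1 - 0.33), 0.4399, tolerance = 5e-5)
  # equal VIPs: sd = 0, strict inequality selects nothing
  v$vip <- rep(1, 3)
  expect_equal(select_vips(v, 0.33)$selected, rep(FALSE, 3))
  v1 <- v[1, ]
  class(v1) <- class(v)
  expect_warning(out1 <- select_vips(v1, 0.33), "single variable")
  expect_false(out1$selected)
})

test_that("sign splitting partitions the selected set by correlation", {
  set.seed(9)
  n <- 18
  resp <- rnorm(n)
  X <- cbind(pos = resp, neg = -resp, noise = rnorm(n))
  X <- scale(X)
  rownames(X) <- paste0("s", 1:n)
  v <- structure(
    data.frame(variable = colnames(X), block = "one",
               raw_vip = 1, vip = 1,
               selected = c(TRUE, TRUE, TRUE), sign = NA_character_,
               stringsAsFactors = FALSE),
    class = c("vip_table", "data.frame"))
  out <- split_by_sign(v, list(one = X), resp)
  expect_equal(out$sign, c("+", "-", ifelse(out$cor[3] < 0, "-", "+")))
  expect_equal(sum(out$sign %in% c("+", "-")), sum(out$selected))
  expect_error(split_by_sign(v, list(one = X), rep(1, n)), "constant")
})

test_that("VIP against an unexplained response errors", {
  set.seed(10)
  n <- 10
  X <- scale(matrix(rnorm(n * 4), n, 4)); colnames(X) <- paste0("v", 1:4)
  Y <- cbind(y1 = as.numeric(scale(rnorm(n))), dead = rep(0, n))
  m <- fit_mbpls(list(one = X), Y, A = 2, orient = "y1")
  expect_error(compute_vip(m, "dead"), "explains no variance")
})
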