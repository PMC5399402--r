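#' Low-rank PCA smoothing of an expression matrix
#'
#' Reconstructs the matrix from its first `n_pcs` principal components
#' (column-centered SVD truncation). Used to denoise gene profiles before
#' k-means summarization: the modeled values from the leading components
#' retain the coordinated temporal structure while shedding
#' feature-specific noise.
#'
#' @param X numeric matrix with the objects to smooth in rows (genes) and
#'   observations in columns (samples).
#' @param n_pcs number of components retained; must not exceed the
#'   numerical rank of the centered matrix.
#' @return matrix of the same shape as `X`.
#' @export
pca_smooth <- function(X, n_pcs = 10) {
  stopifnot(is.matrix(X), n_pcs >= 1)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  rk <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1])
  if (n_pcs > rk)
    stop("n_pcs = ", n_pcs, " exceeds the rank (", rk,
         ") of the centered matrix")
  k <- seq_len(n_pcs)
  out <- sv$u[, k, drop = FALSE] %*%
    (sv$d[k] * t(sv$v[, k, drop = FALSE])) # D V'
  out <- sweep(out, 2L, ctr, `+`)
  dimnames(out) <- dimnames(X)
  out
}

#' Summarize gene profiles by k-means clustering
#'
#' Lloyd's algorithm with Euclidean distance on gene profiles (genes are
#' points, samples are dimensions). A single initialization draws `k_init`
#' centroids uniformly from the gene points without replacement; clusters
#' left empty after convergence are deleted, so the returned cluster count
#' can be smaller than `k_init`. Within-cluster SSE is asserted to be
#' non-increasing across iterations. Deterministic given `seed`.
#'
#' @param X genes x samples matrix (typically [pca_smooth()]ed, autoscaled
#'   expression) with gene ids as rownames.
#' @param k_init number of initial centroids (capped at the number of
#'   genes).
#' @param seed integer seed for the centroid draw.
#' @param max_iter iteration cap (convergence = unchanged assignments).
#' @return an object of class `cluster_model`: list with `assignment`
#'   (named integer vector gene -> cluster, clusters renumbered 1..k),
#'   `centroids` (clusters x samples, in the smoothed space), `sizes`,
#'   `k_init`, `seed`, `iterations`, `sse`.
#' @export
kmeans_summarize <- function(X, k_init = 100, seed, max_iter = 300) {
  stopifnot(is.matrix(X), k_init >= 1)
  if (missing(seed)) stop("a seed is required")
  n <- nrow(X)
  if (n < 1) stop("no gene profiles to cluster")
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(n))
  m <- min(k_init, n)
  centers <- X[withr::with_seed(seed, sample.int(n, m)), , drop = FALSE]
  xx <- rowSums(X^2)
  assign_pts <- function(centers) {
    # squared distances via ||x||^2 - 2 x.c + ||c||^2; ties -> lowest index
    cross <- tcrossprod(X, centers)
    d2 <- outer(xx, rowSums(centers^2), `+`) - 2 * cross
    max.col(-d2, ties.method = "first")
  }
  cl <- assign_pts(centers)
  sse_of <- function(cl, centers) sum((X - centers[cl, , drop = FALSE])^2)
  sse <- sse_of(cl, centers)
  iterations <- 0L
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    # update step: empty clusters keep their previous centroid
    rs <- rowsum(X, group = cl)
    lev <- as.integer(rownames(rs))
    cnt <- tabulate(cl, nbins = m)
    centers[lev, ] <- rs / cnt[lev]
    cl_new <- assign_pts(centers)
    sse_new <- sse_of(cl_new, centers)
    if (sse_new > sse + 1e-8 * max(1, sse))
      stop("internal error: within-cluster SSE increased during Lloyd's ",
           "algorithm")
    sse <- sse_new
    if (identical(cl_new, cl)) { cl <- cl_new; break }
    cl <- cl_new
  }
  keep <- sort(unique(cl))               # delete empty clusters
  relabel <- match(cl, keep)
  centroids <- centers[keep, , drop = FALSE]
  rownames(centroids) <- sprintf("C%02d", seq_along(keep))
  structure(list(assignment = setNames(relabel, rownames(X)),
                 centroids = centroids,
                 sizes = tabulate(relabel, length(keep)),
                 k_init = k_init, seed = seed,
                 iterations = iterations, sse = sse),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(paste0("cluster_model: %d genes in %d clusters ",
                     "(k_init = %d, %d iterations, SSE = %.4g)\n"),
              length(x$assignment), nrow(x$centroids), x$k_init,
              x$iterations, x$sse))
  invisible(x)
}

#' Cluster-mean expression profiles
#'
#' Averages the (scaled but unsmoothed) expression of the genes in each
#' cluster; smoothing is only used to estimate the centroids, while the
#' summary profiles average the expression itself.
#'
#' @param model a [kmeans_summarize()] model.
#' @param X genes x samples expression matrix covering every assigned
#'   gene.
#' @return clusters x samples matrix with rownames `C01`, `C02`, ...
#' @export
cluster_means <- function(model, X) {
  stopifnot(inherits(model, "cluster_model"), is.matrix(X))
  genes <- names(model$assignment)
  miss <- setdiff(genes, rownames(X))
  if (length(miss))
    stop("genes missing from the expression matrix: ",
         paste(miss, collapse = ", "))
  k <- nrow(model$centroids)
  sub <- X[genes, , drop = FALSE]
  sums <- rowsum(sub, group = factor(model$assignment, levels = seq_len(k)))
  out <- sums / model$sizes
  rownames(out) <- rownames(model$centroids)
  out
}
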