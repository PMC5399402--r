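#' Principal component analysis by singular value decomposition
#'
#' Column-centers the input and decomposes it; components are oriented so
#' the largest-magnitude loading of each component is positive, making the
#' decomposition deterministic.
#'
#' @param X numeric samples x variables matrix (typically autoscaled).
#' @param A number of components; at most `min(nrow(X) - 1, ncol(X))`.
#' @return an object of class `pca_model`: list with `loadings`
#'   (variables x A), `scores` (samples x A), `explained_variance`
#'   (fraction of total variance per component, over all components of the
#'   decomposition, so the stored `A` entries need not sum to 1), `A`,
#'   `center`.
#' @export
fit_pca <- function(X, A) {
  X <- block_values(X)
  A_max <- min(nrow(X) - 1L, ncol(X))
  if (A < 1 || A > A_max)
    stop("A must lie in 1..", A_max, " for a ", nrow(X), " x ", ncol(X),
         " matrix")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  ev <- sv$d^2 / sum(sv$d^2)
  loadings <- sv$v[, seq_len(A), drop = FALSE]
  scores <- sv$u[, seq_len(A), drop = FALSE] %*% diag(sv$d[seq_len(A)], A)
  # orient: largest-|loading| entry positive
  for (a in seq_len(A)) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(A)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(A)))
  structure(list(loadings = loadings, scores = scores,
                 explained_variance = ev[seq_len(A)], A = A, center = ctr),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components; explained variance %s\n", x$A,
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  invisible(x)
}

#' Fit a multi-block PLS (MBPLS-DA) model
#'
#' NIPALS multi-block PLS with a super-score layer: each data block is
#' modelled separately and their common structure is expressed through an
#' additional top level. Per component, block weights and scores are
#' computed against the current Y-residual; the super score is the
#' unit-norm-weighted combination of the block scores; Y is regressed on
#' the super score; blocks and Y are deflated by the super score (which
#' makes successive super scores mutually orthogonal). With a single block
#' the model coincides with ordinary PLS2.
#'
#' Before fitting, each (autoscaled) block is divided by the square root of
#' its variable count so a wide transcript block cannot overshadow a narrow
#' metabolite block; block weights are reported per block with unit norm,
#' so downstream VIPs are unaffected by this block scaling.
#'
#' @param blocks named list of [omics_block()]s or samples x variables
#'   matrices, all with identical sample order.
#' @param Y a [build_response()] design, or a numeric samples x responses
#'   matrix.
#' @param A number of components (default 3: the first three latent
#'   variables carry the interpreted treatment/time/severity structure).
#' @param orient response whose Y-weight is made non-negative on every
#'   component (sign convention); defaults to the last response column.
#' @param tol,max_iter NIPALS convergence controls.
#' @return an object of class `mbpls_model` with elements
#'   `block_weights` (per block: variables x A, unit-norm columns),
#'   `block_scores` (per block: samples x A), `super_weights` (blocks x A,
#'   unit-norm columns), `super_scores` (samples x A), `y_weights`
#'   (responses x A regression coefficients of Y on the super scores),
#'   `ssy` (A x responses explained sum-of-squares of each response per
#'   component), `ssy_total` (initial sum of squares per response),
#'   `p_b` (variable count per block), `blocks`, `responses`, `A`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("v", 1:6)))
#' y <- X[, 1] - X[, 4] + rnorm(10, sd = 0.1)
#' fit_mbpls(list(demo = scale(X)), cbind(y = scale(y)), A = 2)
#' @export
fit_mbpls <- function(blocks, Y, A = 3, orient = NULL,
                      tol = 1e-10, max_iter = 500) {
  stopifnot(length(blocks) >= 1, A >= 1)
  Xs <- lapply(blocks, block_values)
  if (is.null(names(Xs)) || any(!nzchar(names(Xs))))
    names(Xs) <- if (all(vapply(blocks, inherits, TRUE, "omics_block")))
      vapply(blocks, `[[`, character(1), "block_name")
    else paste0("block", seq_along(Xs))
  resp <- if (inherits(Y, "response_design")) Y$Y else as.matrix(Y)
  n <- nrow(resp)
  for (b in seq_along(Xs)) {
    if (nrow(Xs[[b]]) != n)
      stop("block '", names(Xs)[b], "' has ", nrow(Xs[[b]]),
           " samples; Y has ", n)
    if (!is.null(rownames(Xs[[b]])) && !is.null(rownames(resp)) &&
        !identical(rownames(Xs[[b]]), rownames(resp)))
      stop("sample order of block '", names(Xs)[b],
           "' does not match the response design")
  }
  p_b <- vapply(Xs, ncol, integer(1))
  if (A > min(n - 1L, sum(p_b)))
    stop("A = ", A, " exceeds the attainable rank (",
         min(n - 1L, sum(p_b)), ")")
  if (is.null(colnames(resp)))
    colnames(resp) <- paste0("y", seq_len(ncol(resp)))
  if (is.null(orient)) orient <- ncol(resp)
  orient <- resolve_response(orient, colnames(resp))

  # block scaling: equal a-priori block weight
  Xw <- mapply(function(X, p) X / sqrt(p), Xs, p_b, SIMPLIFY = FALSE)
  B <- length(Xw)
  r <- ncol(resp)
  ssy_total <- colSums(resp^2)

  W <- lapply(p_b, function(p) matrix(0, p, A))
  Tb <- lapply(seq_len(B), function(b) matrix(0, n, A))
  Wt <- matrix(0, B, A, dimnames = list(names(Xs), NULL))
  Tt <- matrix(0, n, A, dimnames = list(rownames(resp), NULL))
  Q <- matrix(0, r, A, dimnames = list(colnames(resp), NULL))
  SSY <- matrix(0, A, r, dimnames = list(NULL, colnames(resp)))

  Yres <- resp
  for (a in seq_len(A)) {
    u <- Yres[, which.max(colSums(Yres^2))]
    if (sum(u^2) < 1e-12)
      stop("Y residual exhausted before component ", a,
           "; reduce A")
    tT_old <- rep(0, n)
    w_b <- vector("list", B); t_mat <- matrix(0, n, B)
    wT <- rep(0, B); tT <- rep(0, n)
    for (iter in seq_len(max_iter)) {
      for (b in seq_len(B)) {
        w <- crossprod(Xw[[b]], u)
        nw <- sqrt(sum(w^2))
        w <- if (nw > 1e-14) w / nw else w * 0
        w_b[[b]] <- w
        t_mat[, b] <- Xw[[b]] %*% w
      }
      wT <- crossprod(t_mat, u)
      nwT <- sqrt(sum(wT^2))
      if (nwT < 1e-14)
        stop("blocks carry no covariance with Y at component ", a)
      wT <- wT / nwT
      tT <- drop(t_mat %*% wT)
      q <- crossprod(Yres, tT)
      q <- q / sqrt(sum(q^2))
      u <- drop(Yres %*% q)
      if (sqrt(sum((tT - tT_old)^2)) < tol * max(1, sqrt(sum(tT^2)))) break
      tT_old <- tT
    }
    tt <- sum(tT^2)
    q_reg <- drop(crossprod(Yres, tT)) / tt
    # sign convention: orient the designated response positively
    if (q_reg[orient] < 0) {
      # flip block weights and scores together so t_b = X_b w_b and
      # tT = [t_1..t_B] wT stay consistent; super weights keep their sign
      tT <- -tT; q_reg <- -q_reg
      t_mat <- -t_mat
      w_b <- lapply(w_b, function(w) -w)
    }
    for (b in seq_len(B)) {
      W[[b]][, a] <- w_b[[b]]
      Tb[[b]][, a] <- t_mat[, b]
      p_load <- crossprod(Xw[[b]], tT) / tt
      Xw[[b]] <- Xw[[b]] - tcrossprod(tT, p_load)
    }
    Wt[, a] <- wT
    Tt[, a] <- tT
    Q[, a] <- q_reg
    SSY[a, ] <- q_reg^2 * tt
    Yres <- Yres - tcrossprod(tT, q_reg)
  }
  for (b in seq_len(B)) {
    dimnames(W[[b]]) <- list(colnames(Xs[[b]]), paste0("LV", seq_len(A)))
    dimnames(Tb[[b]]) <- list(rownames(resp), paste0("LV", seq_len(A)))
  }
  names(W) <- names(Tb) <- names(Xs)
  structure(list(block_weights = W, block_scores = Tb,
                 super_weights = Wt, super_scores = Tt,
                 y_weights = Q, ssy = SSY, ssy_total = ssy_total,
                 p_b = p_b, blocks = names(Xs),
                 responses = colnames(resp), A = A),
            class = "mbpls_model")
}

resolve_response <- function(response, responses) {
  if (is.character(response)) {
    idx <- match(response, responses)
    if (is.na(idx))
      stop("response '", response, "' not in model (",
           paste(responses, collapse = ", "), ")")
    idx
  } else {
    stopifnot(response >= 1, response <= length(responses))
    as.integer(response)
  }
}

#' @export
print.mbpls_model <- function(x, ...) {
  cat(sprintf("mbpls_model: %d blocks (%s), %d components, %d responses\n",
              length(x$blocks),
              paste(sprintf("%s: %d", x$blocks, x$p_b), collapse = "; "),
              x$A, length(x$responses)))
  frac <- colSums(x$ssy) / x$ssy_total
  cat("  explained Y-variance:",
      paste(sprintf("%s %.1f%%", x$responses, 100 * frac), collapse = ", "),
      "\n")
  invisible(x)
}

#' Variable Importance in Projection for a multi-block model
#'
#' Computes, per variable, the Wold VIP with respect to one response: a
#' weighted sum of squared block weights, the weights being the
#' per-component explained variance of that response. Within each block b
#' (p_b variables) the raw VIP satisfies `sum(VIP^2) = p_b`, the
#' single-block convention under which the average VIP is one. The raw
#' VIPs are then block-rescaled so every block contributes the same VIP
#' total (`sum = P_total / B`), giving the blocks equal total contribution
#' towards explaining the response and a grand mean VIP of exactly one;
#' with blocks of very different widths, the narrow block's variables are
#' correspondingly up-weighted (e.g. 610 metabolites vs 36,253 transcripts
#' puts the metabolite block mean about 60-fold above the transcript one).
#'
#' @param model an [fit_mbpls()] model.
#' @param response response name or index the VIP is computed against.
#' @return an object of class `vip_table` (a data.frame): columns
#'   `variable`, `block`, `raw_vip`, `vip`, `selected` (NA until
#'   [select_vips()]), `sign` (NA until [split_by_sign()]).
#' @export
compute_vip <- function(model, response) {
  stopifnot(inherits(model, "mbpls_model"))
  ridx <- resolve_response(response, model$responses)
  ssy_r <- model$ssy[, ridx]
  if (sum(ssy_r) <= 0)
    stop("model explains no variance of response '",
         model$responses[ridx], "'")
  P_total <- sum(model$p_b)
  B <- length(model$p_b)
  target <- P_total / B
  out <- lapply(seq_len(B), function(b) {
    w <- model$block_weights[[b]]
    raw <- sqrt(model$p_b[b] * drop(w^2 %*% ssy_r) / sum(ssy_r))
    data.frame(variable = rownames(w),
               block = model$blocks[b],
               raw_vip = raw,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  sums <- tapply(out$raw_vip, out$block, sum)
  if (any(sums == 0))
    warning("block(s) with all-zero VIPs left unrescaled: ",
            paste(names(sums)[sums == 0], collapse = ", "))
  fac <- ifelse(sums > 0, target / sums, 1)
  out$vip <- out$raw_vip * fac[out$block]
  out$selected <- NA
  out$sign <- NA_character_
  attr(out, "response") <- model$responses[ridx]
  class(out) <- c("vip_table", "data.frame")
  out
}

#' Select high-VIP variables by the upper-tail rule
#'
#' Within each block, flags variables whose block-rescaled VIP exceeds
#' `mean + qnorm(1 - p) * sd` of that block's VIPs, i.e. the
#' `VIP > mu + t(p, Inf) * sigma` rule with the t quantile at infinite
#' degrees of freedom (standard normal). At the default `p = 0.33` the
#' multiplier is 0.4399.
#'
#' @param vips a [compute_vip()] table.
#' @param p upper-tail probability in (0, 0.5].
#' @return the table with the `selected` column filled.
#' @export
select_vips <- function(vips, p = 0.33) {
  stopifnot(inherits(vips, "vip_table"), p > 0, p <= 0.5)
  tcrit <- qnorm(1 - p)
  vips$selected <- FALSE
  for (b in unique(vips$block)) {
    idx <- vips$block == b
    v <- vips$vip[idx]
    if (sum(idx) < 2) {
      warning("block '", b, "' has a single variable; VIP sd undefined, ",
              "nothing selected")
      next
    }
    thr <- mean(v) + tcrit * sd(v)
    vips$selected[idx] <- v > thr
  }
  vips
}

#' Split selected VIP variables by sign of association with a response
#'
#' Assigns each selected variable the sign of its Pearson correlation with
#' the response values across all observations (the convention that splits
#' a scald VIP list into positively and negatively associated members).
#' Zero correlation is assigned to the positive list with a message.
#'
#' @param vips a [select_vips()] table.
#' @param blocks named list of the data blocks the model was fitted on
#'   (matrices or [omics_block()]s, samples x variables), names matching
#'   the table's `block` column.
#' @param response numeric response values over the same samples (e.g. the
#'   raw scald scores).
#' @return the table with `sign` (`"+"`/`"-"`) and `cor` filled for
#'   selected variables.
#' @export
split_by_sign <- function(vips, blocks, response) {
  stopifnot(inherits(vips, "vip_table"))
  if (sd(response) == 0) stop("response is constant; sign undefined")
  vips$cor <- NA_real_
  sel <- which(vips$selected %in% TRUE)
  if (!length(sel)) return(vips)
  for (b in unique(vips$block[sel])) {
    if (!b %in% names(blocks))
      stop("no data block supplied for '", b, "'")
    vals <- block_values(blocks[[b]])
    idx <- sel[vips$block[sel] == b]
    vars <- vips$variable[idx]
    miss <- setdiff(vars, colnames(vals))
    if (length(miss))
      stop("variables missing from block '", b, "': ",
           paste(miss, collapse = ", "))
    cc <- suppressWarnings(cor(vals[, vars, drop = FALSE], response))
    cc[is.na(cc)] <- 0
    vips$cor[idx] <- drop(cc)
  }
  zero <- sel[vips$cor[sel] == 0]
  if (length(zero))
    message(length(zero), " selected variable(s) with zero correlation ",
            "assigned to the positive list")
  vips$sign[sel] <- ifelse(vips$cor[sel] < 0, "-", "+")
  vips
}

#' @export
print.vip_table <- function(x, ...) {
  cat(sprintf("vip_table: %d variables in %d block(s)",
              nrow(x), length(unique(x$block))))
  if (!is.null(attr(x, "response")))
    cat(", response '", attr(x, "response"), "'", sep = "")
  if (any(x$selected %in% TRUE))
    cat(sprintf("; %d selected (%d +, %d -)",
                sum(x$selected %in% TRUE),
                sum(x$sign %in% "+"), sum(x$sign %in% "-")))
  cat("\n")
  invisible(x)
}
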