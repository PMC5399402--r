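#' Expand hierarchical bin paths into all ancestor bins
#'
#' A gene annotated to `"a.b.c"` belongs to bins `"a"`, `"a.b"` and
#' `"a.b.c"`. Returns the gene-to-bin membership as a long data.frame.
#'
#' @param annotation data.frame with columns `gene_id`, `bin_path`.
#' @param hierarchical expand ancestors (`TRUE`) or use the full paths
#'   as flat bins (`FALSE`).
#' @return data.frame with columns `gene_id`, `bin`.
#' @export
expand_bins <- function(annotation, hierarchical = TRUE) {
  stopifnot(all(c("gene_id", "bin_path") %in% names(annotation)))
  if (!hierarchical)
    return(data.frame(gene_id = annotation$gene_id,
                      bin = annotation$bin_path, stringsAsFactors = FALSE))
  parts <- strsplit(annotation$bin_path, ".", fixed = TRUE)
  bins <- lapply(parts, function(p)
    vapply(seq_along(p), function(i) paste(p[seq_len(i)], collapse = "."),
           character(1)))
  data.frame(gene_id = rep(annotation$gene_id, lengths(bins)),
             bin = unlist(bins), stringsAsFactors = FALSE)
}

#' Fisher-exact over/under-representation analysis of functional bins
#'
#' For each functional bin with at least one background member, tests the
#' gene list for over-representation (hypergeometric upper tail,
#' `P(X >= k)`) and under-representation (lower tail, `P(X <= k)`) against
#' the background, with Bonferroni correction across the tested bins.
#' Direction is called from the smaller adjusted tail at `alpha`.
#'
#' @param gene_list character vector of genes of interest; must be a
#'   subset of `background`.
#' @param background character vector of all measured genes.
#' @param annotation data.frame with columns `gene_id`, `bin_path`
#'   (hierarchical, `.`-separated); genes without annotation count toward
#'   the totals but belong to no bin.
#' @param alpha significance level for the direction call.
#' @param hierarchical test every ancestor level of the bin paths.
#' @return an `ora_table` data.frame sorted by `p_over`: columns `bin`,
#'   `k` (list genes in bin), `n` (list size), `K` (background genes in
#'   bin), `N` (background size), `p_over`, `p_under`, `adj_p_over`,
#'   `adj_p_under`, `direction`.
#' @examples
#' ann <- data.frame(gene_id = paste0("g", 1:10),
#'                   bin_path = rep(c("wall.pectin", "stress"), each = 5))
#' fisher_ora(paste0("g", 1:4), paste0("g", 1:10), ann)
#' @export
fisher_ora <- function(gene_list, background, annotation, alpha = 0.05,
                       hierarchical = TRUE) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  stray <- setdiff(gene_list, background)
  if (length(stray))
    stop("gene(s) in the list but not the background: ",
         paste(stray, collapse = ", "))
  memb <- expand_bins(annotation, hierarchical)
  memb <- unique(memb[memb$gene_id %in% background, ])
  if (!nrow(memb)) stop("no annotated background genes")
  N <- length(background)
  n <- length(gene_list)
  K <- tapply(memb$gene_id, memb$bin, function(g) length(unique(g)))
  k_tab <- tapply(memb$gene_id[memb$gene_id %in% gene_list],
                  factor(memb$bin[memb$gene_id %in% gene_list],
                         levels = names(K)),
                  function(g) length(unique(g)))
  k <- ifelse(is.na(k_tab), 0L, k_tab)
  p_over <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_under <- phyper(k, K, N - K, n)
  n_bins <- length(K)
  adj_over <- pmin(1, p_over * n_bins)
  adj_under <- pmin(1, p_under * n_bins)
  direction <- ifelse(adj_over <= alpha & p_over < p_under, "over",
                      ifelse(adj_under <= alpha & p_under < p_over,
                             "under", "none"))
  out <- data.frame(bin = names(K), k = as.integer(k), n = n,
                    K = as.integer(K), N = N,
                    p_over = unname(p_over), p_under = unname(p_under),
                    adj_p_over = unname(adj_over),
                    adj_p_under = unname(adj_under),
                    direction = unname(direction),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_over, out$bin), ]
  rownames(out) <- NULL
  class(out) <- c("ora_table", "data.frame")
  out
}
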