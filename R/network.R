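#' Build a windowed correlation network over gene clusters and metabolites
#'
#' Restricts every profile to the replicate-level observations whose
#' storage day falls in `window`, computes pairwise Pearson correlations
#' among all gene-cluster means and individual metabolites, and adds an
#' undirected edge wherever `r^2 >= r2_min` (sign-agnostic; the signed r is
#' stored on the edge). Edge weight is `1 - r^2`, so tightly correlated
#' pairs are close. Profiles constant within the window cannot be
#' correlated; they are excluded from pairing and recorded. The
#' pre-symptomatic network uses the first-two-months window
#' (days 0-61), the symptomatic one the full course.
#'
#' @param cluster_means clusters x samples matrix (see [cluster_means()]).
#' @param metabolites an [omics_block()] or samples x metabolites matrix.
#' @param meta sample metadata supplying the day of each observation.
#' @param window storage days defining the observation window; needs at
#'   least 3 observations.
#' @param r2_min minimum squared correlation for an edge.
#' @param label window label stored on the network (e.g. `"2month"`).
#' @return an object of class `correlation_network`: list with `graph`
#'   (an undirected igraph with vertex attribute `kind` and edge
#'   attributes `r`, `r2`, `weight`), `window`, `label`, `excluded`
#'   (constant-profile node ids).
#' @export
build_network <- function(cluster_means, metabolites, meta, window,
                          r2_min = 0.700, label = NULL) {
  met <- t(block_values(metabolites))        # metabolites x samples
  stopifnot(is.matrix(cluster_means))
  samples <- colnames(cluster_means)
  if (!identical(sort(samples), sort(colnames(met))))
    stop("cluster means and metabolite block cover different samples")
  met <- met[, samples, drop = FALSE]
  days <- meta$day[match(samples, meta$sample_id)]
  if (anyNA(days)) stop("samples missing from metadata")
  bad_days <- setdiff(window, meta$day)
  if (length(bad_days))
    stop("window days not in the design: ", paste(bad_days, collapse = ", "))
  in_win <- days %in% window
  if (sum(in_win) < 3)
    stop("window covers fewer than 3 observations")
  prof <- rbind(cluster_means, met)[, in_win, drop = FALSE]
  kind <- c(rep("gene_cluster", nrow(cluster_means)),
            rep("metabolite", nrow(met)))
  names(kind) <- rownames(prof)
  sds <- apply(prof, 1L, sd)
  excluded <- rownames(prof)[sds == 0]
  if (length(excluded))
    message("excluding constant profile(s) in window: ",
            paste(excluded, collapse = ", "))
  active <- sds > 0
  cmat <- cor(t(prof[active, , drop = FALSE]))
  hit <- which(upper.tri(cmat) & cmat^2 >= r2_min, arr.ind = TRUE)
  edges <- data.frame(from = rownames(cmat)[hit[, 1L]],
                      to = colnames(cmat)[hit[, 2L]],
                      r = cmat[hit],
                      stringsAsFactors = FALSE)
  edges$r2 <- edges$r^2
  edges$weight <- 1 - edges$r2
  vertices <- data.frame(name = rownames(prof), kind = unname(kind),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  structure(list(graph = g,
                 window = window,
                 label = if (is.null(label))
                   paste0("days_", min(window), "-", max(window)) else label,
                 excluded = excluded),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network '%s': %d nodes, %d edges\n",
              x$label, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' First-neighbor subnetwork of an anchor node
#'
#' Induced subnetwork on the anchor and every node sharing a qualifying
#' edge with it, retaining all qualifying edges among those nodes.
#'
#' @param net a [build_network()] network.
#' @param anchor node id (e.g. `"CTOL"` or `"methanol"`).
#' @return a `correlation_network` restricted to the anchor neighborhood.
#' @export
first_neighbors <- function(net, anchor) {
  stopifnot(inherits(net, "correlation_network"))
  g <- net$graph
  if (!anchor %in% igraph::V(g)$name)
    stop("anchor '", anchor, "' not present in the network")
  nb <- igraph::neighbors(g, anchor)
  sub <- igraph::induced_subgraph(g, c(anchor, igraph::V(g)$name[nb]))
  structure(list(graph = sub, window = net$window,
                 label = paste0(net$label, ":", anchor),
                 excluded = character(0)),
            class = "correlation_network")
}

#' Refine cluster members by direct correlation with an anchor metabolite
#'
#' k-means clusters include outlier genes less correlated with the anchor
#' than the cluster mean is; refinement keeps only the genes whose own
#' squared Pearson correlation with the anchor trace over the window
#' observations reaches `r2_min`.
#'
#' @param gene_ids genes to screen.
#' @param expr an [omics_block()] or samples x genes matrix containing
#'   them.
#' @param anchor_trace numeric anchor metabolite profile over the same
#'   samples.
#' @param meta sample metadata (for the day of each observation).
#' @param window storage days to correlate over.
#' @param r2_min minimum squared correlation to keep a gene.
#' @return character vector of retained gene ids.
#' @export
refine_members <- function(gene_ids, expr, anchor_trace, meta, window,
                           r2_min = 0.700) {
  vals <- block_values(expr)
  if (length(anchor_trace) != nrow(vals))
    stop("anchor trace length does not match the expression samples")
  days <- meta$day[match(rownames(vals), meta$sample_id)]
  if (anyNA(days)) stop("samples missing from metadata")
  in_win <- days %in% window
  if (!any(in_win)) stop("empty observation window")
  miss <- setdiff(gene_ids, colnames(vals))
  if (length(miss))
    stop("genes missing from the expression block: ",
         paste(miss, collapse = ", "))
  x <- vals[in_win, gene_ids, drop = FALSE]
  y <- anchor_trace[in_win]
  if (sd(y) == 0) stop("anchor trace is constant in the window")
  cc <- suppressWarnings(cor(x, y))
  cc[is.na(cc)] <- 0
  gene_ids[drop(cc)^2 >= r2_min]
}

#' Per-node topology metrics
#'
#' Degree, neighborhood connectivity (mean degree of a node's neighbors;
#' 0 for isolated nodes) and local clustering coefficient (fraction of
#' possible edges present among a node's neighbors; 0 by convention for
#' nodes of degree < 2).
#'
#' @param net a [build_network()] network (or first-neighbor subnetwork).
#' @return data.frame with columns `node`, `kind`, `degree`,
#'   `neighborhood_connectivity`, `clustering_coefficient`.
#' @export
node_metrics <- function(net) {
  stopifnot(inherits(net, "correlation_network"))
  g <- net$graph
  deg <- igraph::degree(g)
  nc <- vapply(igraph::V(g), function(v) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) == 0) 0 else mean(deg[as.integer(nb)])
  }, numeric(1))
  cc <- igraph::transitivity(g, type = "localundirected",
                             vids = igraph::V(g), isolates = "zero")
  data.frame(node = igraph::V(g)$name,
             kind = igraph::V(g)$kind,
             degree = unname(deg),
             neighborhood_connectivity = unname(nc),
             clustering_coefficient = cc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a correlation network
#'
#' `write_graphml()` writes the graph (vertex attribute `kind`, edge
#' attributes `r`, `r2`, `weight`) for downstream viewers, which own the
#' layout; `edge_table()` returns the edge list as a data.frame.
#'
#' @param net a [build_network()] network.
#' @param path output path for the GraphML file.
#' @return `path` (invisibly) / the edge-list data.frame.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "correlation_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
edge_table <- function(net) {
  stopifnot(inherits(net, "correlation_network"))
  el <- igraph::as_data_frame(net$graph, what = "edges")
  names(el)[1:2] <- c("from", "to")
  el
}
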