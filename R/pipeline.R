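#' Assemble a pipeline configuration
#'
#' Collects every tunable of the analysis in one validated list. Input
#' data come either from `inputs` (paths to the four TSV tables) or from
#' `synthetic` (arguments forwarded to [generate_dataset()]); exactly one
#' must be supplied.
#'
#' @param seed integer seed used for every stochastic stage (required).
#' @param outdir output directory for the artifact bundle.
#' @param inputs optional list with paths `expression`, `metabolites`,
#'   `metadata`, `annotation`.
#' @param synthetic optional list of [generate_dataset()] arguments
#'   (`n_genes`, `n_metabolites`, `noise_sd`, ...).
#' @param A number of MBPLS-DA components.
#' @param rpkm_threshold cell replicate-sum threshold of the gene filter.
#' @param n_pcs components for PCA smoothing before clustering.
#' @param k_init initial k-means centroids.
#' @param r2_min edge / refinement threshold on squared correlation.
#' @param vip_p upper-tail probability of the VIP selection rule.
#' @param response response variable the VIPs are computed against.
#' @param anchor_early,anchor_late anchor metabolite ids for the
#'   pre-symptomatic and symptomatic subnetworks.
#' @param window_early storage days of the pre-symptomatic (2-month)
#'   window; the symptomatic window is the full design.
#' @param log2_metabolites log2-transform the metabolite block before
#'   scaling.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, outdir = "scaldnet-out",
                            inputs = NULL, synthetic = NULL,
                            A = 3, rpkm_threshold = 5, n_pcs = 10,
                            k_init = 100, r2_min = 0.700, vip_p = 0.33,
                            response = "scald",
                            anchor_early = "CTOL", anchor_late = "methanol",
                            window_early = c(0, 7, 14, 28, 61),
                            log2_metabolites = FALSE) {
  if (missing(seed)) stop("pipeline_config: a seed is required")
  if (is.null(inputs) && is.null(synthetic))
    synthetic <- list()
  if (!is.null(inputs) && !is.null(synthetic))
    stop("supply either inputs or synthetic, not both")
  cfg <- list(seed = as.integer(seed), outdir = outdir, inputs = inputs,
              synthetic = synthetic, A = A,
              rpkm_threshold = rpkm_threshold, n_pcs = n_pcs,
              k_init = k_init, r2_min = r2_min, vip_p = vip_p,
              response = response, anchor_early = anchor_early,
              anchor_late = anchor_late, window_early = window_early,
              log2_metabolites = log2_metabolites)
  stopifnot(cfg$A >= 1, cfg$n_pcs >= 1, cfg$k_init >= 1,
            cfg$r2_min > 0, cfg$r2_min <= 1,
            cfg$vip_p > 0, cfg$vip_p <= 0.5)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments; `seed` is mandatory.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config must state a seed")
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pca_summary <- function(model) {
  list(A = model$A,
       explained_variance = as.numeric(model$explained_variance))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: read (or simulate) and validate the inputs; filter
#' low-expression genes; autoscale blocks and build the response design;
#' PCA per block; MBPLS-DA; VIP computation, selection and sign-splitting;
#' PCA-smoothing and k-means summarization; pre-symptomatic and
#' symptomatic correlation networks; anchor first-neighbor subnetworks;
#' per-gene refinement of anchor-linked clusters; ORA of the VIP lists and
#' refined lists; and a run manifest. All tables are written to
#' `config$outdir` as TSV/GraphML/JSON; a fixed config and seed reproduce
#' the bundle byte for byte.
#'
#' @param config a [pipeline_config()], a list of its arguments, or the
#'   path to a YAML config file.
#' @return invisibly, a list with the main in-memory results (`dataset`,
#'   `filter`, `scaled`, `response`, `pca`, `mbpls`, `vip`, `clusters`,
#'   `networks`, `subnetworks`, `refined`, `ora`, `files`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) {
    p <- file.path(config$outdir, name)
    files <<- c(files, p)
    p
  }

  dataset <- stage("load_inputs", {
    if (!is.null(config$synthetic)) {
      args <- config$synthetic
      args$seed <- config$seed
      do.call(generate_dataset, args)
    } else {
      inp <- config$inputs
      need <- c("expression", "metabolites", "metadata", "annotation")
      miss <- setdiff(need, names(inp))
      if (length(miss))
        stop("inputs missing: ", paste(miss, collapse = ", "))
      meta <- read_metadata(inp$metadata)
      list(expression = read_block(inp$expression, "transcriptome"),
           metabolites = read_block(inp$metabolites, "metabolome"),
           meta = meta,
           annotation = read_annotation(inp$annotation),
           truth = NULL)
    }
  })
  meta <- dataset$meta
  stage("check_anchors", {
    anchors <- c(config$anchor_early, config$anchor_late)
    miss <- setdiff(anchors, dataset$metabolites$variable_ids)
    if (length(miss))
      stop("anchor metabolite(s) absent from the metabolite block: ",
           paste(miss, collapse = ", "))
  })

  filt <- stage("filter_genes", {
    expr <- align_block(dataset$expression, meta)
    filter_genes(expr, meta, threshold = config$rpkm_threshold)
  })
  write_tsv(filt$report, out("filter_report.tsv"))

  scaled <- stage("autoscale", {
    list(expression = autoscale(filt$block),
         metabolites = autoscale(align_block(dataset$metabolites, meta),
                                 log2_transform = config$log2_metabolites))
  })
  response <- stage("build_response", build_response(meta))

  pca <- stage("pca", {
    A_pca <- min(config$A, nrow(meta) - 1L)
    list(expression = fit_pca(scaled$expression$block$values, A_pca),
         metabolites = fit_pca(scaled$metabolites$block$values, A_pca))
  })
  jsonlite::write_json(lapply(pca, pca_summary), out("pca_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  mbpls <- stage("mbpls", {
    fit_mbpls(list(metabolome = scaled$metabolites$block,
                   transcriptome = scaled$expression$block),
              response, A = config$A, orient = config$response)
  })
  jsonlite::write_json(
    list(A = mbpls$A, blocks = as.list(mbpls$p_b),
         super_weights = apply(mbpls$super_weights, 2, as.list),
         explained_y_variance =
           as.list(colSums(mbpls$ssy) / mbpls$ssy_total)),
    out("mbpls_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  vip <- stage("vip", {
    v <- compute_vip(mbpls, config$response)
    v <- select_vips(v, p = config$vip_p)
    split_by_sign(v,
                  list(metabolome = scaled$metabolites$block,
                       transcriptome = scaled$expression$block),
                  response$raw[[config$response]])
  })
  write_tsv(vip, out("vip_table.tsv"))

  clusters <- stage("clustering", {
    expr_t <- t(scaled$expression$block$values)   # genes x samples
    sm <- pca_smooth(expr_t, n_pcs = min(config$n_pcs,
                                         min(dim(expr_t)) - 1L))
    km <- kmeans_summarize(sm, k_init = config$k_init, seed = config$seed)
    list(model = km, means = cluster_means(km, expr_t))
  })
  write_tsv(data.frame(gene_id = names(clusters$model$assignment),
                       cluster_id = rownames(clusters$model$centroids)[
                         clusters$model$assignment],
                       stringsAsFactors = FALSE),
            out("cluster_assignment.tsv"))
  write_tsv(data.frame(cluster_id = rownames(clusters$means),
                       clusters$means, check.names = FALSE),
            out("cluster_means.tsv"))

  windows <- list(`2month` = config$window_early,
                  `6month` = sort(unique(meta$day)))
  networks <- stage("networks", {
    lapply(names(windows), function(lbl)
      build_network(clusters$means, scaled$metabolites$block, meta,
                    window = windows[[lbl]], r2_min = config$r2_min,
                    label = lbl))
  })
  names(networks) <- names(windows)
  for (lbl in names(networks)) {
    write_graphml(networks[[lbl]], out(sprintf("network_%s.graphml", lbl)))
    write_tsv(edge_table(networks[[lbl]]),
              out(sprintf("network_%s_edges.tsv", lbl)))
    write_tsv(node_metrics(networks[[lbl]]),
              out(sprintf("network_%s_metrics.tsv", lbl)))
  }

  anchors <- c(`2month` = config$anchor_early, `6month` = config$anchor_late)
  subnetworks <- stage("subnetworks", {
    lapply(names(anchors), function(lbl)
      first_neighbors(networks[[lbl]], anchors[[lbl]]))
  })
  names(subnetworks) <- names(anchors)
  for (lbl in names(subnetworks))
    write_graphml(subnetworks[[lbl]],
                  out(sprintf("subnetwork_%s_%s.graphml", anchors[[lbl]],
                              lbl)))

  refined <- stage("refine_members", {
    expr_scaled <- scaled$expression$block
    metab_scaled <- scaled$metabolites$block$values
    res <- list()
    for (lbl in names(anchors)) {
      anchor <- anchors[[lbl]]
      sub <- subnetworks[[lbl]]
      cl_ids <- igraph::V(sub$graph)$name[
        igraph::V(sub$graph)$kind == "gene_cluster"]
      genes <- names(clusters$model$assignment)[
        rownames(clusters$model$centroids)[clusters$model$assignment] %in%
          cl_ids]
      res[[anchor]] <- if (length(genes))
        refine_members(genes, expr_scaled, metab_scaled[, anchor],
                       meta, windows[[lbl]], r2_min = config$r2_min)
      else character(0)
    }
    res
  })
  for (anchor in names(refined))
    write_tsv(data.frame(gene_id = refined[[anchor]],
                         stringsAsFactors = FALSE),
              out(sprintf("refined_%s.tsv", anchor)))

  ora <- stage("ora", {
    background <- filt$block$variable_ids
    gene_vips <- vip[vip$block == "transcriptome" & vip$selected %in% TRUE, ]
    lists <- list(
      vip_pos = gene_vips$variable[gene_vips$sign %in% "+"],
      vip_neg = gene_vips$variable[gene_vips$sign %in% "-"])
    for (anchor in names(refined))
      lists[[paste0("refined_", anchor)]] <- refined[[anchor]]
    lapply(lists, function(gl)
      if (length(gl)) fisher_ora(gl, background, dataset$annotation)
      else NULL)
  })
  for (nm in names(ora))
    if (!is.null(ora[[nm]]))
      write_tsv(ora[[nm]], out(sprintf("ora_%s.tsv", nm)))

  manifest <- list(
    package = "scaldnet",
    version = as.character(packageVersion("scaldnet")),
    seed = config$seed,
    config = config[setdiff(names(config), "outdir")],
    n_samples = nrow(meta),
    n_genes_input = length(dataset$expression$variable_ids),
    n_genes_filtered = length(filt$block$variable_ids),
    n_metabolites = length(dataset$metabolites$variable_ids),
    n_clusters = nrow(clusters$model$centroids),
    files = basename(files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       force = TRUE)

  invisible(list(dataset = dataset, filter = filt, scaled = scaled,
                 response = response, pca = pca, mbpls = mbpls, vip = vip,
                 clusters = clusters, networks = networks,
                 subnetworks = subnetworks, refined = refined, ora = ora,
                 files = files))
}
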