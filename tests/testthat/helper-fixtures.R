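# Small fixtures built in code.

# A reduced synthetic dataset: full study design, fewer features.
tiny_dataset <- function(seed, noise_sd = 0.3, n_genes = 300,
                         n_metabolites = 40,
                         signals = default_signals(15, 20, 25)) {
  generate_dataset(n_genes = n_genes, n_metabolites = n_metabolites,
                   signals = signals, noise_sd = noise_sd, seed = seed)
}

# Metadata for a toy 2-treatment, 2-day, 2-replicate design (8 samples).
toy_meta <- function() {
  grid <- expand.grid(replicate = 1:2, day = c(0, 7),
                      treatment = c("control", "DPA"),
                      stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_d%03d_r%d", grid$treatment, grid$day,
                                 grid$replicate),
             treatment = grid$treatment, day = grid$day,
             replicate = grid$replicate, scald = 1L,
             stringsAsFactors = FALSE)
}

# Expression block over toy_meta() with prescribed per-cell replicate sums:
# sums is a genes x 4 matrix of cell sums, cells in the order
# (control,0), (control,7), (DPA,0), (DPA,7); each cell's two replicates
# split the sum evenly.
toy_expr_from_cell_sums <- function(sums, gene_ids = rownames(sums)) {
  meta <- toy_meta()
  cells <- paste(meta$treatment, meta$day)
  order_cells <- c("control 0", "control 7", "DPA 0", "DPA 7")
  vals <- matrix(0, nrow(meta), nrow(sums),
                 dimnames = list(meta$sample_id, gene_ids))
  for (j in seq_len(nrow(sums)))
    vals[, j] <- (sums[j, match(cells, order_cells)]) / 2
  omics_block(vals, "transcriptome")
}

# Round-trip a metadata data.frame through the TSV reader (validation path).
validate_meta_for_test <- function(meta) {
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  write.table(meta, p, sep = "\t", quote = FALSE, row.names = FALSE)
  read_metadata(p)
}

# Build a correlation network from explicit node profiles (rows) observed
# on a flat 3-day design.
net_from_profiles <- function(cluster_profiles, metabolite_profiles,
                              r2_min = 0.700) {
  n_obs <- ncol(cluster_profiles)
  meta <- data.frame(sample_id = paste0("s", seq_len(n_obs)),
                     treatment = "control",
                     day = seq_len(n_obs), replicate = 1,
                     scald = 1L, stringsAsFactors = FALSE)
  colnames(cluster_profiles) <- meta$sample_id
  mp <- t(metabolite_profiles)            # samples x metabolites
  rownames(mp) <- meta$sample_id
  met_block <- omics_block(mp, "metabolome")
  build_network(cluster_profiles, met_block, meta, window = meta$day,
                r2_min = r2_min)
}
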