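#' Define the storage-study design
#'
#' Encodes the experimental layout of the cold-storage time course: three
#' postharvest treatments (untreated control, the antioxidant diphenylamine
#' DPA, and the ethylene-perception inhibitor 1-MCP), eight storage
#' durations (harvest plus seven removals out to 183 d) and three
#' replicates per treatment/day cell, together with the expected scald
#' severity trajectory on the ordinal 1-4 scale
#' (1 = none, 2 = <25\%, 3 = 25-50\%, 4 = >50\% of the peel surface).
#'
#' @param treatments treatment labels; first label is taken as the
#'   untreated control whose day-0 state is shared by all treatments.
#' @param days strictly increasing storage days, starting at 0.
#' @param replicates_per_cell replicate count per (treatment, day) cell.
#' @param scald_trajectory optional data.frame with columns `treatment`,
#'   `day`, `scald` overriding the default severity trajectory.
#' @return an object of class `study_design`.
#' @export
study_design <- function(treatments = c("control", "DPA", "MCP"),
                         days = c(0, 7, 14, 28, 61, 92, 123, 183),
                         replicates_per_cell = 3,
                         scald_trajectory = NULL) {
  stopifnot(length(treatments) >= 1, !anyDuplicated(treatments),
            length(days) >= 2, replicates_per_cell >= 1)
  if (days[1] != 0 || is.unsorted(days, strictly = TRUE))
    stop("days must be strictly increasing and start at 0")
  design <- structure(list(treatments = treatments, days = days,
                           replicates_per_cell = replicates_per_cell,
                           scald_trajectory = scald_trajectory),
                      class = "study_design")
  design$scald_trajectory <- scald_scores(design)
  validate_scald(design$scald_trajectory, design)
  design
}

validate_scald <- function(tab, design) {
  if (!all(tab$scald %in% 1:4)) stop("scald scores must lie in 1..4")
  for (tr in design$treatments) {
    s <- tab$scald[tab$treatment == tr][order(tab$day[tab$treatment == tr])]
    if (is.unsorted(s)) stop("scald must be non-decreasing over days (", tr, ")")
  }
  invisible(tab)
}

#' Expected scald severity by treatment and storage day
#'
#' Returns the (treatment, day) -> scald score table of a design. The
#' default trajectory mirrors the observed phenotype: control fruit stay
#' symptomless through 61 d, then scores rise to 4 (>50\% coverage) by
#' 183 d; 1-MCP fruit never develop symptoms; DPA fruit show only minor
#' symptoms (score 2) at 183 d.
#'
#' @param design a [study_design()].
#' @return data.frame with columns `treatment`, `day`, `scald`.
#' @examples
#' tab <- scald_scores(study_design())
#' subset(tab, treatment == "MCP")$scald  # all 1
#' @export
scald_scores <- function(design) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(design$scald_trajectory)) {
    tab <- design$scald_trajectory
    stopifnot(all(c("treatment", "day", "scald") %in% names(tab)))
    return(tab)
  }
  grid <- expand.grid(day = design$days, treatment = design$treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  score1 <- function(tr, d) {
    switch(tr,
           control = if (d <= 61) 1L else if (d <= 92) 2L
                     else if (d <= 123) 3L else 4L,
           DPA = if (d < 183) 1L else 2L,
           MCP = 1L,
           1L)  # unknown treatments: symptomless
  }
  grid$scald <- mapply(score1, grid$treatment, grid$day)
  grid[, c("treatment", "day", "scald")]
}

#' Describe a planted signal for the synthetic generator
#'
#' A planted signal is a temporal curve on the log2 abundance scale that
#' drives a set of generated metabolites and genes, modulated per
#' treatment. Curve kinds:
#' \describe{
#'   \item{`biphasic_early`}{zero before `onset_day`, linear rise to 1 at
#'     `peak_day`, linear decline to 0.25 at the final day. Emulates a
#'     pre-symptomatic oxidation marker (CTOL-like).}
#'   \item{`sigmoidal_late`}{exactly zero up to `onset_day`, then a
#'     logistic rise normalized to 1 at the final day. Emulates a
#'     symptomatic marker (methanol-like).}
#'   \item{`monotone_ripening`}{linear 0 to 1 across the whole course;
#'     ripening background.}
#'   \item{`noise`}{identically zero.}
#' }
#'
#' @param name unique signal label.
#' @param kind one of `"biphasic_early"`, `"sigmoidal_late"`,
#'   `"monotone_ripening"`, `"noise"`.
#' @param onset_day day the signal departs from baseline; must be one of
#'   the design days.
#' @param peak_day peak day (biphasic kind only).
#' @param multipliers named numeric in \[0, 1\], one entry per treatment,
#'   scaling the signal within that treatment.
#' @param n_genes,n_metabolites how many generated genes / metabolites this
#'   signal drives.
#' @param metabolite_names optional explicit ids for the driven
#'   metabolites (first one conventionally the anchor).
#' @param amplitude signal amplitude in log2 units at curve value 1.
#' @return an object of class `planted_signal`.
#' @export
planted_signal <- function(name, kind, onset_day = 0, peak_day = NULL,
                           multipliers, n_genes = 0, n_metabolites = 0,
                           metabolite_names = NULL, amplitude = 2) {
  kind <- match.arg(kind, c("biphasic_early", "sigmoidal_late",
                            "monotone_ripening", "noise"))
  if (any(multipliers < 0 | multipliers > 1))
    stop("treatment multipliers must lie in [0, 1]")
  if (kind == "biphasic_early" && is.null(peak_day))
    stop("biphasic_early signals need a peak_day")
  if (!is.null(metabolite_names) && length(metabolite_names) != n_metabolites)
    stop("metabolite_names must have length n_metabolites")
  structure(list(name = name, kind = kind, onset_day = onset_day,
                 peak_day = peak_day, multipliers = multipliers,
                 n_genes = n_genes, n_metabolites = n_metabolites,
                 metabolite_names = metabolite_names, amplitude = amplitude),
            class = "planted_signal")
}

#' Evaluate a planted signal's curve over days
#'
#' @param signal a [planted_signal()].
#' @param days numeric vector of days.
#' @return numeric curve values in \[0, 1\], exactly 0 before the onset.
#' @export
signal_curve <- function(signal, days) {
  d_max <- max(days)
  switch(signal$kind,
    noise = rep(0, length(days)),
    monotone_ripening = days / d_max,
    biphasic_early = {
      on <- signal$onset_day; pk <- signal$peak_day
      ifelse(days <= on, 0,
        ifelse(days <= pk, (days - on) / (pk - on),
               1 - 0.75 * (days - pk) / (d_max - pk)))
    },
    sigmoidal_late = {
      on <- signal$onset_day
      mid <- (on + d_max) / 2
      s <- (d_max - on) / 8
      l <- function(d) 1 / (1 + exp(-(d - mid) / s))
      val <- (l(days) - l(on)) / (l(d_max) - l(on))
      pmax(0, val)
    })
}

#' Default planted signals for the synthetic schema
#'
#' Three signals emulating the study's structure: a CTOL-like biphasic
#' pre-symptomatic marker (onset 14 d, peak 92 d, suppressed by DPA and
#' 1-MCP), a methanol-like late symptomatic marker (onset 61 d, control
#' only, mirrored by methyl-ester metabolites), and a ripening background
#' shared by control and DPA but damped under 1-MCP.
#'
#' @param n_ctol_genes,n_methanol_genes,n_ripening_genes genes per signal.
#' @return a list of [planted_signal()] objects.
#' @export
default_signals <- function(n_ctol_genes = 40, n_methanol_genes = 60,
                            n_ripening_genes = 100) {
  list(
    planted_signal("ctol", "biphasic_early", onset_day = 14, peak_day = 92,
                   multipliers = c(control = 1, DPA = 0.15, MCP = 0.1),
                   n_genes = n_ctol_genes, n_metabolites = 5,
                   metabolite_names = c("CTOL", "farnesene_ox1",
                                        "farnesene_ox2", "MHO",
                                        "triterpene_ox1")),
    planted_signal("methanol", "sigmoidal_late", onset_day = 61,
                   multipliers = c(control = 1, DPA = 0.1, MCP = 0.05),
                   n_genes = n_methanol_genes, n_metabolites = 7,
                   metabolite_names = c("methanol", "methyl_acetate",
                                        "methyl_propanoate",
                                        "methyl_butyrate",
                                        "methyl_2-methylbutyrate",
                                        "methyl_pentanoate",
                                        "methyl_hexanoate")),
    planted_signal("ripening", "monotone_ripening", onset_day = 0,
                   multipliers = c(control = 1, DPA = 1, MCP = 0.3),
                   n_genes = n_ripening_genes, n_metabolites = 10))
}

#' Generate a synthetic two-block storage time-course dataset
#'
#' Builds expression and metabolite blocks over the full
#' (treatment, day, replicate) observation grid. Each feature's log2 level
#' is `baseline + amplitude * curve(day) * multiplier(treatment) + noise`,
#' with baselines drawn log-uniformly, i.i.d. Gaussian noise on the log2
#' scale, and reported values `2^level` (non-negative, RPKM-like). A
#' signal's genes and metabolites share its amplitude, so at vanishing
#' noise any linked gene is exactly proportional to (hence perfectly
#' correlated with) the signal's metabolites on the raw scale. Day-0
#' observations are generated once and shared across treatments
#' (treatments are applied at harvest). The annotation table places each
#' signal's genes in a distinct `planted.<name>` bin and spreads noise
#' genes across generic background bins.
#'
#' @param design a [study_design()].
#' @param n_genes,n_metabolites total features to generate; must cover the
#'   features claimed by `signals`.
#' @param signals list of [planted_signal()]s with unique names.
#' @param noise_sd Gaussian noise standard deviation on the log2 scale.
#' @param seed integer seed; identical inputs give bitwise-identical output.
#' @param n_background_bins number of annotation bins for noise genes.
#' @return a list with elements `expression` and `metabolites`
#'   ([omics_block()]s, samples x variables), `meta` (sample metadata
#'   data.frame), `annotation` (gene_id/bin_path data.frame) and `truth`
#'   (signal definitions, per-feature truth labels, `noise_sd`, `seed`).
#' @examples
#' d <- generate_dataset(n_genes = 50, n_metabolites = 30,
#'                       signals = default_signals(5, 5, 5),
#'                       noise_sd = 0.3, seed = 7)
#' dim(d$expression$values)  # 72 x 50
#' @export
generate_dataset <- function(design = study_design(), n_genes = 2000,
                             n_metabolites = 120,
                             signals = default_signals(),
                             noise_sd = 0.3, seed,
                             n_background_bins = 15) {
  stopifnot(inherits(design, "study_design"), noise_sd > 0)
  if (missing(seed)) stop("a seed is required")
  nm <- vapply(signals, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate signal names: ", paste(nm[duplicated(nm)], collapse = ", "))
  for (s in signals) {
    if (!s$onset_day %in% design$days)
      stop("signal '", s$name, "': onset_day must be one of the design days")
    miss <- setdiff(design$treatments, names(s$multipliers))
    if (length(miss))
      stop("signal '", s$name, "' lacks multipliers for: ",
           paste(miss, collapse = ", "))
  }
  need_g <- sum(vapply(signals, `[[`, numeric(1), "n_genes"))
  need_m <- sum(vapply(signals, `[[`, numeric(1), "n_metabolites"))
  if (need_g > n_genes)
    stop("signals claim ", need_g, " genes but n_genes = ", n_genes)
  if (need_m > n_metabolites)
    stop("signals claim ", need_m, " metabolites but n_metabolites = ",
         n_metabolites)

  # observation grid: treatment-major, then day, then replicate
  grid <- expand.grid(replicate = seq_len(design$replicates_per_cell),
                      day = design$days, treatment = design$treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("treatment", "day", "replicate")]
  grid$sample_id <- sprintf("%s_d%03d_r%d", grid$treatment, grid$day,
                            grid$replicate)
  n_obs <- nrow(grid)

  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  met_ids <- sprintf("M%03d", seq_len(n_metabolites))

  # feature -> signal truth labels, planted features first
  gene_label <- rep("noise", n_genes)
  met_label <- rep("noise", n_metabolites)
  gi <- 0L; mi <- 0L
  for (s in signals) {
    if (s$n_genes > 0) {
      gene_label[gi + seq_len(s$n_genes)] <- s$name
      gi <- gi + s$n_genes
    }
    if (s$n_metabolites > 0) {
      idx <- mi + seq_len(s$n_metabolites)
      met_label[idx] <- s$name
      if (!is.null(s$metabolite_names)) met_ids[idx] <- s$metabolite_names
      mi <- mi + s$n_metabolites
    }
  }
  if (anyDuplicated(met_ids)) stop("metabolite ids collide")
  names(gene_label) <- gene_ids
  names(met_label) <- met_ids

  # per-observation signal value for each signal (log2 units)
  sig_mat <- vapply(signals, function(s) {
    signal_curve(s, grid$day) * s$amplitude *
      unname(s$multipliers[grid$treatment])
  }, numeric(n_obs))
  colnames(sig_mat) <- nm

  sim <- withr::with_seed(seed, {
    base_g <- runif(n_genes, 0, 10)    # log2-uniform baselines, 1..1024
    base_m <- runif(n_metabolites, 0, 10)
    eps_g <- matrix(rnorm(n_obs * n_genes, sd = noise_sd), n_obs, n_genes)
    eps_m <- matrix(rnorm(n_obs * n_metabolites, sd = noise_sd),
                    n_obs, n_metabolites)
    list(base_g = base_g, base_m = base_m, eps_g = eps_g, eps_m = eps_m)
  })

  # share day-0 noise across treatments: pre-treatment state is common
  ref <- design$treatments[1]
  day0_ref <- which(grid$day == 0 & grid$treatment == ref)
  for (tr in design$treatments[-1]) {
    rows <- which(grid$day == 0 & grid$treatment == tr)
    src <- day0_ref[match(grid$replicate[rows], grid$replicate[day0_ref])]
    sim$eps_g[rows, ] <- sim$eps_g[src, ]
    sim$eps_m[rows, ] <- sim$eps_m[src, ]
  }

  build <- function(baselines, labels, eps) {
    log2val <- matrix(rep(baselines, each = n_obs), n_obs, length(baselines))
    planted <- labels != "noise"
    if (any(planted))
      log2val[, planted] <- log2val[, planted] +
        sig_mat[, labels[planted], drop = FALSE]
    2^(log2val + eps)
  }
  expr <- build(sim$base_g, gene_label, sim$eps_g)
  metab <- build(sim$base_m, met_label, sim$eps_m)
  dimnames(expr) <- list(grid$sample_id, gene_ids)
  dimnames(metab) <- list(grid$sample_id, met_ids)

  scald_tab <- scald_scores(design)
  grid$scald <- scald_tab$scald[match(paste(grid$treatment, grid$day),
                                      paste(scald_tab$treatment,
                                            scald_tab$day))]
  meta <- grid[, c("sample_id", "treatment", "day", "replicate", "scald")]
  rownames(meta) <- NULL

  bg_bins <- sprintf("background.b%02d", seq_len(n_background_bins))
  bin_path <- ifelse(gene_label == "noise",
                     bg_bins[(seq_len(n_genes) - 1L) %% n_background_bins + 1L],
                     paste0("planted.", gene_label))
  annotation <- data.frame(gene_id = gene_ids, bin_path = unname(bin_path),
                           stringsAsFactors = FALSE, row.names = NULL)

  list(expression = omics_block(expr, "transcriptome"),
       metabolites = omics_block(metab, "metabolome"),
       meta = meta,
       annotation = annotation,
       truth = list(signals = signals,
                    gene_labels = gene_label,
                    metabolite_labels = met_label,
                    noise_sd = noise_sd,
                    seed = seed))
}

#' Write a generated dataset to a directory of plain-text files
#'
#' Writes `expression.tsv`, `metabolites.tsv` (variables x samples),
#' `metadata.tsv`, `annotation.tsv` and `truth.yaml`.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_block(dataset$expression, file.path(dir, "expression.tsv"))
  write_block(dataset$metabolites, file.path(dir, "metabolites.tsv"))
  write.table(dataset$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$annotation, file.path(dir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  truth$signals <- lapply(truth$signals, function(s) unclass(s))
  truth$gene_labels <- as.list(truth$gene_labels)
  truth$metabolite_labels <- as.list(truth$metabolite_labels)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
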