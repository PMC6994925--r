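#' Study design for the five-group, two-timepoint nerve study
#'
#' Builds the sample sheet of the emulated design: standard diet (SD),
#' high-fat diet (HFD), HFD plus streptozotocin (HFD-STZ), and the two
#' dietary-reversal arms (HFD-DR, HFD-STZ-DR), sampled at 16 and 24 weeks.
#' Reversal groups only exist at 24 weeks (animals are switched back to
#' SD at 16 weeks), so the default design has 8 group-by-timepoint cells.
#'
#' @param n_per_group Samples per (group, timepoint) cell (default 10).
#' @return data.frame with columns \code{sample}, \code{group},
#'   \code{timepoint}.
#' @examples
#' table(study_design()$group, study_design()$timepoint)
#' @export
study_design <- function(n_per_group = 10) {
  stopifnot(is.numeric(n_per_group), n_per_group >= 1)
  n_per_group <- as.integer(n_per_group)
  cells <- rbind(
    expand.grid(group = c("SD", "HFD", "HFD-STZ"),
                timepoint = c("16wk", "24wk"),
                stringsAsFactors = FALSE),
    data.frame(group = c("HFD-DR", "HFD-STZ-DR"), timepoint = "24wk")
  )
  out <- cells[rep(seq_len(nrow(cells)), each = n_per_group), ]
  out$replicate <- rep(seq_len(n_per_group), times = nrow(cells))
  out$sample <- sprintf("%s_%s_%02d", gsub("-", ".", out$group),
                        out$timepoint, out$replicate)
  rownames(out) <- NULL
  out[, c("sample", "group", "timepoint")]
}

#' Groups carrying the disease effect
#' @return Character vector \code{c("HFD", "HFD-STZ")}.
#' @export
disease_groups <- function() c("HFD", "HFD-STZ")

#' Default lipid class composition of the synthetic lipidome
#'
#' Proportions over the 17 classes, TG-dominated as in nerve shotgun
#' lipidomics; they sum to exactly 1.
#' @return Named numeric vector over \code{\link{lipid_classes}()}.
#' @export
default_class_proportions <- function() {
  c(TG = 0.25, PC = 0.15, PE = 0.12, SM = 0.07, DG = 0.05, CE = 0.04,
    FFA = 0.05, PS = 0.05, PI = 0.04, PG = 0.02, PA = 0.02, CL = 0.03,
    ME = 0.02, LPC = 0.03, LPE = 0.02, pPC = 0.02, pPE = 0.02)
}

#' Simulation configuration
#'
#' All tunable parameters of the paired-omics generator. The defaults
#' emulate the scale of the study the pipeline targets: 578 lipid species
#' over 17 classes, ~6000 genes, 10 samples per group, a 1 log2-unit
#' disease shift on half of the TG/DG species that is absent in the
#' reversal groups, 5\% missing lipid entries, and a planted latent factor
#' jointly loading 50 TG species and 30 genes.
#'
#' @param n_lipids Number of unique lipid species (default 578).
#' @param class_proportions Named proportions over the 17 classes,
#'   summing to 1.
#' @param n_genes Number of genes (default 6024).
#' @param n_affected_genes Number of disease-responsive genes (default 60).
#' @param affected_gene_ids Optional explicit ids; overrides
#'   \code{n_affected_genes}.
#' @param disease_effect_size log2 shift applied to affected features in
#'   HFD/HFD-STZ at both timepoints; reversal groups stay at SD level.
#' @param fraction_tg_affected Fraction of TG and DG species affected.
#' @param joint_factor_strength Loading scale of the planted latent
#'   factor, in units of the residual log2 standard deviation; 0 disables
#'   the factor.
#' @param n_joint_lipids,n_joint_genes Support sizes of the planted
#'   factor (50 TG lipids, 30 genes).
#' @param latent_noise sd of the noise added to the standardized disease
#'   indicator to form the latent score.
#' @param missing_rate Fraction of lipid entries set missing completely
#'   at random, in [0, 1).
#' @param dual_mode_fraction Fraction of lipid species measured in both
#'   ion modes (duplicate rows to be merged downstream).
#' @param lipid_sd Residual per-sample sd of log2 lipid intensity.
#' @param nb_dispersion Common negative-binomial dispersion of gene
#'   counts; 0 gives the Poisson limit.
#' @param seed Integer seed; fully determines every generated output.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_lipids = 578,
                       class_proportions = default_class_proportions(),
                       n_genes = 6024,
                       n_affected_genes = 60,
                       affected_gene_ids = NULL,
                       disease_effect_size = 1.0,
                       fraction_tg_affected = 0.5,
                       joint_factor_strength = 2.5,
                       n_joint_lipids = 50,
                       n_joint_genes = 30,
                       latent_noise = 0.3,
                       missing_rate = 0.05,
                       dual_mode_fraction = 0.15,
                       lipid_sd = 0.5,
                       nb_dispersion = 0.05,
                       seed = 1L) {
  cfg <- list(n_lipids = as.integer(n_lipids),
              class_proportions = class_proportions,
              n_genes = as.integer(n_genes),
              n_affected_genes = as.integer(n_affected_genes),
              affected_gene_ids = affected_gene_ids,
              disease_effect_size = disease_effect_size,
              fraction_tg_affected = fraction_tg_affected,
              joint_factor_strength = joint_factor_strength,
              n_joint_lipids = as.integer(n_joint_lipids),
              n_joint_genes = as.integer(n_joint_genes),
              latent_noise = latent_noise,
              missing_rate = missing_rate,
              dual_mode_fraction = dual_mode_fraction,
              lipid_sd = lipid_sd,
              nb_dispersion = nb_dispersion,
              seed = as.integer(seed))
  .validate_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.validate_config <- function(cfg) {
  p <- cfg$class_proportions
  if (is.null(names(p)) || !setequal(names(p), lipid_classes())) {
    stop("class_proportions must be named over the 17 lipid classes",
         call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("class_proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (cfg$n_lipids < length(lipid_classes())) {
    stop("n_lipids must be at least the number of lipid classes",
         call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (cfg$lipid_sd <= 0) stop("lipid_sd must be positive", call. = FALSE)
  if (cfg$nb_dispersion < 0) {
    stop("nb_dispersion must be non-negative", call. = FALSE)
  }
  if (cfg$fraction_tg_affected < 0 || cfg$fraction_tg_affected > 1) {
    stop("fraction_tg_affected must be in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

# ---- acyl chain pools -------------------------------------------------

# core fatty acids mirroring the targeted TLC-GC panel
.core_fa <- c("16:0", "16:1", "18:0", "18:1", "18:2")
.tg_pool <- c(.core_fa, "14:0", "17:0", "20:1", "20:4")
.cl_pool <- c(.core_fa, "14:0", "18:3", "20:4", "20:5", "22:5", "22:6")

.broad_pool <- function() {
  out <- character(0)
  for (c_ in 12:24) {
    dbmax <- if (c_ <= 16) 2 else if (c_ <= 20) 4 else 6
    out <- c(out, sprintf("%d:%d", c_, 0:dbmax))
  }
  out
}

# non-decreasing k-tuples over pool indices (sorted combinations with
# replacement), returned as chain-string matrices
.combos_with_replacement <- function(pool, k) {
  idx <- seq_along(pool)
  combos <- as.matrix(idx)
  if (k > 1) {
    for (j in 2:k) {
      combos <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
        last <- combos[i, j - 1L]
        cbind(matrix(combos[i, ], nrow = length(idx) - last + 1L,
                     ncol = j - 1L, byrow = TRUE),
              last:length(idx))
      }))
    }
  }
  matrix(pool[combos], nrow = nrow(combos))
}

# draw n elements from pool, exhausting `preferred` (in-pool) first
.sample_prefer <- function(pool, preferred, n) {
  pref <- intersect(preferred, pool)
  if (length(pref) >= n) return(sample(pref, n))
  c(pref, sample(setdiff(pool, pref), n - length(pref)))
}

.class_pool <- function(cls) {
  switch(cls,
         TG = .tg_pool,
         DG = .tg_pool,
         CL = .cl_pool,
         .broad_pool())
}

# integer allocation of n over proportions, largest-remainder rounding,
# every class >= 1
.allocate_counts <- function(n, prop) {
  raw <- n * prop / sum(prop)
  cnt <- pmax(1L, floor(raw))
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    add <- rep(seq_along(prop)[ord], length.out = rem)
    for (i in add) cnt[i] <- cnt[i] + 1L
  } else if (rem < 0) {
    ord <- order(cnt, decreasing = TRUE)
    i <- 1L
    while (rem < 0) {
      j <- ord[((i - 1L) %% length(ord)) + 1L]
      if (cnt[j] > 1L) { cnt[j] <- cnt[j] - 1L; rem <- rem + 1L }
      i <- i + 1L
    }
  }
  cnt
}

# deterministic species id catalogue for one class
.make_species <- function(cls, n) {
  k <- .chain_counts[[cls]]
  pool <- .class_pool(cls)
  combos <- .combos_with_replacement(pool, k)
  # canonical order: ascending (carbons, double bonds)
  key <- apply(combos, 1L, function(ch) {
    cd <- do.call(rbind, strsplit(ch, ":", fixed = TRUE))
    ord <- order(as.integer(cd[, 1L]), as.integer(cd[, 2L]))
    paste(ch[ord], collapse = "/")
  })
  key <- unique(key)
  if (length(key) < n) {
    stop("acyl pool for class ", cls, " supports only ", length(key),
         " species; ", n, " requested", call. = FALSE)
  }
  ids <- sample(key, n)
  sprintf("%s(%s)", cls, ids)
}

# class-specific baseline log2 abundance
.class_baseline <- c(
  TG = 13, PC = 13.5, PE = 12.5, SM = 11.5, DG = 11, CE = 10.5,
  FFA = 12, PS = 10.5, PI = 10, PG = 9.5, PA = 9, CL = 9.5, ME = 8.5,
  LPC = 9, LPE = 8.5, pPC = 9.5, pPE = 9
)

#' Simulate a raw shotgun-lipidomics matrix
#'
#' Generates log-normal lipid intensities for the study design: species
#' ids follow the \code{CLASS(c1:d1/...)} grammar, a configurable
#' fraction of TG and DG species (preferring species carrying saturated
#' 16:0/18:0 chains) is shifted up by \code{disease_effect_size} log2
#' units in the HFD and HFD-STZ groups at both timepoints and restored to
#' SD level in the reversal groups, a configurable subset of species is
#' reported in both ion modes (duplicate \code{_pos}/\code{_neg} rows),
#' one internal-standard feature per class is appended, and entries are
#' set missing completely at random at \code{missing_rate}.
#'
#' @param design Sample sheet from \code{\link{study_design}}.
#' @param config A \code{\link{sim_config}}.
#' @return List with elements \code{om} (an \code{\link{omics_matrix}},
#'   stage \code{"raw"}), \code{standards} (named map lipid class ->
#'   standard feature id) and \code{truth} (list: \code{affected_species},
#'   \code{dual_mode_species}).
#' @export
simulate_lipidome <- function(design, config = sim_config()) {
  .validate_config(config)
  set.seed(config$seed + 101L)
  classes <- names(config$class_proportions)
  counts <- .allocate_counts(config$n_lipids, config$class_proportions)
  species <- unlist(lapply(seq_along(classes), function(i) {
    .make_species(classes[i], counts[i])
  }))
  meta <- parse_lipid_id(species)

  # affected TG/DG species: prefer saturated 16:0/18:0 carriers
  affected <- character(0)
  for (cls in c("TG", "DG")) {
    in_cls <- which(meta$lipid_class == cls)
    n_aff <- round(config$fraction_tg_affected * length(in_cls))
    if (n_aff > 0) {
      sat <- vapply(meta$acyl_chains[in_cls], function(ch) {
        if (nrow(ch) == 0) return(0L)
        sum(ch[, "carbons"] %in% c(16L, 18L) & ch[, "double_bonds"] == 0L)
      }, 0L)
      ord <- order(-sat, meta$species_id[in_cls])
      affected <- c(affected, meta$species_id[in_cls][ord[seq_len(n_aff)]])
    }
  }

  n_dual <- round(config$dual_mode_fraction * length(species))
  dual <- if (n_dual > 0) sort(sample(meta$species_id, n_dual)) else character(0)

  # species-level mean log2 intensity
  mu <- .class_baseline[meta$lipid_class] + rnorm(length(species), 0, 1)
  names(mu) <- meta$species_id

  # expand to raw rows: every species has a primary mode, dual species both
  primary <- sample(c("_pos", "_neg"), length(species), replace = TRUE)
  raw_species <- c(meta$species_id,
                   meta$species_id[meta$species_id %in% dual])
  raw_suffix <- c(primary,
                  ifelse(primary[meta$species_id %in% dual] == "_pos",
                         "_neg", "_pos"))
  raw_ids <- paste0(raw_species, raw_suffix)

  n <- nrow(design)
  dis <- design$group %in% disease_groups()
  eff <- outer(raw_species %in% affected, dis) * config$disease_effect_size
  logv <- mu[raw_species] + eff +
    matrix(rnorm(length(raw_ids) * n, 0, config$lipid_sd),
           nrow = length(raw_ids))
  values <- 2^logv

  # internal standards, one per class, near-constant across samples
  std_ids <- paste0("STD_", classes)
  std <- 2^(10 + matrix(rnorm(length(classes) * n, 0, 0.05),
                        nrow = length(classes)))
  values <- rbind(values, std)
  rownames(values) <- c(raw_ids, std_ids)
  colnames(values) <- design$sample

  if (config$missing_rate > 0) {
    n_cells <- length(raw_ids) * n
    miss <- which(runif(n_cells) < config$missing_rate)
    block <- values[seq_along(raw_ids), , drop = FALSE]
    block[miss] <- NA_real_
    # no feature may be missing everywhere
    dead <- which(rowSums(!is.na(block)) == 0L)
    for (f in dead) block[f, 1L] <- 2^(mu[raw_species[f]])
    values[seq_along(raw_ids), ] <- block
  }

  feat <- parse_lipid_id(raw_ids)
  feat$is_standard <- FALSE
  std_feat <- data.frame(
    raw_id = std_ids, species_id = std_ids, lipid_class = classes,
    ion_mode = "merged", total_carbons = NA_integer_,
    total_double_bonds = NA_integer_, resolved = FALSE,
    stringsAsFactors = FALSE
  )
  std_feat$acyl_chains <- rep(list(matrix(integer(0), 0, 2)),
                              length(classes))
  std_feat$is_standard <- TRUE
  feat <- rbind(feat, std_feat[, names(feat)])

  standards <- stats::setNames(std_ids, classes)
  om <- omics_matrix(values, design, features = feat, stage = "raw")
  list(om = om, standards = standards,
       truth = list(affected_species = sort(affected),
                    dual_mode_species = dual))
}

#' Simulate an RNA-seq count matrix
#'
#' Negative-binomial counts with gene-specific log-normal means, a common
#' dispersion, and library sizes varying by +/-30\%. The affected genes
#' are shifted by \code{disease_effect_size} log2 units in HFD/HFD-STZ
#' at both timepoints and restored in the reversal groups. A dispersion
#' of 0 gives the Poisson limit.
#'
#' @inheritParams simulate_lipidome
#' @return List with \code{om} (counts as an \code{\link{omics_matrix}})
#'   and \code{truth} (list: \code{affected_genes}, \code{size_factors}).
#' @export
simulate_transcriptome <- function(design, config = sim_config()) {
  .validate_config(config)
  set.seed(config$seed + 202L)
  genes <- sprintf("gene_%05d", seq_len(config$n_genes))
  affected <- config$affected_gene_ids
  if (is.null(affected)) {
    affected <- sort(sample(genes, min(config$n_affected_genes,
                                       config$n_genes)))
  } else {
    stopifnot(all(affected %in% genes))
  }
  base_mu <- 2^rnorm(config$n_genes, mean = 5, sd = 2)
  sf <- runif(nrow(design), 0.7, 1.3)
  dis <- design$group %in% disease_groups()
  shift <- outer(genes %in% affected, dis) * config$disease_effect_size
  mu <- base_mu * 2^shift
  mu <- sweep(mu, 2L, sf, `*`)
  counts <- if (config$nb_dispersion == 0) {
    matrix(rpois(length(mu), lambda = mu), nrow = config$n_genes)
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
           nrow = config$n_genes)
  }
  rownames(counts) <- genes
  colnames(counts) <- design$sample
  om <- omics_matrix(counts, design, stage = "raw")
  list(om = om, truth = list(affected_genes = affected,
                             size_factors = sf))
}

#' Plant a shared latent factor across the paired matrices
#'
#' Adds rank-one joint covariation on the log2 scale: a per-sample latent
#' score \eqn{s} (the standardized disease indicator plus noise) times
#' sparse positive loading vectors over designated TG lipid species and
#' designated genes. Lipid intensities become \eqn{2^{\log_2 x + s w}};
#' counts are multiplied by \eqn{2^{s w}} and rounded, so a strength of 0
#' leaves both matrices exactly unchanged. The designated support sets
#' and latent scores are returned as ground truth.
#'
#' @param lipid_om,gene_om \code{\link{omics_matrix}} objects sharing the
#'   sample axis (raw lipidome with feature metadata, raw counts).
#' @param config A \code{\link{sim_config}}.
#' @param affected_lipids,affected_genes Optional disease-affected
#'   feature sets; the factor support is drawn from these first (the
#'   latent factor emulates the disease axis, whose lipids and genes are
#'   the disease-responsive ones), topped up from the remaining pool.
#' @return List \code{lipid_om}, \code{gene_om}, \code{truth} (list:
#'   \code{latent_scores}, \code{joint_lipids} (species ids),
#'   \code{joint_genes}).
#' @export
plant_joint_factor <- function(lipid_om, gene_om, config = sim_config(),
                               affected_lipids = NULL,
                               affected_genes = NULL) {
  stopifnot(identical(lipid_om$samples$sample, gene_om$samples$sample))
  set.seed(config$seed + 303L)
  affected_first <- affected_lipids
  affected_genes_first <- affected_genes
  n <- ncol(lipid_om$values)
  dis <- as.numeric(lipid_om$samples$group %in% disease_groups())
  s <- as.numeric(scale(dis)) + rnorm(n, 0, config$latent_noise)

  feat <- lipid_om$features
  tg <- unique(feat$species_id[!feat$is_standard &
                                 feat$lipid_class == "TG"])
  if (config$n_joint_lipids > length(tg)) {
    stop("joint-factor lipid support exceeds available TG species",
         call. = FALSE)
  }
  # the latent factor emulates the disease axis, so its support sits
  # preferentially on the disease-affected features
  joint_lip <- sort(.sample_prefer(tg, affected_first, config$n_joint_lipids))
  genes <- rownames(gene_om$values)
  if (config$n_joint_genes > length(genes)) {
    stop("joint-factor gene support exceeds gene count", call. = FALSE)
  }
  joint_gene <- sort(.sample_prefer(genes, affected_genes_first,
                                    config$n_joint_genes))

  if (config$joint_factor_strength != 0) {
    w_rows <- which(feat$species_id %in% joint_lip)
    w_x <- config$joint_factor_strength * runif(length(w_rows), 0.7, 1.3)
    lv <- lipid_om$values
    lv[w_rows, ] <- 2^(log2(lv[w_rows, , drop = FALSE]) + outer(w_x, s))
    lipid_om <- .update_om(lipid_om, lv, stage = lipid_om$stage)

    g_rows <- which(genes %in% joint_gene)
    w_y <- config$joint_factor_strength * runif(length(g_rows), 0.7, 1.3)
    gv <- gene_om$values
    gv[g_rows, ] <- round(gv[g_rows, , drop = FALSE] * 2^outer(w_y, s))
    gene_om <- .update_om(gene_om, gv, stage = gene_om$stage)
  }
  list(lipid_om = lipid_om, gene_om = gene_om,
       truth = list(latent_scores = stats::setNames(
         s, lipid_om$samples$sample),
         joint_lipids = joint_lip, joint_genes = joint_gene))
}

#' Simulate a gene-lipid annotation table and gene sets
#'
#' Emulates a curated lipid-gene association resource: a two-column pair
#' table linking an annotated gene subset (always including the planted
#' joint-factor genes, linked to planted lipids) to lipid species, plus
#' GMT-style gene sets of which one is enriched in the disease-affected
#' genes.
#'
#' @param lipid_species Character vector of (merged) lipid species ids.
#' @param gene_ids Character vector of gene ids.
#' @param truth Ground-truth list from \code{\link{simulate_study}} parts
#'   (\code{affected_genes}, \code{joint_genes}, \code{joint_lipids}).
#' @param config A \code{\link{sim_config}}.
#' @param n_annotated Total number of annotated genes (default 100).
#' @return List with \code{pairs} (data.frame gene, lipid) and
#'   \code{gene_sets} (named list of gene id vectors).
#' @export
simulate_annotation <- function(lipid_species, gene_ids, truth,
                                config = sim_config(),
                                n_annotated = 100) {
  set.seed(config$seed + 404L)
  n_annotated <- min(n_annotated, length(gene_ids))
  core <- unique(c(truth$joint_genes,
                   utils::head(truth$affected_genes, 20)))
  core <- intersect(core, gene_ids)
  extra <- setdiff(gene_ids, core)
  annotated <- c(core, sample(extra, max(0, n_annotated - length(core))))

  joint_lip <- intersect(truth$joint_lipids, lipid_species)
  pairs <- do.call(rbind, lapply(annotated, function(g) {
    if (g %in% truth$joint_genes && length(joint_lip) > 0) {
      lip <- sample(joint_lip, min(3L, length(joint_lip)))
    } else {
      lip <- sample(lipid_species, sample(1:4, 1L))
    }
    data.frame(gene = g, lipid = lip, stringsAsFactors = FALSE)
  }))
  pairs <- unique(pairs)
  rownames(pairs) <- NULL

  gene_sets <- list(
    lipid_metabolism = truth$affected_genes,
    joint_factor_module = truth$joint_genes,
    random_set_1 = sort(sample(gene_ids, min(30, length(gene_ids)))),
    random_set_2 = sort(sample(gene_ids, min(30, length(gene_ids))))
  )
  list(pairs = pairs, gene_sets = gene_sets)
}

#' Simulate a complete paired-omics study
#'
#' Convenience wrapper running \code{\link{simulate_lipidome}},
#' \code{\link{simulate_transcriptome}}, \code{\link{plant_joint_factor}}
#' and \code{\link{simulate_annotation}} under one seed, returning the
#' datasets together with the full ground-truth record needed to score
#' recovery in every downstream module.
#'
#' @inheritParams simulate_lipidome
#' @return Object of class \code{lipidnet_sim}: list with \code{lipids}
#'   (raw \code{omics_matrix}), \code{genes} (count
#'   \code{omics_matrix}), \code{standards}, \code{annotation},
#'   \code{gene_sets}, \code{design}, \code{config} and \code{truth}.
#' @examples
#' sim <- simulate_study(study_design(3), sim_config(n_lipids = 60,
#'   n_genes = 150, n_joint_lipids = 5, n_joint_genes = 5, seed = 7))
#' sim$lipids
#' @export
simulate_study <- function(design = study_design(),
                           config = sim_config()) {
  lip <- simulate_lipidome(design, config)
  gen <- simulate_transcriptome(design, config)
  pl <- plant_joint_factor(lip$om, gen$om, config,
                           affected_lipids = lip$truth$affected_species,
                           affected_genes = gen$truth$affected_genes)
  truth <- c(lip$truth, gen$truth, pl$truth)
  ann <- simulate_annotation(
    unique(lip$om$features$species_id[!lip$om$features$is_standard]),
    rownames(gen$om$values), truth, config)
  structure(list(lipids = pl$lipid_om, genes = pl$gene_om,
                 standards = lip$standards, annotation = ann$pairs,
                 gene_sets = ann$gene_sets, design = design,
                 config = config, truth = truth),
            class = "lipidnet_sim")
}

#' @export
print.lipidnet_sim <- function(x, ...) {
  cat("Synthetic paired-omics study\n")
  cat(sprintf("  lipid features (raw rows): %d (%d species, %d standards)\n",
              nrow(x$lipids$values),
              length(unique(x$lipids$features$species_id[
                !x$lipids$features$is_standard])),
              sum(x$lipids$features$is_standard)))
  cat(sprintf("  genes: %d; samples: %d\n", nrow(x$genes$values),
              nrow(x$design)))
  cat(sprintf("  affected: %d lipid species, %d genes; joint factor: %d lipids, %d genes\n",
              length(x$truth$affected_species),
              length(x$truth$affected_genes),
              length(x$truth$joint_lipids), length(x$truth$joint_genes)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Persists the generator output in plain-text formats: lipid and gene
#' matrices as feature-by-sample TSV (first column the feature id),
#' sample sheet TSV, annotation pair TSV, standard GMT gene sets and a
#' ground-truth JSON.
#'
#' @param sim A \code{\link{simulate_study}} result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    lipids = file.path(dir, "lipids_raw.tsv"),
    genes = file.path(dir, "gene_counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    annotation = file.path(dir, "annotation_pairs.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_omics_matrix(sim$lipids, paths[["lipids"]])
  write_omics_matrix(sim$genes, paths[["genes"]])
  utils::write.table(sim$design, paths[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(sim$gene_sets, paths[["gmt"]])
  truth <- sim$truth
  truth$standards <- as.list(sim$standards)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
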