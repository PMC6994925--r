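#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis. With
#' \code{simulate = TRUE} (the default) the inputs are generated by
#' \code{\link{simulate_study}} from \code{sim}; otherwise the four file
#' paths must point to existing inputs.
#'
#' @param seed Master seed; flows into the simulation and
#'   cross-validation substreams.
#' @param simulate Generate inputs with the synthetic module (default
#'   TRUE).
#' @param sim A \code{\link{sim_config}} (its seed is forced to
#'   \code{seed}).
#' @param n_per_group Samples per design cell for the simulated design.
#' @param lipids,genes,samples,annotation,gmt Input file paths (used
#'   when \code{simulate = FALSE}).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param knn_k KNN imputation neighbours (default 10).
#' @param K,nx,ny O2PLS components (default 2/2/2, six in total).
#' @param p_keep,min_keep Transcript pre-filter settings (see
#'   \code{\link{filter_transcripts}}).
#' @param cor_threshold Network |r| threshold (default 0.6).
#' @param subnetwork_method \code{"modularity"} or \code{"components"}.
#' @param large_size Optional large-subnetwork threshold override.
#' @param network_gene_pool \code{"retained"} (all O2PLS-retained
#'   transcripts) or \code{"top"} (top gene candidates only) as the
#'   candidate pool for the annotation filter.
#' @param top_lipids,top_genes Candidate list sizes (50 / 100).
#' @param outdir Optional output directory for intermediates and the
#'   report.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, simulate = TRUE,
                       sim = sim_config(seed = seed),
                       n_per_group = 10,
                       lipids = NULL, genes = NULL, samples = NULL,
                       annotation = NULL, gmt = NULL,
                       alpha = 0.05, knn_k = 10,
                       K = 2, nx = 2, ny = 2,
                       p_keep = 0.05, min_keep = 100,
                       cor_threshold = 0.6,
                       subnetwork_method = "modularity",
                       large_size = NULL,
                       network_gene_pool = c("retained", "top"),
                       top_lipids = 50, top_genes = 100,
                       outdir = NULL) {
  stopifnot(alpha > 0, alpha <= 1, knn_k >= 1, cor_threshold >= 0,
            cor_threshold < 1)
  network_gene_pool <- match.arg(network_gene_pool)
  sim$seed <- as.integer(seed)
  if (!simulate) {
    for (f in c(lipids, genes, samples)) {
      if (is.null(f) || !file.exists(f)) {
        stop("input file missing: ", f, call. = FALSE)
      }
    }
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full lipidome-transcriptome analysis
#'
#' Executes the pipeline end to end: simulation (or file input),
#' lipidomics preprocessing (KNN imputation, internal-standard
#' normalisation, ion-mode merging), differential lipid and gene
#' analysis with disease/reversal overlap classification and gene-set
#' enrichment, O2PLS integration with candidate extraction, and the
#' annotation-filtered correlation network with subnetwork detection and
#' reversal annotation. All stage funnel counts are collected in the
#' returned report; with \code{config$outdir} set, intermediates and the
#' report (JSON and text) are persisted.
#'
#' @param config A \code{\link{run_config}}.
#' @return Object of class \code{lipidnet_report} (a nested list of
#'   counts, tables and candidate lists; see the vignette).
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  tryCatch({
    # ---- input --------------------------------------------------------
    if (config$simulate) {
      sim <- simulate_study(study_design(config$n_per_group),
                            config$sim)
      lipid_raw <- sim$lipids
      gene_om <- sim$genes
      standards <- sim$standards
      annotation <- sim$annotation
      gene_sets <- sim$gene_sets
    } else {
      sheet <- read_sample_sheet(config$samples)
      lipid_raw <- read_omics_matrix(config$lipids, sheet)
      gene_om <- read_omics_matrix(config$genes, sheet)
      std_ids <- grep("^STD_", rownames(lipid_raw$values), value = TRUE)
      standards <- if (length(std_ids) > 0) {
        stats::setNames(std_ids, sub("^STD_", "", std_ids))
      } else {
        NULL
      }
      lipid_raw <- .attach_lipid_features(lipid_raw, std_ids)
      annotation <- if (!is.null(config$annotation)) {
        read_annotation_pairs(config$annotation)
      } else {
        data.frame(gene = character(0), lipid = character(0))
      }
      gene_sets <- if (!is.null(config$gmt)) read_gmt(config$gmt) else
        list()
    }

    # ---- preprocessing ------------------------------------------------
    stage <- "preprocess"
    imputed <- knn_impute(lipid_raw, k = config$knn_k)
    normalized <- if (!is.null(standards)) {
      normalize_internal_standard(imputed, standards)
    } else {
      .update_om(imputed, imputed$values, stage = "normalized")
    }
    merged <- merge_ion_modes(normalized)
    tg_sum <- class_sum(merged, "TG")

    # ---- differential -------------------------------------------------
    stage <- "differential"
    comparisons <- list(
      c("HFD", "SD", "16wk"), c("HFD-STZ", "SD", "16wk"),
      c("HFD", "SD", "24wk"), c("HFD-STZ", "SD", "24wk"),
      c("HFD-DR", "HFD", "24wk"), c("HFD-STZ-DR", "HFD-STZ", "24wk")
    )
    dal <- lapply(comparisons, function(cc) {
      dal_analysis(merged, cc[1], cc[2], cc[3], alpha = config$alpha)
    })
    n_genes_input <- nrow(gene_om$values)
    # one gene universe across comparisons: drop genes with zero counts
    # inside any comparison's sample set
    expressed <- Reduce(`&`, lapply(comparisons, function(cc) {
      cols <- .sample_idx(gene_om, cc[1:2], cc[3])
      rowSums(gene_om$values[, cols, drop = FALSE]) > 0
    }))
    gene_om <- omics_matrix(
      gene_om$values[expressed, , drop = FALSE], gene_om$samples,
      stage = gene_om$stage)
    deg <- lapply(comparisons, function(cc) {
      nb_wald_deg(gene_om, cc[1], cc[2], cc[3], alpha = config$alpha)
    })
    names(dal) <- names(deg) <- vapply(comparisons, function(cc) {
      paste0(cc[1], " vs ", cc[2], " @", cc[3])
    }, "")

    ov_lip_pre <- overlap_analysis(dal[[3]], dal[[5]],
                                   features = merged$features)
    ov_lip_t2d <- overlap_analysis(dal[[4]], dal[[6]],
                                   features = merged$features)
    cross_lip <- cross_model_common(ov_lip_pre, ov_lip_t2d,
                                    features = merged$features)
    ov_deg_pre <- overlap_analysis(deg[[3]], deg[[5]])
    ov_deg_t2d <- overlap_analysis(deg[[4]], deg[[6]])

    universe <- rownames(gene_om$values)[rowSums(gene_om$values) > 0]
    enr <- if (length(gene_sets) > 0) {
      list(
        prediabetic = enrichment(
          intersect(ov_deg_pre$common$feature, universe), gene_sets,
          universe),
        t2d = enrichment(
          intersect(ov_deg_t2d$common$feature, universe), gene_sets,
          universe)
      )
    } else {
      NULL
    }

    # ---- O2PLS integration -------------------------------------------
    stage <- "o2pls"
    gene_filt <- filter_transcripts(gene_om, deg,
                                    p_keep = config$p_keep,
                                    min_keep = config$min_keep)
    Xs <- scale_transform(merged)
    Ys <- scale_transform(gene_filt)
    fit <- o2pls(Xs, Ys, K = config$K, nx = config$nx, ny = config$ny)
    top_lip <- top_loadings(fit, "x", config$top_lipids)
    top_gene <- top_loadings(fit, "y", config$top_genes)

    # ---- network ------------------------------------------------------
    stage <- "network"
    lipid_mat <- t(Xs)
    gene_mat <- t(Ys)
    pool <- if (config$network_gene_pool == "retained") {
      rownames(gene_mat)
    } else {
      top_gene$feature
    }
    filt <- filter_genes_by_annotation(annotation, pool,
                                       rownames(lipid_mat))
    edges <- pearson_edges(lipid_mat, gene_mat,
                           gene_set = filt$gene_set,
                           threshold = config$cor_threshold)
    net <- suppressWarnings(build_network(edges))
    sub <- if (igraph::vcount(net) > 0) {
      detect_subnetworks(net, method = config$subnetwork_method,
                         large_size = config$large_size)
    } else {
      NULL
    }
    if (igraph::vcount(net) > 0) {
      net <- annotate_reversal(net, list(ov_lip_pre, ov_lip_t2d,
                                         ov_deg_pre, ov_deg_t2d))
      igraph::V(net)$is_top_o2pls <-
        igraph::V(net)$name %in% c(top_lip$feature, top_gene$feature)
      igraph::V(net)$subnetwork <-
        unname(sub$membership[igraph::V(net)$name])
    }

    # ---- report -------------------------------------------------------
    stage <- "report"
    kind <- if (igraph::vcount(net) > 0) igraph::V(net)$kind else
      character(0)
    report <- list(
      software = list(package = "lipidnet",
                      version = as.character(
                        utils::packageVersion("lipidnet"))),
      config = .echo_config(config),
      funnel = list(
        n_raw_lipid_rows = sum(!lipid_raw$features$is_standard),
        n_lipid_species = nrow(merged$values),
        n_genes_input = n_genes_input,
        n_genes_expressed = nrow(gene_om$values),
        n_genes_retained_o2pls = attr(gene_filt, "n_retained"),
        n_genes_annotated = filt$n_annotated,
        n_genes_annotated_and_retained = filt$n_after_candidates,
        n_network_lipid_nodes = sum(kind == "lipid"),
        n_network_gene_nodes = sum(kind == "gene")
      ),
      dal_counts = vapply(dal, function(r) sum(r$significant), 0L),
      deg_counts = vapply(deg, function(r) sum(r$significant), 0L),
      overlaps = list(
        lipid_prediabetic = .overlap_summary(ov_lip_pre),
        lipid_t2d = .overlap_summary(ov_lip_t2d),
        deg_prediabetic = .overlap_summary(ov_deg_pre),
        deg_t2d = .overlap_summary(ov_deg_t2d),
        cross_model = list(n = cross_lip$n,
                           class_counts = as.list(
                             if (is.null(cross_lip$class_counts))
                               integer(0) else cross_lip$class_counts),
                           shared = cross_lip$shared)
      ),
      enrichment = lapply(enr, function(e) {
        e[, c("set", "n_set", "n_overlap", "p", "q")]
      }),
      o2pls = list(
        components = c(K = config$K, nx = config$nx, ny = config$ny),
        variance = variance_decomposition(fit),
        top_lipids = top_lip,
        top_genes = top_gene
      ),
      network = list(
        n_nodes = igraph::vcount(net),
        n_edges = igraph::ecount(net),
        n_subnetworks = if (is.null(sub)) 0L else sub$n_subnetworks,
        n_large_subnetworks = if (is.null(sub)) 0L else
          sum(sub$sizes$large),
        large_size_threshold = if (is.null(sub)) NA else
          sub$large_size,
        tg_class_sum = tg_sum$summary
      )
    )
    report <- structure(report, class = "lipidnet_report")
    if (!is.null(config$outdir)) {
      .persist_run(config$outdir, merged, gene_filt, dal, deg, fit,
                   net, report)
    }
    report
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

.attach_lipid_features <- function(om, std_ids) {
  ids <- rownames(om$values)
  feat_ids <- setdiff(ids, std_ids)
  feat <- parse_lipid_id(feat_ids)
  feat$is_standard <- FALSE
  if (length(std_ids) > 0) {
    sf <- data.frame(raw_id = std_ids, species_id = std_ids,
                     lipid_class = sub("^STD_", "", std_ids),
                     ion_mode = "merged", total_carbons = NA_integer_,
                     total_double_bonds = NA_integer_, resolved = FALSE,
                     stringsAsFactors = FALSE)
    sf$acyl_chains <- rep(list(matrix(integer(0), 0, 2)),
                          length(std_ids))
    sf$is_standard <- TRUE
    feat <- rbind(feat, sf[, names(feat)])
  }
  feat <- feat[match(ids, feat$raw_id), , drop = FALSE]
  rownames(feat) <- NULL
  omics_matrix(om$values, om$samples, features = feat, stage = om$stage)
}

.overlap_summary <- function(ov) {
  dirs <- table(factor(ov$common$direction,
                       levels = c("increased_with_disease",
                                  "decreased_with_reversal",
                                  "discordant")))
  list(disease = ov$disease_comparison,
       reversal = ov$reversal_comparison,
       n_disease_significant = ov$n_disease_significant,
       n_reversal_significant = ov$n_reversal_significant,
       n_common = nrow(ov$common),
       direction = as.list(dirs),
       class_breakdown = as.list(
         if (is.null(ov$class_breakdown)) integer(0) else
           ov$class_breakdown))
}

.echo_config <- function(config) {
  keep <- c("seed", "simulate", "n_per_group", "alpha", "knn_k", "K",
            "nx", "ny", "p_keep", "min_keep", "cor_threshold",
            "subnetwork_method", "network_gene_pool", "top_lipids",
            "top_genes")
  echo <- config[keep]
  echo$sim <- unclass(config$sim)
  echo$sim$affected_gene_ids <- NULL
  echo$sim$class_proportions <- as.list(echo$sim$class_proportions)
  echo
}

.persist_run <- function(outdir, merged, gene_filt, dal, deg, fit, net,
                         report) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_omics_matrix(merged, file.path(outdir, "lipids_merged.tsv"))
  write_omics_matrix(gene_filt, file.path(outdir,
                                          "genes_retained.tsv"))
  for (nm in names(dal)) {
    fn <- gsub("[^A-Za-z0-9]+", "_", nm)
    write_differential(dal[[nm]],
                       file.path(outdir, paste0("dal_", fn, ".tsv")))
    write_differential(deg[[nm]],
                       file.path(outdir, paste0("deg_", fn, ".tsv")))
  }
  utils::write.table(report$o2pls$top_lipids,
                     file.path(outdir, "o2pls_top_lipids.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$o2pls$top_genes,
                     file.path(outdir, "o2pls_top_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (igraph::vcount(net) > 0) {
    write_network(net, graphml = file.path(outdir, "network.graphml"),
                  edgelist = file.path(outdir, "network_edges.tsv"))
  }
  write_report(report, file.path(outdir, "report.json"))
  writeLines(utils::capture.output(print(report)),
             file.path(outdir, "report.txt"))
  invisible(outdir)
}

#' Serialise a run report to JSON
#'
#' Deterministic serialisation (fixed precision, no timestamps): two
#' runs with the same configuration and seed produce byte-identical
#' files.
#'
#' @param report A \code{lipidnet_report}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(report, path) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                           digits = 10, pretty = TRUE, na = "null")
  writeLines(json, path)
  invisible(path)
}

#' @export
print.lipidnet_report <- function(x, ...) {
  cat("lipidnet run report\n")
  cat(sprintf("  lipid species: %d (from %d raw rows); genes: %d\n",
              x$funnel$n_lipid_species, x$funnel$n_raw_lipid_rows,
              x$funnel$n_genes_input))
  cat("  significant DALs per comparison:\n")
  for (nm in names(x$dal_counts)) {
    cat(sprintf("    %-28s %d\n", nm, x$dal_counts[[nm]]))
  }
  cat("  significant DEGs per comparison:\n")
  for (nm in names(x$deg_counts)) {
    cat(sprintf("    %-28s %d\n", nm, x$deg_counts[[nm]]))
  }
  ol <- x$overlaps$lipid_prediabetic
  cat(sprintf("  prediabetic common DALs: %d (%d up with disease, %d down with reversal)\n",
              ol$n_common, ol$direction$increased_with_disease,
              ol$direction$decreased_with_reversal))
  ol <- x$overlaps$lipid_t2d
  cat(sprintf("  T2D common DALs: %d; cross-model: %d\n",
              ol$n_common, x$overlaps$cross_model$n))
  cat(sprintf("  O2PLS retained genes: %d; joint R2 X=%.2f Y=%.2f\n",
              x$funnel$n_genes_retained_o2pls,
              x$o2pls$variance$joint[1], x$o2pls$variance$joint[2]))
  cat(sprintf("  annotation funnel: %d annotated -> %d after candidate filter\n",
              x$funnel$n_genes_annotated,
              x$funnel$n_genes_annotated_and_retained))
  cat(sprintf("  network: %d nodes (%d lipids, %d genes), %d edges, %d subnetworks (%d large)\n",
              x$network$n_nodes, x$funnel$n_network_lipid_nodes,
              x$funnel$n_network_gene_nodes, x$network$n_edges,
              x$network$n_subnetworks, x$network$n_large_subnetworks))
  invisible(x)
}
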