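#' Pearson correlation edges between lipids and genes
#'
#' Computes all lipid-lipid and lipid-gene Pearson correlations across
#' the configured samples and keeps pairs with \eqn{|r|} strictly above
#' the threshold. Gene-gene pairs are never emitted; self-pairs are
#' excluded; constant features are skipped with a message.
#'
#' @param lipid_mat Feature-by-sample lipid matrix (merged species).
#' @param gene_mat Optional feature-by-sample gene matrix over the same
#'   samples.
#' @param gene_set Optional subset of gene ids to use (e.g. the
#'   annotation-filtered set).
#' @param threshold Absolute-correlation threshold (default 0.6).
#' @return data.frame \code{from}, \code{to}, \code{r}, \code{kind}
#'   (\code{"lipid-lipid"} or \code{"lipid-gene"}).
#' @export
pearson_edges <- function(lipid_mat, gene_mat = NULL, gene_set = NULL,
                          threshold = 0.6) {
  stopifnot(is.matrix(lipid_mat))
  if (!is.null(gene_mat)) {
    stopifnot(identical(colnames(lipid_mat), colnames(gene_mat)))
    if (!is.null(gene_set)) {
      missing <- setdiff(gene_set, rownames(gene_mat))
      if (length(missing) > 0) {
        stop("gene_set members absent from gene matrix: ",
             missing[1L], call. = FALSE)
      }
      gene_mat <- gene_mat[rownames(gene_mat) %in% gene_set, ,
                           drop = FALSE]
    }
  }
  drop_constant <- function(m, label) {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0)) {
      message("skipping ", sum(sds == 0), " constant ", label,
              " feature(s)")
      m <- m[sds > 0, , drop = FALSE]
    }
    m
  }
  lipid_mat <- drop_constant(lipid_mat, "lipid")
  edges <- list()
  cl <- stats::cor(t(lipid_mat))
  keep <- which(upper.tri(cl) & abs(cl) > threshold, arr.ind = TRUE)
  if (nrow(keep) > 0) {
    edges$ll <- data.frame(
      from = rownames(cl)[keep[, 1L]], to = rownames(cl)[keep[, 2L]],
      r = cl[keep], kind = "lipid-lipid", stringsAsFactors = FALSE)
  }
  if (!is.null(gene_mat) && nrow(gene_mat) > 0) {
    gene_mat <- drop_constant(gene_mat, "gene")
    if (nrow(gene_mat) > 0) {
      cg <- stats::cor(t(lipid_mat), t(gene_mat))
      keep <- which(abs(cg) > threshold, arr.ind = TRUE)
      if (nrow(keep) > 0) {
        edges$lg <- data.frame(
          from = rownames(cg)[keep[, 1L]],
          to = colnames(cg)[keep[, 2L]],
          r = cg[keep], kind = "lipid-gene", stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), r = numeric(0),
               kind = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Annotation filter for network genes
#'
#' Two-stage gene filter mirroring curated-association network
#' construction: genes annotated to at least one lipid of the network's
#' lipid set, then intersected with the integration-retained candidate
#' genes. Both stage counts are reported.
#'
#' @param annotation data.frame with columns \code{gene}, \code{lipid}.
#' @param candidate_genes Genes retained by the integration step.
#' @param network_lipids Lipid species ids in the network.
#' @return List: \code{gene_set}, \code{n_annotated} (stage-1 count),
#'   \code{n_after_candidates} (stage-2 count).
#' @export
filter_genes_by_annotation <- function(annotation, candidate_genes,
                                       network_lipids) {
  stopifnot(all(c("gene", "lipid") %in% names(annotation)))
  ann <- unique(annotation[annotation$lipid %in% network_lipids,
                           "gene"])
  gene_set <- sort(intersect(ann, candidate_genes))
  if (length(gene_set) == 0) {
    message("annotation filter produced an empty gene set")
  }
  list(gene_set = gene_set, n_annotated = length(unique(ann)),
       n_after_candidates = length(gene_set))
}

#' Build the correlation network graph
#'
#' Undirected simple graph over all edge-incident nodes (isolated
#' features are excluded by construction), with vertex attribute
#' \code{kind} (\code{"lipid"} or \code{"gene"}) and edge attribute
#' \code{r}. Duplicate edges are collapsed keeping the first
#' correlation.
#'
#' @param edges Edge data.frame from \code{\link{pearson_edges}}.
#' @return An \code{igraph} graph.
#' @export
build_network <- function(edges) {
  if (nrow(edges) == 0) {
    warning("empty edge list; returning empty network")
    return(igraph::make_empty_graph(directed = FALSE))
  }
  key <- ifelse(edges$from < edges$to,
                paste(edges$from, edges$to, sep = "\r"),
                paste(edges$to, edges$from, sep = "\r"))
  edges <- edges[!duplicated(key), , drop = FALSE]
  gene_nodes <- unique(edges$to[edges$kind == "lipid-gene"])
  g <- igraph::graph_from_data_frame(edges[, c("from", "to", "r",
                                               "kind")],
                                     directed = FALSE)
  # deterministic lexicographic vertex order
  g <- igraph::permute(g, match(igraph::V(g)$name,
                                sort(igraph::V(g)$name)))
  igraph::V(g)$kind <- ifelse(igraph::V(g)$name %in% gene_nodes,
                              "gene", "lipid")
  kind <- stats::setNames(igraph::V(g)$kind, igraph::V(g)$name)
  ep <- igraph::ends(g, igraph::E(g))
  stopifnot(!any(kind[ep[, 1L]] == "gene" & kind[ep[, 2L]] == "gene"))
  g
}

#' Detect subnetworks
#'
#' Partitions the network into highly interconnected node groups:
#' greedy-modularity communities (default; deterministic given the
#' graph's lexicographic vertex order, unweighted) or connected
#' components. Subnetworks of at least \code{large_size} nodes are
#' flagged large; the default threshold is
#' \code{max(24, ceiling(0.10 * node count))}.
#'
#' @param g Network graph from \code{\link{build_network}}.
#' @param method \code{"modularity"} or \code{"components"}.
#' @param large_size Optional explicit large-subnetwork threshold.
#' @return List: \code{membership} (named integer vector),
#'   \code{sizes} (data.frame subnetwork, size, large),
#'   \code{n_subnetworks}, \code{large_size}.
#' @export
detect_subnetworks <- function(g, method = c("modularity",
                                             "components"),
                               large_size = NULL) {
  method <- match.arg(method)
  if (igraph::vcount(g) == 0) stop("empty network", call. = FALSE)
  memb <- if (method == "components") {
    igraph::components(g)$membership
  } else {
    gs <- igraph::simplify(g, edge.attr.comb = "first")
    fg <- igraph::membership(igraph::cluster_fast_greedy(gs,
                                                         weights = NULL))
    comp <- igraph::components(g)$membership
    # keep the greedy split only where it strictly beats the plain
    # component partition (ties resolve to the coarser partition)
    if (igraph::modularity(gs, fg) >
          igraph::modularity(gs, comp)) fg else comp
  }
  memb <- stats::setNames(as.integer(memb), igraph::V(g)$name)
  # renumber by decreasing size, ties by smallest member name
  tab <- table(memb)
  first_name <- vapply(names(tab), function(m) {
    min(names(memb)[memb == as.integer(m)])
  }, "")
  ord <- names(tab)[order(-as.integer(tab), first_name)]
  memb <- stats::setNames(match(as.character(memb), ord), names(memb))
  if (is.null(large_size)) {
    large_size <- max(24, ceiling(0.10 * igraph::vcount(g)))
  }
  sizes <- as.integer(table(memb))
  sizes_df <- data.frame(subnetwork = seq_along(sizes), size = sizes,
                         large = sizes >= large_size)
  list(membership = memb, sizes = sizes_df,
       n_subnetworks = length(sizes), large_size = large_size)
}

#' Annotate network nodes with dietary-reversal status
#'
#' A node is \code{reversed_up_in_disease} when it is a common
#' differential feature (significant in both the disease and the
#' reversal comparison) with positive disease log2 fold change in either
#' disease model, \code{reversed_down_in_disease} with negative fold
#' change, else \code{not_reversed}. Conflicting directions across
#' models are resolved towards the larger |log2FC| and logged.
#'
#' @param g Network graph.
#' @param overlaps List of \code{\link{overlap_analysis}} results (one
#'   per disease model).
#' @return The graph with vertex attribute \code{reversal_status}; the
#'   attribute \code{"reversal_conflicts"} lists conflicted nodes.
#' @export
annotate_reversal <- function(g, overlaps) {
  status <- stats::setNames(rep("not_reversed", igraph::vcount(g)),
                            igraph::V(g)$name)
  best_fc <- stats::setNames(rep(0, igraph::vcount(g)),
                             igraph::V(g)$name)
  conflicts <- character(0)
  for (ov in overlaps) {
    cm <- ov$common
    hit <- intersect(cm$feature, names(status))
    for (f in hit) {
      fc <- cm$disease_log2fc[cm$feature == f]
      new_status <- if (fc > 0) "reversed_up_in_disease" else
        "reversed_down_in_disease"
      if (status[f] != "not_reversed" && status[f] != new_status) {
        conflicts <- c(conflicts, f)
        message("conflicting reversal direction for '", f,
                "'; using larger |log2FC|")
        if (abs(fc) > abs(best_fc[f])) {
          status[f] <- new_status; best_fc[f] <- fc
        }
      } else if (abs(fc) > abs(best_fc[f]) ||
                 status[f] == "not_reversed") {
        status[f] <- new_status; best_fc[f] <- fc
      }
    }
  }
  igraph::V(g)$reversal_status <- unname(status[igraph::V(g)$name])
  attr(g, "reversal_conflicts") <- unique(conflicts)
  g
}

#' Export a network to GraphML and edge-list TSV
#'
#' @param g Network graph (attributes are preserved in the GraphML).
#' @param graphml Path for the GraphML file (skipped if NULL).
#' @param edgelist Path for a plain \code{from to r kind} TSV (skipped
#'   if NULL).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(g, graphml = NULL, edgelist = NULL) {
  if (!is.null(graphml)) {
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(edgelist)) {
    ends <- igraph::ends(g, igraph::E(g))
    df <- data.frame(from = ends[, 1L], to = ends[, 2L],
                     r = igraph::E(g)$r, kind = igraph::E(g)$kind,
                     stringsAsFactors = FALSE)
    utils::write.table(df, edgelist, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml = graphml, edgelist = edgelist))
}
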