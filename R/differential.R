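#' Two-sample Student's t-test on one feature
#'
#' Pooled-variance (equal-variance) two-sided t-test between two groups,
#' with the log2 fold change computed from the group means
#' (\eqn{\log_2(\bar{x}_A/\bar{x}_B)}, requiring positive means). A
#' Welch test is available behind \code{var_equal = FALSE}.
#'
#' @param om An \code{\link{omics_matrix}}.
#' @param feature Feature id (row name).
#' @param group_a,group_b Group labels (group A is the numerator of the
#'   fold change).
#' @param timepoint Optional timepoint restriction.
#' @param var_equal Pooled-variance Student form (default TRUE).
#' @return List: \code{t}, \code{p}, \code{log2fc}, \code{mean_a},
#'   \code{mean_b}, \code{n_a}, \code{n_b}.
#' @export
t_test_feature <- function(om, feature, group_a, group_b,
                           timepoint = NULL, var_equal = TRUE) {
  stopifnot(inherits(om, "omics_matrix"))
  if (!feature %in% rownames(om$values)) {
    stop("unknown feature '", feature, "'", call. = FALSE)
  }
  a <- om$values[feature, .sample_idx(om, group_a, timepoint)]
  b <- om$values[feature, .sample_idx(om, group_b, timepoint)]
  .t_test_vec(a, b)
}

.t_test_vec <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      stop("zero within-group variance with equal means", call. = FALSE)
    }
    tt <- list(statistic = c(t = sign(mean(a) - mean(b)) * Inf),
               p.value = 0)
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  log2fc <- if (mean(a) > 0 && mean(b) > 0) {
    log2(mean(a) / mean(b))
  } else {
    NA_real_
  }
  list(t = unname(tt$statistic), p = tt$p.value, log2fc = log2fc,
       mean_a = mean(a), mean_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' \eqn{q_i = \min_{j \ge i}(p_{(j)} m / j)} over ascending p-values
#' (delegating to \code{stats::p.adjust}), with input validation.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Differentially altered lipid (DAL) analysis
#'
#' Per-feature Student's t-test between two groups at one timepoint, BH
#' adjustment across features and a significance call at
#' \code{adjusted p < alpha}.
#'
#' @param om A merged, normalised \code{\link{omics_matrix}}.
#' @param group_a,group_b Groups compared (A vs B; A in the fold-change
#'   numerator).
#' @param timepoint Timepoint of the comparison (e.g. \code{"24wk"}).
#' @param alpha Significance level on the adjusted p-value (default
#'   0.05).
#' @param var_equal Pooled-variance t (default TRUE).
#' @return A \code{differential_result}: data.frame with columns
#'   \code{feature}, \code{comparison}, \code{log2fc}, \code{t},
#'   \code{p}, \code{q}, \code{significant}; attributes \code{alpha} and
#'   \code{comparison}.
#' @export
dal_analysis <- function(om, group_a, group_b, timepoint = NULL,
                         alpha = 0.05, var_equal = TRUE) {
  stopifnot(inherits(om, "omics_matrix"))
  for (g in c(group_a, group_b)) {
    if (!g %in% om$samples$group) {
      stop("unknown group label '", g, "'", call. = FALSE)
    }
  }
  ia <- .sample_idx(om, group_a, timepoint)
  ib <- .sample_idx(om, group_b, timepoint)
  res <- t(apply(om$values, 1L, function(v) {
    r <- .t_test_vec(v[ia], v[ib], var_equal = var_equal)
    c(r$log2fc, r$t, r$p)
  }))
  label <- paste0(group_a, " vs ", group_b,
                  if (!is.null(timepoint)) paste0(" @", timepoint))
  out <- data.frame(feature = rownames(om$values),
                    comparison = label,
                    log2fc = res[, 1L], t = res[, 2L], p = res[, 3L],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  attr(out, "alpha") <- alpha
  attr(out, "comparison") <- label
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors for count matrices: the median over
#' genes of the ratio of each sample's count to the gene's geometric
#' mean, using genes with all-positive counts.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene has all-positive counts", call. = FALSE)
  logg <- rowMeans(log(counts[pos, , drop = FALSE]))
  apply(counts[pos, , drop = FALSE], 2L, function(cnt) {
    exp(stats::median(log(cnt) - logg))
  })
}

#' Simplified negative-binomial Wald test for differential expression
#'
#' A light stand-in for full RNA-seq differential-expression machinery:
#' median-of-ratios size factors, per-gene method-of-moments dispersion
#' (pooled within groups, floored at 1e-8), a Wald test on the log2
#' ratio of group means of normalised counts (delta-method standard
#' error under the NB variance \eqn{\mu + \alpha \mu^2}), and BH
#' adjustment. No shrinkage or outlier filtering is attempted. All-zero
#' genes are dropped and reported via the \code{dropped} attribute.
#'
#' @param om An \code{\link{omics_matrix}} of raw counts.
#' @param group_a,group_b,timepoint,alpha As in
#'   \code{\link{dal_analysis}}.
#' @param pseudocount Added to group means before the ratio (default
#'   0.5).
#' @return A \code{differential_result} data.frame (columns as in
#'   \code{\link{dal_analysis}}, with \code{t} holding the Wald z).
#' @export
nb_wald_deg <- function(om, group_a, group_b, timepoint = NULL,
                        alpha = 0.05, pseudocount = 0.5) {
  stopifnot(inherits(om, "omics_matrix"))
  ia <- .sample_idx(om, group_a, timepoint)
  ib <- .sample_idx(om, group_b, timepoint)
  cols <- c(ia, ib)
  counts <- om$values[, cols, drop = FALSE]
  dropped <- rownames(counts)[rowSums(counts) == 0]
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, `/`)
  ga <- seq_along(ia)
  gb <- length(ia) + seq_along(ib)
  mu_a <- rowMeans(norm[, ga, drop = FALSE])
  mu_b <- rowMeans(norm[, gb, drop = FALSE])
  va <- apply(norm[, ga, drop = FALSE], 1L, stats::var)
  vb <- apply(norm[, gb, drop = FALSE], 1L, stats::var)
  # pooled method-of-moments dispersion: (s2 - mu) / mu^2 within groups
  disp_a <- (va - mu_a) / pmax(mu_a, 1e-8)^2
  disp_b <- (vb - mu_b) / pmax(mu_b, 1e-8)^2
  disp <- pmax((disp_a + disp_b) / 2, 1e-8)
  ma <- mu_a + pseudocount
  mb <- mu_b + pseudocount
  beta <- log2(ma / mb)
  inv_sf <- mean(1 / sf)
  var_a <- (ma * inv_sf + disp * ma^2) / length(ga)
  var_b <- (mb * inv_sf + disp * mb^2) / length(gb)
  se <- sqrt(var_a / ma^2 + var_b / mb^2) / log(2)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  label <- paste0(group_a, " vs ", group_b,
                  if (!is.null(timepoint)) paste0(" @", timepoint))
  out <- data.frame(feature = rownames(counts), comparison = label,
                    log2fc = beta, t = z, p = p, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  attr(out, "alpha") <- alpha
  attr(out, "comparison") <- label
  attr(out, "dropped") <- dropped
  attr(out, "size_factors") <- sf
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Disease-versus-reversal overlap of differential results
#'
#' Intersects the significant feature sets of a disease comparison (e.g.
#' HFD vs SD) and a reversal comparison (e.g. HFD-DR vs HFD) and labels
#' every common feature by direction. The partition rule labels each
#' feature by the comparison in which its |log2FC| is larger:
#' \code{increased_with_disease} when the disease change dominates with
#' positive fold change, \code{decreased_with_reversal} when the
#' reversal change dominates with negative fold change, otherwise
#' \code{discordant}. Raw fold changes of both comparisons are retained
#' so alternative partitions can be recomputed.
#'
#' @param disease,reversal \code{differential_result} objects over the
#'   same feature universe.
#' @param features Optional feature metadata (as in
#'   \code{omics_matrix$features}) for the lipid-class breakdown.
#' @return Object of class \code{comparison_overlap}: list with
#'   \code{common} (data.frame feature, disease_log2fc,
#'   reversal_log2fc, direction), \code{class_breakdown} (table or
#'   NULL), the two input comparison labels and counts.
#' @export
overlap_analysis <- function(disease, reversal, features = NULL) {
  if (!setequal(disease$feature, reversal$feature)) {
    stop("feature universes differ between comparisons", call. = FALSE)
  }
  common <- intersect(disease$feature[disease$significant],
                      reversal$feature[reversal$significant])
  d_fc <- disease$log2fc[match(common, disease$feature)]
  r_fc <- reversal$log2fc[match(common, reversal$feature)]
  direction <- ifelse(
    abs(d_fc) >= abs(r_fc),
    ifelse(d_fc > 0, "increased_with_disease", "discordant"),
    ifelse(r_fc < 0, "decreased_with_reversal", "discordant")
  )
  common_df <- data.frame(feature = common, disease_log2fc = d_fc,
                          reversal_log2fc = r_fc, direction = direction,
                          stringsAsFactors = FALSE)
  breakdown <- NULL
  if (!is.null(features) && length(common) > 0 &&
      "species_id" %in% names(features)) {
    cls <- features$lipid_class[match(common, features$species_id)]
    breakdown <- table(cls[!is.na(cls)])
  }
  structure(list(
    common = common_df,
    class_breakdown = breakdown,
    disease_comparison = attr(disease, "comparison"),
    reversal_comparison = attr(reversal, "comparison"),
    n_disease_significant = sum(disease$significant),
    n_reversal_significant = sum(reversal$significant),
    disease = disease, reversal = reversal
  ), class = "comparison_overlap")
}

#' @export
print.comparison_overlap <- function(x, ...) {
  cat(sprintf("overlap: %s (%d sig.) x %s (%d sig.)\n",
              x$disease_comparison, x$n_disease_significant,
              x$reversal_comparison, x$n_reversal_significant))
  cat(sprintf("common features: %d\n", nrow(x$common)))
  if (nrow(x$common) > 0) print(table(x$common$direction))
  invisible(x)
}

#' Features common to two disease-model overlaps
#'
#' Intersects the common-feature sets of two
#' \code{\link{overlap_analysis}} results (e.g. prediabetes and T2D
#' models) and tallies lipid classes where feature ids are parseable.
#'
#' @param overlap_a,overlap_b \code{comparison_overlap} objects.
#' @param features Optional feature metadata for the class tally.
#' @return List: \code{shared} (character ids), \code{n},
#'   \code{class_counts} (table or NULL).
#' @export
cross_model_common <- function(overlap_a, overlap_b, features = NULL) {
  shared <- intersect(overlap_a$common$feature,
                      overlap_b$common$feature)
  counts <- NULL
  if (length(shared) > 0) {
    if (!is.null(features) && "species_id" %in% names(features)) {
      cls <- features$lipid_class[match(shared, features$species_id)]
      counts <- table(cls[!is.na(cls)])
    } else {
      cls <- tryCatch(parse_lipid_id(shared)$lipid_class,
                      error = function(e) NULL)
      if (!is.null(cls)) counts <- table(cls)
    }
  }
  list(shared = sort(shared), n = length(shared), class_counts = counts)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric (one-sided Fisher) test of a gene list
#' against each gene set, restricted to a stated universe, with BH
#' adjustment across sets and the overlapping gene ids reported.
#'
#' @param gene_list Character vector of hit genes (must lie in
#'   \code{universe}).
#' @param gene_sets Named list of gene id vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe Character vector: all assayed genes.
#' @return data.frame: \code{set}, \code{n_set} (set size in universe),
#'   \code{n_overlap}, \code{overlap_genes} (comma-joined), \code{p},
#'   \code{q}.
#' @export
enrichment <- function(gene_list, gene_sets, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!all(gene_list %in% universe)) {
    stop("gene_list must be a subset of the universe", call. = FALSE)
  }
  gene_list <- unique(gene_list)
  n_u <- length(unique(universe))
  n_l <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- intersect(gene_list, set)
    p <- stats::phyper(length(ov) - 1L, length(set), n_u - length(set),
                       n_l, lower.tail = FALSE)
    data.frame(set = nm, n_set = length(set), n_overlap = length(ov),
               overlap_genes = paste(sort(ov), collapse = ","),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-delimited GMT file (set name, description,
#'   genes...).
#' @return Named list of gene id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of gene id vectors.
#' @param path Output path. The description column is set to \code{"na"}.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(length(names(gene_sets)) == length(gene_sets))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a differential result table to TSV
#'
#' @param result A \code{differential_result}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_differential <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
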