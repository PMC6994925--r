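#' K-nearest-neighbour imputation of missing lipid intensities
#'
#' Feature-wise KNN: neighbours are other lipid features, distances are
#' Euclidean over the samples where both features are observed, rescaled
#' by \eqn{\sqrt{n_{total}/n_{obs}}} to stay comparable across different
#' overlaps. Each missing cell is replaced by the mean of the k nearest
#' features that are observed in that sample; observed cells are never
#' touched.
#'
#' @param om An \code{\link{omics_matrix}} (stage \code{"raw"}).
#' @param k Number of neighbours (default 10).
#' @return The imputed \code{omics_matrix}, stage \code{"imputed"}.
#' @export
knn_impute <- function(om, k = 10) {
  stopifnot(inherits(om, "omics_matrix"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  x <- om$values
  if (!anyNA(x)) {
    return(.update_om(om, x, stage = "imputed"))
  }
  dead <- which(rowSums(!is.na(x)) == 0L)
  if (length(dead) > 0) {
    stop("feature missing in all samples: '", rownames(x)[dead[1L]], "'",
         call. = FALSE)
  }
  n_samp <- ncol(x)
  need <- which(rowSums(is.na(x)) > 0L)
  d <- .knn_distances(x)
  out <- x
  for (f in need) {
    miss_cols <- which(is.na(x[f, ]))
    ord <- order(d[f, ])
    for (j in miss_cols) {
      donors <- ord[!is.na(x[ord, j]) & ord != f]
      if (length(donors) == 0L) {
        stop("no observed neighbour for feature '", rownames(x)[f],
             "' in sample '", colnames(x)[j], "'", call. = FALSE)
      }
      use <- donors[seq_len(min(k, length(donors)))]
      out[f, j] <- mean(x[use, j])
    }
  }
  .update_om(om, out, stage = "imputed")
}

# pairwise feature distances over mutually observed samples, scaled by
# sqrt(n_total / n_observed); Inf when no overlap
.knn_distances <- function(x) {
  p <- nrow(x)
  n <- ncol(x)
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  # sum over shared samples of (xi - xj)^2 via cross products on the
  # zero-filled matrix restricted to the observation masks
  sq <- x0^2
  shared <- tcrossprod(obs * 1)                 # n mutually observed
  s_ij <- tcrossprod(sq, obs) + tcrossprod(obs, sq) - 2 * tcrossprod(x0)
  s_ij[s_ij < 0] <- 0                           # numerical guard
  d <- sqrt(s_ij) * sqrt(n / pmax(shared, 1))
  d[shared == 0] <- Inf
  diag(d) <- Inf
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Internal-standard normalisation
#'
#' Divides every lipid feature by the intensity of its class's internal
#' standard in the same sample, then removes the standard features from
#' the matrix. A single global standard can be supplied under the name
#' \code{"*"}.
#'
#' @param om An imputed \code{\link{omics_matrix}} whose \code{features}
#'   metadata carries \code{lipid_class}.
#' @param standards Named character map, lipid class -> standard feature
#'   id (row name of \code{om$values}).
#' @return Normalised \code{omics_matrix} (standards dropped), stage
#'   \code{"normalized"}.
#' @export
normalize_internal_standard <- function(om, standards) {
  stopifnot(inherits(om, "omics_matrix"), !is.null(om$features))
  x <- om$values
  if (!all(standards %in% rownames(x))) {
    miss <- standards[!standards %in% rownames(x)][1L]
    stop("standard feature '", miss, "' not in matrix", call. = FALSE)
  }
  cls <- om$features$lipid_class
  is_std <- rownames(x) %in% standards
  global <- if ("*" %in% names(standards)) standards[["*"]] else NULL
  out <- x
  for (f in which(!is_std)) {
    std_id <- if (cls[f] %in% names(standards)) {
      standards[[cls[f]]]
    } else if (!is.null(global)) {
      global
    } else {
      stop("no internal standard configured for class '", cls[f], "'",
           call. = FALSE)
    }
    s <- x[std_id, ]
    if (any(s == 0, na.rm = TRUE)) {
      stop("zero internal-standard intensity for class '", cls[f], "'",
           call. = FALSE)
    }
    out[f, ] <- x[f, ] / s
  }
  keep <- !is_std
  omics_matrix(out[keep, , drop = FALSE], om$samples,
               features = om$features[keep, , drop = FALSE],
               stage = "normalized")
}

#' Merge positive- and negative-mode measurements of the same species
#'
#' Features sharing a species identity (class + acyl composition) across
#' ion modes are collapsed to their arithmetic mean; species seen in a
#' single mode pass through unchanged. The output has one row per unique
#' species, named by the bare species id.
#'
#' @param om A normalised \code{\link{omics_matrix}} with
#'   \code{species_id} feature metadata.
#' @return Merged \code{omics_matrix}, stage \code{"merged"}.
#' @export
merge_ion_modes <- function(om) {
  stopifnot(inherits(om, "omics_matrix"), !is.null(om$features))
  if (om$stage != "normalized") {
    stop("merge_ion_modes expects a matrix at stage 'normalized', got '",
         om$stage, "'", call. = FALSE)
  }
  sp <- om$features$species_id
  tab <- table(sp)
  if (any(tab > 2L)) {
    stop("species '", names(tab)[tab > 2L][1L],
         "' has more than two ion-mode entries", call. = FALSE)
  }
  uniq <- unique(sp)
  idx <- split(seq_along(sp), factor(sp, levels = uniq))
  vals <- do.call(rbind, lapply(idx, function(i) {
    colMeans(om$values[i, , drop = FALSE])
  }))
  rownames(vals) <- uniq
  first <- vapply(idx, `[`, 0L, 1L)
  feat <- om$features[first, , drop = FALSE]
  feat$raw_id <- uniq
  feat$ion_mode <- ifelse(lengths(idx) == 2L, "merged",
                          feat$ion_mode)
  rownames(feat) <- NULL
  omics_matrix(vals, om$samples, features = feat, stage = "merged")
}

#' Per-feature z-score transform
#'
#' Centres and scales every feature to mean 0 and (n-1) standard
#' deviation 1. By default the transform is computed within each
#' timepoint's sample set separately, matching per-panel heat-map
#' displays; set \code{by_timepoint = FALSE} for a global transform.
#'
#' @param om An \code{\link{omics_matrix}} without missing values.
#' @param by_timepoint Standardise within each timepoint (default TRUE).
#' @return z-scored \code{omics_matrix}, stage \code{"zscored"}.
#' @export
zscore_features <- function(om, by_timepoint = TRUE) {
  stopifnot(inherits(om, "omics_matrix"))
  x <- om$values
  blocks <- if (by_timepoint) {
    split(seq_len(ncol(x)), om$samples$timepoint)
  } else {
    list(seq_len(ncol(x)))
  }
  out <- x
  for (cols in blocks) {
    sub <- x[, cols, drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    if (any(sds == 0)) {
      stop("constant feature cannot be z-scored: '",
           rownames(x)[sds == 0][1L], "'", call. = FALSE)
    }
    out[, cols] <- (sub - rowMeans(sub)) / sds
  }
  .update_om(om, out, stage = "zscored")
}

#' Per-sample lipid class totals
#'
#' Sums all (merged) species of one lipid class per sample and summarises
#' by group and timepoint as mean +/- standard error.
#'
#' @param om A merged \code{\link{omics_matrix}}.
#' @param lipid_class Class abbreviation, e.g. \code{"TG"}.
#' @return List with \code{totals} (data.frame sample, group, timepoint,
#'   total) and \code{summary} (data.frame group, timepoint, n, mean,
#'   sem).
#' @export
class_sum <- function(om, lipid_class) {
  stopifnot(inherits(om, "omics_matrix"), !is.null(om$features))
  std <- if (is.null(om$features$is_standard)) FALSE else
    om$features$is_standard
  rows <- which(om$features$lipid_class == lipid_class & !std)
  if (length(rows) == 0L) {
    stop("no species of class '", lipid_class, "' in matrix",
         call. = FALSE)
  }
  tot <- colSums(om$values[rows, , drop = FALSE])
  totals <- data.frame(om$samples, total = tot, row.names = NULL)
  agg <- split(totals$total,
               list(totals$group, totals$timepoint), drop = TRUE)
  summ <- do.call(rbind, lapply(names(agg), function(k) {
    v <- agg[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(group = parts[1L], timepoint = parts[2L],
               n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  rownames(summ) <- NULL
  list(totals = totals, summary = summ)
}

#' Fatty-acyl composition totals of a lipid class
#'
#' For every fatty-acid chain occurring in the class, the per-sample
#' total \eqn{\sum_{species} abundance \times multiplicity} of that
#' chain, e.g. one unit of TG(16:0/16:0/18:1) contributes twice to
#' C16:0. Requires species with individually resolved chains.
#'
#' @param om A merged \code{\link{omics_matrix}}.
#' @param lipid_class Class abbreviation.
#' @return Numeric matrix, fatty acids (rows, labelled \code{"C16:0"}
#'   style) by samples.
#' @export
fa_composition <- function(om, lipid_class) {
  stopifnot(inherits(om, "omics_matrix"), !is.null(om$features))
  std <- if (is.null(om$features$is_standard)) FALSE else
    om$features$is_standard
  rows <- which(om$features$lipid_class == lipid_class & !std)
  if (length(rows) == 0L) {
    stop("no species of class '", lipid_class, "' in matrix",
         call. = FALSE)
  }
  resolved <- om$features$resolved[rows]
  if (!any(resolved)) {
    stop("class '", lipid_class,
         "' has only total-composition ids; chains unresolved",
         call. = FALSE)
  }
  rows <- rows[resolved]
  chains <- om$features$acyl_chains[rows]
  labels <- sort(unique(unlist(lapply(chains, function(ch) {
    fa_label(ch[, "carbons"], ch[, "double_bonds"])
  }))))
  out <- matrix(0, nrow = length(labels), ncol = ncol(om$values),
                dimnames = list(labels, colnames(om$values)))
  for (i in seq_along(rows)) {
    ch <- chains[[i]]
    lab <- fa_label(ch[, "carbons"], ch[, "double_bonds"])
    mult <- table(lab)
    for (l in names(mult)) {
      out[l, ] <- out[l, ] + om$values[rows[i], ] * as.integer(mult[[l]])
    }
  }
  out
}
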