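#' Construct an omics matrix
#'
#' Light container pairing a numeric feature-by-sample matrix with its
#' sample sheet and per-feature metadata, plus a processing-stage tag.
#' Features are rows and samples are columns (the usual expression-matrix
#' orientation); the O2PLS fitting function transposes internally.
#'
#' @param values Numeric matrix, features in rows, samples in columns,
#'   with rownames (feature ids) and colnames (sample ids). Missing values
#'   are only allowed at stage \code{"raw"}.
#' @param samples data.frame with columns \code{sample}, \code{group} and
#'   \code{timepoint}; one row per column of \code{values}, matched by
#'   \code{sample}.
#' @param features Optional data.frame of per-feature metadata with one
#'   row per row of \code{values} (e.g. the output of
#'   \code{\link{parse_lipid_id}}).
#' @param stage Processing stage tag, one of \code{"raw"},
#'   \code{"imputed"}, \code{"normalized"}, \code{"merged"},
#'   \code{"zscored"}.
#' @return An object of class \code{omics_matrix}: a list with elements
#'   \code{values}, \code{samples}, \code{features}, \code{stage}.
#' @export
omics_matrix <- function(values, samples,
                         features = NULL,
                         stage = c("raw", "imputed", "normalized",
                                   "merged", "zscored")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' needs feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicated feature id: '", dup, "'", call. = FALSE)
  }
  if (!is.data.frame(samples) ||
      !all(c("sample", "group", "timepoint") %in% names(samples))) {
    stop("'samples' must have columns sample, group, timepoint",
         call. = FALSE)
  }
  if (!setequal(samples$sample, colnames(values)) ||
      nrow(samples) != ncol(values)) {
    stop("sample sheet does not match matrix columns", call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(features)) {
    if (nrow(features) != nrow(values)) {
      stop("'features' must have one row per matrix row", call. = FALSE)
    }
  }
  if (stage != "raw" && anyNA(values)) {
    stop("missing values not allowed at stage '", stage, "'", call. = FALSE)
  }
  structure(
    list(values = values, samples = samples, features = features,
         stage = stage),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples [stage: %s]\n",
              nrow(x$values), ncol(x$values), x$stage))
  tab <- table(x$samples$group, x$samples$timepoint)
  cat("samples per group x timepoint:\n")
  print(tab)
  if (anyNA(x$values)) {
    cat(sprintf("missing entries: %d (%.1f%%)\n", sum(is.na(x$values)),
                100 * mean(is.na(x$values))))
  }
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

# replace values/features keeping the rest, with a new stage tag
.update_om <- function(om, values, stage, features = om$features) {
  omics_matrix(values, om$samples, features = features, stage = stage)
}

# column indices for a (group, timepoint) cell; timepoint NULL = both
.sample_idx <- function(om, group = NULL, timepoint = NULL) {
  keep <- rep(TRUE, nrow(om$samples))
  if (!is.null(group)) keep <- keep & om$samples$group %in% group
  if (!is.null(timepoint)) keep <- keep & om$samples$timepoint %in% timepoint
  which(keep)
}
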