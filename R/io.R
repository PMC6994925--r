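#' Read a feature-by-sample matrix from TSV/CSV
#'
#' The first column holds feature ids; remaining columns are samples.
#' With a sample sheet the orientation is auto-detected (a matrix stored
#' samples-in-rows is transposed); duplicate ids are an error naming the
#' offender.
#'
#' @param path TSV (default) or CSV file; delimiter inferred from the
#'   extension.
#' @param samples Optional sample sheet data.frame (columns
#'   \code{sample}, \code{group}, \code{timepoint}); when supplied an
#'   \code{\link{omics_matrix}} is returned.
#' @param orientation \code{"auto"}, \code{"features"} (features in
#'   rows) or \code{"samples"} (samples in rows).
#' @param stage Stage tag for the returned \code{omics_matrix}.
#' @return An \code{omics_matrix} (when \code{samples} is given) or a
#'   plain feature-by-sample matrix.
#' @export
read_omics_matrix <- function(path, samples = NULL,
                              orientation = c("auto", "features",
                                              "samples"),
                              stage = "raw") {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicated feature id in '", path, "': '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "samples" ||
      (orientation == "auto" && !is.null(samples) &&
       !any(colnames(m) %in% samples$sample) &&
       any(ids %in% samples$sample))) {
    m <- t(m)
  }
  if (is.null(samples)) return(m)
  omics_matrix(m, samples, stage = stage)
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param x An \code{\link{omics_matrix}} or plain matrix.
#' @param path Output path; first column is named \code{feature}.
#' @return Invisibly, \code{path}.
#' @export
write_omics_matrix <- function(x, path) {
  m <- if (inherits(x, "omics_matrix")) x$values else x
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns \code{sample}, \code{group},
#'   \code{timepoint}.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "group", "timepoint")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a gene-lipid annotation pair table
#'
#' @param path Two-column TSV with header \code{gene}, \code{lipid};
#'   duplicate pairs are collapsed.
#' @return data.frame with unique pairs.
#' @export
read_annotation_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "lipid") %in% names(df))) {
    stop("annotation table must have columns gene, lipid",
         call. = FALSE)
  }
  unique(df[, c("gene", "lipid")])
}
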