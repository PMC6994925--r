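#' Known lipid class abbreviations
#'
#' The 17 lipid classes handled by the pipeline, as used in shotgun
#' lipidomics class summaries of peripheral-nerve tissue: cholesteryl
#' esters (CE), cardiolipins (CL), diglycerides (DG), free fatty acids
#' (FFA), methyl esters (ME), phosphatidic acids (PA),
#' phosphatidylcholines (PC), phosphatidylethanolamines (PE),
#' phosphatidylglycerols (PG), phosphatidylinositols (PI),
#' phosphatidylserines (PS), sphingomyelins (SM), triglycerides (TG),
#' lyso-PC (LPC), lyso-PE (LPE) and the plasmenyl ethers pPC and pPE.
#'
#' @return Character vector of class abbreviations.
#' @export
lipid_classes <- function() {
  c("CE", "CL", "DG", "FFA", "ME", "PA", "PC", "PE", "PG", "PI", "PS",
    "SM", "TG", "LPC", "LPE", "pPC", "pPE")
}

# number of acyl chains a fully resolved species of each class carries
.chain_counts <- c(
  CE = 1, CL = 4, DG = 2, FFA = 1, ME = 1, PA = 2, PC = 2, PE = 2,
  PG = 2, PI = 2, PS = 2, SM = 2, TG = 3, LPC = 1, LPE = 1, pPC = 2,
  pPE = 2
)

#' Parse a lipid species identifier
#'
#' Identifiers follow the grammar \code{CLASS(c1:d1/c2:d2[/...])} where each
#' \code{c:d} token is an acyl chain given as carbons:double-bonds, e.g.
#' \code{"TG(16:0/18:1/18:2)"}. A single token on a multi-chain class, e.g.
#' \code{"TG(52:2)"}, is interpreted as a total composition: the class is
#' known but individual chains are not resolved (\code{acyl_chains} empty,
#' the token recorded as \code{total}). An optional ion-mode suffix
#' \code{"_pos"} / \code{"_neg"} is stripped and recorded.
#'
#' @param raw_id Character vector of identifiers.
#' @return A data.frame with one row per id: \code{raw_id},
#'   \code{species_id} (id without ion-mode suffix), \code{lipid_class},
#'   \code{ion_mode} (\code{"positive"}, \code{"negative"} or
#'   \code{"merged"}), \code{total_carbons}, \code{total_double_bonds},
#'   \code{resolved} (logical: chains individually known) and
#'   \code{acyl_chains}, a list column of two-column matrices
#'   (carbons, double_bonds).
#' @examples
#' parse_lipid_id("TG(16:0/18:1/18:2)")
#' parse_lipid_id(c("FFA(16:0)", "TG(52:2)"))
#' @export
parse_lipid_id <- function(raw_id) {
  stopifnot(is.character(raw_id), length(raw_id) >= 1L)
  out <- lapply(raw_id, .parse_one_lipid_id)
  df <- data.frame(
    raw_id = raw_id,
    species_id = vapply(out, `[[`, "", "species_id"),
    lipid_class = vapply(out, `[[`, "", "lipid_class"),
    ion_mode = vapply(out, `[[`, "", "ion_mode"),
    total_carbons = vapply(out, `[[`, 0L, "total_carbons"),
    total_double_bonds = vapply(out, `[[`, 0L, "total_double_bonds"),
    resolved = vapply(out, `[[`, NA, "resolved"),
    stringsAsFactors = FALSE
  )
  df$acyl_chains <- lapply(out, `[[`, "acyl_chains")
  rownames(df) <- NULL
  df
}

.parse_one_lipid_id <- function(id) {
  ion_mode <- "merged"
  core <- id
  if (grepl("_pos$", core)) {
    ion_mode <- "positive"
    core <- sub("_pos$", "", core)
  } else if (grepl("_neg$", core)) {
    ion_mode <- "negative"
    core <- sub("_neg$", "", core)
  }
  m <- regmatches(core, regexec("^([A-Za-z]+)\\(([0-9:/ ]+)\\)$", core))[[1]]
  if (length(m) != 3L) {
    stop("malformed lipid id: '", id, "'", call. = FALSE)
  }
  cls <- m[2]
  if (!cls %in% lipid_classes()) {
    stop("unknown lipid class '", cls, "' in id '", id, "'", call. = FALSE)
  }
  tokens <- strsplit(m[3], "/", fixed = TRUE)[[1]]
  parsed <- lapply(tokens, function(tok) {
    parts <- strsplit(trimws(tok), ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts)))) {
      stop("malformed acyl token '", tok, "' in id '", id, "'", call. = FALSE)
    }
    as.integer(parts)
  })
  chains <- do.call(rbind, parsed)
  colnames(chains) <- c("carbons", "double_bonds")
  expected <- .chain_counts[[cls]]
  # one token on a multi-chain class gives a total composition only
  resolved <- !(length(tokens) == 1L && expected > 1L)
  list(
    species_id = core,
    lipid_class = cls,
    ion_mode = ion_mode,
    total_carbons = sum(chains[, 1L]),
    total_double_bonds = sum(chains[, 2L]),
    resolved = resolved,
    acyl_chains = if (resolved) chains else chains[0L, , drop = FALSE]
  )
}

#' Format an acyl chain as a fatty-acid label
#'
#' @param carbons,double_bonds Integer vectors.
#' @return Labels such as \code{"C16:0"}.
#' @export
fa_label <- function(carbons, double_bonds) {
  sprintf("C%d:%d", carbons, double_bonds)
}
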