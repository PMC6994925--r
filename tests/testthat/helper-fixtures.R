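# shared small fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# small but complete synthetic study (cached)
tiny_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_study(
      study_design(4),
      sim_config(n_lipids = 120, n_genes = 300, n_joint_lipids = 8,
                 n_joint_genes = 8, n_affected_genes = 30, seed = 42))
  }
  .fixture_env$sim
}

tiny_merged <- function() {
  if (is.null(.fixture_env$merged)) {
    sim <- tiny_sim()
    .fixture_env$merged <- merge_ion_modes(
      normalize_internal_standard(knn_impute(sim$lipids, 10),
                                  sim$standards))
  }
  .fixture_env$merged
}

# a plain omics_matrix with a two-group design
toy_om <- function(values, groups, timepoint = "24wk",
                   stage = "merged") {
  sheet <- data.frame(sample = colnames(values), group = groups,
                      timepoint = timepoint,
                      stringsAsFactors = FALSE)
  omics_matrix(values, sheet, stage = stage)
}

# independent brute-force BH step-up: q_i = min_{j>=i}(p_(j) * m / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(m)
  out[o] <- pmin(1, q_sorted)
  out
}

# brute-force all-pairs Pearson edge list (loops, no vectorisation)
pearson_oracle <- function(lipid_mat, gene_mat = NULL, threshold = 0.6) {
  edges <- list()
  ln <- rownames(lipid_mat)
  for (i in seq_len(nrow(lipid_mat))) {
    for (j in seq_len(nrow(lipid_mat))) {
      if (j > i) {
        r <- cor(lipid_mat[i, ], lipid_mat[j, ])
        if (abs(r) > threshold) {
          edges[[length(edges) + 1L]] <-
            data.frame(from = ln[i], to = ln[j], r = r)
        }
      }
    }
    if (!is.null(gene_mat)) {
      for (k in seq_len(nrow(gene_mat))) {
        r <- cor(lipid_mat[i, ], gene_mat[k, ])
        if (abs(r) > threshold) {
          edges[[length(edges) + 1L]] <-
            data.frame(from = ln[i], to = rownames(gene_mat)[k], r = r)
        }
      }
    }
  }
  if (length(edges) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      r = numeric(0)))
  }
  do.call(rbind, edges)
}

edge_key <- function(df) {
  sort(paste(pmin(df$from, df$to), pmax(df$from, df$to)))
}
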