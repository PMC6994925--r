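make_om <- function(values, stage = "raw", classes = NULL) {
  sheet <- data.frame(sample = colnames(values),
                      group = rep_len(c("SD", "HFD"), ncol(values)),
                      timepoint = "24wk", stringsAsFactors = FALSE)
  om <- omics_matrix(values, sheet, stage = stage)
  if (!is.null(classes)) {
    om$features <- data.frame(raw_id = rownames(values),
                              species_id = rownames(values),
                              lipid_class = classes,
                              ion_mode = "merged",
                              resolved = FALSE, is_standard = FALSE,
                              stringsAsFactors = FALSE)
  }
  om
}

test_that("knn imputation leaves complete matrices untouched", {
  m <- matrix(rexp(24), 6, 4,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:4)))
  om <- make_om(m)
  out <- knn_impute(om, 2)
  expect_identical(out$values, m)
  expect_equal(out$stage, "imputed")
})

test_that("an exact duplicate neighbour reproduces the missing value", {
  a <- c(1, 2, 3, 4)
  m <- rbind(A = a, B = c(1, 2, NA, 4), C = c(9, 1, 4, 7),
             D = c(0, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  out <- knn_impute(make_om(m), 1)
  expect_equal(out$values["B", "s3"], 3)
})

test_that("knn imputation matches a brute-force neighbour-mean oracle", {
  set.seed(31)
  m <- matrix(rexp(6 * 4, 0.2), 6, 4,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:4)))
  m[cbind(c(1, 3, 5), c(2, 4, 1))] <- NA
  k <- 2
  out <- knn_impute(make_om(m), k)

  # oracle: explicit pairwise distances over mutually observed samples
  for (f in which(rowSums(is.na(m)) > 0)) {
    for (j in which(is.na(m[f, ]))) {
      d <- sapply(seq_len(nrow(m)), function(g) {
        if (g == f) return(Inf)
        both <- !is.na(m[f, ]) & !is.na(m[g, ])
        if (!any(both)) return(Inf)
        sqrt(sum((m[f, both] - m[g, both])^2) *
               ncol(m) / sum(both))
      })
      donors <- order(d)
      donors <- donors[!is.na(m[donors, j])]
      expected <- mean(m[donors[seq_len(k)], j])
      expect_equal(out$values[f, j], expected)
    }
  }
  # observed cells untouched (restricted Frobenius difference zero)
  obs <- !is.na(m)
  expect_equal(sum((out$values[obs] - m[obs])^2), 0)
})

test_that("imputation errors on fully missing features and bad k", {
  m <- matrix(c(NA, NA, NA, 1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("gone", "ok"), paste0("s", 1:3)))
  expect_error(knn_impute(make_om(m), 1), "missing in all samples")
  expect_error(knn_impute(make_om(matrix(1, 1, 1,
                                         dimnames = list("a", "b"))),
                          0), "k must be")
})

test_that("internal-standard normalisation divides by the class standard", {
  set.seed(5)
  m <- rbind(matrix(rexp(5 * 8), 5, 8), 2^rnorm(8, 0, 0.1))
  rownames(m) <- c(sprintf("TG(18:%d/18:1/18:2)", 0:4), "STD_TG")
  colnames(m) <- paste0("s", 1:8)
  om <- make_om(m, stage = "raw",
                classes = c(rep("TG", 5), "TG"))
  om$features$is_standard <- c(rep(FALSE, 5), TRUE)
  out <- normalize_internal_standard(om, c(TG = "STD_TG"))
  expect_equal(out$stage, "normalized")
  expect_false("STD_TG" %in% rownames(out$values))
  # element-wise division oracle
  expect_equal(out$values, sweep(m[1:5, ], 2, m[6, ], "/"))
  # all-one standard leaves values unchanged
  m1 <- m; m1[6, ] <- 1
  om1 <- om; om1$values <- m1
  out1 <- normalize_internal_standard(om1, c(TG = "STD_TG"))
  expect_equal(out1$values, m[1:5, ])
  # zero standard is an error
  m0 <- m; m0[6, 3] <- 0
  om0 <- om; om0$values <- m0
  expect_error(normalize_internal_standard(om0, c(TG = "STD_TG")),
               "zero internal-standard")
})

test_that("ion-mode merging averages dual-mode species exactly", {
  m <- rbind("PC(16:0/18:1)_pos" = c(4, 8), "PC(16:0/18:1)_neg" = c(6, 2),
             "TG(16:0/18:1/18:2)_pos" = c(5, 5))
  colnames(m) <- c("s1", "s2")
  om <- make_om(m, stage = "normalized")
  om$features <- parse_lipid_id(rownames(m))
  om$features$is_standard <- FALSE
  out <- merge_ion_modes(om)
  expect_equal(nrow(out$values), 2)
  expect_equal(unname(out$values["PC(16:0/18:1)", ]), c(5, 5))
  expect_equal(unname(out$values["TG(16:0/18:1/18:2)", ]), c(5, 5))
  expect_equal(out$features$ion_mode[
    out$features$species_id == "PC(16:0/18:1)"], "merged")
})

test_that("merged feature count equals the generator's unique species count", {
  sim <- tiny_sim()
  merged <- tiny_merged()
  feat <- sim$lipids$features
  n_species <- length(unique(feat$species_id[!feat$is_standard]))
  n_raw <- sum(!feat$is_standard)
  n_dual <- length(sim$truth$dual_mode_species)
  expect_equal(n_raw, n_species + n_dual)
  expect_equal(nrow(merged$values), n_species)
  # mean conservation for every dual-mode species
  norm <- normalize_internal_standard(knn_impute(sim$lipids, 10),
                                      sim$standards)
  sp <- sim$truth$dual_mode_species[1]
  rows <- which(norm$features$species_id == sp)
  expect_equal(unname(merged$values[sp, ]),
               unname(colMeans(norm$values[rows, ])))
})

test_that("merging rejects >2 rows per species", {
  m <- matrix(1, 3, 2, dimnames = list(c("a", "b", "c"),
                                       c("s1", "s2")))
  om <- make_om(m, stage = "normalized",
                classes = rep("TG", 3))
  om$features$species_id <- "TG(16:0/16:0/16:0)"
  expect_error(merge_ion_modes(om), "more than two")
})

test_that("z-scoring standardises per feature and is idempotent", {
  m <- matrix(c(1, 2, 3, 10, 20, 40), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:3)))
  om <- make_om(m, stage = "merged")
  z <- zscore_features(om, by_timepoint = FALSE)
  expect_equal(unname(z$values["a", ]), c(-1, 0, 1))
  expect_lt(max(abs(rowMeans(z$values))), 1e-10)
  expect_lt(max(abs(apply(z$values, 1, sd) - 1)), 1e-10)
  z2 <- zscore_features(z, by_timepoint = FALSE)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  # constant features error by name
  m2 <- rbind(m, flat = c(2, 2, 2))
  expect_error(zscore_features(make_om(m2, stage = "merged"),
                               by_timepoint = FALSE), "flat")
})

test_that("z-scoring by timepoint standardises within each panel", {
  sim <- tiny_sim()
  z <- zscore_features(tiny_merged())
  for (tp in c("16wk", "24wk")) {
    cols <- z$samples$timepoint == tp
    expect_lt(max(abs(rowMeans(z$values[, cols]))), 1e-10)
    expect_lt(max(abs(apply(z$values[, cols], 1, sd) - 1)), 1e-10)
  }
})

test_that("class sums add species and conserve the sample totals", {
  m <- rbind("TG(16:0/16:0/16:0)" = c(1, 4), "TG(16:0/16:0/18:1)" = c(2, 5),
             "DG(16:0/18:1)" = c(7, 1))
  colnames(m) <- c("s1", "s2")
  om <- make_om(m, stage = "merged", classes = c("TG", "TG", "DG"))
  cs <- class_sum(om, "TG")
  expect_equal(cs$totals$total, c(3, 9))
  expect_true(all(c("mean", "sem") %in% names(cs$summary)))
  # conservation over all classes
  all_cls <- unique(om$features$lipid_class)
  tot <- Reduce(`+`, lapply(all_cls, function(cl) {
    class_sum(om, cl)$totals$total
  }))
  expect_equal(tot, unname(colSums(m)))
  expect_error(class_sum(om, "PA"), "no species")
})

test_that("planted TG effect raises the HFD class sum at both timepoints", {
  merged <- tiny_merged()
  cs <- class_sum(merged, "TG")$summary
  for (tp in c("16wk", "24wk")) {
    hfd <- cs$mean[cs$group == "HFD" & cs$timepoint == tp]
    sd_ <- cs$mean[cs$group == "SD" & cs$timepoint == tp]
    expect_gt(hfd, sd_)
  }
  # reversal restores SD-like levels at 24wk
  dr <- cs$mean[cs$group == "HFD-DR" & cs$timepoint == "24wk"]
  hfd24 <- cs$mean[cs$group == "HFD" & cs$timepoint == "24wk"]
  expect_lt(dr, hfd24)
})

test_that("fatty-acyl composition counts chain multiplicity and is linear", {
  m <- matrix(c(1, 2), 1, 2,
              dimnames = list("TG(16:0/16:0/18:1)", c("s1", "s2")))
  om <- make_om(m, stage = "merged")
  om$features <- parse_lipid_id(rownames(m))
  om$features$is_standard <- FALSE
  fa <- fa_composition(om, "TG")
  expect_equal(unname(fa["C16:0", ]), c(2, 4))
  expect_equal(unname(fa["C18:1", ]), c(1, 2))
  # doubling abundance doubles every total
  om2 <- om; om2$values <- 2 * om$values
  expect_equal(fa_composition(om2, "TG"), 2 * fa)
  # total-composition-only classes error
  m3 <- matrix(1, 1, 2, dimnames = list("TG(52:2)", c("s1", "s2")))
  om3 <- make_om(m3, stage = "merged")
  om3$features <- parse_lipid_id(rownames(m3))
  om3$features$is_standard <- FALSE
  expect_error(fa_composition(om3, "TG"), "unresolved")
})

test_that("planted saturated-TG effect raises C16:0 totals in HFD", {
  merged <- tiny_merged()
  fa <- fa_composition(merged, "TG")
  idx <- merged$samples
  hfd <- mean(fa["C16:0", idx$group == "HFD"])
  sd_ <- mean(fa["C16:0", idx$group == "SD"])
  expect_gt(hfd, sd_)
})
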