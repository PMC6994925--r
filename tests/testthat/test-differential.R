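two_group_om <- function(values, n_a, n_b, ga = "HFD", gb = "SD") {
  sheet <- data.frame(sample = colnames(values),
                      group = c(rep(ga, n_a), rep(gb, n_b)),
                      timepoint = "24wk", stringsAsFactors = FALSE)
  omics_matrix(values, sheet, stage = "merged")
}

test_that("pooled t-test matches the closed-form computation", {
  m <- rbind(f1 = c(5, 6, 7, 1, 2, 3), f2 = c(1, 2, 3, 1, 2, 3))
  colnames(m) <- paste0("s", 1:6)
  om <- two_group_om(m, 3, 3)
  r <- t_test_feature(om, "f1", "HFD", "SD")
  # t = (mean_a - mean_b) / (sp * sqrt(2/3)), sp^2 pooled variance = 1
  expect_equal(r$t, 4 / sqrt(2 / 3))
  expect_equal(r$p, 2 * pt(-abs(r$t), df = 4))
  expect_equal(r$log2fc, log2(6 / 2))

  r0 <- t_test_feature(om, "f2", "HFD", "SD")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$log2fc, 0)
})

test_that("t statistic is scale-invariant; log2FC shifts under scaling", {
  set.seed(77)
  a <- rexp(6) + 1
  b <- rexp(6) + 1
  m1 <- matrix(c(a, b), 1, 12,
               dimnames = list("f", paste0("s", 1:12)))
  r1 <- t_test_feature(two_group_om(m1, 6, 6), "f", "HFD", "SD")
  # common positive scaling of both groups
  r2 <- t_test_feature(two_group_om(3.7 * m1, 6, 6), "f", "HFD", "SD")
  expect_equal(r2$t, r1$t)
  expect_equal(r2$log2fc, r1$log2fc)
  # scaling group A by 2^c shifts the log2FC by exactly c
  m3 <- m1
  m3[1, 1:6] <- m3[1, 1:6] * 2^1.5
  r3 <- t_test_feature(two_group_om(m3, 6, 6), "f", "HFD", "SD")
  expect_equal(r3$log2fc, r1$log2fc + 1.5)
})

test_that("degenerate zero-variance equal-mean input errors", {
  m <- matrix(2, 1, 6, dimnames = list("f", paste0("s", 1:6)))
  expect_error(t_test_feature(two_group_om(m, 3, 3), "f", "HFD", "SD"),
               "zero within-group variance")
})

test_that("BH adjustment reproduces the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, -0.1)), "0, 1")
})

test_that("BH adjustment agrees with the brute-force oracle", {
  set.seed(123)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p & q <= 1))
    # monotone non-decreasing in sorted-p order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("dal_analysis recovers planted lipids at the study group size", {
  d <- study_design(10)
  cfg <- sim_config(seed = 55, n_genes = 50, n_joint_lipids = 5,
                    n_joint_genes = 5, joint_factor_strength = 0)
  lip <- simulate_lipidome(d, cfg)
  merged <- merge_ion_modes(normalize_internal_standard(
    knn_impute(lip$om, 10), lip$standards))
  res <- dal_analysis(merged, "HFD", "SD", "24wk")
  expect_s3_class(res, "differential_result")
  expect_true(all(res$q >= res$p))
  expect_identical(res$significant, res$q < 0.05)
  recall <- mean(res$significant[match(lip$truth$affected_species,
                                       res$feature)])
  expect_gte(recall, 0.8)
  # alpha -> 0 empties the significant set
  res0 <- dal_analysis(merged, "HFD", "SD", "24wk", alpha = 1e-300)
  expect_equal(sum(res0$significant), 0)
  expect_error(dal_analysis(merged, "HFDX", "SD"), "unknown group")
})

test_that("median-of-ratios size factors recover exact column scalars", {
  set.seed(11)
  base <- rexp(50, 0.01) + 1
  scal <- c(0.5, 1, 1.5, 2, 4)
  cnt <- outer(base, scal)
  dimnames(cnt) <- list(paste0("g", 1:50), paste0("s", 1:5))
  sf <- size_factors(cnt)
  # equal up to one common constant
  expect_equal(unname(sf / sf[2]), scal / scal[2], tolerance = 1e-12)
})

test_that("NB Wald stand-in is calibrated under the null and powered", {
  set.seed(19)
  g <- 2000
  mu <- 2^rnorm(g, 5, 2)
  cnt <- matrix(rnbinom(g * 20, mu = rep(mu, 20), size = 20), g, 20,
                dimnames = list(sprintf("g%04d", 1:g),
                                sprintf("s%02d", 1:20)))
  om <- two_group_om(cnt, 10, 10)
  res <- nb_wald_deg(om, "HFD", "SD")
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)

  aff <- sample(g, 200)
  cnt2 <- cnt
  cnt2[aff, 1:10] <- matrix(
    rnbinom(200 * 10, mu = rep(mu[aff] * 2, 10), size = 20), 200, 10)
  res2 <- nb_wald_deg(two_group_om(cnt2, 10, 10), "HFD", "SD")
  power <- mean(res2$significant[match(rownames(cnt)[aff],
                                       res2$feature)])
  expect_gte(power, 0.7)
  # all-zero rows are dropped and reported
  cnt3 <- rbind(cnt[1:50, ], zero_gene = 0)
  res3 <- nb_wald_deg(two_group_om(cnt3, 10, 10), "HFD", "SD")
  expect_equal(attr(res3, "dropped"), "zero_gene")
  expect_false("zero_gene" %in% res3$feature)
})

test_that("overlap analysis intersects significants and labels directions", {
  mk <- function(features, sig, fc) {
    r <- data.frame(feature = features, comparison = "x",
                    log2fc = fc, t = 1, p = 0.01, q = 0.01,
                    significant = sig, stringsAsFactors = FALSE)
    attr(r, "comparison") <- "x"
    class(r) <- c("differential_result", "data.frame")
    r
  }
  u <- letters[1:5]
  dis <- mk(u, u %in% c("a", "b", "c"), c(2, 1, -0.2, 0, 0))
  rev <- mk(u, u %in% c("b", "c", "d"), c(0, -0.4, -1.5, -2, 0))
  ov <- overlap_analysis(dis, rev)
  expect_setequal(ov$common$feature, c("b", "c"))
  # b: |1| > |-0.4| -> disease dominates, fc>0 -> increased_with_disease
  expect_equal(ov$common$direction[ov$common$feature == "b"],
               "increased_with_disease")
  # c: |-1.5| > |-0.2| -> reversal dominates, fc<0 -> decreased_with_reversal
  expect_equal(ov$common$direction[ov$common$feature == "c"],
               "decreased_with_reversal")
  # disjoint significant sets give an empty common set
  ov0 <- overlap_analysis(mk(u, u == "a", 1), mk(u, u == "e", 1))
  expect_equal(nrow(ov0$common), 0)
  expect_error(overlap_analysis(dis, mk(letters[2:6], TRUE, 1)),
               "universes differ")
})

test_that("cross-model commonality intersects and tallies classes", {
  mk_ov <- function(features) {
    structure(list(common = data.frame(
      feature = features, disease_log2fc = 1, reversal_log2fc = -1,
      direction = "increased_with_disease",
      stringsAsFactors = FALSE)), class = "comparison_overlap")
  }
  tg <- c("TG(16:0/16:0/18:1)", "TG(16:0/18:1/18:2)")
  ov1 <- mk_ov(c(tg, "PC(16:0/18:1)"))
  ov2 <- mk_ov(c(tg, "DG(16:0/18:1)"))
  cm <- cross_model_common(ov1, ov2)
  expect_equal(cm$n, 2)
  expect_equal(unname(cm$class_counts[["TG"]]), 2)
  expect_equal(cross_model_common(ov1, ov1)$shared,
               sort(ov1$common$feature))
  expect_equal(cross_model_common(ov1, mk_ov("ME(18:0)"))$n, 0)
})

test_that("hypergeometric enrichment matches the exact tail sum", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(hit = universe[1:5], other = universe[6:10])
  res <- enrichment(universe[1:5], sets, universe)
  expect_equal(res$p[res$set == "hit"], 1 / choose(20, 5))
  # disjoint set: overlap 0, p = 1
  expect_equal(res$p[res$set == "other"],
               phyper(-1, 5, 15, 5, lower.tail = FALSE))
  expect_equal(res$p[res$set == "other"], 1)
  # list = universe forces every overlap, p = 1 everywhere
  res_all <- enrichment(universe, sets, universe)
  expect_true(all(res_all$p == 1))
  expect_error(enrichment("g01", sets, character(0)), "empty universe")
  expect_error(enrichment("zz", sets, universe), "subset")
})

test_that("simulated enrichment ranks the planted lipid-metabolism set first", {
  sim <- tiny_sim()
  gen <- sim$genes
  universe <- rownames(gen$values)
  deg <- nb_wald_deg(gen, "HFD", "SD", "24wk")
  hits <- deg$feature[deg$significant]
  res <- enrichment(hits, sim$gene_sets, universe)
  # the two planted sets outrank the random ones
  expect_setequal(res$set[1:2],
                  c("lipid_metabolism", "joint_factor_module"))
  expect_lt(res$q[res$set == "lipid_metabolism"], 0.05)
})
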