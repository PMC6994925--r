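rand_feature_mat <- function(n_feat, n_samp, seed, prefix = "f") {
  set.seed(seed)
  matrix(rnorm(n_feat * n_samp), n_feat, n_samp,
         dimnames = list(sprintf("%s%02d", prefix, seq_len(n_feat)),
                         sprintf("s%02d", seq_len(n_samp))))
}

test_that("edges match the brute-force all-pairs Pearson oracle", {
  lm <- rand_feature_mat(20, 15, 1, "lip")
  gm <- rand_feature_mat(10, 15, 2, "gene")
  for (thr in c(0.3, 0.6)) {
    edges <- pearson_edges(lm, gm, threshold = thr)
    oracle <- pearson_oracle(lm, gm, threshold = thr)
    expect_equal(edge_key(edges), edge_key(oracle))
    # correlations agree numerically
    m <- merge(edges, oracle, by = c("from", "to"))
    expect_equal(m$r.x, m$r.y)
  }
})

test_that("no self-edges or gene-gene edges; perfect correlation kept", {
  lm <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 1, 2))
  colnames(lm) <- paste0("s", 1:3)
  gm <- rbind(g1 = c(1, 2, 3), g2 = c(1.1, 2, 3.2))
  colnames(gm) <- paste0("s", 1:3)
  edges <- pearson_edges(lm, gm, threshold = 0.6)
  expect_false(any(edges$from == edges$to))
  expect_true(any(edges$from == "a" & edges$to == "b" &
                    abs(edges$r - 1) < 1e-12))
  # g1-g2 are perfectly correlated but never linked
  expect_false(any(edges$from %in% c("g1", "g2")))
  expect_true(all(edges$kind %in% c("lipid-lipid", "lipid-gene")))
})

test_that("independent features rarely exceed the null threshold", {
  lm <- rand_feature_mat(10, 100, 3)
  edges <- pearson_edges(lm, threshold = 0.6)
  # P(|r| > 0.6) at n = 100 is ~1e-10; 45 pairs -> expect none
  expect_equal(nrow(edges), 0)
})

test_that("edge set is invariant to sample permutation and affine rescaling", {
  lm <- rand_feature_mat(12, 30, 5)
  # add some structure so edges exist
  lm[2, ] <- lm[1, ] + rnorm(30, sd = 0.3)
  lm[4, ] <- -lm[3, ] + rnorm(30, sd = 0.3)
  e1 <- pearson_edges(lm, threshold = 0.6)
  expect_gt(nrow(e1), 0)
  perm <- sample(ncol(lm))
  e2 <- pearson_edges(lm[, perm], threshold = 0.6)
  expect_equal(edge_key(e1), edge_key(e2))
  scaled <- lm * 3.2 + 7
  e3 <- pearson_edges(scaled, threshold = 0.6)
  expect_equal(edge_key(e1), edge_key(e3))
  # lowering the threshold never removes an edge
  e_low <- pearson_edges(lm, threshold = 0.3)
  expect_true(all(edge_key(e1) %in% edge_key(e_low)))
})

test_that("annotation filter intersects annotated and candidate genes", {
  ann <- data.frame(gene = sprintf("g%02d", 1:20),
                    lipid = rep(c("TG(16:0/18:1/18:2)", "absent"), 10),
                    stringsAsFactors = FALSE)
  res <- filter_genes_by_annotation(
    ann, candidate_genes = sprintf("g%02d", c(1, 3, 5, 7, 9, 11, 13, 15)),
    network_lipids = "TG(16:0/18:1/18:2)")
  # odd-numbered rows carry the present lipid
  expect_equal(res$n_annotated, 10)
  expect_equal(res$n_after_candidates, 8)
  expect_equal(res$gene_set, sprintf("g%02d", c(1, 3, 5, 7, 9, 11, 13, 15)))
  empty <- suppressMessages(filter_genes_by_annotation(
    ann[0, ], "g01", "TG(16:0/18:1/18:2)"))
  expect_equal(length(empty$gene_set), 0)
})

test_that("network nodes are exactly the edge endpoints; duplicates collapse", {
  edges <- data.frame(
    from = c("a", "a", "b", "a"), to = c("b", "c", "d", "b"),
    r = c(0.9, -0.8, 0.7, 0.9),
    kind = "lipid-lipid", stringsAsFactors = FALSE)
  g <- build_network(edges)
  expect_equal(sort(igraph::V(g)$name), c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(g), 3)
  expect_warning(g0 <- build_network(edges[0, ]), "empty edge list")
  expect_equal(igraph::vcount(g0), 0)
  # random fixture: node set equals union of endpoints
  lm <- rand_feature_mat(15, 20, 9)
  lm[2, ] <- lm[1, ] + rnorm(20, sd = 0.2)
  e <- pearson_edges(lm, threshold = 0.5)
  gg <- build_network(e)
  expect_setequal(igraph::V(gg)$name, unique(c(e$from, e$to)))
})

test_that("subnetwork detection separates disconnected cliques", {
  tri <- function(nodes) {
    data.frame(from = nodes[c(1, 2, 3)], to = nodes[c(2, 3, 1)],
               r = 0.9, kind = "lipid-lipid", stringsAsFactors = FALSE)
  }
  g <- build_network(rbind(tri(c("a", "b", "c")),
                           tri(c("x", "y", "z"))))
  for (method in c("components", "modularity")) {
    sub <- detect_subnetworks(g, method = method)
    expect_equal(sub$n_subnetworks, 2)
    expect_equal(sort(sub$sizes$size), c(3, 3))
    expect_equal(length(unique(sub$membership[c("a", "b", "c")])), 1)
    expect_equal(length(unique(sub$membership[c("x", "y", "z")])), 1)
  }
  # a single path of 2 nodes is one subnetwork
  p2 <- build_network(data.frame(from = "u", to = "v", r = 0.9,
                                 kind = "lipid-lipid"))
  expect_equal(detect_subnetworks(p2)$n_subnetworks, 1)
  # large flag threshold: max(24, 10% of nodes)
  expect_equal(detect_subnetworks(p2)$large_size, 24)
})

test_that("modularity clustering recovers planted dense blocks", {
  recovered <- sapply(1:10, function(seed) {
    set.seed(seed)
    nodes <- sprintf("n%02d", 1:30)
    block <- rep(1:2, each = 15)
    edges <- NULL
    for (i in 1:29) {
      for (j in (i + 1):30) {
        p <- if (block[i] == block[j]) 0.9 else 0.02
        if (runif(1) < p) {
          edges <- rbind(edges, data.frame(
            from = nodes[i], to = nodes[j], r = 0.9,
            kind = "lipid-lipid", stringsAsFactors = FALSE))
        }
      }
    }
    g <- build_network(edges)
    if (igraph::vcount(g) < 30) return(FALSE)
    sub <- detect_subnetworks(g, method = "modularity")
    memb <- sub$membership[nodes]
    length(unique(memb[1:15])) == 1 &&
      length(unique(memb[16:30])) == 1 &&
      memb[1] != memb[16]
  })
  expect_gte(mean(recovered), 0.9)
})

test_that("subnetwork detection is deterministic", {
  lm <- rand_feature_mat(25, 20, 13)
  for (i in seq(1, 23, by = 2)) {
    lm[i + 1, ] <- lm[i, ] + rnorm(20, sd = 0.4)
  }
  e <- pearson_edges(lm, threshold = 0.5)
  g <- build_network(e)
  s1 <- detect_subnetworks(g)
  s2 <- detect_subnetworks(build_network(e))
  expect_identical(s1$membership, s2$membership)
})

test_that("reversal annotation follows the direction and conflict rules", {
  g <- build_network(data.frame(
    from = c("lip1", "lip2", "lip3"), to = c("lip2", "lip3", "g1"),
    r = 0.9, kind = c("lipid-lipid", "lipid-lipid", "lipid-gene"),
    stringsAsFactors = FALSE))
  mk_ov <- function(features, fc) {
    structure(list(common = data.frame(
      feature = features, disease_log2fc = fc, reversal_log2fc = -fc,
      direction = "increased_with_disease",
      stringsAsFactors = FALSE)), class = "comparison_overlap")
  }
  ov1 <- mk_ov(c("lip1", "lip2"), c(1.2, 0.5))
  ov2 <- mk_ov("lip2", -1.0)
  expect_message(g2 <- annotate_reversal(g, list(ov1, ov2)),
                 "conflicting")
  status <- setNames(igraph::V(g2)$reversal_status,
                     igraph::V(g2)$name)
  expect_equal(unname(status["lip1"]), "reversed_up_in_disease")
  # conflict resolved towards the larger |log2FC| (-1.0 beats +0.5)
  expect_equal(unname(status["lip2"]), "reversed_down_in_disease")
  expect_equal(unname(status["lip3"]), "not_reversed")
  expect_equal(attr(g2, "reversal_conflicts"), "lip2")
})

test_that("network export writes GraphML and an edge list", {
  g <- build_network(data.frame(from = "a", to = "b", r = 0.8,
                                kind = "lipid-lipid"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  el <- withr::local_tempfile(fileext = ".tsv")
  write_network(g, graphml = gml, edgelist = el)
  expect_true(file.exists(gml))
  back <- read.delim(el)
  expect_equal(back$r, 0.8)
})
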