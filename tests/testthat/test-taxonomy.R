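sig <- function(id, content, ord, topology = "linear") {
  structure(list(genome_id = id, content = content, order = ord,
                 topology = topology), class = "genome_signature")
}

test_that("generalized Jaccard: identity, hand case, disjoint, degenerate", {
  expect_equal(generalized_jaccard(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(generalized_jaccard(c(1, 2, 0), c(2, 1, 1)), 0.4)
  expect_equal(generalized_jaccard(c(1, 0), c(0, 2)), 0)
  expect_warning(z <- generalized_jaccard(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 0)
})

test_that("organization similarity: LCS over orientations and rotations", {
  a <- sig("A", c(p1 = 1, p2 = 1, p3 = 1), c("p1", "p2", "p3"))
  b <- sig("B", c(p1 = 1, p2 = 1, p3 = 1), c("p1", "p3", "p2"))
  expect_equal(organization_similarity(a, a), 1)
  expect_equal(organization_similarity(a, b), 2 / 3)
  rev_b <- sig("B", c(p1 = 1, p2 = 1, p3 = 1), c("p3", "p2", "p1"))
  expect_equal(organization_similarity(a, rev_b), 1)
  # circular rotation scores 1 when either genome is circular
  rot <- sig("B", c(p1 = 1, p2 = 1, p3 = 1), c("p3", "p1", "p2"),
             topology = "circular")
  expect_equal(organization_similarity(a, rot), 1)
  rot_lin <- sig("B", c(p1 = 1, p2 = 1, p3 = 1), c("p3", "p1", "p2"))
  expect_equal(organization_similarity(a, rot_lin), 2 / 3)
  # no shared PCs
  other <- sig("C", c(q1 = 1), "q1")
  expect_equal(organization_similarity(a, other), 0)
})

test_that("CGJ distance composes content and order geometrically", {
  # Jc = 0.25 (content ratio 1:4 over 25 PCs), Jo = 0.64 (LIS 16 of 25)
  pcs <- sprintf("p%02d", 1:25)
  a <- sig("A", setNames(rep(1, 25), pcs), pcs)
  b_ord <- pcs[c(1:15, 25:16)]
  b <- sig("B", setNames(rep(4, 25), pcs), b_ord)
  r <- cgj_distance(a, b)
  expect_equal(r$j_content, 0.25)
  expect_equal(r$j_org, 0.64)
  expect_equal(r$distance, 0.6)
  expect_equal(cgj_distance(a, a)$distance, 0)
  # content signal absent forces distance 1
  c0 <- sig("C", setNames(c(rep(0, 25), 1), c(pcs, "q")), "q")
  a2 <- sig("A", setNames(c(rep(1, 25), 0), c(pcs, "q")), pcs)
  expect_equal(cgj_distance(a2, c0)$distance, 1)
})

test_that("UPGMA: hand-computed heights and deterministic ties", {
  D <- matrix(c(0, 0.6, 0.6, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  t2 <- upgma(D)
  expect_equal(t2$merges[[1]]$distance, 0.6)
  expect_equal(unname(t2$phylo$edge.length), c(0.3, 0.3))
  D3 <- matrix(c(0, 0.2, 0.8, 0.2, 0, 0.8, 0.8, 0.8, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- upgma(D3)
  expect_equal(vapply(t3$merges, `[[`, 0, "distance"), c(0.2, 0.8))
  expect_true(ape::is.monophyletic(t3$phylo, c("a", "b")))
  # duplicates merge at height 0
  D0 <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(upgma(D0)$merges[[1]]$distance, 0)
  expect_error(upgma(matrix(c(0, NA, NA, 0), 2, 2,
                            dimnames = list(c("a", "b"), c("a", "b")))),
               "NA")
})

test_that("UPGMA agrees with hclust average linkage on random matrices", {
  set.seed(501)
  for (i in 1:5) {
    n <- sample(5:9, 1)
    m <- matrix(runif(n * n), n, n)
    D <- (m + t(m)) / 2
    diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    ours <- upgma(D)
    hc <- hclust(as.dist(D), method = "average")
    expect_equal(sort(vapply(ours$merges, `[[`, 0, "distance")),
                 sort(hc$height))
  }
})

test_that("family cut: thresholds, degenerate cases, monotone coarsening", {
  ids <- c("g1", "g2", "g3")
  D <- matrix(0.9, 3, 3, dimnames = list(ids, ids))
  diag(D) <- 0
  tr <- upgma(D)
  fam <- cut_families(tr, h = 0.8)
  expect_equal(length(unique(fam)), 3L)
  expect_equal(length(unique(cut_families(tr, h = 0))), 3L)
  expect_equal(length(unique(cut_families(tr, h = 0.95))), 1L)
  set.seed(502)
  m <- matrix(runif(64), 8, 8)
  D2 <- (m + t(m)) / 2
  diag(D2) <- 0
  dimnames(D2) <- list(letters[1:8], letters[1:8])
  tr2 <- upgma(D2)
  prev <- cut_families(tr2, h = 0)
  for (h in seq(0.1, 1, by = 0.1)) {
    cur <- cut_families(tr2, h = h)
    # coarsening: clusters at smaller h nest inside clusters at larger h
    expect_true(all(tapply(cur, prev, function(x) length(unique(x))) == 1L))
    prev <- cur
  }
})

test_that("genus assignment is single-linkage over >60% shared", {
  ids <- c("A", "B", "C")
  sh <- matrix(c(100, 70, 20, 70, 100, 20, 20, 20, 100), 3, 3,
               dimnames = list(ids, ids))
  fam <- setNames(rep("F01", 3), ids)
  g <- assign_genera(fam, sh)
  expect_identical(g[["A"]], g[["B"]])
  expect_false(g[["A"]] == g[["C"]])
  # chain A-B 65, B-C 65, A-C 20 -> one genus by single linkage
  sh2 <- matrix(c(100, 65, 20, 65, 100, 65, 20, 65, 100), 3, 3,
                dimnames = list(ids, ids))
  g2 <- assign_genera(fam, sh2)
  expect_equal(length(unique(g2)), 1L)
  # exactly at the threshold is not enough (strict >)
  sh3 <- matrix(c(100, 60, 60, 60, 100, 60, 60, 60, 100), 3, 3,
                dimnames = list(ids, ids))
  expect_equal(length(unique(assign_genera(fam, sh3))), 3L)
})

test_that("classify: validation, unrelated pair, determinism, nesting", {
  set.seed(503)
  sim <- gen_taxonomy_set(n_families = 2, genera_per_family = 1,
                          genomes_per_genus = 2, family_core = 6,
                          genus_core = 6, private_genes = 3, seed = 503)
  expect_error(classify(sim$genomes[1]), "at least two")
  tx <- classify(sim$genomes)
  expect_equal(ari_of(tx, sim$truth$genomes, "family"), 1)
  expect_equal(ari_of(tx, sim$truth$genomes, "genus"), 1)
  # genus partition refines family partition
  split_fam <- split(tx$assignment$genus, tx$assignment$family)
  expect_true(all(!duplicated(unlist(lapply(split_fam, unique)))))
  # deterministic re-run
  tx2 <- classify(sim$genomes)
  expect_identical(tx$assignment, tx2$assignment)
  expect_identical(tx$tree$newick, tx2$tree$newick)
  # two unrelated genomes -> 2 families, 2 genera
  two <- list(sim$genomes[[1]], sim$genomes[[3]])
  tx3 <- classify(two)
  expect_equal(length(unique(tx3$assignment$family)), 2L)
  expect_equal(length(unique(tx3$assignment$genus)), 2L)
})

test_that("CGJ matrix is a proper distance-like object", {
  set.seed(504)
  sim <- gen_taxonomy_set(n_families = 1, genera_per_family = 2,
                          genomes_per_genus = 2, family_core = 6,
                          genus_core = 6, private_genes = 2, seed = 504)
  tx <- classify(sim$genomes)
  D <- tx$cgj$D
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})
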