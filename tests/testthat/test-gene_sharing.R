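# helpers to build proteome tables directly
ptab <- function(genome, seqs) {
  data.frame(protein_id = paste0(genome, "|p", seq_along(seqs)),
             sequence = seqs, gene_id = paste0("p", seq_along(seqs)),
             start = seq_along(seqs) * 1000L,
             end = seq_along(seqs) * 1000L + 500L,
             strand = "+", stringsAsFactors = FALSE)
}

test_that("identical proteomes give full cross-genome edges at 100% identity", {
  set.seed(401)
  seqs <- replicate(10, rand_aa_string(150))
  g <- all_vs_all(list(A = ptab("A", seqs), B = ptab("B", seqs)))
  e <- g$edges
  cross <- e[substr(e$p1, 1, 1) != substr(e$p2, 1, 1), ]
  expect_equal(nrow(cross), 10L)
  expect_true(all(cross$identity_pct == 100))
  expect_equal(shared_fraction("A", "B", g), 100)
})

test_that("unrelated proteomes give no edges and zero shared fraction", {
  set.seed(402)
  g <- all_vs_all(list(A = ptab("A", replicate(8, rand_aa_string(150))),
                       B = ptab("B", replicate(8, rand_aa_string(150)))))
  expect_equal(nrow(g$edges), 0L)
  expect_equal(shared_fraction("A", "B", g), 0)
  pcs <- protein_clusters(g)
  expect_equal(nrow(pcs$clusters), 16L) # all singletons
  expect_true(all(pcs$clusters$size == 1L))
})

test_that("loosening thresholds can only add edges", {
  set.seed(403)
  base <- replicate(6, rand_aa_string(150))
  mut <- vapply(base, function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(150, 60)
    ch[idx] <- sample(c("A", "R", "N", "D"), 60, replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  prots <- list(A = ptab("A", base), B = ptab("B", mut))
  strict <- all_vs_all(prots, min_identity = 30, max_evalue = 1e-25)
  loose <- all_vs_all(prots, min_identity = 0, max_evalue = 1)
  key <- function(e) paste(pmin(e$p1, e$p2), pmax(e$p1, e$p2))
  expect_true(all(key(strict$edges) %in% key(loose$edges)))
})

test_that("protein clusters are single-linkage components with deterministic ids", {
  # a-b and b-c homologous, a-c not: b is a chimera of a and c
  set.seed(404)
  half1 <- rand_aa_string(120)
  half2 <- rand_aa_string(120)
  a <- paste0(half1, rand_aa_string(120))
  cc <- paste0(rand_aa_string(120), half2)
  b <- paste0(half1, half2)
  g <- all_vs_all(list(G1 = ptab("G1", c(a, b)), G2 = ptab("G2", cc)))
  key <- paste(pmin(g$edges$p1, g$edges$p2), pmax(g$edges$p1, g$edges$p2))
  expect_setequal(key, c("G1|p1 G1|p2", "G1|p2 G2|p1"))
  pcs <- protein_clusters(g)
  expect_equal(nrow(pcs$clusters), 1L)
  expect_equal(pcs$clusters$size, 3L)
  # representative is the longest member (a and c are 240 aa, b 240 too ->
  # lexicographic tie-break)
  expect_identical(pcs$clusters$representative, "G1|p1")
})

test_that("PCs on a planted gene pool match truth labels exactly", {
  set.seed(405)
  sim <- gen_taxonomy_set(n_families = 2, genera_per_family = 2,
                          genomes_per_genus = 2, family_core = 5,
                          genus_core = 5, private_genes = 3, seed = 405)
  g <- all_vs_all(sim$genomes)
  pcs <- protein_clusters(g)
  truth <- sim$truth$genes
  truth$protein_id <- paste0(truth$genome_id, "|", truth$gene_id)
  got <- setNames(pcs$membership$pc_id, pcs$membership$protein_id)
  expect_equal(adjusted_rand_index(got[truth$protein_id],
                                   setNames(truth$pc_truth,
                                            truth$protein_id)), 1)
  # invariant: PC sizes partition the protein set
  expect_equal(sum(pcs$clusters$size), nrow(g$proteins))
})

test_that("shared fraction: hand-constructed 70% case and scale freedom", {
  set.seed(406)
  shared <- replicate(7, rand_aa_string(150))
  privA <- replicate(3, rand_aa_string(150))
  privB <- replicate(2, rand_aa_string(150))
  g <- all_vs_all(list(A = ptab("A", c(shared, privA)),
                       B = ptab("B", c(shared, privB))))
  expect_equal(shared_fraction("A", "B", g), 70)
  expect_equal(shared_fraction("B", "A", g), 700 / 9, tolerance = 1e-10)
  expect_equal(shared_fraction("A", "B", g, symmetric = TRUE),
               (70 + 700 / 9) / 2)
  # duplicating every gene of A leaves the directed fraction unchanged
  g2 <- all_vs_all(list(A = ptab("A", rep(c(shared, privA), 2)),
                        B = ptab("B", c(shared, privB))))
  expect_equal(shared_fraction("A", "B", g2), 70)
  # matrix agrees with the scalar op
  m <- shared_fraction_matrix(g)
  expect_equal(m["A", "B"], 70)
  expect_equal(m["A", "A"], 100)
})

test_that("signatures: content is order-invariant, absent PCs are zero", {
  set.seed(407)
  seqs <- replicate(5, rand_aa_string(150))
  pa <- ptab("A", seqs)
  pb <- ptab("B", seqs[1:3])
  g <- all_vs_all(list(A = pa, B = pb))
  pcs <- protein_clusters(g)
  sig <- signatures(g, pcs)
  expect_setequal(names(sig), c("A", "B"))
  expect_equal(length(sig$A$order), 5L)
  expect_equal(length(sig$B$order), 3L)
  # B lacks two PCs -> zero content there
  expect_equal(sum(sig$B$content == 0), 2L)
  # permuting gene order permutes order but not content
  pa2 <- pa[c(3, 1, 5, 2, 4), ]
  pa2$start <- sort(pa2$start)
  g2 <- all_vs_all(list(A = pa2, B = pb))
  sig2 <- signatures(g2, protein_clusters(g2))
  expect_equal(sort(sig2$A$content), sort(sig$A$content))
  expect_false(identical(sig2$A$order, sig$A$order))
})
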