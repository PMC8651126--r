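test_that("motif counting: palindrome, wraparound, strand handling, N", {
  expect_equal(count_motif("GATCGATC", "GATC"), 2L)
  expect_equal(count_motif("AAAAAA", "GATC"), 0L)
  expect_equal(count_motif("TCGA", "GATC", topology = "circular"), 1L)
  expect_equal(count_motif("TCGA", "GATC", topology = "linear"), 0L)
  # non-palindromic motifs count both strands: GAC forward + GTC (= revcomp)
  expect_equal(count_motif("GACGTC", "GAC"), 2L)
  # overlap-inclusive counting (AA forward 3x; revcomp TT absent)
  expect_equal(count_motif("AAAA", "AA"), 3L)
  # N never matches
  expect_equal(count_motif("GANC", "GATC"), 0L)
  # GATC matches GANC forward and its revcomp GNTC -> both strands count
  expect_equal(count_motif("GATC", "GANC"), 2L)
  expect_equal(count_motif("GANC", "GANC"), 0L)
  expect_error(count_motif("ACGT", "QQ"), "invalid IUPAC")
})

test_that("reverse-complement invariance of strand-symmetric counts", {
  set.seed(801)
  for (i in 1:5) {
    s <- rand_dna_string(3000, gc = 0.62)
    for (motif in c("GATC", "GAC", "GGWCC")) {
      expect_equal(count_motif(s, motif), count_motif(revcomp(s), motif))
    }
  }
})

test_that("counting agrees with a regex oracle on random sequences", {
  set.seed(802)
  iupac_re <- c(A = "A", C = "C", G = "G", T = "T", W = "[AT]", S = "[CG]",
                N = "[ACGT]")
  regex_count <- function(s, motif) {
    pat <- paste0("(?=", paste(iupac_re[strsplit(motif, "")[[1]]],
                               collapse = ""), ")")
    length(gregexpr(pat, s, perl = TRUE)[[1]]) -
      (gregexpr(pat, s, perl = TRUE)[[1]][1] == -1)
  }
  for (i in 1:5) {
    s <- rand_dna_string(2000)
    expect_equal(count_motif(s, "GATC"), regex_count(s, "GATC"))
    expect_equal(count_motif(s, "GGWCC"), regex_count(s, "GGWCC")) # palindromic
    m <- "GACN" # revcomp NGTC: both strands counted
    expect_equal(count_motif(s, m),
                 regex_count(s, m) + regex_count(s, "NGTC"))
  }
})

test_that("freq_per_kbp arithmetic", {
  expect_equal(freq_per_kbp(2, 8), 250)
  expect_equal(freq_per_kbp(0, 5000), 0)
  expect_error(freq_per_kbp(1, 0))
})

test_that("Markov expected counts: closed form and trivial motifs", {
  # near-uniform composition: expected ~ (L - k + 1) / 4^k
  s <- paste(rep("ACGT", 251), collapse = "")
  s <- substr(s, 1, 1003)
  e0 <- expected_count_markov(s, "GATC", order = 0)
  expect_equal(e0, 1000 * (1 / 4)^4, tolerance = 0.01)
  # single-base N motif: every position matches
  expect_equal(expected_count_markov(s, "N", order = 0), 1003)
  # unobserved transition -> 0 with warning
  s2 <- strrep("AC", 200)
  expect_warning(z <- expected_count_markov(s2, "GG", order = 1),
                 "never observed")
  expect_equal(z, 0)
})

test_that("observed/expected is calibrated on true Markov null sequences", {
  set.seed(803)
  for (ord in 0:2) {
    oe <- replicate(60, {
      s <- markov_chain_seq(2500, order = ord)
      count_motif(s, "GATC") / expected_count_markov(s, "GATC", order = ord)
    })
    expect_equal(mean(oe), 1, tolerance = 0.06)
  }
})

test_that("Mann-Whitney U: hand enumeration, symmetry, wilcox oracle", {
  r <- compare_mtase_groups(c(1, 2, 3), c(10, 11, 12),
                            alternative = "less")
  expect_equal(r$U, 0) # no pair has x > y
  expect_equal(r$p_value, 1 / 20) # 1 of choose(6,3)=20 orderings
  r2 <- compare_mtase_groups(c(10, 11, 12), c(1, 2, 3),
                             alternative = "less")
  expect_equal(r2$U, 9)
  expect_equal(r2$p_value, 1)
  same <- compare_mtase_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 4.5) # n*m/2 with full ties
  expect_gt(same$p_value, 0.9)
  # oracle: exact wilcox.test on tie-free data (same U convention)
  set.seed(804)
  for (i in 1:10) {
    x <- runif(6)
    y <- runif(7)
    ours <- compare_mtase_groups(x, y, alternative = "two.sided")
    w <- wilcox.test(x, y, exact = TRUE)
    expect_equal(unname(w$statistic), ours$U)
    expect_equal(ours$p_value, w$p.value, tolerance = 1e-10)
  }
  # normal approximation tracks wilcox.test's for larger groups
  x <- rnorm(12)
  y <- rnorm(15, 0.5)
  ours <- compare_mtase_groups(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
  expect_error(compare_mtase_groups(1:3, 5), "at least 2")
})

test_that("motif genome generator hits its depletion target", {
  sim1 <- gen_motif_genomes(n = 3, length = 20000, depletion_factor = 1,
                            seed = 805)
  rep1 <- motif_report(sim1$genomes)
  expect_true(all(rep1$oe_ratio >= 0.9 & rep1$oe_ratio <= 1.1))
  sim0 <- gen_motif_genomes(n = 2, length = 20000, depletion_factor = 0,
                            seed = 806)
  expect_true(all(motif_report(sim0$genomes)$count == 0))
  simd <- gen_motif_genomes(n = 2, length = 20000, depletion_factor = 0.3,
                            seed = 807)
  repd <- motif_report(simd$genomes)
  expect_true(all(abs(repd$oe_ratio - 0.3) <= 0.03 + 1e-9))
  expect_error(gen_motif_genomes(depletion_factor = 1.5), "unreachable")
})

test_that("frequency of a concatenation lies between the parts", {
  set.seed(808)
  a <- rand_dna_string(8000, gc = 0.62)
  b <- gen_motif_genomes(n = 1, length = 8000, depletion_factor = 0.2,
                         seed = 809)$genomes[[1]]$sequence
  fa <- freq_per_kbp(count_motif(a, "GATC"), nchar(a))
  fb <- freq_per_kbp(count_motif(b, "GATC"), nchar(b))
  fab <- freq_per_kbp(count_motif(paste0(a, b), "GATC"), nchar(a) + nchar(b))
  expect_gte(fab, min(fa, fb) - 0.2)
  expect_lte(fab, max(fa, fb) + 0.2)
})

test_that("motif report fields and MTase status labelling", {
  sim <- gen_motif_genomes(n = 2, length = 15000, seed = 810)
  status <- setNames(c("encodes", "lacks"),
                     vapply(sim$genomes, `[[`, "", "id"))
  rep <- motif_report(sim$genomes, mtase_status = status)
  expect_identical(rep$mtase_status, c("encodes", "lacks"))
  expect_equal(rep$freq_per_kbp, rep$count / (rep$length_bp / 1000))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_motif_report(rep, p)
  expect_equal(nrow(read.table(p, header = TRUE, sep = "\t")), 2L)
})
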