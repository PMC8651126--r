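# Independent oracles and small fixture builders shared across the suite.

# Brute-force affine-gap Smith-Waterman oracle: full three-matrix DP in
# plain R, written independently of the C++ kernels. Gap of length L
# costs go + L * ge.
oracle_sw_score <- function(a, b, sub, go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      FF[i, j] <- max(H[i - 1, j] - go - ge, FF[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[A[i - 1], B[j - 1]],
                     E[i, j], FF[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

rand_aa_string <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n,
               replace = TRUE), collapse = "")
}

rand_dna_string <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# order-`order` Markov chain sampler used as the independent null for the
# observed/expected invariant (kept separate from the package generators)
markov_chain_seq <- function(L, order = 1, trans = NULL, init = NULL) {
  bases <- c("A", "C", "G", "T")
  if (order == 0) {
    p <- if (is.null(init)) rep(0.25, 4) else init
    return(paste(sample(bases, L, replace = TRUE, prob = p), collapse = ""))
  }
  if (is.null(trans)) {
    trans <- matrix(runif(4^order * 4, 0.5, 1.5), ncol = 4)
    trans <- trans / rowSums(trans)
  }
  x <- integer(L)
  x[seq_len(order)] <- sample.int(4, order, replace = TRUE)
  for (i in (order + 1):L) {
    ctx <- if (order == 1) x[i - 1] else (x[i - 2] - 1) * 4 + x[i - 1]
    x[i] <- sample.int(4, 1, prob = trans[ctx, ])
  }
  paste(bases[x], collapse = "")
}

# small two-gene genome fixture: one forward CDS, one reverse CDS
two_gene_genome <- function(id = "fix01", seed = 42) {
  set.seed(seed)
  p1 <- paste0("M", rand_aa_string(40))
  p2 <- paste0("M", rand_aa_string(30))
  nt1 <- viratax:::back_translate(strsplit(p1, "")[[1]], gc = 0.5)
  nt2 <- viratax:::back_translate(strsplit(p2, "")[[1]], gc = 0.5)
  sp <- replicate(3, rand_dna_string(60))
  seqs <- paste0(sp[1], nt1, sp[2], revcomp(nt2), sp[3])
  g1 <- gene_record("geneA", id, start = 60, end = 60 + nchar(nt1),
                    strand = "+", product = "protein A", protein = p1)
  s2 <- 60 + nchar(nt1) + 60
  g2 <- gene_record("geneB", id, start = s2, end = s2 + nchar(nt2),
                    strand = "-", product = "protein B", protein = p2)
  new_genome(id, seqs, genes = rbind(g1, g2))
}

ari_of <- function(tx, truth, level = "family") {
  adjusted_rand_index(
    setNames(tx$assignment[[level]], tx$assignment$genome_id),
    setNames(truth[[level]], truth$genome_id))
}
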