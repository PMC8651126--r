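test_that("GenBank round-trip preserves sequence, coordinates, strands", {
  g <- two_gene_genome()
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g, path)
  back <- read_genbank(path)
  expect_length(back, 1L)
  b <- back[[1]]
  expect_identical(b$sequence, g$sequence)
  expect_identical(b$topology, g$topology)
  expect_equal(nrow(b$genes), 2L)
  expect_identical(b$genes$start, g$genes$start)
  expect_identical(b$genes$end, g$genes$end)
  expect_identical(b$genes$strand, g$genes$strand)
  expect_identical(b$genes$protein, g$genes$protein)
  # second round trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(b, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("multi-record and empty GenBank files", {
  g1 <- two_gene_genome("fixA", seed = 1)
  g2 <- two_gene_genome("fixB", seed = 2)
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(list(g1, g2), path)
  back <- read_genbank(path)
  expect_length(back, 2L)
  expect_identical(vapply(back, `[[`, "", "id"), c("fixA", "fixB"))
  empty <- withr::local_tempfile(fileext = ".gbk")
  writeLines(character(0), empty)
  expect_identical(read_genbank(empty), list())
})

test_that("origin-spanning join() CDS on a circular genome round-trips", {
  set.seed(7)
  prot <- paste0("M", rand_aa_string(18))
  nt <- viratax:::back_translate(strsplit(prot, "")[[1]], gc = 0.5) # 60 nt
  filler <- rand_dna_string(60)
  # genome: last 30 nt of the gene, filler, first 30 nt of the gene
  seqs <- paste0(substr(nt, 31, 60), filler, substr(nt, 1, 30))
  L <- nchar(seqs)
  gn <- gene_record("wrap1", "circ1", start = L - 30L, end = L + 30L,
                    strand = "+", product = "wraparound protein",
                    protein = prot, wraparound = TRUE)
  g <- new_genome("circ1", seqs, topology = "circular", genes = gn)
  expect_identical(viratax:::gene_seq(g, 1L), nt)
  expect_identical(sub("\\*$", "", viratax:::translate_cds(nt)), prot)
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g, path)
  b <- read_genbank(path)[[1]]
  expect_true(b$genes$wraparound[1])
  expect_identical(b$genes$start[1], L - 30L)
  expect_identical(b$genes$end[1], L + 30L)
  expect_identical(b$genes$protein[1], prot)
})

test_that("translation is used from coordinates when qualifier is absent", {
  g <- two_gene_genome()
  path <- withr::local_tempfile(fileext = ".gbk")
  txt <- {
    write_genbank(g, path)
    readLines(path)
  }
  # strip the /translation qualifiers and re-parse
  drop <- grepl('/translation=', txt)
  # translation spans multiple lines until the closing quote
  keep <- rep(TRUE, length(txt))
  i <- 1
  while (i <= length(txt)) {
    if (grepl('/translation="', txt[i])) {
      while (!grepl('"$', txt[i])) { keep[i] <- FALSE; i <- i + 1 }
      keep[i] <- FALSE
    }
    i <- i + 1
  }
  path2 <- withr::local_tempfile(fileext = ".gbk")
  writeLines(txt[keep], path2)
  b <- read_genbank(path2)[[1]]
  expect_identical(b$genes$protein, g$genes$protein)
})

test_that("ambiguity codes other than N are rejected", {
  expect_error(new_genome("bad", "ACGTRY"), "outside")
  g <- new_genome("okN", "ACGTNNACGT")
  expect_identical(g$length, 10L)
})

test_that("ORF caller recovers a planted ORF and mirrors on revcomp", {
  set.seed(11)
  prot <- paste0("M", rand_aa_string(99)) # 100 codons
  nt <- viratax:::back_translate(strsplit(prot, "")[[1]], gc = 0.5)
  left <- rand_dna_string(300)
  right <- rand_dna_string(300)
  seqs <- paste0(left, nt, right)
  orfs <- call_orfs(seqs, min_aa = 50)
  planted_start <- nchar(left)
  planted_end <- nchar(left) + nchar(nt)
  # the planted ORF is recovered; its start may extend upstream only if an
  # in-frame start precedes with no stop, so check the stop-anchored end
  hit <- orfs[orfs$end == planted_end & orfs$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_lte(hit$start, planted_start)
  expect_true(grepl(substr(prot, 2, 100), hit$protein, fixed = TRUE))
  # mirror property on the reverse complement
  rc <- call_orfs(revcomp(seqs), min_aa = 50)
  L <- nchar(seqs)
  mirrored <- data.frame(start = L - rc$end, end = L - rc$start,
                         strand = ifelse(rc$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start, mirrored$end, mirrored$strand), ]
  orig <- orfs[order(orfs$start, orfs$end, orfs$strand),
               c("start", "end", "strand")]
  rownames(orig) <- rownames(mirrored) <- NULL
  expect_equal(mirrored, orig)
})

test_that("ORF caller on all-N sequence returns nothing", {
  expect_equal(nrow(call_orfs(strrep("N", 600))), 0L)
})

test_that("proteome extraction: order, duplicates, empty", {
  g <- two_gene_genome()
  p <- extract_proteome(g)
  expect_identical(p$gene_id, c("geneA", "geneB"))
  expect_identical(p$protein_id, paste0(g$id, "|", c("geneA", "geneB")))
  expect_true(all(diff(p$start) > 0))
  # duplicate ids get suffixed with a warning
  g2 <- g
  g2$genes$gene_id <- c("dup", "dup")
  expect_warning(p2 <- extract_proteome(g2), "duplicate")
  expect_identical(p2$gene_id, c("dup", "dup.1"))
  # zero CDS
  g3 <- new_genome("nogene", "ACGTACGTAC")
  expect_equal(nrow(extract_proteome(g3)), 0L)
})

test_that("FASTA I/O round-trips with 70-column wrap", {
  x <- c(a = rand_dna_string(150), b = rand_dna_string(30))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(x, path, type = "DNA")
  expect_lte(max(nchar(readLines(path))), 70L)
  expect_identical(read_fasta(path, type = "DNA"), x)
})
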