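# Seeded synthetic-data generators: every input the pipeline consumes,
# with ground-truth labels. Protein evolution uses per-site uniform
# substitution (each mutated site moves to one of the 19 other residues),
# which is sufficient to control expected percent identity - the only
# quantity the downstream thresholds see.

rand_dna <- function(n, gc = 0.62) {
  if (n <= 0) return("")
  paste(sample(DNA_ALPHABET[1:4], n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rand_protein_chars <- function(len) {
  c("M", sample(AA20, len - 1L, replace = TRUE))
}

# mutate each site (except the initiator M) with probability e to a
# uniformly chosen different residue
mutate_protein_chars <- function(p, e) {
  n <- length(p)
  if (n < 2L || e <= 0) return(p)
  hit <- which(runif(n - 1L) < e) + 1L
  if (!length(hit)) return(p)
  # uniform over the 19 residues other than the current one: draw an index
  # in 1..19 and skip past the current residue
  cur <- match(p[hit], AA20)
  u <- sample.int(19L, length(hit), replace = TRUE)
  p[hit] <- AA20[u + (u >= cur)]
  p
}

# mismatch probability of a path made of two branches with per-branch
# mismatch probabilities q1, q2 under the uniform-substitution channel
combine_mismatch <- function(q1, q2) q1 + q2 - (20 / 19) * q1 * q2

# per-branch mismatch probability e such that two leaves joined through a
# common ancestor (one branch each) show pairwise mismatch q
branch_error <- function(q) {
  stopifnot(q >= 0, q < 1)
  (19 / 20) * (1 - sqrt(1 - (20 / 19) * q))
}

codon_tables <- function(gc = 0.62) {
  key <- paste0("codons_", gc)
  if (!is.null(.viratax[[key]])) return(.viratax[[key]])
  gc11 <- genetic_code_11()
  by_aa <- split(names(gc11), unname(gc11))
  w_of <- function(codon) {
    b <- strsplit(codon, "")[[1]]
    prod(ifelse(b %in% c("G", "C"), gc / 2, (1 - gc) / 2))
  }
  tabs <- lapply(by_aa, function(cands)
    list(codons = cands, w = vapply(cands, w_of, 0)))
  .viratax[[key]] <- tabs
  tabs
}

# GC-weighted synonymous codon choice (vectorized per residue type)
back_translate <- function(p, gc = 0.62) {
  tabs <- codon_tables(gc)
  codons <- character(length(p))
  codons[1L] <- "ATG"
  rest <- seq_along(p)[-1L]
  for (aa in unique(p[rest])) {
    at <- rest[p[rest] == aa]
    tb <- tabs[[aa]]
    codons[at] <- if (length(tb$codons) == 1L) tb$codons
                  else sample(tb$codons, length(at), replace = TRUE,
                              prob = tb$w)
  }
  tb <- tabs[["*"]]
  stop_codon <- sample(tb$codons, 1L, prob = tb$w)
  paste(c(codons, stop_codon), collapse = "")
}

#' Generate a synthetic multi-family virus genome set with known taxonomy
#'
#' Families share `family_core` ancestral proteins (diverged to
#' `within_family_identity` between genera), genera add `genus_core`
#' proteins (diverged to `within_genus_identity` between genomes), and
#' each genome carries `private_genes` unrelated proteins. Genes are
#' back-translated (GC-weighted synonymous codons) into genomes with
#' 50-150 bp intergenic spacers. Defaults are calibrated so that
#' within-genus pairs share >60% of proteins, within-family pairs 20-50%,
#' and across-family pairs <10% under the standard homology thresholds.
#'
#' @param n_families,genera_per_family,genomes_per_genus set shape
#'   (defaults 3 x 2 x 4 = 24 genomes).
#' @param family_core,genus_core,private_genes gene counts per genome
#'   (15/20/10).
#' @param within_genus_identity,within_family_identity target expected
#'   pairwise protein identities (0.75 / 0.45); the former must exceed
#'   the latter.
#' @param seed RNG seed; same seed reproduces outputs byte-identically.
#' @param gc GC content (haloarchaeal genomes are GC-rich; default 0.62).
#' @param protein_len ancestral protein length range in residues.
#' @param spacer intergenic spacer length range in bp.
#' @return list(genomes = list of `Genome`, truth = list(genomes,
#'   genes, params)).
#' @export
gen_taxonomy_set <- function(n_families = 3L, genera_per_family = 2L,
                             genomes_per_genus = 4L, family_core = 15L,
                             genus_core = 20L, private_genes = 10L,
                             within_genus_identity = 0.75,
                             within_family_identity = 0.45, seed = 1L,
                             gc = 0.62, protein_len = c(160L, 240L),
                             spacer = c(50L, 150L)) {
  stopifnot(n_families >= 1L, genera_per_family >= 1L,
            genomes_per_genus >= 1L, family_core >= 0L, genus_core >= 0L,
            private_genes >= 0L,
            within_genus_identity > 0, within_genus_identity < 1,
            within_family_identity > 0, within_family_identity < 1)
  if (within_genus_identity <= within_family_identity)
    stop("inconsistent identity ordering: within_genus_identity must exceed within_family_identity")
  set.seed(seed)
  eL <- branch_error(1 - within_genus_identity)
  q_leafpair <- 1 - within_genus_identity
  q_total <- 1 - within_family_identity
  g_needed <- (q_total - q_leafpair) / (1 - (20 / 19) * q_leafpair)
  eG <- branch_error(g_needed)
  genomes <- list()
  truth_genomes <- list()
  truth_genes <- list()
  for (f in seq_len(n_families)) {
    fam_anc <- lapply(seq_len(family_core), function(i)
      rand_protein_chars(sample(protein_len[1]:protein_len[2], 1L)))
    for (g in seq_len(genera_per_family)) {
      fam_at_genus <- lapply(fam_anc, mutate_protein_chars, e = eG)
      gen_anc <- lapply(seq_len(genus_core), function(i)
        rand_protein_chars(sample(protein_len[1]:protein_len[2], 1L)))
      for (v in seq_len(genomes_per_genus)) {
        gid <- sprintf("vir_f%02dg%02dn%02d", f, g, v)
        prots <- c(lapply(fam_at_genus, mutate_protein_chars, e = eL),
                   lapply(gen_anc, mutate_protein_chars, e = eL),
                   lapply(seq_len(private_genes), function(i)
                     rand_protein_chars(sample(protein_len[1]:protein_len[2],
                                               1L))))
        pc_truth <- c(sprintf("fam%02d_core%02d", f, seq_len(family_core)),
                      sprintf("fam%02dgen%02d_core%02d", f, g,
                              seq_len(genus_core)),
                      sprintf("%s_private%02d", gid, seq_len(private_genes)))
        # assemble the genome: spacer (gene spacer)*...
        parts <- character(0)
        genes <- list()
        pos <- sample(spacer[1]:spacer[2], 1L)
        parts <- rand_dna(pos, gc)
        for (k in seq_along(prots)) {
          nt <- back_translate(prots[[k]], gc)
          genes[[k]] <- gene_record(
            gene_id = sprintf("gene%03d", k), genome_id = gid,
            start = pos, end = pos + nchar(nt), strand = "+",
            product = pc_truth[k],
            protein = paste(prots[[k]], collapse = ""))
          sp <- rand_dna(sample(spacer[1]:spacer[2], 1L), gc)
          parts <- c(parts, nt, sp)
          pos <- pos + nchar(nt) + nchar(sp)
        }
        seqs <- paste(parts, collapse = "")
        genome <- new_genome(gid, seqs, genes = do.call(rbind, genes),
                             meta = list(family = sprintf("fam%02d", f),
                                         genus = sprintf("fam%02d.gen%02d",
                                                         f, g)))
        genomes[[gid]] <- genome
        truth_genomes[[gid]] <-
          data.frame(genome_id = gid, family = sprintf("fam%02d", f),
                     genus = sprintf("fam%02d.gen%02d", f, g),
                     stringsAsFactors = FALSE)
        truth_genes[[gid]] <-
          data.frame(genome_id = gid,
                     gene_id = sprintf("gene%03d", seq_along(prots)),
                     pc_truth = pc_truth, stringsAsFactors = FALSE)
      }
    }
  }
  truth <- list(genomes = do.call(rbind, unname(truth_genomes)),
                genes = do.call(rbind, unname(truth_genes)),
                params = list(n_families = n_families,
                              genera_per_family = genera_per_family,
                              genomes_per_genus = genomes_per_genus,
                              family_core = family_core,
                              genus_core = genus_core,
                              private_genes = private_genes,
                              within_genus_identity = within_genus_identity,
                              within_family_identity = within_family_identity,
                              seed = seed, gc = gc))
  list(genomes = unname(genomes), truth = truth)
}

#' Generate a synthetic EOP matrix structured by adhesin group
#'
#' Susceptible virus-host pairs get a base titer with multiplicative
#' lognormal noise; with probability `leak` a non-susceptible pair gets an
#' off-target infection at 1e-3 to 1e-6 relative EOP; the detection floor
#' zeroes titers below 1e3 pfu/mL.
#'
#' @param adhesin_groups,viruses_per_group,hosts panel shape (4 x 5 on 24
#'   hosts).
#' @param group_host_susceptibility optional named list group label ->
#'   host ids; default partitions the panel into contiguous blocks.
#' @param leak off-target infection probability (0.02).
#' @param lognormal_sigma noise sd on the log scale (0.5).
#' @param seed RNG seed.
#' @param base_titer isolation-host scale titer in pfu/mL (2e8).
#' @param detection_floor assay detection limit (1e3 pfu/mL).
#' @return list(eop = raw `eop_matrix`, truth = list(viruses, groups,
#'   susceptibility, params)).
#' @export
gen_eop_matrix <- function(adhesin_groups = 4L, viruses_per_group = 5L,
                           hosts = 24L, group_host_susceptibility = NULL,
                           leak = 0.02, lognormal_sigma = 0.5, seed = 1L,
                           base_titer = 2e8, detection_floor = 1e3) {
  set.seed(seed)
  host_ids <- sprintf("host%02d", seq_len(hosts))
  glab <- sprintf("G%d", seq_len(adhesin_groups))
  if (is.null(group_host_susceptibility)) {
    blk <- split(host_ids, sort(rep_len(seq_len(adhesin_groups), hosts)))
    group_host_susceptibility <- setNames(blk, glab)
  }
  if (!all(glab %in% names(group_host_susceptibility)))
    stop("susceptibility map must cover all groups")
  viruses <- character(0)
  groups <- character(0)
  iso <- character(0)
  for (g in seq_len(adhesin_groups)) {
    vids <- sprintf("vir_g%dv%02d", g, seq_len(viruses_per_group))
    viruses <- c(viruses, vids)
    groups <- c(groups, rep(glab[g], viruses_per_group))
    sus <- group_host_susceptibility[[glab[g]]]
    iso <- c(iso, sus[1L + (seq_len(viruses_per_group) - 1L) %% length(sus)])
  }
  names(iso) <- viruses
  names(groups) <- viruses
  m <- matrix(0, length(viruses), hosts, dimnames = list(viruses, host_ids))
  for (vi in viruses) {
    sus <- group_host_susceptibility[[groups[[vi]]]]
    for (h in host_ids) {
      if (h %in% sus) {
        m[vi, h] <- base_titer *
          (if (lognormal_sigma > 0) rlnorm(1, 0, lognormal_sigma) else 1)
      } else if (leak > 0 && runif(1) < leak) {
        m[vi, h] <- base_titer * 10^(-runif(1, 3, 6))
      }
    }
  }
  m[m < detection_floor] <- 0
  truth <- list(viruses = data.frame(virus = viruses, group = unname(groups),
                                     isolation_host = unname(iso),
                                     stringsAsFactors = FALSE),
                groups = groups,
                susceptibility = group_host_susceptibility,
                params = list(adhesin_groups = adhesin_groups,
                              viruses_per_group = viruses_per_group,
                              hosts = hosts, leak = leak,
                              lognormal_sigma = lognormal_sigma,
                              seed = seed, base_titer = base_titer,
                              detection_floor = detection_floor))
  list(eop = eop_matrix(m, iso, detection_floor = detection_floor),
       truth = truth)
}

motif_positions <- function(sequence, motif) {
  codes <- encode_dna(toupper(sequence))
  ch <- iupac_check(motif)
  pos <- which(motif_hits(codes, ch))
  if (!is_palindromic_motif(motif)) {
    rc <- iupac_check(iupac_revcomp(motif))
    pos <- sort(unique(c(pos, which(motif_hits(codes, rc)))))
  }
  pos
}

#' Generate genomes with a controlled motif depletion factor
#'
#' An i.i.d. GC-weighted background (an order-1 chain with identical
#' rows) is adjusted by destroying or planting motif occurrences until
#' observed/expected is within `tol` of `depletion_factor` (exactly zero
#' occurrences for factor 0).
#'
#' @param n number of genomes (10).
#' @param length genome length in bp (40000).
#' @param motif IUPAC motif (GATC).
#' @param depletion_factor target observed/expected in \[0, 1\].
#' @param seed RNG seed.
#' @param gc GC content.
#' @param tol relative tolerance on the realized factor (0.1).
#' @return list(genomes = list of `Genome`, truth = data frame).
#' @export
gen_motif_genomes <- function(n = 10L, length = 40000L, motif = "GATC",
                              depletion_factor = 1, seed = 1L, gc = 0.62,
                              tol = 0.1) {
  if (depletion_factor > 1)
    stop("unreachable depletion target: factor must be in [0, 1]")
  stopifnot(depletion_factor >= 0)
  set.seed(seed)
  k <- length(iupac_check(motif))
  genomes <- vector("list", n)
  for (i in seq_len(n)) {
    s <- rand_dna(length, gc)
    for (iter in seq_len(80L)) {
      cnt <- count_motif(s, motif)
      expd <- expected_count_markov(s, motif, order = 1L)
      if (depletion_factor == 0) {
        if (cnt == 0L) break
      } else if (abs(cnt / expd - depletion_factor) <=
                 tol * depletion_factor) break
      target <- depletion_factor * expd
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      if (cnt > target || depletion_factor == 0) {
        pos <- motif_positions(s, motif)
        ndes <- if (depletion_factor == 0) base::length(pos)
                else min(base::length(pos), max(1L, ceiling(cnt - target)))
        sel <- if (ndes >= base::length(pos)) pos
               else pos[sample.int(base::length(pos), ndes)]
        for (p in sel) {
          off <- sample.int(k, 1L)
          cur <- chars[p + off - 1L]
          chars[p + off - 1L] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
      } else {
        word <- strsplit(motif, "")[[1]]
        concrete <- vapply(word, function(c0) sample(IUPAC_SETS[[c0]], 1L), "")
        nplant <- max(1L, ceiling(target - cnt))
        at <- sample(nchar(s) - k + 1L, nplant)
        for (p in at) chars[p:(p + k - 1L)] <- concrete
      }
      s <- paste(chars, collapse = "")
    }
    genomes[[i]] <- new_genome(sprintf("motif%02d", i), s,
                               meta = list(depletion_factor = depletion_factor))
  }
  truth <- data.frame(genome_id = vapply(genomes, `[[`, "", "id"),
                      depletion_factor = depletion_factor, seed = seed,
                      stringsAsFactors = FALSE)
  list(genomes = genomes, truth = truth)
}

#' Plant provirus insertions into a synthetic host contig
#'
#' Inserts the virus sequence flanked by a duplicated attachment-site
#' direct repeat (attL + virus + attR) at `n_insertions` positions in an
#' i.i.d. background contig; optionally annotates a tRNA-like locus at
#' each attL (the typical integration target).
#'
#' @param virus_genome `Genome` to integrate.
#' @param host_length background contig length (200000 bp).
#' @param att_len attachment-site repeat length (20 bp; 0 plants no
#'   repeat).
#' @param n_insertions number of insertions.
#' @param seed RNG seed.
#' @param gc background GC content.
#' @param att_mismatch mismatches introduced into the attR copy.
#' @param trna_target annotate a tRNA feature overlapping each attL?
#' @return list(host = `Genome`, truth = data frame with 0-based
#'   provirus/att coordinates).
#' @export
plant_provirus <- function(virus_genome, host_length = 200000L,
                           att_len = 20L, n_insertions = 1L, seed = 1L,
                           gc = 0.62, att_mismatch = 0L,
                           trna_target = TRUE) {
  stopifnot(inherits(virus_genome, "Genome"),
            virus_genome$length < host_length, att_len >= 0L,
            n_insertions >= 1L)
  set.seed(seed)
  bg <- rand_dna(host_length, gc)
  vseq <- virus_genome$sequence
  vlen <- nchar(vseq)
  frac <- seq_len(n_insertions) / (n_insertions + 1L)
  pos0 <- sort(round(host_length * frac) +
                 sample(-2000L:2000L, n_insertions, replace = TRUE))
  # guard the planted att boundaries: the host base preceding attL must
  # differ from the virus 3' base, and the host base following attR from
  # the virus 5' base, so the planted repeat is the exact maximal one
  other <- function(b) c(A = "C", C = "A", G = "T", T = "G", N = "A")[[b]]
  for (p in pos0) {
    if (substr(bg, p, p) == substr(vseq, vlen, vlen))
      substr(bg, p, p) <- other(substr(bg, p, p))
    if (substr(bg, p + 1L, p + 1L) == substr(vseq, 1L, 1L))
      substr(bg, p + 1L, p + 1L) <- other(substr(bg, p + 1L, p + 1L))
  }
  ins_size <- 2L * att_len + vlen
  pieces <- character(0)
  genes <- list()
  truth <- list()
  prev <- 0L
  for (i in seq_len(n_insertions)) {
    att <- if (att_len > 0L) rand_dna(att_len, gc) else ""
    attR <- att
    if (att_len > 0L && att_mismatch > 0L) {
      ch <- strsplit(attR, "")[[1]]
      at <- sample(att_len, min(att_mismatch, att_len))
      for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      attR <- paste(ch, collapse = "")
    }
    pieces <- c(pieces, substr(bg, prev + 1L, pos0[i]), att, vseq, attR)
    shift <- (i - 1L) * ins_size
    attL_start <- pos0[i] + shift
    region_start <- attL_start + att_len
    region_end <- region_start + vlen
    truth[[i]] <- data.frame(insertion = i, attL_start = attL_start,
                             region_start = region_start,
                             region_end = region_end,
                             attR_start = region_end, att_len = att_len,
                             att_seq = att,
                             virus_id = virus_genome$id,
                             stringsAsFactors = FALSE)
    if (trna_target && att_len > 0L) {
      genes[[i]] <- gene_record(
        gene_id = sprintf("trna%02d", i), genome_id = "host01",
        start = max(0L, attL_start - 40L), end = attL_start + att_len,
        strand = "+", type = "tRNA", product = "tRNA-Leu", protein = "")
    }
    prev <- pos0[i]
  }
  pieces <- c(pieces, substr(bg, prev + 1L, host_length))
  hseq <- paste(pieces, collapse = "")
  gn <- if (length(genes)) do.call(rbind, genes) else empty_genes()
  host <- new_genome("host01", hseq, genes = gn,
                     meta = list(planted = n_insertions))
  list(host = host, truth = do.call(rbind, truth))
}

#' Write a synthetic taxonomy set to disk
#'
#' Emits a multi-record GenBank file, a genome FASTA, truth tables and a
#' key=value parameter file; byte-identical for identical seeds.
#'
#' @param set [gen_taxonomy_set()] result.
#' @param dir output directory.
#' @return dir, invisibly.
#' @export
write_synthetic_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genbank(set$genomes, file.path(dir, "genomes.gbk"))
  seqs <- setNames(vapply(set$genomes, `[[`, "", "sequence"),
                   vapply(set$genomes, `[[`, "", "id"))
  write_fasta(seqs, file.path(dir, "genomes.fasta"), type = "DNA")
  write.table(set$truth$genomes, file.path(dir, "truth_genomes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(set$truth$genes, file.path(dir, "truth_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  p <- set$truth$params
  writeLines(paste0(names(p), "=", vapply(p, format, "")),
             file.path(dir, "params.txt"))
  invisible(dir)
}
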