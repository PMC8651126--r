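# Protein local/global alignment (exact affine-gap DP, BLAST conventions)
# with Karlin-Altschul E-value statistics, and anchored whole-genome
# substitution counting.

#' Karlin-Altschul parameters
#'
#' Defaults are the published gapped BLOSUM62 values (gap open 11 /
#' extend 1), which reproduce BLAST-scale E-values closely enough for
#' thresholding at 1e-25 / 1e-3.
#'
#' @param lambda nats per score unit.
#' @param K dimensionless constant.
#' @param search_space "pairwise_mn" (E over m x n) or "database_mN"
#'   (E over m x total database length).
#' @return list of class `ka_params`.
#' @export
ka_params <- function(lambda = 0.267, K = 0.041,
                      search_space = c("pairwise_mn", "database_mN")) {
  stopifnot(lambda > 0, K > 0)
  structure(list(lambda = lambda, K = K,
                 search_space = match.arg(search_space)),
            class = "ka_params")
}

#' Karlin-Altschul expectation value
#'
#' E = K * m * n * exp(-lambda * S).
#'
#' @param score raw alignment score (vectorized).
#' @param m,n effective query / subject (or database) lengths, >= 1.
#' @param params [ka_params()].
#' @return expectation value(s).
#' @export
evalue <- function(score, m, n, params = ka_params()) {
  stopifnot(all(m >= 1), all(n >= 1))
  params$K * m * n * exp(-params$lambda * score)
}

#' Bit score from a raw score
#' @param score raw score.
#' @param params [ka_params()].
#' @return bit score (lambda*S - ln K)/ln 2.
#' @export
bitscore <- function(score, params = ka_params()) {
  (params$lambda * score - log(params$K)) / log(2)
}

#' Optimal local (Smith-Waterman) protein alignment
#'
#' Exact affine-gap local alignment; a gap of length L costs
#' `gap_open + L * gap_extend` (BLAST convention). Identity is computed
#' over all alignment columns, gaps included in the denominator. X is
#' tolerated and scored 0; any other non-standard residue is an error.
#'
#' @param query,subject protein strings.
#' @param matrix substitution matrix name (BLOSUM62).
#' @param gap_open,gap_extend gap penalties.
#' @param query_id,subject_id ids carried into the result.
#' @param params [ka_params()] used for the E-value (pairwise m x n).
#' @return one-row data frame: query_id, subject_id, score, bitscore,
#'   evalue, identity_pct, aln_len, mismatches, gapopens, q_start, q_end,
#'   s_start, s_end (0-based half-open). A score of 0 reports no
#'   alignment (aln_len 0, NA coordinates).
#' @export
local_align <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11L, gap_extend = 1L,
                        query_id = "query", subject_id = "subject",
                        params = ka_params()) {
  sub <- protein_submatrix(matrix)
  qa <- encode_protein(query, query_id)
  sa <- encode_protein(subject, subject_id)
  res <- cpp_sw_align(qa, sa, sub, gap_open, gap_extend)
  e <- evalue(res$score, length(qa), length(sa), params)
  if (res$score == 0L) {
    return(data.frame(query_id = query_id, subject_id = subject_id,
                      score = 0L, bitscore = bitscore(0L, params),
                      evalue = e, identity_pct = NA_real_, aln_len = 0L,
                      mismatches = 0L, gapopens = 0L,
                      q_start = NA_integer_, q_end = NA_integer_,
                      s_start = NA_integer_, s_end = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  data.frame(query_id = query_id, subject_id = subject_id,
             score = res$score, bitscore = bitscore(res$score, params),
             evalue = e,
             identity_pct = 100 * res$identities / res$ncol,
             aln_len = res$ncol, mismatches = res$mismatches,
             gapopens = res$gapopens,
             q_start = res$q_start, q_end = res$q_end,
             s_start = res$s_start, s_end = res$s_end,
             stringsAsFactors = FALSE)
}

#' Global (Needleman-Wunsch) protein alignment
#'
#' Same scoring scheme as [local_align()], end gaps penalized.
#'
#' @inheritParams local_align
#' @return one-row data frame with score, identity_pct (over all columns,
#'   gaps included), aln_len, mismatches, gaps, gapopens.
#' @export
global_align <- function(query, subject, matrix = "BLOSUM62",
                         gap_open = 11L, gap_extend = 1L,
                         query_id = "query", subject_id = "subject") {
  sub <- protein_submatrix(matrix)
  qa <- encode_protein(query, query_id)
  sa <- encode_protein(subject, subject_id)
  res <- cpp_nw_align(qa, sa, sub, gap_open, gap_extend)
  data.frame(query_id = query_id, subject_id = subject_id,
             score = res$score,
             identity_pct = 100 * res$identities / res$ncol,
             aln_len = res$ncol, mismatches = res$mismatches,
             gaps = res$gaps, gapopens = res$gapopens,
             stringsAsFactors = FALSE)
}

#' Write alignment hits as 12-column BLAST tabular output
#'
#' outfmt-6 dialect with 1-based inclusive coordinates.
#'
#' @param hits data frame from [local_align()] (rows bound together).
#' @param path output file.
#' @export
write_blast_tab <- function(hits, path) {
  tab <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.2f", hits$identity_pct), hits$aln_len,
                    hits$mismatches, hits$gapopens,
                    hits$q_start + 1L, hits$q_end,
                    hits$s_start + 1L, hits$s_end,
                    format(hits$evalue, digits = 3),
                    sprintf("%.1f", hits$bitscore))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Whole-genome substitution counting (anchored mode)

#' Count nucleotide substitutions between two near-identical genomes
#'
#' Chains unique shared k-mers (k = 21) as exact anchors, aligns the
#' inter-anchor segments, and reports substitution count/positions and the
#' number of indel events (indels are not counted as substitutions).
#'
#' @param genomeA,genomeB `Genome` objects or DNA strings of comparable
#'   length (ratio within \[0.9, 1.1\]).
#' @param k anchor k-mer size.
#' @return list(n_subs, positions (0-based in A), n_indels).
#' @export
count_substitutions <- function(genomeA, genomeB, k = 21L) {
  a <- if (inherits(genomeA, "Genome")) genomeA$sequence else toupper(genomeA)
  b <- if (inherits(genomeB, "Genome")) genomeB$sequence else toupper(genomeB)
  la <- nchar(a); lb <- nchar(b)
  ratio <- la / lb
  if (ratio < 0.9 || ratio > 1.1)
    stop("genome lengths differ by more than 10%; anchored mode requires comparable lengths")
  ka <- substring(a, seq_len(la - k + 1L), seq_len(la - k + 1L) + k - 1L)
  kb <- substring(b, seq_len(lb - k + 1L), seq_len(lb - k + 1L) + k - 1L)
  ua <- which(!(duplicated(ka) | duplicated(ka, fromLast = TRUE)))
  ub <- which(!(duplicated(kb) | duplicated(kb, fromLast = TRUE)))
  mb <- match(ka[ua], kb[ub])
  keep <- !is.na(mb)
  posA <- ua[keep]
  posB <- ub[mb[keep]]
  ord <- order(posA)
  posA <- posA[ord]; posB <- posB[ord]
  if (length(posA)) {
    lis <- longest_increasing(posB)
    posA <- posA[lis]; posB <- posB[lis]
  }
  if (!length(posA)) stop("genomes too divergent to anchor; use a full alignment instead")
  # anchored coverage of A
  cov <- coverage_of_anchors(posA, k, la)
  if (cov < 0.5 * la)
    stop("anchors cover <50% of the genome; too divergent for anchored mode, use a full alignment instead")
  # merge contiguous anchor runs on the same diagonal into exact blocks
  # (a gap between same-diagonal anchors can hide substitutions, so any
  # break in contiguity starts a new block and its gap gets compared)
  d <- posB - posA
  newblk <- c(TRUE, diff(d) != 0L | diff(posA) != 1L)
  blk <- factor(cumsum(newblk), levels = unique(cumsum(newblk)))
  bA1 <- as.integer(tapply(posA, blk, min))
  bA2 <- as.integer(tapply(posA, blk, max)) + k - 1L
  bB1 <- as.integer(tapply(posB, blk, min))
  nblk <- length(bA1)
  subs <- integer(0)
  n_indels <- 0L
  seg <- function(sa, ea, sb, eb) {
    # compare A[sa..ea] vs B[sb..eb] (1-based inclusive, possibly empty)
    wa <- if (ea >= sa) substr(a, sa, ea) else ""
    wb <- if (eb >= sb) substr(b, sb, eb) else ""
    na <- nchar(wa); nb <- nchar(wb)
    if (na == 0L && nb == 0L) return(invisible())
    if (na == nb) {
      ca <- strsplit(wa, "")[[1]]; cb <- strsplit(wb, "")[[1]]
      mm <- which(ca != cb)
      subs <<- c(subs, sa - 1L + mm - 1L)  # 0-based in A
    } else if (na == 0L || nb == 0L) {
      n_indels <<- n_indels + 1L
    } else {
      res <- cpp_nw_align(encode_dna(wa), encode_dna(wb), dna_submatrix(),
                          5L, 2L)
      n_indels <<- n_indels + res$gapopens
      ai <- res$ai; bj <- res$bj # 0-based, -1 for gap
      mmcols <- which(ai >= 0L & bj >= 0L &
                        substring(wa, ai + 1L, ai + 1L) !=
                        substring(wb, bj + 1L, bj + 1L))
      subs <<- c(subs, sa - 1L + ai[mmcols])
    }
    invisible()
  }
  # head
  seg(1L, bA1[1] - 1L, 1L, bB1[1] - 1L)
  for (i in seq_len(nblk - 1L)) {
    sa <- bA2[i] + 1L
    ea <- bA1[i + 1L] - 1L
    sb <- bB1[i] + (bA2[i] - bA1[i]) + 1L
    eb <- bB1[i + 1L] - 1L
    seg(sa, ea, sb, eb)
  }
  # tail
  seg(bA2[nblk] + 1L, la, bB1[nblk] + (bA2[nblk] - bA1[nblk]) + 1L, lb)
  list(n_subs = length(subs), positions = sort(unique(subs)),
       n_indels = n_indels)
}

# indices of a longest strictly increasing subsequence (patience sorting)
longest_increasing <- function(x) {
  n <- length(x)
  if (n <= 1L) return(seq_len(n))
  tails <- numeric(0)      # pile-top values
  tails_idx <- integer(0)  # pile-top indices into x
  prev <- integer(n)
  for (i in seq_len(n)) {
    pos <- findInterval(x[i] - 0.5, tails) + 1L # first pile top >= x[i]
    prev[i] <- if (pos > 1L) tails_idx[pos - 1L] else 0L
    tails[pos] <- x[i]
    tails_idx[pos] <- i
  }
  out <- integer(0)
  i <- tails_idx[length(tails_idx)]
  while (i > 0L) {
    out <- c(i, out)
    i <- prev[i]
  }
  out
}

coverage_of_anchors <- function(posA, k, la) {
  st <- posA; en <- posA + k - 1L
  keep_st <- st; keep_en <- en
  o <- order(keep_st)
  st <- keep_st[o]; en <- keep_en[o]
  tot <- 0L; cur_s <- st[1]; cur_e <- en[1]
  for (i in seq_along(st)[-1]) {
    if (st[i] <= cur_e + 1L) cur_e <- max(cur_e, en[i])
    else { tot <- tot + (cur_e - cur_s + 1L); cur_s <- st[i]; cur_e <- en[i] }
  }
  tot + (cur_e - cur_s + 1L)
}
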