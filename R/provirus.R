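# Provirus detection in host genomes: protein-homology hit chaining,
# attachment-site direct-repeat search in the flanking windows, and
# family assignment by shared-gene fraction against a classified
# reference set.

#' Find candidate provirus regions in a host genome
#'
#' Host ORFs are called naively and aligned (exact Smith-Waterman) against
#' the reference virus proteomes; hits below the E-value cutoff are
#' chained along the contig, and maximal chains with at least `min_hits`
#' hits and inter-hit gaps of at most `max_gap` bp become candidate
#' regions. This replaces the blastx screen with a single in-repo
#' alignment engine (ORF calling + protein-protein alignment); the
#' E-value uses the database search space (m x total reference length).
#'
#' @param host_genome `Genome` (host contig).
#' @param virus_proteomes named list (by reference virus id) of proteome
#'   data frames from [extract_proteome()], or list of `Genome`s.
#' @param min_hits minimum number of hit ORFs per region (default 10).
#' @param max_gap maximum gap between consecutive hit ORFs in bp
#'   (default 15000).
#' @param max_evalue hit threshold (default 1e-5, the provirus screen
#'   cutoff).
#' @param min_aa minimum ORF length for the host ORF calling.
#' @return data frame: host_contig_id, start, end (0-based half-open),
#'   n_hits, n_virus_pcs_hit, reference_virus. Zero rows when nothing is
#'   found.
#' @export
find_provirus_regions <- function(host_genome, virus_proteomes,
                                  min_hits = 10L, max_gap = 15000L,
                                  max_evalue = 1e-5, min_aa = 50L) {
  stopifnot(inherits(host_genome, "Genome"), length(virus_proteomes) >= 1L)
  if (inherits(virus_proteomes[[1]], "Genome")) {
    nm <- vapply(virus_proteomes, `[[`, "", "id")
    virus_proteomes <- setNames(lapply(virus_proteomes, extract_proteome), nm)
  }
  empty <- data.frame(host_contig_id = character(), start = integer(),
                      end = integer(), n_hits = integer(),
                      n_virus_pcs_hit = integer(),
                      reference_virus = character(),
                      stringsAsFactors = FALSE)
  orfs <- call_orfs(host_genome$sequence, min_aa = min_aa,
                    genome_id = host_genome$id)
  if (!nrow(orfs)) return(empty)
  ref <- do.call(rbind, lapply(names(virus_proteomes), function(v) {
    p <- virus_proteomes[[v]]
    if (!nrow(p)) return(NULL)
    data.frame(protein_id = p$protein_id, virus = v, sequence = p$sequence,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ref) || !nrow(ref)) stop("empty reference proteomes")
  sub <- protein_submatrix()
  enc_orf <- lapply(seq_len(nrow(orfs)),
                    function(i) encode_protein(orfs$protein[i], "orf"))
  enc_ref <- lapply(seq_len(nrow(ref)),
                    function(i) encode_protein(ref$sequence[i],
                                               ref$protein_id[i]))
  sc <- cpp_sw_score_cross(enc_orf, enc_ref, sub, 11L, 1L)
  ka <- ka_params(search_space = "database_mN")
  Ntot <- sum(nchar(ref$sequence))
  m_len <- nchar(orfs$protein)
  best_j <- max.col(sc, ties.method = "first")
  best_score <- sc[cbind(seq_len(nrow(sc)), best_j)]
  best_e <- evalue(best_score, m_len, Ntot, ka)
  hit <- best_e < max_evalue
  if (!any(hit)) return(empty)
  hits <- data.frame(start = orfs$start[hit], end = orfs$end[hit],
                     ref_protein = ref$protein_id[best_j[hit]],
                     ref_virus = ref$virus[best_j[hit]],
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$start), , drop = FALSE]
  gap <- c(0L, pmax(hits$start[-1] - head(hits$end, -1L), 0L))
  chain <- cumsum(gap > max_gap)
  rows <- lapply(split(seq_len(nrow(hits)), chain), function(ii) {
    if (length(ii) < min_hits) return(NULL)
    h <- hits[ii, ]
    refv <- names(sort(table(h$ref_virus), decreasing = TRUE))
    data.frame(host_contig_id = host_genome$id,
               start = min(h$start), end = max(h$end),
               n_hits = nrow(h),
               n_virus_pcs_hit = length(unique(h$ref_protein)),
               reference_virus = refv[1], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Locate attachment-site direct repeats flanking a region
#'
#' Searches the `window` bp around the region edges (detected boundaries
#' are fuzzy, so each window straddles its edge) for the best pair of
#' same-orientation repeats of length >= `min_len` with at most
#' `max_mismatch` differences. Candidates are ranked by a
#' mismatch-penalized score (length - 4 x mismatches) and reported only
#' when the score exceeds the chance threshold for the window sizes and
#' host base composition (`significance`): two random 2-kb flanks contain
#' ~12-14 bp repeats by chance alone, so a plain longest-repeat rule would
#' almost always "find" an attachment site. Absence is a valid result
#' (NULL).
#'
#' @param host_genome `Genome`.
#' @param region list or one-row data frame with `start`, `end` (0-based
#'   half-open).
#' @param min_len minimum repeat length (default 12).
#' @param max_mismatch maximum mismatches (default 1).
#' @param window flank window size in bp (default 2000).
#' @param significance maximum tolerated expected number of chance
#'   repeats at the reporting threshold (default 0.005).
#' @return NULL, or list(attL = list(start, end, seq), attR = ...,
#'   length, mismatches, score).
#' @export
find_att_repeats <- function(host_genome, region, min_len = 12L,
                             max_mismatch = 1L, window = 2000L,
                             significance = 0.005) {
  s <- host_genome$sequence
  L <- host_genome$length
  rs <- as.integer(region$start); re <- as.integer(region$end)
  stopifnot(rs >= 0L, re <= L, rs < re)
  l_from <- max(0L, rs - window)
  l_to <- min(L, rs + window %/% 2L)
  left <- substr(s, l_from + 1L, l_to)
  r_from <- max(0L, re - window %/% 2L, l_to)
  r_to <- min(L, re + window)
  right <- substr(s, r_from + 1L, r_to)
  if (nchar(left) < min_len || nchar(right) < min_len) return(NULL)
  hit <- cpp_longest_direct_repeat(encode_dna(left), encode_dna(right),
                                   min_len, max_mismatch)
  if (!length(hit)) return(NULL)
  len <- hit[1]; i <- hit[2]; j <- hit[3]; mm <- hit[4]
  score <- len - 4L * mm
  # chance threshold: E[#repeats of score >= t] ~ nL*nR * p2^t < significance
  codes <- encode_dna(s)
  p <- tabulate(codes[codes < 4L] + 1L, 4L)
  p <- p / sum(p)
  p2 <- sum(p^2)
  lstar <- ceiling(log(significance / (as.double(nchar(left)) *
                                         nchar(right))) / log(p2))
  if (score < max(min_len, lstar)) return(NULL)
  attL_start <- l_from + i
  attR_start <- r_from + j
  list(attL = list(start = attL_start, end = attL_start + len,
                   seq = substr(s, attL_start + 1L, attL_start + len)),
       attR = list(start = attR_start, end = attR_start + len,
                   seq = substr(s, attR_start + 1L, attR_start + len)),
       length = len, mismatches = mm, score = score)
}

#' Assign a provirus region to a reference virus family
#'
#' Computes the symmetric shared-gene fraction between the region's
#' proteome and one representative genome per reference family (largest
#' proteome, ties by id) under the reference homology thresholds, and
#' returns the best family when the fraction reaches `min_shared` percent
#' (default 20, the lower bound of the within-family range), otherwise
#' "unassigned".
#'
#' @param region_proteome data frame (protein_id, sequence), non-empty.
#' @param reference_taxonomy [classify()] result for the reference virus
#'   set.
#' @param min_shared assignment threshold in percent.
#' @return family label or "unassigned".
#' @export
assign_provirus_family <- function(region_proteome, reference_taxonomy,
                                   min_shared = 20) {
  stopifnot(inherits(reference_taxonomy, "virus_taxonomy"))
  if (!nrow(region_proteome)) stop("empty region proteome")
  prot <- reference_taxonomy$graph$proteins
  asg <- reference_taxonomy$assignment
  fams <- sort(unique(asg$family))
  # representative genome per family: largest proteome, ties by id
  rep_of <- vapply(fams, function(f) {
    ids <- sort(asg$genome_id[asg$family == f])
    sizes <- vapply(ids, function(g) sum(prot$genome_id == g), 0L)
    ids[order(-sizes, ids)][1]
  }, "")
  th <- reference_taxonomy$parameters
  frac <- vapply(fams, function(f) {
    g <- rep_of[[f]]
    rp <- data.frame(protein_id = paste0(g, "|", seq_len(sum(prot$genome_id == g))),
                     sequence = prot$sequence[prot$genome_id == g],
                     start = prot$start[prot$genome_id == g],
                     stringsAsFactors = FALSE)
    qp <- data.frame(protein_id = paste0("region|", seq_len(nrow(region_proteome))),
                     sequence = region_proteome$sequence,
                     start = seq_len(nrow(region_proteome)),
                     stringsAsFactors = FALSE)
    gr <- all_vs_all(list(region = qp, reference = rp),
                     min_identity = th$min_identity,
                     max_evalue = th$max_evalue)
    shared_fraction("region", "reference", gr, symmetric = TRUE)
  }, 0)
  best <- max(frac)
  if (best < min_shared) return("unassigned")
  cand <- fams[frac == best]
  if (length(cand) > 1L)
    message("family tie for provirus region; picking lexicographically first of ",
            paste(cand, collapse = ","))
  sort(cand)[1]
}

#' End-to-end provirus scan of a host genome
#'
#' Runs [find_provirus_regions()], [find_att_repeats()] and (when a
#' classified reference taxonomy is supplied) [assign_provirus_family()],
#' and classifies the integration target from host annotations when
#' present (overlap of attL with an annotated tRNA/CDS feature).
#'
#' @param host_genome `Genome`.
#' @param virus_proteomes reference proteomes (see
#'   [find_provirus_regions()]).
#' @param reference_taxonomy optional [classify()] result.
#' @param ... passed to [find_provirus_regions()].
#' @param att_min_len,att_max_mismatch,att_window att-repeat search
#'   parameters.
#' @return data frame of provirus calls: host_contig_id, start, end,
#'   n_hits, n_virus_pcs_hit, reference_virus, att_present, attL_start,
#'   attR_start, att_len, att_seq, family_assignment, integration_target.
#' @export
provirus_scan <- function(host_genome, virus_proteomes,
                          reference_taxonomy = NULL, att_min_len = 12L,
                          att_max_mismatch = 1L, att_window = 2000L, ...) {
  regions <- find_provirus_regions(host_genome, virus_proteomes, ...)
  n <- nrow(regions)
  regions$att_present <- logical(n)
  regions$attL_start <- rep(NA_integer_, n)
  regions$attR_start <- rep(NA_integer_, n)
  regions$att_len <- rep(NA_integer_, n)
  regions$att_seq <- rep(NA_character_, n)
  regions$family_assignment <- rep("unassigned", n)
  regions$integration_target <- rep("unknown", n)
  if (!n) return(regions)
  orfs <- call_orfs(host_genome$sequence, genome_id = host_genome$id)
  for (i in seq_len(n)) {
    att <- find_att_repeats(host_genome, regions[i, ], min_len = att_min_len,
                            max_mismatch = att_max_mismatch,
                            window = att_window)
    if (!is.null(att)) {
      regions$att_present[i] <- TRUE
      regions$attL_start[i] <- att$attL$start
      regions$attR_start[i] <- att$attR$start
      regions$att_len[i] <- att$length
      regions$att_seq[i] <- att$attL$seq
      # integration target from host annotations overlapping attL
      ann <- host_genome$genes
      if (nrow(ann)) {
        ov <- ann$start < att$attL$end & ann$end > att$attL$start
        if (any(ov)) {
          types <- ann$type[ov]
          prods <- ann$product[ov]
          regions$integration_target[i] <-
            if (any(types == "tRNA" | grepl("tRNA", prods))) "tRNA" else "CDS"
        } else {
          regions$integration_target[i] <- "intergenic"
        }
      }
    }
    if (!is.null(reference_taxonomy)) {
      inside <- orfs$start >= regions$start[i] & orfs$end <= regions$end[i]
      if (any(inside)) {
        rp <- data.frame(protein_id = sprintf("r%04d", which(inside)),
                         sequence = orfs$protein[inside],
                         stringsAsFactors = FALSE)
        regions$family_assignment[i] <-
          assign_provirus_family(rp, reference_taxonomy)
      }
    }
  }
  regions
}
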