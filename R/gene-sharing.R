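# Thresholded homology graph over all proteins, protein clusters (PCs),
# shared-gene fractions and per-genome content/order signatures.

#' All-vs-all protein homology graph
#'
#' Every protein pair is evaluated once by exact Smith-Waterman (symmetry
#' exploited); an edge is kept when the pair exceeds the identity
#' threshold and falls below the E-value threshold. Defaults reproduce the
#' "homologous protein" definition used for gene-sharing statistics:
#' identity > 30% and E < 1e-25.
#'
#' @param proteomes named list (by genome id) of proteome data frames from
#'   [extract_proteome()], or a list of `Genome` objects.
#' @param min_identity identity threshold in percent (strict >).
#' @param max_evalue E-value threshold (strict <).
#' @param matrix,gap_open,gap_extend scoring scheme.
#' @param params [ka_params()]; the default pairwise m x n search space is
#'   used for genome-pair homology calls.
#' @return object of class `homology_graph`: proteins table, edges table,
#'   raw score matrix, thresholds.
#' @export
all_vs_all <- function(proteomes, min_identity = 30, max_evalue = 1e-25,
                       matrix = "BLOSUM62", gap_open = 11L, gap_extend = 1L,
                       params = ka_params()) {
  if (length(proteomes) >= 1L && inherits(proteomes[[1]], "Genome")) {
    nm <- vapply(proteomes, `[[`, "", "id")
    proteomes <- setNames(lapply(proteomes, extract_proteome), nm)
  }
  stopifnot(length(proteomes) >= 1L, !is.null(names(proteomes)))
  tabs <- lapply(names(proteomes), function(g) {
    p <- proteomes[[g]]
    if (!nrow(p)) return(NULL)
    data.frame(protein_id = p$protein_id, genome_id = g,
               sequence = p$sequence, start = p$start,
               stringsAsFactors = FALSE)
  })
  prot <- do.call(rbind, tabs)
  if (is.null(prot) || !nrow(prot)) stop("no proteins in input proteomes")
  if (anyDuplicated(prot$protein_id)) stop("duplicate protein ids across proteomes")
  prot$length <- nchar(prot$sequence)
  sub <- protein_submatrix(matrix)
  enc <- lapply(seq_len(nrow(prot)),
                function(i) encode_protein(prot$sequence[i], prot$protein_id[i]))
  scores <- cpp_sw_score_matrix(enc, sub, gap_open, gap_extend)
  dimnames(scores) <- list(prot$protein_id, prot$protein_id)
  n <- nrow(prot)
  # search space for E
  if (params$search_space == "pairwise_mn") {
    sp <- outer(prot$length, prot$length)
  } else {
    sp <- outer(prot$length, rep(sum(prot$length), n))
  }
  E <- params$K * sp * exp(-params$lambda * scores)
  cand <- which(upper.tri(E) & E < max_evalue, arr.ind = TRUE)
  edges <- NULL
  if (nrow(cand)) {
    idp <- numeric(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      al <- cpp_sw_align(enc[[i]], enc[[j]], sub, gap_open, gap_extend)
      idp[r] <- 100 * al$identities / max(al$ncol, 1L)
    }
    keep <- idp > min_identity
    cand <- cand[keep, , drop = FALSE]
    idp <- idp[keep]
    if (nrow(cand)) {
      sc <- scores[cand]
      edges <- data.frame(p1 = prot$protein_id[cand[, 1]],
                          p2 = prot$protein_id[cand[, 2]],
                          score = sc, bitscore = bitscore(sc, params),
                          identity_pct = idp, evalue = E[cand],
                          stringsAsFactors = FALSE)
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(p1 = character(), p2 = character(),
                        score = numeric(), bitscore = numeric(),
                        identity_pct = numeric(), evalue = numeric(),
                        stringsAsFactors = FALSE)
  }
  structure(list(proteins = prot, edges = edges, scores = scores,
                 thresholds = list(min_identity = min_identity,
                                   max_evalue = max_evalue),
                 params = params,
                 scoring = list(matrix = matrix, gap_open = gap_open,
                                gap_extend = gap_extend)),
            class = "homology_graph")
}

#' @export
print.homology_graph <- function(x, ...) {
  cat(sprintf("<homology_graph> %d proteins / %d genomes, %d edges (identity > %g%%, E < %g)\n",
              nrow(x$proteins), length(unique(x$proteins$genome_id)),
              nrow(x$edges), x$thresholds$min_identity,
              x$thresholds$max_evalue))
  invisible(x)
}

#' Protein clusters (single-linkage connected components)
#'
#' PCs are the transitive closure of the pairwise homology relation;
#' singletons are PCs of size one. Cluster ids are deterministic: clusters
#' are ordered by their lexicographically smallest member id. The
#' representative is the longest member (ties broken by id).
#'
#' @param graph [all_vs_all()] result.
#' @return object of class `protein_clusters`: `membership` (protein_id,
#'   pc_id) and `clusters` (pc_id, size, representative).
#' @export
protein_clusters <- function(graph) {
  ids <- graph$proteins$protein_id
  ig <- igraph::graph_from_data_frame(graph$edges[, c("p1", "p2")],
                                      directed = FALSE,
                                      vertices = data.frame(name = ids))
  comp <- igraph::components(ig)$membership[ids]
  smallest <- tapply(ids, comp, min)
  ord <- order(smallest)
  relabel <- setNames(seq_along(ord), names(smallest)[ord])
  pc_idx <- relabel[as.character(comp)]
  pc_id <- sprintf("PC%05d", pc_idx)
  membership <- data.frame(protein_id = ids, pc_id = pc_id,
                           stringsAsFactors = FALSE)
  len <- graph$proteins$length
  reps <- vapply(split(seq_along(ids), pc_id), function(ii) {
    ii <- ii[order(-len[ii], ids[ii])]
    ids[ii[1]]
  }, "")
  clusters <- data.frame(pc_id = names(reps),
                         size = as.integer(table(pc_id)[names(reps)]),
                         representative = unname(reps),
                         stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$pc_id), , drop = FALSE]
  rownames(clusters) <- NULL
  structure(list(membership = membership, clusters = clusters),
            class = "protein_clusters")
}

#' Shared-gene fraction between two genomes
#'
#' Directed: percentage of A's proteins with at least one homolog in B
#' (each query protein counts once however many homologs it has). The
#' symmetric variant is the mean of the two directions.
#'
#' @param A,B genome ids present in the graph.
#' @param graph [all_vs_all()] result.
#' @param symmetric return the symmetric variant?
#' @return percentage in \[0, 100\].
#' @export
shared_fraction <- function(A, B, graph, symmetric = FALSE) {
  if (symmetric)
    return((shared_fraction(A, B, graph) + shared_fraction(B, A, graph)) / 2)
  prot <- graph$proteins
  pa <- prot$protein_id[prot$genome_id == A]
  pb <- prot$protein_id[prot$genome_id == B]
  if (!length(pa)) stop("empty proteome for genome ", A)
  if (!length(pb)) stop("empty proteome for genome ", B)
  if (A == B) return(100)
  e <- graph$edges
  hitsA <- unique(c(e$p1[e$p1 %in% pa & e$p2 %in% pb],
                    e$p2[e$p2 %in% pa & e$p1 %in% pb]))
  100 * length(hitsA) / length(pa)
}

#' Directed shared-fraction matrix over all genomes in a graph
#'
#' @param graph [all_vs_all()] result.
#' @return matrix M with M\[A, B\] = percentage of A's proteins having a
#'   homolog in B; diagonal 100.
#' @export
shared_fraction_matrix <- function(graph) {
  prot <- graph$proteins
  genomes <- sort(unique(prot$genome_id))
  gi <- setNames(match(prot$genome_id, genomes), prot$protein_id)
  m <- matrix(0, length(genomes), length(genomes),
              dimnames = list(genomes, genomes))
  diag(m) <- 100
  e <- graph$edges
  if (nrow(e)) {
    g1 <- gi[e$p1]; g2 <- gi[e$p2]
    cross <- g1 != g2
    p <- c(e$p1[cross], e$p2[cross])
    gp <- c(g1[cross], g2[cross])
    gq <- c(g2[cross], g1[cross])
    key <- paste(p, gq)
    first <- !duplicated(key)
    cnt <- table(factor(gp[first], seq_along(genomes)),
                 factor(gq[first], seq_along(genomes)))
    sizes <- as.integer(table(factor(gi, seq_along(genomes))))
    m <- m + 100 * as.matrix(cnt) / sizes
    dimnames(m) <- list(genomes, genomes)
  }
  m
}

#' Per-genome content and order signatures over protein clusters
#'
#' Content: for each PC present in the genome, the bit score of the best
#' member gene aligned to the PC representative (0 when absent). Order:
#' the genome's gene PCs in coordinate order.
#'
#' @param graph [all_vs_all()] result.
#' @param pcs [protein_clusters()] result.
#' @param topologies optional named character vector genome -> topology
#'   ("linear"/"circular"), used by the gene-order comparison.
#' @return named list of `genome_signature` objects.
#' @export
signatures <- function(graph, pcs, topologies = NULL) {
  prot <- graph$proteins
  mem <- setNames(pcs$membership$pc_id, pcs$membership$protein_id)
  rep_of <- setNames(pcs$clusters$representative, pcs$clusters$pc_id)
  universe <- pcs$clusters$pc_id
  genomes <- sort(unique(prot$genome_id))
  out <- lapply(genomes, function(g) {
    rows <- which(prot$genome_id == g)
    rows <- rows[order(prot$start[rows])]
    ids <- prot$protein_id[rows]
    ord <- unname(mem[ids])
    content <- setNames(numeric(length(universe)), universe)
    if (length(ids)) {
      sc <- vapply(seq_along(ids), function(k) {
        graph$scores[ids[k], rep_of[[ord[k]]]]
      }, 0)
      bits <- bitscore(sc, graph$params)
      best <- tapply(bits, ord, max)
      content[names(best)] <- best
    }
    topo <- if (!is.null(topologies) && g %in% names(topologies))
      topologies[[g]] else "linear"
    structure(list(genome_id = g, content = content, order = ord,
                   topology = topo), class = "genome_signature")
  })
  setNames(out, genomes)
}

#' Write a protein-cluster table
#' @param pcs [protein_clusters()] result.
#' @param path output TSV (pc_id, size, members).
#' @export
write_pc_table <- function(pcs, path) {
  members <- vapply(split(pcs$membership$protein_id, pcs$membership$pc_id),
                    function(m) paste(sort(m), collapse = ","), "")
  tab <- data.frame(pc_id = pcs$clusters$pc_id,
                    size = pcs$clusters$size,
                    members = members[pcs$clusters$pc_id])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
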