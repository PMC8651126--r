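# Distance-based phylogenetics for adhesin grouping: global-identity
# distance matrices, neighbor joining, outgroup rooting, Newick I/O.

#' Pairwise global-identity distance matrix
#'
#' d_ij = 1 - identity_pct(i, j)/100 under Needleman-Wunsch global
#' alignment (same matrix and gap costs as the local mode).
#'
#' @param proteins named character vector of protein sequences (>= 3 for
#'   tree building; 2 accepted for plain distances).
#' @param matrix,gap_open,gap_extend scoring scheme.
#' @return symmetric distance matrix with zero diagonal.
#' @export
identity_distance_matrix <- function(proteins, matrix = "BLOSUM62",
                                     gap_open = 11L, gap_extend = 1L) {
  stopifnot(length(proteins) >= 2L, !is.null(names(proteins)))
  ids <- names(proteins)
  sub <- protein_submatrix(matrix)
  enc <- lapply(seq_along(proteins),
                function(i) encode_protein(proteins[[i]], ids[i]))
  n <- length(proteins)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- cpp_nw_align(enc[[i]], enc[[j]], sub, gap_open, gap_extend)
      d <- 1 - al$identities / al$ncol
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration with deterministic tie-breaking
#' (lexicographically smallest label pair). Negative branch lengths are
#' clamped to 0 with the deficit moved to the sister branch.
#'
#' @param D symmetric distance matrix with labels (>= 3 taxa).
#' @return unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  labels <- rownames(D)
  stopifnot(!is.null(labels), nrow(D) >= 3L)
  clamp <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  nwk <- labels
  first <- labels # lexicographic representative per active node
  d <- D
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    hit <- which(Q == qmin, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    key <- apply(hit, 1, function(rc) {
      paste(sort(c(first[rc[1]], first[rc[2]])), collapse = " ")
    })
    pick <- hit[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    ll <- clamp(li, lj)
    newnwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], ll[1], nwk[j], ll[2])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nwk <- c(nwk[keep], newnwk)
    first <- c(first[keep], min(first[i], first[j]))
    dimnames(d2) <- NULL
    d <- d2
  }
  # terminal 3-node star: closed-form branch lengths
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nwk[1], max(la, 0),
                 nwk[2], max(lb, 0), nwk[3], max(lc, 0))
  ape::read.tree(text = nwk)
}

#' Root a tree on an outgroup leaf
#'
#' The root is placed at the midpoint of the outgroup's pendant edge.
#' Idempotent on topology.
#'
#' @param tree `phylo`.
#' @param taxon outgroup leaf label.
#' @return rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, taxon) {
  if (!taxon %in% tree$tip.label) stop("outgroup taxon not in tree: ", taxon)
  rooted <- ape::root(tree, outgroup = taxon, resolve.root = TRUE)
  rootnode <- length(rooted$tip.label) + 1L
  kids <- which(rooted$edge[, 1] == rootnode)
  tipidx <- match(taxon, rooted$tip.label)
  og_edge <- kids[rooted$edge[kids, 2] == tipidx]
  if (length(og_edge) == 1L && length(kids) == 2L) {
    total <- sum(rooted$edge.length[kids])
    rooted$edge.length[kids] <- total / 2
  }
  rooted
}

#' Single-linkage adhesin groups from global identity
#'
#' Clusters protein sequences with single linkage at identity >=
#' `linkage_identity` percent; groups are labelled "Group 1", "Group 2",
#' ... by decreasing size (ties by smallest member id).
#'
#' @param proteins named character vector (>= 2).
#' @param linkage_identity percent identity threshold (default 45).
#' @return named character vector protein id -> group label.
#' @export
adhesin_groups <- function(proteins, linkage_identity = 45) {
  stopifnot(length(proteins) >= 2L)
  D <- identity_distance_matrix(proteins)
  idp <- (1 - D) * 100
  adj <- idp >= linkage_identity
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  ids <- names(proteins)
  comp <- igraph::components(ig)$membership[ids]
  sz <- table(comp)
  smallest <- tapply(ids, comp, min)
  ord <- order(-as.integer(sz), smallest)
  relabel <- setNames(seq_along(ord), names(sz)[ord])
  setNames(sprintf("Group %d", relabel[as.character(comp)]), ids)
}

#' Read a Newick tree file
#' @param path file.
#' @return `phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a tree in Newick format
#' @param tree `phylo`.
#' @param path file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
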