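# Composite generalized Jaccard (CGJ) genome distances, UPGMA dendrogram,
# family cut at CGJ 0.8 and genus demarcation at >60% shared proteins.

#' Generalized Jaccard similarity of two non-negative vectors
#'
#' sum(min(x, y)) / sum(max(x, y)). Vectors are matched by name when both
#' are named.
#'
#' @param x,y non-negative vectors of equal length.
#' @return similarity in \[0, 1\]; 0 (with a warning) when both vectors
#'   are all-zero.
#' @export
generalized_jaccard <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    stopifnot(setequal(names(x), names(y)))
    y <- y[names(x)]
  }
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  den <- sum(pmax(x, y))
  if (den == 0) {
    warning("both vectors are all-zero; generalized Jaccard defined as 0")
    return(0)
  }
  sum(pmin(x, y)) / den
}

#' Gene-order (organization) similarity of two genome signatures
#'
#' Longest common subsequence of the shared-PC order, best over both
#' orientations (and over all rotations for circular genomes), divided by
#' the number of shared PCs. 0 when no PC is shared.
#'
#' @param sigA,sigB `genome_signature` objects from [signatures()].
#' @return similarity in \[0, 1\].
#' @export
organization_similarity <- function(sigA, sigB) {
  shared <- intersect(unique(sigA$order), unique(sigB$order))
  if (!length(shared)) return(0)
  oa <- match(sigA$order[sigA$order %in% shared], shared)
  ob <- match(sigB$order[sigB$order %in% shared], shared)
  variants <- list(ob, rev(ob))
  if (sigA$topology == "circular" || sigB$topology == "circular") {
    nb <- length(ob)
    if (nb > 1L) {
      rots <- lapply(seq_len(nb - 1L), function(r) c(ob[-seq_len(r)], ob[seq_len(r)]))
      variants <- c(variants, rots, lapply(rots, rev))
    }
  }
  best <- max(vapply(variants, function(v) cpp_lcs_length(oa, v), 0L))
  min(1, best / length(shared))
}

#' Composite generalized Jaccard distance between two signatures
#'
#' 1 - sqrt(J_content * J_org): the geometric-mean composition forces
#' distance 1 whenever either the gene-content or gene-order signal is
#' absent.
#'
#' @param sigA,sigB `genome_signature` objects.
#' @return list(distance, j_content, j_org).
#' @export
cgj_distance <- function(sigA, sigB) {
  jc <- suppressWarnings(generalized_jaccard(sigA$content, sigB$content))
  jo <- organization_similarity(sigA, sigB)
  list(distance = 1 - sqrt(jc * jo), j_content = jc, j_org = jo)
}

#' CGJ distance matrix over a set of signatures
#'
#' @param sigs named list from [signatures()].
#' @return object of class `cgj_matrix`: `D` (distances), `j_content`,
#'   `j_org` component matrices.
#' @export
cgj_matrix <- function(sigs) {
  ids <- names(sigs)
  n <- length(ids)
  D <- Jc <- Jo <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(Jc) <- diag(Jo) <- 1
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- cgj_distance(sigs[[i]], sigs[[j]])
        D[i, j] <- D[j, i] <- r$distance
        Jc[i, j] <- Jc[j, i] <- r$j_content
        Jo[i, j] <- Jo[j, i] <- r$j_org
      }
    }
  }
  structure(list(D = D, j_content = Jc, j_org = Jo), class = "cgj_matrix")
}

#' UPGMA dendrogram with deterministic tie-breaking
#'
#' Average-linkage agglomeration; among equally close pairs the one whose
#' lexicographically smallest member comes first wins. Node heights are
#' merge distance / 2 (ultrametric convention).
#'
#' @param D symmetric distance matrix with labels, no NAs.
#' @return object of class `upgma_tree`: `merges` (list of member-id sets
#'   with merge distances), `newick`, `phylo` (ape).
#' @export
upgma <- function(D) {
  if (inherits(D, "cgj_matrix")) D <- D$D
  D <- as.matrix(D)
  if (any(is.na(D))) stop("NA/NaN in distance matrix")
  labels <- rownames(D)
  stopifnot(!is.null(labels), all(labels == colnames(D)))
  n <- nrow(D)
  if (n < 2) stop("need at least two leaves")
  members <- lapply(labels, identity)
  newick <- labels
  heights <- rep(0, n)
  sizes <- rep(1L, n)
  active <- seq_len(n)
  d <- D
  merges <- list()
  while (length(active) > 1L) {
    sub <- d[active, active, drop = FALSE]
    diag(sub) <- Inf
    dmin <- min(sub)
    hit <- which(sub == dmin, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    # deterministic tie-break: smallest member id, then the partner's
    key <- apply(hit, 1, function(rc) {
      a <- min(members[[active[rc[1]]]][1], members[[active[rc[2]]]][1])
      b <- max(members[[active[rc[1]]]][1], members[[active[rc[2]]]][1])
      paste(a, b)
    })
    pick <- hit[order(key)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    h <- dmin / 2
    nk <- sprintf("(%s:%.10g,%s:%.10g)", newick[i], h - heights[i],
                  newick[j], h - heights[j])
    # UPGMA update: size-weighted average to every other cluster
    others <- setdiff(active, c(i, j))
    newd <- (sizes[i] * d[i, others] + sizes[j] * d[j, others]) /
      (sizes[i] + sizes[j])
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    sizes[i] <- sizes[i] + sizes[j]
    newick[i] <- nk
    heights[i] <- h
    d[i, others] <- newd
    d[others, i] <- newd
    active <- setdiff(active, j)
    merges[[length(merges) + 1L]] <-
      list(members = members[[i]], distance = dmin)
  }
  nwk <- paste0(newick[active], ";")
  structure(list(merges = merges, newick = nwk,
                 phylo = ape::read.tree(text = nwk), labels = labels),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, %d merges\n", length(x$labels),
              length(x$merges)))
  invisible(x)
}

#' Cut a UPGMA dendrogram into family-level clusters
#'
#' Clusters are the leaves joined by merges at distance < `h`; pairs whose
#' merge distance is >= h are never co-clustered. Default h = 0.8, the
#' family-level CGJ threshold.
#'
#' @param tree [upgma()] result.
#' @param h cut height (CGJ distance).
#' @param prefix label prefix.
#' @return named character vector genome id -> family label; families are
#'   numbered by their lexicographically smallest member.
#' @export
cut_families <- function(tree, h = 0.8, prefix = "F") {
  labels <- tree$labels
  parent <- setNames(labels, labels)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (m in tree$merges) {
    if (m$distance < h) {
      roots <- unique(vapply(m$members, find, ""))
      for (r in roots[-1]) parent[[r]] <- roots[1]
    }
  }
  comp <- vapply(labels, find, "")
  smallest <- tapply(labels, comp, min)
  ord <- order(smallest)
  lab <- setNames(sprintf("%s%02d", prefix, seq_along(ord)),
                  names(smallest)[ord])
  setNames(unname(lab[comp]), labels)
}

#' Genus assignment within families by shared-protein linkage
#'
#' Single-linkage components over pairs whose symmetric shared fraction
#' exceeds `min_shared` percent, computed within each family.
#'
#' @param families named genome -> family vector from [cut_families()].
#' @param shared_sym symmetric shared-fraction matrix (percent).
#' @param min_shared genus threshold (strict >), default 60.
#' @return named genome -> genus vector; genus labels nest in family
#'   labels (e.g. "F01.G02").
#' @export
assign_genera <- function(families, shared_sym, min_shared = 60) {
  out <- character(0)
  for (fam in sort(unique(families))) {
    ids <- sort(names(families)[families == fam])
    s <- shared_sym[ids, ids, drop = FALSE]
    adj <- s > min_shared
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                              diag = FALSE)
    comp <- igraph::components(ig)$membership[ids]
    smallest <- tapply(ids, comp, min)
    ord <- order(smallest)
    relabel <- setNames(seq_along(ord), names(smallest)[ord])
    out[ids] <- sprintf("%s.G%02d", fam, relabel[as.character(comp)])
  }
  out
}

#' End-to-end taxonomy classification
#'
#' Runs all-vs-all homology, protein clustering, signatures, CGJ
#' distances, UPGMA, family cut and genus assignment.
#'
#' @param genomes list of `Genome` objects (>= 2).
#' @param min_identity,max_evalue homology thresholds (30%, 1e-25).
#' @param family_cut CGJ distance threshold for families (0.8).
#' @param genus_min_shared symmetric shared-protein threshold for genera
#'   (60%).
#' @param ... passed to [all_vs_all()].
#' @return object of class `virus_taxonomy`: assignment table, cgj matrix,
#'   tree, shared-fraction matrices, PCs, graph, parameters.
#' @export
classify <- function(genomes, min_identity = 30, max_evalue = 1e-25,
                     family_cut = 0.8, genus_min_shared = 60, ...) {
  if (length(genomes) < 2L)
    stop("classification requires at least two genomes [stage: input validation]")
  ids <- vapply(genomes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate genome ids [stage: input validation]")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  topo <- setNames(vapply(genomes, `[[`, "", "topology"), ids)
  graph <- stage("all_vs_all", all_vs_all(genomes, min_identity = min_identity,
                                          max_evalue = max_evalue, ...))
  pcs <- stage("protein_clusters", protein_clusters(graph))
  sigs <- stage("signatures", signatures(graph, pcs, topologies = topo))
  cgj <- stage("cgj", cgj_matrix(sigs))
  tree <- stage("upgma", upgma(cgj$D))
  fams <- stage("cut_families", cut_families(tree, h = family_cut))
  sh <- stage("shared_fraction", shared_fraction_matrix(graph))
  sh_sym <- (sh + t(sh)) / 2
  gen <- stage("assign_genera", assign_genera(fams, sh_sym,
                                              min_shared = genus_min_shared))
  assignment <- data.frame(genome_id = sort(ids),
                           family = fams[sort(ids)],
                           genus = gen[sort(ids)],
                           stringsAsFactors = FALSE)
  rownames(assignment) <- NULL
  structure(list(assignment = assignment, cgj = cgj, tree = tree,
                 shared_directed = sh, shared_symmetric = sh_sym,
                 pcs = pcs, graph = graph, signatures = sigs,
                 parameters = list(min_identity = min_identity,
                                   max_evalue = max_evalue,
                                   family_cut = family_cut,
                                   genus_min_shared = genus_min_shared)),
            class = "virus_taxonomy")
}

#' @export
print.virus_taxonomy <- function(x, ...) {
  cat(sprintf("<virus_taxonomy> %d genomes: %d families, %d genera\n",
              nrow(x$assignment), length(unique(x$assignment$family)),
              length(unique(x$assignment$genus))))
  print(x$assignment, ...)
  invisible(x)
}

#' Write the outputs of a classification run
#' @param tx [classify()] result.
#' @param dir output directory (created if needed).
#' @return dir, invisibly.
#' @export
write_taxonomy <- function(tx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(tx$assignment, file.path(dir, "assignment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(round(tx$cgj$D, 6), file.path(dir, "cgj_distance.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(round(tx$shared_directed, 3),
              file.path(dir, "shared_fraction_directed.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  writeLines(tx$tree$newick, file.path(dir, "cgj_upgma.nwk"))
  write_pc_table(tx$pcs, file.path(dir, "protein_clusters.tsv"))
  invisible(dir)
}
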