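# Efficiency-of-plating (EOP) host-range analysis: normalization to the
# isolation host, log10 binning, sensitive-host profiles, the hs host-range
# similarity statistic, host clustering and adhesin association.

#' Construct an EOP matrix
#'
#' @param values viruses x hosts numeric matrix (raw titers in pfu/mL, or
#'   already-normalized ratios with `raw = FALSE`), non-negative.
#' @param isolation_host named character vector virus -> isolation host.
#'   Every virus needs its isolation host in the host panel unless a
#'   substitute titer is supplied (the HRTV-26 case: the reference host
#'   occasionally forms no lawn and the externally measured titer is used).
#' @param detection_floor titer below which a raw value is recorded as 0
#'   (default 1e3 pfu/mL, the plaque-assay detection limit).
#' @param substitute_titer optional named numeric vector virus ->
#'   reference titer used as the normalization denominator.
#' @param raw are `values` raw titers (floor applied) or normalized?
#' @return object of class `eop_matrix`.
#' @export
eop_matrix <- function(values, isolation_host, detection_floor = 1e3,
                       substitute_titer = NULL, raw = TRUE) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)),
            all(values >= 0))
  miss <- setdiff(rownames(values), names(isolation_host))
  if (length(miss)) stop("no isolation host for: ", paste(miss, collapse = ","))
  no_panel <- !(isolation_host[rownames(values)] %in% colnames(values))
  no_sub <- !(rownames(values) %in% names(substitute_titer))
  if (any(no_panel & no_sub))
    stop("isolation host absent from panel and no substitute titer for: ",
         paste(rownames(values)[no_panel & no_sub], collapse = ","))
  if (raw) values[values < detection_floor] <- 0
  structure(list(values = values,
                 isolation_host = isolation_host[rownames(values)],
                 detection_floor = detection_floor,
                 substitute_titer = substitute_titer,
                 normalized = !raw),
            class = "eop_matrix")
}

#' Normalize an EOP matrix to the isolation host
#'
#' Each virus row is divided by its titer on the isolation host (or by the
#' substitute reference titer), so the isolation host reads 1. Idempotent.
#'
#' @param m [eop_matrix()].
#' @return normalized `eop_matrix`.
#' @export
normalize_eop <- function(m) {
  stopifnot(inherits(m, "eop_matrix"))
  v <- m$values
  for (vi in rownames(v)) {
    host <- m$isolation_host[[vi]]
    denom <- if (vi %in% names(m$substitute_titer)) {
      if (m$normalized) 1 else m$substitute_titer[[vi]]
    } else {
      v[vi, host]
    }
    if (is.na(denom) || denom <= 0)
      stop("zero or missing isolation-host titer for ", vi,
           " and no substitute value")
    v[vi, ] <- v[vi, ] / denom
  }
  m$values <- v
  m$normalized <- TRUE
  m
}

#' Bin normalized EOP values into log10 categories
#'
#' category = round(log10(value)) with half away from zero; 0 means equal
#' to the isolation host (displayed "1"), -1 means 10^-1, +1 means 10^1.
#' Zeros (no infection) become NA ("ni").
#'
#' @param x normalized values (vector or matrix), >= 0.
#' @return integer categories, same shape; NA for zeros.
#' @export
bin_log10 <- function(x) {
  if (inherits(x, "eop_matrix")) x <- x$values
  if (any(x < 0)) stop("negative EOP value")
  lg <- suppressWarnings(log10(x))
  cat <- sign(lg) * floor(abs(lg) + 0.5)
  cat[!is.finite(lg)] <- NA
  storage.mode(cat) <- "integer"
  cat
}

#' Display labels for log10 EOP categories
#' @param cat integer categories from [bin_log10()].
#' @return character labels: "1" for 0, "+n"/"-n", "ni" for NA.
#' @export
format_eop_category <- function(cat) {
  out <- ifelse(is.na(cat), "ni",
                ifelse(cat == 0L, "1",
                       ifelse(cat > 0L, paste0("+", cat),
                              as.character(cat))))
  dim(out) <- dim(cat)
  dimnames(out) <- dimnames(cat)
  out
}

#' Sensitive-host profiles
#'
#' A host is sensitive when the normalized EOP is detectable (> 0 after
#' the detection floor).
#'
#' @param m normalized [eop_matrix()].
#' @return named list virus -> character vector of sensitive hosts.
#' @export
sensitive_hosts <- function(m) {
  stopifnot(inherits(m, "eop_matrix"))
  if (!m$normalized) m <- normalize_eop(m)
  v <- m$values
  setNames(lapply(rownames(v), function(vi) colnames(v)[v[vi, ] > 0]),
           rownames(v))
}

#' Host-range similarity (hs) of two sensitive-host profiles
#'
#' Shared sensitive hosts over total (union of) sensitive hosts.
#'
#' @param profileA,profileB character vectors of sensitive hosts.
#' @return similarity in \[0, 1\]; 0 with a warning when both are empty.
#' @export
hs <- function(profileA, profileB) {
  u <- union(profileA, profileB)
  if (!length(u)) {
    warning("both host-range profiles are empty; hs defined as 0")
    return(0)
  }
  length(intersect(profileA, profileB)) / length(u)
}

#' Pairwise hs matrix
#' @param profiles list from [sensitive_hosts()].
#' @return symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
hs_matrix <- function(profiles) {
  ids <- names(profiles)
  n <- length(ids)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- suppressWarnings(hs(profiles[[i]], profiles[[j]]))
      }
    }
  }
  m
}

#' Cluster hosts by EOP-category similarity
#'
#' Average-linkage hierarchical clustering on Manhattan distance between
#' host category columns; "not infected" (NA) is treated as category -9.
#'
#' @param cats integer category matrix from [bin_log10()] (viruses x
#'   hosts, >= 2 hosts).
#' @param sentinel category substituted for NA.
#' @return `phylo` dendrogram over hosts.
#' @export
cluster_hosts <- function(cats, sentinel = -9L) {
  stopifnot(ncol(cats) >= 2L)
  m <- cats
  m[is.na(m)] <- sentinel
  d <- dist(t(m), method = "manhattan")
  ape::as.phylo(hclust(d, method = "average"))
}

#' Association between host-range similarity and adhesin identity
#'
#' Spearman rank correlation between pairwise hs and pairwise adhesin
#' identity, overall and within adhesin groups, with a Mantel-style
#' permutation test (virus labels permuted; one-sided, positive
#' association). The permutation test is an added diagnostic, not part of
#' the original heat-map analysis.
#'
#' @param hs_mat symmetric hs matrix.
#' @param id_mat symmetric adhesin identity matrix (same viruses, percent
#'   or fraction).
#' @param groups optional named virus -> adhesin-group vector for
#'   per-group summaries.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @return list(overall = list(rho, p_value), by_group data frame or NULL,
#'   n_perm, seed).
#' @export
associate_adhesin <- function(hs_mat, id_mat, groups = NULL, n_perm = 999L,
                              seed = 1L) {
  ids <- rownames(hs_mat)
  if (length(ids) < 4L) stop("need at least 4 viruses")
  if (!setequal(ids, rownames(id_mat)))
    stop("hs and identity matrices cover different virus sets")
  if (n_perm < 99L) stop("n_perm must be >= 99")
  id_mat <- id_mat[ids, ids]
  lt <- lower.tri(hs_mat)
  mantel <- function(sub_ids) {
    h <- hs_mat[sub_ids, sub_ids]
    p <- id_mat[sub_ids, sub_ids]
    ltt <- lower.tri(h)
    obs <- suppressWarnings(cor(h[ltt], p[ltt], method = "spearman"))
    if (is.na(obs)) return(list(rho = NA_real_, p_value = NA_real_))
    ge <- 0L
    nn <- length(sub_ids)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(nn)
      r <- suppressWarnings(cor(h[perm, perm][ltt], p[ltt],
                                method = "spearman"))
      if (!is.na(r) && r >= obs) ge <- ge + 1L
    }
    list(rho = obs, p_value = (1 + ge) / (n_perm + 1))
  }
  set.seed(seed)
  overall <- mantel(ids)
  by_group <- NULL
  if (!is.null(groups)) {
    rows <- lapply(sort(unique(groups)), function(g) {
      sub <- intersect(ids, names(groups)[groups == g])
      if (length(sub) < 4L) {
        data.frame(group = g, n = length(sub), rho = NA_real_,
                   p_value = NA_real_, stringsAsFactors = FALSE)
      } else {
        r <- mantel(sub)
        data.frame(group = g, n = length(sub), rho = r$rho,
                   p_value = r$p_value, stringsAsFactors = FALSE)
      }
    })
    by_group <- do.call(rbind, rows)
  }
  list(overall = overall, by_group = by_group, n_perm = n_perm, seed = seed)
}

#' Read an EOP table and isolation-host map from TSV files
#'
#' @param eop_path viruses x hosts tab-separated table (first column =
#'   virus id).
#' @param isolation_path two-column file (virus, host); an optional third
#'   column supplies a substitute reference titer.
#' @param ... passed to [eop_matrix()].
#' @return `eop_matrix`.
#' @export
read_eop_table <- function(eop_path, isolation_path, ...) {
  v <- as.matrix(read.table(eop_path, header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE))
  iso <- read.table(isolation_path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  ih <- setNames(iso[[2]], iso[[1]])
  subs <- NULL
  if (ncol(iso) >= 3) {
    has <- !is.na(iso[[3]])
    if (any(has)) subs <- setNames(as.numeric(iso[[3]][has]), iso[[1]][has])
  }
  eop_matrix(v, ih, substitute_titer = subs, ...)
}

#' Write an EOP matrix (values or categories) as TSV
#' @param m `eop_matrix` or matrix.
#' @param path output file.
#' @export
write_eop_table <- function(m, path) {
  v <- if (inherits(m, "eop_matrix")) m$values else m
  write.table(v, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
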