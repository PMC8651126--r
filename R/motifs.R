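# Restriction-site motif counting (IUPAC, overlap-inclusive,
# strand-symmetric), Markov-null expected counts, per-kbp frequencies and
# the MTase-carriage group comparison (in-repo Mann-Whitney U).

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))
IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

iupac_check <- function(motif) {
  ch <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  if (!length(ch) || !all(ch %in% names(IUPAC_SETS)))
    stop("invalid IUPAC motif: ", motif)
  ch
}

iupac_revcomp <- function(motif) {
  ch <- iupac_check(motif)
  paste(rev(unname(IUPAC_COMPLEMENT[ch])), collapse = "")
}

is_palindromic_motif <- function(motif) {
  toupper(motif) == iupac_revcomp(motif)
}

# logical: does each start position of `codes` match the motif?
# N in the sequence (code 5) never matches.
motif_hits <- function(codes, motif_ch) {
  k <- length(motif_ch)
  L <- length(codes)
  if (L < k) return(logical(0))
  npos <- L - k + 1L
  ok <- rep(TRUE, npos)
  for (p in seq_len(k)) {
    allowed <- match(IUPAC_SETS[[motif_ch[p]]], DNA_ALPHABET) - 1L
    ok <- ok & (codes[seq_len(npos) + p - 1L] %in% allowed)
  }
  ok
}

#' Count motif occurrences in a genome sequence
#'
#' Overlapping occurrences on the forward strand; when the motif is not
#' its own reverse complement, reverse-strand occurrences are added.
#' Palindromic sites (e.g. GATC) are therefore counted once per site.
#' Circular topology counts origin-spanning matches once.
#'
#' @param sequence DNA string (or `Genome`); N never matches.
#' @param motif IUPAC motif.
#' @param topology "linear" or "circular" (taken from a `Genome` input).
#' @return integer count.
#' @export
count_motif <- function(sequence, motif, topology = c("linear", "circular")) {
  if (inherits(sequence, "Genome")) {
    topology <- sequence$topology
    sequence <- sequence$sequence
  } else {
    topology <- match.arg(topology)
    sequence <- toupper(sequence)
    check_dna(sequence)
  }
  ch <- iupac_check(motif)
  k <- length(ch)
  s <- sequence
  if (topology == "circular" && nchar(sequence) >= k) {
    s <- paste0(sequence, substr(sequence, 1L, k - 1L))
  }
  codes <- encode_dna(s)
  n <- sum(motif_hits(codes, ch))
  if (!is_palindromic_motif(motif)) {
    rc <- iupac_check(iupac_revcomp(motif))
    n <- n + sum(motif_hits(codes, rc))
  }
  as.integer(n)
}

#' Motif frequency per kilobase
#' @param count occurrence count.
#' @param length sequence length in bp (> 0).
#' @return occurrences per kbp.
#' @export
freq_per_kbp <- function(count, length) {
  stopifnot(all(length > 0))
  count / (length / 1000)
}

#' Expected motif count under a Markov null model
#'
#' Fits an order-0/1/2 Markov chain to the sequence composition and
#' returns the expected number of overlapping occurrences:
#' sum over motif-compatible words w of P(w) * (L - k + 1) (L positions
#' for circular sequences). Reverse-strand words are added for
#' non-palindromic motifs, mirroring [count_motif()].
#'
#' @param sequence DNA string or `Genome`.
#' @param motif IUPAC motif.
#' @param order Markov order (0, 1 or 2).
#' @param topology "linear" or "circular".
#' @return expected count (0 with a warning when every compatible word
#'   requires an unobserved transition).
#' @export
expected_count_markov <- function(sequence, motif, order = 1L,
                                  topology = c("linear", "circular")) {
  if (inherits(sequence, "Genome")) {
    topology <- sequence$topology
    sequence <- sequence$sequence
  } else {
    topology <- match.arg(topology)
    sequence <- toupper(sequence)
  }
  stopifnot(order %in% 0:2)
  ch <- iupac_check(motif)
  k <- length(ch)
  codes <- encode_dna(sequence)
  codes <- codes[codes < 4L] # drop N from composition fitting
  L <- nchar(sequence)
  if (length(codes) < max(10L, order + 2L))
    stop("sequence too short to estimate the Markov null")
  p1 <- tabulate(codes + 1L, 4L) / length(codes)
  trans1 <- trans2 <- NULL
  if (order >= 1L) {
    a <- codes[-length(codes)]; b <- codes[-1L]
    tab <- table(factor(a, 0:3), factor(b, 0:3))
    trans1 <- sweep(as.matrix(tab), 1, pmax(rowSums(tab), 1), "/")
  }
  if (order == 2L) {
    a <- codes[seq_len(length(codes) - 2L)]
    b <- codes[seq_len(length(codes) - 2L) + 1L]
    cc <- codes[seq_len(length(codes) - 2L) + 2L]
    tab2 <- table(factor(a * 4L + b, 0:15), factor(cc, 0:3))
    trans2 <- sweep(as.matrix(tab2), 1, pmax(rowSums(tab2), 1), "/")
    pair <- table(factor(codes[-length(codes)] * 4L + codes[-1L], 0:15))
    p2 <- as.numeric(pair) / sum(pair)
  }
  word_prob <- function(w) { # w: 0-based codes
    if (order == 0L) return(prod(p1[w + 1L]))
    if (order == 1L) {
      pr <- p1[w[1] + 1L]
      for (t in seq_len(length(w) - 1L))
        pr <- pr * trans1[w[t] + 1L, w[t + 1L] + 1L]
      return(pr)
    }
    if (length(w) == 1L) return(p1[w + 1L])
    pr <- p2[w[1] * 4L + w[2] + 1L]
    for (t in seq_len(length(w) - 2L))
      pr <- pr * trans2[w[t] * 4L + w[t + 1L] + 1L, w[t + 2L] + 1L]
    pr
  }
  expand <- function(ch_vec) {
    sets <- lapply(ch_vec, function(c0) match(IUPAC_SETS[[c0]], DNA_ALPHABET) - 1L)
    nw <- prod(lengths(sets))
    if (nw > 65536) stop("motif ambiguity expansion too large")
    as.matrix(do.call(expand.grid, rev(sets)))[, rev(seq_along(sets)), drop = FALSE]
  }
  words <- expand(ch)
  if (!is_palindromic_motif(motif)) {
    words <- rbind(words, expand(iupac_check(iupac_revcomp(motif))))
  }
  ptot <- sum(apply(words, 1, word_prob))
  npos <- if (topology == "circular") L else L - k + 1L
  expected <- ptot * max(npos, 0L)
  if (expected == 0)
    warning("motif requires transitions never observed in the sequence; expected count 0")
  expected
}

#' Per-genome motif report
#'
#' @param genomes list of `Genome` objects.
#' @param motif IUPAC motif (default GATC, the Dam site).
#' @param order Markov null order.
#' @param mtase_status optional named vector genome -> "encodes"/"lacks";
#'   anything else/missing is "unknown".
#' @return data frame: genome_id, motif, count, length_bp, freq_per_kbp,
#'   expected, oe_ratio, mtase_status.
#' @export
motif_report <- function(genomes, motif = "GATC", order = 1L,
                         mtase_status = NULL) {
  rows <- lapply(genomes, function(g) {
    cnt <- count_motif(g, motif)
    expd <- expected_count_markov(g, motif, order = order)
    st <- if (!is.null(mtase_status) && g$id %in% names(mtase_status) &&
              mtase_status[[g$id]] %in% c("encodes", "lacks"))
      mtase_status[[g$id]] else "unknown"
    data.frame(genome_id = g$id, motif = toupper(motif), count = cnt,
               length_bp = g$length,
               freq_per_kbp = freq_per_kbp(cnt, g$length),
               expected = expd,
               oe_ratio = if (expd > 0) cnt / expd else NA_real_,
               mtase_status = st, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mann-Whitney U comparison of motif frequency between MTase groups
#'
#' In-repo rank-sum test: exact null distribution by complete enumeration
#' when both groups have <= 8 observations, normal approximation with tie
#' correction (and continuity correction) otherwise. U counts pairs where
#' the first group is smaller (+ 1/2 per tie).
#'
#' @param x,y numeric vectors (e.g. freq_per_kbp of MTase-encoding vs
#'   MTase-lacking genomes), each of length >= 2. Alternatively pass a
#'   [motif_report()] data frame as `x` and a named status vector as `y`.
#' @param alternative "two.sided", "less" or "greater" (of x relative
#'   to y).
#' @return list(U, p_value, method, alternative).
#' @export
compare_mtase_groups <- function(x, y,
                                 alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  if (is.data.frame(x)) {
    st <- if (is.null(y)) x$mtase_status else y[x$genome_id]
    xx <- x$freq_per_kbp[st == "encodes"]
    yy <- x$freq_per_kbp[st == "lacks"]
    x <- xx; y <- yy
  }
  n <- length(x); m <- length(y)
  if (n < 2L || m < 2L) stop("each group needs at least 2 genomes")
  u_stat <- function(xv, yv) {
    sum(outer(xv, yv, ">")) + 0.5 * sum(outer(xv, yv, "=="))
  }
  U <- u_stat(x, y)
  if (n <= 8L && m <= 8L) {
    pool <- c(x, y)
    idx <- combn(n + m, n)
    us <- apply(idx, 2, function(ii) u_stat(pool[ii], pool[-ii]))
    total <- ncol(idx)
    p <- switch(alternative,
                less = sum(us <= U) / total,
                greater = sum(us >= U) / total,
                two.sided = min(1, 2 * min(sum(us <= U), sum(us >= U)) / total))
    method <- "exact enumeration"
  } else {
    mu <- n * m / 2
    ties <- table(c(x, y))
    N <- n + m
    tie_corr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n * m / 12 * (N + 1 - tie_corr))
    z_less <- (U - mu + 0.5) / sigma
    z_greater <- (U - mu - 0.5) / sigma
    p <- switch(alternative,
                less = pnorm(z_less),
                greater = pnorm(z_greater, lower.tail = FALSE),
                two.sided = min(1, 2 * min(pnorm(z_less),
                                           pnorm(z_greater,
                                                 lower.tail = FALSE))))
    method <- "normal approximation with tie correction"
  }
  list(U = U, p_value = p, method = method, alternative = alternative)
}

#' Write a motif report as TSV
#' @param report [motif_report()] data frame.
#' @param path output file.
#' @export
write_motif_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an MTase-status table (two columns: genome_id, status)
#' @param path TSV file.
#' @return named character vector.
#' @export
read_mtase_table <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  setNames(tab[[2]], tab[[1]])
}
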