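# Genome container plus GenBank flat-file I/O, naive ORF calling and
# proteome extraction. Coordinates are 0-based half-open internally and
# 1-based inclusive in GenBank files. Origin-spanning features on circular
# replicons are stored with end > length and wraparound = TRUE.

empty_genes <- function() {
  data.frame(gene_id = character(), genome_id = character(),
             start = integer(), end = integer(), strand = character(),
             type = character(), product = character(),
             protein = character(), wraparound = logical(),
             stringsAsFactors = FALSE)
}

#' Construct a genome
#'
#' @param id unique identifier.
#' @param sequence DNA string over A,C,G,T,N (other ambiguity codes are
#'   rejected).
#' @param name human-readable name; defaults to `id`.
#' @param topology "linear" or "circular".
#' @param genes data frame of gene records (see [gene_record()]).
#' @param meta free-form key/value list (host, isolation site, ...).
#' @return object of class `Genome`.
#' @export
new_genome <- function(id, sequence, name = id,
                       topology = c("linear", "circular"),
                       genes = empty_genes(), meta = list()) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  check_dna(sequence, id)
  g <- structure(list(id = id, name = name, sequence = sequence,
                      length = nchar(sequence), topology = topology,
                      genes = genes, meta = meta),
                 class = "Genome")
  validate_genome(g)
}

validate_genome <- function(g) {
  stopifnot(inherits(g, "Genome"))
  if (g$length != nchar(g$sequence)) stop("length does not match sequence")
  gn <- g$genes
  if (nrow(gn)) {
    if (any(gn$start >= gn$end)) stop("gene with start >= end in ", g$id)
    if (any(gn$start < 0L | gn$start >= g$length))
      stop("gene start outside [0, length) in ", g$id)
    bad <- !gn$wraparound & gn$end > g$length
    if (any(bad)) stop("gene end beyond sequence in ", g$id)
    if (any(gn$wraparound & (gn$end <= g$length | gn$end > 2L * g$length)))
      stop("invalid wraparound coordinates in ", g$id)
  }
  g
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("<Genome> %s (%s): %d bp, %s, %d gene record(s)\n",
              x$id, x$name, x$length, x$topology, nrow(x$genes)))
  invisible(x)
}

#' Construct a gene record row
#'
#' @param gene_id,genome_id identifiers.
#' @param start,end 0-based half-open interval on the forward strand; for
#'   origin-spanning genes on circular genomes `end` may exceed the genome
#'   length and `wraparound` must be `TRUE`.
#' @param strand "+" or "-".
#' @param type feature type ("CDS", "tRNA", ...).
#' @param product free-text product.
#' @param protein amino-acid string; non-empty iff the record is a CDS.
#' @param wraparound does the feature span the origin of a circular genome?
#' @return one-row data frame.
#' @export
gene_record <- function(gene_id, genome_id, start, end, strand,
                        type = "CDS", product = "", protein = "",
                        wraparound = FALSE) {
  stopifnot(strand %in% c("+", "-"), start < end)
  data.frame(gene_id = gene_id, genome_id = genome_id,
             start = as.integer(start), end = as.integer(end),
             strand = strand, type = type, product = product,
             protein = protein, wraparound = wraparound,
             stringsAsFactors = FALSE)
}

# Extract the (strand-corrected) nucleotide sequence of gene i.
gene_seq <- function(genome, i) {
  gn <- genome$genes[i, ]
  s <- if (gn$wraparound) {
    paste0(substr(genome$sequence, gn$start + 1L, genome$length),
           substr(genome$sequence, 1L, gn$end - genome$length))
  } else {
    substr(genome$sequence, gn$start + 1L, gn$end)
  }
  if (gn$strand == "-") revcomp(s) else s
}

# ---------------------------------------------------------------------------
# GenBank flat files

#' Read a (possibly multi-record) GenBank flat file
#'
#' CDS and tRNA features are imported; a CDS `/translation` qualifier is
#' used verbatim when present, otherwise the protein is translated from the
#' coordinates with translation table 11. A CDS whose protein cannot be
#' resolved is skipped with a warning. `join()` locations are supported
#' only for the two-segment origin-spanning case on circular genomes.
#'
#' @param path GenBank flat file.
#' @return list of [new_genome()] objects (empty list for an empty file).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) return(list())
  rec_end <- grep("^//", lines)
  if (!length(rec_end)) stop("malformed GenBank file (no // terminator): ", path)
  starts <- c(1L, head(rec_end, -1L) + 1L)
  out <- list()
  for (r in seq_along(rec_end)) {
    rec <- lines[starts[r]:(rec_end[r] - 1L)]
    rec <- rec[nzchar(trimws(rec)) | grepl("^ {9,}", rec)]
    if (!length(rec)) next
    g <- parse_genbank_record(rec)
    out[[g$id]] <- g
  }
  unname(out)
}

parse_genbank_record <- function(rec) {
  locus_line <- grep("^LOCUS", rec, value = TRUE)
  if (!length(locus_line)) stop("malformed GenBank record: missing LOCUS")
  toks <- strsplit(trimws(locus_line[1]), "[[:space:]]+")[[1]]
  id <- toks[2]
  topology <- if ("circular" %in% toks) "circular" else "linear"
  def_line <- grep("^DEFINITION", rec, value = TRUE)
  name <- if (length(def_line)) trimws(sub("^DEFINITION", "", def_line[1])) else id

  ori <- grep("^ORIGIN", rec)
  if (!length(ori)) stop("malformed GenBank record ", id, ": missing ORIGIN")
  seq_lines <- rec[(ori[1] + 1L):length(rec)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  check_dna(sequence, id)
  len <- nchar(sequence)

  genes <- empty_genes()
  fstart <- grep("^FEATURES", rec)
  if (length(fstart) && fstart[1] + 1L <= ori[1] - 1L) {
    flines <- rec[(fstart[1] + 1L):(ori[1] - 1L)]
    keycol <- substr(flines, 6L, 20L)
    is_new <- nzchar(trimws(keycol)) & !grepl("^ {0,4}\\S", flines)
    idx <- which(is_new)
    cds_n <- 0L
    for (fi in seq_along(idx)) {
      from <- idx[fi]
      to <- if (fi < length(idx)) idx[fi + 1L] - 1L else length(flines)
      key <- trimws(keycol[from])
      if (!key %in% c("CDS", "tRNA")) next
      block <- flines[from:to]
      parsed <- tryCatch(
        parse_feature_block(block, key, id, len, topology),
        error = function(e) stop("malformed record at locus ", id, ": ",
                                 conditionMessage(e)))
      if (is.null(parsed)) next
      cds_n <- cds_n + 1L
      if (!nzchar(parsed$gene_id)) parsed$gene_id <- sprintf("cds%03d", cds_n)
      if (parsed$type == "CDS" && !nzchar(parsed$protein)) {
        nt <- tryCatch({
          gtmp <- structure(list(sequence = sequence, length = len,
                                 genes = parsed, id = id), class = "Genome")
          gene_seq(gtmp, 1L)
        }, error = function(e) "")
        prot <- tryCatch(sub("\\*$", "", translate_cds(nt)),
                         error = function(e) "")
        if (!nzchar(prot) || grepl("\\*", prot)) {
          warning("CDS without resolvable protein skipped in ", id)
          cds_n <- cds_n - 1L
          next
        }
        parsed$protein <- prot
      }
      genes <- rbind(genes, parsed)
    }
  }
  if (nrow(genes)) genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  new_genome(id = id, sequence = sequence, name = name, topology = topology,
             genes = genes)
}

parse_feature_block <- function(block, key, genome_id, len, topology) {
  # location: first line plus continuations until a /qualifier line
  qual_at <- grep("^ {21}/", block)
  loc_to <- if (length(qual_at)) qual_at[1] - 1L else length(block)
  loc <- gsub("[[:space:]]", "", paste(substring(block[1:loc_to], 22L),
                                       collapse = ""))
  loc <- sub("^CDS", "", sub("^tRNA", "", loc)) # safety if key leaked in
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraparound <- FALSE
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    iv <- lapply(parts, parse_interval)
    if (length(iv) == 2L && topology == "circular" &&
        iv[[1]][2] == len && iv[[2]][1] == 1L) {
      start <- iv[[1]][1] - 1L
      end <- len + iv[[2]][2]
      wraparound <- TRUE
    } else {
      stop("unsupported join() location: ", loc)
    }
  } else {
    iv <- parse_interval(loc)
    start <- iv[1] - 1L
    end <- iv[2]
  }
  quals <- parse_qualifiers(block[seq_len(length(block)) >= loc_to + 1L])
  protein <- if (!is.null(quals$translation))
    gsub("[[:space:]]", "", quals$translation) else ""
  gene_id <- quals$locus_tag %||% quals$gene %||% ""
  gene_record(gene_id = gene_id, genome_id = genome_id, start = start,
              end = end, strand = strand, type = key,
              product = quals$product %||% "", protein = protein,
              wraparound = wraparound)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_interval <- function(x) {
  x <- gsub("[<>]", "", x)
  m <- regmatches(x, regexec("^([0-9]+)\\.\\.([0-9]+)$", x))[[1]]
  if (length(m) != 3L) stop("cannot parse location interval: ", x)
  c(as.integer(m[2]), as.integer(m[3]))
}

parse_qualifiers <- function(lines) {
  lines <- lines[grepl("^ {21}", lines)]
  if (!length(lines)) return(list())
  txt <- substring(lines, 22L)
  starts <- grepl("^/", txt)
  grp <- cumsum(starts)
  out <- list()
  for (g in unique(grp[starts])) {
    joined <- paste(txt[grp == g], collapse = "")
    m <- regmatches(joined, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?', joined))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

#' Write genomes to a GenBank flat file
#'
#' Inverse of [read_genbank()]: sequence, coordinates and strands
#' round-trip exactly.
#'
#' @param genomes a `Genome` or list of them.
#' @param path output file.
#' @export
write_genbank <- function(genomes, path) {
  if (inherits(genomes, "Genome")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s PHG 01-JAN-2000",
                       g$id, g$length, g$topology), con)
    writeLines(paste0("DEFINITION  ", g$name), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", g$length), con)
    if (nrow(g$genes)) {
      for (i in seq_len(nrow(g$genes))) {
        gn <- g$genes[i, ]
        loc <- if (gn$wraparound) {
          sprintf("join(%d..%d,1..%d)", gn$start + 1L, g$length,
                  gn$end - g$length)
        } else {
          sprintf("%d..%d", gn$start + 1L, gn$end)
        }
        if (gn$strand == "-") loc <- sprintf("complement(%s)", loc)
        writeLines(sprintf("     %-15s %s", gn$type, loc), con)
        writeLines(wrap_qualifier(sprintf('/locus_tag="%s"', gn$gene_id)), con)
        if (nzchar(gn$product))
          writeLines(wrap_qualifier(sprintf('/product="%s"', gn$product)), con)
        if (nzchar(gn$protein))
          writeLines(wrap_qualifier(sprintf('/translation="%s"', gn$protein)),
                     con)
      }
    }
    writeLines("ORIGIN", con)
    s <- tolower(g$sequence)
    pos <- seq(1L, g$length, 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, g$length))
      tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

wrap_qualifier <- function(x, indent = 21L, width = 79L) {
  avail <- width - indent
  if (nchar(x) <= avail) return(paste0(strrep(" ", indent), x))
  pieces <- substring(x, seq(1L, nchar(x), avail),
                      pmin(seq(avail, nchar(x) + avail - 1L, avail), nchar(x)))
  paste0(strrep(" ", indent), pieces)
}

# ---------------------------------------------------------------------------
# ORF calling

#' Call ORFs naively on both strands (translation table 11)
#'
#' All maximal ORFs (first ATG/GTG/TTG after the previous stop, through the
#' stop codon) with protein length >= `min_aa`, non-nested per frame.
#'
#' @param sequence DNA string.
#' @param min_aa minimum protein length in residues (>= 1).
#' @param genome_id id recorded on the returned gene records.
#' @return gene-record data frame (0-based half-open coordinates include
#'   the stop codon).
#' @export
call_orfs <- function(sequence, min_aa = 50L, genome_id = "genome") {
  stopifnot(min_aa >= 1L)
  sequence <- toupper(sequence)
  check_dna(sequence, genome_id)
  L <- nchar(sequence)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3L
      if (ncod < min_aa + 1L) next
      from <- frame + seq(1L, by = 3L, length.out = ncod)
      codons <- substring(s, from, from + 2L)
      gc <- genetic_code_11()
      aa <- unname(gc[codons])
      aa[is.na(aa)] <- "X"
      is_stop <- aa == "*"
      is_start <- codons %in% c("ATG", "GTG", "TTG")
      seg_id <- cumsum(c(TRUE, head(is_stop, -1L)))
      for (seg in split(seq_len(ncod), seg_id)) {
        last <- seg[length(seg)]
        if (!is_stop[last]) next # ORF must terminate in a stop
        starts <- seg[is_start[seg]]
        if (!length(starts)) next
        st <- starts[1]
        plen <- last - st # codons before the stop
        if (plen < min_aa) next
        beg0 <- frame + (st - 1L) * 3L  # 0-based on strand s
        end0 <- frame + last * 3L
        prot <- paste(c("M", aa[seq(st + 1L, last - 1L)][seq_len(plen - 1L)]),
                      collapse = "")
        if (strand == "+") {
          b <- beg0; e <- end0
        } else {
          b <- L - end0; e <- L - beg0
        }
        out[[length(out) + 1L]] <-
          gene_record(gene_id = "", genome_id = genome_id, start = b, end = e,
                      strand = strand, product = "predicted ORF",
                      protein = prot)
      }
    }
  }
  if (!length(out)) return(empty_genes())
  genes <- do.call(rbind, out)
  genes <- genes[order(genes$start, genes$end, genes$strand), , drop = FALSE]
  genes$gene_id <- sprintf("orf%04d", seq_len(nrow(genes)))
  rownames(genes) <- NULL
  genes
}

# ---------------------------------------------------------------------------
# Proteomes

#' Extract the proteome of a genome
#'
#' @param genome a `Genome` with CDS annotations.
#' @return data frame (protein_id, sequence, gene_id, start, end, strand)
#'   in coordinate order; protein ids are `genomeId|geneId`, suffixed when
#'   gene ids collide.
#' @export
extract_proteome <- function(genome) {
  gn <- genome$genes
  gn <- gn[gn$type == "CDS" & nzchar(gn$protein), , drop = FALSE]
  if (!nrow(gn)) {
    return(data.frame(protein_id = character(), sequence = character(),
                      gene_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  gn <- gn[order(gn$start, gn$end), , drop = FALSE]
  ids <- gn$gene_id
  if (anyDuplicated(ids)) {
    warning("duplicate gene_ids in ", genome$id, "; suffixing to be unique")
    ids <- make.unique(ids, sep = ".")
  }
  data.frame(protein_id = paste0(genome$id, "|", ids),
             sequence = gn$protein, gene_id = ids, start = gn$start,
             end = gn$end, strand = gn$strand, stringsAsFactors = FALSE)
}
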