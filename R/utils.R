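# Shared low-level helpers: alphabets, encodings, scoring matrices,
# translation, adjusted Rand index.

.viratax <- new.env(parent = emptyenv())

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET <- c(AA20, "X")
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Protein substitution matrix with X scored 0
#'
#' BLOSUM62 (from Biostrings) restricted to the 20 canonical residues plus
#' X, with every X score set to 0 so that unknown residues neither reward
#' nor penalize an alignment.
#'
#' @param name matrix name; only "BLOSUM62" is shipped.
#' @return integer matrix over `c(AA20, "X")`.
#' @export
protein_submatrix <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (!is.null(.viratax[[key]])) return(.viratax[[key]])
  if (name != "BLOSUM62") stop("unknown substitution matrix: ", name)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  .viratax[[key]] <- m
  m
}

# match +2 / mismatch -3 (N scores 0 against everything), used for the
# banded DNA segment alignments in count_substitutions()
dna_submatrix <- function() {
  if (!is.null(.viratax$dna_submat)) return(.viratax$dna_submat)
  m <- matrix(-3L, 5, 5, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  diag(m) <- 2L
  m["N", ] <- 0L
  m[, "N"] <- 0L
  .viratax$dna_submat <- m
  m
}

encode_protein <- function(x, id = "protein") {
  if (!nzchar(x)) stop("empty protein sequence: ", id)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  code <- match(ch, AA_ALPHABET)
  if (anyNA(code)) {
    bad <- unique(ch[is.na(code)])
    stop(sprintf("invalid residue(s) %s in %s (only the 20 amino acids and X are accepted)",
                 paste(bad, collapse = ","), id))
  }
  code - 1L
}

encode_dna <- function(x, id = "sequence") {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  code <- match(ch, DNA_ALPHABET)
  if (anyNA(code)) {
    bad <- unique(ch[is.na(code)])
    stop(sprintf("invalid base(s) %s in %s (alphabet is A,C,G,T,N)",
                 paste(bad, collapse = ","), id))
  }
  code - 1L
}

check_dna <- function(x, id = "sequence") {
  if (grepl("[^ACGTN]", x))
    stop(sprintf("sequence of %s contains characters outside A,C,G,T,N (other IUPAC ambiguity codes are rejected)",
                 id))
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param x DNA string over A,C,G,T,N.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

genetic_code_11 <- function() {
  if (!is.null(.viratax$gc11)) return(.viratax$gc11)
  .viratax$gc11 <- Biostrings::getGeneticCode("11")
  .viratax$gc11
}

# Translate a CDS nucleotide string (table 11). Codons containing N become
# X; alternative starts (GTG/TTG) are rendered as M when `init = TRUE`.
translate_cds <- function(x, init = TRUE) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3")
  codons <- substring(x, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  gc <- genetic_code_11()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  if (init && length(aa) && codons[1] %in% c("ATG", "GTG", "TTG"))
    aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b vectors of cluster labels over the same items (matched by
#'   names when both are named, by position otherwise).
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    stopifnot(setequal(names(a), names(b)))
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  si <- sum(choose2(rowSums(tab)))
  sj <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

#' Read sequences from a FASTA file
#' @param path file path.
#' @param type "DNA" or "AA".
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write sequences to a FASTA file (70-column wrap)
#' @param x named character vector of sequences.
#' @param path file path.
#' @param type "DNA" or "AA".
#' @export
write_fasta <- function(x, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::DNAStringSet(x)
         else Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
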