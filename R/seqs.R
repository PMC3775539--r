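# Nucleotide alphabet used throughout; anything else (N, IUPAC degenerate
# codes, gaps) is treated as missing and excluded from mutation calls.
DNA_BASES <- c("A", "C", "G", "T")

#' Convert sequences to an integer matrix
#'
#' Encodes equal-length nucleotide strings as an integer matrix with
#' A,C,G,T -> 1..4 and any other symbol -> `NA`. Row names are taken from
#' the input names. Used internally by all distance/tree routines.
#'
#' @param x named character vector of equal-length sequences, or an
#'   already-encoded integer matrix (returned unchanged).
#' @return integer matrix, one row per sequence.
#' @export
seq_to_int <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "integer"
    return(x)
  }
  if (length(x) == 0L) stop("no sequences given")
  L <- unique(nchar(x))
  if (length(L) != 1L) stop("sequences must all have the same length")
  chars <- unlist(strsplit(toupper(x), "", fixed = TRUE), use.names = FALSE)
  M <- matrix(match(chars, DNA_BASES), nrow = length(x), ncol = L, byrow = TRUE)
  rownames(M) <- names(x)
  M
}

#' Convert an integer matrix back to sequence strings
#'
#' Inverse of [seq_to_int()]; `NA` cells become `"N"`.
#'
#' @param M integer matrix with values in 1..4 or `NA`.
#' @return named character vector of sequences.
#' @export
int_to_seq <- function(M) {
  if (!is.matrix(M)) M <- matrix(M, nrow = 1)
  ch <- c(DNA_BASES, "N")[ifelse(is.na(M), 5L, M)]
  out <- apply(matrix(ch, nrow = nrow(M)), 1, paste0, collapse = "")
  names(out) <- rownames(M)
  out
}

#' Read a FASTA file into a named character vector
#'
#' Bases are normalised to upper case; record order is preserved.
#' Duplicate identifiers are an error (ids are the interchange keys between
#' FASTA, Newick and TSV outputs).
#'
#' @param path FASTA file path.
#' @return named character vector of sequences in file order.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- toupper(as.character(ss))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    cat(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
        sep = "\n", file = con)
  }
  invisible(path)
}

#' Classify a codon substitution as synonymous or non-synonymous
#'
#' A substitution is synonymous (S) when the two codons translate to the
#' same amino acid under the standard genetic code, and non-synonymous (NS)
#' otherwise; changes that create or destroy a stop codon are NS.
#' Classification is always relative to the direct ancestor's codon, not to
#' the germline or a consensus.
#'
#' @param from_codon,to_codon character vectors of 3-nt codons over ACGT.
#' @return character vector of `"S"`/`"NS"`; `NA` where a codon contains a
#'   base outside ACGT (unclassifiable; callers skip such events).
#' @export
classify_mutation <- function(from_codon, to_codon) {
  if (length(from_codon) != length(to_codon)) {
    stop("from_codon and to_codon must have the same length")
  }
  from_codon <- toupper(from_codon)
  to_codon <- toupper(to_codon)
  if (any(nchar(from_codon) != 3L) || any(nchar(to_codon) != 3L)) {
    stop("codons must be 3 nt long")
  }
  if (any(from_codon == to_codon)) {
    stop("codons must differ in at least one position")
  }
  gc <- Biostrings::GENETIC_CODE
  aa_from <- unname(gc[from_codon])
  aa_to <- unname(gc[to_codon])
  ifelse(is.na(aa_from) | is.na(aa_to), NA_character_,
         ifelse(aa_from == aa_to, "S", "NS"))
}
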