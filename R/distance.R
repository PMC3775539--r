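#' Pairwise Hamming distance matrix
#'
#' Counts, for every sequence pair, the positions at which both sequences
#' carry an unambiguous base (A/C/G/T) and the bases differ. Positions where
#' either sequence is N (or any other non-ACGT symbol) are skipped, so
#' degenerate bases never contribute mutations.
#'
#' @param sequences named character vector of equal-length sequences, or an
#'   integer matrix from [seq_to_int()].
#' @return symmetric numeric matrix of mismatch counts with zero diagonal
#'   and sequence ids as dimnames.
#' @export
hamming_matrix <- function(sequences) {
  M <- seq_to_int(sequences)
  if (nrow(M) < 2L) stop("need at least 2 sequences")
  valid <- !is.na(M)
  Mz <- M
  Mz[!valid] <- 0L
  matches <- matrix(0, nrow(M), nrow(M))
  for (b in 1:4) {
    Ib <- (Mz == b) + 0
    matches <- matches + tcrossprod(Ib)
  }
  d <- tcrossprod(valid + 0) - matches
  diag(d) <- 0
  dimnames(d) <- list(rownames(M), rownames(M))
  d
}
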