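#' Partition a clone-group tree into clones by an edge mutation cutoff
#'
#' Sequences with the same V, J and junction length may still derive from
#' independent rearrangement events; within a group, clones are separated
#' by cutting every tree edge carrying more than `cutoff` nucleotide
#' differences between the sequences at its two endpoints (reconstructed
#' ancestors included). Each connected component of the remaining forest
#' defines one clone; its members are the reads behind the component's
#' leaves. Singleton clones are allowed. The component containing the
#' germline root is a clone like any other (its sampled leaves, not the
#' root itself).
#'
#' @param tree a `lineage_tree` for the whole group, after
#'   [fitch_reconstruct()] so every node has a sequence.
#' @param cutoff maximum within-clone edge mutation count (default 4).
#' @return list of character vectors of read ids, largest clone first.
#' @export
partition_into_clones <- function(tree, cutoff = 4L) {
  if (is.null(tree$seqmat)) stop("tree carries no sequences")
  if (anyNA(tree$seqmat[!is_leaf(tree), , drop = FALSE])) {
    stop("internal sequences missing: run fitch_reconstruct() first")
  }
  np <- length(tree$parent)
  comp <- seq_len(np)
  find <- function(x) {
    while (comp[x] != x) {
      comp[x] <<- comp[comp[x]]
      x <- comp[x]
    }
    x
  }
  S <- tree$seqmat
  for (v in seq_len(np)) {
    p <- tree$parent[v]
    if (is.na(p)) next
    diffs <- sum(!is.na(S[v, ]) & !is.na(S[p, ]) & S[v, ] != S[p, ])
    if (diffs <= cutoff) {
      comp[find(v)] <- find(p)
    }
  }
  roots <- vapply(seq_len(np), find, integer(1))
  leaf <- is_leaf(tree)
  clones <- split(which(leaf), roots[leaf])
  members <- lapply(clones, function(idx) {
    unlist(lapply(idx, function(v) {
      if (!is.null(tree$members) && !is.null(tree$members[[v]])) {
        tree$members[[v]]
      } else tree$label[v]
    }), use.names = FALSE)
  })
  members <- unname(members)
  members[order(-lengths(members))]
}
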