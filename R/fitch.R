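# Fitch small parsimony on a rooted binary lineage tree.
#
# States are held as 4-bit masks (A=1, C=2, G=4, T=8); an N/unknown leaf
# position is the full set 15 and therefore never forces a substitution.
# On binary trees the Fitch bottom-up sets coincide with Hartigan's exact
# minimising sets, so the top-down pass below attains the parsimony
# minimum — including when the root state is pinned to a known germline:
# picking a set member costs at most as much as any state outside the set.

BIT_OF_BASE <- c(1L, 2L, 4L, 8L)
LOW_BASE <- integer(15L)  # lowest set bit -> base index (A<C<G<T order)
for (.b in 4:1) LOW_BASE[bitwAnd(1:15, BIT_OF_BASE[.b]) > 0L] <- .b
rm(.b)

#' Reconstruct internal-node sequences by Fitch parsimony
#'
#' Bottom-up set union/intersection per site, then a top-down refinement
#' that prefers the parent's state whenever it is attainable (deterministic
#' ties: A < C < G < T). If the tree was rooted at a germline (see
#' [root_at_germline()]), the root keeps its germline sequence at every
#' position where that sequence is unambiguous; positions where the
#' germline is N (e.g. the unknowable V-J junction) are reconstructed
#' freely. The parsimony score is the total number of parent/child
#' mismatches over all edges, counted only at positions where both states
#' are unambiguous.
#'
#' @param tree a `lineage_tree` whose leaves all carry sequences.
#' @return the tree with all internal sequences filled in and a
#'   `parsimony_score` element added.
#' @export
fitch_reconstruct <- function(tree) {
  if (is.null(tree$seqmat)) stop("tree carries no sequences")
  S <- tree$seqmat
  np <- nrow(S)
  L <- ncol(S)
  leaf <- is_leaf(tree)
  if (any(leaf & apply(is.na(S), 1, all))) {
    # leaves must be observed; all-NA rows mean a missing sequence
    bad <- which(leaf)[apply(is.na(S[leaf, , drop = FALSE]), 1, all)]
    stop("leaf without sequence: ", paste(tree$label[bad], collapse = ", "))
  }

  B <- matrix(15L, np, L)
  obs <- !is.na(S)
  B[obs] <- BIT_OF_BASE[S[obs]]

  post <- postorder_nodes(tree)
  for (v in post) {
    kids <- tree$children[[v]]
    if (length(kids) == 0L) next
    bv <- B[kids[1], ]
    if (length(kids) > 1L) {
      for (k in kids[-1]) {
        inter <- bitwAnd(bv, B[k, ])
        un <- bitwOr(bv, B[k, ])
        bv <- ifelse(inter > 0L, inter, un)
      }
    }
    B[v, ] <- bv
  }

  # top-down refinement
  A <- S  # final assignment (base indices)
  r <- tree$root
  root_state <- BIT_OF_BASE[LOW_BASE[B[r, ]]]
  if (tree$root_fixed) {
    known <- !is.na(S[r, ])
    root_state[known] <- BIT_OF_BASE[S[r, known]]
  }
  state_bits <- matrix(0L, np, L)
  state_bits[r, ] <- root_state
  A[r, ] <- LOW_BASE[root_state]
  for (v in rev(post)) {           # preorder
    kids <- tree$children[[v]]
    pv <- state_bits[v, ]
    for (k in kids) {
      if (leaf[k]) {
        kb <- B[k, ]
        kb[!obs[k, ]] <- 0L        # leave leaf Ns unknown
        state_bits[k, ] <- ifelse(kb > 0L, kb, pv)
        next
      }
      hit <- bitwAnd(pv, B[k, ])
      sb <- ifelse(hit > 0L, pv, BIT_OF_BASE[LOW_BASE[B[k, ]]])
      state_bits[k, ] <- sb
      A[k, ] <- LOW_BASE[sb]
    }
  }

  score <- 0L
  for (v in seq_len(np)) {
    p <- tree$parent[v]
    if (is.na(p)) next
    cmp <- !is.na(A[v, ]) & !is.na(A[p, ]) & A[v, ] != A[p, ]
    score <- score + sum(cmp)
  }

  tree$seqmat <- A
  tree$parsimony_score <- as.integer(score)
  tree
}
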