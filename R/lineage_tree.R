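# Rooted lineage tree container.
#
# A lineage_tree is a list with parallel per-node vectors:
#   parent       integer, NA at the root
#   children     list of integer vectors
#   label        character node labels (unique)
#   edge_length  numeric length of the edge to the parent (NA at the root)
#   multiplicity integer; for leaves, the number of sampled reads collapsed
#                into that leaf (identical sequences are collapsed before
#                tree building and expanded again through leaf counts)
#   leaf_count   integer; leaves: multiplicity, internal: sum over children
#   seqmat       integer matrix (nodes x sites) of sequences, NA = unknown
#   members      optional list of read ids behind each leaf
#   root         integer index of the root
# The root represents the germline/founder ancestor: it is not a sampled
# leaf and never contributes to leaf counts.

new_lineage_tree <- function(parent, children, label, edge_length,
                             multiplicity, seqmat, root, members = NULL,
                             root_fixed = FALSE) {
  tr <- list(parent = as.integer(parent), children = children,
             label = label, edge_length = edge_length,
             multiplicity = as.integer(multiplicity),
             leaf_count = integer(length(parent)),
             seqmat = seqmat, members = members,
             root = as.integer(root), root_fixed = isTRUE(root_fixed))
  class(tr) <- "lineage_tree"
  recount_leaves(tr)
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("lineage_tree:", sum(is_leaf(x)), "leaves (",
      x$leaf_count[x$root], "reads ),",
      length(x$parent) - sum(is_leaf(x)), "internal nodes,",
      if (is.null(x$seqmat)) "no sequences" else
        paste0(ncol(x$seqmat), "-nt sequences"), "\n")
  invisible(x)
}

is_leaf <- function(tree) lengths(tree$children) == 0L

# depth-first postorder (children before parents)
postorder_nodes <- function(tree) {
  n <- length(tree$parent)
  out <- integer(n)
  stack <- tree$root
  k <- n
  # reverse preorder == postorder for our purposes (parents after children
  # when read back to front)
  i <- 0L
  pre <- integer(n)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    i <- i + 1L
    pre[i] <- v
    stack <- c(stack, tree$children[[v]])
  }
  rev(pre[seq_len(i)])
}

recount_leaves <- function(tree) {
  lc <- integer(length(tree$parent))
  for (v in postorder_nodes(tree)) {
    kids <- tree$children[[v]]
    lc[v] <- if (length(kids) == 0L) max(tree$multiplicity[v], 1L)
             else sum(lc[kids])
  }
  tree$leaf_count <- lc
  tree
}

#' Root an unrooted tree at its germline leaf
#'
#' The tree (typically from [neighbor_joining()] over the clone members plus
#' the artificial germline reference) is rooted on the node adjacent to the
#' germline leaf, and the germline leaf itself is removed: the germline is
#' the known ancestor, not a sampled sequence, so it must not contribute to
#' leaf counts. The root's sequence is initialised to the germline sequence,
#' which later pins the ancestral state during parsimony reconstruction.
#'
#' @param phy unrooted `phylo` tree whose tips include `germline_id`.
#' @param germline_id tip label of the germline reference.
#' @param sequences named character vector with one equal-length sequence
#'   per tip, including the germline.
#' @param multiplicity optional named integer vector of read counts per tip
#'   (defaults to 1 each); used when identical reads were collapsed.
#' @param members optional named list mapping tip labels to read ids.
#' @return a `lineage_tree` whose root carries the germline sequence.
#' @export
root_at_germline <- function(phy, germline_id, sequences,
                             multiplicity = NULL, members = NULL) {
  tips <- phy$tip.label
  g <- match(germline_id, tips)
  if (is.na(g)) stop("germline id '", germline_id, "' is not a tip of the tree")
  if (!all(tips %in% names(sequences))) {
    stop("missing sequences for tips: ",
         paste(setdiff(tips, names(sequences)), collapse = ", "))
  }
  n <- length(tips)
  # undirected adjacency from the edge matrix
  E <- phy$edge
  el <- if (is.null(phy$edge.length)) rep(NA_real_, nrow(E)) else phy$edge.length
  nn <- n + phy$Nnode
  adj <- vector("list", nn)
  alen <- vector("list", nn)
  for (k in seq_len(nrow(E))) {
    a <- E[k, 1]; b <- E[k, 2]
    adj[[a]] <- c(adj[[a]], b); alen[[a]] <- c(alen[[a]], el[k])
    adj[[b]] <- c(adj[[b]], a); alen[[b]] <- c(alen[[b]], el[k])
  }
  root_old <- adj[[g]][1]  # germline leaf has exactly one neighbour
  if (length(adj[[g]]) != 1L) stop("germline id must be a leaf")

  # orient away from root_old, skipping the germline leaf
  keep_old <- setdiff(seq_len(nn), g)
  new_id <- integer(nn)
  new_id[keep_old] <- seq_along(keep_old)
  np <- length(keep_old)
  parent <- rep(NA_integer_, np)
  elen_new <- rep(NA_real_, np)
  children <- vector("list", np)
  visited <- logical(nn)
  visited[g] <- TRUE
  stack <- root_old
  visited[root_old] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- adj[[v]]
    ln <- alen[[v]]
    for (q in seq_along(nb)) {
      w <- nb[q]
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[new_id[w]] <- new_id[v]
        elen_new[new_id[w]] <- ln[q]
        children[[new_id[v]]] <- c(children[[new_id[v]]], new_id[w])
        stack <- c(stack, w)
      }
    }
  }

  node_label <- character(np)
  old_is_tip <- keep_old <= n
  node_label[new_id[keep_old[old_is_tip]]] <- tips[keep_old[old_is_tip]]
  int_old <- keep_old[!old_is_tip]
  if (!is.null(phy$node.label) && length(phy$node.label) == phy$Nnode) {
    node_label[new_id[int_old]] <- phy$node.label[int_old - n]
  }
  blank <- !nzchar(node_label)
  node_label[blank] <- paste0("anc", seq_len(sum(blank)))
  if (anyDuplicated(node_label)) {
    node_label[blank] <- paste0("anc", seq_len(sum(blank)), "_x")
  }

  L <- unique(nchar(sequences[tips]))
  if (length(L) != 1L) stop("tip sequences must all have the same length")
  seqmat <- matrix(NA_integer_, np, L)
  tip_rows <- new_id[keep_old[old_is_tip]]
  seqmat[tip_rows, ] <- seq_to_int(unname(sequences[tips[keep_old[old_is_tip]]]))
  # the root inherits the germline sequence: it is the known ancestor
  seqmat[new_id[root_old], ] <- seq_to_int(unname(sequences[germline_id]))

  mult <- rep(1L, np)
  if (!is.null(multiplicity)) {
    mm <- multiplicity[tips[keep_old[old_is_tip]]]
    mm[is.na(mm)] <- 1L
    mult[tip_rows] <- as.integer(mm)
  }
  mem <- NULL
  if (!is.null(members)) {
    mem <- vector("list", np)
    mem[tip_rows] <- members[tips[keep_old[old_is_tip]]]
  }

  new_lineage_tree(parent, children, node_label, elen_new, mult, seqmat,
                   root = new_id[root_old], members = mem, root_fixed = TRUE)
}

#' Build a lineage tree directly from a rooted `phylo` object
#'
#' Polytomies are resolved into arbitrary binary subtrees with zero-length
#' edges (via `ape::multi2di`), because mutation events are defined on
#' two-branch comparisons. The root keeps whatever sequence is supplied for
#' its label (if any); otherwise its state is reconstructed freely.
#'
#' @param phy rooted `phylo`, possibly with `node.label`.
#' @param sequences named character vector of sequences for (at least) all
#'   tips; internal labels present here are attached too.
#' @param multiplicity optional named integer vector of per-tip read counts.
#' @return a `lineage_tree`.
#' @export
lineage_tree_from_phylo <- function(phy, sequences = NULL, multiplicity = NULL) {
  if (!ape::is.binary(phy)) phy <- ape::multi2di(phy, random = FALSE)
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  n <- length(phy$tip.label)
  np <- n + phy$Nnode
  parent <- rep(NA_integer_, np)
  children <- vector("list", np)
  elen <- rep(NA_real_, np)
  el <- if (is.null(phy$edge.length)) rep(NA_real_, nrow(phy$edge)) else phy$edge.length
  for (k in seq_len(nrow(phy$edge))) {
    a <- phy$edge[k, 1]; b <- phy$edge[k, 2]
    parent[b] <- a
    elen[b] <- el[k]
    children[[a]] <- c(children[[a]], b)
  }
  label <- character(np)
  label[seq_len(n)] <- phy$tip.label
  if (!is.null(phy$node.label) && length(phy$node.label) == phy$Nnode) {
    label[n + seq_len(phy$Nnode)] <- phy$node.label
  }
  blank <- !nzchar(label)
  label[blank] <- paste0("anc", seq_len(sum(blank)))

  seqmat <- NULL
  root_fixed <- FALSE
  if (!is.null(sequences)) {
    miss <- setdiff(phy$tip.label, names(sequences))
    if (length(miss)) stop("missing sequences for tips: ",
                           paste(miss, collapse = ", "))
    L <- unique(nchar(sequences))
    if (length(L) != 1L) stop("sequences must all have the same length")
    seqmat <- matrix(NA_integer_, np, L)
    have <- label %in% names(sequences)
    seqmat[have, ] <- seq_to_int(unname(sequences[label[have]]))
    root_fixed <- label[n + 1L] %in% names(sequences)
  }
  mult <- rep(1L, np)
  if (!is.null(multiplicity)) {
    mm <- multiplicity[label[seq_len(n)]]
    mm[is.na(mm)] <- 1L
    mult[seq_len(n)] <- as.integer(mm)
  }
  new_lineage_tree(parent, children, label, elen, mult, seqmat,
                   root = n + 1L, root_fixed = root_fixed)
}

#' Convert a lineage tree to an ape `phylo` object
#'
#' Internal node labels carry the reconstructed-sequence ids, so a Newick
#' file plus a companion FASTA of node sequences round-trips the tree.
#'
#' @param tree a `lineage_tree`.
#' @return a rooted `phylo`.
#' @export
lineage_tree_to_phylo <- function(tree) {
  leaf <- is_leaf(tree)
  n <- sum(leaf)
  np <- length(tree$parent)
  # phylo numbering: tips 1..n in our node order, root = n+1, then others
  ph_id <- integer(np)
  ph_id[leaf] <- seq_len(n)
  internal <- which(!leaf)
  internal <- c(tree$root, setdiff(internal, tree$root))
  ph_id[internal] <- n + seq_along(internal)
  kids_edges <- which(!is.na(tree$parent))
  edge <- cbind(ph_id[tree$parent[kids_edges]], ph_id[kids_edges])
  storage.mode(edge) <- "integer"
  elen <- tree$edge_length[kids_edges]
  tl <- character(n); tl[ph_id[leaf]] <- tree$label[leaf]
  nl <- character(length(internal)); nl[ph_id[internal] - n] <- tree$label[internal]
  phy <- list(edge = edge, tip.label = tl, node.label = nl,
              Nnode = length(internal))
  if (!all(is.na(elen))) phy$edge.length <- ifelse(is.na(elen), 0, elen)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Extract node sequences as character strings
#'
#' @param tree a `lineage_tree` with sequences.
#' @return named character vector (names = node labels); unknown positions
#'   appear as `"N"`.
#' @export
node_sequences <- function(tree) {
  if (is.null(tree$seqmat)) stop("tree carries no sequences")
  out <- int_to_seq(tree$seqmat)
  names(out) <- tree$label
  out
}

#' Write a lineage tree as Newick plus a node-sequence FASTA
#'
#' @param tree a `lineage_tree`.
#' @param newick_path output Newick path.
#' @param fasta_path optional output FASTA path for all node sequences.
#' @return `newick_path`, invisibly.
#' @export
write_lineage_tree <- function(tree, newick_path, fasta_path = NULL) {
  phy <- lineage_tree_to_phylo(tree)
  ape::write.tree(phy, file = newick_path)
  if (!is.null(fasta_path)) write_fasta(node_sequences(tree), fasta_path)
  invisible(newick_path)
}

#' Read a lineage tree from Newick plus a sequence FASTA
#'
#' The Newick tree must be rooted; polytomies are resolved into zero-length
#' binary splits. Sequences are matched to nodes by label; internal labels
#' found in the FASTA are attached as reconstructed sequences.
#'
#' @param newick_path Newick file.
#' @param fasta_path FASTA of leaf (and optionally internal-node) sequences.
#' @param multiplicity optional named integer vector of per-leaf read counts.
#' @return a `lineage_tree`.
#' @export
read_lineage_tree <- function(newick_path, fasta_path, multiplicity = NULL) {
  phy <- ape::read.tree(newick_path)
  seqs <- read_fasta(fasta_path)
  lineage_tree_from_phylo(phy, seqs, multiplicity)
}

#' Collapse identical sequences before tree building
#'
#' Identical reads are collapsed into one representative so the distance
#' matrix and tree stay small; the read count is preserved as the leaf
#' multiplicity, and leaf counts (hence LONR) are computed over reads, not
#' unique sequences.
#'
#' @param seqs named character vector of reads.
#' @return list with `sequences` (unique, named by representative id),
#'   `multiplicity` (named integer), `members` (named list of read ids).
#' @export
collapse_duplicates <- function(seqs) {
  grp <- match(seqs, unique(seqs))
  reps <- !duplicated(grp)
  uniq <- seqs[reps]
  mult <- as.integer(tabulate(grp))
  names(mult) <- names(uniq)
  members <- split(names(seqs), grp)
  names(members) <- names(uniq)
  list(sequences = uniq, multiplicity = mult, members = members)
}
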