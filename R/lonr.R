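#' Map a nucleotide position to its region label
#'
#' Regions are half-open, 0-based intervals `[start, end)` over the
#' analysis frame (e.g. CDR2/FWR3/CDR3 over the truncated read, or the two
#' mutation-rate regions of the simulator). Positions covered by no
#' interval are labelled `"other"`.
#'
#' @param position integer vector of 0-based positions.
#' @param region_map data frame with columns `region`, `start`, `end`
#'   (non-overlapping, half-open, 0-based).
#' @return character vector of region labels.
#' @export
map_position_to_region <- function(position, region_map) {
  out <- rep("other", length(position))
  if (is.null(region_map) || nrow(region_map) == 0L) return(out)
  for (i in seq_len(nrow(region_map))) {
    hit <- position >= region_map$start[i] & position < region_map$end[i]
    out[hit] <- region_map$region[i]
  }
  out
}

#' Construct a region map
#'
#' @param region character labels.
#' @param start,end 0-based half-open interval bounds.
#' @return validated region-map data frame.
#' @export
region_map <- function(region, start, end) {
  rm <- data.frame(region = as.character(region), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (any(rm$end <= rm$start)) stop("empty or reversed region interval")
  o <- order(rm$start)
  if (any(rm$end[o][-nrow(rm)] > rm$start[o][-1])) {
    stop("region intervals must not overlap")
  }
  rm
}

empty_events <- function() {
  data.frame(
    clone_id = character(), node_id = character(), position = integer(),
    from_base = character(), to_base = character(), from_codon = character(),
    to_codon = character(), mutation_class = character(), region = character(),
    n_mut = integer(), n_sib = integer(), lonr = numeric(),
    stringsAsFactors = FALSE)
}

#' Enumerate mutation events and their LONR values on a lineage tree
#'
#' Walks every internal node (including the germline root) of a
#' reconstructed tree. At each node, a position where exactly one of the
#' two children differs from the node's own sequence is a mutation event on
#' the branch to that child; the event's LONR is
#' `ln(leaf_count(mutated child) / leaf_count(unmutated sibling))`, leaf
#' counts being sampled reads (duplicates expanded). Positions where both
#' children changed have no unmutated sibling and yield no event. Each
#' substitution is classified S/NS by substituting that single position
#' into the ancestral codon (`floor(position/3)` frame); events whose
#' ancestral or derived codon contains an unknown base are skipped and
#' counted in the `skipped_n_codon` attribute.
#'
#' @param tree a `lineage_tree` after [fitch_reconstruct()].
#' @param region_map optional region map (see [region_map()]).
#' @param clone_id label recorded in the output.
#' @return data frame with one row per mutation event: `clone_id`,
#'   `node_id` (mutated child), `position` (0-based), `from_base`,
#'   `to_base`, `from_codon`, `to_codon`, `mutation_class`, `region`,
#'   `n_mut`, `n_sib`, `lonr`.
#' @export
enumerate_mutation_events <- function(tree, region_map = NULL,
                                      clone_id = "clone") {
  if (is.null(tree$seqmat)) stop("tree carries no sequences")
  S <- tree$seqmat
  L <- ncol(S)
  lc <- tree$leaf_count
  acc_pos <- list(); acc_cs <- list(); acc_child <- list()
  acc_nmut <- list(); acc_nsib <- list()
  ai <- 0L
  skipped_pre <- 0L
  internal <- which(!is_leaf(tree))
  for (v in internal) {
    kids <- tree$children[[v]]
    if (length(kids) != 2L) next   # unary root after tiny clones: no sibling
    p <- S[v, ]
    for (q in 1:2) {
      ch <- kids[q]; sib <- kids[3 - q]
      dd <- which(!is.na(p) & !is.na(S[ch, ]) & S[ch, ] != p)
      if (!length(dd)) next
      # drop positions where the sibling also changed: no unmutated branch
      sib_changed <- !is.na(S[sib, dd]) & S[sib, dd] != p[dd]
      dd <- dd[!sib_changed]
      if (!length(dd)) next
      cs <- ((dd - 1L) %/% 3L) * 3L + 1L
      ok <- cs + 2L <= L
      skipped_pre <- skipped_pre + sum(!ok)
      dd <- dd[ok]; cs <- cs[ok]
      if (!length(dd)) next
      ai <- ai + 1L
      acc_pos[[ai]] <- dd; acc_cs[[ai]] <- cs
      acc_child[[ai]] <- rep.int(ch, length(dd))
      acc_nmut[[ai]] <- rep.int(lc[ch], length(dd))
      acc_nsib[[ai]] <- rep.int(lc[sib], length(dd))
    }
  }
  if (ai == 0L) {
    out <- empty_events()
    attr(out, "skipped_n_codon") <- skipped_pre
    return(out)
  }
  dd <- unlist(acc_pos); cs <- unlist(acc_cs); ch <- unlist(acc_child)
  n_mut <- unlist(acc_nmut); n_sib <- unlist(acc_nsib)
  parent_of <- tree$parent[ch]
  c1 <- S[cbind(parent_of, cs)]
  c2 <- S[cbind(parent_of, cs + 1L)]
  c3 <- S[cbind(parent_of, cs + 2L)]
  codon_ok <- !is.na(c1) & !is.na(c2) & !is.na(c3)
  skipped <- skipped_pre + sum(!codon_ok)
  dd <- dd[codon_ok]; cs <- cs[codon_ok]; ch <- ch[codon_ok]
  n_mut <- n_mut[codon_ok]; n_sib <- n_sib[codon_ok]
  c1 <- c1[codon_ok]; c2 <- c2[codon_ok]; c3 <- c3[codon_ok]
  parent_of <- parent_of[codon_ok]
  if (!length(dd)) {
    out <- empty_events()
    attr(out, "skipped_n_codon") <- skipped
    return(out)
  }
  from_codon <- paste0(DNA_BASES[c1], DNA_BASES[c2], DNA_BASES[c3])
  to_codon <- from_codon
  off <- dd - cs  # 0,1,2 within codon
  to_base_int <- S[cbind(ch, dd)]
  substr(to_codon, off + 1L, off + 1L) <- DNA_BASES[to_base_int]
  out <- data.frame(
    clone_id = clone_id,
    node_id = tree$label[ch],
    position = dd - 1L,
    from_base = DNA_BASES[S[cbind(parent_of, dd)]],
    to_base = DNA_BASES[to_base_int],
    from_codon = from_codon,
    to_codon = to_codon,
    mutation_class = classify_mutation(from_codon, to_codon),
    region = map_position_to_region(dd - 1L, region_map),
    n_mut = n_mut,
    n_sib = n_sib,
    lonr = log(n_mut / n_sib),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped_n_codon") <- skipped
  out
}
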