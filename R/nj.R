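#' Neighbor-joining tree from a distance matrix
#'
#' Internal implementation of the Saitou-Nei agglomeration: at each step the
#' pair minimising Q(i,j) = (m-2) d(i,j) - r(i) - r(j) is joined, branch
#' lengths are assigned by the usual three-point formulae, and the matrix is
#' reduced in place. Negative branch lengths are clamped to zero with the
#' deficit shifted onto the sibling branch, so path lengths through the
#' joined pair are preserved. Ties in Q are broken by column-major scan
#' order, which makes the result deterministic for a given input ordering.
#'
#' @param d symmetric distance matrix with row/col names (e.g. from
#'   [hamming_matrix()]).
#' @return an unrooted `phylo` tree (class from the ape package). With two
#'   taxa the single edge is split evenly across a central node.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  tips <- rownames(d)

  if (n == 2L) {
    phy <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                edge.length = rep(d[1, 2] / 2, 2),
                tip.label = tips, Nnode = 1L)
    class(phy) <- "phylo"
    return(phy)
  }

  # D's leading m x m block holds the active clusters; `ids` maps block
  # slots to final phylo node ids (tips 1..n, internal n+1, n+2, ...,
  # renumbered at the end so the closing trifurcation becomes node n+1).
  D <- unname(d)
  ids <- seq_len(n)
  m <- n
  next_id <- n + 1L
  n_edges <- 2L * n - 3L
  epar <- integer(n_edges); echi <- integer(n_edges); elen <- numeric(n_edges)
  ne <- 0L

  while (m > 3L) {
    blk <- seq_len(m)
    Dm <- D[blk, blk]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    k <- which.min(Q)
    i <- (k - 1L) %% m + 1L
    j <- (k - 1L) %/% m + 1L
    dij <- Dm[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    u <- next_id; next_id <- next_id + 1L
    epar[ne + 1L] <- u; echi[ne + 1L] <- ids[i]; elen[ne + 1L] <- li
    epar[ne + 2L] <- u; echi[ne + 2L] <- ids[j]; elen[ne + 2L] <- lj
    ne <- ne + 2L
    du <- (Dm[i, ] + Dm[j, ] - dij) / 2
    du[i] <- 0
    # new cluster takes slot i; last active slot moves into slot j
    D[blk, i] <- du; D[i, blk] <- du
    ids[i] <- u
    if (j != m) {
      D[blk, j] <- D[blk, m]; D[j, blk] <- D[m, blk]
      D[j, j] <- 0
      ids[j] <- ids[m]
    }
    m <- m - 1L
  }

  # final trifurcation (or the 3-taxon base case)
  u <- next_id
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  lf <- c(l1, l2, l3)
  for (q in 1:3) {
    ne <- ne + 1L
    epar[ne] <- u; echi[ne] <- ids[q]; elen[ne] <- max(lf[q], 0)
  }

  # renumber internal nodes so the final join is n+1 (ape root convention)
  remap <- function(x) ifelse(x > n, n + 1L + (u - x), x)
  edge <- cbind(remap(epar[seq_len(ne)]), remap(echi[seq_len(ne)]))
  storage.mode(edge) <- "integer"
  phy <- list(edge = edge, edge.length = elen[seq_len(ne)],
              tip.label = tips, Nnode = u - n)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}
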