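test_that("hamming distances skip degenerate positions", {
  expect_equal(hamming_matrix(c(a = "ACGT", b = "ACGT"))[1, 2], 0)
  expect_equal(hamming_matrix(c(a = "ACGT", b = "ACGA"))[1, 2], 1)
  expect_equal(hamming_matrix(c(a = "ACNT", b = "ACGA"))[1, 2], 1)
  expect_error(hamming_matrix(c(a = "ACGT")), "at least 2")
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  d <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  phy <- neighbor_joining(d)
  # l_a = (d_ab + d_ac - d_bc)/2 etc.
  lens <- setNames(phy$edge.length, phy$tip.label[phy$edge[, 2]])
  expect_equal(unname(lens[c("a", "b", "c")]), c(3, 2, 6))
})

test_that("NJ recovers the best 4-taxon topology (least-squares oracle)", {
  # additive matrix from ((a,b),(c,d)) with all branch lengths 1
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  d <- ape::cophenetic.phylo(tr)
  d <- d[c("a", "b", "c", "d"), c("a", "b", "c", "d")]
  # oracle: least-squares fit of each of the 3 unrooted quartet topologies
  quartets <- list(c("a", "b", "c", "d"), c("a", "c", "b", "d"),
                   c("a", "d", "b", "c"))
  rss <- vapply(quartets, function(q) {
    # topology ((q1,q2),(q3,q4)): 5 branches, design matrix over 6 pairs
    pairs <- t(combn(q, 2))
    X <- matrix(0, 6, 5)
    for (r in 1:6) {
      i <- match(pairs[r, 1], q); j <- match(pairs[r, 2], q)
      X[r, i] <- 1; X[r, j] <- 1
      if ((i <= 2) != (j <= 2)) X[r, 5] <- 1
    }
    y <- d[cbind(pairs[, 1], pairs[, 2])]
    sum(stats::lm.fit(X, y)$residuals^2)
  }, 0)
  best <- quartets[[which.min(rss)]]
  phy <- neighbor_joining(d)
  split_of <- function(p, pair) {
    as.numeric(ape::dist.topo(ape::unroot(p), ape::unroot(ape::read.tree(
      text = sprintf("((%s,%s),(%s,%s));",
                     pair[1], pair[2], pair[3], pair[4])))))
  }
  expect_equal(split_of(phy, best), 0)
  # exact branch lengths on additive input: patristic distances match
  expect_equal(ape::cophenetic.phylo(phy)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
})

test_that("NJ reconstructs random additive trees up to 8 leaves exactly", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    d <- ape::cophenetic.phylo(tr)
    phy <- neighbor_joining(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(phy))), 0)
    expect_equal(ape::cophenetic.phylo(phy)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
    # independent implementation agrees on the topology
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ape::nj(d)),
                                       ape::unroot(phy))), 0)
  }
})

test_that("all-zero distances give a tree with zero branch lengths", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  phy <- neighbor_joining(d)
  expect_true(all(phy$edge.length == 0))
  expect_identical(sort(phy$tip.label), letters[1:4])
})

test_that("rooting at the germline drops it from leaf counts", {
  seqs <- c(s1 = "AAAA", s2 = "AAAT", s3 = "AATT", GL = "AAAA")
  phy <- neighbor_joining(hamming_matrix(seqs))
  tr <- root_at_germline(phy, "GL", seqs)
  expect_s3_class(tr, "lineage_tree")
  expect_identical(tr$leaf_count[tr$root], 3L)
  expect_false("GL" %in% tr$label)
  # root carries the germline sequence
  expect_identical(int_to_seq(tr$seqmat[tr$root, , drop = FALSE])[[1]], "AAAA")
  # leaf_count sum rule at every internal node
  for (v in which(lengths(tr$children) > 0)) {
    expect_identical(tr$leaf_count[v], sum(tr$leaf_count[tr$children[[v]]]))
  }
  expect_error(root_at_germline(phy, "nope", seqs), "not a tip")
})

test_that("a germline identical to a sampled read keeps that read as a leaf", {
  seqs <- c(s1 = "AAAA", s2 = "TTAA", GL = "AAAA")
  phy <- neighbor_joining(hamming_matrix(seqs))
  tr <- root_at_germline(phy, "GL", seqs)
  expect_setequal(tr$label[lengths(tr$children) == 0], c("s1", "s2"))
  expect_identical(tr$leaf_count[tr$root], 2L)
})

test_that("duplicate collapsing preserves read counts through leaf counts", {
  seqs <- c(a = "AAAA", b = "AAAA", c = "AATT", d = "AAAA")
  cd <- collapse_duplicates(seqs)
  expect_identical(unname(cd$multiplicity), c(3L, 1L))
  expect_setequal(cd$members[["a"]], c("a", "b", "d"))
  all_seqs <- c(cd$sequences, GL = "AAAA")
  tr <- root_at_germline(neighbor_joining(hamming_matrix(all_seqs)),
                         "GL", all_seqs, multiplicity = cd$multiplicity)
  expect_identical(tr$leaf_count[tr$root], 4L)
})

test_that("Newick + FASTA round trip preserves topology and sequences", {
  set.seed(21)
  seqs <- c(s1 = "ACGTAC", s2 = "ACGTAA", s3 = "ACCTAA", s4 = "TCGTAC",
            GL = "ACGTAC")
  phy <- neighbor_joining(hamming_matrix(seqs))
  tr <- fitch_reconstruct(root_at_germline(phy, "GL", seqs))
  nwk <- withr::local_tempfile(fileext = ".nwk")
  fas <- withr::local_tempfile(fileext = ".fasta")
  write_lineage_tree(tr, nwk, fas)
  tr2 <- read_lineage_tree(nwk, fas)
  expect_setequal(tr2$label, tr$label)
  ns1 <- node_sequences(tr); ns2 <- node_sequences(tr2)
  expect_identical(ns2[sort(names(ns1))], ns1[sort(names(ns1))])
  p1 <- lineage_tree_to_phylo(tr)
  p2 <- lineage_tree_to_phylo(tr2)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(p1), ape::unroot(p2))), 0)
  # branch lengths survive within float-print precision
  d1 <- ape::cophenetic.phylo(p1); d2 <- ape::cophenetic.phylo(p2)
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-6)
})

test_that("polytomies are resolved into zero-length binary splits", {
  phy <- ape::read.tree(text = "(a:1,b:1,c:1,d:1)r;")
  seqs <- c(a = "AAA", b = "AAT", c = "ATT", d = "TTT", r = "AAA")
  tr <- lineage_tree_from_phylo(phy, seqs)
  expect_true(all(lengths(tr$children) %in% c(0L, 2L)))
  expect_identical(tr$leaf_count[tr$root], 4L)
})
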