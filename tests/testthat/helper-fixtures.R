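# Fixtures are generated in code: a small synthetic germline library and
# read builders emulating V + junction + J rearrangements.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# V genes are exactly 159 nt (the truncation window), so the whole gene is
# the analysis tail and match fractions have denominator 159.
make_library <- function(n_v = 3, n_j = 2, seed = 42) {
  set.seed(seed)
  lib <- list()
  for (i in seq_len(n_v)) {
    lib[[length(lib) + 1L]] <- germline_gene(
      paste0("V", i), "V", rand_seq(159),
      regions = data.frame(region = c("CDR2", "FWR3"),
                           start = c(60L, 84L), end = c(84L, 159L)))
  }
  for (i in seq_len(n_j)) {
    lib[[length(lib) + 1L]] <- germline_gene(paste0("J", i), "J", rand_seq(30))
  }
  lib
}

lib_gene <- function(lib, name) {
  lib[[which(vapply(lib, `[[`, "", "name") == name)]]
}

# read = full V + vjd junction nt + full J, with optional substitutions
# given as list(pos = 0-based read position, base = new base)
make_read <- function(lib, v = "V1", j = "J1", vjd = 6, subs = list()) {
  vs <- lib_gene(lib, v)$sequence
  js <- lib_gene(lib, j)$sequence
  read <- paste0(vs, rand_seq(vjd), js)
  for (s in subs) {
    substr(read, s$pos + 1L, s$pos + 1L) <- s$base
  }
  read
}

# substitute position `pos` (0-based) to a different base deterministically
mutate_base <- function(seq, pos) {
  old <- substr(seq, pos + 1L, pos + 1L)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(seq, pos + 1L, pos + 1L) <- new
  seq
}

# random rooted binary lineage tree with random leaf sequences, for
# parsimony property tests; root sequence optionally pinned
random_fitch_tree <- function(n_leaves, n_sites, root_fixed = TRUE) {
  phy <- ape::rtree(n_leaves)
  labs <- c(phy$tip.label, if (root_fixed) "rootseq")
  seqs <- vapply(labs, function(x) rand_seq(n_sites), "")
  names(seqs) <- labs
  if (root_fixed) {
    phy$node.label <- c("rootseq", paste0("i", seq_len(phy$Nnode - 1L)))
  }
  lineage_tree_from_phylo(phy, seqs)
}

# exhaustive small-parsimony oracle: per site, enumerate every assignment
# of the internal nodes (root pinned to its given state when root_fixed)
# and count parent/child mismatches over all edges
exhaustive_parsimony <- function(tree) {
  S <- tree$seqmat
  internal <- which(lengths(tree$children) > 0L)
  edges <- which(!is.na(tree$parent))
  par_of <- tree$parent[edges]
  total <- 0L
  for (site in seq_len(ncol(S))) {
    free <- internal
    if (tree$root_fixed && !is.na(S[tree$root, site])) {
      free <- setdiff(internal, tree$root)
    }
    combos <- as.matrix(expand.grid(rep(list(1:4), length(free))))
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      st <- S[, site]
      st[free] <- combos[r, ]
      cost <- sum(!is.na(st[edges]) & !is.na(st[par_of]) &
                    st[edges] != st[par_of])
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  total
}

# build the worked-example tree: a germline root and two internal nodes,
# with leaf multiplicities standing for collapsed identical reads
toy_imbalance_tree <- function() {
  # root: CTA; left subtree ancestor ATA (mutated, 70 reads) vs right CTA
  # (30 reads); under ATA: TTA x30 vs ATA x40; under CTA: CTG x20 vs CTA x10
  txt <- "((L_TTA:1,L_ATA:1)N_ATA:1,(L_CTG:1,L_CTA:1)N_CTA:1)root:0;"
  phy <- ape::read.tree(text = txt)
  seqs <- c(L_TTA = "TTA", L_ATA = "ATA", L_CTG = "CTG", L_CTA = "CTA",
            N_ATA = "ATA", N_CTA = "CTA", root = "CTA")
  mult <- c(L_TTA = 30L, L_ATA = 40L, L_CTG = 20L, L_CTA = 10L)
  lineage_tree_from_phylo(phy, seqs, multiplicity = mult)
}
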