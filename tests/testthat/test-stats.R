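# closed-form Welch oracle, written independently of the implementation
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                   vb^2 / (length(b)^2 * (length(b) - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

test_that("identical samples give t = 0, p = 1", {
  res <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_identical(res$flag, "ok")
})

test_that("Welch test matches the closed-form oracle exactly", {
  # frozen worked example: equal sizes and variances, df = n1 + n2 - 2
  a <- c(1, 2, 3, 4); b <- c(5, 6, 7, 8)
  orc <- welch_oracle(a, b)
  expect_equal(orc$t, -4.38178, tolerance = 1e-5)
  expect_equal(orc$df, 6)
  res <- welch_t_test(a, b)
  expect_equal(res$t, orc$t)
  expect_equal(res$df, orc$df)
  expect_equal(res$p, orc$p)

  set.seed(41)
  for (rep in 1:25) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    orc <- welch_oracle(a, b)
    res <- welch_t_test(a, b)
    expect_equal(res$t, orc$t)
    expect_equal(res$df, orc$df)
    expect_equal(res$p, orc$p)
  }
})

test_that("Welch p agrees with a t-statistic permutation test", {
  set.seed(42)
  a <- rnorm(15); b <- rnorm(15, mean = 0.8)
  res <- welch_t_test(a, b)
  pooled <- c(a, b)
  n_perm <- 10000
  tobs <- abs(res$t)
  texc <- replicate(n_perm, {
    idx <- sample(30, 15)
    abs(welch_oracle(pooled[idx], pooled[-idx])$t) >= tobs
  })
  p_perm <- mean(texc)
  expect_lt(abs(res$p - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / n_perm) + 0.01)
})

test_that("degenerate inputs are flagged, not dropped", {
  expect_identical(welch_t_test(c(1), c(1, 2, 3))$flag, "too_few")
  expect_identical(welch_t_test(c(2, 2, 2), c(2, 2, 2))$flag, "zero_variance")
  expect_identical(welch_t_test(c(2, 2), c(3, 3))$flag, "zero_variance")
})

make_events <- function(lonr_ns, lonr_s, region = "CDR2", clone = "c1") {
  rbind(
    if (length(lonr_ns)) data.frame(clone_id = clone, node_id = "n",
                                    position = 0L, from_base = "A",
                                    to_base = "T", from_codon = "AAA",
                                    to_codon = "TAA",
                                    mutation_class = "NS", region = region,
                                    n_mut = 1L, n_sib = 1L, lonr = lonr_ns),
    if (length(lonr_s)) data.frame(clone_id = clone, node_id = "n",
                                   position = 0L, from_base = "A",
                                   to_base = "G", from_codon = "AAA",
                                   to_codon = "AAG",
                                   mutation_class = "S", region = region,
                                   n_mut = 1L, n_sib = 1L, lonr = lonr_s))
}

test_that("region report computes the NS-S mean difference per region", {
  x <- 0.4
  jit <- seq(-0.05, 0.05, length.out = 5)   # mean-zero spread keeps 2x exact
  ev <- rbind(make_events(x + jit, -x + jit),
              make_events(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3), region = "FWR3"))
  rep_ <- region_report(ev)
  r1 <- rep_[rep_$region == "CDR2" & rep_$subset == "all", ]
  expect_equal(r1$mean_difference, 2 * x)
  expect_gt(r1$t_statistic, 0)
  expect_identical(r1$n_ns, 5L)
  r2 <- rep_[rep_$region == "FWR3" & rep_$subset == "all", ]
  expect_equal(r2$mean_difference, 0)
  # single event per class -> flagged undefined, still reported
  ev1 <- make_events(0.5, -0.5)
  r <- region_report(ev1)
  expect_identical(r$flag, "too_few")
  expect_true(is.na(r$p_value))
})

test_that("report is invariant under event order and clone relabeling", {
  set.seed(43)
  ev <- rbind(make_events(rnorm(8), rnorm(6), clone = "c1"),
              make_events(rnorm(5), rnorm(7), clone = "c2"))
  r1 <- region_report(ev)
  shuffled <- ev[sample(nrow(ev)), ]
  shuffled$clone_id <- paste0("x_", shuffled$clone_id)
  r2 <- region_report(shuffled)
  expect_equal(r1$mean_difference, r2$mean_difference)
  expect_equal(r1$t_statistic, r2$t_statistic)
  expect_equal(r1$per_clone_mean_difference, r2$per_clone_mean_difference)
})

test_that("significant-only rows keep only clones with p below threshold", {
  set.seed(44)
  # c1 has a strong, consistent difference; c2 is pure noise
  ev <- rbind(make_events(rnorm(20, 2, 0.1), rnorm(20, -2, 0.1), clone = "c1"),
              make_events(rnorm(20, 0, 2), rnorm(20, 0, 2), clone = "c2"))
  rep_ <- region_report(ev, sig_p = 0.01)
  sig <- rep_[rep_$subset == "significant", ]
  expect_identical(sig$n_clones, 1L)
  expect_identical(sig$n_ns, 20L)
})

test_that("position profile averages per codon and leaves gaps as NA", {
  ev <- make_events(c(0.5), numeric(0))
  ev$position <- 4L
  prof <- position_profile(ev, 9)
  expect_equal(prof$mean_lonr[prof$codon == 1], 0.5)
  expect_true(is.na(prof$mean_lonr[prof$codon == 0]))
  expect_true(is.na(prof$mean_lonr[prof$codon == 2]))

  ev2 <- rbind(ev, ev)
  ev2$position <- c(3L, 5L)
  ev2$lonr <- c(0.2, 0.6)
  prof2 <- position_profile(ev2, 9)
  expect_equal(prof2$mean_lonr[prof2$codon == 1], 0.4)
})

test_that("ns_fraction averages leaf mutation counts against the ancestor", {
  anc <- "AAATTTCCC"
  # single leaf: AAA->TAA (NS), TTT->TTC (S): fraction 1/2 over one leaf? no:
  # counts per leaf averaged; here 1 NS and 1 S -> 0.5
  leaf <- c(l1 = "TAATTCCCC")
  r <- ns_fraction(leaf, anc)
  expect_equal(r$fraction, 0.5)
  # two leaves, (1 NS, 0 S) and (0 NS, 1 S) -> means 0.5/0.5 -> 0.5
  leaves <- c(l1 = "TAATTTCCC", l2 = "AAATTCCCC")
  r2 <- ns_fraction(leaves, anc)
  expect_equal(r2$fraction, 0.5)
  expect_equal(r2$mean_ns, 0.5)
  # identical leaves -> undefined, flagged
  r3 <- ns_fraction(c(l1 = anc), anc)
  expect_identical(r3$flag, "no_mutations")
  expect_true(is.na(r3$fraction))
  expect_error(ns_fraction(c(l1 = "AAA"), anc), "length")
})

test_that("spearman correlation handles ties like the brute-force ranks", {
  expect_equal(spearman_correlation(1:3, 1:3)$rho, 1)
  expect_equal(spearman_correlation(1:4, 4:1)$rho, -1)
  x <- c(1, 2, 2, 3); y <- c(4, 4, 5, 6)
  # brute force: average ranks, then Pearson on ranks
  rk <- function(v) {
    sapply(v, function(vi) mean(which(sort(v) == vi)))
  }
  rho_oracle <- stats::cor(rk(x), rk(y))
  expect_equal(spearman_correlation(x, y)$rho, rho_oracle)
  expect_identical(spearman_correlation(c(1, 1, 1), 1:3)$flag,
                   "constant_input")
})
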