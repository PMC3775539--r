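small_cfg <- function(founder_length = 48L, generations = 5L,
                      sample_size = 20L, region_rates = c(0.5, 1.0), ...) {
  sim_config(founder_length = founder_length, generations = generations,
             sample_size = sample_size, region_rates = region_rates, ...)
}

test_that("zero mutation rates give identical leaves", {
  cfg <- small_cfg(region_rates = c(0, 0))
  lin <- simulate_pool(cfg, seed = 1)
  final <- lin$generations[[6]]$seq
  expect_identical(nrow(final), 32L)
  expect_true(all(final == rep(final[1, ], each = 32)))
  expect_null(lin$mutation_log)
})

test_that("the same seed reproduces the pool and sample byte-identically", {
  cfg <- small_cfg(seed = 77)
  a <- simulate_pool(cfg)
  b <- simulate_pool(cfg)
  expect_identical(a$generations[[6]]$seq, b$generations[[6]]$seq)
  expect_identical(a$mutation_log, b$mutation_log)
  sa <- sample_biased(a, cfg, seed = 5)
  sb <- sample_biased(b, cfg, seed = 5)
  expect_identical(sa, sb)
})

test_that("per-generation mutation counts have the configured Poisson mean", {
  cfg <- sim_config(founder_length = 348L, generations = 6L,
                    sample_size = 10L, region_rates = c(0.5, 1.0))
  lin <- simulate_pool(cfg, seed = 3)
  # mutation_log rows per child per generation: mean ~ 1.5
  n_children <- sum(2^(1:6))
  rate <- nrow(lin$mutation_log) / n_children
  se <- sqrt(1.5 / n_children)
  expect_lt(abs(rate - 1.5), 4 * se)
  # region split ~ 1/3 vs 2/3
  frac_r1 <- mean(lin$mutation_log$pos <= 174)
  expect_lt(abs(frac_r1 - 1 / 3), 0.1)
})

test_that("replaying the mutation log reproduces every leaf exactly", {
  cfg <- small_cfg(seed = 11)
  lin <- simulate_pool(cfg)
  G <- cfg$generations
  seqs <- lin$generations[[1]]$seq
  for (g in seq_len(G)) {
    gen <- lin$generations[[g + 1]]
    child <- seqs[gen$parent, , drop = FALSE]
    log_g <- lin$mutation_log[lin$mutation_log$generation == g, ]
    for (r in seq_len(nrow(log_g))) {
      expect_identical(child[log_g$cell[r], log_g$pos[r]], log_g$from[r])
      child[log_g$cell[r], log_g$pos[r]] <- log_g$to[r]
    }
    expect_identical(child, gen$seq)
    seqs <- child
  }
})

test_that("biased sampling favours the chosen third-generation lineage", {
  cfg <- sim_config(founder_length = 30L, generations = 7L,
                    sample_size = 64L, region_rates = c(0, 0))
  lin <- simulate_pool(cfg, seed = 2)
  # bias_factor 1: all 2^7 cells equally likely; with factor Inf-ish the
  # chosen branch (1/8 of cells = 16) fills the sample as far as it can
  cfg1 <- cfg; cfg1$bias_factor <- 1e9; cfg1$sample_size <- 16L
  s <- sample_biased(lin, cfg1, seed = 4)
  anc <- lin$generations[[8]]$anc[attr(s, "cell_index")]
  expect_identical(length(unique(anc)), 1L)

  # factor 2: expected biased-branch share ~ 2/9 (weights 2 on 1/8 of the
  # cells); keep the sample small so without-replacement depletion is mild
  cfg2 <- cfg; cfg2$sample_size <- 16L
  set.seed(6)
  shares <- replicate(300, {
    ss <- sample_biased(lin, cfg2)
    anc <- lin$generations[[8]]$anc[attr(ss, "cell_index")]
    mean(anc == attr(ss, "biased_ancestor"))
  })
  expect_lt(abs(mean(shares) - 2 / 9), 0.025)
})

test_that("sample_size larger than the population errors", {
  cfg <- small_cfg(sample_size = 33L)
  lin <- simulate_pool(cfg, seed = 1)
  expect_error(sample_biased(lin, cfg), "exceeds")
})

test_that("selection with delta_mu = 0 equals the neutral simulator", {
  cfg0 <- small_cfg(seed = 13)
  cfg1 <- small_cfg(seed = 13,
                    selection = list(region = "R2", delta_mu = 0))
  a <- simulate_pool(cfg0)
  b <- simulate_with_selection(cfg1)
  expect_identical(a$generations[[6]]$seq, b$generations[[6]]$seq)
})

test_that("selected lineages out-reproduce neutral ones", {
  cfg <- sim_config(founder_length = 48L, generations = 7L,
                    sample_size = 10L, region_rates = c(0.5, 0.5),
                    selection = list(region = "R2", delta_mu = 1),
                    max_population = 2^16)
  lin <- simulate_with_selection(cfg, seed = 21)
  final <- lin$generations[[8]]
  expect_gt(nrow(final$seq), 2^7)          # faster than neutral growth
  expect_gt(mean(final$selected), 0.5)     # advantaged flag dominates
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(region_rates = c(-1, 1)), "rates")
  expect_error(sim_config(region_rates = c(1, 1, 1)), "one mutation rate")
  expect_error(sim_config(bias_factor = 0), "bias_factor")
  cfg <- small_cfg(generations = 20L)
  expect_error(simulate_pool(cfg, seed = 1), "max_population")
})
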