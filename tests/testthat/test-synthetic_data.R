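base_cfg <- function(...) {
  sim_config(n_diploid = 100, n_sites = 5, sequence_length = 1e6,
             generations = 50, split_generation = 0, mutation_rate = 0,
             recombination_rate = 1e-8, ...)
}

test_that("fixed seed gives bit-identical panels and phenotypes", {
  cfg <- sim_config(n_diploid = c(50, 50), n_sites = 30, generations = 40,
                    split_generation = 20)
  set.seed(99); a <- simulate_populations(cfg)
  set.seed(99); b <- simulate_populations(cfg)
  expect_identical(a$panels$pop1$haps, b$panels$pop1$haps)
  expect_identical(a$panels$pop2$haps, b$panels$pop2$haps)
  expect_identical(a$truth, b$truth)
  arch <- trait_architecture(causal = data.frame(id = a$truth$id[1], beta = 0.3))
  set.seed(7); p1 <- simulate_phenotypes(a$panels$pop1, arch)
  set.seed(7); p2 <- simulate_phenotypes(a$panels$pop1, arch)
  expect_identical(p1$phenotypes, p2$phenotypes)
})

test_that("neutral drift is a martingale: mean final frequency near p0", {
  set.seed(10)
  finals <- replicate(200, {
    sim <- simulate_populations(base_cfg(init_freq = rep(0.3, 5)))
    mean(colMeans(sim$panels$pop1$haps))
  })
  # per-replicate variance ~ p q t/(2N); CI on the mean of 200 replicates
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.3), 2.5 * se + 1e-12)
  expect_lt(abs(mean(finals) - 0.3), 0.02)
})

test_that("one-generation selection response matches the diffusion oracle", {
  # genic s = 0.05, h = 0.5, p0 = 0.1: E[dp] ~ s p (1-p) / w_bar = 0.00448
  s <- 0.05; p0 <- 0.1; h <- 0.5
  w_bar <- p0^2 * (1 + 2 * s) + 2 * p0 * (1 - p0) * (1 + 2 * h * s) + (1 - p0)^2
  exp_dp <- (p0^2 * (1 + 2 * s) + p0 * (1 - p0) * (1 + 2 * h * s)) / w_bar - p0
  expect_equal(exp_dp, 0.00448, tolerance = 0.01)
  set.seed(11)
  cfg <- sim_config(n_diploid = 2000, n_sites = 1, sequence_length = 1000,
                    generations = 1, split_generation = 0,
                    selection = data.frame(site = 1L, pop = 0L, s = s, h = h),
                    init_freq = p0, n_ancestral = 2000)
  dps <- replicate(300, {
    sim <- simulate_populations(cfg)
    colMeans(sim$panels$pop1$haps) - p0
  })
  se <- sd(dps) / sqrt(length(dps))
  expect_lt(abs(mean(dps) - exp_dp), 3 * se)
})

test_that("split at the final generation leaves populations identical", {
  set.seed(12)
  cfg <- sim_config(n_diploid = c(80, 80), n_sites = 40, generations = 30,
                    split_generation = 30)
  sim <- simulate_populations(cfg)
  expect_identical(colMeans(sim$panels$pop1$haps),
                   colMeans(sim$panels$pop2$haps))
})

test_that("selected final frequencies are stochastically larger than neutral", {
  set.seed(13)
  run <- function(s) replicate(200, {
    cfg <- sim_config(n_diploid = 100, n_sites = 1, sequence_length = 1000,
                      generations = 50, split_generation = 0,
                      selection = if (s > 0)
                        data.frame(site = 1L, pop = 0L, s = s, h = 0.5) else NULL,
                      init_freq = 0.2)
    colMeans(simulate_populations(cfg)$panels$pop1$haps)
  })
  w <- wilcox.test(run(0.05), run(0), alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("new-mutation site-frequency spectrum is monotone decreasing", {
  set.seed(14)
  # near-infinite-sites regime: ~0.15 mutation events per site over the run
  cfg <- sim_config(n_diploid = 50, n_sites = 40000, sequence_length = 4e7,
                    generations = 150, split_generation = 0,
                    mutation_rate = 1e-5, init_freq = rep(0, 40000))
  sim <- simulate_populations(cfg)
  counts <- colSums(sim$panels$pop1$haps)
  seg <- counts[counts > 0 & counts < 100]
  expect_gt(length(seg), 300)
  sfs <- as.integer(table(factor(seg, levels = 1:9)))
  expect_gt(sfs[1], sfs[2])
  expect_gt(sfs[2], sfs[3])
  expect_lt(cor(sfs, 1:9, method = "spearman"), -0.7)
})

test_that("require_segregating retries and errors at the cap", {
  set.seed(15)
  cfg <- sim_config(n_diploid = 30, n_sites = 2, generations = 200,
                    split_generation = 0, init_freq = c(0.01, 0.5),
                    require_segregating = 1L, retry_cap = 3)
  expect_error(simulate_populations(cfg), "segregating")
})

test_that("drift_frequencies mirrors the haplotype simulator's moments", {
  set.seed(16)
  f <- drift_frequencies(rep(0.5, 4000), n_diploid = c(100, 100),
                         generations = 40, split_generation = 20)
  expect_equal(mean(f), 0.5, tolerance = 0.01)
  # total drift variance ~ p q (1 - (1 - 1/2N)^t)
  expect_equal(var(f[, 1]), 0.25 * (1 - (1 - 1 / 200)^40), tolerance = 0.15)
  # shared-history covariance ~ p q (1 - (1 - 1/2N)^t_shared)
  expect_equal(cov(f[, 1], f[, 2]), 0.25 * (1 - (1 - 1 / 200)^20),
               tolerance = 0.2)
})

test_that("ordinal phenotypes honor thresholds, confusion and rater count", {
  set.seed(17)
  cfg <- sim_config(n_diploid = 1500, n_sites = 10, generations = 1,
                    split_generation = 0, init_freq = rep(0.5, 10))
  panel <- simulate_populations(cfg)$panels$pop1
  # flat architecture with tertile thresholds: marginals ~ (1/3, 1/3, 1/3)
  arch <- trait_architecture(sex_effect = 0, age_slope = 0, noise_sd = 1,
                             thresholds = qnorm(c(1/3, 2/3)),
                             confusion = diag(3), n_raters = 3)
  ph <- simulate_phenotypes(panel, arch)
  marg <- table(factor(ph$truth$level, levels = 1:3)) / 1500
  expect_true(all(abs(marg - 1/3) < 0.04))
  # identity confusion: all raters agree and equal the true level
  expect_true(all(ph$phenotypes$rater1 == ph$truth$level))
  expect_true(all(ph$phenotypes$rater1 == ph$phenotypes$rater2))
  expect_equal(cohens_kappa(ph$phenotypes$rater1, ph$phenotypes$rater2)$kappa, 1)
  expect_error(trait_architecture(thresholds = c(1, 0)), "ascending")
  expect_error(simulate_phenotypes(panel,
    trait_architecture(causal = data.frame(id = "nope", beta = 1))), "absent")
})
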