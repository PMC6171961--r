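test_that("EHH has the combinatorial form on a hand-built panel", {
  # 6 haplotypes; core at site 3 with 4 carriers of allele 1 splitting into
  # extended-haplotype groups {2,1,1} one site to the right
  h <- rbind(c(0, 0, 1, 0, 0),
             c(0, 0, 1, 0, 0),
             c(0, 0, 1, 1, 0),
             c(0, 1, 1, 1, 1),
             c(0, 0, 0, 0, 0),
             c(1, 0, 0, 1, 0))
  p <- haplotype_panel(h, pos = c(10, 20, 30, 40, 50) * 1000)
  pr <- ehh_profile(p, core = 3, allele = 1, cutoff = 0)
  expect_equal(pr$ehh[pr$offsets == 0], 1)
  # right site 4: groups {1,2} (allele 0) and {3,4} (allele 1): 2*C(2,2)/C(4,2)
  expect_equal(pr$ehh[pr$sites == 4], 2 / 6)
  # right site 5: {1,2} persists, {3,4} splits -> groups {2,1,1}: C(2,2)/C(4,2)
  expect_equal(pr$ehh[pr$sites == 5], 1 / 6)
  # left site 2: groups {1,2,3} and {4}: C(3,2)/C(4,2) = 1/2
  expect_equal(pr$ehh[pr$sites == 2], 1 / 2)
  expect_error(ehh_profile(p, core = 1, allele = 1), "carriers")
})

test_that("identical carrier haplotypes keep EHH at 1 throughout", {
  h <- matrix(0L, 6, 8)
  h[1:3, 4] <- 1L     # carriers share the all-reference background
  p <- haplotype_panel(h, pos = (1:8) * 1e4)
  pr <- ehh_profile(p, 4, 1)
  expect_true(all(pr$ehh == 1))
  expect_true(pr$truncated_left && pr$truncated_right)
})

test_that("optimized EHH equals brute-force substring counting", {
  set.seed(40)
  for (r in 1:25) {
    p <- random_panel(2 * sample(4:16, 1), sample(10:64, 1))
    f <- colMeans(p$haps)
    cores <- which(f >= 0.2 & f <= 0.8)
    if (length(cores) == 0) next
    core <- sample(cores, 1)
    for (allele in 0:1) {
      opt <- ehh_profile(p, core, allele)
      bf <- brute_ehh(p$haps, core, allele)
      expect_equal(opt$ehh[opt$sites > core], bf$right$ehh)
      expect_equal(rev(opt$ehh[opt$sites < core]), bf$left$ehh)
      expect_equal(opt$truncated_right, bf$right$truncated)
      expect_equal(opt$truncated_left, bf$left$truncated)
    }
  }
})

test_that("iHH integration matches hand trapezoids", {
  fake <- structure(list(core_id = "x", core_site = 2, allele = 1,
                         n_carriers = 4, sites = c(1, 2, 3),
                         offsets = c(0, 0, 0), ehh = c(1, 1, 1),
                         truncated_left = FALSE, truncated_right = FALSE),
                    class = "ehh_profile")
  # one-sided profile EHH [1, 0.5, 0.04] at offsets [0, 0.1, 0.2]
  fake$offsets <- c(0, 0.1, 0.2); fake$ehh <- c(1, 0.5, 0.04)
  fake$sites <- c(2, 3, 4)
  ii <- integrate_ihh(fake)
  expect_equal(ii$right, 0.075 + 0.027)
  expect_equal(ii$left, 0)
  expect_equal(ii$ihh, 0.102)
  # constant EHH of 1 over [0, d]: integral d
  fake$ehh <- c(1, 1, 1); fake$offsets <- c(0, 0.3, 0.7)
  expect_equal(integrate_ihh(fake)$right, 0.7)
  # symmetric profile: left = right
  fake2 <- fake
  fake2$offsets <- c(-0.2, -0.1, 0, 0.1, 0.2)
  fake2$ehh <- c(0.3, 0.6, 1, 0.6, 0.3)
  fake2$sites <- 1:5
  ii2 <- integrate_ihh(fake2)
  expect_equal(ii2$left, ii2$right)
  # violating monotonicity errors
  fake2$ehh <- c(0.3, 0.6, 1, 0.7, 0.8)
  expect_error(integrate_ihh(fake2), "non-increasing")
})

test_that("ihs_scan filters by frequency and flips sign with allele labels", {
  set.seed(41)
  cfg <- sim_config(n_diploid = 150, n_sites = 1000, sequence_length = 2.5e7,
                    generations = 100, split_generation = 0,
                    mutation_rate = 1e-7, recombination_rate = 1e-8)
  panel <- simulate_populations(cfg)$panels$pop1
  res <- ihs_scan(panel, min_bin = 5)
  daf <- panel_daf(panel)
  expect_true(all(res$daf >= 0.05 & res$daf <= 0.95))
  expect_false(any(panel$id[daf < 0.05 & daf > 0] %in% res$id))
  # swapping ancestral/derived labels negates ihs_u
  flipped <- panel
  flipped$anc <- 1L - panel$anc
  res2 <- ihs_scan(flipped, min_bin = 5)
  common <- intersect(res$id[res$flag == "ok"], res2$id[res2$flag == "ok"])
  expect_gt(length(common), 10)
  expect_equal(res2$ihs_u[match(common, res2$id)],
               -res$ihs_u[match(common, res$id)], tolerance = 1e-12)
  # standardized scores have mean 0, sd 1 within standardization groups
  ok <- res$flag == "ok" & is.finite(res$ihs_s)
  for (b in unique(res$std_bin[ok])) {
    x <- res$ihs_s[ok & res$std_bin == b]
    expect_lt(abs(mean(x)), 1e-10)
    expect_equal(sd(x), 1, tolerance = 1e-10)
  }
})

test_that("empirical_threshold reports order-statistic cutoffs and hits", {
  set.seed(42)
  x <- c(runif(999, -2, 2), 5)
  suppressWarnings(th <- empirical_threshold(x))
  expect_gt(th$cutoff, 2)
  expect_lte(th$cutoff, 5)
  expect_equal(th$n_hits, 1)
  expect_equal(x[th$hits], 5)
  suppressWarnings(th2 <- empirical_threshold(rep(1.5, 50)))
  expect_equal(th2$cutoff, 1.5)
  expect_equal(th2$n_hits, 0)
  # median-level quantile on symmetric scores ~ median |score|
  z <- rnorm(5000)
  suppressWarnings(th3 <- empirical_threshold(z, 0.5))
  expect_equal(th3$cutoff, median(abs(z)), tolerance = 1e-12)
  expect_error(empirical_threshold(numeric(0)), "finite")
  expect_warning(empirical_threshold(rnorm(100)), "1000")
})
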