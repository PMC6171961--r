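test_that("HWE exact test matches a Monte Carlo pairing oracle", {
  set.seed(1)
  # oracle: condition on allele counts, pair alleles at random, tabulate
  # the heterozygote-count distribution, two-sided exact-style p
  mc_hwe <- function(n_aa, n_ab, n_bb, reps = 40000) {
    n <- n_aa + n_ab + n_bb
    alleles <- rep(c(0L, 1L), c(2 * n_aa + n_ab, 2 * n_bb + n_ab))
    hets <- replicate(reps, {
      a <- sample(alleles)
      sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
    })
    tab <- table(hets) / reps
    obs <- tab[as.character(n_ab)]
    if (is.na(obs)) obs <- 0
    sum(tab[tab <= obs + 1e-9])
  }
  cases <- list(c(30, 40, 30), c(50, 10, 40), c(88, 10, 2), c(5, 0, 5))
  for (cs in cases) {
    p_exact <- hwe_exact_p(cs[1], cs[2], cs[3])
    p_mc <- mc_hwe(cs[1], cs[2], cs[3])
    expect_lt(abs(p_exact - p_mc), 0.02)
  }
  # perfect HWE proportions give p near 1
  expect_gt(hwe_exact_p(25, 50, 25), 0.5)
})

test_that("qc_filter applies sample filter first, then variant rules", {
  set.seed(2)
  n <- 50
  mk <- function(p) rbinom(n, 2, p)
  d <- sapply(rep(0.3, 10), mk)
  colnames(d) <- paste0("V", 1:10)
  rownames(d) <- paste0("S", 1:n)
  # one sample missing 1 of 10 variants = 10% > 5%
  d["S1", 3] <- NA
  res <- qc_filter(d)
  expect_true("S1" %in% res$report$id[res$report$kind == "sample"])
  expect_equal(res$n_samples, n - 1)
  # variant 3's missingness came only from S1, so it survives
  expect_equal(res$n_variants, 10)
})

test_that("qc_filter removes rare, missing, HWE-failing and low-INFO variants", {
  set.seed(3)
  n <- 100
  cols <- list(
    ok1 = rbinom(n, 2, 0.4),
    rare = c(1L, rep(0L, n - 1)),                  # maf 0.005 < 0.01
    miss = {x <- rbinom(n, 2, 0.3); x[1:3] <- NA; x},  # 3% > 2%
    hwe = rep(1L, n),                              # all het
    lowinfo = rbinom(n, 2, 0.3),
    ok2 = rbinom(n, 2, 0.25))
  # filler keeps every sample's missing fraction below the 5% sample filter
  filler <- sapply(1:60, function(i) rbinom(n, 2, 0.5))
  colnames(filler) <- paste0("f", 1:60)
  d <- cbind(do.call(cbind, cols), filler)
  rownames(d) <- paste0("S", 1:n)
  res <- qc_filter(d, info = c(lowinfo = 0.5, ok1 = 0.99))
  rep_v <- res$report[res$report$kind == "variant", ]
  expect_setequal(rep_v$id, c("rare", "miss", "hwe", "lowinfo"))
  expect_equal(rep_v$rule[rep_v$id == "rare"], "maf")
  expect_equal(rep_v$rule[rep_v$id == "miss"], "missingness")
  expect_equal(rep_v$rule[rep_v$id == "hwe"], "hwe")
  expect_equal(rep_v$rule[rep_v$id == "lowinfo"], "info")
  expect_true(all(c("ok1", "ok2") %in% colnames(res$dosages)))
  expect_false(any(rep_v$id %in% colnames(res$dosages)))
})

test_that("generator-constructed disjoint failures are all caught (counting oracle)", {
  set.seed(4)
  n <- 120
  m_ok <- 175; m_maf <- 12; m_miss <- 8; m_hwe <- 5
  mk_ok <- function() {p <- runif(1, 0.2, 0.5); rbinom(n, 2, p)}
  mk_maf <- function() c(rep(1L, 1), rep(0L, n - 1))
  mk_miss <- function() {x <- rbinom(n, 2, 0.3); x[sample(n, 4)] <- NA; x}
  mk_hwe <- function() rep(1L, n)
  d <- cbind(sapply(seq_len(m_ok), function(i) mk_ok()),
             sapply(seq_len(m_maf), function(i) mk_maf()),
             sapply(seq_len(m_miss), function(i) mk_miss()),
             sapply(seq_len(m_hwe), function(i) mk_hwe()))
  colnames(d) <- c(paste0("ok", 1:m_ok), paste0("maf", 1:m_maf),
                   paste0("mis", 1:m_miss), paste0("hwe", 1:m_hwe))
  rownames(d) <- paste0("S", 1:n)
  res <- qc_filter(d)
  expect_equal(res$n_variants, m_ok)
  # exclusion report partitions the input
  rep_v <- res$report[res$report$kind == "variant", ]
  expect_equal(nrow(rep_v) + res$n_variants, ncol(d))
  expect_equal(sum(rep_v$rule == "maf"), m_maf)
  expect_equal(sum(rep_v$rule == "missingness"), m_miss)
  expect_equal(sum(rep_v$rule == "hwe"), m_hwe)
})

test_that("qc_filter is idempotent", {
  set.seed(5)
  d <- sapply(runif(30, 0.1, 0.5), function(p) rbinom(80, 2, p))
  colnames(d) <- paste0("V", 1:30)
  d[sample(length(d), 20)] <- NA
  r1 <- qc_filter(d)
  r2 <- qc_filter(r1$dosages)
  expect_equal(r2$dosages, r1$dosages)
  expect_equal(nrow(r2$report), 0)
})

test_that("ld_prune drops duplicated columns and keeps independent ones", {
  set.seed(6)
  n <- 200
  v1 <- rbinom(n, 2, 0.3)
  v3 <- rbinom(n, 2, 0.4)
  d <- cbind(a = v1, b = v1, c = v3)
  kept <- ld_prune(d)
  expect_length(kept, 2)
  expect_true("c" %in% kept)
  expect_equal(sum(c("a", "b") %in% kept), 1)

  # mutually independent variants: all retained (pairwise r2 oracle)
  ind <- sapply(runif(20, 0.2, 0.8), function(p) rbinom(500, 2, p))
  colnames(ind) <- paste0("V", 1:20)
  r2 <- cor(ind)^2; diag(r2) <- 0
  if (max(r2) <= 0.2) expect_equal(ld_prune(ind), colnames(ind))
  expect_error(ld_prune(ind, window = 1), "window")
})
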