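sim_dosages <- function(n, m, p = NULL) {
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  colnames(d) <- paste0("V", seq_len(m))
  d
}

test_that("additive_scan matches lm() per variant exactly", {
  set.seed(20)
  n <- 120
  d <- sim_dosages(n, 6)
  covs <- cbind(sex = rbinom(n, 1, 0.5), age = runif(n, 20, 60))
  y <- 0.3 * d[, 2] - 0.2 * covs[, "sex"] + rnorm(n)
  scan <- additive_scan(y, d, covs)
  for (j in c(1, 2, 5)) {
    fit <- summary(lm(y ~ d[, j] + covs))$coefficients[2, ]
    expect_equal(scan$records$beta[j], unname(fit[1]), tolerance = 1e-10)
    expect_equal(scan$records$se[j], unname(fit[2]), tolerance = 1e-10)
    expect_equal(scan$records$p[j], unname(fit[4]), tolerance = 1e-10)
  }
})

test_that("null scan is calibrated: type-I rate and lambda near nominal", {
  set.seed(21)
  n <- 500
  d <- sim_dosages(n, 2000)
  y <- rnorm(n)
  scan <- additive_scan(y, d)
  expect_true(mean(scan$records$p < 0.05) > 0.03 &&
                mean(scan$records$p < 0.05) < 0.07)
  expect_gt(scan$lambda_gc, 0.9)
  expect_lt(scan$lambda_gc, 1.1)
})

test_that("effect recovery: simulated beta lands within 2 se", {
  set.seed(22)
  cfg <- sim_config(n_diploid = 300, n_sites = 50, generations = 50,
                    split_generation = 0, init_freq = "uniform")
  panel <- sample_individuals(simulate_populations(cfg)$panels$pop1, 2000)
  f <- colMeans(panel$haps)
  causal <- panel$id[which.min(abs(f - 0.4))]
  arch <- trait_architecture(causal = data.frame(id = causal, beta = 0.5),
                             sex_effect = 0, age_slope = 0,
                             confusion = diag(3))
  ph <- simulate_phenotypes(panel, arch)
  # latent-scale response isolates the regression contract from rater noise
  scan <- additive_scan(ph$truth$latent, panel_dosages(panel))
  rec <- scan$records[scan$records$id == causal, ]
  expect_lt(abs(rec$beta - 0.5), 2 * rec$se)
})

test_that("monomorphic variants are flagged without estimates", {
  set.seed(23)
  d <- cbind(sim_dosages(50, 3), mono = rep(1L, 50))
  scan <- additive_scan(rnorm(50), d)
  expect_true(scan$records$monomorphic[4])
  expect_true(is.na(scan$records$p[4]))
  expect_error(additive_scan(rnorm(50), d[, 1:3],
                             covariates = cbind(a = rep(1, 50))),
               "rank deficient")
})

test_that("scan obeys scale and allele-recoding symmetries", {
  set.seed(24)
  n <- 200
  d <- sim_dosages(n, 5)
  y <- 0.2 * d[, 1] + rnorm(n)
  s1 <- additive_scan(y, d)
  s2 <- additive_scan(3 * y, d)
  expect_equal(s2$records$beta, 3 * s1$records$beta)
  expect_equal(s2$records$se, 3 * s1$records$se)
  expect_equal(s2$records$p, s1$records$p)
  s3 <- additive_scan(y, 2 - d)
  expect_equal(s3$records$beta, -s1$records$beta)
  expect_equal(abs(s3$records$z), abs(s1$records$z))
})

test_that("conditional scan removes the conditioned signal's LD block", {
  set.seed(25)
  n <- 800
  v <- rbinom(n, 2, 0.4)
  proxy <- v
  flip <- sample(n, 40)                     # r2 ~ 0.9 proxy
  proxy[flip] <- rbinom(40, 2, 0.4)
  ind <- rbinom(n, 2, 0.3)
  d <- cbind(causal = v, proxy = proxy, indep = ind)
  y <- 0.5 * v + rnorm(n)
  plain <- additive_scan(y, d)
  expect_lt(plain$records$p[plain$records$id == "proxy"], 1e-8)
  cond <- conditional_scan(y, d, condition_on = "causal")
  expect_false("causal" %in% cond$records$id)
  expect_gt(cond$records$p[cond$records$id == "proxy"], 1e-4)
  # conditioning on an uncorrelated variant barely moves the causal signal
  cond2 <- conditional_scan(y, d, condition_on = "indep")
  lp1 <- log10(plain$records$p[plain$records$id == "causal"])
  lp2 <- log10(cond2$records$p[cond2$records$id == "causal"])
  expect_lt(abs(lp1 - lp2), 0.5)
  # empty conditioning = plain scan
  cond3 <- conditional_scan(y, d, condition_on = character())
  expect_equal(cond3$records, plain$records)
  expect_error(conditional_scan(y, cbind(d, mono = rep(0L, n)),
                                condition_on = "mono"), "monomorphic")
})

test_that("genomic control lambda follows its defining arithmetic", {
  med <- qchisq(0.5, 1)
  expect_equal(genomic_control_lambda(chi2 = rep(med, 5)), 1)
  expect_equal(genomic_control_lambda(chi2 = rep(2 * med, 5)), 2)
  expect_equal(genomic_control_lambda(p = rep(0.5, 3)), 1, tolerance = 1e-10)
  expect_error(genomic_control_lambda(), "supply")
})

test_that("PCA covariates separate drifted populations", {
  set.seed(26)
  cfg <- sim_config(n_diploid = c(100, 100), n_sites = 300, generations = 120,
                    split_generation = 20, init_freq = "uniform")
  sim <- simulate_populations(cfg)
  d <- rbind(panel_dosages(sim$panels$pop1), panel_dosages(sim$panels$pop2))
  poly <- apply(d, 2, var) > 0
  pcs <- pca_covariates(d[, poly], k = 4)
  lab <- rep(c(0, 1), each = 100)
  expect_gt(abs(cor(pcs$scores[, 1], lab)), 0.9)
  # panmictic panel: no dominant axis
  d1 <- panel_dosages(sim$panels$pop1)
  d1 <- d1[, apply(d1, 2, var) > 0]
  p1 <- pca_covariates(d1, k = 2)
  expect_lt(p1$varprop[1], 2 * p1$varprop[2])
  # k = 0 leaves the scan unchanged
  y <- rnorm(200)
  expect_equal(additive_scan(y, d[, poly][, 1:10],
                             pca_covariates(d[, poly], 0)$scores)$records$p,
               additive_scan(y, d[, poly][, 1:10])$records$p)
  expect_error(pca_covariates(d1[, 1:5], k = 10), "rank")
})

test_that("variance explained follows 2p(1-p)b^2/s2", {
  expect_equal(variance_explained(0.5, 0.1, 1), 0.005)
  expect_equal(variance_explained(0.3, 0, 2), 0)
  expect_equal(variance_explained(1e-9, 0.5, 1), 2e-9 * 0.25, tolerance = 1e-6)
  expect_error(variance_explained(0, 0.1, 1), "eaf")
  expect_error(variance_explained(0.5, 0.1, 0), "sigma2")
})
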