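#' Wright-Fisher simulation configuration
#'
#' Describes a forward-in-time discrete-generation simulation of one
#' ancestral population that splits into `length(n_diploid)` daughter
#' populations at `split_generation`. Before the split the populations
#' evolve jointly (as the ancestral population, neutrally); after it each
#' daughter evolves independently, optionally under selection.
#'
#' @param n_diploid integer vector: diploid population size per daughter
#'   population (the ancestral size is `n_ancestral`).
#' @param n_sites number of polymorphic sites to initialize.
#' @param sequence_length chromosome length in bp.
#' @param mutation_rate per-site per-haplotype per-generation flip rate.
#' @param recombination_rate per-bp per-generation crossover rate; ignored
#'   when `map` is supplied.
#' @param map optional [genetic_map] for non-uniform recombination.
#' @param generations total generations simulated.
#' @param split_generation generation at which daughters separate
#'   (`<= generations`); `split_generation = generations` means no
#'   independent evolution.
#' @param selection data.frame with columns `site` (index), `pop` (daughter
#'   index, `0` = all), `s` (per-allele selection coefficient, `>= -1`;
#'   genotype fitnesses 1, 1+2hs, 1+2s), `h` (dominance in `[0,1]`,
#'   0.5 = additive); empty for neutrality.
#' @param n_ancestral ancestral diploid size; default `max(n_diploid)`.
#' @param init_freq initial alternate-allele frequencies: `"neutral"` draws
#'   from the 1/p neutral spectrum truncated to segregating frequencies,
#'   `"uniform"` from U(0.05, 0.95), or a numeric vector of length `n_sites`.
#' @param require_segregating site indices that must remain polymorphic in
#'   every daughter population (resimulated up to `retry_cap` times).
#' @param retry_cap maximum resimulation attempts (default 20).
#' @export
sim_config <- function(n_diploid = c(200, 200), n_sites = 500,
                       sequence_length = 1e6, mutation_rate = 0,
                       recombination_rate = 1e-8, map = NULL,
                       generations = 200, split_generation = 100,
                       selection = NULL, n_ancestral = NULL,
                       init_freq = "neutral", require_segregating = integer(),
                       retry_cap = 20) {
  if (split_generation > generations)
    stop("split_generation must not exceed generations")
  if (is.null(n_ancestral)) n_ancestral <- max(n_diploid)
  if (is.null(selection))
    selection <- data.frame(site = integer(), pop = integer(),
                            s = numeric(), h = numeric())
  if (nrow(selection) > 0) {
    if (any(selection$s < -1)) stop("selection coefficients must be >= -1")
    if (any(selection$h < 0 | selection$h > 1)) stop("dominance h must lie in [0,1]")
  }
  structure(list(n_diploid = as.integer(n_diploid), n_sites = as.integer(n_sites),
                 sequence_length = sequence_length, mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate, map = map,
                 generations = as.integer(generations),
                 split_generation = as.integer(split_generation),
                 selection = selection, n_ancestral = as.integer(n_ancestral),
                 init_freq = init_freq,
                 require_segregating = as.integer(require_segregating),
                 retry_cap = retry_cap),
            class = "sim_config")
}

init_frequencies <- function(config) {
  if (is.numeric(config$init_freq)) {
    stopifnot(length(config$init_freq) == config$n_sites)
    return(config$init_freq)
  }
  n2 <- 2 * config$n_ancestral
  pmin_ <- 1 / n2
  pmax_ <- 1 - 1 / n2
  switch(config$init_freq,
         neutral = {   # f(p) ~ 1/p on [1/2N, 1-1/2N], inverse-CDF draw
           u <- runif(config$n_sites)
           pmin_ * (pmax_ / pmin_)^u
         },
         uniform = runif(config$n_sites, 0.05, 0.95),
         stop("init_freq must be 'neutral', 'uniform' or a numeric vector"))
}

selection_vectors <- function(config, pop_index) {
  s <- numeric(config$n_sites)
  h <- rep(0.5, config$n_sites)
  sel <- config$selection
  if (nrow(sel) > 0) {
    rows <- sel$pop == 0L | sel$pop == pop_index
    for (r in which(rows)) {
      s[sel$site[r]] <- sel$s[r]
      h[sel$site[r]] <- sel$h[r]
    }
  }
  list(s = s, h = h)
}

#' Forward Wright-Fisher simulation of haplotype panels
#'
#' Runs the simulation described by a [sim_config]: each offspring
#' haplotype is a recombinant mosaic of one parent's two haplotypes
#' (crossovers Poisson along the genetic map), parents are drawn with
#' probability proportional to multiplicative diploid fitness at selected
#' sites, and mutations flip alleles at rate `mutation_rate`. Daughter
#' populations share the ancestral panel up to `split_generation`, then
#' evolve independently.
#'
#' @param config a [sim_config].
#' @return list with `panels` (one [haplotype_panel] per daughter
#'   population, ancestral allele = 0 at every site) and `truth` (data.frame
#'   per variant: id, site index, position, initial frequency, per-population
#'   final frequency, per-population selection coefficient).
#' @export
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- length(config$n_diploid)
  pos <- sort(sample.int(config$sequence_length, config$n_sites))
  cm <- if (is.null(config$map)) pos * config$recombination_rate * 100
        else interpolate_cm(config$map, pos)
  ids <- sprintf("sv%05d", seq_len(config$n_sites))

  for (attempt in seq_len(config$retry_cap)) {
    p0 <- init_frequencies(config)
    anc <- matrix(rbinom(2 * config$n_ancestral * config$n_sites, 1L,
                         rep(p0, each = 2 * config$n_ancestral)),
                  nrow = 2 * config$n_ancestral)
    if (config$split_generation > 0) {
      anc <- .wf_evolve_cpp(anc, config$n_ancestral, config$split_generation,
                            cm, numeric(config$n_sites),
                            rep(0.5, config$n_sites), config$mutation_rate)
    }
    post <- config$generations - config$split_generation
    panels <- vector("list", K)
    for (k in seq_len(K)) {
      sel <- selection_vectors(config, k)
      if (post > 0) {
        hk <- .wf_evolve_cpp(anc, config$n_diploid[k], post, cm,
                             sel$s, sel$h, config$mutation_rate)
      } else if (config$n_diploid[k] != config$n_ancestral) {
        rows <- sample.int(2 * config$n_ancestral,
                           2 * config$n_diploid[k], replace = TRUE)
        hk <- anc[rows, , drop = FALSE]
      } else {
        hk <- anc
      }
      panels[[k]] <- haplotype_panel(hk, pos, chrom = "1", id = ids, cm = cm,
                                     anc = rep(0L, config$n_sites))
    }
    if (length(config$require_segregating) > 0) {
      seg <- sapply(panels, function(p) {
        f <- colMeans(p$haps)[config$require_segregating]
        all(f > 0 & f < 1)
      })
      if (!all(seg)) {
        if (attempt == config$retry_cap)
          stop("required segregating site(s) lost in all ", config$retry_cap,
               " attempts")
        next
      }
    }
    freq <- matrix(vapply(panels, function(p) colMeans(p$haps),
                          numeric(config$n_sites)), ncol = K)
    colnames(freq) <- paste0("freq_pop", seq_len(K))
    svec <- matrix(vapply(seq_len(K), function(k) selection_vectors(config, k)$s,
                          numeric(config$n_sites)), ncol = K)
    colnames(svec) <- paste0("s_pop", seq_len(K))
    truth <- data.frame(id = ids, site = seq_len(config$n_sites), pos = pos,
                        p0 = p0, freq, svec, stringsAsFactors = FALSE)
    names(panels) <- paste0("pop", seq_len(K))
    return(list(panels = panels, truth = truth))
  }
}

#' Frequency-level Wright-Fisher drift
#'
#' A haplotype-free companion to [simulate_populations] for calibration
#' experiments at scale: tracks only allele frequencies through binomial
#' resampling (with deterministic selection response before sampling),
#' sharing drift before the split and evolving independently after.
#'
#' @param p0 initial allele frequencies (vector, one per variant).
#' @param n_diploid diploid size per population.
#' @param generations total generations.
#' @param split_generation generations of shared drift (default 0).
#' @param s selection coefficient: scalar, or variants x populations matrix.
#' @param h dominance (scalar, default 0.5).
#' @return variants x populations matrix of final frequencies.
#' @export
drift_frequencies <- function(p0, n_diploid, generations,
                              split_generation = 0, s = 0, h = 0.5) {
  K <- length(n_diploid)
  L <- length(p0)
  smat <- if (is.matrix(s)) s else matrix(s, L, K)
  step <- function(p, n2, sv) {
    if (any(sv != 0)) {
      # genotype fitnesses 1, 1 + 2hs, 1 + 2s (per-allele coefficient s)
      w_bar <- p^2 * (1 + 2 * sv) + 2 * p * (1 - p) * (1 + 2 * h * sv) + (1 - p)^2
      p <- (p^2 * (1 + 2 * sv) + p * (1 - p) * (1 + 2 * h * sv)) / w_bar
    }
    rbinom(length(p), n2, p) / n2
  }
  n2a <- 2 * max(n_diploid)
  p <- p0
  if (split_generation > 0)
    for (g in seq_len(split_generation)) p <- step(p, n2a, rep(0, L))
  out <- matrix(NA_real_, L, K)
  for (k in seq_len(K)) {
    pk <- p
    n2 <- 2 * n_diploid[k]
    post <- generations - split_generation
    if (post > 0) for (g in seq_len(post)) pk <- step(pk, n2, smat[, k])
    out[, k] <- pk
  }
  dimnames(out) <- list(names(p0), paste0("pop", seq_len(K)))
  out
}

#' Trait architecture for the ordinal phenotype generator
#'
#' @param causal data.frame with columns `id` (variant id) and `beta`
#'   (additive effect per alternate-allele copy, latent-scale units).
#' @param sex_effect additive latent shift for sex = 1 (default -0.5:
#'   females thinner-browed than males, matching the direction seen in
#'   rater-scored facial-hair traits).
#' @param age_slope latent change per year of age (default -0.01).
#' @param noise_sd residual latent SD (default 1).
#' @param thresholds two ascending cutpoints mapping the latent scale to
#'   ordinal levels 1/2/3; defaults hit marginals (0.25, 0.55, 0.20) for a
#'   standard-normal latent trait.
#' @param confusion 3x3 row-stochastic rater confusion matrix; rows = true
#'   level, columns = reported level. Default: 85% correct, errors to
#'   adjacent levels.
#' @param n_raters number of independent raters (default 3).
#' @export
trait_architecture <- function(causal = data.frame(id = character(), beta = numeric()),
                               sex_effect = -0.5, age_slope = -0.01,
                               noise_sd = 1,
                               thresholds = qnorm(c(0.25, 0.80)),
                               confusion = default_confusion(),
                               n_raters = 3) {
  if (length(thresholds) != 2 || diff(thresholds) <= 0)
    stop("thresholds must be two ascending cutpoints")
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(3, 3)) ||
      any(abs(rowSums(confusion) - 1) > 1e-8))
    stop("confusion must be a 3x3 row-stochastic matrix")
  structure(list(causal = causal, sex_effect = sex_effect,
                 age_slope = age_slope, noise_sd = noise_sd,
                 thresholds = thresholds, confusion = confusion,
                 n_raters = as.integer(n_raters)),
            class = "trait_architecture")
}

#' Default rater confusion matrix (85% agreement, adjacent-level errors)
#' @export
default_confusion <- function() {
  matrix(c(0.85, 0.15, 0.00,
           0.075, 0.85, 0.075,
           0.00, 0.15, 0.85), nrow = 3, byrow = TRUE)
}

#' Simulate ordinal phenotypes from a haplotype panel
#'
#' Latent trait = sum of causal dosage effects + covariate effects +
#' Gaussian noise; the latent value is discretized to levels 1..3 by the
#' architecture's thresholds; each rater reports a level drawn from the
#' confusion row of the true level; the analyzed phenotype is the mean of
#' the rater reports.
#'
#' @param panel a [haplotype_panel].
#' @param arch a [trait_architecture].
#' @param covariates optional data.frame with `sex` (0/1) and `age` per
#'   individual; simulated (sex ~ Bernoulli(0.5), age ~ U(18, 65)) when
#'   absent.
#' @return list with `phenotypes` (data.frame: id, sex, age, rater columns,
#'   `score` = mean rating) and `truth` (latent value and true level per
#'   individual).
#' @export
simulate_phenotypes <- function(panel, arch, covariates = NULL) {
  stopifnot(inherits(arch, "trait_architecture"))
  n <- n_individuals(panel)
  dos <- panel_dosages(panel)
  if (nrow(arch$causal) > 0) {
    miss <- setdiff(arch$causal$id, colnames(dos))
    if (length(miss) > 0)
      stop("causal variant(s) absent from panel: ", paste(miss, collapse = ", "))
  }
  if (is.null(covariates)) {
    covariates <- data.frame(sex = rbinom(n, 1, 0.5),
                             age = runif(n, 18, 65))
  }
  stopifnot(nrow(covariates) == n)
  genetic <- if (nrow(arch$causal) > 0)
    as.numeric(dos[, arch$causal$id, drop = FALSE] %*% arch$causal$beta)
  else rep(0, n)
  latent <- genetic + arch$sex_effect * covariates$sex +
    arch$age_slope * covariates$age + rnorm(n, 0, arch$noise_sd)
  level <- 1L + (latent > arch$thresholds[1]) + (latent > arch$thresholds[2])
  ratings <- vapply(seq_len(arch$n_raters), function(r) {
    vapply(level, function(l) sample.int(3L, 1L, prob = arch$confusion[l, ]),
           integer(1))
  }, integer(n))
  colnames(ratings) <- paste0("rater", seq_len(arch$n_raters))
  phen <- data.frame(id = paste0("S", seq_len(n)),
                     sex = covariates$sex, age = covariates$age,
                     ratings, score = rowMeans(ratings),
                     stringsAsFactors = FALSE)
  truth <- data.frame(id = phen$id, latent = latent, level = level,
                      stringsAsFactors = FALSE)
  list(phenotypes = phen, truth = truth)
}
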