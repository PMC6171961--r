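#' Pipeline configuration
#'
#' One shared simulation describes the ancestral process; each cohort is a
#' daughter population sampled to its cohort size, phenotyped with the
#' shared trait architecture, scanned, and meta-analyzed.
#'
#' @param sim a [sim_config] whose `n_diploid` has one entry per cohort.
#' @param arch a [trait_architecture] (causal ids refer to simulated
#'   variants).
#' @param cohort_n individuals sampled per cohort (defaults to the
#'   simulated population sizes).
#' @param gwas_threshold genome-wide significance level (default 5e-8).
#' @param locus_window bp separating independent loci when clumping
#'   (default 1 Mb).
#' @param n_pcs PCA covariates per cohort scan (default 4).
#' @param selection_battery run iHS/selection-difference/Qx stages
#'   (default TRUE).
#' @param finemap a [finemap_config].
#' @export
pipeline_config <- function(sim, arch, cohort_n = NULL,
                            gwas_threshold = 5e-8, locus_window = 1e6,
                            n_pcs = 4, selection_battery = TRUE,
                            finemap = finemap_config()) {
  stopifnot(inherits(sim, "sim_config"), inherits(arch, "trait_architecture"))
  if (is.null(cohort_n)) cohort_n <- sim$n_diploid
  stopifnot(length(cohort_n) == length(sim$n_diploid))
  structure(list(sim = sim, arch = arch, cohort_n = as.integer(cohort_n),
                 gwas_threshold = gwas_threshold, locus_window = locus_window,
                 n_pcs = n_pcs, selection_battery = selection_battery,
                 finemap = finemap),
            class = "pipeline_config")
}

# distance-based clumping: genome-wide-significant variants separated by
# more than `window` bp start new loci; returns lead (min-p) id per locus
clump_loci <- function(meta, threshold, window) {
  sig <- meta[!is.na(meta$P_SS) & meta$P_SS < threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(character(0))
  sig <- sig[order(sig$CHR, sig$POS), ]
  locus <- cumsum(c(1, diff(sig$POS) > window | diff(as.integer(factor(sig$CHR))) != 0))
  vapply(split(sig, locus), function(d) d$ID[which.min(d$P_SS)], character(1))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate K cohorts from a shared ancestral process; per cohort: sample
#' individuals, generate ordinal phenotypes, LD-prune, compute PCA
#' covariates, run the additive scan; then harmonize and meta-analyze
#' across cohorts, clump genome-wide-significant variants into loci,
#' fine-map each locus, run the conditional scan on each locus, and (when
#' enabled) the selection battery: iHS per cohort around the hit loci,
#' pairwise selection-difference tests, and the polygenic-score divergence
#' test over the lead variants. All stage outputs are returned and,
#' optionally, written under `out_dir` with a run manifest.
#'
#' @param config a [pipeline_config].
#' @param out_dir optional output directory for stage TSV/JSON files.
#' @param seed optional RNG seed recorded in the manifest.
#' @return list with per-stage results: `truth`, `cohorts` (scan results),
#'   `meta`, `loci`, `credible_sets`, `conditional`, `selection`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) set.seed(seed)
  K <- length(config$sim$n_diploid)
  sim <- simulate_populations(config$sim)

  cohorts <- vector("list", K)
  sumstats <- vector("list", K)
  for (k in seq_len(K)) {
    panel <- sample_individuals(sim$panels[[k]], config$cohort_n[k])
    phen <- simulate_phenotypes(panel, config$arch)
    dos <- panel_dosages(panel)
    poly <- apply(dos, 2, var) > 0
    covs <- cbind(sex = phen$phenotypes$sex, age = phen$phenotypes$age)
    if (config$n_pcs > 0 && sum(poly) > config$n_pcs) {
      pruned <- ld_prune(dos[, poly, drop = FALSE])
      pcs <- pca_covariates(dos[, pruned, drop = FALSE],
                            k = min(config$n_pcs, length(pruned) - 1))
      covs <- cbind(covs, pcs$scores)
    }
    info <- data.frame(id = panel$id, chrom = panel$chrom, pos = panel$pos,
                       effect_allele = panel$alt, other_allele = panel$ref,
                       stringsAsFactors = FALSE)
    scan <- additive_scan(phen$phenotypes$score, dos, covs, variant_info = info)
    cohorts[[k]] <- list(panel = panel, phenotypes = phen$phenotypes,
                         scan = scan, covariates = covs)
    sumstats[[k]] <- scan_to_sumstats(scan)
  }
  names(cohorts) <- names(sumstats) <- paste0("cohort", seq_len(K))

  aligned <- harmonize_effects(sumstats)
  meta <- meta_analyze(aligned)
  leads <- clump_loci(meta, config$gwas_threshold, config$locus_window)

  meta_fm <- data.frame(ID = meta$ID, CHR = meta$CHR, POS = meta$POS,
                        BETA = meta$BETA_FIXED, SE = meta$SE_FIXED,
                        stringsAsFactors = FALSE)
  credible <- lapply(leads, function(v) finemap_locus(meta_fm, v, config$finemap))
  names(credible) <- leads
  conditional <- lapply(leads, function(v) {
    k <- 1L  # conditional scan reported for the first (discovery) cohort
    conditional_scan(cohorts[[k]]$phenotypes$score,
                     panel_dosages(cohorts[[k]]$panel),
                     cohorts[[k]]$covariates, condition_on = v)
  })
  names(conditional) <- leads

  selection <- NULL
  if (config$selection_battery && length(leads) > 0) {
    ihs <- lapply(cohorts, function(co) {
      out <- try(ihs_scan(co$panel, min_bin = 10), silent = TRUE)
      if (inherits(out, "try-error")) NULL else out
    })
    freqs <- sapply(sim$panels, function(p) colMeans(p$haps))
    rownames(freqs) <- sim$truth$id
    nhap <- 2 * config$sim$n_diploid
    pairs <- utils::combn(K, 2)
    lead_rows <- match(leads, sim$truth$id)
    neutral_rows <- setdiff(seq_len(nrow(freqs)), lead_rows)
    seldiff <- apply(pairs, 2, function(pr) {
      a <- pr[1]; b <- pr[2]
      null <- calibrate_null(
        logit_diff(freqs[neutral_rows, a], freqs[neutral_rows, b],
                   nhap[a], nhap[b]),
        (freqs[neutral_rows, a] + freqs[neutral_rows, b]) / 2,
        min_bin = 25)
      cbind(pop_a = a, pop_b = b,
            seldiff_test(leads, freqs[lead_rows, a], freqs[lead_rows, b],
                         nhap[a], nhap[b], null))
    })
    qx <- NULL
    if (K >= 2 && length(leads) >= 1) {
      beta_meta <- meta$BETA_FIXED[match(leads, meta$ID)]
      nc <- try(neutral_covariance(freqs[neutral_rows, , drop = FALSE],
                                   freqs[lead_rows, , drop = FALSE],
                                   n_sets = 200), silent = TRUE)
      if (!inherits(nc, "try-error"))
        qx <- try(qx_test(freqs[lead_rows, , drop = FALSE], beta_meta, nc),
                  silent = TRUE)
      if (inherits(qx, "try-error")) qx <- NULL
    }
    selection <- list(ihs = ihs, seldiff = seldiff, qx = qx)
  }

  result <- list(truth = sim$truth, cohorts = cohorts, meta = meta,
                 loci = leads, credible_sets = credible,
                 conditional = conditional, selection = selection)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(meta, file.path(out_dir, "meta.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (k in seq_len(K))
      write_sumstats(sumstats[[k]],
                     file.path(out_dir, sprintf("cohort%d_sumstats.tsv", k)))
    for (v in leads)
      write.table(credible[[v]],
                  file.path(out_dir, sprintf("credible_%s.tsv", v)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(file.path(out_dir, "manifest.json"), "pipeline",
                   params = list(K = K, cohort_n = config$cohort_n,
                                 gwas_threshold = config$gwas_threshold,
                                 locus_window = config$locus_window,
                                 n_loci = length(leads)),
                   seed = seed)
  }
  result
}
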