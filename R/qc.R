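#' QC thresholds
#'
#' Default values follow standard chip-GWAS practice: drop individuals with
#' more than 5% missing genotypes, then variants with over 2% missingness, minor allele
#' frequency below 1%, Hardy-Weinberg exact P below 1e-5, or imputation INFO
#' below 0.8.
#'
#' @param max_sample_missing,max_variant_missing,min_maf,min_hwe_p,min_info
#'   fractions/probabilities in `[0,1]`.
#' @export
qc_thresholds <- function(max_sample_missing = 0.05, max_variant_missing = 0.02,
                          min_maf = 0.01, min_hwe_p = 1e-5, min_info = 0.8) {
  v <- c(max_sample_missing, max_variant_missing, min_maf, min_hwe_p, min_info)
  if (any(v < 0 | v > 1)) stop("all QC thresholds must lie in [0,1]")
  structure(list(max_sample_missing = max_sample_missing,
                 max_variant_missing = max_variant_missing,
                 min_maf = min_maf, min_hwe_p = min_hwe_p,
                 min_info = min_info), class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test by enumeration of heterozygote counts conditional on
#' the observed allele counts (the Wigginton/Cutler/Abecasis construction):
#' P = sum of probabilities of all heterozygote configurations no more
#' likely than the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom order is
#'   irrelevant).
#' @return exact two-sided p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(NA_real_)
  n_minor <- 2 * min(n_aa, n_bb) + n_ab   # minor allele count
  # heterozygote count shares parity with the minor allele count
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # log P(n_ab = h | allele counts), hypergeometric-type kernel
  lp <- lgamma(n + 1) - lgamma((n_minor - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (n_minor + hets) / 2 + 1) + hets * log(2) -
    (lgamma(2 * n + 1) - lgamma(n_minor + 1) - lgamma(2 * n - n_minor + 1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Genotype quality-control filter
#'
#' Applies sample-level missingness filtering first, then variant-level
#' filters (missingness, MAF, Hardy-Weinberg exact test, imputation INFO)
#' computed on the post-sample-filter matrix, so variant statistics reflect
#' the analyzed sample set.
#'
#' @param dosages `N x M` matrix of hard-call dosages in `{0,1,2,NA}` with
#'   sample rownames and variant colnames.
#' @param thresholds a [qc_thresholds] object.
#' @param info optional named vector of imputation INFO scores per variant;
#'   variants absent from it are treated as genotyped (no INFO filter).
#' @return list with `dosages` (filtered matrix), `report` (data.frame of
#'   exclusions: kind, id, rule, value), `n_samples`, `n_variants`.
#' @export
qc_filter <- function(dosages, thresholds = qc_thresholds(), info = NULL) {
  stopifnot(is.matrix(dosages))
  if (is.null(rownames(dosages))) rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages))) colnames(dosages) <- paste0("V", seq_len(ncol(dosages)))
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be hard calls in {0,1,2} or NA")
  report <- data.frame(kind = character(), id = character(),
                       rule = character(), value = numeric(),
                       stringsAsFactors = FALSE)

  smiss <- rowMeans(is.na(dosages))
  bad_s <- smiss > thresholds$max_sample_missing
  if (any(bad_s)) {
    report <- rbind(report, data.frame(kind = "sample",
                                       id = rownames(dosages)[bad_s],
                                       rule = "missingness",
                                       value = smiss[bad_s]))
    dosages <- dosages[!bad_s, , drop = FALSE]
  }
  if (nrow(dosages) == 0) stop("no samples survive QC")

  vmiss <- colMeans(is.na(dosages))
  eaf <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  hwe <- vapply(seq_len(ncol(dosages)), function(j) {
    g <- dosages[, j]
    hwe_exact_p(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                sum(g == 2, na.rm = TRUE))
  }, numeric(1))

  drop_rule <- rep(NA_character_, ncol(dosages))
  drop_val <- rep(NA_real_, ncol(dosages))
  mark <- function(cond, rule, val) {
    new <- cond & is.na(drop_rule)
    drop_rule[new] <<- rule
    drop_val[new] <<- val[new]
  }
  mark(vmiss > thresholds$max_variant_missing, "missingness", vmiss)
  mark(maf < thresholds$min_maf, "maf", maf)
  mark(!is.na(hwe) & hwe < thresholds$min_hwe_p, "hwe", hwe)
  if (!is.null(info)) {
    iv <- info[colnames(dosages)]
    mark(!is.na(iv) & iv < thresholds$min_info, "info", iv)
  }

  bad_v <- !is.na(drop_rule)
  if (any(bad_v)) {
    report <- rbind(report, data.frame(kind = "variant",
                                       id = colnames(dosages)[bad_v],
                                       rule = drop_rule[bad_v],
                                       value = drop_val[bad_v]))
    dosages <- dosages[, !bad_v, drop = FALSE]
  }
  if (ncol(dosages) == 0) stop("no variants survive QC")
  rownames(report) <- NULL
  list(dosages = dosages, report = report,
       n_samples = nrow(dosages), n_variants = ncol(dosages))
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window, while any variant pair has squared Pearson
#' correlation of dosages above `r2_max`, the member of the worst-offending
#' pair with the lower MAF is dropped (ties broken toward the later
#' position); the window then slides by `step`. Missing dosages are excluded
#' pairwise from the correlation.
#'
#' @param dosages `N x M` dosage matrix, columns in position order.
#' @param r2_max squared-correlation ceiling (default 0.2).
#' @param window window size in variants (default 50).
#' @param step slide in variants (default 5).
#' @return character vector of retained variant ids (column names).
#' @export
ld_prune <- function(dosages, r2_max = 0.2, window = 50, step = 5) {
  if (window < 2) stop("window must be at least 2")
  if (ncol(dosages) < 2) stop("ld_prune needs at least 2 variants")
  if (is.null(colnames(dosages))) colnames(dosages) <- paste0("V", seq_len(ncol(dosages)))
  m <- ncol(dosages)
  keep <- rep(TRUE, m)
  maf <- pmin(colMeans(dosages, na.rm = TRUE) / 2,
              1 - colMeans(dosages, na.rm = TRUE) / 2)
  starts <- seq(1, max(1, m - 1), by = step)
  for (w0 in starts) {
    idx <- which(keep)
    idx <- idx[idx >= w0 & idx < w0 + window]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(cor(dosages[, idx, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    diag(r2) <- 0
    r2[is.na(r2)] <- 0
    while (max(r2) > r2_max) {
      ij <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
      a <- idx[ij[1]]; b <- idx[ij[2]]
      drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
      keep[drop] <- FALSE
      k <- match(drop, idx)
      r2[k, ] <- 0; r2[, k] <- 0
    }
  }
  colnames(dosages)[keep]
}
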