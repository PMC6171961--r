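#' Additive per-variant association scan
#'
#' Ordinary least squares of the phenotype on each variant's dosage plus
#' covariates and an intercept, one variant at a time. Implemented by
#' residualizing the phenotype and every dosage column on the covariate
#' block once (Frisch-Waugh-Lovell), which is numerically identical to the
#' full per-variant regression. P-values use the t distribution with
#' `n - k - 2` residual degrees of freedom (intercept + k covariates +
#' dosage).
#'
#' @param phenotype numeric response, no missing values.
#' @param dosages `N x M` dosage matrix in `[0, 2]` with variant colnames.
#' @param covariates optional `N x k` numeric matrix/data.frame (sex, age,
#'   PCs, ...). Samples with missing covariates are dropped listwise.
#' @param variant_info optional data.frame with columns `id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele` merged into the output.
#' @return object of class `scan_result`: list with `records` (data.frame:
#'   id, eaf, beta, se, z, p, n, monomorphic flag), `lambda_gc`,
#'   `covariates` (names used).
#' @export
additive_scan <- function(phenotype, dosages, covariates = NULL,
                          variant_info = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) colnames(dosages) <- paste0("V", seq_len(ncol(dosages)))
  if (anyNA(phenotype)) stop("phenotype must not contain missing values")
  n0 <- length(phenotype)
  stopifnot(nrow(dosages) == n0)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n0)
    keep <- stats::complete.cases(covariates)
    if (!all(keep)) {
      phenotype <- phenotype[keep]
      dosages <- dosages[keep, , drop = FALSE]
      covariates <- covariates[keep, , drop = FALSE]
    }
  }
  n <- length(phenotype)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("covariate matrix is rank deficient")
  k <- ncol(X)
  ry <- qr.resid(qrX, phenotype)
  rd <- qr.resid(qrX, dosages)
  sxx <- colSums(rd^2)
  mono <- apply(dosages, 2, function(x) var(x) == 0)
  df <- n - k - 1
  beta <- se <- tval <- p <- rep(NA_real_, ncol(dosages))
  ok <- !mono & sxx > .Machine$double.eps * n
  beta[ok] <- colSums(rd[, ok, drop = FALSE] * ry) / sxx[ok]
  rss <- sum(ry^2) - beta[ok]^2 * sxx[ok]
  rss <- pmax(rss, 0)
  se[ok] <- sqrt(rss / df / sxx[ok])
  tval[ok] <- beta[ok] / se[ok]
  p[ok] <- 2 * stats::pt(-abs(tval[ok]), df)
  records <- data.frame(id = colnames(dosages),
                        eaf = colMeans(dosages) / 2,
                        beta = beta, se = se, z = tval, p = p, n = n,
                        monomorphic = mono, stringsAsFactors = FALSE)
  if (!is.null(variant_info)) {
    records <- merge(variant_info, records, by = "id", sort = FALSE)
    if (!is.null(variant_info$pos))
      records <- records[order(records$pos), ]
  }
  rownames(records) <- NULL
  chi2 <- records$z[!records$monomorphic]^2
  structure(list(records = records,
                 lambda_gc = genomic_control_lambda(chi2 = chi2),
                 covariates = colnames(covariates)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d variants, n = %d, lambda_GC = %.3f\n",
              nrow(x$records), x$records$n[1], x$lambda_gc))
  invisible(x)
}

#' Conditional association scan
#'
#' Re-runs [additive_scan] with the dosages of the conditioning variants
#' appended to the covariate block; the conditioned variants themselves are
#' omitted from the output. Used to test for secondary signals at a locus.
#'
#' @inheritParams additive_scan
#' @param condition_on character vector of variant ids to condition on
#'   (empty = plain scan).
#' @export
conditional_scan <- function(phenotype, dosages, covariates = NULL,
                             condition_on = character(),
                             variant_info = NULL) {
  if (length(condition_on) == 0)
    return(additive_scan(phenotype, dosages, covariates, variant_info))
  miss <- setdiff(condition_on, colnames(dosages))
  if (length(miss) > 0)
    stop("conditioning variant(s) not in dosage matrix: ",
         paste(miss, collapse = ", "))
  cond <- dosages[, condition_on, drop = FALSE]
  if (any(apply(cond, 2, var) == 0))
    stop("cannot condition on a monomorphic variant")
  rest <- dosages[, setdiff(colnames(dosages), condition_on), drop = FALSE]
  covs <- if (is.null(covariates)) cond else cbind(as.matrix(covariates), cond)
  if (!is.null(variant_info))
    variant_info <- variant_info[variant_info$id %in% colnames(rest), , drop = FALSE]
  additive_scan(phenotype, rest, covs, variant_info)
}

#' Genomic-control inflation factor
#'
#' Median of the 1-df chi-square association statistics divided by the
#' 1-df chi-square median 0.45494.
#'
#' @param p two-sided p-values (converted via the chi-square quantile), or
#' @param chi2 1-df chi-square statistics directly.
#' @export
genomic_control_lambda <- function(p = NULL, chi2 = NULL) {
  if (is.null(chi2)) {
    if (is.null(p) || length(p) == 0) stop("supply p or chi2")
    chi2 <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) == 0) stop("no finite statistics")
  median(chi2) / qchisq(0.5, df = 1)
}

#' Principal-component covariates from pruned dosages
#'
#' PCA of the column-standardized dosage matrix; the top `k` sample scores
#' are the stratification covariates used by [additive_scan].
#'
#' @param dosages `N x M` dosage matrix, ideally pre-pruned with [ld_prune].
#' @param k number of components (default 4); `k = 0` returns an empty
#'   covariate block.
#' @return list with `scores` (`N x k`), `varprop` (explained-variance
#'   share per component).
#' @export
pca_covariates <- function(dosages, k = 4) {
  dosages <- as.matrix(dosages)
  sds <- apply(dosages, 2, sd)
  X <- scale(dosages[, sds > 0, drop = FALSE])
  if (k == 0)
    return(list(scores = matrix(numeric(0), nrow(dosages), 0), varprop = numeric()))
  pr <- prcomp(X, center = FALSE, scale. = FALSE)
  if (k > ncol(pr$x)) stop("k exceeds the rank of the dosage matrix")
  varprop <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, varprop = varprop)
}

#' Per-variant phenotypic variance explained
#'
#' The standard additive approximation `2 p (1-p) beta^2 / sigma^2`.
#'
#' @param eaf effect-allele frequency in (0, 1).
#' @param beta per-allele effect.
#' @param sigma2 phenotypic variance (> 0).
#' @export
variance_explained <- function(eaf, beta, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must lie strictly in (0,1)")
  2 * eaf * (1 - eaf) * beta^2 / sigma2
}

#' Convert a scan result to the summary-statistic exchange format
#'
#' @param scan a `scan_result`.
#' @param chrom,pos,effect_allele,other_allele per-variant metadata; taken
#'   from the records when present.
#' @export
scan_to_sumstats <- function(scan, chrom = NULL, pos = NULL,
                             effect_allele = NULL, other_allele = NULL) {
  r <- scan$records[!scan$records$monomorphic, , drop = FALSE]
  pick <- function(given, col, default) {
    if (!is.null(given)) given
    else if (!is.null(r[[col]])) r[[col]]
    else default
  }
  data.frame(ID = r$id,
             CHR = pick(chrom, "chrom", "1"),
             POS = pick(pos, "pos", seq_len(nrow(r))),
             EA = pick(effect_allele, "effect_allele", "G"),
             OA = pick(other_allele, "other_allele", "A"),
             EAF = r$eaf, BETA = r$beta, SE = r$se, P = r$p, N = r$n,
             stringsAsFactors = FALSE)
}
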