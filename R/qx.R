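#' Polygenic score per population
#'
#' `Z_m = 2 * sum_l beta_l * p_ml`: twice the effect-size-weighted sum of
#' effect-allele frequencies in population m.
#'
#' @param freq variants x populations matrix of effect-allele frequencies.
#' @param beta per-variant effect sizes aligned to the effect alleles
#'   (rows of `freq`).
#' @return named numeric vector of per-population scores (trait units).
#' @export
genetic_score <- function(freq, beta) {
  freq <- as.matrix(freq)
  stopifnot(length(beta) == nrow(freq))
  if (anyNA(freq)) {
    bad <- which(is.na(freq), arr.ind = TRUE)[1, ]
    stop(sprintf("missing frequency for locus %s in population %s",
                 rownames(freq)[bad[1]] %||% bad[1],
                 colnames(freq)[bad[2]] %||% bad[2]))
  }
  setNames(as.numeric(2 * crossprod(freq, beta)), colnames(freq))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drift covariance from frequency-matched neutral variants
#'
#' Neutral variants are binned by across-population mean frequency; each
#' scored locus draws its matches from its own bin, so resampled sets share
#' the scored loci's frequency composition. The population-relationship
#' matrix F is the M x M covariance across neutral loci of the standardized
#' deviations `x_lm = (p_ml - pbar_l) / sqrt(pbar_l (1 - pbar_l))`, with
#' `pbar_l` the across-population mean.
#'
#' @param neutral_freq neutral variants x populations frequency matrix.
#' @param scored_freq scored loci x populations frequency matrix (defines
#'   the bins to match).
#' @param bin_width mean-frequency bin width (default 0.05).
#' @param n_sets number of matched resampled locus sets (default 1000).
#' @return list with `F` (M x M), `matched_sets` (list of row-index vectors
#'   into `neutral_freq`), `bins` (per scored locus).
#' @export
neutral_covariance <- function(neutral_freq, scored_freq, bin_width = 0.05,
                               n_sets = 1000) {
  neutral_freq <- as.matrix(neutral_freq)
  scored_freq <- as.matrix(scored_freq)
  M <- ncol(neutral_freq)
  stopifnot(ncol(scored_freq) == M, M >= 2)
  pbar <- rowMeans(neutral_freq)
  keep <- pbar > 0 & pbar < 1
  neutral_freq <- neutral_freq[keep, , drop = FALSE]
  pbar <- pbar[keep]
  x <- (neutral_freq - pbar) / sqrt(pbar * (1 - pbar))
  F_mat <- stats::cov(x)

  nb <- function(p) pmin(floor(p / bin_width), round(1 / bin_width) - 1)
  neutral_bin <- nb(pbar)
  scored_bin <- nb(rowMeans(scored_freq))
  candidates <- lapply(scored_bin, function(b) which(neutral_bin == b))
  empty <- vapply(candidates, length, integer(1)) == 0
  if (any(empty))
    stop("no neutral variants in the frequency bin of scored locus ",
         which(empty)[1])
  L <- nrow(scored_freq)
  matched_sets <- lapply(seq_len(n_sets), function(i) {
    used <- integer(0)
    vapply(seq_len(L), function(l) {
      pool <- setdiff(candidates[[l]], used)
      if (length(pool) == 0) pool <- candidates[[l]]  # bin exhausted: reuse
      pick <- if (length(pool) == 1) pool else sample(pool, 1)
      used <<- c(used, pick)
      pick
    }, integer(1))
  })
  list(F = F_mat, matched_sets = matched_sets, bins = scored_bin,
       neutral_freq = neutral_freq)
}

qx_statistic <- function(freq, beta, F_mat, tol = 1e-10) {
  z <- genetic_score(freq, beta)
  M <- length(z)
  pbar <- rowMeans(freq)
  va <- sum(beta^2 * pbar * (1 - pbar))
  if (va <= 0) stop("additive variance V_A is zero (no informative loci)")
  C <- diag(M) - matrix(1 / M, M, M)
  A <- 4 * va * (C %*% F_mat %*% C)
  dvec <- z - mean(z)
  # pseudo-inverse on the rank-(M-1) centered space
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values))
  Ainv <- e$vectors[, pos, drop = FALSE] %*%
    diag(1 / e$values[pos], sum(pos)) %*% t(e$vectors[, pos, drop = FALSE])
  as.numeric(t(dvec) %*% Ainv %*% dvec)
}

#' Polygenic-score divergence (Qx-style) test
#'
#' Compares the divergence of per-population polygenic scores with the
#' multivariate-normal drift expectation encoded by the neutral covariance
#' F. The statistic is the squared Mahalanobis length of the centered score
#' vector under covariance `4 V_A F` (projected onto the (M-1)-dimensional
#' mean-orthogonal space via pseudo-inverse), with
#' `V_A = sum beta_l^2 pbar_l (1 - pbar_l)`. Both the chi-square(M-1)
#' p-value and an empirical p-value from frequency-matched neutral locus
#' sets are reported.
#'
#' @param freq scored loci x populations effect-allele frequency matrix.
#' @param beta per-locus effect sizes.
#' @param neutral a list from [neutral_covariance] (F and matched sets).
#' @return object of class `qx_result`: qx, df, p_chi2, p_empirical,
#'   n_resamples, scores.
#' @export
qx_test <- function(freq, beta, neutral) {
  freq <- as.matrix(freq)
  M <- ncol(freq)
  qx <- qx_statistic(freq, beta, neutral$F)
  p_chi2 <- pchisq(qx, df = M - 1, lower.tail = FALSE)
  null_stats <- vapply(neutral$matched_sets, function(rows) {
    qx_statistic(neutral$neutral_freq[rows, , drop = FALSE], beta, neutral$F)
  }, numeric(1))
  n_res <- length(null_stats)
  p_emp <- if (n_res > 0) (1 + sum(null_stats >= qx)) / (n_res + 1) else NA_real_
  structure(list(qx = qx, df = M - 1, p_chi2 = p_chi2,
                 p_empirical = p_emp, n_resamples = n_res,
                 scores = genetic_score(freq, beta)),
            class = "qx_result")
}

#' @export
print.qx_result <- function(x, ...) {
  cat(sprintf("Qx = %.3f (df = %d), chi-square P = %.3g, empirical P = %.3g (%d resamples)\n",
              x$qx, x$df, x$p_chi2, x$p_empirical, x$n_resamples))
  invisible(x)
}
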