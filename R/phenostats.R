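#' Cohen's kappa for two raters
#'
#' Unweighted kappa from the K x K cross-table: `kappa = (p_o - p_e) /
#' (1 - p_e)` with observed agreement `p_o` and chance agreement `p_e` from
#' the marginal products. A linearly weighted variant is available for
#' ordinal categories.
#'
#' @param a,b equal-length rating vectors over a shared category set.
#' @param weighted use linear weights (default FALSE, matching standard
#'   reporting for 3-level scales).
#' @return list with `kappa`, `p_o`, `p_e`, `n`; `kappa` is `NA` with a
#'   warning when both raters are constant and equal (`p_e = 1`).
#' @export
cohens_kappa <- function(a, b, weighted = FALSE) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  lev <- sort(unique(c(a, b)))
  ta <- factor(a, levels = lev)
  tb <- factor(b, levels = lev)
  tab <- table(ta, tb) / length(a)
  K <- length(lev)
  if (weighted) {
    w <- 1 - abs(outer(seq_len(K), seq_len(K), "-")) / (K - 1)
  } else {
    w <- diag(K)
  }
  p_o <- sum(w * tab)
  p_e <- sum(w * outer(rowSums(tab), colSums(tab)))
  if (1 - p_e < .Machine$double.eps) {
    warning("chance agreement is 1 (both raters constant); kappa undefined")
    return(list(kappa = NA_real_, p_o = p_o, p_e = p_e, n = length(a)))
  }
  list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e, n = length(a))
}

#' Gini(-Simpson) diversity of an ordinal distribution
#'
#' `D = 1 - sum_k f_k^2` over category frequencies: 0 when all observations
#' share one category, maximal (`1 - 1/K`) when uniform.
#'
#' @param levels vector of category labels.
#' @return list with `d` and `freq` (named category frequencies).
#' @export
gini_diversity <- function(levels) {
  if (length(levels) < 1) stop("need at least one observation")
  f <- table(levels) / length(levels)
  list(d = 1 - sum(f^2), freq = c(f))
}

#' Covariate association summary for a phenotype
#'
#' Linear model `phenotype ~ sex + age`; reports per-covariate estimate and
#' two-sided p-value. Constant covariates are flagged and skipped.
#'
#' @param phenotype numeric response.
#' @param sex,age covariates.
#' @return data.frame: term, beta, se, p, flagged.
#' @export
covariate_assoc <- function(phenotype, sex, age) {
  n <- length(phenotype)
  if (n <= 3) stop("too few observations")
  d <- data.frame(phenotype = phenotype, sex = sex, age = age)
  flagged <- c(sex = var(sex) == 0, age = var(age) == 0)
  terms <- names(flagged)[!flagged]
  if (length(terms) == 0) stop("both covariates are constant")
  fit <- lm(stats::reformulate(terms, "phenotype"), data = d)
  cf <- summary(fit)$coefficients
  out <- data.frame(term = names(flagged),
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    flagged = unname(flagged), stringsAsFactors = FALSE)
  hit <- match(rownames(cf), out$term)
  ok <- !is.na(hit)
  out$beta[hit[ok]] <- cf[ok, 1]
  out$se[hit[ok]] <- cf[ok, 2]
  out$p[hit[ok]] <- cf[ok, 4]
  out
}
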