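#' Signed z-score from a two-sided p-value, computed in log space
#'
#' Survives p-values far below double underflow when `log_p` is supplied.
#'
#' @param p two-sided p-value (ignored when `log_p` given).
#' @param direction effect sign (+1/-1).
#' @param log_p optional natural-log p-value.
#' @export
z_from_p <- function(p, direction = 1, log_p = NULL) {
  lp <- if (is.null(log_p)) log(p) else log_p
  if (any(!is.finite(lp))) stop("p = 0 is not representable; supply log_p")
  sign(direction) * qnorm(lp - log(2), log.p = TRUE, lower.tail = FALSE)
}

#' Two-sided p-value (and its log) from a z-score
#' @param z z-score.
#' @return list with `p` and `log_p` (natural log).
#' @export
p_from_z <- function(z) {
  lp <- pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  list(p = exp(lp), log_p = lp)
}

#' Harmonize per-cohort association records to a common effect allele
#'
#' All cohorts are expressed on the first cohort's effect allele: cohorts
#' reporting the swapped allele pair get `beta -> -beta`, `eaf -> 1 - eaf`.
#' Strand-ambiguous A/T and C/G variants are dropped with a warning unless
#' `keep_ambiguous = TRUE`; variants whose allele sets are irreconcilable
#' (neither equal nor complementary to the reference pair) are dropped with
#' a message.
#'
#' @param cohorts named list of summary-stat data.frames (`ID EA OA EAF
#'   BETA SE P N` at minimum), all containing the shared variants.
#' @param keep_ambiguous keep A/T and C/G variants (default FALSE).
#' @return list of aligned data.frames restricted to the common, resolvable
#'   variant set.
#' @export
harmonize_effects <- function(cohorts, keep_ambiguous = FALSE) {
  stopifnot(length(cohorts) >= 1)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  flip <- function(a) unname(comp[a])
  ref <- cohorts[[1]]
  ids <- Reduce(intersect, lapply(cohorts, function(d) d$ID))
  ref <- ref[match(ids, ref$ID), , drop = FALSE]

  ambiguous <- toupper(ref$EA) == flip(toupper(ref$OA))
  if (any(ambiguous) && !keep_ambiguous) {
    warning(sprintf("dropping %d strand-ambiguous (A/T, C/G) variant(s)",
                    sum(ambiguous)))
    ids <- ids[!ambiguous]
    ref <- ref[!ambiguous, , drop = FALSE]
  }

  drop_ids <- character()
  out <- lapply(cohorts, function(d) {
    d <- d[match(ids, d$ID), , drop = FALSE]
    ea <- toupper(d$EA); oa <- toupper(d$OA)
    rea <- toupper(ref$EA); roa <- toupper(ref$OA)
    same <- ea == rea & oa == roa
    swapped <- ea == roa & oa == rea
    strand <- ea == flip(rea) & oa == flip(roa)
    strand_swapped <- ea == flip(roa) & oa == flip(rea)
    bad <- !(same | swapped | strand | strand_swapped)
    if (any(bad)) drop_ids <<- union(drop_ids, d$ID[bad])
    do_flip <- swapped | strand_swapped
    d$BETA[do_flip] <- -d$BETA[do_flip]
    d$EAF[do_flip] <- 1 - d$EAF[do_flip]
    d$EA <- ref$EA; d$OA <- ref$OA
    d
  })
  if (length(drop_ids) > 0) {
    message("dropping ", length(drop_ids),
            " variant(s) with irreconcilable alleles: ",
            paste(utils::head(drop_ids, 5), collapse = ", "))
    out <- lapply(out, function(d) d[!(d$ID %in% drop_ids), , drop = FALSE])
  }
  out
}

#' Sample-size-weighted fixed-effects meta-analysis
#'
#' The METAL z-score scheme: per-cohort signed z from the two-sided p and
#' effect direction; pooled `Z = sum(sqrt(n_i) z_i) / sqrt(sum n_i)`.
#'
#' @param p per-cohort two-sided p-values.
#' @param direction per-cohort effect signs (+1/-1, or the beta itself).
#' @param n per-cohort sample sizes.
#' @param log_p optional natural-log p-values (for underflowed p).
#' @return list with `z`, `p`, `log10_p`, `n_total`, `k`, `directions`.
#' @export
meta_fixed_ss <- function(p, direction, n, log_p = NULL) {
  k <- length(n)
  stopifnot(length(direction) == k, is.null(log_p) || length(log_p) == k)
  if (is.null(log_p) && any(p <= 0))
    stop("p = 0 must be supplied on the log scale (log_p)")
  z <- z_from_p(p, direction, log_p)
  Z <- sum(sqrt(n) * z) / sqrt(sum(n))
  pp <- p_from_z(Z)
  list(z = Z, p = pp$p, log10_p = pp$log_p / log(10),
       n_total = sum(n), k = k,
       directions = paste(ifelse(sign(direction) >= 0, "+", "-"), collapse = ""))
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' @param beta per-cohort effect estimates (harmonized).
#' @param se per-cohort standard errors (> 0).
#' @return list with `beta`, `se`, `z`, `p`, `log10_p`, `k`.
#' @export
meta_fixed_iv <- function(beta, se) {
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  pp <- p_from_z(z)
  list(beta = b, se = s, z = z, p = pp$p, log10_p = pp$log_p / log(10),
       k = length(beta))
}

#' Cochran's Q and I-squared heterogeneity
#'
#' `Q = sum w_i (beta_i - beta_pooled)^2` with inverse-variance weights;
#' `I2 = max(0, (Q - (k-1)) / Q) * 100`.
#'
#' @param beta,se per-cohort effects and standard errors (k >= 2), or
#' @param q,k a precomputed Q statistic with its cohort count.
#' @return list with `q`, `q_df`, `i2` (percent), `p_q`.
#' @export
heterogeneity <- function(beta = NULL, se = NULL, q = NULL, k = NULL) {
  if (is.null(q)) {
    if (length(beta) < 2) stop("heterogeneity needs at least 2 cohorts")
    if (any(se <= 0)) stop("all standard errors must be positive")
    w <- 1 / se^2
    b <- sum(w * beta) / sum(w)
    q <- sum(w * (beta - b)^2)
    k <- length(beta)
  }
  if (k < 2) stop("heterogeneity needs at least 2 cohorts")
  df <- k - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  list(q = q, q_df = df, i2 = i2,
       p_q = pchisq(q, df, lower.tail = FALSE))
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Between-study variance `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 /
#' sum w))` with fixed-effect weights, then inverse-variance pooling with
#' weights `1 / (se_i^2 + tau2)`.
#'
#' @inheritParams meta_fixed_iv
#' @return list with `beta`, `se`, `z`, `p`, `tau2`, `k`.
#' @export
meta_random_dl <- function(beta, se) {
  if (length(beta) < 2) stop("random-effects meta needs at least 2 cohorts")
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  het <- heterogeneity(beta, se)
  tau2 <- max(0, (het$q - (length(beta) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  b <- sum(wr * beta) / sum(wr)
  s <- 1 / sqrt(sum(wr))
  z <- b / s
  pp <- p_from_z(z)
  list(beta = b, se = s, z = z, p = pp$p, log10_p = pp$log_p / log(10),
       tau2 = tau2, k = length(beta))
}

#' Meta-analyze a set of harmonized cohort summary-statistic tables
#'
#' Runs both fixed-effects schemes plus heterogeneity (and the
#' DerSimonian-Laird random-effects fallback) per shared variant.
#'
#' @param cohorts named list of harmonized summary-stat data.frames (see
#'   [harmonize_effects]).
#' @return data.frame, one row per variant: both fixed-effect results,
#'   Q/I2, random-effects result, total N and a METAL-style direction
#'   string.
#' @export
meta_analyze <- function(cohorts) {
  ids <- Reduce(intersect, lapply(cohorts, function(d) d$ID))
  rows <- lapply(ids, function(v) {
    recs <- lapply(cohorts, function(d) d[d$ID == v, ])
    beta <- sapply(recs, `[[`, "BETA")
    se <- sapply(recs, `[[`, "SE")
    p <- sapply(recs, `[[`, "P")
    n <- sapply(recs, `[[`, "N")
    ss <- meta_fixed_ss(p, sign(beta), n)
    iv <- meta_fixed_iv(beta, se)
    het <- if (length(beta) >= 2) heterogeneity(beta, se)
           else list(q = NA_real_, q_df = NA_integer_, i2 = NA_real_, p_q = NA_real_)
    re <- if (length(beta) >= 2) meta_random_dl(beta, se)
          else list(beta = beta, se = se, p = p)
    data.frame(ID = v, CHR = recs[[1]]$CHR, POS = recs[[1]]$POS,
               EA = recs[[1]]$EA, OA = recs[[1]]$OA,
               BETA_FIXED = iv$beta, SE_FIXED = iv$se, P_FIXED = iv$p,
               Z_SS = ss$z, P_SS = ss$p, N = ss$n_total,
               Q = het$q, Q_DF = het$q_df, I2 = het$i2, P_Q = het$p_q,
               BETA_RANDOM = re$beta, SE_RANDOM = re$se, P_RANDOM = re$p,
               DIRECTIONS = ss$directions, K = length(beta),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$CHR, out$POS), ]
}
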