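#' Fine-mapping configuration
#'
#' @param window_halfwidth bp flanking the lead variant on each side
#'   (default 500 kb, i.e. a 1 Mb locus).
#' @param credible_mass cumulative posterior mass the credible set must
#'   strictly exceed (default 0.99).
#' @param prior_w prior variance W of the true effect under the alternative
#'   (default 0.04, prior SD 0.2 phenotype units).
#' @export
finemap_config <- function(window_halfwidth = 5e5, credible_mass = 0.99,
                           prior_w = 0.04) {
  if (credible_mass <= 0 || credible_mass >= 1)
    stop("credible_mass must lie strictly in (0,1)")
  if (prior_w <= 0) stop("prior_w must be positive")
  structure(list(window_halfwidth = window_halfwidth,
                 credible_mass = credible_mass, prior_w = prior_w),
            class = "finemap_config")
}

#' Restrict summary statistics to the locus window around a lead variant
#'
#' Keeps variants on the lead variant's chromosome within
#' `window_halfwidth` bp of it (closed interval at the boundary).
#'
#' @param records summary-stat data.frame (`ID CHR POS ...`).
#' @param top lead variant id (must be present).
#' @param config a [finemap_config].
#' @export
locus_window <- function(records, top, config = finemap_config()) {
  i <- match(top, records$ID)
  if (is.na(i)) stop("lead variant ", top, " not found")
  keep <- records$CHR == records$CHR[i] &
    abs(records$POS - records$POS[i]) <= config$window_halfwidth
  records[keep, , drop = FALSE]
}

#' Approximate Bayes factor for association
#'
#' The single-causal-variant normal-normal approximation: with observed
#' effect variance `V = se^2` and prior effect variance `W`,
#' `BF = sqrt(V / (V + W)) * exp(z^2 W / (2 (V + W)))` in favor of
#' association. Computed and returned on the natural-log scale.
#'
#' @param beta,se effect estimate and standard error (se > 0).
#' @param prior_w prior effect variance W.
#' @return natural-log Bayes factor (vectorized).
#' @export
approx_bf <- function(beta, se, prior_w = 0.04) {
  if (any(se <= 0)) stop("se must be positive")
  v <- se^2
  z <- beta / se
  0.5 * log(v / (v + prior_w)) + z^2 * prior_w / (2 * (v + prior_w))
}

#' Credible set from per-locus Bayes factors
#'
#' Posterior causal probability of each variant is its BF divided by the
#' locus BF sum (log-sum-exp). Variants are ranked by descending posterior
#' (ties broken by position, then id); the smallest prefix whose cumulative
#' posterior strictly exceeds `credible_mass` forms the credible set.
#'
#' @param log_bf natural-log Bayes factors.
#' @param id variant ids.
#' @param pos physical positions (tie-break; defaults to input order).
#' @param credible_mass target mass (default 0.99).
#' @return data.frame: id, log_bf, posterior, rank, in_credible_set, sorted
#'   by rank.
#' @export
credible_set <- function(log_bf, id, pos = seq_along(log_bf),
                         credible_mass = 0.99) {
  if (length(log_bf) == 0) stop("empty locus")
  if (any(!is.finite(log_bf))) stop("non-finite log Bayes factor")
  lse <- max(log_bf) + log(sum(exp(log_bf - max(log_bf))))
  posterior <- exp(log_bf - lse)
  o <- order(-posterior, pos, id)
  cum <- cumsum(posterior[o])
  m <- which(cum > credible_mass)[1]
  if (is.na(m)) m <- length(o)     # numerical guard: mass sums to 1
  out <- data.frame(id = id[o], pos = pos[o], log_bf = log_bf[o],
                    posterior = posterior[o], rank = seq_along(o),
                    in_credible_set = seq_along(o) <= m,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fine-map one locus from summary statistics
#'
#' Convenience wrapper: [locus_window] then [approx_bf] then
#' [credible_set].
#'
#' @param records summary-stat data.frame (`ID CHR POS BETA SE ...`).
#' @param top lead variant id.
#' @param config a [finemap_config].
#' @export
finemap_locus <- function(records, top, config = finemap_config()) {
  win <- locus_window(records, top, config)
  lbf <- approx_bf(win$BETA, win$SE, config$prior_w)
  credible_set(lbf, win$ID, win$POS, config$credible_mass)
}
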