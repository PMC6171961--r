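#' Extended haplotype homozygosity profile around a core allele
#'
#' Haplotypes carrying the core allele are partitioned by their extended
#' haplotype from the core to each flanking site; EHH at that site is
#' `sum_h C(n_h, 2) / C(n_c, 2)` over partition groups. The profile extends
#' outward until EHH drops below `cutoff` (the first sub-cutoff point is
#' included) or the chromosome end is reached, in which case the side is
#' flagged truncated.
#'
#' @param panel a [haplotype_panel].
#' @param core variant id or site index of the core SNP.
#' @param allele core allele code: 0 or 1, or `"ancestral"` / `"derived"`
#'   (requires ancestral codes in the panel).
#' @param cutoff EHH decay boundary (default 0.05).
#' @return object of class `ehh_profile`: offsets (signed cM, 0 at core),
#'   ehh values, site indices, truncation flags, carrier count.
#' @export
ehh_profile <- function(panel, core, allele = 1, cutoff = 0.05) {
  j <- if (is.character(core)) match(core, panel$id) else as.integer(core)
  if (is.na(j) || j < 1 || j > ncol(panel$haps)) stop("core variant not found")
  if (is.character(allele)) {
    if (is.null(panel$anc)) stop("panel has no ancestral allele codes")
    allele <- switch(allele,
                     ancestral = panel$anc[j],
                     derived = 1L - panel$anc[j],
                     stop("allele must be 0, 1, 'ancestral' or 'derived'"))
  }
  res <- .ehh_core_cpp(panel$haps, j - 1L, as.integer(allele), cutoff)
  lefts <- res$left_sites + 1L
  rights <- res$right_sites + 1L
  structure(list(core_id = panel$id[j], core_site = j, allele = allele,
                 n_carriers = res$n_carriers,
                 sites = c(rev(lefts), j, rights),
                 offsets = c(rev(panel$cm[lefts]), panel$cm[j],
                             panel$cm[rights]) - panel$cm[j],
                 ehh = c(rev(res$left_ehh), 1, res$right_ehh),
                 truncated_left = res$truncated_left,
                 truncated_right = res$truncated_right),
            class = "ehh_profile")
}

#' @export
print.ehh_profile <- function(x, ...) {
  cat(sprintf("ehh_profile: core %s allele %d, %d carriers, %d points%s\n",
              x$core_id, x$allele, x$n_carriers, length(x$ehh),
              if (x$truncated_left || x$truncated_right) " (truncated)" else ""))
  invisible(x)
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Integrated haplotype homozygosity
#'
#' Trapezoidal integral of the EHH profile against genetic distance (cM),
#' computed separately left and right of the core out to and including the
#' first point with EHH below the decay cutoff; `ihh = left + right`.
#'
#' @param profile an [ehh_profile].
#' @return list with `ihh`, `left`, `right` (cM units).
#' @export
integrate_ihh <- function(profile) {
  stopifnot(inherits(profile, "ehh_profile"))
  core <- which(profile$offsets == 0)[1]
  lo <- profile$offsets[seq_len(core)]
  le <- profile$ehh[seq_len(core)]
  ro <- profile$offsets[core:length(profile$offsets)]
  re <- profile$ehh[core:length(profile$ehh)]
  if (is.unsorted(le) || is.unsorted(rev(re)))
    stop("EHH profile must be non-increasing away from the core")
  left <- if (core > 1) trapezoid(lo, le) else 0
  right <- if (core < length(profile$offsets)) trapezoid(ro, re) else 0
  list(ihh = left + right, left = left, right = right)
}

#' Genome-wide iHS scan
#'
#' For each site with derived-allele frequency in `[min_daf, 1 - min_daf]`,
#' the unstandardized score is `ln(iHH_ancestral / iHH_derived)`. Scores
#' are standardized to mean 0, SD 1 within derived-allele-frequency bins of
#' width `bin_width`; two-sided p-values assume the standardized scores are
#' standard normal under neutrality. Sites with truncated EHH profiles or
#' profiles spanning a physical gap larger than `max_gap_bp` are excluded
#' from standardization and flagged.
#'
#' @param panel a [haplotype_panel] with ancestral allele codes.
#' @param min_daf frequency bounds for scored sites (default 0.05).
#' @param max_gap_bp maximum physical gap a profile may span (default
#'   200 kb).
#' @param bin_width derived-allele-frequency bin width (default 0.05).
#' @param min_bin minimum variants per bin; thinner bins are merged with
#'   their neighbor (default 20).
#' @param cutoff EHH decay boundary (default 0.05).
#' @return data.frame, one row per site in frequency range: id, daf,
#'   ihh_a, ihh_d, ihs_u, bin, ihs_s, p, flag ("ok", "truncated",
#'   "gap", "no_variation").
#' @export
ihs_scan <- function(panel, min_daf = 0.05, max_gap_bp = 2e5,
                     bin_width = 0.05, min_bin = 20, cutoff = 0.05) {
  if (is.null(panel$anc)) stop("iHS needs ancestral allele codes")
  daf <- panel_daf(panel)
  use <- which(daf >= min_daf & daf <= 1 - min_daf)
  if (length(use) == 0) stop("no sites pass the frequency filter")

  rows <- lapply(use, function(j) {
    out <- data.frame(id = panel$id[j], site = j, pos = panel$pos[j],
                      daf = daf[j], ihh_a = NA_real_, ihh_d = NA_real_,
                      ihs_u = NA_real_, flag = "ok", stringsAsFactors = FALSE)
    pa <- try(ehh_profile(panel, j, "ancestral", cutoff), silent = TRUE)
    pd <- try(ehh_profile(panel, j, "derived", cutoff), silent = TRUE)
    if (inherits(pa, "try-error") || inherits(pd, "try-error")) {
      out$flag <- "no_variation"
      return(out)
    }
    trunc <- pa$truncated_left || pa$truncated_right ||
      pd$truncated_left || pd$truncated_right
    gap <- max(profile_gap(panel, pa), profile_gap(panel, pd))
    ia <- integrate_ihh(pa)$ihh
    id_ <- integrate_ihh(pd)$ihh
    out$ihh_a <- ia
    out$ihh_d <- id_
    if (ia > 0 && id_ > 0) out$ihs_u <- log(ia / id_)
    if (trunc) out$flag <- "truncated"
    else if (gap > max_gap_bp) out$flag <- "gap"
    else if (ia == 0 || id_ == 0) out$flag <- "no_variation"
    out
  })
  res <- do.call(rbind, rows)
  res$bin <- pmin(floor(res$daf / bin_width), 1 / bin_width - 1)

  ok <- res$flag == "ok" & is.finite(res$ihs_u)
  res$ihs_s <- NA_real_
  res$p <- NA_real_
  bin_params <- NULL
  if (any(ok)) {
    merged <- merge_bins(res$bin[ok], min_bin)
    res$std_bin <- NA_integer_
    res$std_bin[ok] <- merged
    bp <- lapply(sort(unique(merged)), function(b) {
      sel <- which(ok)[merged == b]
      data.frame(group = b, bin_lo = min(res$bin[sel]),
                 bin_hi = max(res$bin[sel]),
                 mean = mean(res$ihs_u[sel]), sd = sd(res$ihs_u[sel]),
                 n = length(sel))
    })
    bin_params <- do.call(rbind, bp)
    for (i in seq_len(nrow(bin_params))) {
      sel <- which(ok)[merged == bin_params$group[i]]
      if (!is.na(bin_params$sd[i]) && bin_params$sd[i] > 0)
        res$ihs_s[sel] <- (res$ihs_u[sel] - bin_params$mean[i]) / bin_params$sd[i]
    }
    res$p <- 2 * pnorm(-abs(res$ihs_s))
  }
  rownames(res) <- NULL
  attr(res, "bin_params") <- bin_params
  res
}

#' Standardize unstandardized iHS against reference bin parameters
#'
#' Applies the frequency-bin means and SDs estimated by [ihs_scan] on a
#' reference (e.g. genome-wide, predominantly neutral) panel to scores from
#' another region, mirroring the genome-wide empirical standardization used
#' in practice.
#'
#' @param ihs_u unstandardized scores.
#' @param daf derived-allele frequencies of the scored sites.
#' @param bin_params the `bin_params` attribute of a reference [ihs_scan]
#'   result.
#' @param bin_width frequency bin width the reference used (default 0.05).
#' @export
ihs_standardize <- function(ihs_u, daf, bin_params, bin_width = 0.05) {
  bin <- pmin(floor(daf / bin_width), round(1 / bin_width) - 1)
  out <- rep(NA_real_, length(ihs_u))
  for (i in seq_along(ihs_u)) {
    row <- which(bin_params$bin_lo <= bin[i] & bin_params$bin_hi >= bin[i])
    if (length(row) == 0) row <- which.min(pmin(abs(bin_params$bin_lo - bin[i]),
                                                abs(bin_params$bin_hi - bin[i])))
    row <- row[1]
    if (bin_params$sd[row] > 0)
      out[i] <- (ihs_u[i] - bin_params$mean[row]) / bin_params$sd[row]
  }
  out
}

# largest physical gap between consecutive sites covered by a profile
profile_gap <- function(panel, profile) {
  s <- sort(profile$sites)
  if (length(s) < 2) return(0)
  max(diff(panel$pos[s]))
}

# merge adjacent frequency bins (left to right) until every merged group
# holds >= min_bin members; a small final group joins its predecessor
merge_bins <- function(bin, min_bin) {
  ub <- sort(unique(bin))
  counts <- as.integer(table(factor(bin, levels = ub)))
  group <- integer(length(ub))
  g <- 1L
  acc <- 0L
  for (i in seq_along(ub)) {
    group[i] <- g
    acc <- acc + counts[i]
    if (acc >= min_bin && i < length(ub)) {
      g <- g + 1L
      acc <- 0L
    }
  }
  if (acc < min_bin && acc > 0 && g > 1L) group[group == g] <- g - 1L
  unname(group[match(bin, ub)])
}

#' Empirical |score| significance threshold
#'
#' The absolute-score quantile at the given level (default the top 0.1%),
#' with the variants exceeding it.
#'
#' @param scores standardized scores (NA dropped).
#' @param quantile_level tail quantile (default 0.999).
#' @return list with `cutoff`, `n_hits` (strict exceedances), `hits`
#'   (indices into `scores`).
#' @export
empirical_threshold <- function(scores, quantile_level = 0.999) {
  keep <- which(is.finite(scores))
  if (length(keep) == 0) stop("no finite scores")
  if (length(keep) < 1000)
    warning("fewer than 1000 scores; the extreme-tail quantile is unstable")
  a <- abs(scores[keep])
  cutoff <- unname(quantile(a, quantile_level, type = 7))
  hits <- keep[a > cutoff]
  list(cutoff = cutoff, n_hits = length(hits), hits = hits)
}
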