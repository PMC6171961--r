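#' Phased haplotype panel
#'
#' The central genotype container: a matrix of phased binary alleles
#' (rows = haplotypes, columns = sites; rows `2i-1` and `2i` are the two
#' haplotypes of diploid individual `i`), together with per-site metadata.
#' Alleles are coded 0 (reference/ancestral as written) and 1 (alternate).
#'
#' @param haps integer matrix of 0/1 alleles, `2N x L`.
#' @param pos integer vector of 1-based physical positions (bp), ascending.
#' @param chrom chromosome label (single string).
#' @param id variant identifiers; defaults to `chrom:pos`.
#' @param ref,alt allele strings per site.
#' @param cm genetic-map position per site in centimorgans, non-decreasing;
#'   defaults to `pos * 1e-6` (1 cM/Mb).
#' @param anc ancestral allele code per site (0 or 1), or `NULL` if unknown.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haps, pos, chrom = "1", id = NULL,
                            ref = NULL, alt = NULL, cm = NULL, anc = NULL) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  L <- ncol(haps)
  if (nrow(haps) %% 2L != 0L)
    stop("haplotype count must be even (phased diploids)")
  if (anyNA(haps)) stop("missing alleles not allowed in a haplotype panel")
  if (!all(haps %in% c(0L, 1L))) stop("alleles must be coded 0/1")
  pos <- as.integer(pos)
  if (length(pos) != L) stop("pos length must equal site count")
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must be strictly ascending")
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("G", L)
  if (is.null(cm)) cm <- pos * 1e-6
  if (is.unsorted(cm)) stop("cm must be non-decreasing")
  if (!is.null(anc) && !all(anc %in% c(0L, 1L)))
    stop("ancestral allele codes must be 0 or 1")
  structure(list(haps = haps, chrom = as.character(chrom)[1], pos = pos,
                 id = as.character(id), ref = as.character(ref),
                 alt = as.character(alt), cm = as.numeric(cm),
                 anc = if (is.null(anc)) NULL else as.integer(anc)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes (%d diploids) x %d sites, chr%s:%d-%d\n",
              nrow(x$haps), nrow(x$haps) / 2, ncol(x$haps), x$chrom,
              min(x$pos), max(x$pos)))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$haps)

#' Number of diploid individuals in a panel
#' @param panel a `haplotype_panel`.
#' @export
n_individuals <- function(panel) nrow(panel$haps) / 2L

#' Per-individual allele dosages
#'
#' Collapses the two haplotypes of each individual into a 0/1/2 count of the
#' alternate (code 1) allele.
#'
#' @param panel a `haplotype_panel`.
#' @return `N x L` integer matrix with variant ids as column names.
#' @export
panel_dosages <- function(panel) {
  h <- panel$haps
  d <- h[seq(1, nrow(h), by = 2L), , drop = FALSE] +
       h[seq(2, nrow(h), by = 2L), , drop = FALSE]
  colnames(d) <- panel$id
  d
}

#' Alternate-allele frequency per site
#' @param panel a `haplotype_panel`.
#' @export
panel_freq <- function(panel) setNames(colMeans(panel$haps), panel$id)

#' Derived-allele frequency per site
#'
#' Requires ancestral allele codes; the derived allele is the non-ancestral
#' one.
#' @param panel a `haplotype_panel` with `anc` set.
#' @export
panel_daf <- function(panel) {
  if (is.null(panel$anc)) stop("panel has no ancestral allele codes")
  p1 <- colMeans(panel$haps)
  setNames(ifelse(panel$anc == 0L, p1, 1 - p1), panel$id)
}

#' Resample diploid individuals from a panel
#'
#' Draws `n` individuals by pairing haplotypes sampled with replacement from
#' the panel (random union of gametes), emulating a cohort sampled from the
#' population the panel represents.
#'
#' @param panel a `haplotype_panel`.
#' @param n number of diploid individuals to draw.
#' @return a new `haplotype_panel` with `2n` haplotype rows.
#' @export
sample_individuals <- function(panel, n) {
  rows <- sample.int(nrow(panel$haps), 2L * n, replace = TRUE)
  haplotype_panel(panel$haps[rows, , drop = FALSE], panel$pos, panel$chrom,
                  panel$id, panel$ref, panel$alt, panel$cm, panel$anc)
}

#' Subset a panel by site index
#' @param panel a `haplotype_panel`.
#' @param sites integer or logical index over sites.
#' @export
subset_sites <- function(panel, sites) {
  haplotype_panel(panel$haps[, sites, drop = FALSE], panel$pos[sites],
                  panel$chrom, panel$id[sites], panel$ref[sites],
                  panel$alt[sites], panel$cm[sites],
                  if (is.null(panel$anc)) NULL else panel$anc[sites])
}
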