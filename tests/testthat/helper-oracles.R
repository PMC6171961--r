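# Independent oracles and small fixture builders shared across tests.

# Brute-force EHH: materialize the substring from the core to each flanking
# site for every carrier and count identical strings. Independent of the
# package's partition-refinement walk.
brute_ehh <- function(haps, core, allele, cutoff = 0.05) {
  carriers <- which(haps[, core] == allele)
  nc <- length(carriers)
  stopifnot(nc >= 2)
  denom <- choose(nc, 2)
  one_side <- function(dir) {
    sites <- integer(0); ehh <- numeric(0); truncated <- TRUE
    j <- core + dir
    while (j >= 1 && j <= ncol(haps)) {
      rng <- if (dir < 0) j:core else core:j
      key <- apply(haps[carriers, rng, drop = FALSE], 1, paste, collapse = "")
      e <- sum(choose(table(key), 2)) / denom
      sites <- c(sites, j); ehh <- c(ehh, e)
      if (e < cutoff) { truncated <- FALSE; break }
      j <- j + dir
    }
    list(sites = sites, ehh = ehh, truncated = truncated)
  }
  list(left = one_side(-1L), right = one_side(1L))
}

# random 0/1 panel with strictly ascending positions
random_panel <- function(n_hap, n_sites, seed = NULL, maf_min = 0) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    h <- matrix(rbinom(n_hap * n_sites, 1, runif(n_sites, 0.1, 0.9)[rep(seq_len(n_sites), each = n_hap)]),
                nrow = n_hap)
    f <- colMeans(h)
    if (all(pmin(f, 1 - f) >= maf_min)) break
  }
  pos <- sort(sample.int(n_sites * 1000L, n_sites))
  haplotype_panel(h, pos, anc = rep(0L, n_sites))
}

# write a small phased VCF by hand (independent of write_haplotypes)
write_fixture_vcf <- function(path, body_lines, samples = c("S1", "S2", "S3")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}

vcf_line <- function(pos, id, ref, alt, gts) {
  paste(c("1", pos, id, ref, alt, ".", "PASS", ".", "GT", gts), collapse = "\t")
}
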