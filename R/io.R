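#' Read phased haplotypes from a VCF
#'
#' Parses a VCF 4.x file with phased `GT` fields into a [haplotype_panel].
#' Only biallelic SNVs are retained; multiallelic sites are skipped with a
#' warning. Unphased or missing genotypes are errors: downstream haplotype
#' statistics (EHH/iHS) require complete phased data.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param region optional `"chrom:start-end"` restriction (1-based, closed).
#' @param map optional [genetic_map] used to assign centimorgan coordinates;
#'   default 1 cM/Mb.
#' @return a [haplotype_panel]; haplotype rows are ordered sample-major
#'   (sample 1 hap 1, sample 1 hap 2, sample 2 hap 1, ...).
#' @export
read_haplotypes <- function(path, region = NULL, map = NULL) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  nalt <- S4Vectors::elementNROWS(altl)

  keep <- nalt == 1L
  if (any(!keep)) {
    warning(sprintf("skipping %d multiallelic site(s): %s", sum(!keep),
                    paste(utils::head(rownames(gt)[!keep], 5), collapse = ", ")))
  }
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    keep <- keep & chrom == m[2] & pos >= as.integer(m[3]) & pos <= as.integer(m[4])
  }
  if (!any(keep)) stop("no biallelic sites retained")
  gt <- gt[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]
  alt <- as.character(unlist(altl[keep]))
  ids <- rownames(gt)

  if (length(unique(chrom)) > 1) stop("panel must be single-chromosome; use region=")
  o <- order(pos)
  gt <- gt[o, , drop = FALSE]
  pos <- pos[o]; ref <- ref[o]; alt <- alt[o]; ids <- ids[o]

  bad <- which(matrix(!grepl("^[01]\\|[01]$", gt), nrow = nrow(gt)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("unphased or missing GT '%s' at site %s (sample %s)",
                 gt[i, j], ids[i], colnames(gt)[j]))
  }
  a1 <- substr(gt, 1L, 1L) == "1"
  a2 <- substr(gt, 3L, 3L) == "1"
  nsamp <- ncol(gt)
  haps <- matrix(0L, nrow = 2L * nsamp, ncol = nrow(gt))
  haps[seq(1, 2 * nsamp, by = 2), ] <- t(a1) + 0L
  haps[seq(2, 2 * nsamp, by = 2), ] <- t(a2) + 0L
  rownames(haps) <- paste0(rep(colnames(gt), each = 2), "_", c(1, 2))

  cm <- if (is.null(map)) pos * 1e-6 else interpolate_cm(map, pos)
  haplotype_panel(haps, pos, chrom[1], ids, ref, alt, cm)
}

#' Write a haplotype panel as a phased VCF 4.2 file
#'
#' @param panel a [haplotype_panel].
#' @param path output path.
#' @param sample_names optional diploid sample names; default `S1..SN`.
#' @export
write_haplotypes <- function(panel, path, sample_names = NULL) {
  n <- n_individuals(panel)
  if (is.null(sample_names)) sample_names <- paste0("S", seq_len(n))
  stopifnot(length(sample_names) == n)
  h <- panel$haps
  g1 <- h[seq(1, 2 * n, by = 2), , drop = FALSE]
  g2 <- h[seq(2, 2 * n, by = 2), , drop = FALSE]
  gt <- matrix(paste0(t(g1), "|", t(g2)), nrow = ncol(h))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", panel$chrom),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_names), collapse = "\t"))
  body <- paste(panel$chrom, panel$pos, panel$id, panel$ref, panel$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

SUMSTAT_COLS <- c("ID", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")

#' Read GWAS summary statistics
#'
#' Expects the tab-separated dialect `ID CHR POS EA OA EAF BETA SE P N`.
#' @param path file path.
#' @return data.frame of association records.
#' @export
read_sumstats <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(ID = "character", CHR = "character",
                                 EA = "character", OA = "character"))
  missing <- setdiff(SUMSTAT_COLS, names(d))
  if (length(missing) > 0)
    stop("summary-stat file lacks columns: ", paste(missing, collapse = ", "))
  d[, SUMSTAT_COLS]
}

#' Write GWAS summary statistics
#' @param records data.frame with the summary-stat columns.
#' @param path output path.
#' @export
write_sumstats <- function(records, path) {
  cols <- intersect(SUMSTAT_COLS, names(records))
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a whitespace-separated covariate/phenotype table
#'
#' PLINK-style: a header line followed by one row per individual; the first
#' column is the individual id.
#' @param path file path.
#' @export
read_covariates <- function(path) {
  read.table(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Read a long-format multi-population allele-frequency table
#'
#' Columns `ID POP FREQ NHAP`: effect/derived-allele frequency and haplotype
#' count per variant per population.
#' @param path file path.
#' @return list with `freq` (variants x populations matrix) and `nhap`
#'   (named vector of haplotype counts per population).
#' @export
read_freq_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("ID", "POP", "FREQ", "NHAP")
  if (!all(need %in% names(d))) stop("frequency table needs columns ID POP FREQ NHAP")
  pops <- unique(d$POP); ids <- unique(d$ID)
  f <- matrix(NA_real_, length(ids), length(pops), dimnames = list(ids, pops))
  f[cbind(match(d$ID, ids), match(d$POP, pops))] <- d$FREQ
  nhap <- sapply(pops, function(p) d$NHAP[d$POP == p][1])
  list(freq = f, nhap = nhap)
}

#' Write a run manifest
#'
#' Records package version, R version, seed, timestamp and the parameters of
#' a pipeline stage as JSON, so every output directory is self-describing.
#'
#' @param path output JSON path.
#' @param stage stage name.
#' @param params named list of parameters.
#' @param seed RNG seed used (or `NULL`).
#' @export
write_manifest <- function(path, stage, params = list(), seed = NULL) {
  manifest <- list(stage = stage,
                   package = "ordgwas",
                   version = as.character(packageVersion("ordgwas")),
                   r_version = R.version.string,
                   seed = seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   params = params)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
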