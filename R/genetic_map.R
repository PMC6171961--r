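#' Genetic map
#'
#' Physical-to-genetic coordinate lookup with a piecewise-linear
#' interpolation contract. Positions outside the mapped range are
#' extrapolated with the slope of the terminal interval (constant recombination
#' rate beyond the map ends).
#'
#' @param positions ascending physical positions (bp).
#' @param cm centimorgan values, non-decreasing, same length.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(positions, cm) {
  positions <- as.numeric(positions)
  cm <- as.numeric(cm)
  if (length(positions) != length(cm)) stop("positions and cm must have equal length")
  if (length(positions) < 2) stop("a genetic map needs at least 2 points")
  if (is.unsorted(positions, strictly = TRUE)) stop("positions must be strictly ascending")
  if (is.unsorted(cm)) stop("cm must be non-decreasing in position")
  structure(list(positions = positions, cm = cm), class = "genetic_map")
}

#' Interpolate genetic-map position
#'
#' @param map a `genetic_map`.
#' @param pos physical positions (bp) to convert.
#' @return centimorgan values.
#' @export
interpolate_cm <- function(map, pos) {
  stopifnot(inherits(map, "genetic_map"))
  p <- map$positions; g <- map$cm; n <- length(p)
  out <- approx(p, g, xout = pos, rule = 2)$y
  # linear extrapolation with terminal slopes beyond the map ends
  lo <- pos < p[1]
  hi <- pos > p[n]
  if (any(lo)) {
    sl <- (g[2] - g[1]) / (p[2] - p[1])
    out[lo] <- g[1] + (pos[lo] - p[1]) * sl
  }
  if (any(hi)) {
    sl <- (g[n] - g[n - 1]) / (p[n] - p[n - 1])
    out[hi] <- g[n] + (pos[hi] - p[n]) * sl
  }
  out
}

#' Read a genetic map from a two-column TSV (`POS`, `CM`)
#' @param path file path.
#' @export
read_genetic_map <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(d) <- toupper(names(d))
  genetic_map(d$POS, d$CM)
}
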