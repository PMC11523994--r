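#' Genomic bin grid
#'
#' A bin grid is the shared coordinate system for all copy-number profiles:
#' fixed-width genomic bins (default 100 kbp, the usual shallow-WGS bin size)
#' sorted by chromosome and start, with a mask of analyzable ("usable") bins.
#'
#' @param chrom character vector of chromosome labels, one per bin.
#' @param start,end 1-based inclusive bin coordinates.
#' @param usable logical mask of analyzable bins (defaults to all usable).
#' @return An object of class \code{bin_grid}: a data.frame with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{usable}.
#' @examples
#' g <- bin_grid(rep("1", 5), seq(1, by = 1e5, length.out = 5),
#'               seq(1e5, by = 1e5, length.out = 5))
#' @export
bin_grid <- function(chrom, start, end, usable = rep(TRUE, length(chrom))) {
  if (!(length(chrom) == length(start) && length(start) == length(end) &&
        length(end) == length(usable)))
    stop_input("bin_grid: chrom, start, end, usable must have equal length")
  chrom <- as.character(chrom)
  if (any(end < start)) stop_input("bin_grid: end < start")
  g <- data.frame(chrom = chrom, start = as.numeric(start),
                  end = as.numeric(end), usable = as.logical(usable),
                  stringsAsFactors = FALSE)
  # sort by (chrom in order of first appearance, start)
  chrom_levels <- unique(chrom)
  g <- g[order(match(g$chrom, chrom_levels), g$start), , drop = FALSE]
  rownames(g) <- NULL
  for (cc in chrom_levels) {
    i <- which(g$chrom == cc)
    if (length(i) > 1 && any(g$start[i][-1] <= g$end[i][-length(i)]))
      stop_input("bin_grid: overlapping bins on chromosome ", cc)
  }
  if (!any(g$usable)) stop_input("bin_grid: no usable bins")
  class(g) <- c("bin_grid", "data.frame")
  g
}

#' Regular bin grid over given chromosome sizes
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param bin_width bin width in bp (default 100,000).
#' @return A \code{\link{bin_grid}}.
#' @export
regular_grid <- function(chrom_sizes, bin_width = 1e5) {
  stopifnot(!is.null(names(chrom_sizes)), all(chrom_sizes >= bin_width))
  pieces <- lapply(names(chrom_sizes), function(cc) {
    n <- floor(chrom_sizes[[cc]] / bin_width)
    data.frame(chrom = cc,
               start = (seq_len(n) - 1) * bin_width + 1,
               end = seq_len(n) * bin_width,
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, pieces)
  bin_grid(g$chrom, g$start, g$end)
}

#' Miniature default grid for fast experiments and tests
#'
#' Three 10-Mbp chromosomes of one hundred 100-kbp bins each (300 bins).
#' @return A \code{\link{bin_grid}}.
#' @export
mini_grid <- function() {
  regular_grid(c("1" = 1e7, "2" = 1e7, "3" = 1e7))
}

#' Genome-scale grid preset
#'
#' An approximately human-scale grid: 22 autosomes plus X with lengths scaled
#' from the GRCh38 assembly, 100-kbp bins (about 30,000 bins in total).
#' @return A \code{\link{bin_grid}}.
#' @export
genome_grid <- function() {
  sizes <- c(248.9, 242.2, 198.3, 190.2, 181.5, 170.8, 159.3, 145.1,
             138.4, 133.8, 135.1, 133.3, 114.4, 107.0, 101.9, 90.3,
             83.3, 80.4, 58.6, 64.4, 46.7, 50.8, 156.0) * 1e6
  names(sizes) <- c(as.character(1:22), "X")
  regular_grid(sizes)
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("bin grid:", nrow(x), "bins on", length(unique(x$chrom)),
      "chromosomes;", sum(x$usable), "usable\n")
  invisible(x)
}

bin_width_of <- function(grid) grid$end - grid$start + 1

bin_mid <- function(grid) (grid$start + grid$end) / 2
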