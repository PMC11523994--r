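#' Read segmented copy-number profiles (SEG-like TSV)
#'
#' Reads a tab-delimited segment file with columns \code{sample}, \code{chrom},
#' \code{start}, \code{end}, \code{n_bins}, \code{seg_log2} (1-based inclusive
#' coordinates) and rasterizes each sample's segments onto the bin grid. A bin
#' belongs to the segment covering its midpoint; bins covered by no segment
#' are marked unusable for that sample. An optional \code{call} column (five
#' level calls, an extension written by \code{\link{write_seg}}) is rasterized
#' the same way.
#'
#' @param path segment file path.
#' @param grid the \code{\link{bin_grid}} to rasterize onto.
#' @param purity named numeric vector of purities per sample, or the path of a
#'   TSV with columns \code{sample}, \code{purity}.
#' @return Named list of \code{\link{cn_profile}} objects.
#' @export
read_seg <- function(path, grid, purity) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "seg_log2")
  if (!all(need %in% names(seg)))
    stop_input("read_seg: missing columns: ",
               paste(setdiff(need, names(seg)), collapse = ", "))
  if (is.character(purity) && length(purity) == 1 && file.exists(purity)) {
    pt <- utils::read.delim(purity, stringsAsFactors = FALSE)
    purity <- setNames(pt$purity, pt$sample)
  }
  seg$chrom <- as.character(seg$chrom)
  unknown <- setdiff(unique(seg$chrom), unique(grid$chrom))
  if (length(unknown) > 0)
    stop_input("read_seg: unknown chromosome(s): ", paste(unknown, collapse = ", "))
  samples <- unique(seg$sample)
  no_purity <- setdiff(samples, names(purity))
  if (length(no_purity) > 0)
    stop_input("read_seg: samples without purity: ",
               paste(no_purity, collapse = ", "))
  mids <- bin_mid(grid)
  out <- lapply(samples, function(s) {
    ss <- seg[seg$sample == s, , drop = FALSE]
    # overlapping segments are a file defect: detect per chromosome
    for (cc in unique(ss$chrom)) {
      sc <- ss[ss$chrom == cc, , drop = FALSE]
      sc <- sc[order(sc$start), , drop = FALSE]
      if (nrow(sc) > 1 && any(sc$start[-1] <= sc$end[-nrow(sc)])) {
        k <- which(sc$start[-1] <= sc$end[-nrow(sc)])[1]
        stop_input("read_seg: overlapping segments for sample ", s,
                   " at ", cc, ":", sc$start[k + 1])
      }
    }
    log2_seg <- rep(NA_real_, nrow(grid))
    call <- rep(NA_integer_, nrow(grid))
    covered <- rep(FALSE, nrow(grid))
    for (k in seq_len(nrow(ss))) {
      hit <- grid$chrom == ss$chrom[k] & mids >= ss$start[k] & mids <= ss$end[k]
      log2_seg[hit] <- ss$seg_log2[k]
      if ("call" %in% names(ss)) call[hit] <- ss$call[k]
      covered <- covered | hit
    }
    cn_profile(s, log2_obs = log2_seg, log2_seg = log2_seg, call = call,
               purity = purity[[s]], grid = grid,
               usable = covered & grid$usable)
  })
  names(out) <- samples
  out
}

#' Write profiles as a SEG-like TSV
#'
#' Run-length encodes each profile's segmented log2 (and call, when present)
#' over its usable bins, closing a segment at every change of value, call or
#' chromosome and at unusable gaps.
#'
#' @param profiles list of \code{\link{cn_profile}} objects.
#' @param grid the shared \code{\link{bin_grid}}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_seg <- function(profiles, grid, path) {
  rows <- lapply(profiles, function(pr) {
    idx <- which(pr$usable & !is.na(pr$log2_seg))
    if (length(idx) == 0) return(NULL)
    # new run whenever chrom/value/call changes or bins are non-adjacent
    brk <- c(TRUE, grid$chrom[idx][-1] != grid$chrom[idx][-length(idx)] |
               pr$log2_seg[idx][-1] != pr$log2_seg[idx][-length(idx)] |
               differs_na(pr$call[idx][-1], pr$call[idx][-length(idx)]) |
               diff(idx) != 1)
    run <- cumsum(brk)
    first <- idx[!duplicated(run)]
    last <- idx[!duplicated(run, fromLast = TRUE)]
    data.frame(sample = pr$sample_id, chrom = grid$chrom[first],
               start = grid$start[first], end = grid$end[last],
               n_bins = as.integer(tabulate(run)),
               seg_log2 = pr$log2_seg[first], call = pr$call[first],
               stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, rows)
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# elementwise "values differ", treating NA==NA as equal (for call runs)
differs_na <- function(a, b) {
  !(is.na(a) & is.na(b) | (!is.na(a) & !is.na(b) & a == b))
}

#' Read GISTIC peak regions from BED
#'
#' BED is 0-based half-open; coordinates are converted to the internal
#' 1-based inclusive convention. Columns: chrom, start, end, name (peak id),
#' direction (\code{gain}/\code{deletion}), source_cluster
#' (\code{CN-high}/\code{CN-low}).
#'
#' @param path BED file path.
#' @return A \code{\link{peak_regions}} table.
#' @export
read_peaks_bed <- function(path) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (ncol(b) < 6) stop_input("read_peaks_bed: expected 6 columns")
  names(b)[1:6] <- c("chrom", "start", "end", "peak_id", "direction",
                     "source_cluster")
  peak_regions(b$peak_id, b$chrom, b$start + 1, b$end, b$direction,
               b$source_cluster)
}

#' Write peak regions as BED (0-based half-open)
#'
#' @param peaks a \code{\link{peak_regions}} table.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- data.frame(peaks$chrom, peaks$start - 1, peaks$end, peaks$peak_id,
                    peaks$direction, peaks$source_cluster)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a samples-by-peaks matrix as TSV
#'
#' Rows are samples (first column \code{sample}), remaining columns peak ids.
#' @param x matrix with dimnames, as from \code{\link{summarize_peaks}}.
#' @param path file path.
#' @return \code{read_peak_matrix}: the matrix; \code{write_peak_matrix}: the
#'   path, invisibly.
#' @export
write_peak_matrix <- function(x, path) {
  df <- data.frame(sample = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_matrix
#' @export
read_peak_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  m
}

#' Write/read a bin grid as TSV
#'
#' @param grid a \code{\link{bin_grid}}.
#' @param path file path.
#' @return \code{read_grid}: the grid; \code{write_grid}: the path, invisibly.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  bin_grid(g$chrom, g$start, g$end, g$usable)
}
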