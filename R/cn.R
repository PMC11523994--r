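#' Copy-number profile for one sample
#'
#' Per-bin observed and segmented log2 ratios, five-level calls and tumor
#' purity for a single sample on a shared \code{\link{bin_grid}}. Calls use
#' the usual convention: -2 homozygous deletion, -1 loss, 0 neutral, +1 gain,
#' +2 amplification.
#'
#' @param sample_id sample identifier.
#' @param log2_obs observed log2 ratio per bin (may be NA on unusable bins).
#' @param log2_seg segmented log2 ratio per bin.
#' @param call integer call per bin in \{-2,...,2\} (NA allowed on unusable
#'   bins).
#' @param purity tumor cell fraction in (0, 1].
#' @param usable per-sample usable mask (defaults to the grid mask); bins not
#'   covered by any segment should be marked unusable.
#' @param grid the \code{\link{bin_grid}} the vectors are aligned to.
#' @return An object of class \code{cn_profile}.
#' @export
cn_profile <- function(sample_id, log2_obs, log2_seg, call, purity, grid,
                       usable = grid$usable) {
  n <- nrow(grid)
  if (length(log2_obs) != n || length(log2_seg) != n || length(call) != n ||
      length(usable) != n)
    stop_input("cn_profile: per-bin vectors must match the grid (", n, " bins)")
  if (!is.numeric(purity) || length(purity) != 1 || is.na(purity) ||
      purity <= 0 || purity > 1)
    stop_input("cn_profile: purity must be a single value in (0, 1]")
  bad <- !is.na(call) & !(call %in% -2:2)
  if (any(bad)) stop_input("cn_profile: calls outside {-2,...,2} for sample ",
                           sample_id)
  structure(list(sample_id = as.character(sample_id),
                 log2_obs = as.numeric(log2_obs),
                 log2_seg = as.numeric(log2_seg),
                 call = as.integer(call),
                 purity = as.numeric(purity),
                 usable = as.logical(usable) & grid$usable),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat("cn_profile", x$sample_id, "-", sum(x$usable), "usable bins, purity",
      format(x$purity, digits = 3), "\n")
  invisible(x)
}

#' Forward admixture model: expected log2 ratio of a tumor/normal mixture
#'
#' With tumor copy number \code{copies} at cellularity \code{purity}, the
#' expected observed ratio relative to diploid is
#' \code{(purity * copies + 2 * (1 - purity)) / 2}; this returns its log2,
#' floored at \code{2^-10} so deep deletions stay finite.
#'
#' @param copies tumor copy number (vector).
#' @param purity tumor cell fraction in (0, 1].
#' @return log2 ratio vector.
#' @seealso \code{\link{purity_correct}}, its inverse on the log2 scale.
#' @export
mix_log2 <- function(copies, purity) {
  check_purity(purity)
  log2(pmax(2^-10, (purity * copies + 2 * (1 - purity)) / 2))
}

check_purity <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_input("purity must lie in (0, 1]")
  invisible(p)
}

#' Purity correction of log2 ratios
#'
#' Inverts the tumor/normal admixture model \code{2^r = p * 2^q + (1 - p)}
#' where \code{r} is the observed log2 ratio, \code{p} the tumor purity and
#' \code{q} the tumor-intrinsic log2 ratio:
#' \deqn{q = \log_2(\max(\epsilon, (2^r - (1-p)) / p))}
#' with floor \eqn{\epsilon = 2^{-10}} keeping the logarithm defined at deep
#' deletions in low-purity samples. At \code{p = 1} the correction is the
#' identity, and a neutral ratio (\code{r = 0}) is a fixed point for any
#' purity.
#'
#' @param r observed log2 ratio(s); finite.
#' @param p tumor purity in (0, 1].
#' @param floor lower floor on the corrected linear ratio (default 2^-10).
#' @return Corrected log2 ratio(s).
#' @export
purity_correct <- function(r, p, floor = 2^-10) {
  check_purity(p)
  out <- log2(pmax(floor, (2^r - (1 - p)) / p))
  out[is.na(r)] <- NA_real_
  out
}

#' Peak region table
#'
#' GISTIC-style recurrent aberration peaks. Coordinates are stored 1-based
#' inclusive; use \code{\link{read_peaks_bed}} for BED (0-based half-open)
#' input.
#'
#' @param peak_id identifiers.
#' @param chrom,start,end 1-based inclusive coordinates.
#' @param direction \code{"gain"} or \code{"deletion"}.
#' @param source_cluster \code{"CN-high"} or \code{"CN-low"}: the reference
#'   cluster in which the peak recurred.
#' @return Object of class \code{peak_regions} (a data.frame).
#' @export
peak_regions <- function(peak_id, chrom, start, end, direction, source_cluster) {
  if (any(end < start)) stop_input("peak_regions: end < start")
  if (!all(direction %in% c("gain", "deletion")))
    stop_input("peak_regions: direction must be 'gain' or 'deletion'")
  if (!all(source_cluster %in% c("CN-high", "CN-low")))
    stop_input("peak_regions: source_cluster must be 'CN-high' or 'CN-low'")
  if (anyDuplicated(peak_id)) stop_input("peak_regions: duplicated peak_id")
  p <- data.frame(peak_id = as.character(peak_id), chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end),
                  direction = direction, source_cluster = source_cluster,
                  stringsAsFactors = FALSE)
  class(p) <- c("peak_regions", "data.frame")
  p
}

is_sex_chrom <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE)) %in% c("X", "Y")
}

#' Drop peaks on sex chromosomes
#'
#' Removes peaks on chromosome X (and Y, if present) before classification,
#' since X-linked log2 ratios are confounded by patient sex. Reports the
#' number removed.
#'
#' @param peaks a \code{\link{peak_regions}} table.
#' @return The filtered \code{peak_regions} table.
#' @export
filter_autosomal_peaks <- function(peaks) {
  drop <- is_sex_chrom(peaks$chrom)
  message("filter_autosomal_peaks: removed ", sum(drop), " of ", nrow(peaks),
          " peaks on sex chromosomes; ", sum(!drop), " remain")
  out <- peaks[!drop, , drop = FALSE]
  if (nrow(out) == 0) warning("filter_autosomal_peaks: no peaks remain")
  rownames(out) <- NULL
  out
}

#' Peak-level summary matrix of corrected log2 values
#'
#' For each sample and peak region, the length-weighted mean of the
#' purity-corrected segmented log2 ratio over the usable bins overlapping the
#' peak. Peaks overlapping no usable bin get \code{NA}. This is the feature
#' matrix the GS/CIN nearest-centroid classifier operates on.
#'
#' @param profiles list of \code{\link{cn_profile}} objects on one grid.
#' @param peaks a \code{\link{peak_regions}} table.
#' @param grid the shared \code{\link{bin_grid}}.
#' @param correct apply \code{\link{purity_correct}} to the segmented values
#'   with each sample's purity (default TRUE).
#' @return A numeric matrix (samples x peaks) with sample ids as rownames and
#'   peak ids as colnames, in the order of the peak table.
#' @export
summarize_peaks <- function(profiles, peaks, grid, correct = TRUE) {
  missing_chr <- setdiff(unique(peaks$chrom), unique(grid$chrom))
  if (length(missing_chr) > 0)
    stop_input("summarize_peaks: peak chromosome(s) absent from grid: ",
               paste(missing_chr, collapse = ", "))
  # per-peak overlap weights against the bin grid (sample independent)
  ov <- lapply(seq_len(nrow(peaks)), function(j) {
    on_chr <- which(grid$chrom == peaks$chrom[j])
    w <- pmin(grid$end[on_chr], peaks$end[j]) -
      pmax(grid$start[on_chr], peaks$start[j]) + 1
    keep <- w > 0
    list(bins = on_chr[keep], w = w[keep])
  })
  out <- matrix(NA_real_, nrow = length(profiles), ncol = nrow(peaks),
                dimnames = list(vapply(profiles, `[[`, "", "sample_id"),
                                peaks$peak_id))
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    v <- if (correct) purity_correct(pr$log2_seg, pr$purity) else pr$log2_seg
    for (j in seq_len(nrow(peaks))) {
      b <- ov[[j]]$bins
      use <- pr$usable[b] & !is.na(v[b])
      if (any(use)) {
        w <- ov[[j]]$w[use]
        out[i, j] <- sum(w * v[b][use]) / sum(w)
      }
    }
  }
  out
}

#' Genome instability index (GII)
#'
#' The percentage of the called genome carrying a non-neutral call: the
#' summed length of usable bins with call != 0, divided by the summed length
#' of all usable bins, times 100. With equal-width bins this reduces to a
#' bin-count fraction.
#'
#' @param profile a \code{\link{cn_profile}} (or a list of them).
#' @param grid the shared \code{\link{bin_grid}}.
#' @return For a single profile, a numeric percent in \[0, 100\]; for a list, a
#'   data.frame with columns \code{sample_id} and \code{gii}.
#' @export
compute_gii <- function(profile, grid) {
  if (is.list(profile) && !inherits(profile, "cn_profile")) {
    return(data.frame(
      sample_id = vapply(profile, `[[`, "", "sample_id"),
      gii = vapply(profile, compute_gii, 0, grid = grid),
      stringsAsFactors = FALSE))
  }
  use <- profile$usable & !is.na(profile$call)
  if (!any(use)) stop_input("compute_gii: no usable called bins for sample ",
                            profile$sample_id)
  w <- bin_width_of(grid)[use]
  100 * sum(w[profile$call[use] != 0]) / sum(w)
}

#' Dichotomize GII at a cutoff
#'
#' @param gii numeric GII percentages.
#' @param cutoff cutoff g*; values <= g* are "low", values > g* "high".
#' @return factor with levels \code{low}, \code{high}.
#' @export
classify_gii <- function(gii, cutoff) {
  factor(ifelse(gii <= cutoff, "low", "high"), levels = c("low", "high"))
}
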