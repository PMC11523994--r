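#' Calls matrix across a cohort
#'
#' Stacks per-sample five-level calls into a samples-by-bins matrix restricted
#' to the bins usable in every profile (the shared analyzable genome).
#'
#' @param profiles list of \code{\link{cn_profile}} objects on one grid.
#' @param grid the shared \code{\link{bin_grid}}.
#' @return list: \code{calls} (samples x bins integer matrix), \code{bins}
#'   (grid row indices of the retained bins).
#' @export
calls_matrix <- function(profiles, grid) {
  usable <- Reduce(`&`, lapply(profiles, `[[`, "usable"), grid$usable)
  bins <- which(usable)
  if (length(bins) == 0) stop_input("calls_matrix: no commonly usable bins")
  m <- do.call(rbind, lapply(profiles, function(p) p$call[bins]))
  rownames(m) <- vapply(profiles, `[[`, "", "sample_id")
  if (anyNA(m)) stop_input("calls_matrix: NA calls on usable bins")
  list(calls = m, bins = bins)
}

#' Collapse bins into regions of near-constant call signature
#'
#' Greedy left-to-right merge of adjacent usable bins within each chromosome:
#' a bin joins the running region while the fraction of samples whose call at
#' that bin differs from the region's running signature (the per-sample modal
#' call over the region so far, ties keeping the current value) stays at or
#' below \code{tau}. Chromosome boundaries always split. This is a simplified
#' dimension-reduction in the spirit of cohort-level region finding for
#' called copy-number data.
#'
#' @param profiles list of \code{\link{cn_profile}} objects.
#' @param grid the shared \code{\link{bin_grid}}.
#' @param tau maximum tolerated fraction of samples deviating from the
#'   region signature when absorbing a bin (default 0.01).
#' @return Object of class \code{region_set}: \code{regions} (data.frame
#'   region_id, chrom, start, end, n_bins), \code{bin_region} (region index
#'   per retained bin), \code{bins} (grid row indices), \code{signature}
#'   (samples x regions matrix of per-sample modal calls).
#' @export
regionize <- function(profiles, grid, tau = 0.01) {
  cm <- calls_matrix(profiles, grid)
  calls <- cm$calls
  bins <- cm$bins
  n <- nrow(calls)
  chrom <- grid$chrom[bins]
  region_of <- integer(length(bins))
  reg <- 0L
  lev <- -2:2
  counts <- NULL   # n x 5 tally of calls in the running region
  sig <- NULL      # running per-sample modal call
  for (j in seq_along(bins)) {
    cj <- calls[, j]
    new_region <- j == 1 || chrom[j] != chrom[j - 1] ||
      mean(cj != sig) > tau
    if (new_region) {
      reg <- reg + 1L
      counts <- matrix(0L, n, 5)
      sig <- cj
    }
    counts[cbind(seq_len(n), match(cj, lev))] <-
      counts[cbind(seq_len(n), match(cj, lev))] + 1L
    # update modal signature; on ties keep the current signature value
    best <- counts[cbind(seq_len(n), match(sig, lev))]
    mx <- apply(counts, 1, max)
    upd <- mx > best
    if (any(upd))
      sig[upd] <- lev[apply(counts[upd, , drop = FALSE], 1, which.max)]
    region_of[j] <- reg
  }
  first <- !duplicated(region_of)
  last <- !duplicated(region_of, fromLast = TRUE)
  regions <- data.frame(region_id = paste0("r", seq_len(reg)),
                        chrom = chrom[first],
                        start = grid$start[bins[first]],
                        end = grid$end[bins[last]],
                        n_bins = as.integer(tabulate(region_of)),
                        stringsAsFactors = FALSE)
  signature <- vapply(seq_len(reg), function(r) {
    sub <- calls[, region_of == r, drop = FALSE]
    apply(sub, 1, function(v) {
      tab <- tabulate(match(v, lev), 5)
      lev[which.max(tab)]
    })
  }, integer(n))
  if (is.null(dim(signature))) signature <- matrix(signature, nrow = n)
  dimnames(signature) <- list(rownames(calls), regions$region_id)
  structure(list(regions = regions, bin_region = region_of, bins = bins,
                 signature = signature, tau = tau),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region set:", nrow(x$regions), "regions over", length(x$bins),
      "bins (tau =", x$tau, ")\n")
  invisible(x)
}

#' Compare regional aberration frequencies between two groups
#'
#' Per region, the samples' signatures are collapsed to sign (loss < 0,
#' neutral = 0, gain > 0) and the 2 x 3 group-by-state chi-square statistic
#' is computed. Significance comes from permuting the group labels \code{B}
#' times: \eqn{p = (1 + \#\{stat_{perm} \ge stat_{obs}\}) / (B + 1)}. The FDR
#' at each observed statistic threshold is the mean number of permutation
#' discoveries divided by the observed discoveries, clipped to \[0, 1\] and
#' made monotone in p.
#'
#' @param regions a \code{\link{regionize}} result.
#' @param groups two-level factor (or character) of group membership per
#'   sample, aligned with the signature rows or named by sample id.
#' @param B number of permutations (default 10000).
#' @param seed optional RNG seed.
#' @return data.frame of class \code{freq_compare}: per region the gain/loss
#'   frequencies per group, chi-square \code{stat}, permutation \code{p} and
#'   \code{fdr}.
#' @export
compare_groups <- function(regions, groups, B = 10000, seed = NULL) {
  sig <- regions$signature
  if (!is.null(names(groups))) groups <- groups[rownames(sig)]
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop_input("compare_groups: exactly two groups")
  if (any(table(groups) < 2))
    stop_input("compare_groups: each group needs >= 2 samples")
  if (B < 100) stop_input("compare_groups: B >= 100 required")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sig)
  R <- ncol(sig)
  state <- sign(sig)                      # -1, 0, 1
  L <- (state < 0) * 1                    # n x R indicators
  N <- (state == 0) * 1
  G <- (state > 0) * 1
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1)
  tl <- colSums(L); tn <- colSums(N); tg <- colSums(G)
  stat_for <- function(sel) {
    c1 <- rbind(colSums(L[sel, , drop = FALSE]),
                colSums(N[sel, , drop = FALSE]),
                colSums(G[sel, , drop = FALSE]))
    c2 <- rbind(tl, tn, tg) - c1
    e1 <- (c1 + c2) * n1 / n
    e2 <- (c1 + c2) * (n - n1) / n
    d1 <- (c1 - e1)^2
    d2 <- (c2 - e2)^2
    colSums(ifelse(e1 > 0, d1 / e1, 0)) + colSums(ifelse(e2 > 0, d2 / e2, 0))
  }
  obs <- stat_for(g1)
  exceed <- numeric(R)
  perm_stats <- matrix(0, B, R)
  for (b in seq_len(B)) {
    sel <- sample.int(n, n1)
    perm_stats[b, ] <- stat_for(sel)
  }
  p <- (1 + colSums(perm_stats >= rep(obs, each = B))) / (B + 1)
  # permutation FDR at each observed statistic threshold
  sorted_perm <- sort(as.numeric(perm_stats))
  sorted_obs <- sort(obs)
  n_perm_ge <- function(s) length(sorted_perm) -
    findInterval(s, sorted_perm, left.open = TRUE)
  n_obs_ge <- function(s) length(sorted_obs) -
    findInterval(s, sorted_obs, left.open = TRUE)
  fdr_raw <- vapply(obs, function(s) {
    expected <- n_perm_ge(s) / B
    observed <- n_obs_ge(s)
    min(1, expected / observed)
  }, 0)
  # enforce monotone nonincreasing FDR as the p threshold tightens
  o <- order(p)
  fdr <- numeric(R)
  fdr[o] <- rev(cummin(rev(fdr_raw[o])))
  freq <- function(ind, grp) colMeans(ind[grp, , drop = FALSE])
  out <- data.frame(regions$regions,
                    freq_gain_1 = freq(G, g1), freq_loss_1 = freq(L, g1),
                    freq_gain_2 = freq(G, !g1), freq_loss_2 = freq(L, !g1),
                    stat = obs, p = p, fdr = fdr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "groups") <- levels(groups)
  attr(out, "B") <- B
  class(out) <- c("freq_compare", "data.frame")
  out
}

#' Per-bin gain/loss frequencies (frequency-plot data)
#'
#' @param profiles list of \code{\link{cn_profile}} objects.
#' @param grid the shared \code{\link{bin_grid}}.
#' @param groups optional grouping factor per sample; frequencies are
#'   computed per group.
#' @return data.frame: chrom, start, end, group, freq_gain, freq_loss.
#' @export
bin_frequencies <- function(profiles, grid, groups = NULL) {
  cm <- calls_matrix(profiles, grid)
  if (is.null(groups)) groups <- rep("all", nrow(cm$calls))
  groups <- factor(groups)
  rows <- lapply(levels(groups), function(g) {
    sub <- cm$calls[groups == g, , drop = FALSE]
    data.frame(chrom = grid$chrom[cm$bins], start = grid$start[cm$bins],
               end = grid$end[cm$bins], group = g,
               freq_gain = colMeans(sub > 0), freq_loss = colMeans(sub < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Frequency plot of gains and losses
#'
#' Gains are drawn upward and losses downward along the genome, one panel of
#' lines per group, in the style of cohort copy-number frequency plots.
#'
#' @param freq output of \code{\link{bin_frequencies}} for a single group.
#' @param main plot title.
#' @export
plot_frequencies <- function(freq, main = unique(freq$group)[1]) {
  stopifnot(length(unique(freq$group)) == 1)
  idx <- seq_len(nrow(freq))
  plot(NA, xlim = range(idx), ylim = c(-1, 1), xlab = "bin",
       ylab = "frequency (gain up / loss down)", main = main)
  segments(idx, 0, idx, freq$freq_gain, col = "blue")
  segments(idx, 0, idx, -freq$freq_loss, col = "red")
  bound <- which(diff(match(freq$chrom, unique(freq$chrom))) != 0)
  abline(v = bound + 0.5, col = "grey", lty = 3)
  abline(h = 0)
  invisible(freq)
}
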