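# standardized two-group log-rank z for many candidate dichotomizations of a
# continuous marker, vectorized across candidates.
# membership matrix M: n x k, M[i,j] = 1 if sample i is in the "high" group of
# candidate j. Returns z = U / sqrt(V) with U = sum over death times of
# (d1 - d * n1 / n) and V the hypergeometric variance.
logrank_z_scan <- function(time, event, M) {
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  M <- M[ord, , drop = FALSE]
  dt <- unique(t_s[e_s == 1])
  # at risk at death time t: all with t_s >= t
  pos <- findInterval(dt, t_s, left.open = TRUE)  # #{t_s < dt}
  n_at <- length(t_s) - pos
  d_at <- as.numeric(rowsum(e_s, t_s)[match(dt, sort(unique(t_s))), 1])
  # n1 at dt: suffix sums of membership
  suff <- apply(M, 2, function(m) rev(cumsum(rev(m))))
  if (is.null(dim(suff))) suff <- matrix(suff, ncol = ncol(M))
  N1 <- suff[pos + 1, , drop = FALSE]
  D1 <- rowsum(M * e_s, t_s)[match(dt, sort(unique(t_s))), , drop = FALSE]
  Eterm <- d_at * N1 / n_at
  U <- colSums(D1 - Eterm)
  Vterm <- d_at * (N1 / n_at) * (1 - N1 / n_at) *
    ifelse(n_at > 1, (n_at - d_at) / (n_at - 1), 0)
  V <- colSums(Vterm)
  ifelse(V > 0, U / sqrt(V), 0)
}

#' Maximally selected survival cutpoint
#'
#' Finds the dichotomization threshold of a continuous marker (e.g. the
#' genome instability index) that maximizes the absolute standardized
#' two-group log-rank statistic, in the manner of maximally selected rank
#' statistics. Candidate cutoffs are the unique observed values whose split
#' (low: value <= cutoff, high: value > cutoff) leaves at least
#' \code{minprop} of the samples on each side. Ties in the maximal statistic
#' go to the smaller cutoff.
#'
#' @param values finite numeric marker per sample.
#' @param time,event follow-up (months) and event indicator.
#' @param minprop minimum group proportion on each side (default 0.1).
#' @return Object of class \code{cutpoint_result}: \code{cutoff},
#'   \code{statistic} (signed standardized log-rank z at the cutoff),
#'   \code{candidates} (data.frame cutoff, z), \code{minprop}, and
#'   \code{labels} (factor low/high per sample).
#' @export
max_sel_cutpoint <- function(values, time, event, minprop = 0.1) {
  if (any(!is.finite(values))) stop_input("max_sel_cutpoint: non-finite values")
  n <- length(values)
  if (n < 10) stop_input("max_sel_cutpoint: need >= 10 samples")
  if (length(time) != n || length(event) != n)
    stop_input("max_sel_cutpoint: length mismatch")
  v <- sort(unique(values))
  n_low <- vapply(v, function(x) sum(values <= x), 0L)
  ok <- n_low >= minprop * n & (n - n_low) >= minprop * n
  cand <- v[ok]
  if (length(cand) == 0)
    stop_stat("max_sel_cutpoint: no admissible cutpoint (constant values or ",
              "minprop too strict)")
  M <- outer(values, cand, ">") * 1
  z <- logrank_z_scan(time, event, M)
  best <- which.max(abs(z))           # which.max takes the first (smallest cutoff)
  structure(list(cutoff = cand[best], statistic = z[best],
                 candidates = data.frame(cutoff = cand, z = z),
                 minprop = minprop,
                 labels = classify_gii(values, cand[best])),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("maximally selected cutpoint: %.4g (|z| = %.3f, %d candidates, minprop %.2f)\n",
              x$cutoff, abs(x$statistic), nrow(x$candidates), x$minprop))
  cat("  groups:", sum(x$labels == "low"), "low /", sum(x$labels == "high"),
      "high\n")
  invisible(x)
}

#' @export
plot.cutpoint_result <- function(x, xlab = "cutoff",
                                 ylab = "|standardized log-rank|", ...) {
  plot(x$candidates$cutoff, abs(x$candidates$z), type = "l",
       xlab = xlab, ylab = ylab, ...)
  abline(v = x$cutoff, lty = 2)
  invisible(x)
}

# all binary partitions of a level set, as a list of "left" level subsets
level_partitions <- function(levels) {
  k <- length(levels)
  if (k < 2) return(list())
  out <- list()
  # enumerate subsets containing the first level (avoids mirror duplicates)
  for (code in 0:(2^(k - 1) - 1)) {
    members <- c(TRUE, as.logical(intToBits(code)[seq_len(k - 1)]))
    if (all(members)) next
    out[[length(out) + 1]] <- levels[members]
  }
  out
}

tree_node <- function(idx, depth, time, event, factors, max_depth, min_node,
                      alpha) {
  n <- length(idx)
  node <- list(n = n, events = sum(event[idx]), depth = depth, split = NULL)
  if (depth >= max_depth || n < 2 * min_node) return(node)
  best <- NULL
  for (f in names(factors)) {
    x <- factor(factors[[f]][idx])
    obs_lev <- levels(droplevels(x))
    if (length(obs_lev) < 2 || length(obs_lev) > 8) next
    for (left in level_partitions(obs_lev)) {
      g <- x %in% left
      if (sum(g) < min_node || sum(!g) < min_node) next
      z <- logrank_z_scan(time[idx], event[idx], matrix(as.numeric(g), ncol = 1))
      stat <- z^2
      if (is.null(best) || stat > best$statistic)
        best <- list(factor = f, left_levels = left, statistic = stat,
                     p = pchisq(stat, 1, lower.tail = FALSE))
    }
  }
  if (is.null(best) || best$p >= alpha) return(node)
  g <- factors[[best$factor]][idx] %in% best$left_levels
  node$split <- best
  node$left <- tree_node(idx[g], depth + 1, time, event, factors, max_depth,
                         min_node, alpha)
  node$right <- tree_node(idx[!g], depth + 1, time, event, factors, max_depth,
                          min_node, alpha)
  node
}

#' Simplified log-rank survival tree
#'
#' Greedy recursive partitioning for censored outcomes: at each node, over
#' all supplied categorical factors and all binary partitions of each
#' factor's observed levels, the split maximizing the two-group log-rank
#' chi-square is taken, provided its p-value is below \code{alpha} and both
#' children keep at least \code{min_node} samples. This is a deliberately
#' simplified stand-in for CART survival trees (no exponential scaling,
#' pruning or cross-validation).
#'
#' @param time,event follow-up and event indicator.
#' @param factors data.frame (or named list) of categorical covariates.
#' @param max_depth maximum tree depth (default 2).
#' @param min_node minimum samples per node (default 20).
#' @param alpha split significance threshold (default 0.05).
#' @return Object of class \code{survival_tree} (nested node list with a
#'   \code{splits} summary: data.frame of depth, factor, left levels, p).
#' @export
survival_tree <- function(time, event, factors, max_depth = 2, min_node = 20,
                          alpha = 0.05) {
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (ncol(factors) < 1) stop_input("survival_tree: need >= 1 factor")
  if (nrow(factors) != length(time))
    stop_input("survival_tree: factor rows must match time length")
  root <- tree_node(seq_along(time), 0, time, event, factors, max_depth,
                    min_node, alpha)
  splits <- collect_splits(root)
  structure(list(root = root, splits = splits, max_depth = max_depth,
                 min_node = min_node, alpha = alpha),
            class = "survival_tree")
}

collect_splits <- function(node, depth = 0) {
  if (is.null(node$split)) return(NULL)
  here <- data.frame(depth = depth, factor = node$split$factor,
                     left = paste(node$split$left_levels, collapse = ","),
                     statistic = node$split$statistic, p = node$split$p,
                     stringsAsFactors = FALSE)
  rbind(here, collect_splits(node$left, depth + 1),
        collect_splits(node$right, depth + 1))
}

#' @export
print.survival_tree <- function(x, ...) {
  print_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is.null(node$split)) {
      cat(pad, "leaf: n = ", node$n, ", events = ", node$events, "\n", sep = "")
    } else {
      cat(pad, "split on ", node$split$factor, " {",
          paste(node$split$left_levels, collapse = ","),
          "} vs rest (chisq = ", format(node$split$statistic, digits = 4),
          ", p = ", format(node$split$p, digits = 3), ")\n", sep = "")
      print_node(node$left, indent + 1)
      print_node(node$right, indent + 1)
    }
  }
  cat("survival tree (max depth ", x$max_depth, ", min node ", x$min_node,
      ", alpha ", x$alpha, ")\n", sep = "")
  print_node(x$root, 0)
  invisible(x)
}
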