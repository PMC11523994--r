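#' Fisher's exact test for r x c contingency tables
#'
#' Two-sided Fisher test with the "probability at most that of the observed
#' table" criterion, over tables with the observed margins. The exact mode
#' enumerates via the network algorithm; when the enumeration exceeds the
#' workspace budget the error instructs switching to Monte-Carlo mode, which
#' samples \code{n_mc} tables with fixed margins (Patefield's algorithm) and
#' reports \eqn{p = (1 + \#\{prob(table) \le prob(observed)\}) / (n_{mc}+1)}.
#'
#' All-zero rows and columns are dropped first; a table left with fewer than
#' two rows or columns carries no association information and returns p = 1.
#'
#' @param tab matrix of non-negative integer counts.
#' @param mode \code{"exact"} or \code{"montecarlo"}.
#' @param n_mc number of Monte-Carlo tables (default 1e6).
#' @param seed optional RNG seed for Monte-Carlo mode.
#' @param workspace workspace size for the exact network algorithm.
#' @return list of class \code{fisher_rxc}: \code{p_value}, \code{mode},
#'   \code{n_mc} (NA in exact mode).
#' @examples
#' fisher_rxc(matrix(c(3, 1, 1, 3), 2))
#' @export
fisher_rxc <- function(tab, mode = c("exact", "montecarlo"), n_mc = 1e6,
                       seed = NULL, workspace = 2e7) {
  mode <- match.arg(mode)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop_input("fisher_rxc: counts must be non-negative integers")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(structure(list(p_value = 1, mode = mode, n_mc = NA_real_),
                     class = "fisher_rxc"))
  }
  if (mode == "exact") {
    p <- tryCatch(
      stats::fisher.test(tab, workspace = workspace)$p.value,
      error = function(e) {
        if (grepl("FEXACT|workspace|LDKEY|LDSTP", conditionMessage(e)))
          stop_stat("fisher_rxc: exact enumeration exceeds the workspace ",
                    "budget for this table; use mode = 'montecarlo'")
        stop(e)
      })
    return(structure(list(p_value = p, mode = "exact", n_mc = NA_real_),
                     class = "fisher_rxc"))
  }
  if (n_mc < 100) stop_input("fisher_rxc: n_mc too small")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = n_mc)$p.value
  structure(list(p_value = p, mode = "montecarlo", n_mc = n_mc),
            class = "fisher_rxc")
}

#' @export
print.fisher_rxc <- function(x, ...) {
  cat(sprintf("Fisher r x c (%s%s): p = %.4g\n", x$mode,
              if (x$mode == "montecarlo") paste0(", B = ", format(x$n_mc))
              else "", x$p_value))
  invisible(x)
}

#' One-way ANOVA
#'
#' Classical between/within F test for a continuous variable across groups
#' (equal-variance pooled estimate).
#'
#' @param values numeric observations.
#' @param group grouping factor.
#' @return list of class \code{oneway_anova}: \code{F}, \code{df1},
#'   \code{df2}, \code{p_value}.
#' @export
oneway_anova <- function(values, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop_input("oneway_anova: need >= 2 groups")
  if (any(table(group) == 0)) stop_input("oneway_anova: empty group")
  if (length(values) - nlevels(group) < 1)
    stop_input("oneway_anova: not enough residual degrees of freedom")
  ft <- stats::oneway.test(values ~ group, var.equal = TRUE)
  structure(list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
                 df2 = unname(ft$parameter[2]), p_value = ft$p.value),
            class = "oneway_anova")
}

#' @export
print.oneway_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%g, %g) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p_value))
  invisible(x)
}
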