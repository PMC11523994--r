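#' Fit the GS/CIN nearest-centroid classifier
#'
#' Builds per-cluster centroids from a labeled reference cohort: for each
#' GISTIC peak, the arithmetic mean of the peak-level log2 value over the
#' reference samples labeled GS and over those labeled CIN, ignoring missing
#' entries. Peaks missing in more than \code{max_missing} of either cluster's
#' samples are dropped with a warning. New samples are assigned by Euclidean
#' distance to the nearer centroid via \code{\link{predict.gscin_centroids}}.
#'
#' @param reference numeric matrix (samples x peaks) of peak-level log2
#'   values, as from \code{\link{summarize_peaks}}; must have dimnames.
#' @param labels character/factor of reference labels in \code{c("GS","CIN")},
#'   either aligned with the rows or named by sample id.
#' @param max_missing maximum tolerated fraction of missing entries per peak
#'   within each cluster (default 0.5).
#' @return An object of class \code{gscin_centroids} with elements
#'   \code{peak_ids}, \code{mu_gs}, \code{mu_cin}, \code{n_gs}, \code{n_cin},
#'   \code{dropped_peaks}.
#' @examples
#' ref <- rbind(s1 = c(p1 = 0.1, p2 = 0.3), s2 = c(0.3, 0.1),
#'              s3 = c(1.0, -0.8), s4 = c(1.2, -1.0))
#' fit <- gscin_fit(ref, c("GS", "GS", "CIN", "CIN"))
#' predict(fit, rbind(new = c(0.2, 0.2)))
#' @export
gscin_fit <- function(reference, labels, max_missing = 0.5) {
  if (is.null(dim(reference)) || is.null(colnames(reference)))
    stop_input("gscin_fit: reference must be a matrix with peak colnames")
  if (!is.null(names(labels)) && !is.null(rownames(reference)))
    labels <- labels[rownames(reference)]
  labels <- as.character(labels)
  if (length(labels) != nrow(reference) || anyNA(labels))
    stop_input("gscin_fit: every reference sample must be labeled")
  if (!all(labels %in% c("GS", "CIN")))
    stop_input("gscin_fit: labels must be 'GS' or 'CIN'")
  if (!all(c("GS", "CIN") %in% labels))
    stop_input("gscin_fit: empty cluster: need at least one GS and one CIN sample")
  gs <- reference[labels == "GS", , drop = FALSE]
  cin <- reference[labels == "CIN", , drop = FALSE]
  miss_gs <- colMeans(is.na(gs))
  miss_cin <- colMeans(is.na(cin))
  drop <- miss_gs > max_missing | miss_cin > max_missing
  if (any(drop))
    warning("gscin_fit: dropping ", sum(drop),
            " peak(s) missing in >", max_missing * 100,
            "% of a cluster's samples: ",
            paste(colnames(reference)[drop], collapse = ", "))
  keep <- which(!drop)
  if (length(keep) == 0) stop_input("gscin_fit: no peaks left after filtering")
  structure(list(peak_ids = colnames(reference)[keep],
                 mu_gs = colMeans(gs[, keep, drop = FALSE], na.rm = TRUE),
                 mu_cin = colMeans(cin[, keep, drop = FALSE], na.rm = TRUE),
                 n_gs = nrow(gs), n_cin = nrow(cin),
                 dropped_peaks = colnames(reference)[drop]),
            class = "gscin_centroids")
}

#' @export
print.gscin_centroids <- function(x, ...) {
  cat("GS/CIN nearest-centroid classifier\n")
  cat("  peaks:", length(x$peak_ids), "  reference: n(GS) =", x$n_gs,
      ", n(CIN) =", x$n_cin, "\n")
  cat("  inter-centroid distance:",
      format(sqrt(sum((x$mu_gs - x$mu_cin)^2)), digits = 4), "\n")
  if (length(x$dropped_peaks))
    cat("  dropped peaks:", length(x$dropped_peaks), "\n")
  invisible(x)
}

#' @export
coef.gscin_centroids <- function(object, ...) {
  cbind(mu_GS = object$mu_gs, mu_CIN = object$mu_cin)
}

#' Assign samples to GS or CIN by nearest centroid
#'
#' Euclidean distance to each centroid over the peaks that are non-missing in
#' the sample; the same dimension set is used for both centroids so distances
#' are comparable. The sample gets the label of the nearer centroid; an exact
#' tie is assigned GS and flagged.
#'
#' @param object a fitted \code{\link{gscin_fit}} object.
#' @param newdata numeric matrix (samples x peaks) or a single named vector;
#'   columns are matched to the classifier's peaks by name.
#' @param ... unused.
#' @return A data.frame of class \code{subtype_calls} with columns
#'   \code{sample_id}, \code{label}, \code{d_GS}, \code{d_CIN},
#'   \code{n_peaks_used}, \code{tie}.
#' @export
predict.gscin_centroids <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- rbind(sample = newdata)
  if (!is.null(colnames(newdata))) {
    missing_pk <- setdiff(object$peak_ids, colnames(newdata))
    if (length(missing_pk) == length(object$peak_ids))
      stop_input("predict: no classifier peaks present in newdata")
    # absent peaks enter as missing dimensions
    full <- matrix(NA_real_, nrow(newdata), length(object$peak_ids),
                   dimnames = list(rownames(newdata), object$peak_ids))
    common <- intersect(object$peak_ids, colnames(newdata))
    full[, common] <- newdata[, common, drop = FALSE]
    newdata <- full
  } else if (ncol(newdata) != length(object$peak_ids)) {
    stop_input("predict: newdata has ", ncol(newdata), " columns; classifier has ",
               length(object$peak_ids), " peaks")
  }
  n <- nrow(newdata)
  d_gs <- d_cin <- rep(NA_real_, n)
  used <- integer(n)
  for (i in seq_len(n)) {
    x <- newdata[i, ]
    ok <- !is.na(x)
    if (!any(ok))
      stop_input("predict: sample ", rownames(newdata)[i],
                 " has no usable peak dimensions")
    d_gs[i] <- sqrt(sum((x[ok] - object$mu_gs[ok])^2))
    d_cin[i] <- sqrt(sum((x[ok] - object$mu_cin[ok])^2))
    used[i] <- sum(ok)
  }
  # exact ties up to floating-point noise go to GS and are flagged
  tie <- abs(d_gs - d_cin) <= 1e-12 * pmax(1, d_gs + d_cin)
  d_gs[tie] <- pmin(d_gs, d_cin)[tie]
  d_cin[tie] <- d_gs[tie]
  out <- data.frame(
    sample_id = if (is.null(rownames(newdata))) paste0("s", seq_len(n))
                else rownames(newdata),
    label = factor(ifelse(d_gs <= d_cin, "GS", "CIN"), levels = c("GS", "CIN")),
    d_GS = d_gs, d_CIN = d_cin, n_peaks_used = used, tie = tie,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("subtype_calls", "data.frame")
  out
}

#' Assign a single peak vector
#'
#' Convenience wrapper around \code{\link{predict.gscin_centroids}} for one
#' sample.
#'
#' @param x named numeric vector of peak-level log2 values.
#' @param centroids a \code{\link{gscin_fit}} object.
#' @return One-row \code{subtype_calls} data.frame.
#' @export
assign_subtype <- function(x, centroids) {
  predict(centroids, x)
}

#' Combine GS/CIN calls with Lauren histology into four strata
#'
#' Mixed-type tumors are grouped with diffuse (the worse-differentiated
#' component is assumed to drive outcome); tumors with Lauren type "other"
#' do not fit the classification and are excluded, with the count reported.
#'
#' @param calls a \code{subtype_calls} data.frame (or any data.frame with
#'   \code{sample_id} and \code{label}).
#' @param lauren character/factor of Lauren types in
#'   \code{c("intestinal","diffuse","mixed","other")}, aligned with
#'   \code{calls} or named by sample id.
#' @return An object of class \code{gscin_strata}: list with \code{strata}
#'   (data.frame \code{sample_id}, \code{stratum}), \code{composition}
#'   (data.frame \code{stratum}, \code{n}, \code{percent}) and
#'   \code{n_excluded}.
#' @export
stratify <- function(calls, lauren) {
  if (!is.null(names(lauren))) lauren <- lauren[calls$sample_id]
  lauren <- as.character(lauren)
  if (length(lauren) != nrow(calls) || anyNA(lauren))
    stop_input("stratify: every classified sample needs a Lauren type")
  bad <- setdiff(unique(lauren), c("intestinal", "diffuse", "mixed", "other"))
  if (length(bad) > 0)
    stop_input("stratify: unknown Lauren categor(ies): ",
               paste(bad, collapse = ", "))
  lauren[lauren == "mixed"] <- "diffuse"
  keep <- lauren != "other"
  n_excl <- sum(!keep)
  if (n_excl > 0)
    message("stratify: excluded ", n_excl, " sample(s) with Lauren type 'other'")
  lev <- c("GS-intestinal", "GS-diffuse", "CIN-intestinal", "CIN-diffuse")
  strata <- data.frame(
    sample_id = calls$sample_id[keep],
    stratum = factor(paste(calls$label[keep], lauren[keep], sep = "-"),
                     levels = lev),
    stringsAsFactors = FALSE)
  if (nrow(strata) == 0) warning("stratify: no samples remain after exclusions")
  n <- as.integer(table(strata$stratum))
  comp <- data.frame(stratum = lev, n = n,
                     percent = if (sum(n) > 0) round(100 * n / sum(n), 1)
                               else rep(NA_real_, 4))
  structure(list(strata = strata, composition = comp, n_excluded = n_excl),
            class = "gscin_strata")
}

#' @export
print.gscin_strata <- function(x, ...) {
  cat("TCGA x Lauren stratification (", nrow(x$strata), " samples",
      if (x$n_excluded > 0) paste0(", ", x$n_excluded, " 'other' excluded"),
      ")\n", sep = "")
  print(x$composition, row.names = FALSE)
  invisible(x)
}
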