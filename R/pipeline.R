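#' Write a run manifest
#'
#' Records, per pipeline stage, the seed, package and R versions, md5 digests
#' of input and output files and per-output row counts, so deterministic
#' stages can be verified to reproduce bit-identical outputs.
#'
#' @param out_dir output directory.
#' @param stage stage name.
#' @param inputs,outputs named character vectors of file paths.
#' @param seed the seed used (or NA).
#' @param extra optional named list merged into the manifest.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, stage, inputs = character(0),
                           outputs = character(0), seed = NA, extra = list()) {
  digest <- function(paths) {
    if (length(paths) == 0) return(list())
    d <- tools::md5sum(paths)
    as.list(setNames(unname(d), names(paths)))
  }
  counts <- lapply(outputs, function(p) {
    if (file.exists(p)) length(readLines(p)) else NA_integer_
  })
  manifest <- c(list(stage = stage, seed = seed,
                     r_version = R.version.string,
                     package_version = as.character(packageVersion("gscin")),
                     inputs = digest(inputs), outputs = digest(outputs),
                     output_lines = counts), extra)
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a cohort and write its files
#'
#' Thin orchestration over \code{\link{simulate_cohort}}: writes the grid,
#' SEG segments (with calls), purity table, peak BED, clinical table, truth
#' table, reference peak matrix and labels, plus a manifest.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of output paths, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  paths <- c(
    grid = file.path(out_dir, "grid.tsv"),
    seg = file.path(out_dir, "segments.seg"),
    purity = file.path(out_dir, "purity.tsv"),
    peaks = file.path(out_dir, "peaks.bed"),
    clinical = file.path(out_dir, "clinical.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    reference = file.path(out_dir, "reference_peaks.tsv"),
    ref_labels = file.path(out_dir, "reference_labels.tsv"))
  write_grid(config$grid, paths[["grid"]])
  write_seg(cohort$profiles, config$grid, paths[["seg"]])
  pur <- data.frame(sample = names(cohort$profiles),
                    purity = vapply(cohort$profiles, `[[`, 0, "purity"))
  utils::write.table(pur, paths[["purity"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_peaks_bed(config$peaks, paths[["peaks"]])
  utils::write.table(cohort$clinical, paths[["clinical"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_peak_matrix(cohort$reference$matrix, paths[["reference"]])
  utils::write.table(
    data.frame(sample = names(cohort$reference$labels),
               label = unname(cohort$reference$labels)),
    paths[["ref_labels"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "simulate", outputs = paths, seed = config$seed)
  message("run_simulate: wrote ", length(paths), " files to ", out_dir)
  invisible(paths)
}

#' Classify samples from files
#'
#' Reads segments, purities and peaks; filters peaks to autosomes (unless
#' \code{keep_sex_chroms}); summarizes corrected segmented log2 over peaks;
#' builds centroids from a labeled reference (or loads prebuilt centroids);
#' assigns GS/CIN; computes per-sample GII; writes the calls table (and the
#' centroid table when built here) plus a manifest.
#'
#' @param seg,purity,peaks,grid input file paths (SEG TSV, purity TSV, BED,
#'   grid TSV).
#' @param reference,labels reference peak-matrix TSV and label TSV
#'   (sample, label), used when \code{centroids} is NULL.
#' @param centroids optional prebuilt centroid TSV (peak_id, mu_GS, mu_CIN).
#' @param out_dir output directory.
#' @param keep_sex_chroms keep sex-chromosome peaks (default FALSE).
#' @return The calls data.frame (with \code{gii} column), invisibly; files
#'   \code{calls.tsv} (and \code{centroids.tsv}) are written.
#' @export
run_classify <- function(seg, purity, peaks, grid, reference = NULL,
                         labels = NULL, centroids = NULL, out_dir,
                         keep_sex_chroms = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- read_grid(grid)
  pk <- read_peaks_bed(peaks)
  if (!keep_sex_chroms) pk <- filter_autosomal_peaks(pk)
  profiles <- read_seg(seg, g, purity)
  pm <- summarize_peaks(profiles, pk, g)
  built <- FALSE
  if (is.null(centroids)) {
    if (is.null(reference) || is.null(labels))
      stop_input("run_classify: need either centroids or reference + labels")
    ref <- read_peak_matrix(reference)
    lab_tab <- utils::read.delim(labels, stringsAsFactors = FALSE)
    lab <- setNames(lab_tab$label, lab_tab$sample)
    fit <- gscin_fit(ref[, intersect(colnames(ref), pk$peak_id), drop = FALSE],
                     lab)
    built <- TRUE
  } else {
    ct <- utils::read.delim(centroids, stringsAsFactors = FALSE)
    fit <- structure(list(peak_ids = ct$peak_id,
                          mu_gs = setNames(ct$mu_GS, ct$peak_id),
                          mu_cin = setNames(ct$mu_CIN, ct$peak_id),
                          n_gs = NA_integer_, n_cin = NA_integer_,
                          dropped_peaks = character(0)),
                     class = "gscin_centroids")
  }
  calls <- predict(fit, pm)
  gii <- compute_gii(profiles, g)
  calls$gii <- gii$gii[match(calls$sample_id, gii$sample_id)]
  comp <- table(calls$label)
  message("run_classify: ", comp[["GS"]], " GS (",
          round(100 * comp[["GS"]] / sum(comp), 1), "%), ", comp[["CIN"]],
          " CIN (", round(100 * comp[["CIN"]] / sum(comp), 1), "%)")
  out_calls <- file.path(out_dir, "calls.tsv")
  utils::write.table(calls, out_calls, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outputs <- c(calls = out_calls)
  if (built) {
    out_cent <- file.path(out_dir, "centroids.tsv")
    utils::write.table(
      data.frame(peak_id = fit$peak_ids, mu_GS = unname(fit$mu_gs),
                 mu_CIN = unname(fit$mu_cin)),
      out_cent, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, centroids = out_cent)
  }
  inputs <- c(seg = seg, purity = purity, peaks = peaks, grid = grid)
  write_manifest(out_dir, "classify", inputs = inputs, outputs = outputs)
  invisible(calls)
}

#' Survival and association analysis report
#'
#' Joins subtype calls with the clinical table, stratifies by TCGA x Lauren,
#' and assembles the statistical report: per-stratum composition, five-year
#' cancer-related survival with CI, overall and pairwise log-rank tests,
#' univariable Cox fits per classification, multivariable Cox after backward
#' selection, the GII survival cutpoint, a survival-tree summary and
#' association tests of covariates with the strata (Fisher for categorical,
#' one-way ANOVA for age). With zero events the survival entries are NA
#' rather than errors.
#'
#' @param calls subtype calls data.frame (sample_id, label, gii) or the path
#'   of a calls TSV.
#' @param clinical clinical data.frame or TSV path; needs sample_id, lauren,
#'   time_months, event, and optional covariate columns.
#' @param out_dir optional output directory for \code{report.json} and a
#'   manifest.
#' @param minprop minimum group proportion for the GII cutpoint.
#' @param seed seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return The report as a nested list (class \code{gscin_report}).
#' @export
run_analyze <- function(calls, clinical, out_dir = NULL, minprop = 0.1,
                        seed = NA) {
  if (is.character(calls)) calls <- utils::read.delim(calls,
                                                      stringsAsFactors = FALSE)
  if (is.character(clinical))
    clinical <- utils::read.delim(clinical, stringsAsFactors = FALSE)
  if ("insufficient_dna" %in% names(clinical))
    clinical <- filter_cohort(clinical)$clinical
  unmatched <- setdiff(clinical$sample_id, calls$sample_id)
  if (length(unmatched) > 0)
    warning("run_analyze: ", length(unmatched),
            " clinical sample(s) without calls; dropped")
  dat <- merge(calls, clinical, by = "sample_id")
  st <- stratify(dat[, c("sample_id", "label")], setNames(dat$lauren,
                                                          dat$sample_id))
  dat$stratum <- NULL  # a clinical table may carry its own stratum column
  dat <- merge(dat, st$strata, by = "sample_id")
  dat$stratum <- factor(dat$stratum, levels = levels(st$strata$stratum))
  n_events <- sum(dat$event)
  report <- list(n = nrow(dat), n_events = n_events,
                 composition = st$composition)
  if (n_events == 0) {
    report$five_year_crs <- NA
    report$logrank <- NA
    report$cox_univariable <- NA
    report$cox_multivariable <- NA
    report$gii_cutpoint <- NA
    report$survival_tree <- NA
  } else {
    km <- km_fit(dat$time_months, dat$event, dat$stratum)
    s60 <- survival_at(km, 60)
    report$five_year_crs <- data.frame(
      stratum = s60$group, percent = round(100 * s60$surv, 1),
      lower = round(100 * s60$lower, 1), upper = round(100 * s60$upper, 1))
    lr <- logrank_test(dat$time_months, dat$event, dat$stratum)
    report$logrank <- list(statistic = lr$statistic, df = lr$df,
                           p = lr$p_value)
    cox <- cox_fit(survival::Surv(time_months, event) ~ stratum, dat)
    report$cox_univariable <- cox$table
    # multivariable candidates: the classifications available in the data
    gii_cp <- tryCatch(
      max_sel_cutpoint(dat$gii, dat$time_months, dat$event, minprop = minprop),
      gscin_stat_error = function(e) NULL)
    report$gii_cutpoint <- if (is.null(gii_cp)) NA else
      list(cutoff = gii_cp$cutoff, statistic = gii_cp$statistic,
           n_low = sum(gii_cp$labels == "low"),
           n_high = sum(gii_cp$labels == "high"))
    dat$tcga <- factor(as.character(dat$label), levels = c("GS", "CIN"))
    dat$lauren2 <- factor(ifelse(dat$lauren == "mixed", "diffuse", dat$lauren),
                          levels = c("intestinal", "diffuse"))
    terms <- c("tcga", "lauren2")
    if (!is.null(gii_cp)) {
      dat$gii_class <- gii_cp$labels
      terms <- c(terms, "gii_class")
    }
    bs <- backward_select(dat, terms, threshold = 0.10,
                          time_col = "time_months", event_col = "event")
    report$cox_multivariable <- list(
      retained = bs$retained,
      table = if (is.null(bs$fit)) NA else bs$fit$table)
    tree_factors <- dat[, terms, drop = FALSE]
    tr <- survival_tree(dat$time_months, dat$event, tree_factors)
    report$survival_tree <- if (is.null(tr$splits)) list() else tr$splits
  }
  # Table-1-style association tests against the four strata
  assoc <- list()
  for (covar in intersect(c("sex", "pN", "pT", "stage", "p53_ihc",
                            "cdh1_ihc"), names(dat))) {
    tab <- table(dat[[covar]], dat$stratum)
    # exact enumeration is feasible for 2 x c tables; larger ones go straight
    # to Monte-Carlo (and exact failures fall back to it as well)
    assoc[[covar]] <- if (min(dim(tab)) <= 2) tryCatch(
      fisher_rxc(tab, mode = "exact")$p_value,
      gscin_stat_error = function(e)
        fisher_rxc(tab, mode = "montecarlo", n_mc = 1e5)$p_value)
    else fisher_rxc(tab, mode = "montecarlo", n_mc = 1e5)$p_value
  }
  if ("age" %in% names(dat) && n_events >= 0 && nlevels(droplevels(dat$stratum)) >= 2)
    assoc$age <- oneway_anova(dat$age, dat$stratum)$p_value
  report$associations <- assoc
  class(report) <- c("gscin_report", class(report))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, "report.json")
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
    write_manifest(out_dir, "analyze", outputs = c(report = path), seed = seed)
  }
  report
}

#' @export
print.gscin_report <- function(x, ...) {
  cat("analysis report:", x$n, "samples,", x$n_events, "events\n")
  cat("composition:\n")
  print(x$composition, row.names = FALSE)
  if (is.data.frame(x$five_year_crs)) {
    cat("5-year CRS (%):\n")
    print(x$five_year_crs, row.names = FALSE)
  }
  if (is.list(x$logrank))
    cat(sprintf("log-rank p = %.4g\n", x$logrank$p))
  if (is.list(x$cox_multivariable))
    cat("multivariable Cox retained:",
        paste(x$cox_multivariable$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Compare regional frequencies between two strata, from files
#'
#' @param seg,purity,grid input paths.
#' @param groups named character vector (or two-column TSV path:
#'   sample, group) assigning each profiled sample to one of two groups.
#' @param out_dir output directory.
#' @param tau region merge tolerance.
#' @param B permutations.
#' @param seed RNG seed for the permutation stream.
#' @return The \code{\link{compare_groups}} result, invisibly; writes
#'   \code{regions.tsv} and \code{region_tests.tsv}.
#' @export
run_compare_regions <- function(seg, purity, grid, groups, out_dir,
                                tau = 0.01, B = 10000, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- read_grid(grid)
  profiles <- read_seg(seg, g, purity)
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    gt <- utils::read.delim(groups, stringsAsFactors = FALSE)
    groups <- setNames(gt$group, gt$sample)
  }
  groups <- groups[names(profiles)]
  keep <- !is.na(groups)
  rs <- regionize(profiles[keep], g, tau = tau)
  res <- compare_groups(rs, groups[keep], B = B, seed = seed)
  p_reg <- file.path(out_dir, "regions.tsv")
  p_res <- file.path(out_dir, "region_tests.tsv")
  utils::write.table(rs$regions, p_reg, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(res), p_res, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(out_dir, "compare_regions",
                 inputs = c(seg = seg, purity = purity, grid = grid),
                 outputs = c(regions = p_reg, tests = p_res), seed = seed)
  invisible(res)
}
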