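#' Default peak template for the miniature grid
#'
#' Twenty-four synthetic recurrent-aberration peaks (eight per chromosome of
#' the three-chromosome \code{\link{mini_grid}}, each five 100-kbp bins
#' wide). CIN tumors carry gains (tumor copy 3-4, event probability 0.7) and
#' single-copy deletions (probability 0.6); GS tumors are near-diploid apart
#' from one recurrent gain (the "chromosome 8"-like event seen even in
#' genomically stable gastric tumors) at probability 0.3. The event
#' probabilities sit at the top of their plausible ranges so that the
#' inter-centroid distance is large relative to the within-cluster spread
#' induced by Bernoulli event sampling; see the methods vignette.
#'
#' @param grid the grid the peaks live on (default \code{\link{mini_grid}}).
#' @return A \code{\link{peak_regions}} table with extra template columns
#'   \code{copies} (tumor copy number when the event is present),
#'   \code{f_gs}, \code{f_cin} (per-subtype event probabilities).
#' @export
default_peak_template <- function(grid = mini_grid()) {
  chrom <- rep(c("1", "2", "3"), each = 8)
  from <- rep(seq(6, by = 10, length.out = 8), 3)   # bins 6-10, 16-20, ...
  direction <- c("gain", "gain", "deletion", "gain", "deletion", "deletion",
                 "gain", "deletion",
                 "gain", "deletion", "gain", "deletion", "deletion", "gain",
                 "deletion", "deletion",
                 "deletion", "gain", "deletion", "gain", "deletion", "gain",
                 "deletion", "gain")
  is_gain <- direction == "gain"
  copies <- ifelse(is_gain, rep_len(c(4, 4, 3), 24), 1)
  source_cluster <- rep("CN-high", 24)
  source_cluster[c(4, 16, 19)] <- "CN-low"   # one gain, two deletions
  f_cin <- ifelse(is_gain, 0.70, 0.60)
  f_cin[source_cluster == "CN-low"] <- ifelse(is_gain[c(4, 16, 19)], 0.60, 0.50)
  f_gs <- rep(0.02, 24)
  f_gs[source_cluster == "CN-low"] <- 0.05
  f_gs[1] <- 0.30; f_cin[1] <- 0.70          # the chr8-like gain
  pk <- peak_regions(sprintf("pk%02d", 1:24), chrom,
                     (from - 1) * 1e5 + 1, (from + 4) * 1e5,
                     direction, source_cluster)
  pk$copies <- copies
  pk$f_gs <- f_gs
  pk$f_cin <- f_cin
  pk
}

#' Synthetic genome-scale GISTIC-like peak set
#'
#' A synthetic stand-in for the TCGA STAD GISTIC 2.0 peak list with the same
#' bookkeeping: 31 gain and 45 deletion peaks recurring in the copy-number
#' high cluster, 13 gain and 25 deletion peaks recurring in the copy-number
#' low cluster (114 in total), of which 7 lie on chromosome X. Gains
#' concentrate on chromosomes 7, 8 and 20 and deletions on 4, 9 and 17, the
#' chromosomes most often aberrant in gastric cancer; coordinates are
#' synthetic (1-Mb peaks spaced along each chromosome of
#' \code{\link{genome_grid}}).
#'
#' @return A \code{\link{peak_regions}} table with template columns
#'   \code{copies}, \code{f_gs}, \code{f_cin}.
#' @export
synthetic_tcga_peaks <- function() {
  gain_high <- c(rep("8", 5), rep("20", 4), rep("7", 4),
                 "1", "2", "3", "5", "6", "10", "11", "12", "13", "17", "19",
                 "21", "22", "14", "15", "16", rep("X", 2))
  del_high <- c(rep("17", 5), rep("4", 5), rep("9", 5),
                "1", "2", "3", "5", "6", "7", "8", "10", "11", "12", "13",
                "14", "15", "16", "18", "19", "20", "21", "22",
                "1", "2", "3", "5", "6", "10", "11", "12", rep("X", 3))
  gain_low <- c(rep("8", 3), rep("20", 2), rep("7", 2),
                "2", "5", "13", "19", "10", "X")
  del_low <- c(rep("17", 3), rep("4", 3), rep("9", 3),
               "1", "2", "3", "5", "6", "7", "8", "10", "11", "12", "13",
               "14", "15", "16", "18", "X")
  stopifnot(length(gain_high) == 31, length(del_high) == 45,
            length(gain_low) == 13, length(del_low) == 25)
  chrom <- c(gain_high, del_high, gain_low, del_low)
  direction <- rep(c("gain", "deletion", "gain", "deletion"),
                   c(31, 45, 13, 25))
  source_cluster <- rep(c("CN-high", "CN-high", "CN-low", "CN-low"),
                        c(31, 45, 13, 25))
  # place peaks at 6-Mb spacing along each chromosome, 1 Mb wide
  slot <- stats::ave(seq_along(chrom), chrom, FUN = seq_along)
  start <- 2e6 + (slot - 1) * 6e6 + 1
  end <- start + 1e6 - 1
  pk <- peak_regions(sprintf("peak%03d", seq_along(chrom)), chrom, start, end,
                     direction, source_cluster)
  pk$copies <- ifelse(direction == "gain", ifelse(chrom == "8", 4, 3), 1)
  pk$f_gs <- ifelse(direction == "gain" & chrom == "8", 0.30,
                    ifelse(source_cluster == "CN-low", 0.05, 0.02))
  pk$f_cin <- ifelse(direction == "gain", 0.60, 0.50)
  pk
}

#' Synthetic cohort configuration
#'
#' Full parameterization of a synthetic gastric-cancer cohort. The defaults
#' mirror the study conditions of the Dutch D1/D2 EBV-negative/MSS series:
#' 309 analyzable tumors in the four strata at their reported sizes
#' (24/57/142/86), plus 39 tumors of "other" histology and 23 with
#' insufficient DNA (371 before exclusions); stratum-specific exponential
#' survival calibrated to the reported five-year cancer-related survival
#' (61.4/56.5/47.6/31.5%); uniform censoring over the 120-month follow-up
#' horizon; and covariate frequencies taken from the reported
#' clinicopathological table.
#'
#' @param seed integer seed; every generator in the package derives its
#'   stream from it.
#' @param grid bin grid (default \code{\link{mini_grid}}).
#' @param peaks peak template with \code{copies}, \code{f_gs}, \code{f_cin}
#'   columns (default \code{\link{default_peak_template}} on \code{grid}).
#' @param n_strata named integer vector of analyzable samples per stratum.
#' @param n_other number of additional "other"-histology samples.
#' @param n_insufficient number of additional insufficient-DNA samples
#'   (no profile generated).
#' @param sigma per-bin Gaussian noise sd on observed log2 (>= 0).
#' @param sigma_ref per-peak noise sd of the reference panel.
#' @param purity_range uniform purity bounds in (0, 1].
#' @param s5 named five-year survival per stratum, in (0, 1).
#' @param censor_max upper bound of the uniform censoring law (months).
#' @param n_ref named reference panel sizes, \code{c(GS=, CIN=)}.
#' @param covariates named list of per-stratum level frequency matrices
#'   (levels x strata, columns summing to 1).
#' @param age_mean,age_sd normal age model per stratum.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       grid = mini_grid(),
                       peaks = default_peak_template(grid),
                       n_strata = c("GS-intestinal" = 24, "GS-diffuse" = 57,
                                    "CIN-intestinal" = 142, "CIN-diffuse" = 86),
                       n_other = 39,
                       n_insufficient = 23,
                       sigma = 0.10,
                       sigma_ref = 0.10,
                       purity_range = c(0.3, 0.9),
                       s5 = c("GS-intestinal" = 0.614, "GS-diffuse" = 0.565,
                              "CIN-intestinal" = 0.476, "CIN-diffuse" = 0.315),
                       censor_max = 120,
                       n_ref = c(GS = 83, CIN = 210),
                       covariates = default_covariate_freqs(),
                       age_mean = c("GS-intestinal" = 63.0, "GS-diffuse" = 60.9,
                                    "CIN-intestinal" = 65.9, "CIN-diffuse" = 62.6),
                       age_sd = 10) {
  cfg <- list(seed = seed, grid = grid, peaks = peaks, n_strata = n_strata,
              n_other = n_other, n_insufficient = n_insufficient,
              sigma = sigma, sigma_ref = sigma_ref,
              purity_range = purity_range, s5 = s5, censor_max = censor_max,
              n_ref = n_ref, covariates = covariates, age_mean = age_mean,
              age_sd = age_sd)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) stop_input("sim_config: invalid '", field, "': ", why)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) fail("seed", "one integer")
  if (!inherits(cfg$grid, "bin_grid")) fail("grid", "must be a bin_grid")
  need <- c("copies", "f_gs", "f_cin")
  if (!all(need %in% names(cfg$peaks)))
    fail("peaks", "template needs copies, f_gs, f_cin columns")
  if (any(cfg$peaks$f_gs < 0 | cfg$peaks$f_gs > 1 |
          cfg$peaks$f_cin < 0 | cfg$peaks$f_cin > 1))
    fail("peaks", "event probabilities must lie in [0, 1]")
  if (any(cfg$peaks$copies < 0)) fail("peaks", "negative copy state")
  strata <- c("GS-intestinal", "GS-diffuse", "CIN-intestinal", "CIN-diffuse")
  if (!identical(sort(names(cfg$n_strata)), sort(strata)))
    fail("n_strata", "must be named by the four strata")
  if (any(cfg$n_strata < 0)) fail("n_strata", "negative size")
  if (cfg$n_other < 0) fail("n_other", "negative")
  if (cfg$n_insufficient < 0) fail("n_insufficient", "negative")
  if (!is.numeric(cfg$sigma) || cfg$sigma < 0) fail("sigma", "must be >= 0")
  if (cfg$sigma_ref < 0) fail("sigma_ref", "must be >= 0")
  p <- cfg$purity_range
  if (length(p) != 2 || p[1] <= 0 || p[2] > 1 || p[1] > p[2])
    fail("purity_range", "bounds must lie in (0, 1] and be ordered")
  if (!all(names(cfg$s5) %in% strata) || any(cfg$s5 <= 0) || any(cfg$s5 >= 1))
    fail("s5", "five-year survival must lie in (0, 1) per stratum")
  if (cfg$censor_max <= 0) fail("censor_max", "must be positive")
  if (any(cfg$n_ref < 1)) fail("n_ref", "need >= 1 reference sample per cluster")
  for (nm in names(cfg$covariates)) {
    m <- cfg$covariates[[nm]]
    if (any(abs(colSums(m) - 1) > 1e-6))
      fail(paste0("covariates$", nm), "level frequencies must sum to 1")
    if (any(m < 0)) fail(paste0("covariates$", nm), "negative frequency")
  }
  invisible(cfg)
}

#' Default covariate frequencies
#'
#' Per-stratum frequencies for sex and pN stage taken from the reported
#' clinicopathological counts of the four subgroups.
#'
#' @return named list of levels-by-strata frequency matrices.
#' @export
default_covariate_freqs <- function() {
  strata <- c("GS-intestinal", "GS-diffuse", "CIN-intestinal", "CIN-diffuse")
  sex <- cbind(c(9, 15) / 24, c(23, 34) / 57, c(91, 51) / 142, c(40, 46) / 86)
  dimnames(sex) <- list(c("male", "female"), strata)
  pn <- cbind(c(14, 3, 2, 5) / 24, c(23, 7, 14, 13) / 57,
              c(44, 32, 39, 27) / 142, c(18, 16, 18, 34) / 86)
  dimnames(pn) <- list(c("pN0", "pN1", "pN2", "pN3"), strata)
  list(sex = sex, pN = pn)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("synthetic cohort config: seed", x$seed, "\n")
  cat("  grid:", nrow(x$grid), "bins;", nrow(x$peaks), "template peaks\n")
  cat("  n per stratum:", paste(names(x$n_strata), x$n_strata, sep = "=",
                                collapse = ", "), "\n")
  cat("  + other histology:", x$n_other, "; insufficient DNA:",
      x$n_insufficient, "\n")
  cat("  sigma:", x$sigma, " purity: U(", x$purity_range[1], ",",
      x$purity_range[2], ")\n")
  cat("  5-year CRS:", paste(names(x$s5), x$s5, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# sample sheet shared by the generators: stratum/subtype/lauren per sample
sim_sample_sheet <- function(config) {
  strata <- rep(names(config$n_strata), config$n_strata)
  subtype <- sub("-.*$", "", strata)
  lauren <- sub("^.*-", "", strata)
  n_core <- length(strata)
  p_gs <- sum(config$n_strata[grep("^GS", names(config$n_strata))]) /
    max(sum(config$n_strata), 1)
  sheet <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_core + config$n_other +
                                           config$n_insufficient)),
    stratum = c(strata, rep(NA_character_,
                            config$n_other + config$n_insufficient)),
    subtype = c(subtype, rep(NA_character_,
                             config$n_other + config$n_insufficient)),
    lauren = c(lauren, rep("other", config$n_other),
               rep(NA_character_, config$n_insufficient)),
    insufficient_dna = c(rep(FALSE, n_core + config$n_other),
                         rep(TRUE, config$n_insufficient)),
    stringsAsFactors = FALSE)
  attr(sheet, "p_gs") <- p_gs
  sheet
}

#' Simulate binned copy-number profiles
#'
#' Per sample: draw purity uniformly; include each template peak event with
#' its subtype-specific probability; set tumor copies per bin (baseline 2);
#' the observed log2 per bin is the admixture mixture value
#' \code{log2((p*c + 2(1-p))/2)} plus Gaussian noise, the segmented log2 is
#' the noiseless mixture value, and the five-level call follows the true copy
#' state (0 copies -> -2, 1 -> -1, 2 -> 0, 3 -> +1, >= 4 -> +2).
#'
#' @param config a \code{\link{sim_config}}.
#' @param .seed RNG seed (default \code{config$seed}); \code{NULL} to use the
#'   current RNG state.
#' @return list of class \code{sim_profiles}: \code{profiles} (named list of
#'   \code{\link{cn_profile}}), \code{truth} (data.frame with sample_id,
#'   stratum, subtype, lauren, purity, insufficient_dna), \code{copies}
#'   (samples x bins true copy matrix), \code{events} (samples x peaks
#'   logical).
#' @export
simulate_profiles <- function(config, .seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(.seed)) set.seed(.seed)
  sheet <- sim_sample_sheet(config)
  # "other"-histology tumors still carry a molecular subtype
  idx_other <- which(sheet$lauren == "other")
  if (length(idx_other) > 0)
    sheet$subtype[idx_other] <- ifelse(
      runif(length(idx_other)) < attr(sheet, "p_gs"), "GS", "CIN")
  grid <- config$grid
  n_bins <- nrow(grid)
  mids <- bin_mid(grid)
  peak_bins <- lapply(seq_len(nrow(config$peaks)), function(j)
    which(grid$chrom == config$peaks$chrom[j] &
            mids >= config$peaks$start[j] & mids <= config$peaks$end[j]))
  profiled <- which(!sheet$insufficient_dna)
  copies_mat <- matrix(2L, length(profiled), n_bins,
                       dimnames = list(sheet$sample_id[profiled], NULL))
  events <- matrix(FALSE, length(profiled), nrow(config$peaks),
                   dimnames = list(sheet$sample_id[profiled],
                                   config$peaks$peak_id))
  purity <- runif(length(profiled), config$purity_range[1],
                  config$purity_range[2])
  profiles <- vector("list", length(profiled))
  for (k in seq_along(profiled)) {
    i <- profiled[k]
    f <- if (sheet$subtype[i] == "GS") config$peaks$f_gs else config$peaks$f_cin
    ev <- runif(nrow(config$peaks)) < f
    events[k, ] <- ev
    copies <- rep(2, n_bins)
    for (j in which(ev)) copies[peak_bins[[j]]] <- config$peaks$copies[j]
    copies_mat[k, ] <- as.integer(copies)
    seg <- mix_log2(copies, purity[k])
    obs <- seg + if (config$sigma > 0) rnorm(n_bins, 0, config$sigma) else 0
    call <- pmax(-2L, pmin(2L, as.integer(sign(copies - 2))))
    call[copies == 0] <- -2L
    call[copies >= 4] <- 2L
    profiles[[k]] <- cn_profile(sheet$sample_id[i], obs, seg, call,
                                purity[k], grid)
  }
  names(profiles) <- sheet$sample_id[profiled]
  truth <- sheet
  truth$purity <- NA_real_
  truth$purity[profiled] <- purity
  structure(list(profiles = profiles, truth = truth, copies = copies_mat,
                 events = events),
            class = "sim_profiles")
}

#' Simulate cancer-related survival
#'
#' Exponential event times per stratum calibrated to the configured five-year
#' survival (\code{lambda = -log(S5)/60} per month), independent uniform
#' censoring over \code{(0, censor_max)} months. Samples outside the four
#' strata (other histology, insufficient DNA) get the cohort-weighted mean
#' hazard.
#'
#' @param truth data.frame with columns \code{sample_id}, \code{stratum}.
#' @param config a \code{\link{sim_config}}.
#' @param .seed RNG seed (default \code{config$seed + 1}).
#' @return data.frame: sample_id, time_months, event.
#' @export
simulate_survival <- function(truth, config, .seed = config$seed + 1) {
  if (any(config$s5 <= 0 | config$s5 >= 1))
    stop_input("simulate_survival: s5 outside (0, 1)")
  if (!is.null(.seed)) set.seed(.seed)
  lam <- -log(config$s5) / 60
  w <- config$n_strata[names(config$s5)]
  lam_pooled <- sum(lam * w) / sum(w)
  lambda <- ifelse(is.na(truth$stratum), lam_pooled, lam[truth$stratum])
  t_event <- rexp(nrow(truth), rate = lambda)
  t_cens <- runif(nrow(truth), 0, config$censor_max)
  data.frame(sample_id = truth$sample_id,
             time_months = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

#' Simulate a labeled reference panel at peak level
#'
#' Draws peak-level log2 vectors directly: the cluster template mean per peak
#' (event probability times the pure-tumor log2 of the event copy state) plus
#' Gaussian noise.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_ref named sizes \code{c(GS=, CIN=)} (default from config).
#' @param .seed RNG seed (default \code{config$seed + 3}).
#' @return list: \code{matrix} (samples x peaks), \code{labels} (character).
#' @export
simulate_reference <- function(config, n_ref = config$n_ref,
                               .seed = config$seed + 3) {
  if (any(n_ref < 1)) stop_input("simulate_reference: n_ref must be >= 1")
  if (!is.null(.seed)) set.seed(.seed)
  tmpl <- peak_template_centroids(config$peaks)
  n <- sum(n_ref)
  labels <- rep(c("GS", "CIN"), c(n_ref[["GS"]], n_ref[["CIN"]]))
  mu <- rbind(matrix(tmpl[, "GS"], n_ref[["GS"]], nrow(tmpl), byrow = TRUE),
              matrix(tmpl[, "CIN"], n_ref[["CIN"]], nrow(tmpl), byrow = TRUE))
  noise <- if (config$sigma_ref > 0)
    matrix(rnorm(n * nrow(tmpl), 0, config$sigma_ref), n) else 0
  m <- mu + noise
  dimnames(m) <- list(sprintf("REF%04d", seq_len(n)), config$peaks$peak_id)
  list(matrix = m, labels = setNames(labels, rownames(m)))
}

#' Template centroids implied by a peak template
#'
#' @param peaks peak template with \code{copies}, \code{f_gs}, \code{f_cin}.
#' @return matrix peaks x c("GS","CIN") of expected peak-level log2 values.
#' @export
peak_template_centroids <- function(peaks) {
  pure <- log2(pmax(2^-10, peaks$copies / 2))
  cbind(GS = peaks$f_gs * pure, CIN = peaks$f_cin * pure)
}

#' Simulate clinical covariates
#'
#' Categorical covariates are drawn per sample from the stratum-specific
#' level frequencies; age from a stratum-specific normal. Samples outside the
#' four strata use the cohort-weighted marginal frequencies.
#'
#' @param truth data.frame with \code{sample_id}, \code{stratum}.
#' @param config a \code{\link{sim_config}}.
#' @param .seed RNG seed (default \code{config$seed + 2}).
#' @return data.frame: sample_id, one column per covariate, age.
#' @export
simulate_covariates <- function(truth, config, .seed = config$seed + 2) {
  for (nm in names(config$covariates)) {
    m <- config$covariates[[nm]]
    if (any(abs(colSums(m) - 1) > 1e-6))
      stop_input("simulate_covariates: frequencies of '", nm,
                 "' do not sum to 1")
  }
  if (!is.null(.seed)) set.seed(.seed)
  n <- nrow(truth)
  w <- config$n_strata / sum(config$n_strata)
  out <- data.frame(sample_id = truth$sample_id, stringsAsFactors = FALSE)
  for (nm in names(config$covariates)) {
    m <- config$covariates[[nm]]
    marginal <- as.numeric(m[, names(w), drop = FALSE] %*% w)
    out[[nm]] <- vapply(seq_len(n), function(i) {
      p <- if (is.na(truth$stratum[i])) marginal else m[, truth$stratum[i]]
      sample(rownames(m), 1, prob = p)
    }, "")
  }
  mu_age <- ifelse(is.na(truth$stratum),
                   sum(config$age_mean[names(w)] * w),
                   config$age_mean[truth$stratum])
  out$age <- round(rnorm(n, mu_age, config$age_sd), 1)
  out
}

#' Simulate a complete synthetic cohort
#'
#' Runs all generators under seeds derived from \code{config$seed}
#' (profiles, survival, covariates, reference panel) and assembles the
#' clinical table.
#'
#' @param config a \code{\link{sim_config}}.
#' @return Object of class \code{synthetic_cohort}: \code{config},
#'   \code{profiles}, \code{truth}, \code{copies}, \code{events},
#'   \code{clinical} (sample_id, stratum, subtype, lauren, insufficient_dna,
#'   time_months, event, covariates, age), \code{reference} (matrix +
#'   labels).
#' @export
simulate_cohort <- function(config) {
  sim <- simulate_profiles(config)
  surv <- simulate_survival(sim$truth, config)
  cov <- simulate_covariates(sim$truth, config)
  ref <- simulate_reference(config)
  clinical <- merge(merge(sim$truth, surv, by = "sample_id"), cov,
                    by = "sample_id")
  clinical <- clinical[order(clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  structure(list(config = config, profiles = sim$profiles, truth = sim$truth,
                 copies = sim$copies, events = sim$events,
                 clinical = clinical, reference = ref),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort:", nrow(x$clinical), "samples (",
      length(x$profiles), "profiled ), seed", x$config$seed, "\n")
  invisible(x)
}

#' Apply the cohort exclusions
#'
#' From the EBV-negative/MSS series, excludes tumors whose histology does not
#' fit the Lauren classification ("other") and tumors with insufficient DNA
#' for copy-number analysis, reporting both counts.
#'
#' @param clinical clinical data.frame with \code{lauren} and
#'   \code{insufficient_dna} columns.
#' @return list of class \code{cohort_filter}: \code{clinical} (filtered),
#'   \code{n_input}, \code{n_other}, \code{n_insufficient}, \code{n_analyzable}.
#' @export
filter_cohort <- function(clinical) {
  n_input <- nrow(clinical)
  other <- !is.na(clinical$lauren) & clinical$lauren == "other"
  insuff <- clinical$insufficient_dna | is.na(clinical$lauren)
  keep <- !other & !insuff
  structure(list(clinical = clinical[keep, , drop = FALSE],
                 n_input = n_input,
                 n_other = sum(other),
                 n_insufficient = sum(insuff),
                 n_analyzable = sum(keep)),
            class = "cohort_filter")
}

#' @export
print.cohort_filter <- function(x, ...) {
  cat("cohort filter:", x$n_input, "->", x$n_analyzable, "analyzable (",
      x$n_other, "'other' histology,", x$n_insufficient,
      "insufficient DNA excluded )\n")
  invisible(x)
}
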