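small_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             n_strata = c("GS-intestinal" = 8, "GS-diffuse" = 12,
                          "CIN-intestinal" = 25, "CIN-diffuse" = 15),
             n_other = 0, n_insufficient = 0, ...)
}

test_that("generators are seed-deterministic", {
  c1 <- simulate_cohort(small_config(seed = 7))
  c2 <- simulate_cohort(small_config(seed = 7))
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$copies, c2$copies)
  expect_identical(lapply(c1$profiles, `[[`, "log2_obs"),
                   lapply(c2$profiles, `[[`, "log2_obs"))
  expect_identical(c1$reference$matrix, c2$reference$matrix)
  c3 <- simulate_cohort(small_config(seed = 8))
  expect_false(identical(c1$clinical$time_months, c3$clinical$time_months))
})

test_that("noiseless full-purity profiles follow the closed-form mixture", {
  grid <- mini_grid()
  pk <- default_peak_template(grid)
  pk$f_gs <- 0; pk$f_cin <- 1  # all events present in CIN samples
  cfg <- sim_config(seed = 3,
                    n_strata = c("GS-intestinal" = 2, "GS-diffuse" = 2,
                                 "CIN-intestinal" = 2, "CIN-diffuse" = 2),
                    n_other = 0, n_insufficient = 0, peaks = pk,
                    sigma = 0, purity_range = c(1, 1))
  sim <- simulate_profiles(cfg)
  cin <- sim$profiles[[which(sim$truth$subtype == "CIN")[1]]]
  amp_peak <- pk[pk$copies == 4, ][1, ]
  bins <- which(grid$chrom == amp_peak$chrom &
                  (grid$start + grid$end) / 2 >= amp_peak$start &
                  (grid$start + grid$end) / 2 <= amp_peak$end)
  expect_equal(cin$log2_obs[bins], rep(1, length(bins)))   # log2(4/2)
  expect_equal(cin$call[bins], rep(2L, length(bins)))
  del_peak <- pk[pk$direction == "deletion", ][1, ]
  dbins <- which(grid$chrom == del_peak$chrom &
                   (grid$start + grid$end) / 2 >= del_peak$start &
                   (grid$start + grid$end) / 2 <= del_peak$end)
  expect_equal(cin$log2_obs[dbins], rep(-1, length(dbins)))  # log2(1/2)
  expect_equal(cin$call[dbins], rep(-1L, length(dbins)))
  gs <- sim$profiles[[which(sim$truth$subtype == "GS")[1]]]
  expect_true(all(gs$log2_obs == 0))
})

test_that("GS cohorts are more stable than CIN cohorts", {
  cfg <- small_config(seed = 10)
  sim <- simulate_profiles(cfg)
  gii <- compute_gii(sim$profiles, cfg$grid)
  gii$subtype <- sim$truth$subtype[match(gii$sample_id, sim$truth$sample_id)]
  expect_lt(mean(gii$gii[gii$subtype == "GS"]),
            mean(gii$gii[gii$subtype == "CIN"]))
  # GII equals the configured expected altered fraction up to binomial error
  cin_pk <- cfg$peaks
  bins_per_pk <- cin_pk$end - cin_pk$start + 1
  expected <- 100 * sum(cin_pk$f_cin * bins_per_pk) / 3e7
  cin_mean <- mean(gii$gii[gii$subtype == "CIN"])
  expect_lt(abs(cin_mean - expected), 5)
})

test_that("survival generator matches its exponential calibration", {
  expect_error(
    sim_config(s5 = c("GS-intestinal" = 1.2, "GS-diffuse" = 0.5,
                      "CIN-intestinal" = 0.5, "CIN-diffuse" = 0.5)),
    class = "gscin_input_error")
  # near-certain survival -> near-zero event rate
  cfg <- small_config(seed = 12,
                      s5 = c("GS-intestinal" = 0.999, "GS-diffuse" = 0.999,
                             "CIN-intestinal" = 0.999, "CIN-diffuse" = 0.999))
  surv <- simulate_survival(data.frame(
    sample_id = paste0("x", 1:2000),
    stratum = rep(names(cfg$n_strata), 500)), cfg)
  expect_lt(mean(surv$event), 0.03)
  # two-stratum hazard ratio equals the ratio of calibrated hazards
  set.seed(1)
  tr <- data.frame(sample_id = paste0("x", 1:2000),
                   stratum = rep(c("GS-intestinal", "CIN-diffuse"), 1000))
  surv2 <- simulate_survival(tr, small_config(seed = 5), .seed = 6)
  d <- merge(tr, surv2, by = "sample_id")
  d$grp <- factor(d$stratum, levels = c("GS-intestinal", "CIN-diffuse"))
  fit <- cox_fit(survival::Surv(time_months, event) ~ grp, d)
  hr_true <- log(0.315) / log(0.614)
  expect_lt(abs(fit$table$HR - hr_true) / hr_true, 0.15)
})

test_that("reference panel reproduces the template and tightens with n", {
  cfg <- small_config(seed = 2, sigma_ref = 0)
  ref0 <- simulate_reference(cfg)
  tmpl <- peak_template_centroids(cfg$peaks)
  gs_rows <- ref0$matrix[ref0$labels == "GS", ]
  expect_true(all(abs(sweep(gs_rows, 2, tmpl[, "GS"])) < 1e-12))
  fit <- gscin_fit(ref0$matrix, ref0$labels)
  expect_equal(unname(fit$mu_gs), unname(tmpl[, "GS"]))
  expect_equal(unname(fit$mu_cin), unname(tmpl[, "CIN"]))
  # centroid error shrinks roughly like 1/sqrt(n)
  cfg2 <- small_config(seed = 2, sigma_ref = 0.3)
  err <- vapply(c(100, 400), function(nr) {
    errs <- vapply(1:20, function(k) {
      r <- simulate_reference(cfg2, n_ref = c(GS = nr, CIN = nr),
                              .seed = 100 + k)
      f <- gscin_fit(r$matrix, r$labels)
      sqrt(mean((f$mu_gs - tmpl[, "GS"])^2))
    }, 0)
    mean(errs)
  }, 0)
  expect_lt(err[2] / err[1], 0.65)
  expect_error(simulate_reference(cfg, n_ref = c(GS = 0, CIN = 5)),
               class = "gscin_input_error")
})

test_that("covariate generator respects stratum frequencies", {
  cfg <- small_config(seed = 4)
  truth <- data.frame(sample_id = paste0("x", 1:50),
                      stratum = rep(names(cfg$n_strata), length.out = 50))
  # degenerate frequency: every draw lands on the single level
  cfg$covariates$sex <- matrix(rep(c(1, 0), 4), 2,
                               dimnames = dimnames(cfg$covariates$sex))
  cov <- simulate_covariates(truth, cfg)
  expect_true(all(cov$sex == "male"))
  cfg_bad <- cfg
  cfg_bad$covariates$sex[1, 1] <- 0.7
  expect_error(simulate_covariates(truth, cfg_bad),
               class = "gscin_input_error")
  expect_identical(simulate_covariates(truth, cfg),
                   simulate_covariates(truth, cfg))
  # realized counts stay within the multinomial envelope of the source table
  cfg5 <- sim_config(seed = 5, n_other = 0, n_insufficient = 0)
  truth5 <- data.frame(sample_id = sprintf("y%03d", 1:309),
                       stratum = rep(names(cfg5$n_strata), cfg5$n_strata))
  cov5 <- simulate_covariates(truth5, cfg5)
  male_counts <- table(factor(cov5$sex, c("male", "female")),
                       factor(truth5$stratum, names(cfg5$n_strata)))["male", ]
  expected_male <- c(9, 23, 91, 40)
  n_strat <- c(24, 57, 142, 86)
  p_male <- expected_male / n_strat
  lo <- qbinom(0.025, n_strat, p_male)
  hi <- qbinom(0.975, n_strat, p_male)
  expect_true(all(male_counts >= lo & male_counts <= hi))
})

test_that("classification recovers the generating subtype", {
  # at the default separation essentially every sample is recovered
  cfg <- small_config(seed = 20)
  cohort <- simulate_cohort(cfg)
  pm <- summarize_peaks(cohort$profiles, cfg$peaks, cfg$grid)
  fit <- gscin_fit(cohort$reference$matrix, cohort$reference$labels)
  calls <- predict(fit, pm)
  truth <- cohort$truth$subtype[match(calls$sample_id,
                                      cohort$truth$sample_id)]
  expect_gte(mean(as.character(calls$label) == truth), 0.99)
  # noiseless limit: exact recovery, and recovery degrades with noise
  cfg0 <- small_config(seed = 21, sigma = 0, sigma_ref = 0)
  ch0 <- simulate_cohort(cfg0)
  pm0 <- summarize_peaks(ch0$profiles, cfg0$peaks, cfg0$grid)
  calls0 <- predict(gscin_fit(ch0$reference$matrix, ch0$reference$labels),
                    pm0)
  truth0 <- ch0$truth$subtype[match(calls0$sample_id, ch0$truth$sample_id)]
  expect_equal(mean(as.character(calls0$label) == truth0), 1)
})

test_that("cohort exclusions reproduce the trial arithmetic", {
  cfg <- sim_config(seed = 30)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$clinical), 371)
  fc <- filter_cohort(cohort$clinical)
  expect_equal(fc$n_other, 39)
  expect_equal(fc$n_insufficient, 23)
  expect_equal(fc$n_analyzable, 309)
})
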