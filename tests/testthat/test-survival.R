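test_that("product-limit estimate matches hand computation", {
  km <- km_fit(c(10, 20, 30, 40), c(1, 1, 1, 1))
  at25 <- survival_at(km, 25)
  expect_equal(at25$surv, 0.5)
  expect_equal(survival_at(km, 0)$surv, 1)
  # no events -> flat at 1
  km0 <- km_fit(c(5, 10, 15), c(0, 0, 0))
  expect_equal(suppressWarnings(survival_at(km0, 12))$surv, 1)
  expect_error(km_fit(c(-1, 2), c(1, 0)), class = "gscin_input_error")
  # without censoring KM equals the empirical survival function
  set.seed(2)
  t <- rexp(50, 0.02)
  km2 <- km_fit(t, rep(1, 50))
  for (q in c(10, 30, 60)) {
    expect_equal(survival_at(km2, q)$surv, mean(t > q))
  }
})

test_that("truncation time is the first time under 10% at risk", {
  t <- 1:20
  km <- km_fit(t, rep(1, 20))
  # at-risk drops below 2 when 19 subjects have left: at time 20
  expect_equal(unname(km$truncation["all"]), 20)
  expect_warning(survival_at(km, 50), "beyond last follow-up")
})

test_that("KM at 60 months matches the exponential closed form", {
  set.seed(60)
  s5 <- 0.615
  lambda <- -log(s5) / 60
  d <- sim_exp_surv(20000, lambda)
  km <- km_fit(d$time, d$event)
  expect_lt(abs(survival_at(km, 60)$surv - s5), 0.01)
})

test_that("log-rank test is calibrated and matches permutation enumeration", {
  # duplicated groups: no difference
  t <- c(3, 6, 9, 12, 15)
  e <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(t, e, factor(rep("a", 5), levels = c("a", "b"))),
               class = "gscin_input_error")
  # small-sample chi-square p close to the exhaustive permutation p
  time <- c(2, 4, 5, 7, 9, 11, 13, 16)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  group <- rep(c("a", "b"), 4)
  p_perm <- perm_logrank_p(time, event, group)
  p_chisq <- logrank_test(time, event, group)$p_value
  expect_lt(abs(p_chisq - p_perm), 0.1)
  # type-I error at the nominal level under the null
  set.seed(14)
  rej <- mean(replicate(1000, {
    d <- sim_exp_surv(40, 0.01)
    logrank_test(d$time, d$event, rep(c("a", "b"), 20))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("Cox fit maximizes the partial likelihood", {
  # identical arms -> beta ~ 0
  d <- data.frame(time = rep(c(3, 6, 9, 12), 2), event = rep(c(1, 1, 0, 1), 2),
                  x = rep(0:1, each = 4))
  fit <- cox_fit(survival::Surv(time, event) ~ x, d)
  expect_lt(abs(fit$table$beta), 1e-6)
  # one continuous covariate, untied times: matches a 1-D grid maximizer
  set.seed(8)
  n <- 120
  x <- rnorm(n)
  t_ev <- rexp(n, 0.02 * exp(0.7 * x))
  t_c <- runif(n, 0, 100)
  d2 <- data.frame(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c),
                   x = x)
  fit2 <- cox_fit(survival::Surv(time, event) ~ x, d2)
  opt <- optimize(function(b) breslow_loglik(b, d2$time, d2$event, d2$x),
                  c(-3, 3), maximum = TRUE, tol = 1e-8)
  expect_lt(abs(fit2$table$beta - opt$maximum), 1e-4)
  # local maximality of the returned coefficient
  b <- fit2$table$beta
  ll <- function(bb) breslow_loglik(bb, d2$time, d2$event, d2$x)
  expect_gte(ll(b), ll(b + 0.01))
  expect_gte(ll(b), ll(b - 0.01))
  expect_error(cox_fit(survival::Surv(time, event) ~ x,
                       transform(d2, event = 0)),
               class = "gscin_stat_error")
})

test_that("backward selection drops noise and keeps signal", {
  # all-significant model is fully retained
  set.seed(21)
  n <- 400
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.02 * exp(1.0 * x1 + 0.8 * x2))
  d <- data.frame(time = pmin(t_ev, runif(n, 0, 100)),
                  event = as.integer(t_ev <= runif(n, 0, 100)))
  # regenerate censoring consistently
  t_c <- runif(n, 0, 100)
  d <- data.frame(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c),
                  x1 = factor(x1), x2 = factor(x2))
  bs <- backward_select(d, c("x1", "x2"))
  expect_setequal(bs$retained, c("x1", "x2"))
  # a pure-noise covariate is dropped at close to the theoretical rate:
  # under the null its LRT p is uniform, so it survives selection at
  # threshold 0.10 in about 10% of replicates
  set.seed(31)
  res <- replicate(30, {
    n <- 1000
    strong <- rbinom(n, 1, 0.5)
    noise <- factor(sample(letters[1:3], n, replace = TRUE))
    t_ev <- rexp(n, 0.02 * exp(1.0 * strong))
    t_c <- runif(n, 0, 120)
    dd <- data.frame(time = pmin(t_ev, t_c),
                     event = as.integer(t_ev <= t_c),
                     strong = factor(strong), noise = noise)
    bs <- backward_select(dd, c("strong", "noise"))
    c(noise_dropped = !("noise" %in% bs$retained),
      strong_kept = "strong" %in% bs$retained)
  })
  expect_true(all(res["strong_kept", ]))
  expect_gte(mean(res["noise_dropped", ]), 0.75)
  # a lone non-significant term yields the null model
  set.seed(41)
  n <- 200
  dd <- data.frame(time = rexp(n, 0.02), event = 1,
                   z = factor(rbinom(n, 1, 0.5)))
  dd$event <- as.integer(dd$time <= (cc <- runif(n, 0, 100)))
  dd$time <- pmin(dd$time, cc)
  bs <- backward_select(dd, "z")
  expect_length(bs$retained, 0)
  expect_null(bs$fit)
  expect_error(backward_select(dd, character(0)),
               class = "gscin_input_error")
})

test_that("Fisher r x c agrees with the hypergeometric closed form", {
  set.seed(12)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8) + 1, 2, 2)
    expect_equal(fisher_rxc(tab)$p_value, fisher_2x2_oracle(tab),
                 tolerance = 1e-12)
  }
  # single nonzero column: margins carry no information
  expect_equal(fisher_rxc(matrix(c(3, 5, 0, 0), 2))$p_value, 1)
  expect_error(fisher_rxc(matrix(c(-1, 2, 3, 4), 2)),
               class = "gscin_input_error")
  # Monte-Carlo mode converges to the exact p
  tab <- matrix(c(12, 5, 3, 14), 2)
  p_exact <- fisher_rxc(tab)$p_value
  p_mc <- fisher_rxc(tab, mode = "montecarlo", n_mc = 2e5, seed = 99)$p_value
  se <- sqrt(p_exact * (1 - p_exact) / 2e5)
  expect_lt(abs(p_mc - p_exact), 4 * se)
})

test_that("one-way ANOVA reduces to the squared t statistic for two groups", {
  # duplicated data across groups: no between-group variance
  v <- c(1.2, 3.4, 2.2, 5.6)
  an <- oneway_anova(c(v, v), rep(c("a", "b"), each = 4))
  expect_lt(an$F, 1e-12)
  expect_gt(an$p_value, 0.999)
  set.seed(17)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  an2 <- oneway_anova(c(x, y), rep(c("a", "b"), c(30, 25)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(an2$F, unname(tt$statistic^2), tolerance = 1e-9)
  expect_equal(an2$p_value, tt$p.value, tolerance = 1e-9)
  expect_error(oneway_anova(x, rep("a", 30)), class = "gscin_input_error")
  # type-I calibration under equal means
  set.seed(23)
  rej <- mean(replicate(1000, {
    vals <- rnorm(45)
    oneway_anova(vals, rep(c("a", "b", "c"), 15))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})
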