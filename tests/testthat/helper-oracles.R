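# Independent brute-force oracles used across tests. These deliberately use
# naive direct computation, separate from the package implementation paths.

# tiny grid: one chromosome of n equal bins (width 1e5)
tiny_grid <- function(n = 10, chrom = "1") {
  regular_grid(setNames(n * 1e5, chrom))
}

# quick profile constructor: constant-by-segment values given per bin
quick_profile <- function(id, grid, seg_values, calls = NULL, purity = 1,
                          usable = grid$usable) {
  if (is.null(calls)) calls <- rep(0L, nrow(grid))
  cn_profile(id, log2_obs = seg_values, log2_seg = seg_values, call = calls,
             purity = purity, grid = grid, usable = usable)
}

# length-weighted mean of corrected segmented log2 over usable bins
# overlapping [start, end] on chrom; naive double loop
peak_mean_oracle <- function(profile, grid, chrom, start, end) {
  v <- purity_correct(profile$log2_seg, profile$purity)
  num <- 0; den <- 0
  for (i in seq_len(nrow(grid))) {
    if (grid$chrom[i] != chrom) next
    w <- min(grid$end[i], end) - max(grid$start[i], start) + 1
    if (w <= 0) next
    if (!profile$usable[i] || is.na(v[i])) next
    num <- num + w * v[i]
    den <- den + w
  }
  if (den == 0) NA_real_ else num / den
}

# nearest-centroid assignment, one sample, plain loop
assign_oracle <- function(x, mu_gs, mu_cin) {
  ok <- !is.na(x)
  d_gs <- sqrt(sum((x[ok] - mu_gs[ok])^2))
  d_cin <- sqrt(sum((x[ok] - mu_cin[ok])^2))
  list(label = if (d_gs <= d_cin) "GS" else "CIN", d_gs = d_gs, d_cin = d_cin)
}

# exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Breslow log partial likelihood for untied survival data, one covariate
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# exhaustive permutation p for the log-rank test with fixed group sizes
perm_logrank_p <- function(time, event, group) {
  n <- length(time)
  g1 <- sum(group == levels(factor(group))[1])
  obs <- logrank_test(time, event, group)$statistic
  combs <- utils::combn(n, g1)
  stats <- apply(combs, 2, function(idx) {
    g <- rep("b", n); g[idx] <- "a"
    logrank_test(time, event, g)$statistic
  })
  mean(stats >= obs - 1e-12)
}

# direct re-statement of the region merge rule, written independently:
# running per-sample modal signature with ties keeping the previous value
regionize_oracle <- function(calls, chrom, tau) {
  n <- nrow(calls)
  region <- integer(ncol(calls))
  r <- 0
  for (j in seq_len(ncol(calls))) {
    start_new <- j == 1 || chrom[j] != chrom[j - 1]
    if (!start_new) {
      # recompute the modal signature of the running region bin by bin
      member <- which(region == r)
      sig <- vapply(seq_len(n), function(i) {
        v <- calls[i, member]
        counts <- table(factor(v, levels = -2:2))
        # walk the region again to reproduce tie-keeps-previous updates
        cur <- v[1]
        tally <- setNames(rep(0, 5), as.character(-2:2))
        for (b in v) {
          tally[as.character(b)] <- tally[as.character(b)] + 1
          if (max(tally) > tally[as.character(cur)])
            cur <- as.integer(names(tally)[which.max(tally)])
        }
        cur
      }, 0L)
      if (mean(calls[, j] != sig) > tau) start_new <- TRUE
    }
    if (start_new) r <- r + 1
    region[j] <- r
  }
  region
}

# simulate a simple exponential two-group survival dataset
sim_exp_surv <- function(n, lambda, censor_max = 120) {
  t_ev <- rexp(n, lambda)
  t_c <- runif(n, 0, censor_max)
  data.frame(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}
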