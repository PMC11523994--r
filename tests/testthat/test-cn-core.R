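test_that("segment rasterization follows the midpoint convention", {
  g <- tiny_grid(10)
  seg <- data.frame(sample = "s1", chrom = "1", start = 1, end = 1e6,
                    n_bins = 10, seg_log2 = 0.3)
  f <- tempfile(fileext = ".seg")
  write.table(seg, f, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- read_seg(f, g, c(s1 = 1))
  expect_equal(prof$s1$log2_seg, rep(0.3, 10))

  # two abutting segments split exactly at the bin boundary
  seg2 <- data.frame(sample = "s1", chrom = "1", start = c(1, 400001),
                     end = c(400000, 1e6), n_bins = c(4, 6),
                     seg_log2 = c(0.2, -0.1))
  write.table(seg2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- read_seg(f, g, c(s1 = 1))
  expect_equal(prof$s1$log2_seg, c(rep(0.2, 4), rep(-0.1, 6)))

  # segment ending mid-bin: the bin goes to the segment covering its midpoint
  seg3 <- data.frame(sample = "s1", chrom = "1", start = c(1, 430001),
                     end = c(430000, 1e6), n_bins = c(4, 6),
                     seg_log2 = c(0.2, -0.1))
  write.table(seg3, f, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- read_seg(f, g, c(s1 = 1))
  # bin 5 spans 400001-500000, midpoint 450000.5 -> second segment
  expect_equal(prof$s1$log2_seg[5], -0.1)
  # uncovered bins become unusable
  seg4 <- data.frame(sample = "s1", chrom = "1", start = 1, end = 500000,
                     n_bins = 5, seg_log2 = 0.1)
  write.table(seg4, f, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- read_seg(f, g, c(s1 = 1))
  expect_equal(prof$s1$usable, rep(c(TRUE, FALSE), each = 5))
})

test_that("read_seg rejects malformed input", {
  g <- tiny_grid(10)
  f <- tempfile(fileext = ".seg")
  overlapping <- data.frame(sample = "s1", chrom = "1", start = c(1, 300001),
                            end = c(500000, 1e6), n_bins = c(5, 7),
                            seg_log2 = c(0.1, 0.2))
  write.table(overlapping, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_seg(f, g, c(s1 = 1)), "overlapping.*s1",
               class = "gscin_input_error")
  unknown <- data.frame(sample = "s1", chrom = "7", start = 1, end = 1e6,
                        n_bins = 10, seg_log2 = 0)
  write.table(unknown, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_seg(f, g, c(s1 = 1)), "unknown chromosome")
  ok <- data.frame(sample = "s2", chrom = "1", start = 1, end = 1e6,
                   n_bins = 10, seg_log2 = 0)
  write.table(ok, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_seg(f, g, c(s1 = 1)), "without purity")
})

test_that("seg write/read round-trip preserves values and boundaries", {
  set.seed(7)
  g <- regular_grid(c("1" = 2e6, "2" = 1.5e6))
  profiles <- lapply(1:4, function(i) {
    # piecewise-constant values over random runs
    n <- nrow(g)
    brk <- sort(sample(2:(n - 1), 3))
    vals <- round(rnorm(4, 0, 0.5), 4)
    v <- rep(vals, diff(c(0, brk, n)))
    calls <- as.integer(sign(v) * (abs(v) > 0.3))
    quick_profile(paste0("s", i), g, v, calls, purity = runif(1, 0.4, 1))
  })
  names(profiles) <- vapply(profiles, `[[`, "", "sample_id")
  f <- tempfile(fileext = ".seg")
  write_seg(profiles, g, f)
  pur <- vapply(profiles, `[[`, 0, "purity")
  back <- read_seg(f, g, pur)
  for (id in names(profiles)) {
    expect_identical(back[[id]]$log2_seg, profiles[[id]]$log2_seg)
    expect_identical(back[[id]]$call, profiles[[id]]$call)
    expect_identical(back[[id]]$usable, profiles[[id]]$usable)
  }
})

test_that("purity correction inverts the admixture model", {
  expect_equal(purity_correct(0, 0.7), 0)
  r <- c(-1.2, -0.3, 0, 0.4, 1.1)
  expect_equal(purity_correct(r, 1), r)
  expect_equal(purity_correct(log2(1.25), 0.5), log2(1.5))
  expect_error(purity_correct(0, 0), class = "gscin_input_error")
  expect_error(purity_correct(0, 1.2), class = "gscin_input_error")
  # round trip: forward(correct(r)) == r whenever the floor is not hit
  set.seed(1)
  for (i in 1:200) {
    p <- runif(1, 0.05, 1)
    copies <- sample(0:6, 1)
    r_obs <- mix_log2(copies, p)
    q <- purity_correct(r_obs, p)
    if (copies > 0) expect_lt(abs(mix_log2(2 * 2^q, p) - r_obs), 1e-9)
  }
})

test_that("peak summarization is a length-weighted mean over usable bins", {
  g <- tiny_grid(10)
  pk <- peak_regions("p1", "1", 200001, 500000, "gain", "CN-high")
  prof <- list(quick_profile("s1", g, rep(0.3, 10)))
  expect_equal(summarize_peaks(prof, pk, g)[1, 1], 0.3)

  # 75% of overlapped length at 0.2 and 25% at 0.6 -> 0.3
  v <- c(rep(0.2, 3), 0.6, rep(0, 6))
  pk2 <- peak_regions("p1", "1", 1, 400000, "gain", "CN-high")
  prof2 <- list(quick_profile("s1", g, v))
  expect_equal(summarize_peaks(prof2, pk2, g)[1, 1], 0.3)

  # peak in an unusable desert -> NA
  usable <- rep(TRUE, 10); usable[3:6] <- FALSE
  prof3 <- list(quick_profile("s1", g, v, usable = usable))
  pk3 <- peak_regions("p1", "1", 250001, 550000, "gain", "CN-high")
  expect_true(is.na(summarize_peaks(prof3, pk3, g)[1, 1]))

  pk4 <- peak_regions("p1", "9", 1, 1000, "gain", "CN-high")
  expect_error(summarize_peaks(prof, pk4, g), "absent from grid")
})

test_that("peak summarization matches the brute-force oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n_bins <- sample(20:100, 1)
    g <- regular_grid(setNames(c(0.6, 0.4) * n_bins * 1e5, c("1", "2")))
    prof <- lapply(1:3, function(i) {
      v <- rep(round(rnorm(5), 3), length.out = nrow(g))
      usable <- runif(nrow(g)) > 0.1
      quick_profile(paste0("s", i), g, v, usable = usable,
                    purity = runif(1, 0.3, 1))
    })
    n_pk <- sample(2:10, 1)
    chrom <- sample(c("1", "2"), n_pk, replace = TRUE)
    start <- sample(seq(1, n_bins * 0.3 * 1e5, by = 5e4), n_pk)
    pk <- peak_regions(paste0("p", 1:n_pk), chrom, start,
                       start + sample(1:20, n_pk) * 7e4,
                       "gain", "CN-high")
    got <- summarize_peaks(prof, pk, g)
    for (i in seq_along(prof)) for (j in seq_len(n_pk)) {
      want <- peak_mean_oracle(prof[[i]], g, pk$chrom[j], pk$start[j],
                               pk$end[j])
      expect_equal(got[i, j], want, tolerance = 1e-12)
    }
  }
})

test_that("sex-chromosome peaks are excluded from the classification set", {
  pk <- synthetic_tcga_peaks()
  expect_equal(nrow(pk), 114)
  expect_equal(sum(is_sex <- pk$chrom == "X"), 7)
  kept <- suppressMessages(filter_autosomal_peaks(pk))
  expect_equal(nrow(kept), 107)
  # no sex chromosomes -> identity
  auto <- pk[pk$chrom != "X", ]
  expect_equal(nrow(suppressMessages(filter_autosomal_peaks(auto))), nrow(auto))
  # all on X -> empty with warning
  xonly <- pk[pk$chrom == "X", ]
  expect_warning(suppressMessages(filter_autosomal_peaks(xonly)), "no peaks")
})

test_that("GII is the altered fraction of the called genome", {
  g <- tiny_grid(10)
  zero <- quick_profile("s", g, rep(0, 10), rep(0L, 10))
  expect_equal(compute_gii(zero, g), 0)
  allalt <- quick_profile("s", g, rep(1, 10), rep(1L, 10))
  expect_equal(compute_gii(allalt, g), 100)
  three <- quick_profile("s", g, rep(0, 10), c(rep(1L, 3), rep(0L, 7)))
  expect_equal(compute_gii(three, g), 30)
  # permutation invariance of bin order
  set.seed(3)
  calls <- sample(c(-2L, -1L, 0L, 1L, 2L), 10, replace = TRUE)
  perm <- sample(10)
  expect_equal(compute_gii(quick_profile("a", g, rep(0, 10), calls), g),
               compute_gii(quick_profile("b", g, rep(0, 10), calls[perm]), g))
  # adding a neutral bin never increases GII
  g11 <- tiny_grid(11)
  gii10 <- compute_gii(quick_profile("a", g, rep(0, 10), calls), g)
  gii11 <- compute_gii(quick_profile("a", g11, rep(0, 11), c(calls, 0L)), g11)
  expect_lte(gii11, gii10)
  # no usable bins -> error
  none <- quick_profile("s", g, rep(0, 10), rep(0L, 10),
                        usable = rep(FALSE, 10))
  expect_error(compute_gii(none, g), class = "gscin_input_error")
})
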