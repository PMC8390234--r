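# Organization layer: arrays, array signal, interpolation, Welch PSD,
# phasing, spacing and positioning.

test_that("detect_arrays splits on gaps, state changes and chromosomes", {
  d <- toy_nuc_table(states = c(1L, 1L, 1L), gaps = c(200L, 400L))
  arr <- detect_arrays(d)
  expect_equal(arr$nucleosomes$array_id, c(1L, 1L, 2L))  # 400 >= 350 splits
  alt <- toy_nuc_table(states = c(1L, 2L, 1L, 2L), gaps = rep(180L, 3))
  expect_equal(detect_arrays(alt)$nucleosomes$array_id, 1:4)
  # per-state mean member count
  expect_equal(arr$per_state$ave_no, 1.5)
  expect_error(detect_arrays(toy_nuc_table(c(1L, 1L), gaps = -50L)),
               "not sorted")
  # random layouts match the quadratic oracle
  set.seed(9)
  for (rep in 1:10) {
    n <- 40
    d <- data.frame(chrom = sort(sample(c("chr1", "chr2"), n, TRUE)),
                    state = sample(1:3, n, TRUE))
    d <- d[order(d$chrom), ]
    d$dyad <- as.integer(unlist(tapply(
      rep(200L, n), d$chrom, function(x) 1000L + cumsum(sample(c(150L, 400L),
                                                               length(x),
                                                               TRUE)))))
    got <- detect_arrays(d)$nucleosomes$array_id
    expect_equal(got, brute_arrays(d, 350L))
  }
})

test_that("array_signal averages aligned member coverage", {
  base <- c(0, 1, 3, 1, 0)  # 50 bp of 10 bp/point signal
  d <- data.frame(chrom = "chr1", state = 1L,
                  start = c(1000L, 1200L, 5000L),
                  end = c(1050L, 1250L, 5050L),
                  dyad = c(1025L, 1225L, 5025L),
                  array_id = c(1L, 1L, 2L))
  sig <- array_signal(d, list(base, base, base), window = 1000L)
  expect_length(sig, 1L)
  v <- sig[["1"]]$values
  # array 1: copies at offsets 0 and 200 bp; array 2: copy at offset 0
  one <- numeric(100); one[1:5] <- base
  two <- one; two[21:25] <- base
  expect_equal(v, (two + one) / 2)
  # averaging two identical arrays is idempotent; constant signal conserved
  d2 <- d[c(1, 3), ]; d2$array_id <- c(1L, 2L); d2$state <- 2L
  s2 <- array_signal(d2, list(base, base), window = 50L)
  expect_equal(s2[["2"]]$values, base)
  cs <- array_signal(d2, list(rep(1, 5), rep(1, 5)), window = 50L)
  expect_equal(cs[["2"]]$values, rep(1, 5))
})

test_that("interpolation is linear, endpoint-preserving and validated", {
  s <- nuc_array_signal(c(0, 10), fs = 100)
  up <- interpolate_signal(s, 1000)
  expect_equal(up$values, seq(0, 10, by = 1))
  expect_equal(up$fs, 1000)
  const <- interpolate_signal(nuc_array_signal(rep(2, 7), 100), 1000)
  expect_equal(const$values, rep(2, 61))
  expect_error(interpolate_signal(s, 250), "integer multiple")
  # sine sampled every 10 bp then upsampled: deviation bounded by the
  # analytic linear-interpolation error A*(1 - cos(pi*h/P)), which is
  # 4.9% of amplitude at period 100 and under 2% for periods >= 160
  x10 <- seq(0, 990, by = 10)
  for (period in c(100, 185, 250)) {
    s <- nuc_array_signal(sin(2 * pi * x10 / period), fs = 100)
    up <- interpolate_signal(s, 1000)
    x1 <- seq(0, 990, by = 1)
    err <- max(abs(up$values - sin(2 * pi * x1 / period)))
    expect_lt(err, (1 - cos(pi * 10 / period)) + 1e-9)
    if (period >= 160) expect_lt(err, 0.02)
  }
})

test_that("welch_psd locates periodicity and satisfies Parseval", {
  x <- seq(0, 999)
  sine <- nuc_array_signal(sin(2 * pi * x / 200), fs = 1000)
  psd <- welch_psd(sine, frame_len = 512L)
  expect_length(psd$psd, 257L)
  peak_freq <- psd$freq[which.max(psd$psd)]
  expect_lt(abs(peak_freq - 5), 1000 / 512)  # within one bin of 5 Hz
  # constant signal: band power limited to Hann sidelobe leakage of the
  # DC line (first sidelobe -31 dB, decaying; an exact zero is not
  # attainable with the windowed periodogram)
  flat <- welch_psd(nuc_array_signal(rep(3, 600), 1000), frame_len = 512L)
  band <- flat$psd[flat$freq >= 4 & flat$freq <= 10]
  expect_lt(sum(band), 1e-4 * sum(flat$psd))
  # Parseval with a single frame: sum of the two-sided periodogram equals
  # the windowed frame energy
  set.seed(2)
  y <- rnorm(256)
  full <- welch_psd(nuc_array_signal(y, 1000), frame_len = 256L,
                    hop = 256L, onesided = FALSE)
  w <- 0.5 * (1 - cos(2 * pi * (0:255) / 255))
  expect_equal(sum(full$psd), sum((w * y)^2), tolerance = 1e-6)
  expect_error(welch_psd(nuc_array_signal(y, 1000), frame_len = 512L),
               "exceeds signal length")
})

test_that("phasing_score takes 1000x the band maximum, scaling as c^2", {
  psd <- data.frame(freq = 0:20, psd = 0)
  expect_equal(phasing_score(psd), 0)
  psd$psd[psd$freq == 6] <- 0.25
  expect_equal(phasing_score(psd), 250)
  expect_error(phasing_score(data.frame(freq = c(1, 2), psd = c(1, 1))),
               "inside the band")
  # amplitude scaling by c scales the score by c^2
  sig <- simulate_array_signal(period = 185, n_nucleosomes = 5, seed = 1)
  s1 <- phasing_score(welch_psd(sig, 512L))
  sig$values <- 3 * sig$values
  expect_equal(phasing_score(welch_psd(sig, 512L)), 9 * s1,
               tolerance = 1e-9)
})

test_that("frequency/period conversion is exact and involutive", {
  expect_equal(freq_to_period(4, fs = 1000), 250)
  expect_equal(freq_to_period(10, fs = 1000), 100)
  expect_equal(freq_to_period(5, fs = 500), 100)
  expect_error(freq_to_period(0), "positive")
  expect_error(period_to_freq(-5), "positive")
  for (f in c(0.5, 4, 7.3, 10)) {
    expect_equal(period_to_freq(freq_to_period(f, 1000), 1000), f)
  }
})

test_that("array_spacing finds maxima with the plateau rule", {
  v <- numeric(600)
  v[c(101, 286, 471)] <- 1  # maxima at 100, 285, 470 bp (0-based)
  sp <- array_spacing(nuc_array_signal(v, 1000))
  expect_equal(as.numeric(sp), 185)
  expect_equal(attr(sp, "maxima_bp"), c(100, 285, 470))
  # flat plateau at indices 10..14 (1-based 11..15) -> middle index
  p <- c(rep(0, 10), rep(1, 5), rep(0, 10), 2, 0)
  pm <- suppressWarnings(array_spacing(nuc_array_signal(p, 1000)))
  expect_equal(attr(pm, "maxima_bp")[1], 12)
  # even plateau: lower-middle
  pe <- c(0, rep(1, 4), 0, 2, 0)
  me <- suppressWarnings(array_spacing(nuc_array_signal(pe, 1000)))
  expect_equal(attr(me, "maxima_bp")[1], 2)
  expect_warning(one <- array_spacing(nuc_array_signal(c(0, 1, 0), 1000)),
                 "fewer than two")
  expect_true(is.na(one))
  # noiseless periodic signal: exact period at 1 bp resolution
  sig <- simulate_array_signal(period = 185, n_nucleosomes = 5,
                               decay = 1, noise_sd = 0, fs = 1000)
  expect_equal(as.numeric(array_spacing(sig)), 185)
  # max_intervals limits the averaged gaps
  sp4 <- array_spacing(sig, max_intervals = 2)
  expect_equal(attr(sp4, "n_intervals"), 2L)
})

test_that("spacing_range applies the rank-scaled tolerance", {
  expect_equal(spacing_range(185, interval = 1, rank = 3, coef_range = 1),
               c(177, 193))
  expect_equal(spacing_range(185, interval = 2, rank = 4, coef_range = 0),
               c(175, 195))
  degenerate <- spacing_range(185, interval = 0, rank = 1)
  expect_equal(degenerate, c(185, 185))
  expect_error(spacing_range(185, 1, 1, coef_range = -1), ">= 0")
})

test_that("iqr_normalize centers at Q1 and scales by the IQR", {
  v <- iqr_normalize(1:101)
  expect_equal(v[51], 0.5)
  expect_equal(v[26], 0)   # Q1 -> 0
  expect_equal(v[76], 1)   # Q3 -> 1
  # invariance under positive affine transforms
  set.seed(4)
  x <- rnorm(50)
  expect_equal(iqr_normalize(3.7 * x + 11), iqr_normalize(x),
               tolerance = 1e-9)
  expect_error(iqr_normalize(rep(5, 10)), "zero interquartile")
  expect_error(iqr_normalize(c(1, 2)), "at least 4")
})

test_that("rnp_score follows norm(enrich) / (norm(fwhm) + norm(std))", {
  set.seed(10)
  enrich <- runif(40, 50, 150); fwhm <- runif(40, 10, 80)
  std <- runif(40, 5, 45)
  got <- rnp_score(enrich, fwhm, std)
  manual <- iqr_normalize(enrich) /
    pmax(iqr_normalize(fwhm) + iqr_normalize(std), 0.1)
  expect_equal(got, manual)
  expect_true(all(is.finite(got)))
})

test_that("np_score applies median replacement and the Eq-8 form", {
  set.seed(12)
  n <- 40
  rec <- data.frame(
    height = runif(n, 1, 3), width = runif(n, 80, 160),
    area = runif(n, 5, 25), pval_peak = runif(n, 1, 12),
    pval_valley = runif(n, 1, 9),
    array_id = rep(1:10, each = 4))
  got <- np_score(rec)
  pv <- rec$pval_valley
  pv[seq(4, n, by = 4)] <- median(rec$pval_valley)
  manual <- (iqr_normalize(rec$height) +
               log2(pmax(iqr_normalize(rec$pval_peak) *
                           iqr_normalize(pv) + 1, 0.1)) +
               iqr_normalize(rec$area)) /
    (3 * pmax(iqr_normalize(rec$width), 0.1))
  expect_equal(as.numeric(got), manual)
  # a singleton array's only nucleosome is its own last member and gets the
  # replacement too
  rec1 <- rec
  rec1$array_id <- c(1L, rep(2:14, each = 3))
  got1 <- np_score(rec1)
  pv1 <- rec1$pval_valley
  pv1[c(1L, seq(4, n, by = 3))] <- median(rec1$pval_valley)
  manual1 <- (iqr_normalize(rec1$height) +
                log2(pmax(iqr_normalize(rec1$pval_peak) *
                            iqr_normalize(pv1) + 1, 0.1)) +
                iqr_normalize(rec1$area)) /
    (3 * pmax(iqr_normalize(rec1$width), 0.1))
  expect_equal(as.numeric(got1), manual1)
})

test_that("positioning_filter trims quantile tails per group", {
  s <- as.numeric(1:1000)
  pf <- positioning_filter(s)
  expect_equal(sum(pf$retained), 900L)
  expect_equal(pf$means$mean_score, mean(51:950))
  all_kept <- positioning_filter(s, q_low = 0, q_high = 1)
  expect_true(all(all_kept$retained))
  # grouped: equals the brute-force trimmed mean per group
  set.seed(13)
  g <- sample(c("a", "b"), 400, TRUE)
  x <- rnorm(400)
  pf2 <- positioning_filter(x, group = g)
  for (gg in c("a", "b")) {
    xi <- x[g == gg]
    q <- quantile(xi, c(0.05, 0.95), names = FALSE)
    expect_equal(pf2$means$mean_score[pf2$means$group == gg],
                 mean(xi[xi >= q[1] & xi <= q[2]]))
  }
})

test_that("organization_table assembles per-state metrics end to end", {
  truth <- sim_truth_model(2, 2, seed = 3)
  gen <- simulate_genome(20, seed = 31)
  sim <- simulate_states_and_marks(gen$genes, truth, seed = 32, n_marks = 2)
  nucs <- sim$nucleosomes
  org <- organization_table(nucs, sim$signals)
  expect_setequal(org$table$state, sort(unique(nucs$state)))
  expect_true(all(org$table$ave_no >= 1))
  expect_true(all(is.finite(org$table$phasing_score)))
  expect_true(all(is.finite(org$table$positioning_score)))
  # detected spacing should sit near the generating 185 bp for states with
  # enough arrays
  expect_true(all(abs(org$table$spacing_bp - 185) < 60, na.rm = TRUE))
})
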