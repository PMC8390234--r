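# Observation encoding: bitmask alphabet, fragment filter, mark assignment
# and sequence construction.

test_that("encode/decode implement the bitmask alphabet", {
  expect_identical(encode_observation(c("H3K4me3", "H3K79me2"), n = 7), 9L)
  expect_identical(encode_observation(integer(0), n = 7), 0L)
  expect_identical(encode_observation(0:6, n = 7), 127L)
  expect_identical(decode_observation(9L, n = 7), c(0L, 3L))
  expect_identical(decode_observation(0L, n = 7), integer(0))
  expect_error(encode_observation(7L, n = 7), "out of range")
  expect_error(encode_observation("H3K9ac", n = 7), "unknown mark")
  expect_error(decode_observation(128L, n = 7), "out of range")
  # full round trip over the 2^7 alphabet
  for (sym in 0:127) {
    expect_identical(encode_observation(decode_observation(sym, 7), 7), sym)
  }
})

test_that("filter_fragments keeps the inclusive length window", {
  frag <- data.frame(start = 0L, end = c(120L, 130L, 150L, 180L, 181L))
  kept <- filter_fragments(frag)
  expect_equal(kept$end, c(130L, 150L, 180L))
  expect_identical(nrow(filter_fragments(frag[0, ])), 0L)
  same <- filter_fragments(data.frame(start = 0L, end = 149:151),
                           min_len = 150, max_len = 150)
  expect_equal(same$end, 150L)
  expect_error(filter_fragments(data.frame(start = 10L, end = 5L)),
               "negative")
  # subset of input and idempotent
  set.seed(1)
  f <- data.frame(start = 0L, end = sample(100:220, 50, replace = TRUE))
  k1 <- filter_fragments(f)
  expect_true(all(k1$end %in% f$end))
  expect_equal(filter_fragments(k1), k1)
})

test_that("assign_marks follows the overlap-fraction rule", {
  nuc <- data.frame(chrom = "chr1", start = 100L, end = 247L)
  pk <- data.frame(chrom = "chr1", start = 150L, end = 400L, mark_id = 2L)
  expect_identical(assign_marks(nuc, pk, 0.5), 2L)  # 97/147 ~ 0.66
  disjoint <- data.frame(chrom = "chr1", start = 300L, end = 400L,
                         mark_id = 1L)
  expect_identical(assign_marks(nuc, disjoint, 0.5), integer(0))
  contains <- data.frame(chrom = "chr1", start = 0L, end = 1000L,
                         mark_id = 0L)
  expect_identical(assign_marks(nuc, contains, 1), 0L)
  other_chr <- data.frame(chrom = "chr2", start = 100L, end = 247L,
                          mark_id = 0L)
  expect_identical(assign_marks(nuc, other_chr, 0.5), integer(0))
  # stacked same-mark peaks are merged, not double counted
  stacked <- data.frame(chrom = "chr1", start = c(100L, 100L),
                        end = c(160L, 160L), mark_id = 0L)
  expect_identical(assign_marks(nuc, stacked, 0.5), integer(0))
})

test_that("assign_marks matches an oracle and is monotone in overlap fraction", {
  set.seed(42)
  for (rep in 1:20) {
    ns <- sample(1000L, 1)
    nuc <- data.frame(chrom = "chr1", start = ns, end = ns + 147L)
    pk <- data.frame(chrom = "chr1",
                     start = ns + sample(-150:150, 5, replace = TRUE),
                     mark_id = sample(0:2, 5, replace = TRUE))
    pk$end <- pk$start + sample(50:300, 5, replace = TRUE)
    frac <- runif(1, 0.1, 1)
    got <- assign_marks(nuc, pk, frac)
    # oracle: per-bp coverage per mark
    for (id in 0:2) {
      cov <- logical(147)
      sub <- pk[pk$mark_id == id, ]
      for (i in seq_len(nrow(sub))) {
        lo <- max(sub$start[i], nuc$start); hi <- min(sub$end[i], nuc$end)
        if (hi > lo) cov[(lo - nuc$start + 1):(hi - nuc$start)] <- TRUE
      }
      expect_identical(id %in% got, sum(cov) >= frac * 147)
    }
    # monotonicity: higher fraction never adds marks
    expect_true(all(assign_marks(nuc, pk, min(frac + 0.2, 1)) %in% got))
  }
})

make_toy_world <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
    tss = c(10000L, 30000L), tts = c(14000L, 26000L))
  dy <- c(9500L, 10500L, 13000L, 26500L, 28000L, 29500L)
  nucs <- data.frame(chrom = "chr1", start = dy - 73L, end = dy + 74L,
                     dyad = dy)
  peaks <- data.frame(chrom = "chr1", start = dy[c(1, 4)] - 80L,
                      end = dy[c(1, 4)] + 80L, mark_id = c(0L, 1L))
  list(genes = genes, nucs = nucs, peaks = peaks)
}

test_that("build_sequences orients, windows and duplicates correctly", {
  w <- make_toy_world()
  seqs <- build_sequences(w$nucs, w$peaks, w$genes, upstream_bp = 1000L,
                          downstream_bp = 500L, n_marks = 2L)
  sl <- sequence_list(seqs)
  # gA (+): nucleosomes at 9500 (marked bit0), 10500, 13000 in order
  expect_equal(sl$gA, c(1L, 0L, 0L))
  # gB (-): genomic order 26500 (bit1), 28000, 29500 -> reversed
  expect_equal(sl$gB, c(0L, 0L, 2L))
  # strand flip exactly reverses the sequence
  flipped <- w$genes
  flipped$strand <- c("-", "+")
  flipped$tss <- w$genes$tts; flipped$tts <- w$genes$tss
  seqs2 <- build_sequences(w$nucs, w$peaks, flipped, upstream_bp = 1000L,
                           downstream_bp = 500L, n_marks = 2L)
  sl2 <- sequence_list(seqs2)
  expect_equal(sl2$gA, rev(sl$gA))
  expect_equal(sl2$gB, rev(sl$gB))
})

test_that("build_sequences excludes distant nucleosomes, shares window overlaps", {
  w <- make_toy_world()
  far <- rbind(w$nucs, data.frame(chrom = "chr1", start = 499927L,
                                  end = 500074L, dyad = 500000L))
  seqs <- build_sequences(far, w$peaks, w$genes, upstream_bp = 1000L,
                          downstream_bp = 500L, n_marks = 2L)
  expect_false(500000L %in% seqs$dyad)
  # widen windows until they overlap: the shared nucleosome appears twice
  wide <- build_sequences(w$nucs, w$peaks, w$genes, upstream_bp = 20000L,
                          downstream_bp = 20000L, n_marks = 2L)
  expect_true(any(table(wide$nuc_id) == 2L))
  # dyad membership oracle on the wide windows
  for (i in seq_len(nrow(w$genes))) {
    g <- w$genes[i, ]
    lo <- if (g$strand == "+") g$tss - 20000L else g$tts - 20000L
    hi <- if (g$strand == "+") g$tts + 20000L else g$tss + 20000L
    expect_setequal(wide$dyad[wide$gene_id == g$gene_id],
                    w$nucs$dyad[w$nucs$dyad >= lo & w$nucs$dyad < hi])
  }
  bad <- w$genes
  bad$tts[1] <- bad$tss[1] - 100L
  expect_error(build_sequences(w$nucs, w$peaks, bad, n_marks = 2L),
               "TTS before TSS")
})
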