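# Synthetic-data generators: everything the pipeline reads can be emitted
# from a known ground truth, so every stage is testable offline.

#' A separated ground-truth HMM for simulations
#'
#' Builds an S-state model over the `2^n_marks` alphabet the way real
#' nucleosome states look: sticky transitions (diagonal mass
#' `self_prob`) and emissions concentrated on one anchor mark combination
#' per state (probability `anchor_prob`) with Dirichlet background over the
#' remaining symbols.
#'
#' @param n_states Number of states.
#' @param n_marks Number of marks (alphabet `2^n_marks`).
#' @param seed RNG seed.
#' @param self_prob Transition self-loop probability.
#' @param anchor_prob Emission mass on the state's anchor symbol.
#' @return An `hmm_model`.
#' @export
sim_truth_model <- function(n_states = 4L, n_marks = 3L, seed = 1L,
                            self_prob = 0.7, anchor_prob = 0.7) {
  V <- bitwShiftL(1L, n_marks)
  stopifnot(n_states <= V)
  set.seed(as.integer(seed))
  pi <- rep(1 / n_states, n_states)
  A <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states)) {
    off <- rdirichlet_row(n_states - 1L, 1) * (1 - self_prob)
    A[i, -i] <- off
    A[i, i] <- self_prob
  }
  if (n_states == 1L) A <- matrix(1, 1, 1)
  anchors <- sample(V, n_states) - 1L  # distinct anchor symbols
  B <- matrix(0, n_states, V)
  for (i in seq_len(n_states)) {
    bg <- rdirichlet_row(V, 0.3) * (1 - anchor_prob)
    B[i, ] <- bg
    B[i, anchors[i] + 1L] <- B[i, anchors[i] + 1L] + anchor_prob
  }
  m <- hmm_model(pi, A, B)
  attr(m, "anchors") <- anchors
  m
}

#' Simulate a gene annotation
#'
#' Places non-overlapping genes with unique TSS on one synthetic chromosome,
#' alternating strand at random, with intergenic gaps wide enough for
#' desk-scale training windows.
#'
#' @param n_genes Number of genes (>= 1).
#' @param gene_len_range Gene length range in bp.
#' @param intergenic_range Gap range between genes in bp.
#' @param seed RNG seed.
#' @param chrom Chromosome name.
#' @return List with `genes` (gene_id, chrom, strand, tss, tts) and
#'   `chrom_sizes` (named vector).
#' @export
simulate_genome <- function(n_genes, gene_len_range = c(5000L, 20000L),
                            intergenic_range = c(4500L, 9000L), seed = 1L,
                            chrom = "chrS") {
  stopifnot(n_genes >= 1L)
  set.seed(as.integer(seed))
  lens <- sample(gene_len_range[1]:gene_len_range[2], n_genes,
                 replace = TRUE)
  gaps <- sample(intergenic_range[1]:intergenic_range[2], n_genes,
                 replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  left <- cumsum(c(10000L, head(lens + gaps, -1L)))
  right <- left + lens
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    chrom = chrom, strand = strand,
    tss = ifelse(strand == "+", left, right),
    tts = ifelse(strand == "+", right, left),
    stringsAsFactors = FALSE)
  sizes <- setNames(max(right) + 10000L, chrom)
  list(genes = genes, chrom_sizes = sizes)
}

#' Simulate nucleosomes, states and mark peaks from a known HMM
#'
#' Walks each gene window 5' to 3' placing nucleosome dyads at spacings
#' `N(spacing_mean, spacing_sd)` (truncated at the 147 bp core), samples a
#' hidden state path from the model's Markov chain, samples an observation
#' symbol per nucleosome from the emission row, and writes each set mark bit
#' out as a peak fully covering the nucleosome (so re-encoding through the
#' overlap rule reproduces the symbols).  Nucleosome-call attributes are
#' drawn at plausible scales so downstream organization code always has
#' complete records.
#'
#' @param genes Gene table from [simulate_genome()].
#' @param model Generating `hmm_model`.
#' @param seed RNG seed.
#' @param n_marks Number of marks encoded in the alphabet.
#' @param spacing_mean,spacing_sd Dyad spacing distribution in bp.
#' @param upstream,downstream Window extents used for placement in bp.
#' @param peak_pad Peak extension beyond the nucleosome span in bp.
#' @return List with `nucleosomes` (including true `state` and `symbol`),
#'   `peaks`, `signals` (per-nucleosome 10 bp/point coverage) and `truth`
#'   (per-gene state paths and the model).
#' @export
simulate_states_and_marks <- function(genes, model, seed = 1L,
                                      n_marks = round(log2(n_symbols(model))),
                                      spacing_mean = 185, spacing_sd = 15,
                                      upstream = 2000L, downstream = 1000L,
                                      peak_pad = 30L) {
  stopifnot(bitwShiftL(1L, n_marks) == n_symbols(model))
  set.seed(as.integer(seed))
  S <- n_states(model)
  nuc_list <- list(); peak_list <- list(); paths <- list()
  sig_list <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    glen <- abs(g$tts - g$tss)
    span <- upstream + glen + downstream
    n_nuc <- max(1L, floor(span / spacing_mean) - 1L)
    gaps <- pmax(round(rnorm(n_nuc, spacing_mean, spacing_sd)), 147)
    off <- cumsum(gaps)  # 5'->3' offsets from window start
    off <- off[off < span - 80]
    n_nuc <- length(off)
    if (!n_nuc) next
    # genomic dyads: window start depends on strand
    dyad <- if (g$strand == "+") g$tss - upstream + off
            else g$tss + upstream - off
    states <- integer(n_nuc)
    states[1] <- sample.int(S, 1, prob = model$pi)
    for (t in seq_len(n_nuc)[-1]) {
      states[t] <- sample.int(S, 1, prob = model$A[states[t - 1], ])
    }
    symbols <- vapply(states, function(s) {
      sample.int(n_symbols(model), 1, prob = model$B[s, ]) - 1L
    }, integer(1))
    height <- pmax(rnorm(n_nuc, 2, 0.3), 0.2)
    nuc <- data.frame(
      chrom = g$chrom, start = dyad - 73L, end = dyad + 74L, dyad = dyad,
      height = height,
      width = pmax(rnorm(n_nuc, 120, 15), 60),
      area = pmax(rnorm(n_nuc, 15, 3), 2),
      pval_peak = pmax(rnorm(n_nuc, 8, 2), 0.1),
      pval_valley = pmax(rnorm(n_nuc, 5, 1.5), 0.1),
      state = states, symbol = symbols, gene_id = g$gene_id,
      stringsAsFactors = FALSE)
    # smoothed coverage: one Gaussian bump per nucleosome at 10 bp/point
    xs <- seq(-70, 70, by = 10)
    sig_list[[gi]] <- lapply(height, function(h) h * exp(-xs^2 / (2 * 30^2)))
    for (id in 0:(n_marks - 1L)) {
      has <- bitwAnd(symbols, bitwShiftL(1L, id)) > 0L
      if (!any(has)) next
      iv <- reduce_intervals(dyad[has] - 73L - peak_pad,
                             dyad[has] + 74L + peak_pad)
      peak_list[[length(peak_list) + 1L]] <- data.frame(
        chrom = g$chrom, start = iv$start, end = iv$end, mark_id = id)
    }
    nuc_list[[gi]] <- nuc
    paths[[g$gene_id]] <- states
  }
  nucs <- do.call(rbind, nuc_list)
  signals <- do.call(c, sig_list)
  o <- order(nucs$chrom, nucs$dyad)
  nucs <- nucs[o, ]
  signals <- signals[o]
  nucs$nuc_id <- seq_len(nrow(nucs))
  rownames(nucs) <- NULL
  peaks <- do.call(rbind, peak_list) %||%
    data.frame(chrom = character(), start = integer(), end = integer(),
               mark_id = integer())
  list(nucleosomes = nucs, peaks = peaks, signals = signals,
       truth = list(paths = paths, model = model))
}

#' Simulate a nucleosome-array coverage signal
#'
#' Sum of Gaussian peaks at dyad positions `start_bp + k * period`
#' (k = 0..n-1) with amplitudes `decay^k`, plus white noise.  `decay = 1`
#' and zero noise give an exactly periodic signal; stronger decay emulates
#' loss of phasing along the array.
#'
#' @param period Dyad-to-dyad period in bp.
#' @param n_nucleosomes Number of peaks.
#' @param decay Amplitude decay per peak in (0, 1].
#' @param noise_sd White-noise standard deviation (signal peak height = 1).
#' @param fs Sample rate in points per kb.
#' @param window_bp Signal span in bp.
#' @param peak_sd Gaussian peak width (sd) in bp.
#' @param start_bp Position of the first dyad (default half a period in).
#' @param seed Optional RNG seed for the noise.
#' @return A `nuc_array_signal`.
#' @export
simulate_array_signal <- function(period = 185, n_nucleosomes = 5L,
                                  decay = 1, noise_sd = 0, fs = 1000,
                                  window_bp = 1000L, peak_sd = 30,
                                  start_bp = round(period / 2),
                                  seed = NULL) {
  stopifnot(period > 0, decay > 0, decay <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- seq(0, window_bp - 1000 / fs, by = 1000 / fs)
  centers <- start_bp + (seq_len(n_nucleosomes) - 1L) * period
  y <- rep(0, length(x))
  for (k in seq_along(centers)) {
    y <- y + decay^(k - 1) * exp(-(x - centers[k])^2 / (2 * peak_sd^2))
  }
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  nuc_array_signal(y, fs = fs)
}

#' Simulate raw reads and nucleosome-call attributes
#'
#' Well-positioned nucleosomes get tightly stacked read centers
#' (sd 10 bp); fuzzy nucleosomes get dispersed centers (sd 40 bp).
#' Call attributes (height, width, area, peak/valley significance) are
#' derived from the generated pileup, so positioning scores computed from
#' either route rank the archetypes consistently.
#'
#' @param nucleosomes data.frame with `chrom`, `start`, `end`, `dyad`.
#' @param archetype Character vector ("well"/"fuzzy") per nucleosome, or a
#'   numeric vector of read-center dispersions (sd in bp) for a continuum
#'   of positioning degrees (the Fig.-4B-style correlation screen needs a
#'   continuum rather than two extremes).
#' @param seed RNG seed.
#' @param reads_per_nuc Expected reads per nucleosome; the same mean across
#'   archetypes, so systematic enrichment differences come from dispersion.
#' @param poisson_depth Draw per-nucleosome read counts as Poisson
#'   (sequencing-depth variation; default).  Set FALSE for exactly equal
#'   counts, the construction used by the pairwise positioning contract.
#' @return List with `reads` (chrom, center), `read_centers` (per-nucleosome
#'   list), and `inps` (attribute table).
#' @export
simulate_reads_and_inps <- function(nucleosomes, archetype, seed = 1L,
                                    reads_per_nuc = 100L,
                                    poisson_depth = TRUE) {
  if (is.character(archetype)) {
    stopifnot(all(archetype %in% c("well", "fuzzy")))
    archetype <- ifelse(archetype == "well", 10, 40)
  }
  stopifnot(is.numeric(archetype), all(archetype > 0),
            length(archetype) == nrow(nucleosomes))
  set.seed(as.integer(seed))
  n <- nrow(nucleosomes)
  centers <- vector("list", n)
  inps <- data.frame(nucleosomes,
                     height = NA_real_, width = NA_real_, area = NA_real_,
                     pval_peak = NA_real_, pval_valley = NA_real_)
  nread <- if (poisson_depth) pmax(rpois(n, reads_per_nuc), 5L)
           else rep(as.integer(reads_per_nuc), n)
  for (i in seq_len(n)) {
    sdv <- archetype[i]
    rc <- round(rnorm(nread[i], nucleosomes$dyad[i], sdv))
    centers[[i]] <- rc
    # pileup-derived call attributes over a +/-150 bp span; the heavy
    # smoothing mirrors the Gaussian/LoG convolution nucleosome callers
    # apply before measuring peak shape (a light kernel leaves Poisson
    # noise that fakes narrow widths on dispersed pileups)
    grid <- seq(nucleosomes$dyad[i] - 150L, nucleosomes$dyad[i] + 150L)
    h <- tabulate(findInterval(rc, grid), nbins = length(grid))
    hs <- as.numeric(stats::filter(h, rep(1 / 30, 30), sides = 2))
    hs[is.na(hs)] <- 0
    pk <- max(hs)
    half <- pk / 2
    inps$height[i] <- pk
    inps$width[i] <- max(sum(hs >= half), 1L)
    inps$area[i] <- sum(hs)
    # significance scales (log-scale style): sharper pileups more
    # significant, mild noise so populations overlap realistically
    inps$pval_peak[i] <- pmax(pk * 2 + rnorm(1, 0, 0.3), 0.05)
    inps$pval_valley[i] <- pmax(pk * 1.2 + rnorm(1, 0, 0.3), 0.05)
  }
  reads <- data.frame(chrom = rep(nucleosomes$chrom, times = nread),
                      center = unlist(centers))
  list(reads = reads, read_centers = centers, inps = inps)
}

#' Simulate a skipped-exon event table
#'
#' Reliable events carry high isoform-specific read support (`X + Y`
#' comfortably above the cutoff, `Y >= 1`) and confidence-interval widths on
#' the designated side of the population median; unreliable events fail
#' Rule 1 by construction (low support or `Y = 0`).
#'
#' @param n_events Number of events.
#' @param reliable_frac Fraction of planted reliable events.
#' @param seed RNG seed.
#' @param n_cutoff Read-support cutoff the reliable events are planted
#'   above.
#' @param chrom Chromosome name for event coordinates.
#' @return List with `events` (event_id, chrom, start, end, strand, X, Y,
#'   ci_width), `labels` (planted reliability) and `n_cutoff`.
#' @export
simulate_se_table <- function(n_events = 200L, reliable_frac = 0.3,
                              seed = 1L, n_cutoff = 20L, chrom = "chrS") {
  stopifnot(reliable_frac >= 0, reliable_frac <= 1)
  set.seed(as.integer(seed))
  n_rel <- round(n_events * reliable_frac)
  labels <- c(rep(TRUE, n_rel), rep(FALSE, n_events - n_rel))
  X <- integer(n_events); Y <- integer(n_events); ci <- numeric(n_events)
  for (i in seq_len(n_events)) {
    if (labels[i]) {
      tot <- n_cutoff + rpois(1, 40)
      Y[i] <- 1L + rbinom(1, tot - 1L, 0.3)
      X[i] <- tot - Y[i]
      ci[i] <- runif(1, 0.55, 0.9)
    } else if (runif(1) < 0.5) {
      tot <- sample.int(n_cutoff, 1) - 1L  # below the cutoff
      Y[i] <- rbinom(1, tot, 0.3)
      X[i] <- tot - Y[i]
      ci[i] <- runif(1, 0.05, 0.45)
    } else {
      X[i] <- n_cutoff + rpois(1, 20)  # supported but Y = 0
      Y[i] <- 0L
      ci[i] <- runif(1, 0.05, 0.45)
    }
  }
  start <- sort(sample.int(1e6, n_events))
  events <- data.frame(
    event_id = sprintf("se%04d", seq_len(n_events)),
    chrom = chrom, start = start,
    end = start + sample(80:300, n_events, replace = TRUE),
    strand = sample(c("+", "-"), n_events, replace = TRUE),
    X = X, Y = Y, ci_width = ci, stringsAsFactors = FALSE)
  list(events = events, labels = labels, n_cutoff = n_cutoff)
}
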