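# Nucleosome organization: array detection, array signal averaging, Welch
# phasing, inter-maximum spacing and positioning scores.

#' Nucleosome array signal container
#'
#' @param values Numeric coverage samples (>= 0 expected for real coverage).
#' @param fs Sample rate in points per kb (100 native for 10 bp/point iNPS
#'   signal, 1000 after interpolation).
#' @param state Optional state label.
#' @return An object of class `nuc_array_signal`.
#' @export
nuc_array_signal <- function(values, fs, state = NA) {
  stopifnot(is.numeric(values), length(values) >= 1L, fs > 0)
  structure(list(values = as.numeric(values), fs = fs, state = state),
            class = "nuc_array_signal")
}

#' @export
print.nuc_array_signal <- function(x, ...) {
  cat(sprintf("<nuc_array_signal> state=%s, %d points at fs=%g\n",
              as.character(x$state), length(x$values), x$fs))
  invisible(x)
}

#' Detect same-state nucleosome arrays
#'
#' An array is a maximal run of consecutive nucleosomes sharing one decoded
#' state whose adjacent dyad-to-dyad distances are all below `max_gap`
#' (default 350 bp).  Input must be sorted by chromosome then dyad.
#'
#' @param nucleosomes data.frame with `chrom`, `dyad`, `state` (and any
#'   other columns, which are preserved).
#' @param max_gap Gap threshold in bp; a gap `>= max_gap` splits the array.
#' @return List with `nucleosomes` (input plus `array_id` and `array_order`,
#'   the 1-based position within the array) and `per_state`
#'   (state, n_arrays, ave_no = mean member count).
#' @export
detect_arrays <- function(nucleosomes, max_gap = 350L) {
  dt <- data.table::as.data.table(nucleosomes)
  stopifnot(all(c("chrom", "dyad", "state") %in% names(dt)))
  # sortedness check: dyads non-decreasing within contiguous chrom blocks
  chr <- rleidv(dt$chrom)
  if (anyDuplicated(dt$chrom[!duplicated(chr)])) {
    stop("input not sorted: chromosome blocks are not contiguous")
  }
  gap <- c(NA, diff(dt$dyad))
  gap[c(TRUE, diff(chr) != 0)] <- NA
  if (any(gap < 0, na.rm = TRUE)) {
    stop("input not sorted: dyads decrease within a chromosome")
  }
  newblock <- is.na(gap) | gap >= max_gap |
    dt$state != data.table::shift(dt$state)
  newblock[1] <- TRUE
  dt[, array_id := cumsum(newblock)]
  dt[, array_order := seq_len(.N), by = array_id]
  per_state <- dt[, .(n = .N), by = .(state, array_id)][
    , .(n_arrays = .N, ave_no = mean(n)), by = state]
  data.table::setorder(per_state, state)
  list(nucleosomes = dt[], per_state = per_state[])
}

rleidv <- function(x) cumsum(c(TRUE, x[-1] != x[-length(x)]))

#' Average per-state array coverage signal
#'
#' Each array's member signals (iNPS smoothed coverage at 10 bp/point over
#' the nucleosome span) are laid onto a `window` bp grid anchored at the
#' array start (first member's `start`; for minus-strand arrays the last
#' member's `end`, read leftward, so the window runs 5' to 3').  Arrays
#' shorter than the window are zero-padded; per-state signals are the mean
#' over that state's arrays.
#'
#' @param array_nucs Table from [detect_arrays()] (`nucleosomes` element)
#'   with `start`, `end`, `state`, `array_id`, optionally `strand`.
#' @param signals List of numeric vectors, one per nucleosome row, sampled
#'   at 10 bp/point over `[start, end)`.
#' @param window Window width in bp (default 1000).
#' @return Named list (by state) of `nuc_array_signal` objects at fs = 100.
#' @export
array_signal <- function(array_nucs, signals, window = 1000L) {
  dt <- data.table::as.data.table(array_nucs)
  stopifnot(nrow(dt) == length(signals))
  step <- 10L
  npt <- as.integer(window / step)
  acc <- list(); cnt <- list()
  split_idx <- split(seq_len(nrow(dt)), dt$array_id)
  for (rows in split_idx) {
    st <- as.character(dt$state[rows[1]])
    minus <- !is.null(dt$strand) && dt$strand[rows[1]] == "-"
    anchor <- if (minus) max(dt$end[rows]) else min(dt$start[rows])
    vec <- numeric(npt)
    for (r in rows) {
      sig <- signals[[r]]
      if (!length(sig)) next
      pos <- dt$start[r] + step * (seq_along(sig) - 1L)
      off <- if (minus) (anchor - pos - step) else (pos - anchor)
      idx <- off %/% step + 1L
      ok <- idx >= 1L & idx <= npt
      if (minus) sig <- sig  # orientation handled through offsets
      vec[idx[ok]] <- vec[idx[ok]] + sig[ok]
    }
    if (is.null(acc[[st]])) { acc[[st]] <- vec; cnt[[st]] <- 1L }
    else { acc[[st]] <- acc[[st]] + vec; cnt[[st]] <- cnt[[st]] + 1L }
  }
  out <- lapply(names(acc), function(st) {
    nuc_array_signal(acc[[st]] / cnt[[st]], fs = 100, state = st)
  })
  names(out) <- names(acc)
  out[order(names(out))]
}

#' Linearly interpolate an array signal to a higher sample rate
#'
#' Raises the sample rate by an integer factor with linear interpolation;
#' original samples are preserved at their positions.  Output length is
#' `(L - 1) * factor + 1`.
#'
#' @param signal A `nuc_array_signal`.
#' @param target_fs Target sample rate (default 1000, i.e. 1 bp/point).
#' @return Interpolated `nuc_array_signal`.
#' @export
interpolate_signal <- function(signal, target_fs = 1000) {
  factor <- target_fs / signal$fs
  if (factor != round(factor) || factor < 1) {
    stop("target_fs must be an integer multiple of the native sample rate")
  }
  L <- length(signal$values)
  if (L < 2L) stop("signal too short to interpolate")
  y <- approx(x = seq_len(L), y = signal$values,
              xout = seq(1, L, by = 1 / factor))$y
  nuc_array_signal(y, fs = target_fs, state = signal$state)
}

#' Welch power spectral density estimate
#'
#' Splits the signal into `K` frames of `frame_len` points advanced by
#' `hop`, applies a Hann window, averages the per-frame periodograms
#' `|FFT|^2 / M`, and returns the one-sided spectrum with its frequency
#' axis in Hz (cycles per kb, since fs is in points per kb).
#'
#' @param signal A `nuc_array_signal`.
#' @param frame_len Frame length M in samples (default 512).
#' @param hop Hop size R in samples (default `frame_len / 2`, 50% overlap).
#' @param onesided Return only frequencies up to Nyquist (default TRUE);
#'   set FALSE for the full two-sided spectrum (e.g. Parseval checks).
#' @return data.frame with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(signal, frame_len = 512L, hop = frame_len %/% 2L,
                      onesided = TRUE) {
  x <- signal$values
  M <- as.integer(frame_len)
  stopifnot(hop >= 1L)
  if (M > length(x)) stop("frame_len exceeds signal length")
  K <- (length(x) - M) %/% hop + 1L
  w <- 0.5 * (1 - cos(2 * pi * (0:(M - 1)) / (M - 1)))  # Hann
  psd <- numeric(M)
  for (m in 0:(K - 1L)) {
    frame <- w * x[(m * hop + 1L):(m * hop + M)]
    psd <- psd + Mod(fft(frame))^2 / M
  }
  psd <- psd / K
  freq <- (0:(M - 1)) * signal$fs / M
  if (onesided) {
    nf <- M %/% 2L + 1L
    psd <- psd[seq_len(nf)]
    freq <- freq[seq_len(nf)]
  }
  data.frame(freq = freq, psd = psd)
}

#' Phasing score from a PSD table
#'
#' 1000 times the maximum spectral density within the analyzed band
#' (default 4-10 Hz, i.e. periods of 100-250 bp at fs = 1000).
#'
#' @param psd data.frame from [welch_psd()].
#' @param band Frequency band `c(low, high)` in Hz, inclusive.
#' @return Numeric phasing score.
#' @export
phasing_score <- function(psd, band = c(4, 10)) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stop("no PSD frequencies fall inside the band")
  1000 * max(psd$psd[sel])
}

#' Convert a frequency to a genomic period
#'
#' `period = fs / freq`: at fs = 1000 points per kb, 4 Hz corresponds to a
#' 250 bp period and 10 Hz to 100 bp.
#'
#' @param freq Frequency in Hz (> 0).
#' @param fs Sample rate in points per kb.
#' @return Period in bp.
#' @export
freq_to_period <- function(freq, fs = 1000) {
  if (any(freq <= 0)) stop("freq must be positive")
  fs / freq
}

#' @rdname freq_to_period
#' @param period Genomic period in bp (> 0).
#' @export
period_to_freq <- function(period, fs = 1000) {
  if (any(period <= 0)) stop("period must be positive")
  fs / period
}

# Local maxima with the flat-plateau rule: a run of equal values flanked on
# both sides by smaller values is one maximum at its middle index
# (lower-middle for even-length plateaus).  Optional prominence filter.
local_maxima <- function(x, min_prominence = 0) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  if (nr < 3L) return(integer(0))
  cand <- which(r$values[-c(1L, nr)] > r$values[-c(nr - 1L, nr)] &
                  r$values[-c(1L, nr)] > r$values[-c(1L, 2L)]) + 1L
  idx <- (starts[cand] + ends[cand]) %/% 2L
  if (min_prominence > 0 && length(idx)) {
    keep <- vapply(idx, function(i) {
      v <- x[i]
      left <- x[seq_len(i - 1L)]
      hi <- which(left > v)
      base_l <- if (length(hi)) min(left[(max(hi) + 1L):(i - 1L)])
                else min(left)
      right <- x[(i + 1L):length(x)]
      hi <- which(right > v)
      base_r <- if (length(hi)) min(right[seq_len(min(hi) - 1L)])
                else min(right)
      (v - max(base_l, base_r)) >= min_prominence
    }, logical(1))
    idx <- idx[keep]
  }
  idx
}

#' Nucleosome spacing from an array signal
#'
#' Finds local maxima of the array coverage (sharp peaks: a sample whose two
#' direct neighbors are smaller; flat peaks: the middle index of the
#' plateau) and returns the mean of consecutive inter-maximum distances in
#' bp.  Noisy signals can be smoothed with a centered moving average and/or
#' screened with a prominence threshold before extrema detection.
#'
#' @param signal A `nuc_array_signal`.
#' @param smooth_bp Moving-average window in bp (0 = none).  Symmetric
#'   smoothing preserves the maxima locations of symmetric peaks.
#' @param min_prominence Minimum peak prominence, in signal units.
#' @param max_intervals Use only the first k inter-maximum intervals
#'   (default all within the window).
#' @return Mean spacing in bp, with attributes `maxima_bp` (maxima
#'   positions) and `n_intervals`; `NA` (flagged by a warning) when fewer
#'   than two maxima are found.
#' @export
array_spacing <- function(signal, smooth_bp = 0, min_prominence = 0,
                          max_intervals = Inf) {
  x <- signal$values
  bp_per_pt <- 1000 / signal$fs
  if (smooth_bp > 0) {
    k <- max(1L, round(smooth_bp / bp_per_pt))
    if (k %% 2L == 0L) k <- k + 1L
    kern <- rep(1 / k, k)
    x <- as.numeric(stats::filter(x, kern, sides = 2))
    pad <- (k - 1L) %/% 2L
    x[seq_len(pad)] <- x[pad + 1L]
    x[(length(x) - pad + 1L):length(x)] <- x[length(x) - pad]
  }
  idx <- local_maxima(x, min_prominence = min_prominence)
  if (length(idx) < 2L) {
    warning("fewer than two local maxima: spacing undefined")
    out <- NA_real_
    attr(out, "maxima_bp") <- (idx - 1) * bp_per_pt
    attr(out, "n_intervals") <- 0L
    return(out)
  }
  pos <- (idx - 1) * bp_per_pt
  gaps <- diff(pos)
  if (is.finite(max_intervals)) gaps <- head(gaps, max_intervals)
  out <- mean(gaps)
  attr(out, "maxima_bp") <- pos
  attr(out, "n_intervals") <- length(gaps)
  out
}

#' Allowed spacing range for the k-th nucleosome of an array
#'
#' Returns `spacing +/- interval * (5 + rank * coef_range)` where `interval`
#' is the nucleosome's order in the array minus one, and `rank` is the
#' state's descending phasing-score rank (1 = most phased).  The first
#' nucleosome (interval 0) yields a degenerate range and is always retained.
#'
#' @param spacing_nucs Mean state spacing in bp.
#' @param interval Nucleosome order minus one (>= 0).
#' @param rank Phasing rank (>= 1).
#' @param coef_range Range-adjustment coefficient in bp (default 1).
#' @return Numeric `c(low, high)`.
#' @export
spacing_range <- function(spacing_nucs, interval, rank, coef_range = 1) {
  if (coef_range < 0) stop("coef_range must be >= 0")
  stopifnot(interval >= 0, rank >= 1)
  half <- interval * (5 + rank * coef_range)
  c(spacing_nucs - half, spacing_nucs + half)
}

#' Interquartile-range normalization
#'
#' `(x - Q1) / (Q3 - Q1)`; invariant under positive affine transforms of
#' the population.
#'
#' @param values Numeric vector (>= 4 finite values with nonzero IQR).
#' @return Normalized vector.
#' @export
iqr_normalize <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4L) stop("need at least 4 finite values")
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  if (q[2] - q[1] <= 0) stop("zero interquartile range")
  (values - q[1]) / (q[2] - q[1])
}

#' Read-based reference positioning score (rNP)
#'
#' `rNP = norm(enrich) / (norm(fwhm) + norm(std))` where `norm` is IQR
#' normalization over the nucleosome population and the denominator is
#' floored at 1e-6.  High read enrichment with a tight, narrow pileup
#' (well-positioned) scores high; dispersed pileups (fuzzy) score low.
#'
#' @param enrich Read count within +/- 73 bp of the dyad, per nucleosome.
#' @param fwhm Full width at half maximum of the smoothed read-center
#'   histogram, bp.
#' @param std Standard deviation of read-center offsets, bp.
#' @return Numeric rNP per nucleosome (NA where features are missing).
#' @export
rnp_score <- function(enrich, fwhm, std) {
  ne <- iqr_normalize(enrich)
  nf <- iqr_normalize(fwhm)
  ns <- iqr_normalize(std)
  ne / pmax(nf + ns, 0.1)
}

#' Read-pileup features for the rNP score
#'
#' For each nucleosome, computes the three raw-read features of
#' [rnp_score()] from the read centers assigned to it: enrichment (reads
#' within +/- 73 bp of the dyad), the standard deviation of read-center
#' offsets, and the full width at half maximum of the read-center histogram
#' smoothed with a 10 bp moving-average kernel and restricted to the
#' nucleosome span.
#'
#' @param read_centers List of numeric vectors of read-center coordinates,
#'   one per nucleosome.
#' @param dyad,start,end Per-nucleosome coordinates.
#' @return data.frame with `enrich`, `fwhm`, `std` (NA rows where a
#'   nucleosome has no reads).
#' @export
rnp_features <- function(read_centers, dyad, start, end) {
  n <- length(read_centers)
  out <- data.frame(enrich = rep(NA_real_, n), fwhm = NA_real_,
                    std = NA_real_)
  for (i in seq_len(n)) {
    rc <- read_centers[[i]]
    if (!length(rc)) next
    off <- rc - dyad[i]
    out$enrich[i] <- sum(abs(off) <= 73)
    out$std[i] <- if (length(rc) > 1L) sd(off) else 0
    grid <- seq(start[i], end[i] - 1L)
    h <- tabulate(findInterval(rc, grid), nbins = length(grid))
    k <- rep(1 / 10, 10)
    hs <- as.numeric(stats::filter(h, k, sides = 2, circular = FALSE))
    hs[is.na(hs)] <- 0
    # robust width at half maximum: count of in-span positions at or above
    # half the peak (a contiguous scan collapses on noisy flat pileups)
    out$fwhm[i] <- sum(hs >= max(hs) / 2)
  }
  out
}

#' Nucleosome-call positioning score (NP)
#'
#' `NP = (height + log2(pval_peak * pval_valley + 1) + area) / (3 * width)`
#' over IQR-normalized nucleosome-call attributes.  Because the valley
#' significance is abnormally high for the last nucleosome of an array
#' regardless of its true shape, that nucleosome's `pval_valley` is first
#' replaced by the population median.  The normalized width denominator and
#' the log argument are floored at 1e-6.
#'
#' @param records data.frame with `height`, `width`, `area`, `pval_peak`,
#'   `pval_valley`, `array_id`, `array_order` (from [detect_arrays()]).
#' @return Numeric NP score per nucleosome, with attribute `n_floored`
#'   counting floored denominators.
#' @export
np_score <- function(records) {
  dt <- data.table::as.data.table(records)
  need <- c("height", "width", "area", "pval_peak", "pval_valley",
            "array_id")
  stopifnot(all(need %in% names(dt)))
  pv <- dt$pval_valley
  last_in_array <- !duplicated(dt$array_id, fromLast = TRUE)
  pv[last_in_array] <- median(dt$pval_valley)
  h <- iqr_normalize(dt$height)
  w <- iqr_normalize(dt$width)
  a <- iqr_normalize(dt$area)
  pp <- iqr_normalize(dt$pval_peak)
  pvn <- iqr_normalize(pv)
  wfloor <- pmax(w, 0.1)
  np <- (h + log2(pmax(pp * pvn + 1, 0.1)) + a) / (3 * wfloor)
  attr(np, "n_floored") <- sum(w < 0.1)
  np
}

#' Quantile filter for positioning scores
#'
#' Drops scores outside the `[q_low, q_high]` quantiles of their group and
#' reports the per-group mean of the retained scores (the state positioning
#' score).
#'
#' @param scores Numeric vector.
#' @param group Optional grouping factor (e.g. the HMM state).
#' @param q_low,q_high Quantile cutoffs (defaults 0.05 and 0.95).
#' @return List with `retained` (logical vector) and `means` (data.frame of
#'   group, n_retained, mean_score).
#' @export
positioning_filter <- function(scores, group = NULL, q_low = 0.05,
                               q_high = 0.95) {
  stopifnot(q_low >= 0, q_high <= 1, q_low < q_high)
  if (is.null(group)) group <- rep(1L, length(scores))
  retained <- logical(length(scores))
  for (g in unique(group)) {
    i <- which(group == g & is.finite(scores))
    if (!length(i)) next
    q <- quantile(scores[i], c(q_low, q_high), names = FALSE)
    retained[i] <- scores[i] >= q[1] & scores[i] <= q[2]
  }
  means <- data.frame(
    group = unique(group),
    n_retained = vapply(unique(group),
                        function(g) sum(retained[group == g]), integer(1)),
    mean_score = vapply(unique(group), function(g) {
      s <- scores[retained & group == g]
      if (length(s)) mean(s) else NA_real_
    }, numeric(1)))
  list(retained = retained, means = means)
}

#' Per-state nucleosome organization table
#'
#' Chains array detection, array-signal averaging, interpolation, Welch
#' phasing, inter-maximum spacing and NP positioning into the per-state
#' organization summary (state, ave_no, spacing_bp, phasing_score,
#' positioning_score).  When `eq6_filter` is TRUE, nucleosomes whose
#' observed dyad gap falls outside the state's [spacing_range()] are dropped
#' and phasing/spacing are recomputed on the retained set.
#'
#' @param nucleosomes Decoded, sorted nucleosome table with `chrom`, `dyad`,
#'   `start`, `end`, `state` and the five nucleosome-call attributes.
#' @param signals List of per-nucleosome smoothed signals at 10 bp/point.
#' @param max_gap Array gap threshold (bp).
#' @param window Array-signal window (bp).
#' @param frame_len,hop Welch parameters (samples at fs = 1000).
#' @param band Phasing band in Hz.
#' @param coef_range Eq-6-style range coefficient (bp).
#' @param eq6_filter Apply the spacing-range nucleosome filter.
#' @param smooth_bp,min_prominence Passed to [array_spacing()].
#' @param max_intervals Spacing intervals used per window (default 4).
#' @param q_low,q_high Positioning quantile cutoffs.
#' @return List with `table` (per-state organization data.frame),
#'   `signals` (per-state interpolated `nuc_array_signal`s), `arrays`
#'   (annotated nucleosome table with `np` scores) and `spacing_retained`
#'   (logical Eq-6 filter mask).
#' @export
organization_table <- function(nucleosomes, signals, max_gap = 350L,
                               window = 1000L, frame_len = 512L,
                               hop = frame_len %/% 2L, band = c(4, 10),
                               coef_range = 1, eq6_filter = TRUE,
                               smooth_bp = 30, min_prominence = 0,
                               max_intervals = 4L,
                               q_low = 0.05, q_high = 0.95) {
  arr <- detect_arrays(nucleosomes, max_gap = max_gap)
  dt <- arr$nucleosomes

  state_stats <- function(dtx, sigx) {
    sigs <- array_signal(dtx, sigx, window = window)
    lapply(sigs, function(sg) {
      up <- interpolate_signal(sg, 1000)
      fl <- min(frame_len, length(up$values))
      psd <- welch_psd(up, frame_len = fl, hop = max(1L, fl %/% 2L))
      sp <- suppressWarnings(array_spacing(
        up, smooth_bp = smooth_bp, min_prominence = min_prominence,
        max_intervals = max_intervals))
      list(signal = up, phasing = phasing_score(psd, band),
           spacing = as.numeric(sp))
    })
  }
  st1 <- state_stats(dt, signals)
  states <- names(st1)
  phas <- vapply(st1, `[[`, numeric(1), "phasing")
  spac <- vapply(st1, `[[`, numeric(1), "spacing")
  rank_by_phasing <- rank(-phas, ties.method = "first")

  retained <- rep(TRUE, nrow(dt))
  if (eq6_filter) {
    gaps <- c(NA, diff(dt$dyad))
    gaps[dt$array_order == 1L] <- NA
    for (i in seq_len(nrow(dt))) {
      st <- as.character(dt$state[i])
      if (is.na(gaps[i]) || !(st %in% states) || is.na(spac[st])) next
      rng <- spacing_range(spac[st], interval = dt$array_order[i] - 1L,
                           rank = rank_by_phasing[st],
                           coef_range = coef_range)
      retained[i] <- gaps[i] >= rng[1] & gaps[i] <= rng[2]
    }
    if (!all(retained)) {
      st2 <- state_stats(dt[retained], signals[retained])
      for (nm in names(st2)) st1[[nm]] <- st2[[nm]]
      phas <- vapply(st1, `[[`, numeric(1), "phasing")
      spac <- vapply(st1, `[[`, numeric(1), "spacing")
    }
  }

  np <- np_score(dt)
  dt[, np := np]
  pf <- positioning_filter(np, group = dt$state, q_low = q_low,
                           q_high = q_high)
  pos <- setNames(pf$means$mean_score, as.character(pf$means$group))

  tab <- data.frame(
    state = states,
    ave_no = arr$per_state$ave_no[match(states,
                                        as.character(arr$per_state$state))],
    spacing_bp = as.numeric(spac[states]),
    phasing_score = as.numeric(phas[states]),
    positioning_score = as.numeric(pos[states]),
    stringsAsFactors = FALSE)
  list(table = tab,
       signals = lapply(st1, `[[`, "signal"),
       arrays = dt[],
       spacing_retained = retained)
}
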