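# Skipped-exon splicing potentiality: reliable/unreliable event
# classification, discrete Frechet curve comparison, SPSE and SE affinity.

#' Classify skipped-exon events as reliable or unreliable
#'
#' Rule 1: `X + Y >= N` and `Y >= 1`, where X and Y are read counts
#' consistent with only the first or only the second isoform.  Rule 2:
#' the event's inclusion-level confidence-interval width exceeds the median
#' CI width (as printed; `invert_rule2` flips the direction since the
#' printed sense is counter-intuitive).  Reliable events pass both rules;
#' all remaining candidate events are the unreliable group.
#'
#' @param events data.frame with `X`, `Y`, `ci_width` (and any identifier
#'   columns, preserved).
#' @param n_cutoff Read-support cutoff N; when NULL it is derived from the
#'   `X + Y` frequency distribution as its upper quartile.
#' @param invert_rule2 Use `ci_width < median` instead of `>`.
#' @return List with `reliable`, `unreliable` (row subsets), `n_cutoff` and
#'   `labels` (logical reliability per input row).
#' @export
classify_se <- function(events, n_cutoff = NULL, invert_rule2 = FALSE) {
  if (!nrow(events)) stop("empty skipped-exon event table")
  stopifnot(all(events$X >= 0), all(events$Y >= 0),
            all(events$ci_width >= 0 & events$ci_width <= 1))
  total <- events$X + events$Y
  N <- n_cutoff %||% as.numeric(quantile(total, 0.75, names = FALSE))
  stopifnot(N >= 1)
  rule1 <- total >= N & events$Y >= 1
  med <- median(events$ci_width)
  rule2 <- if (invert_rule2) events$ci_width < med else events$ci_width > med
  rel <- rule1 & rule2
  list(reliable = events[rel, , drop = FALSE],
       unreliable = events[!rel, , drop = FALSE],
       n_cutoff = N, labels = rel)
}

#' Discrete Frechet distance between two curves
#'
#' Dynamic program over monotone couplings of the two point sequences
#' (Euclidean point distance).  Numeric vectors are treated as curves of
#' points `(index, value)`, matching how mean array signals are compared.
#'
#' @param curve_a,curve_b Numeric vectors or point matrices (rows = points).
#' @return The discrete Frechet distance (>= 0, symmetric).
#' @export
frechet_distance <- function(curve_a, curve_b) {
  as_curve <- function(x) {
    if (is.matrix(x)) x else cbind(seq_along(x), as.numeric(x))
  }
  a <- as_curve(curve_a); b <- as_curve(curve_b)
  if (!nrow(a) || !nrow(b)) stop("curves must be nonempty")
  frechet_cpp(a, b)
}

minmax <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[2] - r[1] <= 0) stop("min-max normalization undefined: no spread")
  (x - r[1]) / (r[2] - r[1])
}

#' Splicing potentiality of skipped exons (SPSE)
#'
#' Per nucleosome state, the product of three components min-max scaled to
#' `[0, 1]` across the compared states: the Frechet distance between the
#' state's mean array signals in reliable vs unreliable events, the absolute
#' difference of median positioning scores between the two groups, and the
#' event-count coefficient (the state's abundance among reliable events).
#'
#' @param frechet Numeric vector of Frechet distances, one per state.
#' @param diff_nucpos Differences of median positioning scores (sign
#'   ignored).
#' @param counts_rse Count of the state's nucleosomes in reliable events.
#' @param counts_total Total count of the state's nucleosomes.
#' @param nucs_id Optional state identifiers.
#' @return data.frame with the raw components, `coef_event_counts` and
#'   `spse` in `[0, 1]`.
#' @export
spse <- function(frechet, diff_nucpos, counts_rse, counts_total,
                 nucs_id = NULL) {
  k <- length(frechet)
  if (k < 2L) stop("SPSE needs at least two states for normalization")
  stopifnot(length(diff_nucpos) == k, length(counts_rse) == k,
            length(counts_total) == k)
  coef <- minmax(counts_rse / counts_total)
  score <- minmax(frechet) * minmax(abs(diff_nucpos)) * coef
  data.frame(nucs_id = nucs_id %||% as.character(seq_len(k)),
             frechet = frechet, diff_nucpos = diff_nucpos,
             coef_event_counts = coef, spse = score,
             stringsAsFactors = FALSE)
}

#' Skipped-exon affinity per nucleosome state
#'
#' Compares the observed number of SE events carrying each state with the
#' number predicted under random association (total events times state
#' abundance); the affinity is observed / predicted.
#'
#' @param observed Observed SE event counts per state.
#' @param abundance State abundances (must sum to 1 over the compared
#'   states).
#' @return data.frame with observed, predicted and affinity (Inf, flagged
#'   by a warning, where abundance is 0 with nonzero observed).
#' @export
se_affinity <- function(observed, abundance) {
  stopifnot(length(observed) == length(abundance),
            abs(sum(abundance) - 1) < 1e-6)
  predicted <- sum(observed) * abundance
  aff <- observed / predicted
  if (any(is.infinite(aff))) {
    warning("zero abundance with nonzero observed count: infinite affinity")
  }
  data.frame(observed = observed, predicted = predicted, affinity = aff)
}

#' Meta-exon state profiles
#'
#' Per state, the frequency of nucleosome dyads in bins centered on exon
#' centers (strand-oriented offsets), normalized to sum 1.
#'
#' @param nucs data.frame with `chrom`, `dyad` and a state label column
#'   `nucs_id` (or `state`).
#' @param exons data.frame with `chrom`, `start`, `end`, `strand`.
#' @param flank Half-window around the exon center in bp.
#' @param bin_bp Bin width in bp.
#' @return List with `profile` (states x bins, rows sum to 1) and
#'   `offsets` (bin centers in bp, 5'->3').
#' @export
exon_profile <- function(nucs, exons, flank = 1000L, bin_bp = 50L) {
  lab <- nucs$nucs_id %||% nucs$state
  stopifnot(!is.null(lab), all(exons$strand %in% c("+", "-")))
  edges <- seq(-flank, flank, by = bin_bp)
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  states <- sort(unique(as.character(lab)))
  counts <- matrix(0, length(states), length(centers),
                   dimnames = list(states, NULL))
  ecenter <- (exons$start + exons$end) %/% 2
  for (i in seq_len(nrow(exons))) {
    sel <- nucs$chrom == exons$chrom[i] &
      abs(nucs$dyad - ecenter[i]) <= flank
    if (!any(sel)) next
    off <- nucs$dyad[sel] - ecenter[i]
    if (exons$strand[i] == "-") off <- -off
    bi <- findInterval(off, edges, rightmost.closed = TRUE)
    bi[bi < 1L] <- 1L; bi[bi > length(centers)] <- length(centers)
    for (j in seq_along(bi)) {
      s <- as.character(lab[sel][j])
      counts[s, bi[j]] <- counts[s, bi[j]] + 1
    }
  }
  list(profile = counts / pmax(rowSums(counts), 1), offsets = centers,
       counts = counts)
}
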