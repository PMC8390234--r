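# Observation encoding: nucleosome calls + histone-mark peaks + genes
# -> directional nucleosome-level observation sequences.

#' Default histone-mark bit ordering
#'
#' Marks are mapped to bits of the observation symbol: the first mark in the
#' ordering is bit 0 (value 1), the second bit 1 (value 2), and so on.  With
#' the default seven-mark ordering, a nucleosome carrying H3K4me3 (bit 0) and
#' H3K79me2 (bit 3) is encoded as symbol 1 + 8 = 9.  The ordering is written
#' into every output header so downstream stages decode consistently.
#'
#' @return Character vector of mark names, bit 0 first.
#' @export
default_mark_order <- function() {
  c("H3K4me3", "H3K4me1", "H3K27ac", "H3K79me2",
    "H3K36me3", "H3K9me3", "H3K27me3")
}

#' Encode a set of marks as an observation symbol
#'
#' The observation alphabet has `2^n` symbols, one per subset of the `n`
#' declared histone marks; a symbol is the sum of `2^mark_id` over the marks
#' present on the nucleosome.
#'
#' @param marks_present Integer vector of 0-based mark bit indices (may be
#'   empty), or character vector of mark names resolved against `mark_order`.
#' @param n Number of declared marks.
#' @param mark_order Character vector used to resolve mark names; defaults to
#'   [default_mark_order()].
#' @return A single integer symbol in `[0, 2^n - 1]`.
#' @examples
#' encode_observation(c("H3K4me3", "H3K79me2"), n = 7) # 9
#' @export
encode_observation <- function(marks_present, n,
                               mark_order = default_mark_order()) {
  stopifnot(length(n) == 1L, n >= 1L)
  if (is.character(marks_present)) {
    idx <- match(marks_present, mark_order)
    if (anyNA(idx)) {
      stop("unknown mark name(s): ",
           paste(marks_present[is.na(idx)], collapse = ", "))
    }
    marks_present <- idx - 1L
  }
  marks_present <- unique(as.integer(marks_present))
  if (length(marks_present) && (min(marks_present) < 0L ||
                                max(marks_present) >= n)) {
    stop("mark_id out of range [0, n)")
  }
  as.integer(sum(bitwShiftL(1L, marks_present)))
}

#' Decode an observation symbol into its mark set
#'
#' Inverse of [encode_observation()]: returns the 0-based bit indices set in
#' `symbol`.
#'
#' @param symbol Integer in `[0, 2^n - 1]`.
#' @param n Number of declared marks.
#' @return Integer vector of mark bit indices (possibly empty).
#' @export
decode_observation <- function(symbol, n) {
  stopifnot(length(symbol) == 1L)
  symbol <- as.integer(symbol)
  if (symbol < 0L || symbol >= bitwShiftL(1L, n)) {
    stop("symbol out of range [0, 2^n)")
  }
  bits <- 0:(n - 1L)
  bits[bitwAnd(symbol, bitwShiftL(1L, bits)) > 0L]
}

#' Filter paired-end fragments by length
#'
#' Keeps fragments whose length is within `[min_len, max_len]` (both ends
#' inclusive); the default 130-180 bp window retains mononucleosome plus
#' linker-histone fragments.
#'
#' @param fragments data.frame with `start`, `end` (0-based half-open) and
#'   optionally `chrom`.
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return The retained rows of `fragments`.
#' @export
filter_fragments <- function(fragments, min_len = 130L, max_len = 180L) {
  stopifnot(min_len <= max_len)
  len <- fragments$end - fragments$start
  if (any(len < 0)) stop("negative-length fragment interval")
  fragments[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Assign histone marks to a nucleosome by peak overlap
#'
#' A mark is assigned when the total overlap of that mark's peaks with the
#' nucleosome span reaches `min_overlap_frac` of the nucleosome width.
#' Peaks of the same mark are merged before summing so stacked peak calls are
#' not double-counted.  Peaks on other chromosomes are ignored.
#'
#' @param nucleosome One-row data.frame (or list) with `chrom`, `start`,
#'   `end`.
#' @param peaks data.frame with `chrom`, `start`, `end`, `mark_id` (0-based).
#' @param min_overlap_frac Required covered fraction of the nucleosome,
#'   in `(0, 1]`.
#' @return Integer vector of assigned mark bit indices.
#' @export
assign_marks <- function(nucleosome, peaks, min_overlap_frac = 0.5) {
  stopifnot(min_overlap_frac > 0, min_overlap_frac <= 1)
  ns <- nucleosome$start[1]; ne <- nucleosome$end[1]
  span <- ne - ns
  stopifnot(span > 0)
  p <- peaks[peaks$chrom == nucleosome$chrom[1] &
               peaks$end > ns & peaks$start < ne, , drop = FALSE]
  if (!nrow(p)) return(integer(0))
  out <- integer(0)
  for (id in sort(unique(p$mark_id))) {
    q <- p[p$mark_id == id, , drop = FALSE]
    iv <- reduce_intervals(pmax(q$start, ns), pmin(q$end, ne))
    if (sum(iv$end - iv$start) >= min_overlap_frac * span) {
      out <- c(out, as.integer(id))
    }
  }
  out
}

# merge overlapping/adjacent half-open intervals
reduce_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ks <- numeric(0); ke <- numeric(0)
  cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce) ce <- max(ce, end[i])
    else { ks <- c(ks, cs); ke <- c(ke, ce); cs <- start[i]; ce <- end[i] }
  }
  list(start = c(ks, cs), end = c(ke, ce))
}

# Vectorized symbol assignment for a nucleosome table (used by
# build_sequences); returns one symbol per nucleosome row.
encode_nucleosomes <- function(nucleosomes, peaks, n,
                               min_overlap_frac = 0.5) {
  nuc <- data.table::as.data.table(nucleosomes)[, .(chrom, start, end)]
  nuc[, nuc_row := .I]
  symbols <- integer(nrow(nuc))
  if (nrow(peaks)) {
    pk <- data.table::as.data.table(peaks)[, .(chrom, start, end, mark_id)]
    data.table::setkey(pk, chrom, start, end)
    ov <- data.table::foverlaps(nuc, pk, type = "any", nomatch = NULL)
    if (nrow(ov)) {
      ov[, `:=`(os = pmax(start, i.start), oe = pmin(end, i.end))]
      # per (nucleosome, mark): merge clipped peak intervals, sum coverage
      cov <- ov[, {
        iv <- reduce_intervals(os, oe)
        .(bp = sum(iv$end - iv$start))
      }, by = .(nuc_row, mark_id)]
      cov <- merge(cov, nuc[, .(nuc_row, width = end - start)],
                   by = "nuc_row")
      cov <- cov[bp >= min_overlap_frac * width]
      if (nrow(cov)) {
        add <- cov[, .(sym = sum(bitwShiftL(1L, mark_id))), by = nuc_row]
        symbols[add$nuc_row] <- as.integer(add$sym)
      }
    }
  }
  if (any(symbols >= bitwShiftL(1L, n))) stop("mark_id out of range [0, n)")
  symbols
}

#' Build per-gene observation sequences
#'
#' For every gene, nucleosomes whose dyad falls in the gene-centric window
#' (`upstream_bp` upstream of the 5' TSS through `downstream_bp` past the
#' TTS) are collected, encoded against the mark peaks, and ordered 5' to 3'
#' in gene orientation (genomic order is reversed for minus-strand genes).
#' A nucleosome inside two gene windows appears in both sequences; sequences
#' are treated independently by training.
#'
#' @param nucleosomes data.frame with `chrom`, `start`, `end`, `dyad` and
#'   optionally `nuc_id`.
#' @param peaks data.frame with `chrom`, `start`, `end`, `mark_id`.
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, `tss`, `tts`.
#' @param upstream_bp,downstream_bp Window extents in bp.
#' @param n_marks Number of declared marks (alphabet is `2^n_marks`).
#' @param min_overlap_frac Passed to the mark-assignment rule.
#' @return A `data.table` with columns `gene_id`, `chrom`, `dyad`, `symbol`,
#'   `nuc_id`, ordered 5'->3' within each gene; attribute `n_marks` records
#'   the alphabet size.
#' @export
build_sequences <- function(nucleosomes, peaks, genes,
                            upstream_bp = 100000L, downstream_bp = 10000L,
                            n_marks = 7L, min_overlap_frac = 0.5) {
  stopifnot(all(genes$strand %in% c("+", "-")))
  bad <- ifelse(genes$strand == "+", genes$tts < genes$tss,
                genes$tss < genes$tts)
  if (any(bad)) stop("gene with TTS before TSS in gene orientation: ",
                     paste(genes$gene_id[bad], collapse = ", "))
  nuc <- data.table::as.data.table(nucleosomes)
  if (is.null(nuc$nuc_id)) nuc[, nuc_id := seq_len(.N)]
  nuc[, symbol := encode_nucleosomes(nuc, peaks, n_marks, min_overlap_frac)]

  gn <- data.table::as.data.table(genes)
  gn[, `:=`(
    wstart = ifelse(strand == "+", tss - upstream_bp, tts - downstream_bp),
    wend   = ifelse(strand == "+", tts + downstream_bp, tss + upstream_bp)
  )]
  # identical-TSS ties resolved by lexical gene_id order
  data.table::setorder(gn, chrom, tss, gene_id)

  pieces <- vector("list", nrow(gn))
  for (i in seq_len(nrow(gn))) {
    g <- gn[i]
    m <- nuc[chrom == g$chrom & dyad >= g$wstart & dyad < g$wend,
             .(chrom, dyad, symbol, nuc_id)]
    if (!nrow(m)) next
    data.table::setorder(m, dyad)
    if (g$strand == "-") m <- m[rev(seq_len(nrow(m)))]
    m[, gene_id := g$gene_id]
    pieces[[i]] <- m
  }
  out <- data.table::rbindlist(pieces)
  if (!nrow(out)) {
    out <- data.table::data.table(gene_id = character(), chrom = character(),
                                  dyad = integer(), symbol = integer(),
                                  nuc_id = integer())
  }
  data.table::setcolorder(out, c("gene_id", "chrom", "dyad", "symbol",
                                 "nuc_id"))
  data.table::setattr(out, "n_marks", as.integer(n_marks))
  out[]
}

#' Split an observation table into per-gene symbol vectors
#'
#' @param seq_table Output of [build_sequences()] (or a compatible table).
#' @return Named list of integer symbol vectors, one per gene, in table
#'   order.
#' @export
sequence_list <- function(seq_table) {
  sp <- split(seq_table$symbol,
              factor(seq_table$gene_id, levels = unique(seq_table$gene_id)))
  lapply(sp, as.integer)
}
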