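# Genomic-region annotation of decoded states and assembly of the
# functional-nucleosome-state summary.

#' Gene-centric region scheme
#'
#' Regions tile the training window without overlap: Distal
#' (`-upstream .. -distal_boundary`), Proximal (`-distal_boundary ..
#' -promoter_bp`), Promoter (`-promoter_bp .. TSS`), Genebody (TSS..TTS,
#' profiled as percent of gene length) and Downstream (TTS ..
#' `+downstream`).  All offsets are in gene orientation.
#'
#' @param upstream,downstream Window extents in bp.
#' @param promoter_bp Promoter width upstream of the TSS.
#' @param distal_boundary Distal/Proximal split distance from the TSS.
#' @return A `region_scheme` list.
#' @export
region_scheme <- function(upstream = 100000L, downstream = 10000L,
                          promoter_bp = 1000L, distal_boundary = 10000L) {
  stopifnot(upstream > distal_boundary, distal_boundary > promoter_bp)
  structure(list(upstream = upstream, downstream = downstream,
                 promoter_bp = promoter_bp,
                 distal_boundary = distal_boundary),
            class = "region_scheme")
}

# bin axis: 1 kb bins upstream/downstream, percent bins in the gene body
region_bins <- function(scheme, genebody_bins = 100L, flank_bin = 1000L) {
  up <- seq(-scheme$upstream, -flank_bin, by = flank_bin)
  up_lab <- ifelse(up < -scheme$distal_boundary, "Distal",
                   ifelse(up < -scheme$promoter_bp, "Proximal", "Promoter"))
  # promoter occupies the final promoter_bp; with 1 kb bins and the default
  # 1 kb promoter this is exactly one bin
  dn <- seq(0, scheme$downstream - flank_bin, by = flank_bin)
  data.frame(
    region = c(up_lab, rep("Genebody", genebody_bins),
               rep("Downstream", length(dn))),
    lo = c(up, seq(0, 100 - 100 / genebody_bins,
                   length.out = genebody_bins), dn),
    axis = c(rep("upstream_bp", length(up)),
             rep("genebody_pct", genebody_bins),
             rep("downstream_bp", length(dn))),
    stringsAsFactors = FALSE)
}

#' Per-state region frequency profiles
#'
#' Assigns each decoded nucleosome (by dyad) to a position relative to its
#' gene — upstream offset, percent of gene length, or downstream offset, all
#' strand-aware — bins the positions, and normalizes each state's profile to
#' sum 1.
#'
#' @param decoded Table with `gene_id`, `dyad`, `state` (from
#'   [decode_states()]).
#' @param genes Gene table with `gene_id`, `strand`, `tss`, `tts`.
#' @param scheme A [region_scheme()].
#' @param genebody_bins Number of percent-length bins (default 100).
#' @param flank_bin Upstream/downstream bin width in bp (default 1000).
#' @return List with `profile` (states x bins matrix, rows sum to 1),
#'   `counts` (raw counts) and `bins` (bin metadata).
#' @export
region_profile <- function(decoded, genes, scheme = region_scheme(),
                           genebody_bins = 100L, flank_bin = 1000L) {
  bins <- region_bins(scheme, genebody_bins, flank_bin)
  dt <- data.table::as.data.table(decoded)
  gn <- data.table::as.data.table(genes)
  short <- gn$strand %in% c("+", "-") &
    abs(gn$tts - gn$tss) < genebody_bins
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than one gene-body bin skipped")
    gn <- gn[!short]
  }
  dt <- merge(dt, gn[, .(gene_id, strand, tss, tts)], by = "gene_id")
  d5 <- ifelse(dt$strand == "+", dt$dyad - dt$tss, dt$tss - dt$dyad)
  glen <- abs(dt$tts - dt$tss)
  n_up <- sum(bins$axis == "upstream_bp")
  bin_idx <- rep(NA_integer_, nrow(dt))
  upstream <- d5 < 0
  bin_idx[upstream] <- (d5[upstream] + scheme$upstream) %/% flank_bin + 1L
  body <- d5 >= 0 & d5 <= glen
  pct <- pmin(floor(d5[body] / pmax(glen[body], 1) * genebody_bins),
              genebody_bins - 1L)
  bin_idx[body] <- n_up + pct + 1L
  down <- d5 > glen
  bin_idx[down] <- n_up + genebody_bins +
    (d5[down] - glen[down] - 1L) %/% flank_bin + 1L
  ok <- !is.na(bin_idx) & bin_idx >= 1L & bin_idx <= nrow(bins)
  states <- sort(unique(dt$state))
  counts <- matrix(0, nrow = length(states), ncol = nrow(bins),
                   dimnames = list(as.character(states), NULL))
  tab <- table(factor(dt$state[ok], levels = states), bin_idx[ok])
  counts[, as.integer(colnames(tab))] <- tab
  profile <- counts / pmax(rowSums(counts), 1)
  list(profile = profile, counts = counts, bins = bins)
}

#' Most enriched region per state
#'
#' Region enrichment is the state's fraction of nucleosomes in the region
#' divided by the all-state fraction in that region; the label with the
#' maximum ratio is reported (ties joined with "/").
#'
#' @param profiles Output of [region_profile()].
#' @return Named character vector, one region label per state.
#' @export
dominant_region <- function(profiles) {
  regions <- unique(profiles$bins$region)
  state_frac <- t(vapply(regions, function(r) {
    rowSums(profiles$profile[, profiles$bins$region == r, drop = FALSE])
  }, numeric(nrow(profiles$profile))))
  if (nrow(profiles$profile) == 1L) {
    state_frac <- matrix(state_frac, ncol = 1,
                         dimnames = list(regions, rownames(profiles$profile)))
  }
  bg <- rowMeans(state_frac)  # all-state fraction per region
  ratio <- state_frac / pmax(bg, .Machine$double.eps)
  vapply(seq_len(ncol(ratio)), function(s) {
    r <- ratio[, s]
    paste(regions[r >= max(r) - 1e-12], collapse = "/")
  }, character(1), USE.NAMES = FALSE) -> lab
  names(lab) <- colnames(state_frac)
  lab
}

#' Call marks present in each state
#'
#' @param mark_state Matrix from [mark_state_matrix()].
#' @param threshold Marginal-probability cutoff in (0,1); the default 0.5 is
#'   a pragmatic convention, not a statistically derived value.
#' @return Named list of mark-name vectors per state.
#' @export
mark_call <- function(mark_state, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  out <- apply(mark_state, 1, function(p) {
    colnames(mark_state)[p >= threshold]
  }, simplify = FALSE)
  names(out) <- rownames(mark_state) %||%
    as.character(seq_len(nrow(mark_state)))
  out
}

#' Functional nucleosome-state summary
#'
#' Joins per-state mark calls, organization metrics and dominant regions
#' into one row per surviving HMM state.  States with no called marks are
#' flagged `unlabeled` (they are not given a functional label).
#'
#' @param mark_sets List from [mark_call()].
#' @param org_table Per-state organization data.frame from
#'   [organization_table()].
#' @param dominant_regions Named vector from [dominant_region()].
#' @param label_map Optional named character vector mapping state ->
#'   functional label.
#' @return data.frame with state, label, marks, ave_no, region, spacing,
#'   positioning and phasing columns.
#' @export
build_summary <- function(mark_sets, org_table, dominant_regions,
                          label_map = NULL) {
  states <- as.character(org_table$state)
  marks <- vapply(states, function(s) {
    ms <- mark_sets[[s]]
    if (is.null(ms) || !length(ms)) "" else paste(ms, collapse = "/")
  }, character(1))
  label <- vapply(states, function(s) {
    if (!is.null(label_map) && s %in% names(label_map)) label_map[[s]]
    else if (!length(mark_sets[[s]])) "unlabeled"
    else NA_character_
  }, character(1))
  region <- dominant_regions[states]
  miss <- states[!states %in% names(dominant_regions)]
  if (length(miss)) {
    warning("no region profile for state(s): ", paste(miss, collapse = ", "))
  }
  data.frame(state = states, label = label, marks = marks,
             ave_no = org_table$ave_no, region = unname(region),
             spacing_bp = org_table$spacing_bp,
             positioning_score = org_table$positioning_score,
             phasing_score = org_table$phasing_score,
             stringsAsFactors = FALSE, row.names = NULL)
}
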