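# Readers/writers for the standard input formats and the package's own
# tables.  All coordinates are 0-based half-open internally; dialects that
# are 1-based inclusive (iNPS-style tables, refGene-free text exports) are
# converted on read.

skip_comment_lines <- function(path) {
  lines <- readLines(path, n = 200L)
  sum(cumprod(startsWith(lines, "#")))
}

#' Read an iNPS-style positioned-nucleosome table
#'
#' Tab-separated, one row per nucleosome, with coordinates plus the call
#' attributes used by the positioning score (height, width, area, peak and
#' valley significance) and optionally a comma-separated `signal` column
#' holding the 10 bp/point smoothed coverage.  Dialects vary by version, so
#' nonstandard column names can be remapped with `column_map`.
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping
#'   standard name -> file column name.
#' @param one_based Convert 1-based inclusive coordinates (default TRUE).
#' @return List with `nucleosomes` (data.table) and `signals` (list of
#'   numeric vectors, NULL if the file has no signal column).
#' @export
read_inps <- function(path, column_map = NULL, one_based = TRUE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          skip = skip_comment_lines(path))
  if (!is.null(column_map)) {
    data.table::setnames(dt, unname(column_map), names(column_map),
                         skip_absent = TRUE)
  }
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(dt))) {
    stop("malformed nucleosome table ", path, ": need columns ",
         paste(need, collapse = ", "))
  }
  if (one_based) dt[, start := start - 1L]
  if (is.null(dt$dyad)) dt[, dyad := (start + end) %/% 2L]
  signals <- NULL
  if ("signal" %in% names(dt)) {
    signals <- lapply(strsplit(dt$signal, ","), as.numeric)
    dt[, signal := NULL]
  }
  list(nucleosomes = dt[], signals = signals)
}

#' Write an iNPS-style nucleosome table
#'
#' @param nucleosomes Nucleosome data.frame.
#' @param path Output path.
#' @param signals Optional per-nucleosome signal list (written as a
#'   comma-separated column).
#' @param one_based Write 1-based inclusive starts (default TRUE, matching
#'   the read dialect).
#' @return Invisibly, the path.
#' @export
write_inps <- function(nucleosomes, path, signals = NULL,
                       one_based = TRUE) {
  dt <- data.table::as.data.table(nucleosomes)
  if (one_based) dt[, start := start + 1L]
  if (!is.null(signals)) {
    dt[, signal := vapply(signals, function(s)
      paste(signif(s, 6), collapse = ","), character(1))]
  }
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

bed_cols <- c("chrom", "start", "end", "name", "score", "strand")

#' Read a BED3/BED6 file
#'
#' @param path File path.
#' @return data.table with as many of chrom/start/end/name/score/strand as
#'   the file has columns.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3L) stop("malformed BED file ", path, ": fewer than 3 columns")
  data.table::setnames(dt, head(bed_cols, min(ncol(dt), 6L)))
  dt[]
}

#' Write a BED file
#' @param intervals data.frame with BED-ordered columns.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bed <- function(intervals, path) {
  keep <- intersect(bed_cols, names(intervals))
  data.table::fwrite(data.table::as.data.table(intervals)[, keep,
                                                          with = FALSE],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a narrowPeak (10 columns) or broadPeak (9 columns) file
#'
#' @param path File path.
#' @param mark_id Optional 0-based mark bit to attach as a `mark_id`
#'   column.
#' @return data.table of peaks.
#' @export
read_narrowpeak <- function(path, mark_id = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) != 10L) {
    stop("malformed narrowPeak ", path, ": expected 10 columns, got ",
         ncol(dt))
  }
  data.table::setnames(dt, c(bed_cols, "signalValue", "pValue", "qValue",
                             "peak"))
  if (!is.null(mark_id)) dt[, mark_id := as.integer(mark_id)]
  dt[]
}

#' @rdname read_narrowpeak
#' @export
read_broadpeak <- function(path, mark_id = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) != 9L) {
    stop("malformed broadPeak ", path, ": expected 9 columns, got ",
         ncol(dt))
  }
  data.table::setnames(dt, c(bed_cols, "signalValue", "pValue", "qValue"))
  if (!is.null(mark_id)) dt[, mark_id := as.integer(mark_id)]
  dt[]
}

#' Write peaks in narrowPeak format
#' @param peaks data.frame with chrom/start/end (other columns filled with
#'   placeholders if missing).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_narrowpeak <- function(peaks, path) {
  dt <- data.table::as.data.table(peaks)
  out <- data.table::data.table(
    chrom = dt$chrom, start = dt$start, end = dt$end,
    name = dt$name %||% sprintf("peak%d", seq_len(nrow(dt))),
    score = dt$score %||% 0L, strand = dt$strand %||% ".",
    signalValue = dt$signalValue %||% 0, pValue = dt$pValue %||% -1,
    qValue = dt$qValue %||% -1, peak = dt$peak %||% -1L)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a refGene-style gene table
#'
#' Accepts the UCSC refGene dump layout (with or without the leading `bin`
#' column): name, chrom, strand, txStart, txEnd, ...  Returns one record per
#' gene with strand-aware 5' TSS and TTS; duplicate TSS are resolved by
#' keeping the lexically first gene_id.
#'
#' @param path File path.
#' @param unique_tss Drop genes sharing a TSS (default TRUE).
#' @return data.table with gene_id, chrom, strand, tss, tts.
#' @export
read_refgene <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 5L) stop("malformed refGene table ", path)
  # UCSC dumps have an integer bin column first
  off <- if (is.numeric(dt[[1]]) && is.character(dt[[2]])) 1L else 0L
  out <- data.table::data.table(
    gene_id = as.character(dt[[off + 1L]]),
    chrom = as.character(dt[[off + 2L]]),
    strand = as.character(dt[[off + 3L]]),
    txStart = as.integer(dt[[off + 4L]]),
    txEnd = as.integer(dt[[off + 5L]]))
  if (!all(out$strand %in% c("+", "-"))) {
    stop("malformed refGene table ", path, ": bad strand column")
  }
  out[, `:=`(tss = ifelse(strand == "+", txStart, txEnd),
             tts = ifelse(strand == "+", txEnd, txStart))]
  out[, c("txStart", "txEnd") := NULL]
  out[]
}

#' Read a BED12 gene annotation
#'
#' @param path File path.
#' @return data.table with gene_id, chrom, strand, tss, tts.
#' @export
read_bed12 <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) != 12L) {
    stop("malformed BED12 ", path, ": expected 12 columns, got ", ncol(dt))
  }
  data.table::data.table(
    gene_id = as.character(dt[[4]]), chrom = as.character(dt[[1]]),
    strand = as.character(dt[[6]]),
    tss = ifelse(dt[[6]] == "+", dt[[2]], dt[[3]]),
    tts = ifelse(dt[[6]] == "+", dt[[3]], dt[[2]]))
}

#' Write a gene table in refGene-style layout
#' @param genes data.frame with gene_id, chrom, strand, tss, tts.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_refgene <- function(genes, path) {
  out <- data.frame(
    name = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    txStart = pmin(genes$tss, genes$tts),
    txEnd = pmax(genes$tss, genes$tts))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Normalize chromosome naming
#'
#' Maps between `chr1` and `1` styles in place.
#'
#' @param x data.frame with a `chrom` column.
#' @param style Either "chr" or "plain".
#' @return The data with normalized chromosome names.
#' @export
normalize_chroms <- function(x, style = c("chr", "plain")) {
  style <- match.arg(style)
  ch <- as.character(x$chrom)
  bare <- sub("^chr", "", ch)
  x$chrom <- if (style == "chr") paste0("chr", bare) else bare
  x
}

#' Serialize / load an HMM model as JSON
#'
#' The JSON records the matrices, the mark ordering, the seed and the
#' training trace so a run is fully reconstructable.
#'
#' @param result An `hmm_model` or `nuc_training_result`.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @return Invisibly, the path.
#' @export
write_model_json <- function(result, path, seed = NULL) {
  if (inherits(result, "nuc_training_result")) {
    model <- result$model
    extra <- list(log_likelihood_trace = result$log_likelihood_trace,
                  loglik = result$loglik, bic = result$bic,
                  state_occupancy = result$state_occupancy)
  } else {
    model <- result
    extra <- list()
  }
  obj <- c(list(pi = model$pi, A = model$A, B = model$B,
                mark_order = model$mark_order, seed = seed), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json` returns the `hmm_model` with attributes
#'   `seed`, `bic`, `loglik` and `trace` when present.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- hmm_model(obj$pi, as.matrix(obj$A), as.matrix(obj$B),
                 mark_order = obj$mark_order)
  for (a in c("seed", "bic", "loglik")) {
    if (!is.null(obj[[a]])) attr(m, a) <- obj[[a]]
  }
  if (!is.null(obj$log_likelihood_trace)) {
    attr(m, "trace") <- obj$log_likelihood_trace
  }
  m
}

#' Write decoded states as BED
#'
#' One record per nucleosome with the state in the name field.
#'
#' @param decoded Table with chrom, dyad (or start/end) and state.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_state_bed <- function(decoded, path) {
  dt <- data.table::as.data.table(decoded)
  out <- data.table::data.table(
    chrom = dt$chrom,
    start = dt$start %||% (dt$dyad - 73L),
    end = dt$end %||% (dt$dyad + 74L),
    name = paste0("S", dt$state), score = 0L,
    strand = dt$strand %||% ".")
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---- bespoke headed TSV tables -------------------------------------------

write_headed_tsv <- function(dt, path, header = list()) {
  lines <- vapply(names(header), function(nm) {
    sprintf("#%s=%s", nm,
            jsonlite::toJSON(header[[nm]], auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

read_headed_tsv <- function(path) {
  lines <- readLines(path)
  hdr_n <- sum(cumprod(startsWith(lines, "#")))
  header <- list()
  for (ln in head(lines, hdr_n)) {
    kv <- sub("^#", "", ln)
    key <- sub("=.*$", "", kv)
    header[[key]] <- jsonlite::fromJSON(sub("^[^=]*=", "", kv))
  }
  dt <- data.table::fread(text = lines[(hdr_n + 1L):length(lines)],
                          sep = "\t", header = TRUE)
  attr(dt, "header") <- header
  dt
}

#' Write / read per-gene observation sequences
#'
#' Tab-separated gene_id/chrom/dyad/symbol records preceded by `#` header
#' lines recording the mark ordering and configuration hash, so the
#' encoding is self-describing.
#'
#' @param seq_table Table from [build_sequences()].
#' @param path File path.
#' @param mark_order Mark ordering to record.
#' @param config Optional config list; its hash is recorded.
#' @return Invisibly the path (write) or the table with the header attached
#'   as attributes (read).
#' @export
write_sequences <- function(seq_table, path,
                            mark_order = default_mark_order(),
                            config = NULL) {
  hdr <- list(mark_order = mark_order,
              n_marks = attr(seq_table, "n_marks") %||% length(mark_order))
  if (!is.null(config)) hdr$config_hash <- config_hash(config)
  write_headed_tsv(data.table::as.data.table(seq_table), path, hdr)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  dt <- read_headed_tsv(path)
  hdr <- attr(dt, "header")
  data.table::setattr(dt, "n_marks", as.integer(hdr$n_marks))
  data.table::setattr(dt, "mark_order", hdr$mark_order)
  dt
}

#' Write / read the per-state organization table
#' @param org Organization data.frame (`table` element of
#'   [organization_table()]).
#' @param path File path.
#' @param config Optional config list recorded as a hash.
#' @return Invisibly the path (write); the data.table (read).
#' @export
write_org_tsv <- function(org, path, config = NULL) {
  hdr <- list()
  if (!is.null(config)) hdr$config_hash <- config_hash(config)
  write_headed_tsv(data.table::as.data.table(org), path, hdr)
}

#' @rdname write_org_tsv
#' @export
read_org_tsv <- function(path) read_headed_tsv(path)

#' Read / write a skipped-exon event table
#'
#' Summary-style TSV with event_id, coordinates, isoform-specific read
#' counts X and Y, and the inclusion-level confidence-interval width.
#'
#' @param path File path.
#' @param events Event data.frame.
#' @return data.table (read); invisibly the path (write).
#' @export
read_se_table <- function(path) {
  dt <- read_headed_tsv(path)
  need <- c("event_id", "X", "Y", "ci_width")
  if (!all(need %in% names(dt))) {
    stop("malformed SE table ", path, ": need columns ",
         paste(need, collapse = ", "))
  }
  dt
}

#' @rdname read_se_table
#' @export
write_se_table <- function(events, path) {
  write_headed_tsv(data.table::as.data.table(events), path)
}

# ---- run configuration ----------------------------------------------------

#' Default run configuration
#'
#' All tunable parameters of the pipeline in one validated list; the
#' configuration (and its hash) is serialized into every output header so
#' two runs with equal hash and seed are reproducible.
#'
#' @return A named list of parameters.
#' @export
default_run_config <- function() {
  list(
    mark_order = default_mark_order(),
    min_overlap_frac = 0.5,
    upstream_bp = 100000L, downstream_bp = 10000L,
    state_range = c(15L, 25L), replicates = 5L,
    max_iter_round1 = 300L, max_iter_round2 = 200L, tol = 1e-4,
    prune_cutoff = 0.005,
    array_max_gap = 350L, array_window = 1000L,
    welch_frame_len = 512L, welch_hop = 256L, phasing_band = c(4, 10),
    coef_range = 1, spacing_max_intervals = 4L,
    spacing_smooth_bp = 30, positioning_quantiles = c(0.05, 0.95),
    promoter_bp = 1000L, distal_boundary = 10000L,
    mark_call_threshold = 0.5,
    se_n_cutoff = NA, se_invert_rule2 = FALSE,
    chrom_style = "chr",
    seed = 1L)
}

#' Load and validate a run configuration
#'
#' JSON file of overrides merged onto [default_run_config()].
#'
#' @param path JSON file (NULL for pure defaults).
#' @return Validated config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  stopifnot(cfg$min_overlap_frac > 0, cfg$min_overlap_frac <= 1,
            cfg$prune_cutoff >= 0, cfg$prune_cutoff < 1,
            cfg$array_max_gap > 0, length(cfg$phasing_band) == 2L,
            cfg$replicates >= 1L)
  cfg
}

#' Configuration hash
#'
#' FNV-1a hash of the canonical JSON serialization; stamped into output
#' headers for provenance.
#'
#' @param config Config list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  js <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                         digits = NA)
  bytes <- utf8ToInt(as.character(js))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keeps h a double so the
    # 32-bit arithmetic never overflows R's integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}
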