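# Assembly QC: k-mer based consensus quality (QV) and read-depth anomaly
# flagging.

#' Parameters for k-mer QV estimation
#' @param k K-mer length (default 21).
#' @param cap Optional maximum reported QV (finite sentinel for E = 0).
#' @return A `qv_params` object.
#' @export
qv_params <- function(k = 21, cap = NULL) {
  if (k < 11) abort("k must be >= 11")
  structure(list(k = as.integer(k), cap = cap), class = "qv_params")
}

#' Canonical k-mer set of one or more sequences
#' @param seqs Character vector of DNA strings.
#' @param k K-mer length.
#' @return Character vector of distinct canonical k-mers.
#' @export
kmer_set <- function(seqs, k) {
  unique(unlist(lapply(seqs, function(s) canonical_kmers(s, k)$kmer),
                use.names = FALSE))
}

#' Estimate assembly consensus quality (QV) from k-mer sets
#'
#' An assembly k-mer is erroneous iff absent from the read k-mer set.
#' QV = -10 log10(1 - (1 - E/T)^(1/k)), Phred-scaled: the per-base error
#' rate is inferred from the fraction of clean k-mers.
#'
#' @param assembly_kmers Character vector of assembly canonical k-mers (or
#'   DNA sequences, converted with [kmer_set()] when any element is longer
#'   than `k`).
#' @param read_kmers Read canonical k-mers (same convention).
#' @param params A [qv_params()] object.
#' @return A `qv_result`: list with `E` (erroneous k-mers), `T` (total),
#'   `error_rate` (per-base), `qv` (Inf when E = 0 and no cap is set).
#' @export
estimate_qv <- function(assembly_kmers, read_kmers, params = qv_params()) {
  k <- params$k
  if (any(nchar(assembly_kmers) > k))
    assembly_kmers <- kmer_set(assembly_kmers, k)
  if (any(nchar(read_kmers) > k))
    read_kmers <- kmer_set(read_kmers, k)
  assembly_kmers <- unique(assembly_kmers)
  total <- length(assembly_kmers)
  if (total == 0) abort("no assembly k-mers")
  E <- sum(!(assembly_kmers %in% read_kmers))
  if (E > total) abort("erroneous k-mers exceed total")  # unreachable guard
  err <- 1 - (1 - E / total)^(1 / k)
  qv <- if (E == 0) Inf else -10 * log10(err)
  if (!is.null(params$cap)) qv <- min(qv, params$cap)
  structure(list(E = E, T = total, error_rate = err, qv = qv),
            class = "qv_result")
}

#' @export
print.qv_result <- function(x, ...) {
  cat("<qv_result> QV=", format(x$qv, digits = 4), " (E=", x$E, ", T=", x$T,
      ", per-base error=", format(x$error_rate, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Per-bin read depth from alignment spans
#'
#' @param alignments Tibble with `start`, `end` (0-based half-open reference
#'   spans; read-origin truth from [simulate_reads()] works directly).
#' @param seq_length Reference length in bp.
#' @param bin_bp Bin width (default 1000).
#' @return Tibble (`start`, `end`, `depth`) with mean per-bp depth per bin.
#' @export
depth_profile <- function(alignments, seq_length, bin_bp = 1000) {
  starts <- seq(0L, max(0L, seq_length - 1L), by = bin_bp)
  ends <- pmin(starts + bin_bp, seq_length)
  bp <- numeric(length(starts))
  if (nrow(alignments) == 0) {
    warn("no alignments: depth profile is all zero")
  } else {
    for (i in seq_len(nrow(alignments))) {
      s <- alignments$start[i]; e <- alignments$end[i]
      b1 <- s %/% bin_bp + 1L
      b2 <- min((e - 1L) %/% bin_bp + 1L, length(starts))
      for (b in b1:b2) {
        bp[b] <- bp[b] + min(e, ends[b]) - max(s, starts[b])
      }
    }
  }
  tibble(start = starts, end = ends, depth = bp / (ends - starts))
}

#' Flag depth anomalies (collapses / misjoins) in a depth track
#'
#' Maximal runs of bins whose depth deviates from the track median by more
#' than `z_threshold` robust SDs (1.4826 x MAD) and spanning at least
#' `min_run_bp` are flagged `low_depth` or `high_depth`.
#'
#' @param track Depth tibble from [depth_profile()].
#' @param z_threshold Deviation threshold in robust SDs (default 3).
#' @param min_run_bp Minimum flagged run length in bp (default 10,000).
#' @return Tibble (`start`, `end`, `reason`).
#' @export
flag_depth_anomalies <- function(track, z_threshold = 3, min_run_bp = 10000) {
  if (nrow(track) == 0) abort("empty track")
  med <- median(track$depth)
  rsd <- mad(track$depth)
  state <- rep("ok", nrow(track))
  if (rsd > 0) {
    dev <- track$depth - med
    state[dev > z_threshold * rsd] <- "high_depth"
    state[dev < -z_threshold * rsd] <- "low_depth"
  }
  r <- rle(state)
  out <- list()
  idx <- cumsum(r$lengths)
  for (j in seq_along(r$values)) {
    if (r$values[j] == "ok") next
    i2 <- idx[j]
    i1 <- i2 - r$lengths[j] + 1L
    s <- track$start[i1]; e <- track$end[i2]
    if (e - s >= min_run_bp)
      out[[length(out) + 1L]] <- tibble(start = s, end = e,
                                        reason = r$values[j])
  }
  if (length(out) == 0)
    tibble(start = integer(0), end = integer(0), reason = character(0))
  else bind_rows(out)
}
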