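# HOR annotation: monomer decomposition (DP), HOR-unit calling with variant
# signatures, live-array metrics, self-identity heatmaps and layer
# segmentation.

#' Decompose a tandem-repeat sequence into monomer hits
#'
#' Finds the optimal tiling of the sequence by monomer templates (both
#' strands) with a dynamic program minimising total edit cost over template
#' choices; bases not assigned to a monomer are gap at a fixed per-base cost.
#' The DP optimum equals the edit distance between the sequence and the best
#' concatenation of templates. Hits whose identity falls below
#' `min_identity` are discarded (treated as gap).
#'
#' @param array_seq DNA string.
#' @param templates Monomer template tibble (`id`, `sequence`).
#' @param min_identity Minimum reported hit identity (default 0.7).
#' @param gap_cost Per-base cost of leaving sequence unassigned (default 1).
#' @param both_strands Also search reverse-complement templates (default
#'   TRUE).
#' @return Tibble (`start`, `end`, `template_id`, `strand`, `identity`),
#'   sorted and non-overlapping.
#' @export
decompose_monomers <- function(array_seq, templates, min_identity = 0.7,
                               gap_cost = 1, both_strands = TRUE) {
  if (nrow(templates) < 1) abort("need at least one template")
  empty <- tibble(start = integer(0), end = integer(0),
                  template_id = character(0), strand = character(0),
                  identity = numeric(0))
  if (nchar(array_seq) == 0) return(empty)
  tpl_seq <- templates$sequence
  tpl_id <- templates$id
  tpl_strand <- rep("+", length(tpl_seq))
  if (both_strands) {
    tpl_seq <- c(tpl_seq, vapply(templates$sequence, revcomp, character(1)))
    tpl_id <- c(tpl_id, templates$id)
    tpl_strand <- c(tpl_strand, rep("-", nrow(templates)))
  }
  res <- .decompose_dp(array_seq, tpl_seq, gap_cost)
  if (length(res$start) == 0) return(empty)
  hits <- tibble(start = as.integer(res$start), end = as.integer(res$end),
                 template_id = tpl_id[res$template_index],
                 strand = tpl_strand[res$template_index])
  hits$identity <- vapply(seq_len(nrow(hits)), function(i) {
    seg <- substr(array_seq, hits$start[i] + 1L, hits$end[i])
    tpl <- tpl_seq[res$template_index[i]]
    1 - edit_distance(seg, tpl) / max(nchar(seg), nchar(tpl))
  }, numeric(1))
  hits %>% filter(.data$identity >= min_identity) %>% arrange(.data$start)
}

# global alignment of two label vectors; match 0, mismatch 1, indel 1.
# ties prefer diagonal, then deletion (gap in b), then insertion.
align_label_strings <- function(a, b) {
  na <- length(a); nb <- length(b)
  D <- matrix(0, na + 1, nb + 1)
  D[, 1] <- 0:na
  D[1, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    D[i + 1, j + 1] <- min(D[i, j] + (a[i] != b[j]),
                           D[i, j + 1] + 1,
                           D[i + 1, j] + 1)
  }
  ops <- list()
  i <- na; j <- nb
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && D[i + 1, j + 1] == D[i, j] + (a[i] != b[j])) {
      ops[[length(ops) + 1L]] <- tibble(
        op = if (a[i] == b[j]) "match" else "mismatch",
        a_idx = i, b_idx = j, a_label = a[i], b_label = b[j])
      i <- i - 1; j <- j - 1
    } else if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] + 1) {
      ops[[length(ops) + 1L]] <- tibble(op = "del", a_idx = i, b_idx = NA,
                                        a_label = a[i], b_label = NA)
      i <- i - 1
    } else {
      ops[[length(ops) + 1L]] <- tibble(op = "ins", a_idx = NA, b_idx = j,
                                        a_label = NA, b_label = b[j])
      j <- j - 1
    }
  }
  list(score = D[na + 1, nb + 1],
       ops = bind_rows(rev(ops)))
}

variant_signature <- function(run_ids, hor_defs) {
  # label an unmatched monomer run relative to the closest canonical HOR
  best <- NULL
  for (i in seq_len(nrow(hor_defs))) {
    al <- align_label_strings(hor_defs$monomer_ids[[i]], run_ids)
    if (is.null(best) || al$score < best$score)
      best <- list(score = al$score, id = hor_defs$hor_id[[i]], ops = al$ops)
  }
  if (is.null(best) || best$score >= length(run_ids) +
        min(lengths(hor_defs$monomer_ids))) {
    return(paste0("var:", paste(run_ids, collapse = "-")))
  }
  sig <- best$ops %>%
    filter(.data$op != "match") %>%
    mutate(tag = dplyr::case_when(
      op == "del" ~ paste0("del", .data$a_idx),
      op == "ins" ~ paste0("ins", .data$b_idx),
      TRUE ~ paste0("sub", .data$a_idx)))
  if (nrow(sig) == 0) return(best$id)
  paste0(best$id, "[", paste(sig$tag, collapse = ","), "]")
}

#' Call HOR units and structural variants from a monomer stream
#'
#' Greedy left-to-right matching of the monomer-id sequence against the HOR
#' definitions; maximal unmatched runs are labelled with a variant signature
#' relative to the closest canonical HOR (e.g. `horA[del3]`).
#'
#' @param monomer_annotations Tibble from [decompose_monomers()] (sorted).
#' @param hor_defs Tibble of [hor_definition()] rows.
#' @param live_hors Character vector of HOR ids considered "live"
#'   (kinetochore-competent); defaults to all canonical ids.
#' @param max_gap_bp Maximum gap between consecutive monomers within one HOR
#'   unit (default 10).
#' @return Tibble (`start`, `end`, `hor_label`, `canonical`, `live`,
#'   `n_monomers`).
#' @export
call_hors <- function(monomer_annotations, hor_defs,
                      live_hors = hor_defs$hor_id, max_gap_bp = 10) {
  mons <- monomer_annotations %>% arrange(.data$start)
  out <- list()
  n <- nrow(mons)
  emit_variant <- function(run) {
    sig <- variant_signature(run$template_id, hor_defs)
    canonical_part <- sub("\\[.*$", "", sig)
    tibble(start = min(run$start), end = max(run$end), hor_label = sig,
           canonical = FALSE,
           live = canonical_part %in% live_hors,
           n_monomers = nrow(run))
  }
  i <- 1L
  run_start <- NA_integer_
  while (i <= n) {
    matched <- FALSE
    for (d in seq_len(nrow(hor_defs))) {
      ids <- hor_defs$monomer_ids[[d]]
      p <- length(ids)
      if (i + p - 1L > n) next
      cand <- mons[i:(i + p - 1L), ]
      if (!all(cand$template_id == ids)) next
      if (p > 1 && any(cand$start[-1] - cand$end[-p] > max_gap_bp)) next
      if (!is.na(run_start)) {
        out[[length(out) + 1L]] <- emit_variant(mons[run_start:(i - 1L), ])
        run_start <- NA_integer_
      }
      out[[length(out) + 1L]] <-
        tibble(start = cand$start[1], end = cand$end[p],
               hor_label = hor_defs$hor_id[[d]], canonical = TRUE,
               live = hor_defs$hor_id[[d]] %in% live_hors, n_monomers = p)
      i <- i + p
      matched <- TRUE
      break
    }
    if (!matched) {
      if (is.na(run_start)) run_start <- i
      i <- i + 1L
    }
  }
  if (!is.na(run_start))
    out[[length(out) + 1L]] <- emit_variant(mons[run_start:n, ])
  if (length(out) == 0)
    return(tibble(start = integer(0), end = integer(0),
                  hor_label = character(0), canonical = logical(0),
                  live = logical(0), n_monomers = integer(0)))
  bind_rows(out)
}

#' HOR composition string of an annotation
#' @param hor_annotations Tibble from [call_hors()].
#' @return Single string, unit labels joined by spaces in array order.
#' @export
hor_composition_string <- function(hor_annotations) {
  paste(hor_annotations %>% arrange(.data$start) %>% pull("hor_label"),
        collapse = " ")
}

#' Measure the live alpha-satellite HOR array
#'
#' Live-array span = minimum start to maximum end over live HOR units (the
#' min/max coordinate rule), so interior gaps are included in the length.
#'
#' @param hor_annotations Tibble from [call_hors()] (needs a `live` column).
#' @return An `array_metrics` list: `live_span` (tibble, possibly empty),
#'   `length_bp`, `hor_variant_counts` (tibble `hor_label`, `n`).
#' @export
measure_live_array <- function(hor_annotations) {
  live <- hor_annotations %>% filter(.data$live)
  counts <- hor_annotations %>%
    dplyr::count(.data$hor_label, name = "n") %>%
    arrange(dplyr::desc(.data$n))
  if (nrow(live) == 0) {
    return(structure(list(live_span = interval_tbl(), length_bp = 0L,
                          hor_variant_counts = counts),
                     class = "array_metrics"))
  }
  span <- interval_tbl(min(live$start), max(live$end))
  structure(list(live_span = span,
                 length_bp = as.integer(span$end - span$start),
                 hor_variant_counts = counts),
            class = "array_metrics")
}

#' @export
print.array_metrics <- function(x, ...) {
  cat("<array_metrics> live array ",
      if (nrow(x$live_span)) paste0("[", x$live_span$start, ",",
                                    x$live_span$end, ") = ", x$length_bp,
                                    " bp") else "(none)",
      "; ", nrow(x$hor_variant_counts), " distinct unit label(s)\n", sep = "")
  invisible(x)
}

# identity between two equal-ish windows: alignment (edit distance) based
window_pair_identity <- function(a, b) {
  1 - edit_distance(a, b) / max(nchar(a), nchar(b))
}

# k-mer Jaccard mapped to identity via the Mash distance formula
jaccard_identity <- function(kmers_a, kmers_b, k) {
  j <- length(intersect(kmers_a, kmers_b)) /
    max(1L, length(union(kmers_a, kmers_b)))
  if (j == 0) return(0)
  max(0, 1 + log(2 * j / (1 + j)) / k)
}

#' Windowed self-identity heatmap of a sequence
#'
#' Splits the sequence into non-overlapping windows and computes all pairwise
#' window identities: full alignment identity up to `max_align_windows`
#' windows, a k-mer Jaccard approximation (Mash-style) above that. The
#' method used is recorded in the result.
#'
#' @param seq DNA string (>= 2 windows long).
#' @param window_bp Window width (default 5000).
#' @param max_align_windows Alignment/k-mer switch point (default 400).
#' @param jaccard_k K-mer size for the approximation (default 15).
#' @return An `identity_heatmap`: list with `window_bp`, `windows` (tibble
#'   `start`, `end`), `matrix` (symmetric, unit diagonal), `method`.
#' @export
self_identity_heatmap <- function(seq, window_bp = 5000,
                                  max_align_windows = 400, jaccard_k = 15) {
  n <- nchar(seq)
  nw <- n %/% window_bp
  if (nw < 2) abort("sequence shorter than two windows")
  starts <- (seq_len(nw) - 1L) * window_bp
  wins <- substring(seq, starts + 1L, starts + window_bp)
  M <- diag(1, nw)
  if (nw <= max_align_windows) {
    method <- "alignment"
    d <- adist(wins) / window_bp
    M <- 1 - d
    diag(M) <- 1
  } else {
    method <- "kmer_jaccard"
    ksets <- lapply(wins, function(w) unique(canonical_kmers(w, jaccard_k)$kmer))
    for (i in seq_len(nw - 1L)) for (j in (i + 1L):nw) {
      M[i, j] <- M[j, i] <- jaccard_identity(ksets[[i]], ksets[[j]],
                                             jaccard_k)
    }
  }
  structure(list(window_bp = window_bp,
                 windows = tibble(start = starts, end = starts + window_bp),
                 matrix = M, method = method),
            class = "identity_heatmap")
}

#' @export
print.identity_heatmap <- function(x, ...) {
  cat("<identity_heatmap> ", nrow(x$matrix), " x ", nrow(x$matrix),
      " windows of ", x$window_bp, " bp (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Segment an array into identity layers from a self-identity heatmap
#'
#' Each window is scored by its median identity to neighbouring windows
#' (local mutual identity), assigned to an identity bin, and contiguous
#' same-bin windows are merged into layer segments.
#'
#' @param heatmap An `identity_heatmap`.
#' @param identity_bins Strictly decreasing identity thresholds; a window
#'   falls in bin i when its score >= `identity_bins[i]` (scores below the
#'   last threshold go to an overflow bin).
#' @param local_radius Neighbourhood radius in windows (default 3).
#' @return Tibble (`start`, `end`, `bin`, `median_identity`), one row per
#'   merged layer segment.
#' @export
segment_layers <- function(heatmap, identity_bins = c(0.999, 0.99, 0.95),
                           local_radius = 3) {
  if (is.unsorted(rev(identity_bins), strictly = TRUE))
    abort("identity_bins must be strictly decreasing")
  M <- heatmap$matrix
  nw <- nrow(M)
  score <- vapply(seq_len(nw), function(i) {
    nb <- setdiff(max(1, i - local_radius):min(nw, i + local_radius), i)
    median(M[i, nb])
  }, numeric(1))
  # bin 1 = most identical; scores below the last threshold overflow
  cnt <- findInterval(score, sort(identity_bins))
  bin <- length(identity_bins) - cnt + 1L
  r <- rle(bin)
  idx <- cumsum(r$lengths)
  purrr::map_dfr(seq_along(r$values), function(j) {
    i2 <- idx[j]; i1 <- i2 - r$lengths[j] + 1L
    tibble(start = heatmap$windows$start[i1],
           end = heatmap$windows$end[i2],
           bin = r$values[j],
           median_identity = median(score[i1:i2]))
  })
}
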