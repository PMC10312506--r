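# Windowed sequence identity between haplotypes: CIGAR-based windowing,
# fragment-based alignment, tandem-aware CIGAR restricted to HOR arrays,
# and stratification by pericentromeric region class.

#' Parse an extended CIGAR string
#'
#' Only explicit operations are accepted: `=` (match), `X` (mismatch),
#' `I` (insertion to the reference), `D` (deletion from the reference).
#' Ambiguous `M` is an error.
#'
#' @param cigar CIGAR string, e.g. `"100=2X30I"` (comma separators allowed).
#' @return Tibble (`len`, `op`).
#' @export
parse_cigar <- function(cigar) {
  cigar <- gsub(",", "", cigar, fixed = TRUE)
  m <- gregexpr("[0-9]+[=XIDM]", cigar)[[1]]
  if (m[1] == -1 ||
        sum(attr(m, "match.length")) != nchar(cigar))
    abort(paste0("malformed CIGAR: ", cigar))
  toks <- regmatches(cigar, gregexpr("[0-9]+[=XIDM]", cigar))[[1]]
  op <- substr(toks, nchar(toks), nchar(toks))
  if (any(op == "M"))
    abort("ambiguous M operations: an extended (=/X) CIGAR is required")
  tibble(len = as.integer(substr(toks, 1, nchar(toks) - 1L)), op = op)
}

# accumulate one alignment record's cigar into per-window tallies.
# convention: deletion bases count against the reference window containing
# them; insertion bases against the window containing the insertion point.
tally_record <- function(ref_start, cigar, window_bp, acc) {
  ops <- parse_cigar(cigar)
  pos <- ref_start
  add <- function(acc, w, col, x) {
    key <- as.character(w)
    if (is.null(acc[[key]])) acc[[key]] <- c(m = 0, x = 0, i = 0, d = 0)
    acc[[key]][[col]] <- acc[[key]][[col]] + x
    acc
  }
  for (r in seq_len(nrow(ops))) {
    len <- ops$len[r]; op <- ops$op[r]
    if (op == "I") {
      acc <- add(acc, pos %/% window_bp, "i", len)
      next
    }
    # ref-consuming ops: split across window boundaries
    left <- len
    while (left > 0) {
      w <- pos %/% window_bp
      take <- min(left, (w + 1L) * window_bp - pos)
      col <- c(`=` = "m", X = "x", D = "d")[[op]]
      acc <- add(acc, w, col, take)
      pos <- pos + take
      left <- left - take
    }
  }
  acc
}

finalize_windows <- function(acc, n_aln, window_bp) {
  if (length(acc) == 0)
    return(tibble(window = integer(0), start = integer(0), end = integer(0),
                  mean_identity = numeric(0), aligned_bp = numeric(0),
                  n_alignments = integer(0)))
  w <- as.integer(names(acc))
  tb <- purrr::map_dfr(acc, ~ tibble(m = .x[["m"]], x = .x[["x"]],
                                     i = .x[["i"]], d = .x[["d"]])) %>%
    mutate(window = w) %>%
    arrange(.data$window)
  tb %>%
    mutate(start = .data$window * window_bp,
           end = (.data$window + 1L) * window_bp,
           aligned_bp = .data$m + .data$x + .data$i + .data$d,
           mean_identity = if_else(.data$aligned_bp > 0,
                                   .data$m / .data$aligned_bp, NA_real_),
           n_alignments = dplyr::coalesce(
             unname(n_aln[as.character(.data$window)]), 0L)) %>%
    select("window", "start", "end", "mean_identity", "aligned_bp",
           "n_alignments")
}

#' Windowed identity from alignment records (strategy: full alignments)
#'
#' Partitions alignments into non-overlapping reference windows and computes
#' per-window identity = matches / (matches + mismatches + inserted +
#' deleted bases), pooled over all records intersecting the window (i.e.
#' weighted by aligned bp). The bp-weighted mean of window identities
#' therefore equals the whole-alignment identity exactly.
#'
#' @param records Tibble with `ref_start` and `cigar` (one row per
#'   alignment; all on one reference sequence).
#' @param window_bp Window width (default 10,000).
#' @return Tibble (`window`, `start`, `end`, `mean_identity`, `aligned_bp`,
#'   `n_alignments`); windows with no alignment are absent.
#' @export
window_identity_from_alignments <- function(records, window_bp = 10000) {
  acc <- list()
  n_aln <- integer(0)
  for (i in seq_len(nrow(records))) {
    before <- names(acc)
    acc <- tally_record(records$ref_start[i], records$cigar[i], window_bp, acc)
    touched <- names(acc)  # every window this record touched gets +1
    ops <- parse_cigar(records$cigar[i])
    ref_len <- sum(ops$len[ops$op %in% c("=", "X", "D")])
    ws <- records$ref_start[i] %/% window_bp
    we <- max(ws, (records$ref_start[i] + ref_len - 1L) %/% window_bp)
    for (w in as.character(ws:we))
      n_aln[w] <- (if (w %in% names(n_aln)) n_aln[[w]] else 0L) + 1L
  }
  finalize_windows(acc, n_aln, window_bp)
}

# locate a query fragment on the reference by exact k-mer seed voting on
# diagonals; returns NULL when support is insufficient
locate_fragment <- function(frag, ref_kmer_index, ref_len, k,
                            min_seed_hits = 5) {
  best <- NULL
  for (strand in c("+", "-")) {
    fs <- if (strand == "+") frag else revcomp(frag)
    n <- nchar(fs)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    fk <- substring(fs, starts, starts + k - 1L)
    hit <- ref_kmer_index[fk]
    ok <- !vapply(hit, is.null, logical(1))
    if (!any(ok)) next
    qpos <- rep(starts[ok] - 1L, lengths(hit[ok]))
    rpos <- unlist(hit[ok], use.names = FALSE)
    diag_ <- round((rpos - qpos) / 100)
    tab <- table(diag_)
    top <- as.integer(names(tab)[which.max(tab)])
    votes <- max(tab)
    if (votes < min_seed_hits) next
    sel <- abs(diag_ - top) <= 2
    offset <- round(median(rpos[sel] - qpos[sel]))
    if (is.null(best) || votes > best$votes)
      best <- list(strand = strand, offset = offset, votes = votes,
                   frag_seq = fs)
  }
  best
}

build_kmer_index <- function(ref, k) {
  n <- nchar(ref)
  starts <- seq_len(n - k + 1L)
  km <- substring(ref, starts, starts + k - 1L)
  split(starts - 1L, km)
}

#' Windowed identity by fragmenting the query (strategy: fragments)
#'
#' Cuts the query into consecutive fragments, aligns each fragment once to
#' its best reference location (exact k-mer seed voting, then base-level
#' comparison), and pools fragment identities into reference windows.
#' Multiple fragments may align to the same region but each fragment aligns
#' only once. Unplaced fragments are dropped and counted.
#'
#' @param ref,query DNA strings.
#' @param fragment_bp Fragment length (default 10,000).
#' @param window_bp Reference window width (default 10,000).
#' @param min_fragment_alignment_bp Minimum aligned length per fragment
#'   (default half the fragment).
#' @param seed_k Seed k-mer length (default 15).
#' @return List with `windows` (as [window_identity_from_alignments()]),
#'   `fragments` (per-fragment placements) and `n_dropped`.
#' @export
window_identity_fragmented <- function(ref, query, fragment_bp = 10000,
                                       window_bp = 10000,
                                       min_fragment_alignment_bp =
                                         fragment_bp %/% 2,
                                       seed_k = 15) {
  nq <- nchar(query)
  if (nq < 1) abort("query is empty")
  idx <- build_kmer_index(ref, seed_k)
  ref_len <- nchar(ref)
  fstarts <- seq(0L, nq - 1L, by = fragment_bp)
  acc <- list()
  n_aln <- integer(0)
  frags <- list()
  dropped <- 0L
  for (fs in fstarts) {
    fe <- min(fs + fragment_bp, nq)
    frag <- substr(query, fs + 1L, fe)
    loc <- locate_fragment(frag, idx, ref_len, seed_k)
    if (is.null(loc)) { dropped <- dropped + 1L; next }
    rs <- max(0L, loc$offset)
    re <- min(ref_len, loc$offset + nchar(frag))
    if (re - rs < min_fragment_alignment_bp) { dropped <- dropped + 1L; next }
    rseg <- substr(ref, rs + 1L, re)
    fseg <- if (nchar(loc$frag_seq) == nchar(rseg)) loc$frag_seq else
      substr(loc$frag_seq, 1, nchar(rseg))
    if (nchar(fseg) == nchar(rseg)) {
      mism <- hamming(fseg, rseg)
      aligned <- nchar(rseg)
    } else {
      mism <- edit_distance(fseg, rseg)
      aligned <- max(nchar(fseg), nchar(rseg))
    }
    ident <- 1 - mism / aligned
    frags[[length(frags) + 1L]] <-
      tibble(frag_start = fs, frag_end = fe, ref_start = rs, ref_end = re,
             strand = loc$strand, identity = ident, aligned_bp = aligned)
    # spread the fragment's tallies across reference windows by overlap
    pos <- rs
    left <- re - rs
    mism_per_bp <- mism / max(1L, re - rs)
    while (left > 0) {
      w <- pos %/% window_bp
      take <- min(left, (w + 1L) * window_bp - pos)
      key <- as.character(w)
      if (is.null(acc[[key]])) acc[[key]] <- c(m = 0, x = 0, i = 0, d = 0)
      acc[[key]][["x"]] <- acc[[key]][["x"]] + take * mism_per_bp
      acc[[key]][["m"]] <- acc[[key]][["m"]] + take * (1 - mism_per_bp)
      n_aln[key] <- (if (key %in% names(n_aln)) n_aln[[key]] else 0L) + 1L
      pos <- pos + take
      left <- left - take
    }
  }
  list(windows = finalize_windows(acc, n_aln, window_bp),
       fragments = if (length(frags)) bind_rows(frags) else
         tibble(frag_start = integer(0), frag_end = integer(0),
                ref_start = integer(0), ref_end = integer(0),
                strand = character(0), identity = numeric(0),
                aligned_bp = numeric(0)),
       n_dropped = dropped)
}

#' Windowed identity from a tandem-aware alignment, restricted to HOR arrays
#'
#' Same windowing arithmetic as [window_identity_from_alignments()], but only
#' windows whose midpoint falls inside the HOR-array mask are reported.
#'
#' @param records Tibble with `ref_start`, `cigar` (e.g. parsed from a
#'   tandem-aware aligner's output).
#' @param window_bp Window width (default 10,000).
#' @param hor_mask Tibble (`start`, `end`) of HOR-array intervals.
#' @return Window tibble restricted to the mask (empty, with a warning, when
#'   nothing overlaps).
#' @export
window_identity_tandem <- function(records, window_bp = 10000, hor_mask) {
  wins <- window_identity_from_alignments(records, window_bp)
  mid <- (wins$start + wins$end) / 2
  keep <- point_in_intervals(mid, hor_mask)
  if (!any(keep)) warn("no windows inside the HOR mask")
  wins[keep, , drop = FALSE]
}

#' Stratify window identities by pericentromeric region class
#'
#' Windows are assigned to the class covering their midpoint; windows whose
#' midpoint is in no region are reported as class `"unassigned"`.
#'
#' @param window_identities Window tibble.
#' @param region_bed Tibble (`start`, `end`, `class`).
#' @return Tibble (`class`, `n_windows`, `mean_identity`, `sd_identity`,
#'   `aligned_mbp`).
#' @export
stratify_regions <- function(window_identities, region_bed) {
  if (nrow(window_identities) == 0)
    return(tibble(class = character(0), n_windows = integer(0),
                  mean_identity = numeric(0), sd_identity = numeric(0),
                  aligned_mbp = numeric(0)))
  mid <- (window_identities$start + window_identities$end) / 2
  cls <- rep("unassigned", length(mid))
  if (nrow(region_bed) > 0) {
    for (i in seq_len(nrow(region_bed))) {
      inr <- mid >= region_bed$start[i] & mid < region_bed$end[i]
      cls[inr] <- region_bed$class[i]
    }
  }
  window_identities %>%
    mutate(class = cls) %>%
    filter(!is.na(.data$mean_identity)) %>%
    group_by(.data$class) %>%
    summarise(n_windows = n(),
              sd_identity = sd(.data$mean_identity),
              mean_identity = mean(.data$mean_identity),
              aligned_mbp = sum(.data$aligned_bp) / 1e6,
              .groups = "drop") %>%
    select("class", "n_windows", "mean_identity", "sd_identity",
           "aligned_mbp")
}

#' Decide which reference a haplotype matches best
#'
#' Lexicographic rule: higher mean identity wins; ties break on aligned Mbp;
#' full ties give `"tie"`.
#'
#' @param summary_a,summary_b Region-summary tibbles (or any tibble with
#'   `mean_identity` and `aligned_mbp`); multiple rows are pooled weighted
#'   by aligned Mbp.
#' @param labels Names of the two references (default `c("A", "B")`).
#' @return List with `verdict`, `identity_margin`, `mbp_margin`.
#' @export
best_reference_match <- function(summary_a, summary_b,
                                 labels = c("A", "B")) {
  pool <- function(s) {
    w <- s$aligned_mbp
    list(identity = sum(s$mean_identity * w) / sum(w), mbp = sum(w))
  }
  a <- pool(summary_a); b <- pool(summary_b)
  id_margin <- a$identity - b$identity
  mbp_margin <- a$mbp - b$mbp
  verdict <- if (id_margin > 0) labels[1]
             else if (id_margin < 0) labels[2]
             else if (mbp_margin > 0) labels[1]
             else if (mbp_margin < 0) labels[2]
             else "tie"
  list(verdict = verdict, identity_margin = id_margin,
       mbp_margin = mbp_margin)
}
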