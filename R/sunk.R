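# SUNK-based scaffolding: singly unique k-mers barcode contigs and
# ultra-long reads; colinear shared barcodes bridge fragmented contigs.

#' Parameters for SUNK identification and scaffolding
#'
#' @param k K-mer length (default 20).
#' @param min_shared_sunks Minimum colinear shared SUNKs per contig chain for
#'   a join candidate (default 10).
#' @param min_read_length Minimum read length used for bridging (default
#'   100,000 bp, the ultra-long read cutoff).
#' @param offset_tolerance Allowed diagonal (offset) deviation within a
#'   chain, as a fraction of the chain span (default 0.05).
#' @param max_edge_gap_bp Maximum distance between a chain's last shared
#'   SUNK and the contig edge being joined (default 5000); a true join's
#'   chain must reach the edge, which rejects sparse spurious chains.
#' @param min_chain_span_bp Minimum read-coordinate span of a chain
#'   (default 10,000); rejects compact clusters of stacked duplicate
#'   k-mers that are not genuine colinear anchors.
#' @return A `sunk_params` object.
#' @export
sunk_params <- function(k = 20, min_shared_sunks = 10,
                        min_read_length = 100000, offset_tolerance = 0.05,
                        max_edge_gap_bp = 5000, min_chain_span_bp = 10000) {
  if (k < 11) abort("k must be >= 11")
  if (min_read_length <= k) abort("min_read_length must exceed k")
  structure(list(k = as.integer(k),
                 min_shared_sunks = as.integer(min_shared_sunks),
                 min_read_length = as.integer(min_read_length),
                 offset_tolerance = offset_tolerance,
                 max_edge_gap_bp = as.integer(max_edge_gap_bp),
                 min_chain_span_bp = as.integer(min_chain_span_bp)),
            class = "sunk_params")
}

#' Identify singly unique k-mers (SUNKs) in an assembly
#'
#' A SUNK is a canonical k-mer occurring exactly once across the whole
#' assembly (both strands collapsed to canonical form).
#'
#' @param assembly Named character vector of contig sequences.
#' @param params A [sunk_params()] object.
#' @return A `sunk_set`: list with `k` and `sunks`, a tibble
#'   (`sunk_id` = canonical k-mer, `contig`, `pos`, `strand`).
#' @export
find_sunks <- function(assembly, params = sunk_params()) {
  if (length(assembly) == 0) abort("assembly is empty")
  if (is.null(names(assembly)))
    names(assembly) <- paste0("contig", seq_along(assembly))
  if (params$k > min(nchar(assembly)))
    abort("k exceeds the shortest assembly sequence")
  all_kmers <- purrr::imap_dfr(assembly, function(s, nm) {
    canonical_kmers(s, params$k) %>% mutate(contig = nm)
  })
  dup <- duplicated(all_kmers$kmer) |
    duplicated(all_kmers$kmer, fromLast = TRUE)
  sunks <- all_kmers %>%
    filter(!dup) %>%
    rename(sunk_id = "kmer") %>%
    select("sunk_id", "contig", "pos", "strand") %>%
    arrange(.data$contig, .data$pos)
  structure(list(k = params$k, sunks = sunks), class = "sunk_set")
}

#' @export
print.sunk_set <- function(x, ...) {
  cat("<sunk_set> k=", x$k, "; ", nrow(x$sunks), " SUNKs on ",
      length(unique(x$sunks$contig)), " sequence(s)\n", sep = "")
  invisible(x)
}

#' Barcode a sequence with SUNK positions
#'
#' @param seq DNA string (contig or read).
#' @param sunk_set A `sunk_set` from [find_sunks()].
#' @param sequence_id Identifier recorded in the barcode.
#' @return Tibble (`sequence_id`, `pos`, `sunk_id`, `strand`) ordered by
#'   position; `strand` is the orientation of the canonical form in `seq`.
#' @export
barcode_sequence <- function(seq, sunk_set, sequence_id = "seq") {
  stopifnot(inherits(sunk_set, "sunk_set"))
  km <- canonical_kmers(seq, sunk_set$k)
  hits <- km %>%
    filter(.data$kmer %in% sunk_set$sunks$sunk_id) %>%
    rename(sunk_id = "kmer") %>%
    mutate(sequence_id = sequence_id) %>%
    select("sequence_id", "pos", "sunk_id", "strand") %>%
    arrange(.data$pos)
  hits
}

# longest strictly increasing subsequence (patience sorting); returns
# indices into x
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  tails <- numeric(0)     # smallest tail value of an LIS of each length
  tails_idx <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(x[i] - 0.5, tails) + 1L  # first tail >= x[i]
    prev[i] <- if (j > 1L) tails_idx[j - 1L] else 0L
    tails[j] <- x[i]
    tails_idx[j] <- i
  }
  len <- length(tails)
  out <- integer(len)
  k <- tails_idx[len]
  for (j in rev(seq_len(len))) {
    out[j] <- k
    k <- prev[k]
  }
  out
}

# maximal colinear chain between one read barcode and one contig barcode.
# shared: tibble with read_pos, contig_pos (one row per shared SUNK)
best_chain <- function(shared, offset_tolerance) {
  if (nrow(shared) == 0) return(NULL)
  shared <- shared %>% arrange(.data$read_pos, .data$contig_pos)
  try_orient <- function(cp) {
    idx <- lis_indices(cp)
    ch <- shared[idx, ]
    # offset (diagonal) filter: drop hits deviating from the median diagonal
    for (pass in 1:2) {
      off <- if (identical(cp, shared$contig_pos))
        ch$contig_pos - ch$read_pos else ch$contig_pos + ch$read_pos
      span <- max(ch$read_pos) - min(ch$read_pos) + 1
      dev <- abs(off - median(off))
      keep <- dev <= offset_tolerance * span
      if (all(keep)) break
      ch <- ch[keep, , drop = FALSE]
      if (nrow(ch) == 0) return(NULL)
    }
    ch
  }
  fwd <- try_orient(shared$contig_pos)
  rev_ <- try_orient(-shared$contig_pos)
  n_f <- if (is.null(fwd)) 0L else nrow(fwd)
  n_r <- if (is.null(rev_)) 0L else nrow(rev_)
  if (n_f == 0 && n_r == 0) return(NULL)
  if (n_f >= n_r) list(chain = fwd, orientation = "+")
  else list(chain = rev_, orientation = "-")
}

# project a chain's contig extremities into read coordinates; for "-"
# chains read_pos + contig_pos is constant at (read_start + len - k), so k
# must be added back to recover the covered read interval
project_chain <- function(chain, orientation, contig_len, k) {
  if (orientation == "+") {
    d <- median(chain$contig_pos - chain$read_pos)
    list(near = -d, far = contig_len - d, offset = d)
  } else {
    s <- median(chain$contig_pos + chain$read_pos)
    list(near = s - contig_len + k, far = s + k, offset = s)
  }
}

#' Match read barcodes to contig barcodes and emit join candidates
#'
#' For each read, the maximal colinear chain of shared SUNKs is found per
#' contig (longest monotone subsequence, diagonal deviation bounded by the
#' offset tolerance). Reads chaining to two or more contigs with at least
#' `min_shared_sunks` each yield join candidates between contigs adjacent in
#' read order.
#'
#' @param read_barcodes Tibble of barcodes for all reads (from
#'   [barcode_sequence()], bound by row).
#' @param contig_barcodes Tibble of barcodes for all contigs.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param read_lengths Named integer vector of read lengths.
#' @param params A [sunk_params()] object.
#' @return Tibble of join candidates: `read_id`, `contig_a`, `end_a`,
#'   `orient_a`, `contig_b`, `end_b`, `orient_b`, `n_shared_a`, `n_shared_b`,
#'   `chain_span`, `gap_bp`, `read_gap_start`, `read_gap_end`,
#'   `read_flipped`. Coordinates are on the read after flipping it (if
#'   needed) so that contig A reads forward.
#' @export
chain_and_match <- function(read_barcodes, contig_barcodes, contig_lengths,
                            read_lengths, params = sunk_params()) {
  if (nrow(read_barcodes) == 0) return(empty_join_candidates())
  shared <- read_barcodes %>%
    rename(read_id = "sequence_id", read_pos = "pos") %>%
    dplyr::inner_join(
      contig_barcodes %>%
        rename(contig = "sequence_id", contig_pos = "pos") %>%
        select("contig", "contig_pos", "sunk_id"),
      by = "sunk_id")
  if (nrow(shared) == 0) return(empty_join_candidates())

  out <- list()
  for (rid in unique(shared$read_id)) {
    if (!is.na(read_lengths[rid]) && read_lengths[rid] < params$min_read_length)
      next
    rsh <- shared %>% filter(.data$read_id == rid)
    chains <- list()
    for (ctg in unique(rsh$contig)) {
      bc <- best_chain(rsh %>% filter(.data$contig == ctg),
                       params$offset_tolerance)
      if (is.null(bc) || nrow(bc$chain) < params$min_shared_sunks) next
      if (max(bc$chain$read_pos) - min(bc$chain$read_pos) <
            params$min_chain_span_bp) next
      proj <- project_chain(bc$chain, bc$orientation, contig_lengths[[ctg]],
                            params$k)
      chains[[length(chains) + 1L]] <- tibble(
        contig = ctg, orientation = bc$orientation,
        n_shared = nrow(bc$chain),
        read_lo = min(bc$chain$read_pos), read_hi = max(bc$chain$read_pos),
        near = proj$near, far = proj$far)
    }
    if (length(chains) < 2) next
    chains <- bind_rows(chains)
    # spurious chains (scattered duplicate k-mers) sprawl across the read
    # and overlap the dense true chains; keep strongest chains first and
    # drop any chain mostly overlapped by an already-kept one
    chains <- chains %>% arrange(dplyr::desc(.data$n_shared))
    keep <- logical(nrow(chains))
    for (ci in seq_len(nrow(chains))) {
      lo <- chains$read_lo[ci]; hi <- chains$read_hi[ci]
      ov <- 0
      for (cj in which(keep)) {
        ov <- ov + max(0, min(hi, chains$read_hi[cj]) -
                         max(lo, chains$read_lo[cj]))
      }
      keep[ci] <- ov < 0.5 * (hi - lo + 1)
    }
    chains <- chains[keep, , drop = FALSE]
    # a genuine chain reaches at least one of its projected contig edges
    # within the read; chains anchored to neither edge are spurious
    chains <- chains %>%
      filter(.data$far - .data$read_hi <= params$max_edge_gap_bp |
               .data$read_lo - .data$near <= params$max_edge_gap_bp)
    if (nrow(chains) < 2) next
    chains <- chains %>% arrange(.data$near)
    rlen <- read_lengths[[rid]]
    for (i in seq_len(nrow(chains) - 1L)) {
      a <- chains[i, ]; b <- chains[i + 1L, ]
      # the chains must reach the contig edges being joined
      if (a$far - a$read_hi > params$max_edge_gap_bp) next
      if (b$read_lo - b$near > params$max_edge_gap_bp) next
      flipped <- a$orientation == "-"
      if (flipped) {
        # flip the read so contig A reads forward: r' = rlen - 1 - r
        flip <- function(x) rlen - x  # interval edge transform
        new_a <- tibble(contig = a$contig, orientation = "+",
                        n_shared = a$n_shared,
                        read_lo = flip(a$read_hi), read_hi = flip(a$read_lo),
                        near = flip(a$far), far = flip(a$near))
        new_b <- tibble(contig = b$contig,
                        orientation = if (b$orientation == "+") "-" else "+",
                        n_shared = b$n_shared,
                        read_lo = flip(b$read_hi), read_hi = flip(b$read_lo),
                        near = flip(b$far), far = flip(b$near))
        tmp <- new_b; b <- new_a; a <- tmp
        if (a$near > b$near) { tmp <- a; a <- b; b <- tmp }
      }
      gap_start <- a$far
      gap_end <- b$near
      gap_bp <- max(0, round(gap_end - gap_start))
      end_a <- if (a$orientation == "+") "right" else "left"
      end_b <- if (b$orientation == "+") "left" else "right"
      span <- (a$read_hi - a$read_lo) + (b$read_hi - b$read_lo)
      out[[length(out) + 1L]] <- tibble(
        read_id = rid,
        contig_a = a$contig, end_a = end_a, orient_a = a$orientation,
        contig_b = b$contig, end_b = end_b, orient_b = b$orientation,
        n_shared_a = a$n_shared, n_shared_b = b$n_shared,
        chain_span = as.integer(span),
        gap_bp = as.integer(gap_bp),
        read_gap_start = as.integer(round(max(0, gap_start))),
        read_gap_end = as.integer(round(max(0, gap_end))),
        read_flipped = flipped)
    }
  }
  if (length(out) == 0) return(empty_join_candidates())
  bind_rows(out)
}

empty_join_candidates <- function() {
  tibble(read_id = character(0), contig_a = character(0),
         end_a = character(0), orient_a = character(0),
         contig_b = character(0), end_b = character(0),
         orient_b = character(0), n_shared_a = integer(0),
         n_shared_b = integer(0), chain_span = integer(0),
         gap_bp = integer(0), read_gap_start = integer(0),
         read_gap_end = integer(0), read_flipped = logical(0))
}

#' Scaffold contigs using resolved join candidates
#'
#' Joins are resolved greedily per contig end: most shared SUNKs first, then
#' longest chain span, then lexicographic read id. Gap sequence comes from
#' the single bridging read; every read-derived interval is recorded in the
#' patch table. A cycle in the join graph is an error.
#'
#' @param contigs Named character vector of contig sequences.
#' @param candidates Join-candidate tibble from [chain_and_match()].
#' @param reads Tibble with at least `read_id` and `sequence` (read sequences
#'   as simulated/observed; coordinates in `candidates` refer to these).
#' @return List with `scaffolds` (named character vector), `patches` (tibble
#'   `scaffold`, `start`, `end`, `read_id` of read-derived intervals) and
#'   `layout` (per-contig placement: `scaffold`, `contig`, `start`, `end`,
#'   `orientation`).
#' @export
scaffold <- function(contigs, candidates, reads = NULL) {
  if (nrow(candidates) == 0) {
    return(list(scaffolds = contigs,
                patches = tibble(scaffold = character(0), start = integer(0),
                                 end = integer(0), read_id = character(0)),
                layout = tibble(scaffold = names(contigs),
                                contig = names(contigs),
                                start = 0L, end = nchar(contigs),
                                orientation = "+")))
  }
  stopifnot(!is.null(reads))
  flip_or <- function(o) if (o == "+") "-" else "+"
  # resolve at most one join per contig end, greedy
  cand <- candidates %>%
    arrange(dplyr::desc(pmin(.data$n_shared_a, .data$n_shared_b)),
            dplyr::desc(.data$chain_span), .data$read_id)
  used_ends <- character(0)
  accepted <- list()
  for (i in seq_len(nrow(cand))) {
    cc <- cand[i, ]
    ea <- paste0(cc$contig_a, ":", cc$end_a)
    eb <- paste0(cc$contig_b, ":", cc$end_b)
    if (ea %in% used_ends || eb %in% used_ends) next
    if (cc$contig_a == cc$contig_b) next
    used_ends <- c(used_ends, ea, eb)
    accepted[[length(accepted) + 1L]] <- cc
  }
  if (length(accepted) == 0) return(scaffold(contigs, empty_join_candidates()))
  acc <- bind_rows(accepted)

  adj <- list()
  for (i in seq_len(nrow(acc))) {
    cc <- acc[i, ]
    adj[[cc$contig_a]] <- c(adj[[cc$contig_a]], i)
    adj[[cc$contig_b]] <- c(adj[[cc$contig_b]], i)
  }

  visited <- setNames(rep(FALSE, length(contigs)), names(contigs))
  scaffolds <- character(0)
  patches <- list()
  layout <- list()
  sc_i <- 0L

  read_seq <- function(rid) {
    s <- reads$sequence[match(rid, reads$read_id)]
    if (is.na(s)) abort(paste0("read not found: ", rid))
    s
  }

  for (start_contig in names(contigs)) {
    if (visited[[start_contig]]) next
    # collect the connected component and verify it is a simple path
    comp <- start_contig
    frontier <- start_contig
    while (length(frontier)) {
      nxt <- character(0)
      for (f in frontier) for (ei in adj[[f]]) {
        cc <- acc[ei, ]
        other <- if (cc$contig_a == f) cc$contig_b else cc$contig_a
        if (!(other %in% comp)) { comp <- c(comp, other); nxt <- c(nxt, other) }
      }
      frontier <- nxt
    }
    comp_edges <- unique(unlist(adj[comp]))
    if (length(comp_edges) >= length(comp))
      abort(paste0("cycle in join graph involving: ",
                   paste(comp, collapse = ", ")))
    ends <- comp[vapply(comp, function(n)
      length(adj[[n]] %||% integer(0)) <= 1, logical(1))]
    cur <- sort(ends)[[1]]

    # the first edge (if any) dictates the starting scaffold orientation:
    # entering as stored contig_a means scaffold forward = read forward
    first_edge <- (adj[[cur]] %||% integer(0))
    cur_orient <- "+"
    if (length(first_edge) >= 1) {
      cc0 <- acc[first_edge[[1]], ]
      cur_orient <- if (cc0$contig_a == cur) cc0$orient_a
                    else flip_or(cc0$orient_b)
    }

    sc_i <- sc_i + 1L
    sc_name <- paste0("scaffold", sc_i)
    seq_parts <- character(0)
    pos <- 0L
    used_edges <- integer(0)
    repeat {
      visited[[cur]] <- TRUE
      cseq <- if (cur_orient == "+") contigs[[cur]] else revcomp(contigs[[cur]])
      seq_parts <- c(seq_parts, cseq)
      layout[[length(layout) + 1L]] <-
        tibble(scaffold = sc_name, contig = cur, start = pos,
               end = pos + nchar(cseq), orientation = cur_orient)
      pos <- pos + nchar(cseq)
      nxt_edge <- setdiff(adj[[cur]] %||% integer(0), used_edges)
      if (length(nxt_edge) == 0) break
      ei <- nxt_edge[[1]]
      used_edges <- c(used_edges, ei)
      cc <- acc[ei, ]
      raw_gap <- ""
      if (cc$gap_bp > 0) {
        rs <- read_seq(cc$read_id)
        # candidate coordinates live on the flipped read when read_flipped
        if (cc$read_flipped) rs <- revcomp(rs)
        raw_gap <- substr(rs, cc$read_gap_start + 1L, cc$read_gap_end)
      }
      if (cc$contig_a == cur) {
        # traversing a -> b: scaffold forward must equal read forward
        if (cur_orient != cc$orient_a)
          abort(paste0("orientation conflict at contig ", cur))
        gseq <- raw_gap
        nxt <- cc$contig_b
        nxt_orient <- cc$orient_b
      } else {
        # traversing b -> a: scaffold forward = read backward
        if (cur_orient != flip_or(cc$orient_b))
          abort(paste0("orientation conflict at contig ", cur))
        gseq <- if (nchar(raw_gap)) revcomp(raw_gap) else ""
        nxt <- cc$contig_a
        nxt_orient <- flip_or(cc$orient_a)
      }
      if (nchar(gseq) > 0) {
        patches[[length(patches) + 1L]] <-
          tibble(scaffold = sc_name, start = pos,
                 end = pos + nchar(gseq), read_id = cc$read_id)
        seq_parts <- c(seq_parts, gseq)
        pos <- pos + nchar(gseq)
      }
      if (visited[[nxt]])
        abort(paste0("cycle in join graph involving: ", nxt))
      cur <- nxt
      cur_orient <- nxt_orient
    }
    scaffolds[[sc_name]] <- paste(seq_parts, collapse = "")
  }
  list(scaffolds = scaffolds,
       patches = if (length(patches)) bind_rows(patches) else
         tibble(scaffold = character(0), start = integer(0),
                end = integer(0), read_id = character(0)),
       layout = bind_rows(layout))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Replace read-derived scaffold intervals with local high-accuracy contigs
#'
#' Each patch interval is re-derived from a local (HiFi-like) contig whose
#' flanking anchors align to the scaffold around the interval with at least
#' `min_flank_identity`; non-qualifying intervals are left as-is with a
#' warning.
#'
#' @param scaffold_seq Single scaffold DNA string.
#' @param patches Patch tibble (`start`, `end`, ...) for this scaffold.
#' @param patch_contigs Named character vector of local contigs.
#' @param min_flank_identity Minimum anchor identity (default 0.98).
#' @param anchor_bp Anchor length on each side (default 500).
#' @return List with `sequence` (patched scaffold) and `patches` (input with
#'   `patched` logical and `source` contig), coordinates updated to the
#'   patched sequence.
#' @export
patch_with_local_contigs <- function(scaffold_seq, patches, patch_contigs,
                                     min_flank_identity = 0.98,
                                     anchor_bp = 500) {
  if (nrow(patches) == 0 || length(patch_contigs) == 0) {
    if (nrow(patches) > 0) warn("no patch contigs supplied")
    patches$patched <- rep(FALSE, nrow(patches))
    patches$source <- rep(NA_character_, nrow(patches))
    return(list(sequence = scaffold_seq, patches = patches))
  }
  max_mm <- floor((1 - min_flank_identity) * anchor_bp)
  patches <- patches %>% arrange(.data$start) %>%
    mutate(patched = FALSE, source = NA_character_)
  # process right-to-left so earlier coordinates stay valid, then re-shift
  for (i in rev(seq_len(nrow(patches)))) {
    s <- patches$start[i]; e <- patches$end[i]
    ls <- max(0L, s - anchor_bp)
    left_anchor <- substr(scaffold_seq, ls + 1L, s)
    right_anchor <- substr(scaffold_seq, e + 1L,
                           min(nchar(scaffold_seq), e + anchor_bp))
    if (nchar(left_anchor) < anchor_bp / 2 ||
          nchar(right_anchor) < anchor_bp / 2) next
    done <- FALSE
    for (nm in names(patch_contigs)) {
      for (ori in c("+", "-")) {
        pc <- if (ori == "+") patch_contigs[[nm]] else
          revcomp(patch_contigs[[nm]])
        # among allowed hits keep the unique best (fewest mismatches)
        best_hit <- function(anchor) {
          m <- Biostrings::matchPattern(anchor, pc, max.mismatch = max_mm)
          if (length(m) == 0) return(NULL)
          if (length(m) > 1) {
            mm <- vapply(seq_along(m), function(h)
              hamming(as.character(m[[h]]), anchor), integer(1))
            if (sum(mm == min(mm)) > 1) return(NULL)
            m <- m[which.min(mm)]
          }
          m
        }
        lm <- best_hit(left_anchor)
        rm_ <- best_hit(right_anchor)
        if (is.null(lm) || is.null(rm_)) next
        le <- BiocGenerics::end(lm)[1]
        rs <- BiocGenerics::start(rm_)[1]
        if (rs <= le) next
        replacement <- substr(pc, le + 1L, rs - 1L)
        scaffold_seq <- paste0(substr(scaffold_seq, 1, s), replacement,
                               substr(scaffold_seq, e + 1L,
                                      nchar(scaffold_seq)))
        delta <- nchar(replacement) - (e - s)
        patches$end[i] <- e + delta
        if (i < nrow(patches)) {
          sel <- (i + 1L):nrow(patches)
          patches$start[sel] <- patches$start[sel] + delta
          patches$end[sel] <- patches$end[sel] + delta
        }
        patches$patched[i] <- TRUE
        patches$source[i] <- nm
        done <- TRUE
        break
      }
      if (done) break
    }
    if (!done) warn(sprintf("no qualifying patch for interval [%d,%d)", s, e))
  }
  list(sequence = scaffold_seq, patches = patches)
}
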