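#' @keywords internal
"_PACKAGE"

#' @import tibble
#' @importFrom dplyr %>% mutate filter select arrange summarise group_by ungroup
#'   bind_rows bind_cols left_join n lag lead row_number distinct pull rename
#'   slice first last across everything if_else case_when
#' @importFrom rlang .data abort warn inform
#' @importFrom stats median mad rpois runif rbinom setNames sd quantile dist
#'   as.dist
#' @importFrom utils head tail adist
#' @importFrom Rcpp sourceCpp
#' @useDynLib alphasat, .registration = TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")

# run code under a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# transition partner under the two-state purine/pyrimidine scheme
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Generate a random DNA sequence
#'
#' @param n Length in bp.
#' @param gc GC content as a fraction (default 0.5).
#' @return A single character string over {A,C,G,T}.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param seq A character string over {A,C,G,T,N}.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

seq_to_chars <- function(seq) {
  if (nchar(seq) == 0) return(character(0))
  strsplit(seq, "", fixed = TRUE)[[1]]
}

chars_to_seq <- function(x) paste(x, collapse = "")

#' Substitute bases in a sequence under a two-class substitution scheme
#'
#' Places `n_subs` substitutions at distinct positions chosen uniformly; each is
#' a transition with probability `titv / (titv + 1)` (Kimura two-parameter
#' scheme), otherwise one of the two transversions equiprobably.
#'
#' @param seq DNA string.
#' @param n_subs Number of substitutions (distinct sites).
#' @param titv Transition/transversion rate ratio (default 2).
#' @param positions Optional 0-based positions to mutate (overrides `n_subs`).
#' @return List with `seq` (mutated string) and `events`, a tibble with
#'   0-based `pos`, `ref`, `alt`.
#' @export
mutate_sequence <- function(seq, n_subs, titv = 2, positions = NULL) {
  n <- nchar(seq)
  if (is.null(positions)) {
    n_subs <- min(n_subs, n)
    if (n_subs == 0) {
      return(list(seq = seq, events = tibble(pos = integer(0),
                                             ref = character(0),
                                             alt = character(0))))
    }
    positions <- sample.int(n, n_subs) - 1L
  }
  if (length(positions) == 0) {
    return(list(seq = seq, events = tibble(pos = integer(0),
                                           ref = character(0),
                                           alt = character(0))))
  }
  chars <- seq_to_chars(seq)
  ref <- chars[positions + 1L]
  is_ti <- runif(length(positions)) < titv / (titv + 1)
  alt <- character(length(positions))
  alt[is_ti] <- TRANSITION[ref[is_ti]]
  if (any(!is_ti)) {
    tv <- !is_ti
    alt[tv] <- vapply(ref[tv], function(b) {
      sample(setdiff(DNA_BASES, c(b, TRANSITION[[b]])), 1L)
    }, character(1))
  }
  chars[positions + 1L] <- alt
  list(seq = chars_to_seq(chars),
       events = tibble(pos = as.integer(positions), ref = ref, alt = alt) %>%
         arrange(.data$pos))
}

#' Canonical k-mers of a sequence with positions
#'
#' A k-mer's canonical form is the lexicographic minimum of itself and its
#' reverse complement, so counting is strand-collapsed.
#'
#' @param seq DNA string.
#' @param k K-mer length.
#' @return Tibble with 0-based `pos`, `kmer` (canonical form) and `strand`
#'   ("+" when the forward k-mer is canonical).
#' @export
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(tibble(pos = integer(0), kmer = character(0),
                           strand = character(0)))
  starts <- seq_len(n - k + 1L)
  fwd <- substring(seq, starts, starts + k - 1L)
  rcseq <- revcomp(seq)
  # the reverse complement of the k-mer at 0-based pos i is the k-mer at
  # 0-based pos n-k-i of the reverse-complemented sequence
  rc <- substring(rcseq, rev(starts), rev(starts) + k - 1L)
  canon <- pmin(fwd, rc)
  tibble(pos = starts - 1L, kmer = canon,
         strand = if_else(fwd <= rc, "+", "-"))
}

#' Hamming distance between equal-length strings
#' @param a,b DNA strings of equal length.
#' @return Integer count of differing positions.
#' @export
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# edit distance via base adist (C implementation); counts = substitutions,
# insertions, deletions all cost 1
edit_distance <- function(a, b) {
  as.integer(adist(a, b))
}

#' Construct an interval tibble
#'
#' Intervals are 0-based half-open throughout the package.
#' @param start,end Integer vectors.
#' @param ... Further columns.
#' @return A tibble with `start`, `end` and any extra columns.
#' @export
interval_tbl <- function(start = integer(0), end = integer(0), ...) {
  stopifnot(length(start) == length(end), all(end >= start))
  tibble(start = as.integer(start), end = as.integer(end), ...)
}

# length covered by an interval set (assumes disjoint)
interval_span_bp <- function(x) {
  if (nrow(x) == 0) return(0L)
  sum(x$end - x$start)
}

# does point p (0-based) fall in any interval?
point_in_intervals <- function(p, x) {
  if (nrow(x) == 0) return(rep(FALSE, length(p)))
  vapply(p, function(pp) any(pp >= x$start & pp < x$end), logical(1))
}

#' Read a BED file into a tibble
#'
#' Supports 3-6 columns (chrom, start, end, name, score, strand); coordinates
#' stay 0-based half-open as in the file.
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` and any of `name`, `score`,
#'   `strand` present in the file.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character", comment.char = "#")
  names(x) <- cols[seq_len(ncol(x))]
  out <- as_tibble(x) %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  if ("score" %in% names(out)) out$score <- suppressWarnings(as.numeric(out$score))
  out
}

#' Write a tibble of intervals as BED
#'
#' @param x Tibble with `chrom` (optional; filled with "seq" if absent),
#'   `start`, `end`, and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  chrom <- if ("chrom" %in% names(x)) x$chrom else rep("seq", nrow(x))
  out <- data.frame(chrom = chrom, start = x$start, end = x$end)
  for (col in c("name", "score", "strand")) {
    if (col %in% names(x)) out[[col]] <- x[[col]] else break
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BedGraph file into a tibble
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "integer", "integer",
                                        "numeric"))
  as_tibble(x)
}

#' Write a track tibble as BedGraph
#' @param x Tibble with `start`, `end`, a value column, optional `chrom`.
#' @param path Output path.
#' @param value Name of the value column (default the first numeric column
#'   that is not `start`/`end`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path, value = NULL) {
  if (is.null(value)) {
    cand <- setdiff(names(x)[vapply(x, is.numeric, logical(1))],
                    c("start", "end"))
    stopifnot(length(cand) >= 1)
    value <- cand[[1]]
  }
  chrom <- if ("chrom" %in% names(x)) x$chrom else rep("seq", nrow(x))
  out <- data.frame(chrom = chrom, start = x$start, end = x$end,
                    value = x[[value]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write named sequences to FASTA
#' @param seqs Named character vector of DNA strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
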