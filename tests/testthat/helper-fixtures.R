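# Shared fixtures. Heavy fixtures are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small monomer set + two HOR definitions used across module tests
fixture_monomers <- function() {
  cached("monomers", make_monomer_set(6, pairwise_divergence = 0.1, seed = 101))
}

fixture_hor_defs <- function() {
  mons <- fixture_monomers()
  dplyr::bind_rows(
    hor_definition("horA", mons$id[1:4]),
    hor_definition("horB", mons$id[c(1, 2, 5, 6)]))
}

# a small layered centromere (~100 kb) with flanks, built once
fixture_truth_small <- function() {
  cached("truth_small", {
    plan <- array_plan(
      layers = tibble::tibble(
        hor_id = c("horA", "horB", "horA"),
        copy_count = c(40L, 30L, 40L),
        per_copy_substitution_rate = c(0.01, 0.01, 0.01)),
      flank_monomeric_bp = 5000, flank_unique_bp = 10000, seed = 7)
    build_array(plan, fixture_hor_defs(), fixture_monomers())
  })
}

# the 2-Mbp scaffolding truth: a long near-identical HOR array flanked by
# unique sequence; shared by the SUNK acceptance check and module tests
fixture_truth_scaffolding <- function() {
  cached("truth_scaffolding", {
    mons <- make_monomer_set(6, pairwise_divergence = 0.1, seed = 1)
    defs <- hor_definition("horA", mons$id[1:4])
    plan <- array_plan(
      layers = tibble::tibble(hor_id = "horA", copy_count = 2700L,
                              per_copy_substitution_rate = 0.02),
      flank_monomeric_bp = 50000, flank_unique_bp = 50000, seed = 5)
    build_array(plan, defs, mons)$sequence
  })
}

# a medium centromere (~600 kb) for methylation-track simulation
fixture_truth_cdr <- function() {
  cached("truth_cdr", {
    mons <- make_monomer_set(4, pairwise_divergence = 0.1, seed = 11)
    defs <- hor_definition("horC", mons$id)
    plan <- array_plan(
      layers = tibble::tibble(hor_id = "horC", copy_count = 800L,
                              per_copy_substitution_rate = 0.02),
      flank_monomeric_bp = 20000, flank_unique_bp = 30000, seed = 12)
    build_array(plan, defs, mons)
  })
}

# independent brute-force longest-strictly-increasing-subsequence length
oracle_lis_length <- function(x) {
  n <- length(x)
  if (n == 0) return(0L)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    v <- x[idx]
    if (all(diff(v) > 0)) best <- length(idx)
  }
  best
}

# independent CDR caller: plain loops, no shared helpers
oracle_cdrs <- function(track, sat, bin_bp, min_bp, margin_pts) {
  bins <- sort(unique(track$pos %/% bin_bp))
  val <- vapply(bins, function(b) mean(track$freq[track$pos %/% bin_bp == b]),
                numeric(1))
  s <- bins * bin_bp
  e <- s + bin_bp
  keep <- vapply(seq_along(bins), function(i)
    nrow(sat) > 0 && any(s[i] < sat$end & e[i] > sat$start), logical(1))
  bins <- bins[keep]; val <- val[keep]
  if (length(bins) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      n_bins = integer(0), mean_freq = numeric(0)))
  cutoff <- median(val) - margin_pts / 100
  sel <- val < cutoff
  rows <- list()
  i <- 1L
  while (i <= length(bins)) {
    if (!sel[i]) { i <- i + 1L; next }
    j <- i
    while (j < length(bins) && sel[j + 1L] && bins[j + 1L] == bins[j] + 1L)
      j <- j + 1L
    st <- bins[i] * bin_bp
    en <- (bins[j] + 1L) * bin_bp
    if (en - st > min_bp)
      rows[[length(rows) + 1L]] <-
        data.frame(start = st, end = en, n_bins = j - i + 1L,
                   mean_freq = mean(val[i:j]))
    i <- j + 1L
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      n_bins = integer(0), mean_freq = numeric(0)))
  do.call(rbind, rows)
}

# exhaustive label-string alignment cost by plain recursion (no DP reuse)
oracle_label_align <- function(a, b) {
  if (length(a) == 0) return(length(b))
  if (length(b) == 0) return(length(a))
  min(oracle_label_align(a[-1], b[-1]) + (a[1] != b[1]),
      oracle_label_align(a[-1], b) + 1L,
      oracle_label_align(a, b[-1]) + 1L)
}

# extended CIGAR (=/X only) for two equal-length strings
cigar_from_pair <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  r <- rle(ca == cb)
  paste0(r$lengths, ifelse(r$values, "=", "X"), collapse = "")
}

# whole-alignment identity implied by one extended CIGAR
cigar_identity <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op == "="]) / sum(ops$len)
}

# the 9-taxon genealogy (years) used by the phylogeny recovery check:
# clade {h1,h2,h3} has crown age 1 Myr; root (outgroup split) at 6 Myr
fixture_genealogy <- function() {
  txt <- paste0(
    "(((((h1:1e6,(h2:5e5,h3:5e5):5e5):1e6,h4:2e6):1e6,",
    "((h5:1e6,h6:1e6):1e6,h7:2e6):1e6):1e6,h8:4e6):2e6,outgroup:6e6);")
  ape::read.tree(text = txt)
}
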