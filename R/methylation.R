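# CpG methylation filtering, centromere dip region (CDR) detection,
# CENP-A enrichment ratios and kinetochore comparison.

#' CDR detection parameters
#'
#' @param bin_bp Bin width (default 5000).
#' @param min_cdr_bp Minimum merged-run length; runs must be strictly longer
#'   (default 50,000).
#' @param below_median_margin Margin below the regional median, in
#'   percentage points (default 10); the literal strictly-below-median rule
#'   is margin 0.
#' @param merge_gap_bins Number of unselected bins allowed inside a merged
#'   run (default 0 = strictly consecutive).
#' @param bin_stat Per-bin summary of CpG frequencies: "mean" (default) or
#'   "median".
#' @return A `cdr_params` object.
#' @export
cdr_params <- function(bin_bp = 5000, min_cdr_bp = 50000,
                       below_median_margin = 10, merge_gap_bins = 0,
                       bin_stat = c("mean", "median")) {
  if (bin_bp <= 0) abort("bin_bp must be positive")
  if (min_cdr_bp < bin_bp) abort("min_cdr_bp must be >= bin_bp")
  structure(list(bin_bp = as.integer(bin_bp),
                 min_cdr_bp = as.integer(min_cdr_bp),
                 below_median_margin = below_median_margin,
                 merge_gap_bins = as.integer(merge_gap_bins),
                 bin_stat = match.arg(bin_stat)),
            class = "cdr_params")
}

#' Filter methylation calls by log-likelihood ratio
#'
#' A call is high-quality iff |LLR| >= `llr_threshold` (>= +threshold
#' methylated, <= -threshold unmethylated; the boundary is inclusive).
#' Reads with no high-quality call are removed entirely.
#'
#' @param calls Tibble with `read_id`, `pos`, `llr`.
#' @param llr_threshold Threshold (default 2.5).
#' @return List with `calls` (kept calls plus `methylated` logical) and
#'   `read_status` (per input read: `n_total`, `n_kept`, `kept`).
#' @export
filter_calls <- function(calls, llr_threshold = 2.5) {
  if (llr_threshold <= 0) abort("llr_threshold must be positive")
  kept <- calls %>%
    filter(abs(.data$llr) >= llr_threshold) %>%
    mutate(methylated = .data$llr > 0)
  status <- calls %>%
    group_by(.data$read_id) %>%
    summarise(n_total = n(),
              n_kept = sum(abs(.data$llr) >= llr_threshold),
              .groups = "drop") %>%
    mutate(kept = .data$n_kept > 0)
  list(calls = kept, read_status = status)
}

#' Per-CpG methylation frequency from filtered calls
#'
#' @param kept_calls Kept-call tibble from [filter_calls()] (needs `pos` and
#'   `methylated`).
#' @return Tibble (`pos`, `freq`, `n_calls`); sites with no kept call are
#'   absent.
#' @export
methylation_frequency <- function(kept_calls) {
  if (nrow(kept_calls) == 0) abort("no calls")
  kept_calls %>%
    group_by(.data$pos) %>%
    summarise(freq = mean(.data$methylated), n_calls = n(),
              .groups = "drop") %>%
    arrange(.data$pos)
}

# bin a per-CpG frequency track; returns one row per bin that contains CpGs
bin_methylation <- function(freq_track, bin_bp, region_end = NULL,
                            stat = "mean") {
  f <- freq_track %>%
    mutate(bin = .data$pos %/% bin_bp) %>%
    group_by(.data$bin) %>%
    summarise(value = if (stat == "median") median(.data$freq)
              else mean(.data$freq),
              n_cpg = n(), .groups = "drop") %>%
    mutate(start = .data$bin * bin_bp, end = (.data$bin + 1L) * bin_bp)
  f %>% select("bin", "start", "end", "value", "n_cpg")
}

#' Detect centromere dip regions (CDRs) in a methylation track
#'
#' The binned-median rule: (1) bin the track; (2) restrict to bins
#' overlapping the satellite annotation; (3) take the median bin frequency
#' over those bins; (4) select bins below median minus margin; (5) merge
#' consecutive selected bins; (6) keep merged runs strictly longer than the
#' minimum CDR size.
#'
#' @param freq_track Per-CpG tibble (`pos`, `freq`), frequencies in \[0, 1\].
#' @param satellite_bed Tibble (`start`, `end`) of satellite-containing
#'   intervals.
#' @param params A [cdr_params()] object.
#' @return Tibble (`start`, `end`, `n_bins`, `mean_freq`); empty (with a
#'   warning) when no bin overlaps the satellite annotation.
#' @export
find_cdrs <- function(freq_track, satellite_bed, params = cdr_params()) {
  stopifnot(inherits(params, "cdr_params"))
  empty <- tibble(start = integer(0), end = integer(0), n_bins = integer(0),
                  mean_freq = numeric(0))
  bins <- bin_methylation(freq_track, params$bin_bp, stat = params$bin_stat)
  overlaps_sat <- function(s, e) {
    nrow(satellite_bed) > 0 &&
      any(pmin(e, satellite_bed$end) > pmax(s, satellite_bed$start))
  }
  sat <- vapply(seq_len(nrow(bins)), function(i)
    overlaps_sat(bins$start[i], bins$end[i]), logical(1))
  if (!any(sat)) {
    warn("no bins overlap the satellite annotation")
    return(empty)
  }
  bins <- bins[sat, , drop = FALSE]
  med <- median(bins$value)
  cutoff <- med - params$below_median_margin / 100
  sel <- bins$value < cutoff
  if (!any(sel)) return(empty)
  # merge selected bins, allowing up to merge_gap_bins unselected bins
  # between consecutive selected bins (bins must also be adjacent in
  # genomic coordinates)
  runs <- list()
  cur <- NULL
  sel_idx <- which(sel)
  for (i in sel_idx) {
    if (!is.null(cur) &&
          (bins$bin[i] - cur$last_bin) <= params$merge_gap_bins + 1L) {
      cur$last_bin <- bins$bin[i]
      cur$idx <- c(cur$idx, i)
    } else {
      if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
      cur <- list(first_bin = bins$bin[i], last_bin = bins$bin[i], idx = i)
    }
  }
  runs[[length(runs) + 1L]] <- cur
  out <- purrr::map_dfr(runs, function(r) {
    s <- r$first_bin * params$bin_bp
    e <- (r$last_bin + 1L) * params$bin_bp
    tibble(start = as.integer(s), end = as.integer(e),
           n_bins = length(r$idx), mean_freq = mean(bins$value[r$idx]))
  })
  out %>% filter(.data$end - .data$start > params$min_cdr_bp)
}

#' Binned enrichment ratio of a target over a control coverage track
#'
#' @param target_track,control_track Tibbles (`start`, `end`, `depth`) on
#'   identical bins (rebinned internally to `bin_bp` by averaging when the
#'   input bins are finer).
#' @param bin_bp Output bin width (default 1000).
#' @param pseudocount Added to both numerator and denominator (default 1).
#' @return Tibble (`start`, `end`, `ratio`).
#' @export
enrichment_ratio <- function(target_track, control_track, bin_bp = 1000,
                             pseudocount = 1) {
  stopifnot(nrow(target_track) == nrow(control_track),
            all(target_track$start == control_track$start))
  rebin <- function(tr) {
    tr %>%
      mutate(bin = .data$start %/% bin_bp) %>%
      group_by(.data$bin) %>%
      summarise(start = min(.data$start) %/% bin_bp * bin_bp,
                end = max(.data$end), depth = mean(.data$depth),
                .groups = "drop")
  }
  t2 <- rebin(target_track); c2 <- rebin(control_track)
  if (all(t2$depth == 0) && all(c2$depth == 0))
    warn("both tracks are zero everywhere; ratio track is all 1")
  tibble(start = t2$start, end = t2$end,
         ratio = (t2$depth + pseudocount) / (c2$depth + pseudocount))
}

#' Call kinetochore sites from CDRs and a CENP-A enrichment track
#'
#' Each CDR becomes a candidate site carrying its peak enrichment ratio; the
#' primary site has the highest peak. Dual kinetochores are reported when at
#' least two sites are separated by more than `dual_separation_bp`.
#'
#' @param cdrs CDR tibble from [find_cdrs()].
#' @param ratio_track Enrichment ratio tibble from [enrichment_ratio()].
#' @param transition_coord Coordinate of the HOR-to-monomeric transition
#'   used as the anchor for distances.
#' @param dual_separation_bp Separation threshold (default 150,000).
#' @return List with `sites` (tibble: `start`, `end`, `size_bp`,
#'   `cenpa_peak_ratio`, `anchor_distance_bp`, `primary`), `dual_sites`
#'   (logical) and `separation_bp` (max pairwise midpoint separation, NA for
#'   < 2 sites).
#' @export
call_kinetochore_sites <- function(cdrs, ratio_track, transition_coord,
                                   dual_separation_bp = 150000) {
  if (nrow(cdrs) == 0)
    return(list(sites = tibble(start = integer(0), end = integer(0),
                               size_bp = integer(0),
                               cenpa_peak_ratio = numeric(0),
                               anchor_distance_bp = numeric(0),
                               primary = logical(0)),
                dual_sites = FALSE, separation_bp = NA_real_))
  peak <- vapply(seq_len(nrow(cdrs)), function(i) {
    sel <- ratio_track$end > cdrs$start[i] & ratio_track$start < cdrs$end[i]
    if (!any(sel)) return(NA_real_)
    max(ratio_track$ratio[sel])
  }, numeric(1))
  mid <- (cdrs$start + cdrs$end) / 2
  sites <- tibble(start = cdrs$start, end = cdrs$end,
                  size_bp = cdrs$end - cdrs$start,
                  cenpa_peak_ratio = peak,
                  anchor_distance_bp = abs(mid - transition_coord)) %>%
    mutate(primary = dplyr::row_number(dplyr::desc(
      dplyr::coalesce(.data$cenpa_peak_ratio, -Inf))) == 1L)
  sep <- if (nrow(sites) >= 2) max(dist((sites$start + sites$end) / 2))
         else NA_real_
  list(sites = sites,
       dual_sites = isTRUE(sep > dual_separation_bp),
       separation_bp = sep)
}

#' Compare kinetochore placement between two haplotypes
#'
#' Distances are measured from each haplotype's HOR-to-monomeric transition
#' (the anchor), so the comparison is meaningful even when array lengths
#' differ. The shift class uses the 100-kbp and 500-kbp thresholds.
#'
#' @param sites_a,sites_b Results of [call_kinetochore_sites()].
#' @return List with `distance_bp` (difference of primary anchor distances),
#'   `shift_class` (one of `"<100 kbp"`, `">=100 kbp"`, `">=500 kbp"`),
#'   `size_diff_bp`, and `dual` (per-haplotype dual flags).
#' @export
compare_kinetochores <- function(sites_a, sites_b) {
  pa <- sites_a$sites %>% filter(.data$primary)
  pb <- sites_b$sites %>% filter(.data$primary)
  if (nrow(pa) == 0 || nrow(pb) == 0)
    return(list(distance_bp = NA_real_, shift_class = "incomparable",
                size_diff_bp = NA_real_,
                dual = c(a = sites_a$dual_sites, b = sites_b$dual_sites)))
  d <- abs(pa$anchor_distance_bp - pb$anchor_distance_bp)
  cls <- if (d >= 5e5) ">=500 kbp" else if (d >= 1e5) ">=100 kbp"
         else "<100 kbp"
  list(distance_bp = d, shift_class = cls,
       size_diff_bp = pa$size_bp - pb$size_bp,
       dual = c(a = sites_a$dual_sites, b = sites_b$dual_sites))
}
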