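test_that("filter_calls applies the inclusive LLR threshold per call", {
  calls <- tibble::tibble(
    read_id = c("r1", "r1", "r1", "r2", "r2", "r3"),
    pos = c(10L, 20L, 30L, 10L, 40L, 50L),
    llr = c(3.0, -2.5, 1.0, 2.49, -0.3, 5.5))
  f <- filter_calls(calls, llr_threshold = 2.5)
  # boundary |llr| == 2.5 is kept; sign gives the state
  expect_equal(nrow(f$calls), 3)
  expect_identical(f$calls$methylated, c(TRUE, FALSE, TRUE))
  # r2 has no high-quality call and is flagged as removed
  st <- f$read_status
  expect_identical(st$kept[st$read_id == "r2"], FALSE)
  expect_identical(st$kept[st$read_id == "r1"], TRUE)
  expect_equal(st$n_kept[st$read_id == "r1"], 2L)
  expect_error(filter_calls(calls, llr_threshold = 0))
})

test_that("methylation_frequency averages calls per site", {
  kept <- tibble::tibble(pos = c(5L, 5L, 5L, 9L),
                         methylated = c(TRUE, TRUE, FALSE, FALSE))
  fr <- methylation_frequency(kept)
  expect_equal(fr$freq, c(2 / 3, 0))
  expect_equal(fr$n_calls, c(3L, 1L))
  expect_error(methylation_frequency(kept[0, ]))
})

test_that("find_cdrs implements the binned-median rule on a hand case", {
  # 80 bins of 5 kb; CpGs every 250 bp; a 55-kb dip (11 bins) and a 50-kb
  # dip (10 bins, exactly at the strict > 50 kb threshold)
  pos <- seq(0L, 400000L - 250L, by = 250L)
  freq <- rep(0.85, length(pos))
  freq[pos >= 25000 & pos < 80000] <- 0.15    # 11 bins -> reported
  freq[pos >= 120000 & pos < 170000] <- 0.15  # 10 bins -> filtered out
  track <- tibble::tibble(pos = pos, freq = freq)
  sat <- interval_tbl(0L, 400000L)
  cdrs <- find_cdrs(track, sat)
  expect_equal(nrow(cdrs), 1)
  expect_equal(cdrs$start, 25000L)
  expect_equal(cdrs$end, 80000L)
  expect_equal(cdrs$n_bins, 11L)
  expect_equal(cdrs$mean_freq, 0.15)
})

test_that("find_cdrs honors the satellite restriction and margin", {
  pos <- seq(0L, 200000L - 250L, by = 250L)
  freq <- rep(0.85, length(pos))
  freq[pos >= 25000 & pos < 80000] <- 0.15
  track <- tibble::tibble(pos = pos, freq = freq)
  # satellite annotation excludes the dip: nothing can be called there
  cdrs <- find_cdrs(track, interval_tbl(100000L, 200000L))
  expect_equal(nrow(cdrs), 0)
  # a shallow dip inside the margin is not called
  freq2 <- rep(0.85, length(pos))
  freq2[pos >= 25000 & pos < 80000] <- 0.80
  cdrs2 <- find_cdrs(tibble::tibble(pos = pos, freq = freq2),
                     interval_tbl(0L, 200000L))
  expect_equal(nrow(cdrs2), 0)
  expect_warning(find_cdrs(track, interval_tbl()), "no bins overlap")
})

test_that("find_cdrs equals the brute-force oracle on random tracks", {
  set.seed(111)
  for (rep in 1:10) {
    n_bins <- sample(50:200, 1)
    pos <- seq(0L, n_bins * 5000L - 500L, by = 500L)
    freq <- runif(length(pos))
    # random contiguous dips to create realistic long runs
    for (d in seq_len(sample(1:3, 1))) {
      s <- sample(pos, 1)
      w <- sample(c(30000, 55000, 70000), 1)
      freq[pos >= s & pos < s + w] <- runif(1, 0, 0.2)
    }
    track <- tibble::tibble(pos = pos, freq = freq)
    sat <- interval_tbl(0L, as.integer(n_bins * 5000L))
    got <- find_cdrs(track, sat)
    want <- oracle_cdrs(track, sat, bin_bp = 5000, min_bp = 50000,
                        margin_pts = 10)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, as.integer(want$start))
      expect_equal(got$end, as.integer(want$end))
      expect_equal(got$n_bins, as.integer(want$n_bins))
      expect_equal(got$mean_freq, want$mean_freq, tolerance = 1e-12)
    }
  }
})

test_that("enrichment_ratio computes pseudocounted binned ratios", {
  target <- tibble::tibble(start = c(0L, 500L), end = c(500L, 1000L),
                           depth = c(90, 110))
  control <- tibble::tibble(start = c(0L, 500L), end = c(500L, 1000L),
                            depth = c(24, 26))
  r <- enrichment_ratio(target, control, bin_bp = 1000)
  expect_equal(nrow(r), 1)
  expect_equal(r$ratio, (100 + 1) / (25 + 1))
  expect_warning(
    enrichment_ratio(dplyr::mutate(target, depth = 0),
                     dplyr::mutate(control, depth = 0), bin_bp = 1000),
    "zero everywhere")
})

test_that("call_kinetochore_sites picks the primary peak and dual status", {
  cdrs <- tibble::tibble(start = c(100000L, 400000L),
                         end = c(160000L, 460000L),
                         n_bins = c(12L, 12L), mean_freq = c(0.1, 0.1))
  ratio <- tibble::tibble(start = seq(0L, 499000L, by = 1000L),
                          end = seq(1000L, 500000L, by = 1000L),
                          ratio = 1)
  ratio$ratio[ratio$start >= 400000 & ratio$start < 460000] <- 8
  ks <- call_kinetochore_sites(cdrs, ratio, transition_coord = 0)
  expect_identical(ks$sites$primary, c(FALSE, TRUE))
  expect_equal(ks$separation_bp, 300000)
  expect_true(ks$dual_sites)  # separation 300 kb > 150 kb
  # closely spaced sites are not dual
  cdrs2 <- dplyr::mutate(cdrs, start = c(100000L, 200000L),
                         end = c(160000L, 260000L))
  ks2 <- call_kinetochore_sites(cdrs2, ratio, transition_coord = 0)
  expect_false(ks2$dual_sites)
  # no CDRs -> empty, non-dual
  ks0 <- call_kinetochore_sites(cdrs[0, ], ratio, transition_coord = 0)
  expect_equal(nrow(ks0$sites), 0)
  expect_false(ks0$dual_sites)
})

test_that("compare_kinetochores classifies shifts by distance", {
  mk <- function(anchor_dist) {
    list(sites = tibble::tibble(start = 0L, end = 10L, size_bp = 10L,
                                cenpa_peak_ratio = 2,
                                anchor_distance_bp = anchor_dist,
                                primary = TRUE),
         dual_sites = FALSE, separation_bp = NA_real_)
  }
  expect_identical(compare_kinetochores(mk(10000), mk(50000))$shift_class,
                   "<100 kbp")
  expect_identical(compare_kinetochores(mk(0), mk(100000))$shift_class,
                   ">=100 kbp")
  expect_identical(compare_kinetochores(mk(0), mk(500000))$shift_class,
                   ">=500 kbp")
  none <- list(sites = tibble::tibble(start = integer(0), end = integer(0),
                                      size_bp = integer(0),
                                      cenpa_peak_ratio = numeric(0),
                                      anchor_distance_bp = numeric(0),
                                      primary = logical(0)),
               dual_sites = FALSE, separation_bp = NA_real_)
  expect_identical(compare_kinetochores(none, mk(0))$shift_class,
                   "incomparable")
})
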