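test_that("make_monomer_set produces templates at the requested divergence", {
  mons <- make_monomer_set(8, length = 171, pairwise_divergence = 0.1,
                           seed = 21)
  expect_equal(nrow(mons), 8)
  expect_true(all(nchar(mons$sequence) == 171))
  expect_equal(anyDuplicated(mons$id), 0)
  pairs <- combn(8, 2)
  d <- apply(pairs, 2, function(ij)
    hamming(mons$sequence[ij[1]], mons$sequence[ij[2]]) / 171)
  expect_gt(mean(d), 0.06)
  expect_lt(mean(d), 0.14)
  # deterministic under the seed
  expect_identical(mons, make_monomer_set(8, length = 171,
                                          pairwise_divergence = 0.1,
                                          seed = 21))
  expect_error(make_monomer_set(3, pairwise_divergence = 0.6))
})

test_that("build_array realizes the plan with consistent ground truth", {
  truth <- fixture_truth_small()
  defs <- fixture_hor_defs()
  unit_len <- 4 * 171
  n_units <- 40 + 30 + 40
  expected_len <- 2 * (10000 + 5000) + n_units * unit_len
  expect_equal(nchar(truth$sequence), expected_len)
  expect_equal(nrow(truth$hor_composition), n_units)
  expect_equal(nrow(truth$monomer_truth), n_units * 4)

  # region classes tile the whole sequence without gaps or overlap
  rc <- dplyr::arrange(truth$region_classes, start)
  expect_equal(rc$start[1], 0L)
  expect_equal(rc$end[nrow(rc)], nchar(truth$sequence))
  expect_true(all(rc$start[-1] == rc$end[-nrow(rc)]))

  # the live array coincides with the HOR region
  hor_rc <- dplyr::filter(rc, class == "hor_array")
  expect_equal(truth$live_array$start, hor_rc$start)
  expect_equal(truth$live_array$end, hor_rc$end)

  # every logged substitution is visible in the sequence
  ev <- dplyr::filter(truth$event_log, type == "substitution")
  expect_gt(nrow(ev), 0)
  got <- substring(truth$sequence, ev$pos + 1L, ev$pos + 1L)
  expect_identical(got, ev$alt)
  expect_true(all(ev$ref != ev$alt))

  # each annotated monomer differs from its template only by logged events
  mons <- fixture_monomers()
  mt <- truth$monomer_truth
  for (i in c(1, 100, nrow(mt))) {
    seg <- substr(truth$sequence, mt$start[i] + 1L, mt$end[i])
    tpl <- mons$sequence[mons$id == mt$template_id[i]]
    n_ev <- sum(ev$pos >= mt$start[i] & ev$pos < mt$end[i])
    expect_equal(hamming(seg, tpl), n_ev)
  }
})

test_that("expected_divergence implements D = 2 mu t/g + 4 Ne mu", {
  p <- pair_evolution_params(mu_per_gen = 1e-8, t_years = 6e6,
                             gen_time_years = 25, Ne = 1e4)
  expect_equal(expected_divergence(p), 5.2e-3)
})

test_that("evolve_pair realizes divergence as pairwise differences", {
  anc <- with_seed(31, random_dna(200000))
  p <- pair_evolution_params(mu_per_gen = 1e-8, t_years = 6e6,
                             gen_time_years = 25, Ne = 1e4, seed = 32)
  ev <- evolve_pair(anc, p)
  expect_equal(nchar(ev$hap_a), nchar(anc))
  # all events hit distinct sites, so pairwise differences == event count
  expect_equal(hamming(ev$hap_a, ev$hap_b), nrow(ev$events))
  expect_equal(anyDuplicated(ev$events$pos), 0)
  # realized count is Poisson(n * D): within 5 sd of the mean
  lambda <- 200000 * 5.2e-3
  expect_lt(abs(nrow(ev$events) - lambda), 5 * sqrt(lambda))
  expect_true(all(ev$events$origin %in% c("lineage", "ancestral")))
  expect_true(all(ev$events$lineage %in% c("A", "B")))
  # deterministic under the seed
  ev2 <- evolve_pair(anc, p)
  expect_identical(ev$hap_a, ev2$hap_a)
  expect_identical(ev$hap_b, ev2$hap_b)
})

test_that("saltatory amplification inserts the new variant consistently", {
  truth <- fixture_truth_small()
  mons0 <- fixture_monomers()
  new_mon <- make_monomer_set(1, pairwise_divergence = 0.1, seed = 41)
  new_mon$id <- "monN"
  mons <- dplyr::bind_rows(mons0, new_mon)
  newdef <- hor_definition("horN", c(mons0$id[1:4], "monN"))
  amp <- simulate_saltatory_amplification(truth, newdef,
                                          n_insertion_sites = 3,
                                          n_new_copies = 10,
                                          monomers = mons, seed = 42)
  unit_len <- 5 * 171
  expect_equal(nchar(amp$sequence), nchar(truth$sequence) + 10 * unit_len)
  comp_new <- dplyr::filter(amp$hor_composition, hor_label == "horN")
  expect_equal(nrow(comp_new), 10)
  # inserted copies are exact unit sequences at their recorded coordinates
  unit_seq <- paste(mons$sequence[match(c(mons0$id[1:4], "monN"), mons$id)],
                    collapse = "")
  for (i in seq_len(nrow(comp_new))) {
    expect_identical(substr(amp$sequence, comp_new$start[i] + 1L,
                            comp_new$end[i]), unit_seq)
  }
  # ancestral units still match the original sequence content
  old <- dplyr::filter(amp$hor_composition, hor_label != "horN")
  expect_equal(nrow(old), nrow(truth$hor_composition))
  i <- which.max(old$start)
  seg <- substr(amp$sequence, old$start[i] + 1L, old$end[i])
  expect_true(grepl(seg, truth$sequence, fixed = TRUE))
  # live array grows by the inserted length
  expect_equal(amp$live_array$end - amp$live_array$start,
               truth$live_array$end - truth$live_array$start + 10L * unit_len)
  expect_equal(sum(amp$event_log$type == "hor_insertion"), 3)
})

test_that("simulate_reads yields faithful substrings at zero error", {
  s <- with_seed(51, random_dna(50000))
  reads <- simulate_reads(s, coverage = 3, read_lengths = 5000,
                          per_base_error = 0, seed = 52)
  expect_gte(sum(reads$length), 3 * 50000)
  expect_true(all(reads$n_errors == 0))
  for (i in seq_len(min(10, nrow(reads)))) {
    raw <- substr(s, reads$start[i] + 1L, reads$end[i])
    if (reads$strand[i] == "-") raw <- revcomp(raw)
    expect_identical(reads$sequence[i], raw)
  }
  # error rate is respected on average
  noisy <- simulate_reads(s, coverage = 3, read_lengths = 5000,
                          per_base_error = 0.05, seed = 53)
  rate <- sum(noisy$n_errors) / sum(noisy$length)
  expect_gt(rate, 0.045)
  expect_lt(rate, 0.055)
  expect_error(simulate_reads(s, per_base_error = 0.5))
})

test_that("simulate_methylation places dips exactly at planted intervals", {
  truth <- fixture_truth_small()
  n <- nchar(truth$sequence)
  dips <- interval_tbl(20000L, 35000L)
  sim <- simulate_methylation(truth, baseline_freq = 0.8, dip_freq = 0.1,
                              dip_intervals = dips)
  tr <- sim$track
  # track covers exactly the CG positions of the sequence
  cg <- gregexpr("CG", truth$sequence, fixed = TRUE)[[1]]
  expect_identical(tr$pos, as.integer(cg) - 1L)
  inside <- tr$pos >= 20000 & tr$pos < 35000
  expect_true(all(tr$freq[inside] == 0.1))
  expect_true(all(tr$freq[!inside] == 0.8))
  expect_equal(as.data.frame(sim$truth$planted_cdrs), as.data.frame(dips))
  expect_error(simulate_methylation(truth, baseline_freq = 0.3,
                                    dip_freq = 0.5))
})

test_that("simulate_coverage plants fold enrichment in the target only", {
  cov <- simulate_coverage(500000L, mean_depth = 30,
                           enrichment_intervals = interval_tbl(100000L,
                                                               200000L),
                           fold = 4, bin_bp = 1000, seed = 61)
  inside <- cov$target$start >= 100000 & cov$target$end <= 200000
  expect_gt(mean(cov$target$depth[inside]), 100)
  expect_lt(mean(cov$target$depth[!inside]), 35)
  expect_lt(abs(mean(cov$control$depth) - 30), 1)
  expect_error(simulate_coverage(1000L, fold = 0.5))
})
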