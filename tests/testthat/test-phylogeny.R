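test_that("extract_flanks takes the window adjacent to the live array", {
  set.seed(131)
  left <- random_dna(30000)
  arr <- strrep(random_dna(171), 100)   # multi-copy: not single-copy mapping
  right <- random_dna(30000)
  seq <- paste0(left, arr, right)
  la <- interval_tbl(30000L, as.integer(30000 + nchar(arr)))
  p <- extract_flanks(seq, la, arm = "p", flank_bp = 20000)
  expect_equal(c(p$start, p$end), c(10000, 30000))
  expect_identical(p$sequence, substr(seq, 10001, 30000))
  expect_equal(p$median_multiplicity, 1)
  q <- extract_flanks(seq, la, arm = "q", flank_bp = 20000)
  expect_identical(q$sequence,
                   substr(seq, nchar(seq) - 30000 + 1, nchar(seq) - 10000))
  # a flank that falls inside the repeat array multi-maps -> error
  la_bad <- interval_tbl(as.integer(30000 + 171 * 50),
                         as.integer(30000 + nchar(arr)))
  expect_error(extract_flanks(seq, la_bad, arm = "p", flank_bp = 5000),
               "multi-maps")
  expect_error(extract_flanks(seq, la, arm = "p", flank_bp = 40000),
               "truncated")
})

test_that("build_tree + calibrate recover a known 5-taxon genealogy", {
  tr <- ape::read.tree(
    text = "(((t1:1e6,t2:1e6):2e6,(t3:2e6,t4:2e6):1e6):3e6,out:6e6);")
  root_seq <- with_seed(132, random_dna(100000))
  msa <- simulate_tree_sequences(tr, root_seq, mu_per_gen = 1e-8,
                                 gen_time_years = 25, seed = 133)
  ct <- build_tree(msa, "out", bootstrap_reps = 25, seed = 134)
  ct <- calibrate(ct, root_age_years = 6e6)
  expect_equal(topology_concordance(ct, tr), 0)
  # calibration anchors the root and zeroes the tips
  td <- generics::tidy(ct)
  expect_true(all(td$age_years[td$is_tip] == 0))
  ntip <- length(ct$tree$tip.label)
  expect_equal(unname(ct$node_ages_years[ntip + 1L]), 6e6)
  # dated sister pairs land near their true ages
  m12 <- test_monophyly(ct, c("t1", "t2"))
  expect_true(m12$monophyletic)
  expect_lt(abs(m12$crown_age_years - 1e6), 0.5e6)
  m34 <- test_monophyly(ct, c("t3", "t4"))
  expect_true(m34$monophyletic)
  expect_lt(abs(m34$crown_age_years - 2e6), 1e6)
  # a non-clade is rejected
  expect_false(test_monophyly(ct, c("t1", "t3"))$monophyletic)
  expect_error(test_monophyly(ct, "nope"), "unknown taxa")
  # internal-edge bootstrap support is high for clean signal
  expect_true(all(ct$support >= 80, na.rm = TRUE))
})

test_that("calibrate orders node ages consistently with the topology", {
  tr <- fixture_genealogy()
  msa <- simulate_tree_sequences(tr, with_seed(135, random_dna(30000)),
                                 mu_per_gen = 1e-8, seed = 136)
  ct <- calibrate(build_tree(msa, "outgroup", bootstrap_reps = 0))
  ages <- ct$node_ages_years
  tree <- ct$tree
  # every parent is at least as old as its child
  internal <- tree$edge[, 2] > length(tree$tip.label)
  expect_true(all(ages[tree$edge[internal, 1]] >=
                    ages[tree$edge[internal, 2]]))
  expect_error(test_monophyly(build_tree(msa, "outgroup",
                                         bootstrap_reps = 0), "h1"),
               "not calibrated")
})

test_that("topology_concordance is 0 for identical and > 0 for different", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  t2 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  expect_equal(topology_concordance(t1, t1), 0)
  expect_gt(topology_concordance(t1, t2), 0)
  t3 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,e:1):1);")
  expect_error(topology_concordance(t1, t3), "leaf sets differ")
})

test_that("hor_structural_diff counts the worked insertion case", {
  # one inserted run of five 6-monomer (1026-bp) units
  a <- rep("horA", 10)
  b <- c(rep("horA", 4), rep("horB", 5), rep("horA", 6))
  ul <- c(horA = 1026, horB = 1026)
  up <- c(horA = 6, horB = 6)
  d <- hor_structural_diff(a, b, ul, up)
  expect_equal(d$hor_unit_diff, 5)
  expect_equal(d$monomer_diff, 30)
  expect_equal(d$bp_diff, 5130)
  expect_equal(d$distinct_changes, 1)
  # identical strings: all zero
  d0 <- hor_structural_diff(a, a, ul, up)
  expect_equal(generics::tidy(d0),
               tibble::tibble(bp_diff = 0, monomer_diff = 0,
                              hor_unit_diff = 0L, distinct_changes = 0L))
  expect_error(hor_structural_diff(a, c(b, "horZ"), ul), "no unit length")
})

test_that("hor_structural_diff is symmetric in its arguments", {
  set.seed(137)
  labs <- c("u1", "u2", "u3")
  ul <- c(u1 = 1026, u2 = 684, u3 = 1710)
  for (rep in 1:20) {
    a <- sample(labs, sample(0:8, 1), replace = TRUE)
    b <- sample(labs, sample(0:8, 1), replace = TRUE)
    if (length(a) == 0 && length(b) == 0) next
    dab <- hor_structural_diff(a, b, ul)
    dba <- hor_structural_diff(b, a, ul)
    expect_equal(dab$bp_diff, dba$bp_diff)
    expect_equal(dab$monomer_diff, dba$monomer_diff)
    expect_equal(dab$hor_unit_diff, dba$hor_unit_diff)
    expect_equal(dab$alignment_score, dba$alignment_score)
  }
})

test_that("emergence_rate spans the endpoint combinations", {
  d <- structure(list(bp_diff = 1e6, monomer_diff = 0, hor_unit_diff = 10,
                      distinct_changes = 1, alignment_score = 10),
                 class = "hor_structural_diff")
  er <- emergence_rate(d, clade_age_years_range = c(1e5, 2e5),
                       gen_time_range = c(20, 29), array_length_mbp = 2)
  expect_equal(er$generations_range, c(1e5 / 29, 2e5 / 20))
  expect_equal(er$nt_per_generation_range, sort(1e6 / c(1e5 / 29, 2e5 / 20)))
  expect_equal(er$nt_per_mbp_per_generation_range,
               er$nt_per_generation_range / 2)
  expect_error(emergence_rate(d, c(0, 1e5), array_length_mbp = 2))
  expect_error(emergence_rate(d, c(1e5, 2e5), array_length_mbp = 0))
})

test_that("sample_monomers_for_phylogeny samples stratified and seeded", {
  truth <- fixture_truth_small()
  bed <- truth$region_classes
  ann <- truth$monomer_truth
  s1 <- sample_monomers_for_phylogeny(ann, truth$sequence, bed,
                                      n_hor = 20, n_monomeric = 0, seed = 5)
  expect_length(s1, 20)
  expect_true(all(grepl("^hor_", names(s1))))
  expect_identical(s1, sample_monomers_for_phylogeny(ann, truth$sequence,
                                                     bed, n_hor = 20,
                                                     n_monomeric = 0,
                                                     seed = 5))
  # requesting more than available returns all, with a warning
  expect_warning(
    s2 <- sample_monomers_for_phylogeny(ann, truth$sequence, bed,
                                        n_hor = 10, n_monomeric = 50,
                                        seed = 5),
    "mono")
  expect_equal(sum(grepl("^hor_", names(s2))), 10)
  # sampled sequences really come from the annotated intervals
  expect_true(all(nchar(s1) == 171))
  expect_error(sample_monomers_for_phylogeny(ann[0, ], truth$sequence, bed))
})

test_that("simulate_tree_sequences is seeded and respects zero rate", {
  tr <- fixture_genealogy()
  root_seq <- with_seed(138, random_dna(5000))
  tips <- simulate_tree_sequences(tr, root_seq, mu_per_gen = 1e-8,
                                  seed = 139)
  expect_length(tips, 9)
  expect_setequal(names(tips), tr$tip.label)
  expect_identical(tips, simulate_tree_sequences(tr, root_seq,
                                                 mu_per_gen = 1e-8,
                                                 seed = 139))
  still <- simulate_tree_sequences(tr, root_seq, mu_per_gen = 0, seed = 140)
  expect_true(all(still == root_seq))
  # closer relatives are more similar
  expect_lt(hamming(tips[["h2"]], tips[["h3"]]),
            hamming(tips[["h2"]], tips[["outgroup"]]))
})
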