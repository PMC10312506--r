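# A small but complete scaffolding scenario: a unique 120-kb sequence split
# into contigs with deleted gaps, bridged by spanning reads.
small_scaffold_case <- function(seed, flip_contig_b = FALSE,
                                read_strand = "+") {
  set.seed(seed)
  truth <- random_dna(120000)
  cut <- 60000L
  gap <- 2000L
  contig_a <- substr(truth, 1, cut)
  contig_b <- substr(truth, cut + gap + 1L, 120000L)
  if (flip_contig_b) contig_b <- revcomp(contig_b)
  contigs <- c(ctgA = contig_a, ctgB = contig_b)
  read_start <- 40000L
  read_len <- 40000L
  read_seq <- substr(truth, read_start + 1L, read_start + read_len)
  if (read_strand == "-") read_seq <- revcomp(read_seq)
  reads <- tibble::tibble(read_id = "r1", sequence = read_seq)
  params <- sunk_params(min_read_length = 30000)
  ss <- find_sunks(contigs, params)
  rb <- barcode_sequence(read_seq, ss, "r1")
  cb <- dplyr::bind_rows(
    barcode_sequence(contig_a, ss, "ctgA"),
    barcode_sequence(contig_b, ss, "ctgB"))
  cand <- chain_and_match(rb, cb, c(ctgA = nchar(contig_a),
                                    ctgB = nchar(contig_b)),
                          c(r1 = read_len), params)
  list(truth = truth, contigs = contigs, reads = reads, cand = cand,
       params = params)
}

test_that("find_sunks matches a brute-force unique-kmer oracle", {
  set.seed(71)
  shared <- random_dna(500)
  ctg1 <- paste0(random_dna(2000), shared)
  ctg2 <- paste0(shared, random_dna(2000))
  asm <- c(c1 = ctg1, c2 = ctg2)
  ss <- find_sunks(asm, sunk_params(k = 15, min_read_length = 1000))
  # oracle: count canonical k-mers across both contigs with plain table()
  all_km <- c(canonical_kmers(ctg1, 15)$kmer, canonical_kmers(ctg2, 15)$kmer)
  counts <- table(all_km)
  oracle <- sort(names(counts)[counts == 1])
  expect_identical(sort(ss$sunks$sunk_id), oracle)
  expect_equal(anyDuplicated(ss$sunks$sunk_id), 0)
  # no SUNK position lies inside the duplicated block
  for (i in seq_len(nrow(ss$sunks))) {
    ctg <- asm[[ss$sunks$contig[i]]]
    km <- substr(ctg, ss$sunks$pos[i] + 1L, ss$sunks$pos[i] + 15L)
    expect_identical(min(km, revcomp(km)), ss$sunks$sunk_id[i])
  }
})

test_that("barcode_sequence reports SUNK hits at correct read offsets", {
  set.seed(72)
  ctg <- random_dna(20000)
  ss <- find_sunks(c(ctg = ctg), sunk_params(k = 20, min_read_length = 1000))
  read <- substr(ctg, 5001, 12000)
  bc <- barcode_sequence(read, ss, "readX")
  expect_gt(nrow(bc), 0)
  expect_true(all(bc$sequence_id == "readX"))
  # every hit maps back to the contig at pos + 5000
  ctg_bc <- barcode_sequence(ctg, ss, "ctg")
  hit <- match(bc$sunk_id, ctg_bc$sunk_id)
  expect_false(anyNA(hit))
  expect_true(all(ctg_bc$pos[hit] == bc$pos + 5000L))
})

test_that("chain_and_match finds one forward join with the true gap size", {
  case <- small_scaffold_case(73)
  expect_equal(nrow(case$cand), 1)
  cc <- case$cand[1, ]
  expect_identical(cc$contig_a, "ctgA")
  expect_identical(cc$contig_b, "ctgB")
  expect_identical(c(cc$end_a, cc$end_b), c("right", "left"))
  expect_identical(c(cc$orient_a, cc$orient_b), c("+", "+"))
  expect_false(cc$read_flipped)
  expect_lt(abs(cc$gap_bp - 2000L), 3)
  expect_gte(cc$n_shared_a, case$params$min_shared_sunks)
})

test_that("scaffold reconstructs the truth, including the deleted gap", {
  for (seed in 74:76) {
    case <- small_scaffold_case(seed)
    sc <- scaffold(case$contigs, case$cand, case$reads)
    expect_length(sc$scaffolds, 1)
    expect_identical(unname(sc$scaffolds[[1]]), case$truth)
    expect_equal(nrow(sc$patches), 1)
    # the patch interval really is read-derived gap sequence
    p <- sc$patches[1, ]
    expect_identical(substr(sc$scaffolds[[1]], p$start + 1L, p$end),
                     substr(case$truth, 60001, 62000))
    expect_equal(nrow(sc$layout), 2)
  }
})

test_that("scaffolding handles reverse-complemented contigs and reads", {
  for (cfg in list(c(TRUE, "+"), c(FALSE, "-"), c(TRUE, "-"))) {
    case <- small_scaffold_case(77, flip_contig_b = as.logical(cfg[1]),
                                read_strand = cfg[2])
    expect_equal(nrow(case$cand), 1)
    sc <- scaffold(case$contigs, case$cand, case$reads)
    got <- unname(sc$scaffolds[[1]])
    expect_true(got == case$truth || got == revcomp(case$truth))
  }
})

test_that("reads below the ultra-long cutoff are ignored", {
  case <- small_scaffold_case(78)
  strict <- sunk_params(min_read_length = 50000)
  ss <- find_sunks(case$contigs, strict)
  rb <- barcode_sequence(case$reads$sequence[1], ss, "r1")
  cb <- dplyr::bind_rows(
    barcode_sequence(case$contigs[["ctgA"]], ss, "ctgA"),
    barcode_sequence(case$contigs[["ctgB"]], ss, "ctgB"))
  cand <- chain_and_match(rb, cb,
                          c(ctgA = nchar(case$contigs[["ctgA"]]),
                            ctgB = nchar(case$contigs[["ctgB"]])),
                          c(r1 = 40000L), strict)
  expect_equal(nrow(cand), 0)
})

test_that("scaffold without candidates returns contigs unchanged", {
  contigs <- c(a = "ACGTACGTACGT", b = "TTTTCCCCGGGG")
  sc <- scaffold(contigs, alphasat:::empty_join_candidates())
  expect_identical(sc$scaffolds, contigs)
  expect_equal(nrow(sc$patches), 0)
  expect_equal(nrow(sc$layout), 2)
})

test_that("patch_with_local_contigs swaps in the high-accuracy sequence", {
  set.seed(79)
  truth <- random_dna(30000)
  # scaffold carrying an error-ridden 1-kb patch interval at [15000, 16000)
  noisy_patch <- mutate_sequence(substr(truth, 15001, 16000), 60)$seq
  scaffold_seq <- paste0(substr(truth, 1, 15000), noisy_patch,
                         substr(truth, 16001, 30000))
  patches <- tibble::tibble(scaffold = "s1", start = 15000L, end = 16000L,
                            read_id = "r1")
  local_ctg <- c(hifi1 = substr(truth, 13001, 18000))
  res <- patch_with_local_contigs(scaffold_seq, patches, local_ctg)
  expect_true(res$patches$patched[1])
  expect_identical(res$patches$source[1], "hifi1")
  expect_identical(res$sequence, truth)
  # a reverse-complemented local contig works too
  res2 <- patch_with_local_contigs(scaffold_seq, patches,
                                   c(hifi1 = revcomp(local_ctg[[1]])))
  expect_true(res2$patches$patched[1])
  expect_identical(res2$sequence, truth)
})
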