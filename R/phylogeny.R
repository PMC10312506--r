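# Calibrated trees from flanking sequence, monophyly of new-HOR
# haplotypes, p/q topology concordance and HOR emergence rates.

#' Extract a flanking region next to the live array
#'
#' Takes the `flank_bp` window adjacent to the live-array edge on the
#' chosen arm and verifies that the region maps uniquely in the assembly
#' (median canonical k-mer multiplicity must be 1).
#'
#' @param assembly_seq Haplotype DNA string.
#' @param live_array Tibble (`start`, `end`) of the live array.
#' @param arm `"p"` (upstream of the array) or `"q"` (downstream).
#' @param flank_bp Flank length (default 20,000).
#' @param uniqueness_check Verify single-copy mapping (default TRUE).
#' @param k K-mer length for the uniqueness check (default 20).
#' @return List with `arm`, `start`, `end`, `sequence`,
#'   `median_multiplicity`.
#' @export
extract_flanks <- function(assembly_seq, live_array, arm = c("p", "q"),
                           flank_bp = 20000, uniqueness_check = TRUE,
                           k = 20) {
  arm <- match.arg(arm)
  if (nrow(live_array) == 0) abort("live array is empty")
  n <- nchar(assembly_seq)
  if (arm == "p") {
    s <- live_array$start - flank_bp
    e <- live_array$start
    if (s < 0) abort("p-arm flank truncated: array too close to sequence end")
  } else {
    s <- live_array$end
    e <- live_array$end + flank_bp
    if (e > n) abort("q-arm flank truncated: array too close to sequence end")
  }
  region <- substr(assembly_seq, s + 1L, e)
  med_mult <- NA_real_
  if (uniqueness_check) {
    asm_counts <- table(canonical_kmers(assembly_seq, k)$kmer)
    reg_km <- canonical_kmers(region, k)$kmer
    med_mult <- median(as.numeric(asm_counts[reg_km]))
    if (med_mult > 1)
      abort(sprintf(
        "flank region multi-maps (median k-mer multiplicity %.1f)", med_mult))
  }
  list(arm = arm, start = s, end = e, sequence = region,
       median_multiplicity = med_mult)
}

tn93_dist_matrix <- function(msa) {
  n <- length(msa)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- suppressWarnings(tn93_distance(msa[[i]], msa[[j]]))
    if (is.na(d)) {
      # saturated pair: fall back to the raw mismatch proportion
      ca <- seq_to_chars(msa[[i]]); cb <- seq_to_chars(msa[[j]])
      ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
      d <- mean(ca[ok] != cb[ok])
    }
    D[i, j] <- D[j, i] <- as.numeric(d)
  }
  D
}

#' Build a rooted neighbour-joining tree from an alignment
#'
#' Neighbour joining on pairwise TN93 distances, rooted on the outgroup,
#' with column-resampling bootstrap support on internal edges.
#'
#' @param msa Named character vector of aligned sequences (>= 4 including
#'   the outgroup).
#' @param outgroup_id Name of the outgroup sequence.
#' @param bootstrap_reps Bootstrap replicates (default 100; 0 disables).
#' @param seed Integer seed.
#' @return A `calibrated_tree`: list with `tree` (rooted `ape::phylo`),
#'   `support` (per internal node, percent), `outgroup_id`; ages are filled
#'   in by [calibrate()].
#' @export
build_tree <- function(msa, outgroup_id, bootstrap_reps = 100, seed = 1) {
  if (length(msa) < 3) abort("need at least 3 taxa including the outgroup")
  if (!outgroup_id %in% names(msa)) abort("outgroup not in alignment")
  if (length(unique(nchar(msa))) != 1) abort("sequences are not aligned")
  nj_from <- function(seqs) {
    D <- tn93_dist_matrix(seqs)
    tr <- ape::nj(as.dist(D))
    tr$edge.length[tr$edge.length < 0] <- 0
    ape::root(tr, outgroup = outgroup_id, resolve.root = TRUE)
  }
  tree <- nj_from(msa)
  support <- NULL
  if (bootstrap_reps > 0) {
    L <- nchar(msa[[1]])
    mat <- do.call(rbind, lapply(msa, seq_to_chars))
    boots <- with_seed(seed, lapply(seq_len(bootstrap_reps), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      seqs <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      nj_from(setNames(seqs, names(msa)))
    }))
    support <- ape::prop.clades(tree, boots, rooted = FALSE)
    support <- support / bootstrap_reps * 100
  }
  structure(list(tree = tree, support = support, outgroup_id = outgroup_id,
                 node_ages_years = NULL, root_age_years = NULL),
            class = "calibrated_tree")
}

#' @export
print.calibrated_tree <- function(x, ...) {
  cat("<calibrated_tree> ", length(x$tree$tip.label), " tips, outgroup ",
      x$outgroup_id,
      if (!is.null(x$node_ages_years))
        paste0(", calibrated to root age ",
               format(x$root_age_years, big.mark = ","), " yr") else
        " (uncalibrated)",
      "\n", sep = "")
  invisible(x)
}

#' Calibrate node ages by strict-clock scaling
#'
#' Each internal node's height is the mean distance to its descendant tips
#' (midpoint-averaging of tip heights); ages scale linearly so the root sits
#' at `root_age_years`. Tips have age 0. The root height is the midpoint of
#' the two root-child subtrees' mean tip depths: outgroup rooting attaches
#' the root by a zero-length edge, so the plain mean over all tips would put
#' the root too low on the ingroup side and inflate ingroup node ages.
#'
#' @param ct A `calibrated_tree` from [build_tree()].
#' @param root_age_years Root calibration (default 6e6 years, the
#'   human-chimpanzee split).
#' @return The `calibrated_tree` with `node_ages_years` (named by node
#'   number) and `root_age_years` filled in.
#' @export
calibrate <- function(ct, root_age_years = 6e6) {
  stopifnot(inherits(ct, "calibrated_tree"))
  tree <- ct$tree
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)  # root-to-node path lengths
  ages <- numeric(ntip + nnode)
  root <- ntip + 1L
  # mean node-to-descendant-tip height per node
  desc_tips <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  root_height <- mean(vapply(kids, function(kid)
    mean(depth[desc_tips(kid)]), numeric(1)))
  if (root_height == 0) {
    ct$node_ages_years <- setNames(ages, seq_along(ages))
    ct$root_age_years <- root_age_years
    return(ct)
  }
  for (node in (ntip + 1L):(ntip + nnode)) {
    tips <- desc_tips(node)
    h <- mean(depth[tips] - depth[node])
    ages[node] <- min(root_age_years, root_age_years * h / root_height)
  }
  ages[root] <- root_age_years
  ct$node_ages_years <- setNames(ages, seq_along(ages))
  ct$root_age_years <- root_age_years
  ct
}

#' Test monophyly of a taxon set and date the containing clade
#'
#' @param ct A calibrated `calibrated_tree`.
#' @param taxon_set Character vector of tip labels.
#' @return List with `monophyletic`, `clade_tips` (leaf set of the smallest
#'   containing clade), `crown_age_years` (age of that clade's root; 0 for a
#'   singleton) and `stem_age_years` (age of its parent node, NA at the tree
#'   root).
#' @export
test_monophyly <- function(ct, taxon_set) {
  stopifnot(inherits(ct, "calibrated_tree"))
  tree <- ct$tree
  unknown <- setdiff(taxon_set, tree$tip.label)
  if (length(unknown) > 0)
    abort(paste0("unknown taxa: ", paste(unknown, collapse = ", ")))
  ntip <- length(tree$tip.label)
  ages <- ct$node_ages_years
  if (is.null(ages)) abort("tree is not calibrated; run calibrate() first")
  tip_idx <- match(taxon_set, tree$tip.label)
  if (length(tip_idx) == 1) {
    parent <- tree$edge[tree$edge[, 2] == tip_idx, 1]
    return(list(monophyletic = TRUE, clade_tips = taxon_set,
                crown_age_years = 0,
                stem_age_years = unname(ages[parent])))
  }
  mrca <- ape::getMRCA(tree, tip_idx)
  desc <- ape::extract.clade(tree, mrca)$tip.label
  mono <- setequal(desc, taxon_set)
  parent <- tree$edge[tree$edge[, 2] == mrca, 1]
  list(monophyletic = mono, clade_tips = desc,
       crown_age_years = unname(ages[mrca]),
       stem_age_years = if (length(parent)) unname(ages[parent]) else NA_real_)
}

#' Topology concordance between two trees (normalized Robinson-Foulds)
#'
#' @param ct_p,ct_q `calibrated_tree` objects (or `phylo`) on the same leaf
#'   set.
#' @return Normalized RF distance in \[0, 1\]; 0 = identical topologies.
#' @export
topology_concordance <- function(ct_p, ct_q) {
  tp <- if (inherits(ct_p, "calibrated_tree")) ct_p$tree else ct_p
  tq <- if (inherits(ct_q, "calibrated_tree")) ct_q$tree else ct_q
  dd <- c(setdiff(tp$tip.label, tq$tip.label),
          setdiff(tq$tip.label, tp$tip.label))
  if (length(dd) > 0)
    abort(paste0("leaf sets differ: ", paste(dd, collapse = ", ")))
  unname(phangorn::RF.dist(ape::unroot(tp), ape::unroot(tq),
                           normalize = TRUE))
}

#' Structural difference between two HOR composition strings
#'
#' Globally aligns the two ordered unit-label strings (match 0, mismatch 1,
#' indel 1) and counts base-pair, monomer, HOR-unit and distinct structural
#' changes. `distinct_changes` is the number of maximal contiguous indel
#' blocks plus mismatch runs (events, not bases).
#'
#' @param composition_a,composition_b Character vectors of ordered HOR-unit
#'   labels.
#' @param unit_lengths Named vector: bp length per unit label.
#' @param unit_periods Named vector: monomers per unit label (optional;
#'   derived as `round(unit_lengths / 171)` when missing).
#' @return A `hor_structural_diff` list: `bp_diff`, `monomer_diff`,
#'   `hor_unit_diff`, `distinct_changes`, `alignment_score`.
#' @export
hor_structural_diff <- function(composition_a, composition_b, unit_lengths,
                                unit_periods = NULL) {
  labs <- unique(c(composition_a, composition_b))
  missing <- setdiff(labs, names(unit_lengths))
  if (length(missing) > 0)
    abort(paste0("no unit length for label(s): ",
                 paste(missing, collapse = ", ")))
  if (is.null(unit_periods))
    unit_periods <- setNames(round(unit_lengths / 171), names(unit_lengths))
  al <- align_label_strings(composition_a, composition_b)
  ops <- al$ops
  indel <- ops$op %in% c("ins", "del")
  mism <- ops$op == "mismatch"
  bp_diff <- sum(unit_lengths[ops$a_label[ops$op == "del"]]) +
    sum(unit_lengths[ops$b_label[ops$op == "ins"]]) +
    sum(abs(unit_lengths[ops$a_label[mism]] -
              unit_lengths[ops$b_label[mism]]))
  monomer_diff <- sum(unit_periods[ops$a_label[ops$op == "del"]]) +
    sum(unit_periods[ops$b_label[ops$op == "ins"]]) +
    sum(abs(unit_periods[ops$a_label[mism]] -
              unit_periods[ops$b_label[mism]]))
  hor_unit_diff <- sum(indel)
  changed <- indel | mism
  distinct <- sum(rle(changed)$values)
  structure(list(bp_diff = unname(bp_diff),
                 monomer_diff = unname(monomer_diff),
                 hor_unit_diff = hor_unit_diff,
                 distinct_changes = distinct,
                 alignment_score = al$score),
            class = "hor_structural_diff")
}

#' @export
print.hor_structural_diff <- function(x, ...) {
  cat("<hor_structural_diff> ", x$bp_diff, " bp, ", x$monomer_diff,
      " monomers, ", x$hor_unit_diff, " HOR units, ", x$distinct_changes,
      " distinct change(s)\n", sep = "")
  invisible(x)
}

#' HOR emergence rate from a structural diff and a dated clade
#'
#' Converts the clade age into generations over the generation-time range
#' and reports nucleotide (and HOR-unit) differences per generation, and per
#' Mbp of array per generation, as ranges over the endpoint combinations.
#'
#' @param diff A [hor_structural_diff()] result.
#' @param clade_age_years_range Coalescent-time range in years (crown to
#'   stem age, or a single value twice).
#' @param gen_time_range Generation-time range (default c(20, 29)).
#' @param array_length_mbp Array length in Mbp (> 0).
#' @return An `emergence_rate` list: `generations_range`,
#'   `nt_per_generation_range`, `nt_per_mbp_per_generation_range`,
#'   `hor_units_per_generation_range`.
#' @export
emergence_rate <- function(diff, clade_age_years_range,
                           gen_time_range = c(20, 29), array_length_mbp) {
  if (any(clade_age_years_range <= 0)) abort("clade age must be positive")
  if (array_length_mbp <= 0) abort("array length must be positive")
  ages <- range(clade_age_years_range)
  gens <- range(outer(ages, range(gen_time_range), "/"))
  nt <- sort(diff$bp_diff / gens)
  structure(list(generations_range = gens,
                 nt_per_generation_range = nt,
                 nt_per_mbp_per_generation_range = nt / array_length_mbp,
                 hor_units_per_generation_range =
                   sort(diff$hor_unit_diff / gens)),
            class = "emergence_rate")
}

#' @export
print.emergence_rate <- function(x, ...) {
  cat("<emergence_rate> ",
      paste(format(round(x$nt_per_generation_range, 1)), collapse = "-"),
      " nt/generation; ",
      paste(format(round(x$nt_per_mbp_per_generation_range, 1)),
            collapse = "-"),
      " nt/Mbp/generation\n", sep = "")
  invisible(x)
}

#' Stratified monomer sample for phylogenetic analysis
#'
#' Randomly selects monomers from the HOR array and from the monomeric
#' regions (default 100 and 50) for downstream alignment and tree building;
#' when fewer are available, all are returned with a warning.
#'
#' @param monomer_annotations Tibble from [decompose_monomers()].
#' @param seq Source DNA string.
#' @param region_bed Tibble (`start`, `end`, `class`) with classes
#'   `hor_array` and `monomeric`.
#' @param n_hor,n_monomeric Sample sizes (defaults 100 and 50).
#' @param seed Integer seed.
#' @return Named character vector of monomer sequences
#'   (`hor_<i>` / `mono_<i>`), reproducible under the seed.
#' @export
sample_monomers_for_phylogeny <- function(monomer_annotations, seq,
                                          region_bed, n_hor = 100,
                                          n_monomeric = 50, seed = 1) {
  if (nrow(monomer_annotations) == 0) abort("no monomer annotations")
  mid <- (monomer_annotations$start + monomer_annotations$end) / 2
  cls <- rep(NA_character_, length(mid))
  for (i in seq_len(nrow(region_bed))) {
    inr <- mid >= region_bed$start[i] & mid < region_bed$end[i]
    cls[inr] <- region_bed$class[i]
  }
  with_seed(seed, {
    pick <- function(idx, nwant, prefix) {
      if (length(idx) < nwant) {
        warn(sprintf("only %d %s monomers available (wanted %d)",
                     length(idx), prefix, nwant))
        chosen <- idx
      } else chosen <- sort(sample(idx, nwant))
      if (length(chosen) == 0) return(character(0))
      out <- vapply(chosen, function(i)
        substr(seq, monomer_annotations$start[i] + 1L,
               monomer_annotations$end[i]), character(1))
      setNames(out, paste0(prefix, "_", seq_along(chosen)))
    }
    c(pick(which(cls == "hor_array"), n_hor, "hor"),
      pick(which(cls == "monomeric"), n_monomeric, "mono"))
  })
}

#' Simulate sequences down a genealogy
#'
#' Evolves a root sequence along a tree whose branch lengths are in years:
#' each branch receives a Poisson number of substitutions with mean
#' `L * mu_per_gen * branch_years / gen_time_years` under the Kimura
#' two-parameter scheme. Used as the known-genealogy harness for tree
#' reconstruction and dating.
#'
#' @param tree An `ape::phylo` with branch lengths in years.
#' @param root_seq Root DNA string.
#' @param mu_per_gen Mutation rate per bp per generation.
#' @param gen_time_years Generation time (default 25).
#' @param titv Transition/transversion ratio (default 2).
#' @param seed Integer seed.
#' @return Named character vector of tip sequences.
#' @export
simulate_tree_sequences <- function(tree, root_seq, mu_per_gen,
                                    gen_time_years = 25, titv = 2,
                                    seed = 1) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  L <- nchar(root_seq)
  with_seed(seed, {
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- root_seq
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      gens <- ord$edge.length[e] / gen_time_years
      nsub <- rpois(1, L * mu_per_gen * gens)
      seqs[[child]] <- mutate_sequence(seqs[[parent]], nsub, titv = titv)$seq
    }
    setNames(unlist(seqs[seq_len(ntip)]), tree$tip.label)
  })
}
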