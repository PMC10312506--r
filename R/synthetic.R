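# Synthetic centromere generator: layered alpha-satellite HOR arrays with
# full ground truth, haplotype pairs evolved under a neutral model, reads,
# methylation and enrichment tracks. Every generator is a pure function of
# (parameters, seed).

#' Generate a set of related alpha-satellite monomer templates
#'
#' Templates are independent mutants of one random ancestral monomer; the
#' per-copy substitution rate is chosen so that the expected pairwise Hamming
#' fraction between any two templates equals `pairwise_divergence`.
#'
#' @param n Number of templates (>= 1).
#' @param length Monomer length in bp (default 171, the canonical
#'   alpha-satellite monomer length).
#' @param pairwise_divergence Expected pairwise difference fraction, in
#'   \[0, 0.5).
#' @param seed Integer seed.
#' @param class_label Free-text class tag attached to every template.
#' @return Tibble with columns `id`, `sequence`, `class_label`.
#' @export
make_monomer_set <- function(n, length = 171, pairwise_divergence = 0.1,
                             seed = NULL, class_label = "alpha") {
  if (n < 1) abort("n must be >= 1")
  if (pairwise_divergence < 0 || pairwise_divergence >= 0.5)
    abort("pairwise_divergence must be in [0, 0.5)")
  with_seed(seed, {
    ancestor <- random_dna(length)
    # two copies mutated at per-site rate r differ with probability
    # 2r(1-r) + 0.5 r^2 (0.5 = P(different alt | both sites hit) under the
    # ti/tv = 2 scheme); invert 2r - 1.5 r^2 = d
    d <- pairwise_divergence
    r <- (2 - sqrt(4 - 6 * d)) / 3
    seqs <- vapply(seq_len(n), function(i) {
      k <- rbinom(1, length, r)
      mutate_sequence(ancestor, k)$seq
    }, character(1))
    tibble(id = sprintf("mon%02d", seq_len(n)), sequence = seqs,
           class_label = class_label)
  })
}

#' Define a higher-order repeat (HOR) unit
#'
#' @param id Short label for the HOR.
#' @param monomer_ids Ordered monomer template ids making up one unit; the
#'   length of this vector is the HOR period in monomers.
#' @return One-row tibble with `hor_id` and list-column `monomer_ids`; rows
#'   from several calls can be combined with [dplyr::bind_rows()].
#' @export
hor_definition <- function(id, monomer_ids) {
  stopifnot(length(monomer_ids) >= 1)
  tibble(hor_id = id, monomer_ids = list(as.character(monomer_ids)))
}

#' Plan a layered alpha-satellite array
#'
#' @param layers Tibble with columns `hor_id`, `copy_count`,
#'   `per_copy_substitution_rate` — one row per evolutionary layer, ordered
#'   from one array edge to the other.
#' @param flank_monomeric_bp Monomeric (diverged, non-HOR) alpha-satellite
#'   flank length on each side.
#' @param flank_unique_bp Unique (non-satellite) flank length on each side.
#' @param seed Integer seed (required: the plan pins its own randomness).
#' @return An `array_plan` object.
#' @export
array_plan <- function(layers, flank_monomeric_bp = 0, flank_unique_bp = 0,
                       seed = 1) {
  stopifnot(all(c("hor_id", "copy_count", "per_copy_substitution_rate") %in%
                  names(layers)))
  if (any(layers$copy_count < 0)) abort("copy_count must be >= 0")
  if (any(layers$per_copy_substitution_rate < 0 |
            layers$per_copy_substitution_rate >= 1))
    abort("per_copy_substitution_rate must be in [0, 1)")
  structure(list(layers = as_tibble(layers),
                 flank_monomeric_bp = as.integer(flank_monomeric_bp),
                 flank_unique_bp = as.integer(flank_unique_bp),
                 seed = as.integer(seed)),
            class = "array_plan")
}

hor_unit_sequence <- function(hor_id, hor_defs, monomers) {
  row <- hor_defs %>% filter(.data$hor_id == !!hor_id)
  if (nrow(row) == 0) abort(paste0("unknown hor_id: ", hor_id))
  ids <- row$monomer_ids[[1]]
  idx <- match(ids, monomers$id)
  if (anyNA(idx)) abort(paste0("unresolved monomer ids: ",
                               paste(ids[is.na(idx)], collapse = ", ")))
  list(seq = paste(monomers$sequence[idx], collapse = ""),
       monomer_ids = ids,
       monomer_lengths = nchar(monomers$sequence[idx]))
}

new_centromere_truth <- function(sequence, region_classes, hor_composition,
                                 monomer_truth, live_array, planted_cdrs,
                                 event_log, seed = NA_integer_) {
  structure(list(sequence = sequence,
                 region_classes = region_classes,
                 hor_composition = hor_composition,
                 monomer_truth = monomer_truth,
                 live_array = live_array,
                 planted_cdrs = planted_cdrs,
                 event_log = event_log,
                 seed = seed),
            class = "centromere_truth")
}

#' @export
print.centromere_truth <- function(x, ...) {
  cat("<centromere_truth> ", nchar(x$sequence), " bp; ",
      nrow(x$hor_composition), " HOR units; live array ",
      if (nrow(x$live_array)) paste0("[", x$live_array$start, ",",
                                     x$live_array$end, ")") else "(empty)",
      "; ", nrow(x$planted_cdrs), " planted CDR(s)\n", sep = "")
  invisible(x)
}

#' Realize a layered array plan as a synthetic centromere with ground truth
#'
#' Layout is symmetric: unique flank, monomeric flank, HOR array (layers in
#' plan order), monomeric flank, unique flank. Each HOR copy receives a
#' binomial number of substitutions at its layer's per-copy rate; every
#' substitution is logged.
#'
#' @param plan An [array_plan()].
#' @param hor_defs Tibble of [hor_definition()] rows.
#' @param monomers Monomer template tibble from [make_monomer_set()].
#' @return A `centromere_truth` object: `sequence`, tiling `region_classes`,
#'   `hor_composition`, per-monomer `monomer_truth`, `live_array`,
#'   `planted_cdrs` (empty), `event_log`, `seed`.
#' @export
build_array <- function(plan, hor_defs, monomers) {
  stopifnot(inherits(plan, "array_plan"))
  with_seed(plan$seed, {
    pieces <- character(0)
    hor_rows <- list()
    mon_rows <- list()
    events <- list()
    pos <- 0L

    u <- plan$flank_unique_bp
    m <- plan$flank_monomeric_bp
    mono_template <- monomers$sequence[[1]]

    monomeric_flank <- function(bp) {
      if (bp == 0) return("")
      ncopies <- ceiling(bp / nchar(mono_template))
      s <- paste(vapply(seq_len(ncopies), function(i) {
        k <- rbinom(1, nchar(mono_template), 0.2)
        mutate_sequence(mono_template, k)$seq
      }, character(1)), collapse = "")
      substr(s, 1, bp)
    }

    left_unique <- random_dna(u)
    left_mono <- monomeric_flank(m)
    pos <- u + m

    for (li in seq_len(nrow(plan$layers))) {
      layer <- plan$layers[li, ]
      if (layer$copy_count == 0) next
      unit <- hor_unit_sequence(layer$hor_id, hor_defs, monomers)
      unit_len <- nchar(unit$seq)
      for (ci in seq_len(layer$copy_count)) {
        k <- rbinom(1, unit_len, layer$per_copy_substitution_rate)
        mut <- mutate_sequence(unit$seq, k)
        pieces <- c(pieces, mut$seq)
        hor_rows[[length(hor_rows) + 1L]] <-
          tibble(start = pos, end = pos + unit_len,
                 hor_label = layer$hor_id, layer = li, copy = ci)
        mstart <- pos + c(0L, cumsum(head(unit$monomer_lengths, -1)))
        mon_rows[[length(mon_rows) + 1L]] <-
          tibble(start = mstart, end = mstart + unit$monomer_lengths,
                 template_id = unit$monomer_ids, strand = "+")
        if (nrow(mut$events) > 0) {
          events[[length(events) + 1L]] <-
            mut$events %>%
            mutate(pos = .data$pos + !!pos, type = "substitution",
                   stage = "build_array", layer = li, copy = ci)
        }
        pos <- pos + unit_len
      }
    }

    array_start <- u + m
    array_end <- pos
    right_mono <- monomeric_flank(m)
    right_unique <- random_dna(u)
    sequence <- paste0(left_unique, left_mono, paste(pieces, collapse = ""),
                       right_mono, right_unique)
    total <- nchar(sequence)

    rc <- tibble(start = integer(0), end = integer(0), class = character(0))
    add_rc <- function(rc, s, e, cl) {
      if (e > s) bind_rows(rc, tibble(start = s, end = e, class = cl)) else rc
    }
    rc <- add_rc(rc, 0L, u, "non_satellite")
    rc <- add_rc(rc, u, u + m, "monomeric")
    rc <- add_rc(rc, array_start, array_end, "hor_array")
    rc <- add_rc(rc, array_end, array_end + m, "monomeric")
    rc <- add_rc(rc, array_end + m, total, "non_satellite")

    hor_composition <- if (length(hor_rows)) bind_rows(hor_rows) else
      tibble(start = integer(0), end = integer(0), hor_label = character(0),
             layer = integer(0), copy = integer(0))
    monomer_truth <- if (length(mon_rows)) bind_rows(mon_rows) else
      tibble(start = integer(0), end = integer(0),
             template_id = character(0), strand = character(0))
    live_array <- if (array_end > array_start)
      interval_tbl(array_start, array_end) else interval_tbl()
    event_log <- if (length(events)) bind_rows(events) else
      tibble(pos = integer(0), ref = character(0), alt = character(0),
             type = character(0), stage = character(0),
             layer = integer(0), copy = integer(0))

    new_centromere_truth(sequence, rc, hor_composition, monomer_truth,
                         live_array, interval_tbl(), event_log,
                         seed = plan$seed)
  })
}

#' Parameters of the neutral divergence model for a haplotype pair
#'
#' Divergence between two sampled haplotypes is modelled as
#' D = 2 mu (t/g) + 4 Ne mu: between-lineage substitutions accumulated over
#' t/g generations on each lineage plus ancestral polymorphism from the
#' coalescent time (2 Ne generations) within the ancestral population.
#'
#' @param mu_per_gen Mutation rate per bp per generation.
#' @param t_years Divergence time in years.
#' @param gen_time_years Generation time g in years.
#' @param Ne Ancestral effective population size.
#' @param seed Integer seed.
#' @param titv Transition/transversion rate ratio (default 2).
#' @return A `pair_evolution_params` object.
#' @export
pair_evolution_params <- function(mu_per_gen, t_years, gen_time_years, Ne,
                                  seed = 1, titv = 2) {
  stopifnot(mu_per_gen >= 0, t_years > 0, gen_time_years > 0, Ne > 0)
  structure(list(mu_per_gen = mu_per_gen, t_years = t_years,
                 gen_time_years = gen_time_years, Ne = Ne,
                 seed = as.integer(seed), titv = titv),
            class = "pair_evolution_params")
}

#' Expected divergence under the neutral model
#' @param params A [pair_evolution_params()] object.
#' @return Expected substitutions per site, 2 mu (t/g) + 4 Ne mu.
#' @export
expected_divergence <- function(params) {
  with(params, mu_per_gen * (2 * t_years / gen_time_years + 4 * Ne))
}

#' Evolve an ancestral sequence into a diverged haplotype pair
#'
#' Substitution counts are Poisson with per-bp mean `expected_D` split into a
#' between-lineage component 2 mu t/g (each event assigned to one lineage
#' uniformly) and an ancestral-polymorphism component 4 Ne mu (each derived
#' allele carried by one sampled lineage). Substitution types follow the
#' Kimura two-parameter scheme at the configured ti/tv ratio.
#'
#' @param ancestor A `centromere_truth` object or a DNA string.
#' @param params A [pair_evolution_params()] object.
#' @return List with `hap_a`, `hap_b` (DNA strings), `expected_D`, and
#'   `events` (tibble with `pos`, `ref`, `alt`, `lineage`, `origin`).
#' @export
evolve_pair <- function(ancestor, params) {
  stopifnot(inherits(params, "pair_evolution_params"))
  seq <- if (inherits(ancestor, "centromere_truth")) ancestor$sequence
         else ancestor
  n <- nchar(seq)
  D <- expected_divergence(params)
  if (D >= 0.75) warn("expected divergence >= 0.75: distances are saturated")
  with_seed(params$seed, {
    d_lineage <- params$mu_per_gen * 2 * params$t_years / params$gen_time_years
    d_anc <- params$mu_per_gen * 4 * params$Ne
    n_lin <- rpois(1, n * d_lineage)
    n_anc <- rpois(1, n * d_anc)
    total <- n_lin + n_anc
    if (total == 0) {
      return(list(hap_a = seq, hap_b = seq, expected_D = D,
                  events = tibble(pos = integer(0), ref = character(0),
                                  alt = character(0), lineage = character(0),
                                  origin = character(0))))
    }
    pos <- sample.int(n, min(total, n)) - 1L
    origin <- rep(c("lineage", "ancestral"),
                  times = c(min(n_lin, length(pos)),
                            max(0L, length(pos) - n_lin)))
    lineage <- sample(c("A", "B"), length(pos), replace = TRUE)
    pa <- pos[lineage == "A"]
    pb <- pos[lineage == "B"]
    ma <- mutate_sequence(seq, length(pa), titv = params$titv, positions = pa)
    mb <- mutate_sequence(seq, length(pb), titv = params$titv, positions = pb)
    events <- bind_rows(
      ma$events %>% mutate(lineage = "A"),
      mb$events %>% mutate(lineage = "B")) %>%
      left_join(tibble(pos = pos, origin = origin), by = "pos") %>%
      arrange(.data$pos)
    list(hap_a = ma$seq, hap_b = mb$seq, expected_D = D, events = events)
  })
}

#' Simulate saltatory amplification of a new HOR variant
#'
#' Inserts runs of a new HOR variant at several HOR-unit boundaries inside
#' the live array, interdigitating new copies with ancestral units. All truth
#' coordinates (composition, regions, live array, planted CDRs) are shifted
#' accordingly and every insertion is logged.
#'
#' @param truth A `centromere_truth` from [build_array()].
#' @param new_variant One-row [hor_definition()] tibble for the new HOR.
#' @param n_insertion_sites Number of distinct insertion sites (>= 1).
#' @param n_new_copies Total copies of the new variant to insert.
#' @param monomers Monomer template tibble (resolves the variant's monomers;
#'   may include new monomer templates).
#' @param seed Integer seed.
#' @return A derived `centromere_truth` with appended `event_log` rows of
#'   type "hor_insertion".
#' @export
simulate_saltatory_amplification <- function(truth, new_variant,
                                             n_insertion_sites, n_new_copies,
                                             monomers, seed = 1) {
  stopifnot(inherits(truth, "centromere_truth"), n_insertion_sites >= 1)
  if (n_new_copies == 0) return(truth)
  if (nrow(truth$live_array) == 0) abort("truth has no live array")
  unit <- hor_unit_sequence(new_variant$hor_id[[1]], new_variant, monomers)
  unit_len <- nchar(unit$seq)
  with_seed(seed, {
    # candidate sites: boundaries between consecutive HOR units (unit starts
    # after the first), all inside the live array
    comp <- truth$hor_composition %>% arrange(.data$start)
    boundaries <- comp$start[-1]
    boundaries <- boundaries[boundaries > truth$live_array$start &
                               boundaries < truth$live_array$end]
    if (length(boundaries) < n_insertion_sites)
      abort("not enough HOR-unit boundaries inside the live array")
    sites <- sort(sample(boundaries, n_insertion_sites))
    # each site gets >= 1 copy; remaining copies multinomial
    if (n_new_copies < n_insertion_sites)
      abort("n_new_copies must be >= n_insertion_sites")
    extra <- stats::rmultinom(1, n_new_copies - n_insertion_sites,
                              rep(1, n_insertion_sites))[, 1]
    copies_per_site <- 1L + extra

    seq <- truth$sequence
    shift_tbl <- function(x, at, by) {
      if (nrow(x) == 0) return(x)
      x %>% mutate(start = .data$start + by * (.data$start >= at),
                   end = .data$end + by * (.data$end > at))
    }
    new_truth <- truth
    events <- list()
    # insert from rightmost site so earlier coordinates stay valid
    for (i in rev(seq_along(sites))) {
      at <- sites[i]
      ncp <- copies_per_site[i]
      ins <- strrep(unit$seq, ncp)
      seq <- paste0(substr(seq, 1, at), ins,
                    substr(seq, at + 1, nchar(seq)))
      by <- ncp * unit_len
      new_truth$hor_composition <- shift_tbl(new_truth$hor_composition, at, by)
      new_truth$monomer_truth <- shift_tbl(new_truth$monomer_truth, at, by)
      new_truth$region_classes <- shift_tbl(new_truth$region_classes, at, by)
      new_truth$live_array <- shift_tbl(new_truth$live_array, at, by)
      new_truth$planted_cdrs <- shift_tbl(new_truth$planted_cdrs, at, by)
      starts <- at + (seq_len(ncp) - 1L) * unit_len
      new_truth$hor_composition <- bind_rows(
        new_truth$hor_composition,
        tibble(start = starts, end = starts + unit_len,
               hor_label = new_variant$hor_id[[1]],
               layer = NA_integer_, copy = seq_len(ncp)))
      mstart_off <- c(0L, cumsum(head(unit$monomer_lengths, -1)))
      new_truth$monomer_truth <- bind_rows(
        new_truth$monomer_truth,
        purrr::map_dfr(starts, function(s)
          tibble(start = s + mstart_off,
                 end = s + mstart_off + unit$monomer_lengths,
                 template_id = unit$monomer_ids, strand = "+")))
      events[[length(events) + 1L]] <-
        tibble(pos = at, ref = NA_character_, alt = NA_character_,
               type = "hor_insertion", stage = "saltatory_amplification",
               layer = NA_integer_, copy = ncp)
    }
    new_truth$sequence <- seq
    new_truth$hor_composition <- new_truth$hor_composition %>%
      arrange(.data$start)
    new_truth$monomer_truth <- new_truth$monomer_truth %>%
      arrange(.data$start)
    new_truth$event_log <- bind_rows(new_truth$event_log, bind_rows(events))
    new_truth
  })
}

#' Simulate long reads from a sequence
#'
#' Read lengths are drawn from `read_lengths` (a numeric vector sampled with
#' replacement, or a single fixed length), truncated below `min_length`;
#' start positions are uniform; errors are i.i.d. substitutions at
#' `per_base_error` (indels optional).
#'
#' @param seq DNA string to sample from.
#' @param coverage Target mean coverage (total read bp / sequence bp).
#' @param read_lengths Numeric vector of candidate lengths (resampled) or a
#'   single length.
#' @param per_base_error Substitution error rate in \[0, 0.3\].
#' @param min_length Minimum read length; candidates below it are redrawn.
#' @param indel_rate Optional per-base indel rate (default 0).
#' @param random_strand Sample reads from either strand (default TRUE).
#' @param seed Integer seed.
#' @return Tibble with `read_id`, `start`, `end` (0-based half-open origin on
#'   the forward strand), `strand`, `length`, `n_errors`, `sequence`.
#' @export
simulate_reads <- function(seq, coverage = 10, read_lengths = 20000,
                           per_base_error = 0, min_length = 1000,
                           indel_rate = 0, random_strand = TRUE, seed = 1) {
  n <- nchar(seq)
  if (per_base_error < 0 || per_base_error > 0.3)
    abort("per_base_error must be in [0, 0.3]")
  if (min_length > n) abort("min_length exceeds sequence length")
  with_seed(seed, {
    target_bp <- coverage * n
    reads <- list()
    total_bp <- 0
    i <- 0L
    while (total_bp < target_bp) {
      len <- NA
      for (try in 1:100) {
        len <- round(sample(read_lengths, 1))
        if (len >= min_length) break
        len <- NA
      }
      if (is.na(len)) abort("could not draw a read length >= min_length")
      len <- min(len, n)
      start <- sample.int(n - len + 1L, 1) - 1L
      raw <- substr(seq, start + 1L, start + len)
      strand <- if (random_strand && runif(1) < 0.5) "-" else "+"
      if (strand == "-") raw <- revcomp(raw)
      n_err <- rbinom(1, len, per_base_error)
      mut <- mutate_sequence(raw, n_err)
      out_seq <- mut$seq
      if (indel_rate > 0) {
        n_ind <- rbinom(1, len, indel_rate)
        if (n_ind > 0) {
          ch <- seq_to_chars(out_seq)
          for (j in seq_len(n_ind)) {
            p <- sample.int(length(ch), 1)
            if (runif(1) < 0.5) ch <- ch[-p]
            else ch <- append(ch, sample(DNA_BASES, 1), after = p)
          }
          out_seq <- chars_to_seq(ch)
        }
      }
      i <- i + 1L
      reads[[i]] <- tibble(read_id = sprintf("read%05d", i),
                           start = start, end = start + len,
                           strand = strand, length = len,
                           n_errors = n_err, sequence = out_seq)
      total_bp <- total_bp + len
    }
    bind_rows(reads)
  })
}

#' Simulate a per-CpG methylation-frequency track with planted dips
#'
#' Frequency is `baseline_freq` at every CpG outside the dip intervals and
#' `dip_freq` inside; optional beta noise jitters each site around its mean.
#' Planted dips are copied into the returned truth's `planted_cdrs`.
#'
#' @param truth A `centromere_truth` (its sequence provides CpG positions).
#' @param baseline_freq Methylation frequency outside dips.
#' @param dip_freq Frequency inside dips; must satisfy
#'   `0 <= dip_freq <= baseline_freq <= 1`.
#' @param dip_intervals Tibble with `start`, `end` (0-based half-open).
#' @param beta_conc Optional beta concentration; `NULL` (default) = no noise.
#' @param seed Integer seed (used only when `beta_conc` is set).
#' @return List with `track` (tibble `pos`, `freq` per CpG) and `truth` (the
#'   input with `planted_cdrs` set).
#' @export
simulate_methylation <- function(truth, baseline_freq = 0.85,
                                 dip_freq = 0.15, dip_intervals = NULL,
                                 beta_conc = NULL, seed = 1) {
  stopifnot(inherits(truth, "centromere_truth"))
  if (is.null(dip_intervals)) dip_intervals <- interval_tbl()
  if (dip_freq < 0 || dip_freq > baseline_freq || baseline_freq > 1)
    abort("need 0 <= dip_freq <= baseline_freq <= 1")
  n <- nchar(truth$sequence)
  if (nrow(dip_intervals) > 0 &&
        any(dip_intervals$start < 0 | dip_intervals$end > n))
    abort("dip interval outside sequence")
  hits <- gregexpr("CG", truth$sequence, fixed = TRUE)[[1]]
  pos <- if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
  freq <- rep(baseline_freq, length(pos))
  freq[point_in_intervals(pos, dip_intervals)] <- dip_freq
  if (!is.null(beta_conc)) {
    freq <- with_seed(seed, {
      a <- pmax(freq * beta_conc, 1e-6)
      b <- pmax((1 - freq) * beta_conc, 1e-6)
      stats::rbeta(length(freq), a, b)
    })
  }
  truth$planted_cdrs <- dip_intervals %>% select("start", "end")
  list(track = tibble(pos = pos, freq = freq), truth = truth)
}

#' Simulate target and control coverage tracks with planted enrichment
#'
#' Control depth is Poisson(`mean_depth`) per bin; target depth is
#' Poisson(`mean_depth * fold`) inside the enrichment intervals and
#' Poisson(`mean_depth`) outside — a CENP-A-like ChIP/input pair.
#'
#' @param truth A `centromere_truth` or an integer sequence length.
#' @param mean_depth Mean per-bin depth (>= 0).
#' @param enrichment_intervals Tibble with `start`, `end`.
#' @param fold Enrichment fold inside intervals (>= 1).
#' @param bin_bp Bin width (default 1000).
#' @param seed Integer seed.
#' @return List with `target` and `control`, each a tibble
#'   (`start`, `end`, `depth`).
#' @export
simulate_coverage <- function(truth, mean_depth = 30,
                              enrichment_intervals = NULL, fold = 1,
                              bin_bp = 1000, seed = 1) {
  if (fold < 1) abort("fold must be >= 1")
  n <- if (inherits(truth, "centromere_truth")) nchar(truth$sequence)
       else as.integer(truth)
  if (is.null(enrichment_intervals)) enrichment_intervals <- interval_tbl()
  with_seed(seed, {
    starts <- seq(0L, n - 1L, by = bin_bp)
    ends <- pmin(starts + bin_bp, n)
    mid <- (starts + ends) / 2
    enriched <- point_in_intervals(mid, enrichment_intervals)
    control <- rpois(length(starts), mean_depth)
    target <- rpois(length(starts), mean_depth * ifelse(enriched, fold, 1))
    list(target = tibble(start = starts, end = ends, depth = target),
         control = tibble(start = starts, end = ends, depth = control))
  })
}
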