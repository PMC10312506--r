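---
title: "Methods: models, estimators and numerical choices in alphasat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and numerical choices in alphasat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r load}
library(alphasat)
library(tibble)
```

`alphasat` is a desk-scale reconstruction of the computational stages of a
telomere-to-telomere centromere study: it *generates* synthetic centromeres
whose internal structure is fully known, and *analyses* them with the same
algorithm families used on real assemblies — SUNK scaffolding, k-mer QV,
monomer/HOR annotation, windowed identity, methylation dip calling,
divergence/mutation-rate estimation and flank phylogenetics. Because every
generator returns its ground truth, every analysis stage can be validated
against exact expectations. This vignette documents the underlying models,
the estimators, and the numerical decisions that are not obvious from the
function reference.

## 1. The synthetic centromere generator

### Monomers, HOR units and layered arrays

Alpha-satellite DNA is organised as ~171-bp **monomers**; a fixed ordering of
$k$ distinct monomers forms a **higher-order repeat (HOR) unit**, and
near-identical copies of one unit tile megabase-scale arrays.
`make_monomer_set()` derives $n$ monomer sequences from one random ancestor
by placing substitutions until all pairwise divergences reach a target
(default 10%, mimicking the ~80–90% inter-monomer identity of real
alpha satellite). `hor_definition()` fixes a monomer ordering, and
`build_array()` tiles **layers** of HOR copies, giving each copy independent
per-copy substitutions:

```{r build}
mons <- make_monomer_set(6, pairwise_divergence = 0.10, seed = 101)
defs <- dplyr::bind_rows(
  hor_definition("horA", mons$id[1:4]),
  hor_definition("horB", mons$id[c(1, 2, 5, 6)]))
plan <- array_plan(
  layers = tibble(hor_id = c("horA", "horB", "horA"),
                  copy_count = c(40L, 30L, 40L),
                  per_copy_substitution_rate = 0.01),
  flank_monomeric_bp = 5000, flank_unique_bp = 10000, seed = 7)
truth <- build_array(plan, defs, mons)
truth
```

The layered design (a younger variant expanding *inside* an older layer)
reproduces the layered-expansion structure inferred for real centromeres.
The returned `centromere_truth` carries the exact coordinates of every
monomer and HOR copy, the region classes (unique flank, monomeric satellite,
HOR array), the live-array span, and an event log of every mutation placed —
this is what the annotation and identity stages are tested against.

**Realism and limits.** The generator captures the *hierarchical identity
structure* (unit-vs-unit ≈ 99%, monomer-vs-monomer ≈ 90%) and layered
expansions, which is what the analysis algorithms key on. It deliberately
omits indel mutation within monomers (substitution-only copies keep
ground-truth coordinates exact), transposon insertions, and chromosome-scale
context. Saltatory expansion is available separately
(`amplify_saltatory()`), which inserts a tandem run of new copies of one
ancestral unit and logs the insertion events.

### Haplotype pairs and the neutral divergence model

`evolve_pair()` evolves two haplotypes from a common ancestor under the
neutral expectation used for sequence pairs from two species (or two alleles):

$$ D = 2\mu \frac{t}{g} + 4 N_e \mu $$

i.e. substitutions accumulate on both lineages for $t/g$ generations at rate
$\mu$ per generation, plus ancestral polymorphism worth $2 N_e$ generations
on *each* lineage in expectation. Numerically, each lineage draws its
substitution count from a Poisson with mean
$\mu\,L\,(t/g + 2N_e)$ — the ancestral-polymorphism term is *realised as
extra branch length* rather than by simulating a coalescent, which keeps the
generator $O(L)$ while matching the expectation exactly. Transitions are
favoured 2:1 over transversions (`titv = 2`).

```{r evolve}
p <- pair_evolution_params(mu_per_gen = 1e-8, t_years = 6e6,
                           gen_time_years = 25, Ne = 1e4, seed = 1)
expected_divergence(p)   # 2*mu*(t/g) + 4*Ne*mu
```

With the worked parameters ($\mu = 10^{-8}$, $t = 6$ Myr, $g = 25$ yr,
$N_e = 10^4$) the expectation is $5.2 \times 10^{-3}$ — the classic
human–chimpanzee scale. On a 1-Mbp ancestor the binomial standard error of a
single estimate is $\sqrt{D/L} \approx 7 \times 10^{-5}$, which sets the
tolerance used in the test suite.

### Reads, methylation and enrichment tracks

`simulate_reads()` draws ultra-long reads as faithful substrings with
optional per-base substitution error and random strand.
`simulate_methylation()` emits a per-CpG methylation-frequency track at a
baseline (default 0.85) with planted dips (default 0.15) — the CDR model.
`simulate_coverage()` adds a CENP-A-like enrichment track with a fold
increase over a chosen interval.

## 2. Analysis stages and their estimators

### SUNK scaffolding

Singly-unique k-mers (SUNKs, $k = 20$) are k-mers occurring exactly once in
the whole contig set. Reads and contigs are reduced to ordered SUNK
**barcodes**; read-to-contig matches are chained, requiring consistent
coordinate offsets (5% tolerance), a minimum chain span and a minimum shared
SUNK count. Reads whose chains end near the ends of two different contigs
join them; the inter-contig gap length is estimated from the offset
difference and filled with read sequence, with each filled interval recorded
as a **patch**. `patch_with_local_contigs()` later swaps each patch for
sequence from a local high-accuracy contig whose 500-bp flanking anchors
align around the patch at ≥ 98% identity — the HiFi-patching step. On
synthetic 2-Mbp centromeres cut into 3–5 contigs with spanning 150-kb reads,
reconstruction is exact (string-equal to truth); with 5% read error the
patched scaffold returns to 100% identity.

### k-mer QV

`estimate_qv()` counts assembly k-mers ($k = 21$, canonical) absent from the
truth/read set ($E$ of $T$) and converts to a per-base error rate by the
Merqury formula

$$ p = 1 - \left(1 - E/T\right)^{1/k}, \qquad QV = -10\log_{10} p . $$

Planted error rates of $10^{-3}$, $10^{-4}$, $10^{-5}$ are recovered within
1 QV point (QV 30/40/50).

### Monomer decomposition and HOR annotation

`decompose_monomers()` tiles a sequence into monomer hits by dynamic
programming over template edit distance (C++ via Rcpp; both strands). Its
internal DP is validated against an exhaustive oracle: the minimum edit
distance over *all* template concatenations. `call_hors()` groups hits into
canonical units and named variants (e.g. deletion variants), and
`measure_live_array()` applies the min/max coordinate rule — the live-array
span runs from the minimum start to the maximum end of live HOR units, so
interior non-HOR gaps are included. `self_identity_heatmap()` and
`segment_layers()` recover evolutionary layers from windowed self-identity.

### Windowed sequence identity

Two strategies are implemented and must agree: (i) window the CIGAR strings
of whole-sequence alignments (`window_identity_from_alignments()`), and
(ii) fragment the query into 10-kb pieces, place each independently
(tolerating inversions via reverse-complement placement), and window the
fragment alignments (`window_identity_fragmented()`). The windowing
arithmetic is conservative by construction: the base-pair-weighted mean of
window identities equals whole-alignment identity exactly, which the tests
assert to $10^{-12}$.

### CDR detection

`find_cdrs()` bins the CpG methylation track (5-kb bins restricted to the
satellite annotation), computes the satellite-wide median bin statistic, and
calls a CDR wherever a run of bins sits more than 10 percentage points below
that median **and** spans strictly more than 50 kb. The strict inequality is
what excludes 30-kb dips by design. An independent plain-loop oracle
(`oracle_cdrs` in the test helpers) reproduces the calls bin-for-bin.

### Divergence and mutation rate

`tn93_distance()` implements the closed-form Tamura–Nei (TN93) estimator and
matches `ape::dist.dna(model = "TN93")` to $10^{-12}$. When the substitution
classes are balanced ($P_1 = P_2 = p/6$, $Q = 4p/6$, equal base
frequencies), TN93 reduces analytically to Jukes–Cantor,
$D = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; the tests verify this to
$10^{-9}$. `mutation_rate()` inverts the neutral model by Monte Carlo: it
draws $(g, t)$ from stated ranges and reports the median and 2.5/97.5
percentiles of $\mu = D / (2 t/g + 4 N_e)$. With fixed draws
($g = 25$, $t = 6$ Myr, $N_e = 10^4$) this is the exact inversion
$\mu = D / 520{,}000$.

### Flank phylogeny and HOR emergence dating

`extract_flanks()` takes the single-copy windows adjacent to the live array
(p- and q-arm), which act as phylogenetic proxies for the unalignable array.
`build_tree()` computes TN93 distances and a neighbour-joining tree with
optional bootstrap; `calibrate()` converts node depths to ages by anchoring
the root at a known age and scaling linearly.

One numerical choice deserves note. After outgroup rooting with
`ape::root(..., resolve.root = TRUE)` the root is attached by a zero-length
edge, so estimating root height as the mean root-to-tip depth over *all*
tips mixes the long outgroup branch into the ingroup scale and inflates
ingroup crown ages by ~30%. `calibrate()` therefore estimates root height as
the midpoint of the two root-child subtree mean depths — the average over
the two root children of the mean tip depth within that child — which is
unbiased under a clock regardless of how the branch below the root was
resolved. Ages are clamped at the root age and the root is pinned exactly.

`test_monophyly()` reports monophyly plus crown and stem ages of a taxon
set; `topology_concordance()` is the Robinson–Foulds distance (p-arm vs
q-arm trees from the same genealogy should be identical, RF = 0).
`hor_structural_diff()` aligns two HOR-unit label strings (unit-level edit
distance, validated against exhaustive oracles) and summarises the
difference in bp, monomers, units and distinct contiguous changes;
`emergence_rate()` converts a bp difference plus a clade-age and
generation-time range into nucleotides per generation:

```{r emergence}
a <- rep("horA", 10)
b <- c(rep("horA", 4), rep("horB", 5), rep("horA", 6))
d <- hor_structural_diff(a, b, c(horA = 1026, horB = 1026),
                         c(horA = 6, horB = 6))
d
```

## 3. Problem sizes and performance envelope

Sizes were chosen so the full test suite runs in minutes on one core while
still exercising the algorithms at meaningful scale: 100-kb to 2-Mbp
synthetic centromeres (hundreds to thousands of HOR copies), 150-kb
ultra-long reads, 1-Mbp divergence pairs, 50–100-kb flank alignments for
9-taxon trees. The two C++ kernels (monomer decomposition DP, k-mer
counting) keep those sizes interactive; everything else is vectorised R on
tibbles.

## 4. Reproducibility

Every stochastic function takes an explicit `seed` (or a params object
carrying one) and restores the caller's RNG state, so pipelines are
reproducible end to end. `scripts/acceptance.R` runs all stages from a
single `--seed` and writes the main computed quantities as JSON.
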