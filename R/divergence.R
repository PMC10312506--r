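# Tamura-Nei divergence estimation and conversion to per-generation
# mutation rates under the neutral model D = 2 mu (t/g) + 4 Ne mu.

#' Tamura-Nei (TN93) distance from substitution counts
#'
#' @param P1 Proportion of sites with an A<->G (purine) transition.
#' @param P2 Proportion of sites with a C<->T (pyrimidine) transition.
#' @param Q Proportion of sites with a transversion.
#' @param freqs Base frequencies, named vector over A, C, G, T.
#' @return Distance in substitutions per site; `NA` (with a warning) when
#'   the counts are saturated (a log argument is non-positive).
#' @export
tn93_from_counts <- function(P1, P2, Q, freqs) {
  freqs <- freqs[c("A", "C", "G", "T")] / sum(freqs)
  gA <- freqs[["A"]]; gC <- freqs[["C"]]
  gG <- freqs[["G"]]; gT <- freqs[["T"]]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    warn("TN93 distance undefined (saturation)")
    return(NA_real_)
  }
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Maximum-likelihood distance from empirical base frequencies (pooled over
#' both sequences) and the two transition classes plus transversions; gap
#' or ambiguous columns are excluded.
#'
#' @param a,b Aligned DNA strings of equal length (gaps as `-`).
#' @return Distance in substitutions per site (`NA` on saturation, with a
#'   warning). The attribute `"n_sites"` carries the number of compared
#'   columns.
#' @export
tn93_distance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  ca <- seq_to_chars(toupper(a))
  cb <- seq_to_chars(toupper(b))
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  if (!any(ok)) abort("no comparable (non-gap) columns")
  ca <- ca[ok]; cb <- cb[ok]
  n <- length(ca)
  freqs <- table(factor(c(ca, cb), levels = DNA_BASES))
  pair <- paste0(pmin(ca, cb), pmax(ca, cb))
  P1 <- sum(pair == "AG") / n
  P2 <- sum(pair == "CT") / n
  Q <- sum(ca != cb & pair != "AG" & pair != "CT") / n
  d <- tn93_from_counts(P1, P2, Q, as.numeric(freqs) %>%
                          setNames(DNA_BASES))
  attr(d, "n_sites") <- n
  d
}

#' Per-window divergence over orthologous alignments
#'
#' One TN93 distance per reference window, computed from the window's
#' aligned pair; windows with fewer than `min_ortholog_bp` orthologous
#' (mutually non-gap) bases are dropped and counted.
#'
#' @param window_alignments Tibble with `start`, `end`, `seq_a`, `seq_b`
#'   (aligned pair per window).
#' @param min_ortholog_bp Minimum orthologous bases per window (default
#'   5000).
#' @return List with `windows` (tibble `start`, `end`, `aligned_bp`, `D`)
#'   and `n_dropped`.
#' @export
window_divergence <- function(window_alignments, min_ortholog_bp = 5000) {
  out <- list()
  dropped <- 0L
  for (i in seq_len(nrow(window_alignments))) {
    wa <- window_alignments[i, ]
    ca <- seq_to_chars(toupper(wa$seq_a))
    cb <- seq_to_chars(toupper(wa$seq_b))
    aligned <- sum(ca %in% DNA_BASES & cb %in% DNA_BASES)
    if (aligned < min_ortholog_bp) { dropped <- dropped + 1L; next }
    D <- suppressWarnings(tn93_distance(wa$seq_a, wa$seq_b))
    out[[length(out) + 1L]] <- tibble(start = wa$start, end = wa$end,
                                      aligned_bp = aligned, D = as.numeric(D))
  }
  if (length(out) == 0) {
    warn("no window met the orthologous-sequence threshold")
    return(list(windows = tibble(start = integer(0), end = integer(0),
                                 aligned_bp = integer(0), D = numeric(0)),
                n_dropped = dropped))
  }
  list(windows = bind_rows(out), n_dropped = dropped)
}

#' Parameters of the neutral rate model
#'
#' @param Ne Ancestral effective population size (default 10,000; fixed, not
#'   drawn).
#' @param gen_time_years_range Generation-time range in years (default
#'   c(20, 29), drawn uniformly).
#' @param divergence_time_years_range Named list of divergence-time ranges
#'   per species pair (defaults: human-macaque 23-25 Myr, human-orangutan
#'   12-14 Myr, human-chimpanzee 4-6 Myr).
#' @param n_draws Monte-Carlo draws (default 1000).
#' @param seed Integer seed.
#' @return A `rate_model_params` object.
#' @export
rate_model_params <- function(Ne = 10000,
                              gen_time_years_range = c(20, 29),
                              divergence_time_years_range = list(
                                human_macaque = c(23e6, 25e6),
                                human_orangutan = c(12e6, 14e6),
                                human_chimpanzee = c(4e6, 6e6)),
                              n_draws = 1000, seed = 1) {
  stopifnot(Ne > 0, diff(gen_time_years_range) >= 0,
            all(vapply(divergence_time_years_range,
                       function(r) diff(r) >= 0, logical(1))))
  structure(list(Ne = Ne, gen_time_years_range = gen_time_years_range,
                 divergence_time_years_range = divergence_time_years_range,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "rate_model_params")
}

#' Convert divergence into a per-generation mutation rate
#'
#' Inverts D = 2 mu (t/g) + 4 Ne mu: for each draw, g and t are sampled
#' uniformly from their ranges and mu = D / (2 (t/g) + 4 Ne). The 2 mu t
#' term is converted to generations with the drawn generation time; Ne is
#' fixed.
#'
#' @param D Divergence in substitutions per site (a single value, e.g. the
#'   median across windows).
#' @param species_pair One of the names in the params' divergence-time list.
#' @param params A [rate_model_params()] object.
#' @return A `mutation_rate_estimate`: list with `draws` (tibble `g`, `t`,
#'   `mu`), `median`, `ci95`, `species_pair`, `D`.
#' @export
mutation_rate <- function(D, species_pair = "human_chimpanzee",
                          params = rate_model_params()) {
  if (is.na(D)) abort("D is undefined (saturated window?)")
  if (D < 0) abort("D must be >= 0")
  tr <- params$divergence_time_years_range[[species_pair]]
  if (is.null(tr)) abort(paste0("unknown species pair: ", species_pair))
  gr <- params$gen_time_years_range
  draws <- with_seed(params$seed, {
    g <- runif(params$n_draws, gr[1], gr[2])
    t <- runif(params$n_draws, tr[1], tr[2])
    tibble(g = g, t = t, mu = D / (2 * (t / g) + 4 * params$Ne))
  })
  structure(list(draws = draws,
                 median = median(draws$mu),
                 ci95 = unname(quantile(draws$mu, c(0.025, 0.975))),
                 species_pair = species_pair, D = D),
            class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat("<mutation_rate_estimate> ", x$species_pair, ": mu = ",
      format(x$median, digits = 3), " /bp/generation (95% CI ",
      format(x$ci95[1], digits = 3), "-", format(x$ci95[2], digits = 3),
      ") from D = ", format(x$D, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Fold increase of mutation rate between two window sets
#'
#' Ratio of medians (e.g. centromere-flank windows over unique windows) with
#' a bootstrap percentile interval over windows.
#'
#' @param mu_flank,mu_unique Numeric vectors of per-window rate estimates.
#' @param n_boot Bootstrap replicates (default 1000; skipped when either set
#'   has a single window).
#' @param seed Integer seed.
#' @return List with `fold`, `ci95` (NA when not bootstrapped).
#' @export
fold_increase <- function(mu_flank, mu_unique, n_boot = 1000, seed = 1) {
  if (length(mu_flank) == 0 || length(mu_unique) == 0)
    abort("both window sets must be non-empty")
  if (median(mu_unique) == 0) abort("unique-region rate is zero")
  fold <- median(mu_flank) / median(mu_unique)
  ci <- c(NA_real_, NA_real_)
  if (length(mu_flank) > 1 && length(mu_unique) > 1) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      median(sample(mu_flank, replace = TRUE)) /
        median(sample(mu_unique, replace = TRUE))
    }, numeric(1)))
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  list(fold = fold, ci95 = ci)
}
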