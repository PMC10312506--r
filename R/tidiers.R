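# broom-style tidiers for the package's result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a QV result
#' @param x A `qv_result`.
#' @param ... Unused.
#' @return One-row tibble: `erroneous_kmers`, `total_kmers`, `error_rate`,
#'   `qv`.
#' @export
tidy.qv_result <- function(x, ...) {
  tibble(erroneous_kmers = x$E, total_kmers = x$T,
         error_rate = x$error_rate, qv = x$qv)
}

#' Tidy a mutation-rate estimate
#' @param x A `mutation_rate_estimate`.
#' @param ... Unused.
#' @return One-row tibble: `species_pair`, `D`, `estimate` (median mu),
#'   `conf.low`, `conf.high`.
#' @export
tidy.mutation_rate_estimate <- function(x, ...) {
  tibble(species_pair = x$species_pair, D = x$D, estimate = x$median,
         conf.low = x$ci95[1], conf.high = x$ci95[2])
}

#' Glance at a mutation-rate estimate
#' @param x A `mutation_rate_estimate`.
#' @param ... Unused.
#' @return One-row tibble with the number of draws and draw ranges.
#' @export
glance.mutation_rate_estimate <- function(x, ...) {
  tibble(n_draws = nrow(x$draws),
         g_min = min(x$draws$g), g_max = max(x$draws$g),
         t_min = min(x$draws$t), t_max = max(x$draws$t))
}

#' Tidy a calibrated tree into a per-node table
#' @param x A `calibrated_tree`.
#' @param ... Unused.
#' @return Tibble (`node`, `label`, `is_tip`, `age_years`, `support`).
#' @export
tidy.calibrated_tree <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  nn <- ntip + x$tree$Nnode
  tibble(node = seq_len(nn),
         label = c(x$tree$tip.label, rep(NA_character_, x$tree$Nnode)),
         is_tip = seq_len(nn) <= ntip,
         age_years = if (is.null(x$node_ages_years)) NA_real_
                     else unname(x$node_ages_years),
         support = c(rep(NA_real_, ntip),
                     if (is.null(x$support)) rep(NA_real_, x$tree$Nnode)
                     else unname(x$support)))
}

#' Tidy a HOR structural diff
#' @param x A `hor_structural_diff`.
#' @param ... Unused.
#' @return One-row tibble of the four difference counts.
#' @export
tidy.hor_structural_diff <- function(x, ...) {
  tibble(bp_diff = x$bp_diff, monomer_diff = x$monomer_diff,
         hor_unit_diff = x$hor_unit_diff,
         distinct_changes = x$distinct_changes)
}

#' Tidy an emergence-rate result
#' @param x An `emergence_rate`.
#' @param ... Unused.
#' @return Tibble with one row per quantity (`quantity`, `low`, `high`).
#' @export
tidy.emergence_rate <- function(x, ...) {
  tibble(quantity = c("generations", "nt_per_generation",
                      "nt_per_mbp_per_generation",
                      "hor_units_per_generation"),
         low = c(x$generations_range[1], x$nt_per_generation_range[1],
                 x$nt_per_mbp_per_generation_range[1],
                 x$hor_units_per_generation_range[1]),
         high = c(x$generations_range[2], x$nt_per_generation_range[2],
                  x$nt_per_mbp_per_generation_range[2],
                  x$hor_units_per_generation_range[2]))
}

#' Tidy array metrics
#' @param x An `array_metrics`.
#' @param ... Unused.
#' @return One-row tibble: `live_start`, `live_end`, `length_bp`,
#'   `n_unit_labels`.
#' @export
tidy.array_metrics <- function(x, ...) {
  tibble(live_start = if (nrow(x$live_span)) x$live_span$start else NA_integer_,
         live_end = if (nrow(x$live_span)) x$live_span$end else NA_integer_,
         length_bp = x$length_bp,
         n_unit_labels = nrow(x$hor_variant_counts))
}
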