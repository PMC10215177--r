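#' Tidy a distance matrix into one row per pair
#'
#' @param x A `mito_dist`.
#' @param ... Unused.
#' @return Tibble `taxon1`, `taxon2`, `distance`, `n_sites` (unordered
#'   pairs, i < j).
#' @export
tidy.mito_dist <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(taxon1 = x$labels[idx[, 1]], taxon2 = x$labels[idx[, 2]],
         distance = x$values[idx], n_sites = x$n_sites[idx]) |>
    arrange(.data$taxon1, .data$taxon2)
}

#' One-row summary of a distance matrix
#'
#' @param x A `mito_dist`.
#' @param ... Unused.
#' @return Tibble: `estimator`, `n_taxa`, `min`, `mean`, `max` distance,
#'   `n_missing` pairs.
#' @export
glance.mito_dist <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  tibble(estimator = x$estimator, n_taxa = length(x$labels),
         min = min(v, na.rm = TRUE), mean = mean(v, na.rm = TRUE),
         max = max(v, na.rm = TRUE), n_missing = sum(is.na(v)))
}

#' Tidy an RSCU table (used codons only)
#'
#' @param x An `rscu_table`.
#' @param ... Unused.
#' @return Tibble sorted by descending count, stop codons dropped.
#' @export
tidy.rscu_table <- function(x, ...) {
  as_tibble(x) |>
    filter(.data$aa != "Stop") |>
    arrange(dplyr::desc(.data$count))
}

#' One-row summary of an RSCU table
#'
#' Reports the total codon count and the number of codons with RSCU > 1
#' (preferred codons).
#'
#' @param x An `rscu_table`.
#' @param ... Unused.
#' @return Tibble: `n_codons`, `n_preferred`, `genetic_code`.
#' @export
glance.rscu_table <- function(x, ...) {
  tibble(
    n_codons = sum(x$count[x$aa != "Stop"]),
    n_preferred = sum(x$rscu > 1, na.rm = TRUE),
    genetic_code = attr(x, "genetic_code", exact = TRUE) %||% NA_character_
  )
}

#' One-row summary of a morphometric range check
#'
#' @param x A `morpho_check`.
#' @param ... Unused.
#' @return Tibble with verdict counts and the fraction of referenced
#'   indices within range.
#' @export
glance.morpho_check <- function(x, ...) {
  tibble(
    species = attr(x, "species", exact = TRUE),
    n_indices = nrow(x),
    n_within = sum(x$verdict == "within"),
    n_below = sum(x$verdict == "below"),
    n_above = sum(x$verdict == "above"),
    n_no_reference = sum(x$verdict == "no_reference"),
    fraction_within = attr(x, "fraction_within", exact = TRUE)
  )
}
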