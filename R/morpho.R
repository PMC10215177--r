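#' Packaged morphometric tables
#'
#' `morpho_reference()` returns the published external-measurement
#' reference ranges for *Myotis aurascens* (two field studies, n = 10 and
#' n = 7) and *M. davidii* (n = 3, several indices measured on a single
#' individual, flagged by `n = 1`). `morpho_specimen()` returns the Hulun
#' Lake *M. aurascens* specimen measurements. Indices: body mass BM in g;
#' FL, LHB, TBL, TL, EL, EW, TRL, LHF, WL, WS and the wing bone indices
#' (McIII..V1) in mm.
#'
#' @return Tibbles: reference ranges (`species`, `source`, `n`, `index`,
#'   `low`, `high`) and specimen measurements (`index`, `value`).
#' @export
morpho_reference <- function() {
  readr::read_csv(system.file("extdata", "myotis_reference_ranges.csv",
                              package = "mitophylo"),
                  col_types = "ccicdd", progress = FALSE)
}

#' @rdname morpho_reference
#' @export
morpho_specimen <- function() {
  readr::read_csv(system.file("extdata", "maurascens_specimen.csv",
                              package = "mitophylo"),
                  col_types = "cd", progress = FALSE)
}

#' Check specimen measurements against species reference ranges
#'
#' Compares each measured index of a specimen with a species' published
#' range using inclusive bounds: a value exactly at a bound is `within`.
#' Single-individual references (`low == high`) are compared with a
#' relative tolerance (default 5%), since a point value is an informal
#' range. Indices without a reference get `no_reference`.
#'
#' @param record Tibble `index`, `value` — the specimen.
#' @param ranges Tibble `species`, `index`, `low`, `high` (e.g.
#'   [morpho_reference()]), optionally `source` to select a study.
#' @param species Species whose ranges to use.
#' @param source Optional source tag filter when a species has several
#'   reference studies.
#' @param point_tol Relative tolerance for single-value references.
#' @return A `morpho_check`: tibble `index`, `value`, `low`, `high`,
#'   `verdict` in `within`/`below`/`above`/`no_reference`, with attribute
#'   `fraction_within` = within / (indices with a reference).
#' @export
#' @examples
#' range_check(morpho_specimen(), morpho_reference(),
#'             species = "M. aurascens", source = "Kim")
range_check <- function(record, ranges, species, source = NULL,
                        point_tol = 0.05) {
  ranges <- as_tibble(ranges) |> filter(.data$species == !!species)
  if (!is.null(source)) {
    ranges <- ranges |> filter(.data$source == !!source)
  }
  if (any(ranges$high < ranges$low)) abort("reference has high < low")
  out <- as_tibble(record) |>
    left_join(ranges |> select("index", "low", "high"), by = "index") |>
    mutate(verdict = dplyr::case_when(
      is.na(.data$low) ~ "no_reference",
      .data$low == .data$high &
        abs(.data$value - .data$low) <= point_tol * .data$low ~ "within",
      .data$value < .data$low ~ "below",
      .data$value > .data$high ~ "above",
      TRUE ~ "within"
    ))
  with_ref <- out$verdict != "no_reference"
  frac <- if (any(with_ref)) mean(out$verdict[with_ref] == "within") else NA
  structure(out, fraction_within = frac,
            species = species,
            class = c("morpho_check", class(tibble())))
}
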