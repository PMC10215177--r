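#' Base composition of a nucleotide sequence
#'
#' Counts A/C/G/T (U counts as T), excluding gaps and IUPAC ambiguity codes
#' from every denominator, and reports base percentages, A+T and G+C
#' content, and the strand-asymmetry skews
#' \deqn{AT\,skew = (A - T)/(A + T), \qquad GC\,skew = (G - C)/(G + C).}
#' Percentages are kept at full precision; render at 2 decimals (and skews
#' at 3) to match the conventional printed form.
#'
#' @param seq Nucleotide string.
#' @return A one-row tibble with columns `n_A`, `n_C`, `n_G`, `n_T`,
#'   `n_excluded`, `pct_A` .. `pct_T`, `at_content`, `gc_content`
#'   (percent), `at_skew`, `gc_skew`.
#' @export
#' @examples
#' composition("ACGT")
composition <- function(seq) {
  s <- chartr("U", "T", toupper(gsub("[[:space:]]", "", seq)))
  chars <- strsplit(s, "")[[1]]
  cnt <- c(A = sum(chars == "A"), C = sum(chars == "C"),
           G = sum(chars == "G"), T = sum(chars == "T"))
  total <- sum(cnt)
  if (total == 0) abort("no unambiguous A/C/G/T bases in input")
  pct <- 100 * cnt / total
  tibble(
    n_A = cnt[["A"]], n_C = cnt[["C"]], n_G = cnt[["G"]], n_T = cnt[["T"]],
    n_excluded = length(chars) - total,
    pct_A = pct[["A"]], pct_C = pct[["C"]], pct_G = pct[["G"]],
    pct_T = pct[["T"]],
    at_content = pct[["A"]] + pct[["T"]],
    gc_content = pct[["G"]] + pct[["C"]],
    at_skew = at_skew(cnt[["A"]], cnt[["T"]]),
    gc_skew = gc_skew(cnt[["G"]], cnt[["C"]])
  )
}

#' AT and GC strand skews
#'
#' `at_skew(A, T) = (A - T)/(A + T)` and `gc_skew(G, C) = (G - C)/(G + C)`.
#' Both are scale-invariant, so raw counts and percentages give identical
#' values. A zero denominator yields `NA` (the skew is undefined), never 0.
#'
#' @param a,t,g,c Counts or percentages of the respective bases
#'   (vectorized).
#' @return Numeric in `[-1, 1]`, or `NA` where undefined.
#' @export
#' @examples
#' at_skew(33.93, 30.94) # 0.046 at 3 decimals
#' gc_skew(12.96, 22.17) # -0.262
at_skew <- function(a, t) {
  ifelse(a + t > 0, (a - t) / (a + t), NA_real_)
}

#' @rdname at_skew
#' @export
gc_skew <- function(g, c) {
  ifelse(g + c > 0, (g - c) / (g + c), NA_real_)
}

#' Per-feature composition and skew report for a genome
#'
#' With a sequence, statistics are computed from the H-strand segment of
#' each feature (the frame of reference annotation tables conventionally
#' print, regardless of coding strand); in sequence-free mode the declared
#' per-feature `pct_*` columns are used directly.
#'
#' @param genome A [mito_genome].
#' @return Tibble with one row per feature plus a `Total` row: name, class,
#'   strand, size, base percentages, at/gc content and skews.
#' @export
genome_composition <- function(genome) {
  feats <- genome$features
  if (!is.null(genome$sequence)) {
    per <- purrr::map(seq_len(nrow(feats)), function(i) {
      f <- feats[i, ]
      f$strand <- "H"  # report in the genome (H-strand) frame of reference
      composition(extract_gene(genome, f))
    })
    per <- bind_rows(per)
    total <- composition(genome$sequence)
  } else {
    need <- c("pct_A", "pct_C", "pct_G", "pct_T")
    if (!all(need %in% names(feats))) {
      abort("sequence-free genome lacks pct_A..pct_T composition columns")
    }
    per <- tibble(
      pct_A = feats$pct_A, pct_C = feats$pct_C,
      pct_G = feats$pct_G, pct_T = feats$pct_T,
      at_content = feats$pct_A + feats$pct_T,
      gc_content = feats$pct_G + feats$pct_C,
      at_skew = at_skew(feats$pct_A, feats$pct_T),
      gc_skew = gc_skew(feats$pct_G, feats$pct_C)
    )
    if (is.null(genome$composition)) {
      abort("sequence-free genome lacks whole-genome composition metadata")
    }
    cg <- genome$composition
    total <- tibble(
      pct_A = cg[["A"]], pct_C = cg[["C"]], pct_G = cg[["G"]],
      pct_T = cg[["T"]],
      at_content = cg[["A"]] + cg[["T"]],
      gc_content = cg[["G"]] + cg[["C"]],
      at_skew = at_skew(cg[["A"]], cg[["T"]]),
      gc_skew = gc_skew(cg[["G"]], cg[["C"]])
    )
  }
  out <- bind_rows(
    dplyr::bind_cols(
      feats[, c("name", "class", "strand")],
      tibble(size = feats$size),
      per[, c("pct_A", "pct_C", "pct_G", "pct_T",
              "at_content", "gc_content", "at_skew", "gc_skew")]
    ),
    dplyr::bind_cols(
      tibble(name = "Total", class = NA_character_, strand = NA_character_,
             size = genome$length),
      total[, c("pct_A", "pct_C", "pct_G", "pct_T",
                "at_content", "gc_content", "at_skew", "gc_skew")]
    )
  )
  class(out) <- c("mito_composition", class(out))
  out
}

#' Feature-class length totals
#'
#' Sums declared feature sizes per functional class (PCG, tRNA, rRNA,
#' control region) and expresses each as a percent of genome length.
#' Overlapping features are summed as printed — totals are plain sums of
#' the annotated sizes, the arithmetic annotation tables use — so the
#' class percentages need not sum to 100.
#'
#' @param genome A [mito_genome].
#' @return Tibble `class`, `n_features`, `total_bp`, `pct_genome`.
#' @export
#' @examples
#' tab2 <- system.file("extdata", "maurascens_features.tsv",
#'                     package = "mitophylo")
#' class_totals(read_feature_table(tab2))
class_totals <- function(genome) {
  genome$features |>
    group_by(class = .data$class) |>
    summarise(n_features = n(), total_bp = sum(.data$size),
              .groups = "drop") |>
    mutate(pct_genome = 100 * .data$total_bp / genome$length)
}
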