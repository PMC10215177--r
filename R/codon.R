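#' The vertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid map for NCBI translation table 2, in the RNA
#' alphabet. It differs from the standard code in four codons: AGA and AGG
#' are stops, AUA codes Met, and UGA codes Trp. Synonymous families for
#' RSCU are defined per amino acid under this table (Leu and Ser are single
#' six-fold families); the four stop codons form no family.
#'
#' @return Tibble `codon`, `aa` (three-letter, `Stop` for terminators),
#'   `family_size`.
#' @export
#' @examples
#' code <- mito_genetic_code()
#' code[code$codon %in% c("AUA", "UGA", "AGA"), ]
mito_genetic_code <- function() {
  bases <- c("U", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aa <- vapply(codons, translate_codon_mt, character(1), USE.NAMES = FALSE)
  tab <- tibble(codon = codons, aa = aa)
  fam <- tab |>
    filter(.data$aa != "Stop") |>
    dplyr::count(.data$aa, name = "family_size")
  left_join(tab, fam, by = "aa")
}

# standard code amino acid, then the four vertebrate-mito overrides
translate_codon_mt <- function(codon) {
  overrides <- c(AGA = "Stop", AGG = "Stop", AUA = "Met", UGA = "Trp")
  if (codon %in% names(overrides)) return(unname(overrides[[codon]]))
  std <- c(
    UUU = "Phe", UUC = "Phe", UUA = "Leu", UUG = "Leu",
    CUU = "Leu", CUC = "Leu", CUA = "Leu", CUG = "Leu",
    AUU = "Ile", AUC = "Ile", AUA = "Ile", AUG = "Met",
    GUU = "Val", GUC = "Val", GUA = "Val", GUG = "Val",
    UCU = "Ser", UCC = "Ser", UCA = "Ser", UCG = "Ser",
    CCU = "Pro", CCC = "Pro", CCA = "Pro", CCG = "Pro",
    ACU = "Thr", ACC = "Thr", ACA = "Thr", ACG = "Thr",
    GCU = "Ala", GCC = "Ala", GCA = "Ala", GCG = "Ala",
    UAU = "Tyr", UAC = "Tyr", UAA = "Stop", UAG = "Stop",
    CAU = "His", CAC = "His", CAA = "Gln", CAG = "Gln",
    AAU = "Asn", AAC = "Asn", AAA = "Lys", AAG = "Lys",
    GAU = "Asp", GAC = "Asp", GAA = "Glu", GAG = "Glu",
    UGU = "Cys", UGC = "Cys", UGA = "Stop", UGG = "Trp",
    CGU = "Arg", CGC = "Arg", CGA = "Arg", CGG = "Arg",
    AGU = "Ser", AGC = "Ser", AGA = "Arg", AGG = "Arg",
    GGU = "Gly", GGC = "Gly", GGA = "Gly", GGG = "Gly"
  )
  unname(std[[codon]])
}

MT_STOPS <- c("UAA", "UAG", "AGA", "AGG")

#' Identify start and stop codons of a mitochondrial CDS
#'
#' Mitochondrial protein genes often end mid-codon: a trailing `T` or `TA`
#' is completed to a UAA stop by polyadenylation of the mRNA. Given a
#' sense-strand CDS, this reports the start codon, the number of complete
#' codons, the number of trailing bases (0-2), and the stop token in the
#' conventional annotation notation: a complete codon (`TAA`, `AGA`, ...)
#' when length is a multiple of 3, else the truncated `TA-` (two trailing
#' bases) or `T--` (one trailing base).
#'
#' @param cds Sense-strand (5' to 3') nucleotide string, length >= 3.
#' @return A one-row tibble: `start_codon`, `stop_codon`,
#'   `n_complete_codons`, `n_trailing_bases`.
#' @export
#' @examples
#' identify_codons("ATGAAATAA")
identify_codons <- function(cds) {
  s <- chartr("U", "T", toupper(gsub("[[:space:]]", "", cds)))
  n <- nchar(s)
  if (n < 3) abort("CDS shorter than one codon")
  n_complete <- n %/% 3L
  n_trailing <- n %% 3L
  stop_token <- if (n_trailing == 0L) {
    substr(s, n - 2, n)
  } else {
    paste0(substr(s, n - n_trailing + 1, n),
           strrep("-", 3L - n_trailing))
  }
  tibble(start_codon = substr(s, 1, 3), stop_codon = stop_token,
         n_complete_codons = n_complete, n_trailing_bases = n_trailing)
}

#' Codon usage of a set of coding sequences
#'
#' Tallies complete codons over one or more sense-strand CDS under the
#' vertebrate mitochondrial code, following the CodonW conventions:
#' trailing partial codons are dropped (counted in `n_incomplete`) and a
#' terminal complete stop codon is excluded from usage. Codons are reported
#' in the RNA alphabet.
#'
#' @param genes Character vector (or list) of sense-strand CDS strings.
#' @return An object of class `codon_usage`: tibble `codon`, `aa`,
#'   `family_size`, `count` over the 64 codons, with attributes
#'   `n_incomplete` (trailing partial codons dropped) and `n_stops_excluded`.
#' @export
#' @examples
#' count_codons("ATGAAATAA") # AUG 1, AAA 1; the TAA stop is excluded
count_codons <- function(genes) {
  genes <- unlist(genes, use.names = FALSE)
  code <- mito_genetic_code()
  counts <- setNames(integer(64), code$codon)
  n_incomplete <- 0L
  n_stops <- 0L
  for (g in genes) {
    info <- identify_codons(g)
    s <- chartr("TU", "UU", toupper(gsub("[[:space:]]", "", g)))
    k <- info$n_complete_codons
    cods <- substring(s, 3 * seq_len(k) - 2, 3 * seq_len(k))
    if (info$n_trailing_bases > 0L) n_incomplete <- n_incomplete + 1L
    if (k > 0 && info$n_trailing_bases == 0L && cods[k] %in% MT_STOPS) {
      cods <- cods[-k]
      n_stops <- n_stops + 1L
    }
    cods <- cods[cods %in% names(counts)]  # ambiguity-containing codons drop
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  out <- code
  out$count <- as.integer(counts[out$codon])
  structure(out, n_incomplete = n_incomplete, n_stops_excluded = n_stops,
            genetic_code = "vertebrate mitochondrial (table 2)",
            class = c("codon_usage", class(out)))
}

#' Codon usage and RSCU for the protein-coding genes of a genome
#'
#' Extracts every PCG in sense orientation and runs [count_codons()] and
#' [rscu()].
#'
#' @param genome A [mito_genome] with sequence.
#' @return An `rscu_table` (see [rscu()]).
#' @export
genome_rscu <- function(genome) {
  pcgs <- genome$features |> filter(.data$class == "PCG")
  if (nrow(pcgs) == 0) abort("genome has no PCG features")
  seqs <- purrr::map_chr(seq_len(nrow(pcgs)),
                         function(i) extract_gene(genome, pcgs[i, ]))
  rscu(count_codons(seqs))
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c in a synonymous family of size k with counts n is
#' \deqn{RSCU_c = n_c / \left(\frac{1}{k}\sum_{j \in family} n_j\right),}
#' the observed count over the count expected if all synonyms were used
#' equally. Values sum to k within each family; 1 means no preference.
#' Stop codons have no family and get `NA`; a family with zero total
#' yields RSCU 0 for all members (the documented convention for unused
#' families).
#'
#' @param usage A `codon_usage` from [count_codons()], or any tibble with
#'   columns `codon`, `aa`, `family_size`, `count`.
#' @return An object of class `rscu_table`: the usage tibble with an
#'   `rscu` column.
#' @export
#' @examples
#' u <- count_codons(c("ATGTTTTTTTTTTTC")) # Phe family counts 3:1
#' r <- rscu(u)
#' r[r$codon %in% c("UUU", "UUC"), ]
rscu <- function(usage) {
  out <- as_tibble(usage) |>
    group_by(.data$aa) |>
    mutate(rscu = dplyr::case_when(
      .data$aa == "Stop" ~ NA_real_,
      sum(.data$count) == 0 ~ 0,
      TRUE ~ .data$count / (sum(.data$count) / .data$family_size)
    )) |>
    ungroup()
  structure(out, class = c("rscu_table", class(tibble())),
            genetic_code = attr(usage, "genetic_code", exact = TRUE))
}
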