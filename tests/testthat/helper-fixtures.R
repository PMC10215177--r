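# small builders shared across test files

# a 2-PCG + 1-tRNA linear toy genome with known sequences
toy_genome <- function() {
  # g1 = ATGAAATAA (H), g2 stored as revcomp of ATGTTTTAA (L)
  seq <- paste0("CC", "ATGAAATAA", "G", revcomp("ATGTTTTAA"), "ACGTACG")
  feats <- tibble::tibble(
    name = c("PCG1", "PCG2", "tRNA-Phe"),
    class = c("PCG", "PCG", "tRNA"),
    strand = c("H", "L", "H"),
    start = c(3L, 13L, 22L),
    end = c(11L, 21L, 26L),
    start_codon = c("ATG", "ATG", NA),
    stop_codon = c("TAA", "TAA", NA)
  )
  mito_genome("toy", feats, sequence = seq, circular = FALSE)
}

write_toy_genbank <- function(path, origin = TRUE, extra_key = FALSE) {
  seq <- paste(rep("acgtacgtac", 12), collapse = "")  # 120 bp
  lines <- c(
    "LOCUS       TESTREC                  120 bp    DNA     circular MAM 01-JAN-2024",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             5..34",
    '                     /gene="ND1"',
    "     tRNA            complement(40..60)",
    '                     /product="tRNA-Phe"',
    "     rRNA            join(100..120,1..20)",
    '                     /product="12S ribosomal RNA"'
  )
  if (extra_key) {
    lines <- c(lines, "     misc_RNA        61..70", '                     /note="odd"')
  }
  if (origin) {
    lines <- c(lines, "ORIGIN",
               paste0("        1 ", gsub("(.{10})", "\\1 ", substr(seq, 1, 60))),
               paste0("       61 ", gsub("(.{10})", "\\1 ", substr(seq, 61, 120))))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(toupper(seq))
}

# canonical topology key: sorted non-trivial bipartitions by tip label
topo_key <- function(tr) {
  tr <- ape::unroot(tr)
  sp <- phangorn::as.splits(tr)
  labs <- attr(sp, "labels")
  n <- length(labs)
  keys <- vapply(sp, function(s) {
    a <- sort(labs[s])
    b <- sort(setdiff(labs, a))
    if (length(a) < 2 || length(b) < 2) return(NA_character_)
    one <- paste(a, collapse = ",")
    two <- paste(b, collapse = ",")
    if (length(a) < length(b) || (length(a) == length(b) && one < two)) {
      one
    } else {
      two
    }
  }, character(1))
  paste(sort(unique(keys[!is.na(keys)])), collapse = "|")
}

# random additive distance matrix: path lengths on a random binary tree
random_additive <- function(n, seed) {
  cfg <- sim_config(seed = seed, n_taxa = n, branch_range = c(0.05, 1))
  tr <- simulate_tree(cfg)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

expect_symmetric_zero_diag <- function(dm) {
  expect_equal(dm$values, t(dm$values))
  expect_equal(unname(diag(dm$values)), rep(0, length(dm$labels)))
}
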