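test_that("the genetic code matches the published table-2 definition", {
  skip_if_not_installed("Biostrings")
  code <- mito_genetic_code()
  ref <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  ref_aa <- setNames(as.character(ref), chartr("T", "U", names(ref)))
  one <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
           Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
           Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
           Tyr = "Y", Val = "V", Stop = "*")
  expect_equal(unname(one[code$aa]), unname(ref_aa[code$codon]))
  # the four departures from the standard code
  expect_equal(code$aa[code$codon == "AUA"], "Met")
  expect_equal(code$aa[code$codon == "UGA"], "Trp")
  expect_equal(code$aa[code$codon %in% c("AGA", "AGG")], rep("Stop", 2))
  # Leu and Ser are single 6-fold families
  expect_equal(unique(code$family_size[code$aa == "Leu"]), 6L)
  expect_equal(unique(code$family_size[code$aa == "Ser"]), 6L)
  expect_equal(sum(code$aa != "Stop"), 60L)
})

test_that("identify_codons handles complete and truncated stops", {
  x <- identify_codons("ATGAAATAA")
  expect_equal(x$start_codon, "ATG")
  expect_equal(x$stop_codon, "TAA")
  expect_equal(x$n_complete_codons, 3L)
  # a 956-bp gene (956 mod 3 = 2) ends in a two-base truncated stop
  g <- suppressMessages(maurascens_genome())
  nd1_len <- g$features$size[g$features$name == "ND1"]
  cds <- paste0("ATG", strrep("AAA", (nd1_len - 5) / 3), "TA")
  y <- identify_codons(cds)
  expect_equal(nchar(cds), 956)
  expect_equal(y$stop_codon, "TA-")
  expect_equal(y$n_complete_codons, 318L)
  # 1042 mod 3 = 1: single trailing T
  z <- identify_codons(paste0("ATT", strrep("CAA", 346), "T"))
  expect_equal(z$stop_codon, "T--")
  expect_equal(z$n_trailing_bases, 1L)
  expect_error(identify_codons("AT"), "shorter")
})

test_that("codon counting drops stops and partial codons, and is additive", {
  u <- count_codons("ATGAAATAA")
  expect_equal(u$count[u$codon == "AUG"], 1L)
  expect_equal(u$count[u$codon == "AAA"], 1L)
  expect_equal(u$count[u$codon == "UAA"], 0L)  # terminal stop excluded
  expect_equal(attr(u, "n_stops_excluded"), 1L)

  v <- count_codons("ATGTTTTTC")  # no stop at all
  expect_equal(sum(v$count), 3L)
  expect_equal(v$count[v$codon %in% c("AUG", "UUU", "UUC")], rep(1L, 3))

  w <- count_codons("ATGAAACCT")  # 9 bp + nothing trailing
  both <- count_codons(c("ATGAAATAA", "ATGAAACCT"))
  expect_equal(both$count, u$count + w$count)

  trunc <- count_codons("ATGAAATA")  # trailing TA dropped
  expect_equal(sum(trunc$count), 2L)
  expect_equal(attr(trunc, "n_incomplete"), 1L)
})

test_that("RSCU follows the family-mean formula", {
  # Phe family counts (3, 1) -> RSCU (1.5, 0.5)
  r <- rscu(count_codons("ATGTTTTTTTTTTTC"))
  expect_equal(r$rscu[r$codon == "UUU"], 1.5)
  expect_equal(r$rscu[r$codon == "UUC"], 0.5)
  # uniform family -> all 1
  r2 <- rscu(count_codons("GTTGTCGTAGTG"))
  expect_equal(r2$rscu[r2$aa == "Val"], rep(1, 4))
  # 4-fold family (4,0,0,0) -> (4,0,0,0)
  r3 <- rscu(count_codons("CCTCCTCCTCCT"))
  expect_equal(sort(r3$rscu[r3$aa == "Pro"], decreasing = TRUE),
               c(4, 0, 0, 0))
  # unused families report 0, stops NA
  expect_equal(r3$rscu[r3$aa == "Gly"], rep(0, 4))
  expect_true(all(is.na(r3$rscu[r3$aa == "Stop"])))
})

test_that("family sums conserve k and RSCU>1 count is scale-invariant", {
  code <- mito_genetic_code()
  set.seed(7)
  for (i in seq_len(1000)) {
    u <- code
    u$count <- ifelse(u$aa == "Stop", 0L,
                      stats::rpois(64, lambda = sample(c(0.5, 3, 20), 1)))
    r <- rscu(u)
    sums <- tapply(r$rscu[r$aa != "Stop"], r$aa[r$aa != "Stop"], sum)
    k <- tapply(r$family_size[r$aa != "Stop"], r$aa[r$aa != "Stop"], unique)
    used <- tapply(r$count[r$aa != "Stop"], r$aa[r$aa != "Stop"], sum) > 0
    expect_equal(as.numeric(sums[used]), as.numeric(k[used]))
    if (i <= 20) {
      u2 <- u
      u2$count <- u$count * 5L
      expect_equal(sum(rscu(u2)$rscu > 1, na.rm = TRUE),
                   sum(r$rscu > 1, na.rm = TRUE))
    }
  }
})

test_that("genome-level RSCU runs on sense-strand PCGs of both strands", {
  g <- toy_genome()
  r <- genome_rscu(g)
  # PCG1 = ATG AAA TAA, PCG2 = ATG TTT TAA (L strand, sense-extracted)
  expect_equal(r$count[r$codon == "AUG"], 2L)
  expect_equal(r$count[r$codon == "AAA"], 1L)
  expect_equal(r$count[r$codon == "UUU"], 1L)
  expect_equal(sum(r$count), 4L)
})
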