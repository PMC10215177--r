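test_that("feature-table rows yield sizes end - start + 1", {
  g <- suppressMessages(maurascens_genome())
  f <- g$features
  expect_equal(f$size[f$name == "ND1"], 956)
  expect_equal(f$size[f$name == "tRNA-Ser1"], 59)
  expect_equal(f$size, f$end - f$start + 1L)
  expect_equal(max(f$end), 16771)
})

test_that("the shipped annotation has the canonical gene inventory", {
  g <- suppressMessages(maurascens_genome())
  tab <- table(g$features$class)
  expect_equal(tab[["PCG"]], 13)
  expect_equal(tab[["tRNA"]], 22)
  expect_equal(tab[["rRNA"]], 2)
  expect_equal(tab[["control_region"]], 1)
  # 37 genes; the control region is an annotated feature, not a gene
  expect_equal(sum(g$features$class != "control_region"), 37)
  # overlapping neighbours are preserved as printed
  atp8 <- g$features[g$features$name == "ATP8", ]
  atp6 <- g$features[g$features$name == "ATP6", ]
  expect_true(atp8$end > atp6$start)
})

test_that("empty or malformed feature tables are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_error(read_feature_table(f), "empty")
  writeLines(c("name\tclass\tstrand\tstart\tend",
               "ND1\tPCG\tH\toops\t3707"), f)
  expect_error(suppressWarnings(read_feature_table(f)), "coordinates")
  writeLines(c("# circular: false",
               "name\tclass\tstrand\tstart\tend",
               "ND1\tPCG\tH\t300\t200",
               "ND2\tPCG\tH\t1\t400"), f)
  expect_error(suppressMessages(read_feature_table(f)), "end < start")
  expect_error(read_feature_table(tempfile()), "no such file")
})

test_that("feature tables round-trip losslessly with metadata", {
  g <- suppressMessages(maurascens_genome())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(g, f)
  g2 <- suppressMessages(read_feature_table(f))
  expect_equal(as.data.frame(g2$features), as.data.frame(g$features))
  expect_equal(g2$length, g$length)
  expect_equal(g2$is_circular, g$is_circular)
  expect_equal(g2$composition, g$composition)
})

test_that("extract_gene honours strand, wrap, and the involution identity", {
  g <- mito_genome("lin", tibble::tibble(
    name = "x", class = "PCG", strand = "H", start = 1, end = 4),
    sequence = "AACGTT", circular = FALSE)
  expect_equal(extract_gene(g, list(start = 1, end = 4, strand = "H")), "AACG")
  expect_equal(extract_gene(g, list(start = 1, end = 4, strand = "L")), "CGTT")
  expect_equal(revcomp(revcomp("AACG")), "AACG")
  # circular wrap: [5..6] + [1..2]
  gc <- mito_genome("circ", tibble::tibble(
    name = "w", class = "tRNA", strand = "H", start = 5, end = 2),
    sequence = "AACGTT", circular = TRUE)
  expect_equal(gc$features$size, 4L)
  expect_equal(extract_gene(gc, gc$features[1, ]), "TTAA")
  expect_error(extract_gene(g, list(start = 5, end = 2, strand = "H")),
               "circular")
  expect_error(extract_gene(g, list(start = 0, end = 4, strand = "H")),
               "out of range")
})

test_that("extraction length equals declared size across a whole genome", {
  g <- synth_genome(sim_config(seed = 11))
  lens <- vapply(seq_len(nrow(g$features)), function(i) {
    nchar(extract_gene(g, g$features[i, ]))
  }, numeric(1))
  expect_equal(lens, as.numeric(g$features$size))
})

test_that("GenBank records parse: strands, origin-wrapping join, errors", {
  f <- withr::local_tempfile(fileext = ".gb")
  seq <- write_toy_genbank(f)
  g <- suppressMessages(read_genbank(f))
  expect_equal(g$length, 120L)
  expect_true(g$is_circular)
  expect_equal(nrow(g$features), 3)
  expect_equal(g$features$strand[g$features$name == "tRNA-Phe"], "L")
  expect_equal(g$features$name[g$features$class == "PCG"], "ND1")
  # wrapped rRNA equals the manual splice
  rr <- g$features[g$features$class == "rRNA", ]
  expect_equal(rr$start, 100L)
  expect_equal(rr$end, 20L)
  expect_equal(extract_gene(g, rr),
               paste0(substr(seq, 100, 120), substr(seq, 1, 20)))

  f2 <- withr::local_tempfile(fileext = ".gb")
  write_toy_genbank(f2, origin = FALSE)
  expect_error(read_genbank(f2), "ORIGIN")

  f3 <- withr::local_tempfile(fileext = ".gb")
  write_toy_genbank(f3, extra_key = TRUE)
  expect_warning(suppressMessages(read_genbank(f3)), "misc_RNA")
})

test_that("gene names normalize to the canonical vocabulary", {
  expect_equal(normalize_gene_name(c("COI", "cox2", "NAD4L", "CYTB", "ATPase6")),
               c("COX1", "COX2", "ND4L", "Cytb", "ATP6"))
  expect_equal(normalize_gene_name(c("s-rRNA", "16S ribosomal RNA", "D-loop")),
               c("12S_rRNA", "16S_rRNA", "D-loop"))
  # Leu/Ser paralogs resolved by anticodon or suffix
  expect_equal(normalize_gene_name(c("trnL-UAA", "trnL-CAA", "tRNA-Ser(GCU)",
                                     "tRNA-Ser2", "trnF")),
               c("tRNA-Leu2", "tRNA-Leu1", "tRNA-Ser1", "tRNA-Ser2",
                 "tRNA-Phe"))
  expect_equal(normalize_gene_name("something_else"), "something_else")
})
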