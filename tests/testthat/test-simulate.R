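test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 12, n_taxa = 4)
  t1 <- simulate_tree(cfg)
  t2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  a1 <- suppressMessages(evolve_sequences(t1, cfg))
  a2 <- suppressMessages(evolve_sequences(t2, cfg))
  expect_identical(unclass(a1), unclass(a2))
  g1 <- synth_genome(cfg)
  g2 <- synth_genome(cfg)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(as.data.frame(g1$features), as.data.frame(g2$features))
  # different seeds diverge
  expect_false(identical(g1$sequence, synth_genome(sim_config(seed = 13))$sequence))
})

test_that("degenerate branch-length ranges are honoured", {
  cfg <- sim_config(seed = 3, n_taxa = 5, branch_range = c(0.1, 0.1))
  tr <- simulate_tree(cfg)
  expect_equal(tr$edge.length, rep(0.1, nrow(tr$edge)))
  expect_equal(length(tr$tip.label), 5)
  expect_error(sim_config(branch_range = c(0.2, 0.1)), "increasing")
})

test_that("topologies are uniform over the 105 six-taxon trees", {
  n_draws <- 10000
  keys <- character(n_draws)
  for (i in seq_len(n_draws)) {
    keys[i] <- topo_key(simulate_tree(sim_config(seed = i, n_taxa = 6)))
  }
  tab <- table(keys)
  expect_equal(length(tab), 105)  # (2n-5)!! for n = 6
  chi <- stats::chisq.test(tab, p = rep(1 / 105, 105))
  expect_gt(chi$p.value, 1e-4)
})

test_that("zero branch lengths transmit the root unchanged", {
  cfg <- sim_config(seed = 5, n_taxa = 4, branch_range = c(0, 0),
                    seq_length = 300)
  aln <- suppressMessages(evolve_sequences(simulate_tree(cfg), cfg))
  m <- unclass(aln)
  expect_true(all(apply(m, 2, function(col) length(unique(col)) == 1)))
})

test_that("two-taxon divergence matches the TN93 expectation", {
  cfg <- sim_config(seed = 8, n_taxa = 2, seq_length = 100000)
  tr <- ape::read.tree(text = "(t1:0.05,t2:0.05);")
  aln <- suppressMessages(evolve_sequences(tr, cfg))
  m <- unclass(aln)
  # closed-form expected mismatch fraction at separation d = 0.1
  P <- mitophylo:::tn93_P(0.1, cfg$kappa1, cfg$kappa2, cfg$pi)
  p_exp <- sum(cfg$pi * (1 - diag(P)))
  p_obs <- p_distance(m[1, ], m[2, ])
  se <- sqrt(p_exp * (1 - p_exp) / cfg$seq_length)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("the JC limit of the evolver is recovered by the TN93 estimator", {
  cfg <- sim_config(seed = 14, n_taxa = 2, seq_length = 100000,
                    pi = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                    kappa1 = 1, kappa2 = 1)
  tr <- ape::read.tree(text = "(t1:0.05,t2:0.05);")
  aln <- suppressMessages(evolve_sequences(tr, cfg))
  m <- unclass(aln)
  d_hat <- tn93_distance(m[1, ], m[2, ])
  # 3 binomial standard errors on p, propagated through the JC curve
  p_exp <- 3 / 4 * (1 - exp(-4 * 0.1 / 3))
  se_d <- 3 * sqrt(p_exp * (1 - p_exp) / cfg$seq_length) / (1 - 4 * p_exp / 3)
  expect_lt(abs(d_hat - 0.1), se_d)
})

test_that("tip base composition converges to the stationary frequencies", {
  cfg <- sim_config(seed = 6, n_taxa = 3, branch_range = c(0.3, 0.3),
                    seq_length = 100000)
  aln <- suppressMessages(evolve_sequences(simulate_tree(cfg), cfg))
  m <- unclass(aln)
  for (i in seq_len(nrow(m))) {
    obs <- table(factor(m[i, ], c("A", "C", "G", "T"))) / ncol(m)
    for (b in c("A", "C", "G", "T")) {
      se <- sqrt(cfg$pi[[b]] * (1 - cfg$pi[[b]]) / ncol(m))
      expect_lt(abs(obs[[b]] - cfg$pi[[b]]), 3 * se + 1e-12)
    }
  }
})

test_that("gap masking exercises pairwise deletion at the configured rate", {
  cfg <- sim_config(seed = 10, n_taxa = 4, seq_length = 5000, gap_rate = 0.1)
  aln <- suppressMessages(evolve_sequences(simulate_tree(cfg), cfg))
  m <- unclass(aln)
  rate <- mean(m == "-")
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / length(m)))
  expect_false(anyNA(dist_p(aln)$values))
})

test_that("synthetic genomes have the canonical layout and honest codons", {
  cfg <- sim_config(seed = 17)
  g <- synth_genome(cfg)
  tab <- table(g$features$class)
  expect_equal(tab[["PCG"]], 13)
  expect_equal(tab[["tRNA"]], 22)
  expect_equal(tab[["rRNA"]], 2)
  expect_equal(tab[["control_region"]], 1)
  expect_true(g$is_circular)
  expect_true(any(g$features$strand == "L"))
  pcgs <- g$features[g$features$class == "PCG", ]
  for (i in seq_len(nrow(pcgs))) {
    info <- identify_codons(extract_gene(g, pcgs[i, ]))
    expect_equal(info$start_codon, pcgs$start_codon[i])
    expect_equal(info$stop_codon, pcgs$stop_codon[i])
  }
  expect_true(any(grepl("-", pcgs$stop_codon, fixed = TRUE)))
  # write -> read round trip
  tf <- withr::local_tempfile(fileext = ".tsv")
  ff <- withr::local_tempfile(fileext = ".fa")
  write_feature_table(g, tf)
  writeLines(c(paste0(">", g$identifier), g$sequence), ff)
  g2 <- suppressMessages(read_feature_table(tf, fasta = ff))
  expect_equal(g2$sequence, g$sequence)
  expect_equal(as.data.frame(g2$features), as.data.frame(g$features))
})
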