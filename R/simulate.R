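#' Simulation configuration
#'
#' Bundles the knobs for the three generators: random unrooted trees,
#' TN93 sequence evolution along them, and synthetic annotated circular
#' mitogenomes. Defaults mirror a small mammalian-mitogenome study:
#' congeneric divergences (branch lengths 0.02-0.2 substitutions/site),
#' AT-rich mammalian mtDNA frequencies, transition-biased rates, and the
#' canonical 37-feature genome layout (13 PCGs, 22 tRNAs, 2 rRNAs, one
#' control region) with a mix of H- and L-strand genes and a fraction of
#' PCGs ending in incomplete stop codons.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param n_taxa Number of tips for tree simulation (>= 3).
#' @param branch_range Length-2 numeric, uniform branch-length range in
#'   substitutions/site.
#' @param seq_length Alignment length in bp.
#' @param pi Equilibrium base frequencies, named A/C/G/T, summing to 1.
#' @param kappa1 Purine transition/transversion rate ratio (alpha1/beta).
#' @param kappa2 Pyrimidine transition/transversion rate ratio.
#' @param gap_rate Fraction of alignment cells masked to gaps afterwards
#'   (exercises pairwise deletion; the evolver itself is indel-free).
#' @param layout Genome layout: list with `n_pcg`, `n_trna`, `n_rrna`,
#'   `n_control`, `l_strand_fraction`, `incomplete_stop_fraction`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_taxa = 6,
                       branch_range = c(0.02, 0.2),
                       seq_length = 10000,
                       pi = c(A = 0.34, C = 0.22, G = 0.13, T = 0.31),
                       kappa1 = 8, kappa2 = 16, gap_rate = 0,
                       layout = list(n_pcg = 13, n_trna = 22, n_rrna = 2,
                                     n_control = 1, l_strand_fraction = 0.25,
                                     incomplete_stop_fraction = 0.4)) {
  pi <- pi[VALID_BASES]
  if (abs(sum(pi) - 1) > 1e-8) abort("base frequencies must sum to 1")
  if (kappa1 <= 0 || kappa2 <= 0) abort("rate ratios must be positive")
  if (seq_length < 1) abort("seq_length must be >= 1")
  if (any(branch_range < 0) || branch_range[2] < branch_range[1]) {
    abort("branch_range must be an increasing non-negative pair")
  }
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 branch_range = branch_range,
                 seq_length = as.integer(seq_length), pi = pi,
                 kappa1 = kappa1, kappa2 = kappa2, gap_rate = gap_rate,
                 layout = layout),
            class = "sim_config")
}

# per-stage child seeds derived from the root seed so adding a stage never
# perturbs earlier draws (kept below 2^31)
stage_seed <- function(cfg, stage) {
  offs <- c(tree = 101L, sequences = 202L, genome = 303L, mask = 404L)
  (cfg$seed * 7919L + offs[[stage]]) %% .Machine$integer.max
}

#' Simulate a random unrooted tree
#'
#' Topology is uniform over the \eqn{(2n-5)!!} labeled unrooted binary
#' topologies, generated by sequential random addition: starting from the
#' 3-taxon star, each next leaf attaches to an edge chosen uniformly at
#' random. Branch lengths are drawn uniformly from `cfg$branch_range`.
#'
#' @param cfg A [sim_config()].
#' @return An unrooted ape `phylo` with branch lengths.
#' @export
simulate_tree <- function(cfg) {
  if (cfg$n_taxa < 3) abort("n_taxa must be >= 3")
  with_preserved_seed(stage_seed(cfg, "tree"), {
    topo <- random_topology(cfg$n_taxa)
    topo$edge.length <- runif(nrow(topo$edge), cfg$branch_range[1],
                              cfg$branch_range[2])
    topo
  })
}

# uniform unrooted topology on n labeled leaves (t1..tn), as ape phylo
random_topology <- function(n) {
  # edges as rows [parent, child] over node ids; leaves 1..n, internals n+1..
  # start from star (center n+1) on leaves 1..3
  edge <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
  next_internal <- n + 2L
  for (leaf in seq_len(n)[-(1:3)]) {
    e <- sample.int(nrow(edge), 1)
    mid <- next_internal; next_internal <- next_internal + 1L
    old_child <- edge[e, 2]
    edge[e, 2] <- mid
    edge <- rbind(edge, c(mid, old_child), c(mid, leaf))
  }
  renumber_phylo(edge, n)
}

# put internal node ids into ape's expected order (root = n+1, preorder)
renumber_phylo <- function(edge, n) {
  internals <- sort(unique(edge[, 1]))
  map <- integer(max(edge))
  map[seq_len(n)] <- seq_len(n)
  # preorder from the original root n+1
  ord <- integer(0)
  stack <- n + 1L
  children <- split(edge[, 2], edge[, 1])
  while (length(stack) > 0) {
    nd <- stack[1]; stack <- stack[-1]
    ord <- c(ord, nd)
    kids <- children[[as.character(nd)]]
    stack <- c(kids[kids > n], stack)
  }
  map[ord] <- n + seq_along(ord)
  edge2 <- cbind(map[edge[, 1]], map[edge[, 2]])
  tr <- list(edge = edge2, tip.label = paste0("t", seq_len(n)),
             Nnode = length(internals))
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Evolve sequences along a tree under TN93
#'
#' Draws the root sequence from the equilibrium frequencies and applies
#' per-edge substitution with the exact TN93 transition-probability matrix
#' \eqn{P(t) = e^{Qt}} (no indels; `cfg$gap_rate > 0` masks random cells
#' to gaps afterwards to exercise pairwise deletion).
#'
#' @param tree An ape `phylo` with branch lengths in substitutions/site.
#' @param cfg A [sim_config()].
#' @return A gap-free (or masked) [alignment()] of the tip sequences.
#' @export
evolve_sequences <- function(tree, cfg) {
  pi <- cfg$pi
  with_preserved_seed(stage_seed(cfg, "sequences"), {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    states <- vector("list", n_tip + tree$Nnode)
    states[[root]] <- sample.int(4, cfg$seq_length, replace = TRUE, prob = pi)
    ord <- ape::reorder.phylo(tree, "cladewise")$edge
    lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (k in seq_len(nrow(ord))) {
      parent <- ord[k, 1]; child <- ord[k, 2]
      P <- tn93_P(lens[k], cfg$kappa1, cfg$kappa2, pi)
      x <- states[[parent]]
      y <- integer(length(x))
      for (s in 1:4) {
        at <- which(x == s)
        if (length(at) > 0) {
          y[at] <- sample.int(4, length(at), replace = TRUE, prob = P[s, ])
        }
      }
      states[[child]] <- y
    }
    m <- do.call(rbind, lapply(seq_len(n_tip),
                               function(i) VALID_BASES[states[[i]]]))
    rownames(m) <- tree$tip.label
    if (cfg$gap_rate > 0) {
      mask_seed <- stage_seed(cfg, "mask")
      m <- with_preserved_seed(mask_seed, {
        hit <- matrix(runif(length(m)) < cfg$gap_rate, nrow(m))
        m[hit] <- "-"
        m
      })
    }
    alignment(m)
  })
}

#' Generate a synthetic annotated circular mitogenome
#'
#' Emulates the canonical vertebrate layout: `layout$n_pcg` protein-coding
#' genes whose sequences genuinely begin with their declared start codon
#' and end with their declared (complete or incomplete) stop, tRNA/rRNA
#' genes, and one control region, placed contiguously with short random
#' spacers on a circular molecule. A configurable fraction of genes is
#' annotated on the L strand, in which case the genome stores the reverse
#' complement of the gene's sense sequence. Feature table and FASTA
#' round-trip losslessly through [write_feature_table()] /
#' [read_feature_table()].
#'
#' @param cfg A [sim_config()].
#' @return A [mito_genome].
#' @export
synth_genome <- function(cfg) {
  lay <- cfg$layout
  with_preserved_seed(stage_seed(cfg, "genome"), {
    code <- mito_genetic_code()
    sense <- gsub("U", "T", code$codon[code$aa != "Stop"])
    specs <- c(
      lapply(seq_len(lay$n_pcg), function(i) list(
        name = sprintf("PCG%02d", i), class = "PCG",
        len = NA)),
      lapply(seq_len(lay$n_trna), function(i) list(
        name = sprintf("tRNA-X%02d", i), class = "tRNA", len = 68L)),
      lapply(seq_len(lay$n_rrna), function(i) list(
        name = sprintf("rRNA%d", i), class = "rRNA", len = 1000L)),
      lapply(seq_len(lay$n_control), function(i) list(
        name = "D-loop", class = "control_region", len = 900L))
    )
    feats <- list()
    chunks <- character(0)
    at <- 0L
    for (sp in specs) {
      if (sp$class == "PCG") {
        start_codon <- sample(c("ATG", "ATA", "ATT"), 1)
        incomplete <- runif(1) < lay$incomplete_stop_fraction
        stop_tok <- if (incomplete) sample(c("TA-", "T--"), 1) else
          sample(c("TAA", "AGA"), 1)
        n_codons <- sample(80:400, 1)
        body <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
        gene_seq <- paste0(start_codon, body, gsub("-", "", stop_tok))
        strand <- if (runif(1) < lay$l_strand_fraction) "L" else "H"
        sc <- start_codon; st <- stop_tok
      } else {
        gene_seq <- paste(sample(VALID_BASES, sp$len, replace = TRUE,
                                 prob = cfg$pi), collapse = "")
        strand <- if (sp$class == "tRNA" &&
                        runif(1) < lay$l_strand_fraction) "L" else "H"
        sc <- NA_character_; st <- NA_character_
      }
      genome_seq <- if (strand == "L") revcomp(gene_seq) else gene_seq
      spacer <- paste(sample(VALID_BASES, sample(0:5, 1), replace = TRUE),
                      collapse = "")
      chunks <- c(chunks, spacer, genome_seq)
      at <- at + nchar(spacer)
      feats[[length(feats) + 1]] <- tibble(
        name = sp$name, class = sp$class, strand = strand,
        start = at + 1L, end = at + nchar(genome_seq),
        start_codon = sc, stop_codon = st)
      at <- at + nchar(genome_seq)
    }
    mito_genome(identifier = sprintf("synthetic-mitogenome-seed%d", cfg$seed),
                features = bind_rows(feats),
                sequence = paste(chunks, collapse = ""), circular = TRUE)
  })
}
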