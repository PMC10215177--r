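#' The packaged *Myotis aurascens* mitogenome annotation
#'
#' Loads the published 16,771-bp genome organization table (37 features:
#' 13 PCGs, 22 tRNAs, 2 rRNAs, D-loop) shipped with the package, in
#' sequence-free mode: per-feature and whole-genome base compositions come
#' from the printed percentages, so every roll-up statistic is available
#' without the GenBank record itself.
#'
#' @return A [mito_genome] (sequence-free).
#' @export
#' @examples
#' g <- maurascens_genome()
#' class_totals(g)
maurascens_genome <- function() {
  read_feature_table(system.file("extdata", "maurascens_features.tsv",
                                 package = "mitophylo"))
}

#' Characterize one annotated mitogenome
#'
#' End-to-end roll-up of a genome's annotation: per-feature composition
#' and skews, whole-genome composition, feature-class length totals, and —
#' when a sequence is present — codon usage and RSCU over the PCGs and the
#' identified start/stop codons per PCG. With `out_dir` the tables are
#' also written as TSV files.
#'
#' @param genome A [mito_genome].
#' @param out_dir Optional output directory for TSV reports.
#' @return A named list of tibbles: `composition`, `class_totals`, and if
#'   sequence is available `codon_usage` (with RSCU) and `pcg_codons`.
#' @export
run_characterize <- function(genome, out_dir = NULL) {
  inform(sprintf("characterizing %s", genome$identifier))
  reports <- list(
    composition = genome_composition(genome),
    class_totals = class_totals(genome)
  )
  if (!is.null(genome$sequence)) {
    reports$codon_usage <- genome_rscu(genome)
    pcgs <- genome$features |> filter(.data$class == "PCG")
    reports$pcg_codons <- bind_rows(lapply(seq_len(nrow(pcgs)), function(i) {
      dplyr::bind_cols(tibble(name = pcgs$name[i]),
                       identify_codons(extract_gene(genome, pcgs[i, ])))
    }))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(reports)) {
      readr::write_tsv(as_tibble(reports[[nm]]),
                       file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  reports
}

#' Distances and NJ tree over a set of per-gene alignments
#'
#' Concatenates the per-gene alignments into a supermatrix (default
#' excluding ND6, the anomalous L-strand PCG), computes p and maximum
#' composite likelihood distance matrices, renders them in the combined
#' journal layout (ML above the diagonal, p below), and builds an NJ tree
#' with bootstrap support. With fewer than 3 taxa the tree stage is
#' skipped with a warning. With `out_dir`, PHYLIP matrices, the combined
#' table and the Newick tree are written.
#'
#' @param genes Named list of per-gene alignments.
#' @param exclude Genes dropped from the supermatrix (default `"ND6"`).
#' @param bootstrap Bootstrap replicates for the NJ tree (0 = no supports).
#' @param seed Seed for the bootstrap.
#' @param tree_estimator Distance estimator used for the tree stage.
#' @param out_dir Optional output directory.
#' @return List: `supermatrix`, `p` and `mcl` (`mito_dist`), `combined`
#'   (matrix, ML above / p below), `tree` (phylo or NULL).
#' @export
run_distances <- function(genes, exclude = "ND6", bootstrap = 1000,
                          seed = 1, tree_estimator = "p", out_dir = NULL) {
  aln <- concatenate(genes, exclude = exclude)
  inform(sprintf("supermatrix: %d taxa x %d sites (%d genes)",
                 nrow(aln), ncol(aln),
                 nrow(attr(aln, "partition", exact = TRUE))))
  p <- dist_p(aln)
  mcl <- dist_mcl(aln)
  combined <- combined_triangle(mcl, p)
  tree <- NULL
  if (nrow(aln) >= 3) {
    tree <- if (bootstrap > 0) {
      bootstrap_support(aln, estimator = tree_estimator, n_reps = bootstrap,
                        seed = seed)
    } else {
      neighbor_joining(switch(tree_estimator, p = p, mcl = mcl,
                              tn93 = dist_tn93(aln)))
    }
  } else {
    warn("fewer than 3 taxa: tree stage skipped")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_phylip(p, file.path(out_dir, "distances_p.phy"))
    write_phylip(mcl, file.path(out_dir, "distances_mcl.phy"))
    readr::write_tsv(
      as_tibble(as.data.frame(combined), rownames = "species"),
      file.path(out_dir, "distances_combined.tsv"))
    if (!is.null(tree)) {
      ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
    }
  }
  list(supermatrix = aln, p = p, mcl = mcl, combined = combined, tree = tree)
}

#' Combined upper/lower-triangle distance table
#'
#' The journal-style presentation: one square table carrying the model
#' distances (e.g. ML/MCL) above the diagonal and p-distances below, with
#' `NA` on the diagonal.
#'
#' @param upper,lower `mito_dist` objects on the same label set.
#' @return A numeric matrix.
#' @export
combined_triangle <- function(upper, lower) {
  if (!identical(upper$labels, lower$labels)) {
    abort("distance matrices have different label sets")
  }
  out <- upper$values
  out[lower.tri(out)] <- lower$values[lower.tri(out)]
  diag(out) <- NA
  out
}
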