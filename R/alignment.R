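#' Multiple sequence alignments
#'
#' A `mito_alignment` is a character matrix of single upper-case nucleotide
#' symbols, taxa in rows (unique rownames), sites in columns, with an
#' optional `partition` attribute — a tibble `gene`, `start`, `end` mapping
#' genes of a concatenated supermatrix to column ranges.
#'
#' @param seqs Named character vector of equal-length (gapped) sequences,
#'   or a character matrix with rownames.
#' @param partition Optional partition tibble.
#' @return A `mito_alignment`.
#' @export
alignment <- function(seqs, partition = NULL) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      abort("sequences must carry unique taxon names")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      abort("alignment rows must all have equal length")
    }
    m <- t(vapply(toupper(seqs), function(s) strsplit(s, "")[[1]],
                  character(lens[1])))
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    abort("alignment matrix needs unique rownames")
  }
  m[m == "U"] <- "T"
  structure(m, partition = partition, class = c("mito_alignment", "matrix"))
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat(sprintf("<mito_alignment> %d taxa x %d sites\n", nrow(x), ncol(x)))
  part <- attr(x, "partition", exact = TRUE)
  if (!is.null(part)) {
    cat("  partitions: ",
        paste(sprintf("%s [%d-%d]", part$gene, part$start, part$end),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read / write multi-FASTA alignments
#'
#' Thin wrappers around ape's FASTA IO returning/accepting
#' [alignment()] objects.
#'
#' @param path FASTA path.
#' @return `read_alignment()`: a `mito_alignment`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) abort(paste0("no sequences in ", path))
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  alignment(setNames(toupper(seqs), names(dna)))
}

#' @rdname read_alignment
#' @param aln A `mito_alignment`.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Columns are appended gene by gene in the order given; a `partition`
#' attribute records each gene's column range. Taxa missing from a gene are
#' filled with gap rows (logged), so downstream pairwise-deletion distances
#' simply ignore those blocks. Supermatrix analyses of mitochondrial PCGs
#' conventionally drop ND6, the one L-strand protein gene, for its
#' anomalous composition; pass `exclude = "ND6"` to do so.
#'
#' @param genes Named list of `mito_alignment` (or named character vector)
#'   objects, one per gene.
#' @param exclude Character vector of gene names to drop.
#' @return A concatenated `mito_alignment`.
#' @export
concatenate <- function(genes, exclude = character()) {
  if (is.null(names(genes)) || anyDuplicated(names(genes))) {
    abort("`genes` must be a uniquely named list of alignments")
  }
  genes <- genes[setdiff(names(genes), exclude)]
  if (length(genes) == 0) abort("no genes left after exclusion")
  genes <- lapply(genes, function(g) {
    if (!inherits(g, "mito_alignment")) alignment(g) else g
  })
  taxa <- unique(unlist(lapply(genes, rownames)))
  for (g in names(genes)) {
    if (anyDuplicated(rownames(genes[[g]]))) {
      abort(paste0("duplicate taxon labels in gene ", g))
    }
  }
  blocks <- list()
  part <- list()
  at <- 0L
  for (g in names(genes)) {
    m <- unclass(genes[[g]])
    absent <- setdiff(taxa, rownames(m))
    if (length(absent) > 0) {
      inform(sprintf("gene %s: gap-filling %d absent taxa", g,
                     length(absent)))
      fill <- matrix("-", nrow = length(absent), ncol = ncol(m),
                     dimnames = list(absent, NULL))
      m <- rbind(m, fill)
    }
    m <- m[taxa, , drop = FALSE]
    blocks[[g]] <- m
    part[[g]] <- tibble(gene = g, start = at + 1L, end = at + ncol(m))
    at <- at + ncol(m)
  }
  alignment(do.call(cbind, blocks), partition = bind_rows(part))
}
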