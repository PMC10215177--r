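#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' \eqn{Q_{ij} = (r-2) d_{ij} - R_i - R_j}: at each step the pair
#' minimizing Q is joined, branch lengths follow the usual three-point
#' formulas, and the reduced matrix uses
#' \eqn{d_{uk} = (d_{ik} + d_{jk} - d_{ij})/2}. Ties on Q are broken
#' deterministically in favor of the lowest index pair (row-major over the
#' current matrix order, which preserves input label order). Negative
#' branch lengths are clamped to zero. NJ is exact on additive matrices:
#' it recovers the generating topology and all path lengths.
#'
#' @param dm A `mito_dist` or a symmetric numeric matrix with dimnames.
#' @return An unrooted `phylo` (ape) tree with branch lengths.
#' @export
#' @examples
#' d <- matrix(c(0, 3, 5, 6,
#'               3, 0, 6, 7,
#'               5, 6, 0, 7,
#'               6, 7, 7, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighbor_joining(d)
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "mito_dist")) dm$values else as.matrix(dm)
  if (nrow(d) < 3) abort("need at least 3 taxa for a tree")
  if (anyNA(d)) {
    abort(paste0("distance matrix contains missing values; review ",
                 "pairwise deletion (some pair may share no valid sites ",
                 "or be saturated)"))
  }
  n <- nrow(d)
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  # each active cluster carries a growing newick substring
  nwk <- labels
  while (nrow(d) > 3) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf            # row-major over i < j
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[[1]]; j <- best[[2]]
    vi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- d[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], vi, nwk[j], vj)
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    rn <- c(rownames(d)[keep], sprintf("joined%d", r))
    dimnames(d2) <- list(rn, rn)
    d <- d2
    nwk <- c(nwk[keep], merged)
  }
  v1 <- max((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)
  v2 <- max((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)
  v3 <- max((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nwk[1], v1, nwk[2], v2, nwk[3], v3)
  ape::read.tree(text = txt)
}

#' Nonparametric bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement (ignoring partitions, the
#' standard site bootstrap), rebuilds an NJ tree per replicate with the
#' chosen distance estimator, and reports for each internal edge of the
#' original tree the percentage of replicates whose tree contains the same
#' bipartition. Fully reproducible under a fixed seed.
#'
#' @param aln A [alignment()].
#' @param estimator One of `"p"`, `"tn93"`, `"mcl"`.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return The NJ tree of the full alignment, an ape `phylo` whose
#'   `node.label` holds the support percentages (root label empty).
#' @export
bootstrap_support <- function(aln, estimator = c("p", "tn93", "mcl"),
                              n_reps = 1000, seed = 1) {
  estimator <- match.arg(estimator)
  if (n_reps < 1) abort("n_reps must be >= 1")
  m <- as_aln_matrix(aln)
  dist_fn <- switch(estimator, p = dist_p, tn93 = dist_tn93, mcl = dist_mcl)
  main <- neighbor_joining(dist_fn(alignment(m)))
  boot_trees <- with_preserved_seed(seed, {
    lapply(seq_len(n_reps), function(rep) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      neighbor_joining(dist_fn(alignment(m[, cols, drop = FALSE])))
    })
  })
  counts <- ape::prop.clades(main, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  support[1] <- NA  # the arbitrary basal node of an unrooted tree
  main$node.label <- ifelse(is.na(support), "", as.character(support))
  attr(main, "n_reps") <- n_reps
  attr(main, "estimator") <- estimator
  main
}

# evaluate code with a fixed seed without disturbing the caller's RNG state
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
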