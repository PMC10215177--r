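#' Pairwise genetic distances
#'
#' Three estimators over aligned nucleotide sequences, all under pairwise
#' deletion (per pair, only columns where both taxa have an unambiguous
#' A/C/G/T are used):
#'
#' * **p** — the proportion of differing valid sites.
#' * **tn93** — the closed-form Tamura-Nei (1993) distance, which corrects
#'   p for multiple hits distinguishing the two transition classes
#'   (purine A<->G, pyrimidine C<->T) from transversions, with unequal
#'   base frequencies.
#' * **mcl** — maximum composite likelihood distances under the same TN93
#'   model: the two transition/transversion rate ratios are shared across
#'   all pairs and estimated by maximizing the sum of pairwise
#'   log-likelihoods; each pair's distance is then its conditional maximum
#'   likelihood estimate under the shared rates. This is the estimator
#'   MEGA labels "maximum composite likelihood".
#'
#' @param aln A [alignment()] (or named character vector of equal-length
#'   sequences).
#' @return A `mito_dist` object: list with `labels`, `values` (symmetric
#'   matrix, zero diagonal), `estimator`, `n_sites` (valid sites per pair),
#'   and for `dist_mcl` the fitted `rates` (kappa1 = alpha1/beta,
#'   kappa2 = alpha2/beta) and pooled frequencies `pi`.
#' @name distances
NULL

VALID_BASES <- c("A", "C", "G", "T")

as_aln_matrix <- function(aln) {
  if (!inherits(aln, "mito_alignment")) aln <- alignment(aln)
  unclass(aln)
}

new_mito_dist <- function(values, n_sites, estimator, ...) {
  structure(list(labels = rownames(values), values = values,
                 n_sites = n_sites, estimator = estimator, ...),
            class = "mito_dist")
}

#' @export
print.mito_dist <- function(x, ...) {
  cat(sprintf("<mito_dist> %s distances, %d taxa\n", x$estimator,
              length(x$labels)))
  print(round(x$values, 4))
  invisible(x)
}

#' p-distance between two aligned rows
#'
#' Mismatches over valid sites, where a valid site has an unambiguous
#' A/C/G/T in both rows (pairwise deletion). Zero valid sites yields `NA`.
#'
#' @param a,b Equal-length character vectors of single bases, or strings.
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
#' @examples
#' p_distance("ACGTACGT", "ACGTACGA")
p_distance <- function(a, b) {
  ab <- pair_chars(a, b)
  ok <- ab$a %in% VALID_BASES & ab$b %in% VALID_BASES
  if (!any(ok)) return(NA_real_)
  mean(ab$a[ok] != ab$b[ok])
}

pair_chars <- function(a, b) {
  if (is.character(a) && length(a) == 1) a <- strsplit(toupper(a), "")[[1]]
  if (is.character(b) && length(b) == 1) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) abort("rows differ in length")
  list(a = chartr("U", "T", a), b = chartr("U", "T", b))
}

# 4x4 site-pattern count matrix over valid columns (rows = a, cols = b)
pair_counts <- function(a, b) {
  ab <- pair_chars(a, b)
  ok <- ab$a %in% VALID_BASES & ab$b %in% VALID_BASES
  table(factor(ab$a[ok], VALID_BASES), factor(ab$b[ok], VALID_BASES))
}

#' Closed-form TN93 distance between two aligned rows
#'
#' Uses the analytic Tamura-Nei (1993) formula from the purine-transition
#' proportion P1, pyrimidine-transition proportion P2 and transversion
#' proportion Q, with base frequencies pooled over the two rows. Saturated
#' inputs where a logarithm argument is non-positive return `NA` with a
#' warning.
#'
#' @inheritParams p_distance
#' @return Distance in substitutions/site, or `NA` when undefined.
#' @export
tn93_distance <- function(a, b) {
  N <- pair_counts(a, b)
  n <- sum(N)
  if (n == 0) return(NA_real_)
  freq <- (rowSums(N) + colSums(N)) / (2 * n)
  tn93_from_counts(N / n, freq)
}

tn93_from_counts <- function(Pmat, freq) {
  piA <- freq[["A"]]; piC <- freq[["C"]]; piG <- freq[["G"]]; piT <- freq[["T"]]
  piR <- piA + piG; piY <- piC + piT
  P1 <- Pmat["A", "G"] + Pmat["G", "A"]
  P2 <- Pmat["C", "T"] + Pmat["T", "C"]
  Q <- sum(Pmat) - sum(diag(Pmat)) - P1 - P2
  if (piA * piG == 0 || piC * piT == 0 || piR * piY == 0) return(NA_real_)
  w1 <- 1 - piR * P1 / (2 * piA * piG) - Q / (2 * piR)
  w2 <- 1 - piY * P2 / (2 * piC * piT) - Q / (2 * piY)
  w3 <- 1 - Q / (2 * piR * piY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    warn("TN93 distance undefined (saturated pair); returning NA")
    return(NA_real_)
  }
  k1 <- 2 * piA * piG / piR
  k2 <- 2 * piC * piT / piY
  k3 <- 2 * (piR * piY - piA * piG * piY / piR - piC * piT * piR / piY)
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

#' @rdname distances
#' @export
dist_p <- function(aln) {
  m <- as_aln_matrix(aln)
  pairwise_matrix(m, p_distance, "p")
}

#' @rdname distances
#' @export
dist_tn93 <- function(aln) {
  m <- as_aln_matrix(aln)
  pairwise_matrix(m, tn93_distance, "tn93")
}

pairwise_matrix <- function(m, fn, estimator) {
  nt <- nrow(m)
  if (nt < 2) abort("need at least 2 taxa")
  d <- matrix(0, nt, nt, dimnames = list(rownames(m), rownames(m)))
  ns <- matrix(ncol(m), nt, nt, dimnames = dimnames(d))
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      d[i, j] <- d[j, i] <- fn(m[i, ], m[j, ])
      ok <- m[i, ] %in% VALID_BASES & m[j, ] %in% VALID_BASES
      ns[i, j] <- ns[j, i] <- sum(ok)
    }
  }
  new_mito_dist(d, ns, estimator)
}

# ---- TN93 model machinery ---------------------------------------------------

# TN93 transition-probability matrix P(d) at distance d (expected
# substitutions/site), rate ratios k1 = alpha1/beta (purine transitions),
# k2 = alpha2/beta (pyrimidine), equilibrium frequencies pi (A,C,G,T order).
tn93_P <- function(d, k1, k2, pi) {
  piA <- pi[["A"]]; piC <- pi[["C"]]; piG <- pi[["G"]]; piT <- pi[["T"]]
  piR <- piA + piG; piY <- piC + piT
  mu <- 2 * piA * piG * k1 + 2 * piC * piT * k2 + 2 * piR * piY  # beta = 1
  t <- d / mu
  e1 <- exp(-t)
  e2 <- exp(-(piR * k1 + piY) * t)
  e3 <- exp(-(piY * k2 + piR) * t)
  P <- matrix(0, 4, 4, dimnames = list(VALID_BASES, VALID_BASES))
  # transversions
  P["A", "C"] <- P["G", "C"] <- piC * (1 - e1)
  P["A", "T"] <- P["G", "T"] <- piT * (1 - e1)
  P["C", "A"] <- P["T", "A"] <- piA * (1 - e1)
  P["C", "G"] <- P["T", "G"] <- piG * (1 - e1)
  # purines
  P["A", "A"] <- piA + piA * piY / piR * e1 + piG / piR * e2
  P["A", "G"] <- piG + piG * piY / piR * e1 - piG / piR * e2
  P["G", "A"] <- piA + piA * piY / piR * e1 - piA / piR * e2
  P["G", "G"] <- piG + piG * piY / piR * e1 + piA / piR * e2
  # pyrimidines
  P["C", "C"] <- piC + piC * piR / piY * e1 + piT / piY * e3
  P["C", "T"] <- piT + piT * piR / piY * e1 - piT / piY * e3
  P["T", "C"] <- piC + piC * piR / piY * e1 - piC / piY * e3
  P["T", "T"] <- piT + piT * piR / piY * e1 + piC / piY * e3
  P
}

# log-likelihood of a pair's 4x4 pattern counts at distance d
tn93_pair_loglik <- function(d, k1, k2, pi, N) {
  P <- tn93_P(d, k1, k2, pi)
  L <- pi * P  # joint probability pi_i * P_ij
  sum(N[N > 0] * log(pmax(L[N > 0], 1e-300)))
}

# conditional MLE of a pair distance given shared rates
tn93_pair_mle <- function(k1, k2, pi, N, upper = 10) {
  if (sum(N) - sum(diag(N)) == 0) return(0)
  opt <- optimise(function(d) -tn93_pair_loglik(d, k1, k2, pi, N),
                  interval = c(1e-9, upper))
  opt$minimum
}

pooled_frequencies <- function(m) {
  chars <- as.vector(m)
  chars <- chars[chars %in% VALID_BASES]
  tab <- table(factor(chars, VALID_BASES))
  as.numeric(tab / sum(tab)) |> setNames(VALID_BASES)
}

#' @rdname distances
#' @param control List of optimizer settings: `maxit` (outer Nelder-Mead
#'   iterations), `reltol`.
#' @export
dist_mcl <- function(aln, control = list(maxit = 500, reltol = 1e-10)) {
  m <- as_aln_matrix(aln)
  nt <- nrow(m)
  if (nt < 2) abort("need at least 2 taxa")
  pi <- pooled_frequencies(m)
  pairs <- utils::combn(nt, 2)
  Ns <- lapply(seq_len(ncol(pairs)), function(k) {
    unclass(pair_counts(m[pairs[1, k], ], m[pairs[2, k], ]))
  })
  neg_composite <- function(logk) {
    k1 <- exp(logk[1]); k2 <- exp(logk[2])
    -sum(vapply(Ns, function(N) {
      tn93_pair_loglik(tn93_pair_mle(k1, k2, pi, N), k1, k2, pi, N)
    }, numeric(1)))
  }
  fit <- optim(c(log(2), log(2)), neg_composite, method = "Nelder-Mead",
               control = list(maxit = control$maxit %||% 500,
                              reltol = control$reltol %||% 1e-10))
  if (fit$convergence != 0) {
    abort(sprintf(paste0("composite-likelihood optimizer failed to converge",
                         " (code %d) at maxit=%d, reltol=%g"),
                  fit$convergence, control$maxit %||% 500,
                  control$reltol %||% 1e-10))
  }
  k1 <- exp(fit$par[1]); k2 <- exp(fit$par[2])
  d <- matrix(0, nt, nt, dimnames = list(rownames(m), rownames(m)))
  ns <- matrix(ncol(m), nt, nt, dimnames = dimnames(d))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d[i, j] <- d[j, i] <- tn93_pair_mle(k1, k2, pi, Ns[[k]])
    ns[i, j] <- ns[j, i] <- sum(Ns[[k]])
  }
  new_mito_dist(d, ns, "mcl", rates = c(kappa1 = k1, kappa2 = k2), pi = pi)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param dm A `mito_dist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  n <- length(dm$labels)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(dm$labels[i], width = -10),
                      paste(sprintf("%.6f", dm$values[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
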