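#' Mitogenome objects
#'
#' A `mito_genome` bundles a (possibly absent) nucleotide sequence with an
#' ordered feature table describing the canonical 37-gene vertebrate
#' mitochondrial layout: 13 protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs
#' and the control region (D-loop). Coordinates are 1-based inclusive, the
#' GenBank convention. On a circular genome a feature may wrap the origin,
#' in which case `end < start` and the feature occupies
#' `[start..length] + [1..end]`.
#'
#' Features live in a tibble with columns `name`, `class` (one of `PCG`,
#' `tRNA`, `rRNA`, `control_region`), `strand` (`H` or `L`), `start`, `end`,
#' `size`, `start_codon`, `stop_codon`, plus optional per-feature base
#' composition percentages (`pct_A`, `pct_C`, `pct_G`, `pct_T`) used in
#' sequence-free mode.
#'
#' @param identifier Free-text accession or name.
#' @param features Feature tibble (see Details); minimally `name`, `class`,
#'   `strand`, `start`, `end`.
#' @param sequence Nucleotide string (IUPAC codes allowed), or `NULL` for
#'   sequence-free statistics mode.
#' @param length Genome length in bp; required when `sequence` is `NULL`,
#'   otherwise derived from the sequence.
#' @param circular Is the molecule circular?
#' @param composition Optional named numeric (A, C, G, T) whole-genome base
#'   percentages for sequence-free mode.
#' @return An object of class `mito_genome`.
#' @export
mito_genome <- function(identifier, features, sequence = NULL, length = NULL,
                        circular = TRUE, composition = NULL) {
  features <- validate_features(features)
  if (!is.null(sequence)) {
    sequence <- toupper(gsub("[[:space:]]", "", sequence))
    sequence <- chartr("U", "T", sequence)
    if (nchar(sequence) < 1L) abort("sequence must have length >= 1")
    length <- nchar(sequence)
  }
  if (is.null(length)) abort("either `sequence` or `length` must be supplied")
  bad <- features$start < 1L | features$start > length |
    features$end < 1L | features$end > length
  if (any(bad)) {
    abort(sprintf("feature(s) %s have coordinates outside [1, %d]",
                  paste(features$name[bad], collapse = ", "), length))
  }
  wraps <- features$end < features$start
  if (any(wraps) && !circular) {
    abort(sprintf("feature '%s' has end < start on a linear genome",
                  features$name[which(wraps)[1]]))
  }
  features$size <- ifelse(wraps,
                          length - features$start + 1L + features$end,
                          features$end - features$start + 1L)
  structure(
    list(identifier = identifier, sequence = sequence, length = length,
         is_circular = circular, features = features,
         composition = composition),
    class = "mito_genome"
  )
}

validate_features <- function(features) {
  features <- as_tibble(features)
  needed <- c("name", "class", "strand", "start", "end")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("feature table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(features) == 0L) abort("feature table is empty")
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (anyNA(features$start) || anyNA(features$end)) {
    abort("malformed coordinates: non-numeric start/end")
  }
  bad_strand <- !features$strand %in% c("H", "L")
  if (any(bad_strand)) {
    abort(sprintf("invalid strand '%s' for feature '%s' (must be H or L)",
                  features$strand[bad_strand][1],
                  features$name[bad_strand][1]))
  }
  known <- c("PCG", "tRNA", "rRNA", "control_region")
  bad_class <- !features$class %in% known
  if (any(bad_class)) {
    abort(sprintf("unknown feature class '%s' (feature '%s')",
                  features$class[bad_class][1], features$name[bad_class][1]))
  }
  for (col in c("start_codon", "stop_codon")) {
    if (!col %in% names(features)) features[[col]] <- NA_character_
    features[[col]][features[[col]] %in% c("-", "")] <- NA_character_
  }
  features
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s\n", x$identifier))
  cat(sprintf("  %s, %d bp, %d features%s\n",
              if (x$is_circular) "circular" else "linear",
              x$length, nrow(x$features),
              if (is.null(x$sequence)) " (sequence-free)" else ""))
  tab <- table(x$features$class)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
format.mito_genome <- function(x, ...) {
  sprintf("<mito_genome %s: %d bp, %d features>", x$identifier, x$length,
          nrow(x$features))
}

# ---- gene-name normalization ------------------------------------------------

#' Normalize mitochondrial gene names to the canonical vocabulary
#'
#' Maps the many spellings found in GenBank records and printed tables
#' (e.g. `COI`, `cox1`, `CYTB`, `trnF`, `tRNA-Ser(UCN)`, `s-rRNA`) onto one
#' canonical set: `ND1`..`ND6`, `ND4L`, `COX1`..`COX3`, `ATP6`, `ATP8`,
#' `Cytb`, `12S_rRNA`, `16S_rRNA`, `D-loop`, and `tRNA-Xaa` with the
#' Leu1/Leu2 and Ser1/Ser2 paralogs disambiguated by anticodon where the
#' input carries one (Leu2 = UUR, Leu1 = CUN; Ser1 = AGY, Ser2 = UCN).
#' Unrecognized names are returned unchanged.
#'
#' @param x Character vector of gene names.
#' @return Character vector of canonical names.
#' @export
normalize_gene_name <- function(x) {
  vapply(x, normalize_one_name, character(1), USE.NAMES = FALSE)
}

normalize_one_name <- function(nm) {
  raw <- nm
  s <- toupper(gsub("[[:space:]*^]", "", nm))
  s <- gsub("[()]", "", s)
  direct <- c(
    "NAD1" = "ND1", "NAD2" = "ND2", "NAD3" = "ND3", "NAD4" = "ND4",
    "NAD4L" = "ND4L", "NAD5" = "ND5", "NAD6" = "ND6",
    "COI" = "COX1", "COII" = "COX2", "COIII" = "COX3",
    "CO1" = "COX1", "CO2" = "COX2", "CO3" = "COX3",
    "COXI" = "COX1", "COXII" = "COX2", "COXIII" = "COX3",
    "CYTB" = "Cytb", "COB" = "Cytb", "CYB" = "Cytb",
    "ATPASE6" = "ATP6", "ATPASE8" = "ATP8",
    "DLOOP" = "D-loop", "D-LOOP" = "D-loop", "CR" = "D-loop",
    "CONTROLREGION" = "D-loop", "MISC_FEATURE" = "D-loop",
    "RRNS" = "12S_rRNA", "RRNL" = "16S_rRNA",
    "S-RRNA" = "12S_rRNA", "L-RRNA" = "16S_rRNA",
    "12S" = "12S_rRNA", "16S" = "16S_rRNA",
    "12SRRNA" = "12S_rRNA", "16SRRNA" = "16S_rRNA",
    "12S_RRNA" = "12S_rRNA", "16S_RRNA" = "16S_rRNA",
    "12SRIBOSOMALRNA" = "12S_rRNA", "16SRIBOSOMALRNA" = "16S_rRNA"
  )
  if (s %in% names(direct)) return(unname(direct[[s]]))
  if (s %in% c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
               "COX1", "COX2", "COX3", "ATP6", "ATP8")) {
    return(s)
  }
  trna <- parse_trna_name(s)
  if (!is.na(trna)) return(trna)
  raw
}

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V")

parse_trna_name <- function(s) {
  m <- regmatches(s, regexec(
    "^(?:TRNA-?|TRN)([A-Z]{1,3})([12])?-?([ACGU]{3})?$", s, perl = TRUE))[[1]]
  if (length(m) == 0) return(NA_character_)
  aa_tok <- m[2]; idx <- m[3]; anticodon <- m[4]
  aa <- NA_character_
  if (nchar(aa_tok) == 3 && aa_tok %in% toupper(names(AA3))) {
    aa <- names(AA3)[match(aa_tok, toupper(names(AA3)))]
  } else if (nchar(aa_tok) == 1 && aa_tok %in% AA3) {
    aa <- names(AA3)[match(aa_tok, AA3)]
  }
  if (is.na(aa)) return(NA_character_)
  if (aa %in% c("Leu", "Ser")) {
    if (nzchar(idx)) return(paste0("tRNA-", aa, idx))
    if (nchar(anticodon) == 3) {
      # Leu2 reads UUR codons (anticodon UAA/TAA), Leu1 reads CUN;
      # Ser1 reads AGY (anticodon GCU), Ser2 reads UCN
      if (aa == "Leu") {
        return(if (substr(anticodon, 1, 2) %in% c("UA", "TA"))
          "tRNA-Leu2" else "tRNA-Leu1")
      }
      return(if (substr(anticodon, 1, 1) %in% c("G"))
        "tRNA-Ser1" else "tRNA-Ser2")
    }
    return(paste0("tRNA-", aa))
  }
  paste0("tRNA-", aa)
}

# ---- feature-table IO -------------------------------------------------------

#' Read a mitogenome feature table
#'
#' Reads the package's tab-separated feature-table format: a header line
#' `name class strand start end start_codon stop_codon` (optionally followed
#' by per-feature composition columns `pct_A pct_C pct_G pct_T`), preceded by
#' optional `#`-comment metadata lines (`# identifier:`, `# length:`,
#' `# circular:`, `# composition: A=.. C=.. G=.. T=..`). An accompanying
#' FASTA file may supply the sequence; without one the genome is loaded in
#' sequence-free mode and downstream statistics use the declared
#' composition columns.
#'
#' @param path Path to the TSV feature table.
#' @param fasta Optional path to a single-record FASTA with the genome
#'   sequence.
#' @return A [mito_genome].
#' @export
#' @examples
#' tab2 <- system.file("extdata", "maurascens_features.tsv",
#'                     package = "mitophylo")
#' g <- read_feature_table(tab2)
#' g
read_feature_table <- function(path, fasta = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    abort(paste0("empty feature table: ", path))
  }
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- parse_feature_meta(meta_lines)
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2) abort(paste0("feature table has no data rows: ", path))
  features <- readr::read_tsv(I(paste(body, collapse = "\n")),
                              col_types = readr::cols(),
                              progress = FALSE)
  features <- tryCatch(
    validate_features(features),
    error = function(e) abort(paste0("parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  sequence <- NULL
  if (!is.null(fasta)) sequence <- read_fasta_single(fasta)
  inform(sprintf("read %d features from %s", nrow(features), basename(path)))
  mito_genome(
    identifier = meta$identifier %||% basename(path),
    features = features, sequence = sequence,
    length = if (is.null(sequence)) {
      meta$length %||% max(features$end)
    },
    circular = meta$circular %||% TRUE,
    composition = meta$composition
  )
}

parse_feature_meta <- function(lines) {
  get <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  comp <- NULL
  comp_raw <- get("composition")
  if (!is.null(comp_raw)) {
    pairs <- regmatches(comp_raw,
                        gregexpr("[ACGT]=[0-9.]+", comp_raw))[[1]]
    comp <- setNames(as.numeric(sub("^[ACGT]=", "", pairs)),
                     substr(pairs, 1, 1))
  }
  len <- get("length")
  circ <- get("circular")
  list(identifier = get("identifier"),
       length = if (!is.null(len)) as.integer(gsub(",", "", len)),
       circular = if (!is.null(circ)) tolower(circ) %in% c("true", "yes", "1"),
       composition = comp)
}

#' Write a mitogenome feature table
#'
#' Inverse of [read_feature_table()]; metadata is emitted as `#` comment
#' lines so a round trip is lossless.
#'
#' @param genome A [mito_genome].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genome, path) {
  meta <- c(
    paste0("# identifier: ", genome$identifier),
    paste0("# length: ", genome$length),
    paste0("# circular: ", tolower(genome$is_circular))
  )
  if (!is.null(genome$composition)) {
    meta <- c(meta, paste0(
      "# composition: ",
      paste(sprintf("%s=%s", names(genome$composition),
                    format(genome$composition, trim = TRUE)),
            collapse = " ")))
  }
  feats <- genome$features
  feats$start_codon[is.na(feats$start_codon)] <- "-"
  feats$stop_codon[is.na(feats$stop_codon)] <- "-"
  body <- readr::format_tsv(feats)
  writeLines(c(meta, sub("\n$", "", body)), path)
  invisible(path)
}

read_fasta_single <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) abort(paste0("no sequences in ", path))
  if (length(dna) > 1) warn(paste0("multiple records in ", path,
                                   "; using the first"))
  toupper(paste(as.character(dna)[[1]], collapse = ""))
}

# ---- GenBank flat-file reader ----------------------------------------------

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Minimal parser for local GenBank flat files: takes the ORIGIN sequence
#' and the `gene`/`CDS`/`tRNA`/`rRNA`/`D-loop`/`misc_feature` entries of the
#' FEATURES block. `complement(..)` locations map to the L strand, and
#' `join(a..b,c..d)` spanning the origin of a circular molecule becomes a
#' single wrapping feature. Feature keys outside the known set are skipped
#' with a warning. Where both a `gene` and a `CDS`/`tRNA`/`rRNA` entry
#' describe the same locus the typed entry wins.
#'
#' @param path Path to a GenBank flat file.
#' @return A [mito_genome].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  circular <- length(locus) > 0 && grepl("circular", locus[1],
                                         ignore.case = TRUE)
  accession <- sub("^LOCUS\\s+(\\S+).*$", "\\1",
                   locus[1] %||% basename(path))

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0) abort(paste0("no ORIGIN sequence in ", path))
  seq_lines <- lines[(origin_at[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) abort(paste0("empty ORIGIN sequence in ", path))

  feat_at <- grep("^FEATURES", lines)
  if (length(feat_at) == 0) abort(paste0("no FEATURES block in ", path))
  feat_lines <- lines[(feat_at[1] + 1):(origin_at[1] - 1)]
  feats <- parse_genbank_features(feat_lines, nchar(sequence), circular)
  inform(sprintf("read %d features from %s", nrow(feats), basename(path)))
  mito_genome(identifier = accession, features = feats, sequence = sequence,
              circular = circular)
}

GENBANK_CLASS <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   "D-loop" = "control_region",
                   misc_feature = "control_region")

parse_genbank_features <- function(lines, genome_len, circular) {
  # a feature entry starts in column 6 with its key; continuation and
  # qualifier lines are indented further
  starts <- grep("^ {5}\\S", lines)
  if (length(starts) == 0) abort("no features found in FEATURES block")
  out <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    chunk <- lines[from:to]
    key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1])
    if (key == "source") next
    if (key == "gene") next  # typed entries carry the same locus
    if (!key %in% names(GENBANK_CLASS)) {
      warn(paste0("skipping unknown feature key: ", key))
      next
    }
    loc <- sub("^ {5}\\S+\\s+", "", chunk[1])
    # location may continue on following non-qualifier lines
    j <- 2
    while (j <= length(chunk) && !grepl("^\\s+/", chunk[j])) {
      loc <- paste0(loc, trimws(chunk[j])); j <- j + 1
    }
    parsed <- parse_genbank_location(loc, circular)
    quals <- paste(chunk[seq_len(length(chunk)) >= j], collapse = " ")
    name <- genbank_feature_name(quals, key)
    out[[length(out) + 1]] <- tibble(
      name = name, class = unname(GENBANK_CLASS[[key]]),
      strand = if (parsed$complement) "L" else "H",
      start = parsed$start, end = parsed$end
    )
  }
  if (length(out) == 0) abort("no usable features in FEATURES block")
  feats <- bind_rows(out)
  feats$name <- normalize_gene_name(feats$name)
  feats
}

parse_genbank_location <- function(loc, circular) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  complement <- grepl("^complement\\(", loc)
  inner <- gsub("^complement\\(|\\)$", "", loc)
  join <- grepl("^join\\(", inner)
  inner <- gsub("^join\\(|\\)$", "", inner)
  parts <- strsplit(inner, ",")[[1]]
  rng <- do.call(rbind, lapply(parts, function(p) {
    xs <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (anyNA(xs)) abort(paste0("malformed location: ", loc))
    if (length(xs) == 1) xs <- c(xs, xs)
    xs
  }))
  if (join && nrow(rng) == 2 && circular && rng[1, 2] > rng[2, 1]) {
    # join wrapping the origin: (a..L, 1..b) -> wrap feature a..b
    return(list(start = rng[1, 1], end = rng[2, 2], complement = complement))
  }
  list(start = min(rng), end = max(rng), complement = complement)
}

genbank_feature_name <- function(quals, key) {
  for (q in c("gene", "product")) {
    m <- regmatches(quals,
                    regexec(paste0('/', q, '="([^"]+)"'), quals))[[1]]
    if (length(m) == 2) return(m[2])
  }
  key
}

# ---- sequence extraction ----------------------------------------------------

#' Reverse-complement a nucleotide string
#'
#' @param x Nucleotide string (IUPAC codes handled).
#' @return The reverse complement, 5' to 3'.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUMRWSYKVHDBN", "TGCAAKYWSRMBDHVN", toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract a gene sequence in sense orientation
#'
#' Returns the nucleotide sequence of a feature, spliced across the origin
#' for wrapping features on circular genomes, and reverse-complemented for
#' L-strand features so the result always reads 5' to 3' in coding sense —
#' downstream codon logic never needs to know the strand.
#'
#' @param genome A [mito_genome] with sequence.
#' @param feature A feature name (matched against the feature table) or a
#'   one-row feature tibble / list with `start`, `end`, `strand`.
#' @return Nucleotide string.
#' @export
extract_gene <- function(genome, feature) {
  if (is.null(genome$sequence)) {
    abort("genome is sequence-free; extraction needs a sequence")
  }
  if (is.character(feature) && length(feature) == 1) {
    hit <- which(genome$features$name == feature)
    if (length(hit) == 0) abort(paste0("no feature named '", feature, "'"))
    feature <- genome$features[hit[1], ]
  }
  start <- as.integer(feature$start)
  end <- as.integer(feature$end)
  strand <- as.character(feature$strand)
  L <- genome$length
  if (start < 1 || start > L || end < 1 || end > L) {
    abort(sprintf("coordinates [%d, %d] out of range [1, %d]", start, end, L))
  }
  if (end < start && !genome$is_circular) {
    abort("end < start is only valid on a circular genome")
  }
  s <- if (end >= start) {
    substr(genome$sequence, start, end)
  } else {
    paste0(substr(genome$sequence, start, L), substr(genome$sequence, 1, end))
  }
  if (strand == "L") revcomp(s) else s
}
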