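BASES <- c("A", "C", "G", "T")
DINUCS <- as.vector(t(outer(BASES, BASES, paste0)))  # lexicographic AA..TT

#' Feature-schema version
#'
#' Embedded in trained models so that a model refuses to predict from a
#' feature matrix built under a different schema.
#' @export
FEATURE_SCHEMA_VERSION <- "guidekit-features/1"

ALL_FAMILIES <- c("global_mono", "global_di", "positional_mono",
                  "positional_di", "gc")

feature_schema <- function(len, families) {
  out <- character()
  if ("global_mono" %in% families) out <- c(out, paste0("glob_", BASES))
  if ("global_di" %in% families) out <- c(out, paste0("glob_", DINUCS))
  if ("positional_mono" %in% families) {
    out <- c(out, paste0("pos", rep(0:(len - 1L), each = 4L), "_", BASES))
  }
  if ("positional_di" %in% families && len >= 2L) {
    out <- c(out, paste0("pos", rep(0:(len - 2L), each = 16L), "_", DINUCS))
  }
  if ("gc" %in% families) out <- c(out, "gc")
  out
}

#' Tokenize a DNA sequence into a numeric feature vector
#'
#' Deterministic encoding of a sequence as, in fixed schema order:
#' global mononucleotide counts (A,C,G,T), global dinucleotide counts
#' (16, lexicographic), positional mononucleotide one-hot indicators
#' (position-major, 0-based), positional dinucleotide one-hot
#' indicators, and GC content (fraction) last. Counts are raw integers;
#' the vector is named by the schema.
#'
#' @param seq A single A/C/G/T string (length >= 2 when a dinucleotide
#'   family is on).
#' @param families Character subset of
#'   `c("global_mono","global_di","positional_mono","positional_di","gc")`;
#'   all on by default.
#' @return Named numeric vector; for a length-L sequence with all
#'   families on, `4 + 16 + 4L + 16(L-1) + 1` entries (685 for L = 34).
#' @examples
#' tokenize("ACGT", families = c("global_mono", "gc"))
#' @export
tokenize <- function(seq, families = ALL_FAMILIES) {
  stopifnot(is.character(seq), length(seq) == 1L)
  families <- match.arg(families, ALL_FAMILIES, several.ok = TRUE)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    stop("non-ACGT character '", substr(seq, bad, bad), "' at position ", bad)
  }
  len <- nchar(seq)
  if (len == 0L) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (any(c("global_di", "positional_di") %in% families) && len < 2L) {
    stop("sequence length must be >= 2 when a dinucleotide family is on")
  }
  vals <- numeric()
  if ("global_mono" %in% families) {
    vals <- c(vals, vapply(BASES, function(b) sum(chars == b), numeric(1)))
  }
  dis <- if (len >= 2L) paste0(chars[-len], chars[-1L]) else character()
  if ("global_di" %in% families) {
    vals <- c(vals, vapply(DINUCS, function(d) sum(dis == d), numeric(1)))
  }
  if ("positional_mono" %in% families) {
    m <- outer(chars, BASES, "==") * 1
    vals <- c(vals, as.vector(t(m)))
  }
  if ("positional_di" %in% families) {
    m <- outer(dis, DINUCS, "==") * 1
    vals <- c(vals, as.vector(t(m)))
  }
  if ("gc" %in% families) {
    vals <- c(vals, sum(chars %in% c("G", "C")) / len)
  }
  stats::setNames(vals, feature_schema(len, families))
}

#' Tokenize named sequence components independently
#'
#' Each component is tokenized on its own ([tokenize()]) and the vectors
#' are concatenated with component-prefixed feature names, in
#' declaration order. No dinucleotide spans a component boundary, so
#' relevant components are not diluted by irrelevant ones.
#'
#' @param components Named list of A/C/G/T strings; names must be
#'   unique.
#' @param families Passed to [tokenize()].
#' @return Named numeric vector.
#' @examples
#' tokenize_components(list(guide = "ACGT", flank = "TTAA"),
#'                     families = c("global_mono", "gc"))
#' @export
tokenize_components <- function(components, families = ALL_FAMILIES) {
  stopifnot(is.list(components), length(components) >= 1L)
  nm <- names(components)
  if (is.null(nm) || any(!nzchar(nm))) stop("components must be named")
  if (anyDuplicated(nm)) stop("duplicate component names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  parts <- lapply(nm, function(n) {
    v <- tokenize(components[[n]], families = families)
    stats::setNames(v, paste0(n, "_", names(v)))
  })
  do.call(c, parts)
}

#' Sliding-window region features
#'
#' Tokenizes windows of fixed width sampled at regular steps along the
#' sequence (starts 0, step, 2*step, ... while start+width <= length),
#' prefixing each window's features with `win<start>_`.
#'
#' @param seq A single A/C/G/T string.
#' @param width Window width (1 <= width <= nchar(seq)).
#' @param step Step between window starts (>= 1, default 1).
#' @param families Passed to [tokenize()].
#' @return Named numeric vector over all windows.
#' @export
window_features <- function(seq, width, step = 1L, families = ALL_FAMILIES) {
  len <- nchar(seq)
  if (width > len) stop("width (", width, ") exceeds sequence length (", len, ")")
  stopifnot(width >= 1L, step >= 1L)
  starts <- seq.int(0L, len - width, by = step)
  parts <- lapply(starts, function(s) {
    v <- tokenize(substr(seq, s + 1L, s + width), families = families)
    stats::setNames(v, paste0("win", s, "_", names(v)))
  })
  do.call(c, parts)
}

#' Validate a 34-nt Cas12a context sequence
#'
#' The canonical Cas12a context is 34 nt read 5'->3' on the PAM-carrying
#' strand: 4-nt 5' flank, 4-nt TTTN PAM, 20-nt protospacer, 6-nt 3'
#' flank (the PAM itself is excluded from the 4+26 flank count).
#'
#' @param seq Character vector of candidate contexts.
#' @param require_pam Require positions 5-8 to match TTTN (default
#'   FALSE: sequence-file inputs are validated for length and alphabet
#'   only).
#' @return Logical vector, TRUE for valid contexts.
#' @export
is_valid_context <- function(seq, require_pam = FALSE) {
  ok <- nchar(seq) == 34L & !grepl("[^ACGT]", seq)
  if (require_pam) ok <- ok & substr(seq, 5L, 7L) == "TTT"
  ok
}

#' Split a 34-nt context into its components
#'
#' @param seq A valid 34-nt context (see [is_valid_context()]).
#' @return Named list: `flank5` (4 nt), `pam` (4 nt), `protospacer`
#'   (20 nt), `flank3` (6 nt).
#' @export
split_context <- function(seq) {
  if (!is_valid_context(seq)) stop("not a valid 34-nt A/C/G/T context")
  list(flank5 = substr(seq, 1L, 4L), pam = substr(seq, 5L, 8L),
       protospacer = substr(seq, 9L, 28L), flank3 = substr(seq, 29L, 34L))
}

#' Build a feature matrix from sequences
#'
#' Rowwise [tokenize()] over equal-length sequences. The default family
#' preset (global mono- and dinucleotide counts plus GC) is the compact
#' encoding used by the guide-efficiency model; pass
#' `families = ALL_FAMILIES` (or any subset) for the full positional
#' encoding.
#'
#' @param seqs Character vector of equal-length A/C/G/T strings.
#' @param families Feature families, see [tokenize()].
#' @return Numeric matrix, one row per sequence, with schema column
#'   names and attribute `schema_version`.
#' @export
featurize_sequences <- function(seqs,
                                families = c("global_mono", "global_di", "gc")) {
  stopifnot(length(seqs) >= 1L)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must all have the same length")
  }
  rows <- lapply(seqs, tokenize, families = families)
  m <- do.call(rbind, rows)
  rownames(m) <- names(seqs)
  attr(m, "schema_version") <- FEATURE_SCHEMA_VERSION
  attr(m, "families") <- families
  m
}

#' Feature matrix for 34-nt Cas12a contexts, component-wise
#'
#' The guide-efficiency model's featurization: each context is split
#' into its components (5' flank, PAM, protospacer, 3' flank) and each
#' component is tokenized independently, so protospacer composition is
#' not diluted by flanking sequence. The default families (global mono-
#' and dinucleotide counts plus GC per component) give 84 features.
#'
#' @param seqs Character vector of valid 34-nt contexts.
#' @param families Feature families per component (see [tokenize()]).
#' @return Numeric matrix with attributes `schema_version`, `families`
#'   and `encoding = "context_components"`.
#' @export
featurize_contexts <- function(seqs,
                               families = c("global_mono", "global_di", "gc")) {
  bad <- !is_valid_context(seqs)
  if (any(bad)) stop("invalid 34-nt context at index ", which(bad)[1L])
  rows <- lapply(seqs, function(s)
    tokenize_components(split_context(s), families = families))
  m <- do.call(rbind, rows)
  rownames(m) <- names(seqs)
  attr(m, "schema_version") <- FEATURE_SCHEMA_VERSION
  attr(m, "families") <- families
  attr(m, "encoding") <- "context_components"
  m
}

#' Read sequences from a plain-text or FASTA file
#'
#' Plain text: one sequence per line (blank lines ignored). FASTA files
#' (first non-blank character `>`) are read with Biostrings.
#'
#' @param path Input file.
#' @return Character vector of upper-cased sequences; for plain text the
#'   element names are input line numbers.
#' @export
read_sequence_file <- function(path) {
  if (!file.exists(path)) stop("sequence file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- lines[nzchar(trimws(lines))]
  if (length(first) && startsWith(trimws(first[1L]), ">")) {
    return(toupper(as.character(Biostrings::readDNAStringSet(path))))
  }
  keep <- nzchar(trimws(lines))
  stats::setNames(toupper(trimws(lines[keep])), which(keep))
}
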