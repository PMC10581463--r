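#' Construct a genome object
#'
#' A lightweight container for one assembly: a set of named contig
#' sequences over the alphabet A/C/G/T/N, total length and GC content
#' computed over non-N bases.
#'
#' @param id Character scalar, assembly identifier.
#' @param sequences Character vector of contig sequences (upper- or
#'   lower-case); names become contig names, unnamed contigs are called
#'   `contig1`, `contig2`, ...
#' @return An object of class `genome`: a list with elements `id`,
#'   `sequences` (named, upper-case), `length` (total bp) and
#'   `gc_content` (fraction in \[0,1\] over non-N bases, `NaN` if the
#'   genome is all N).
#' @examples
#' g <- genome("toy", c(chr1 = "ACGTACGTTTTACCCGGG"))
#' g$gc_content
#' @export
genome <- function(id, sequences) {
  stopifnot(is.character(id), length(id) == 1L)
  stopifnot(is.character(sequences), length(sequences) >= 1L)
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("genome '", id, "': contig ", which(bad)[1L],
         " contains characters outside A/C/G/T/N")
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    names(sequences) <- paste0("contig", seq_along(sequences))
  }
  counts <- base_counts(sequences)
  acgt <- sum(counts[c("A", "C", "G", "T")])
  structure(
    list(
      id = id,
      sequences = sequences,
      length = sum(nchar(sequences)),
      gc_content = if (acgt > 0) sum(counts[c("G", "C")]) / acgt else NaN
    ),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d contig(s), %d bp, GC %.3f\n",
              x$id, length(x$sequences), x$length, x$gc_content))
  invisible(x)
}

base_counts <- function(sequences) {
  tab <- table(factor(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                      levels = c("A", "C", "G", "T", "N")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a genome from a FASTA file
#'
#' Multi-record FASTA (optionally gzip-compressed) is read with
#' Biostrings; every record becomes a contig of a single genome object.
#'
#' @param path Path to a FASTA file.
#' @param id Genome identifier; defaults to the file name without
#'   extension.
#' @return A [genome()] object.
#' @export
read_genome_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (is.null(id)) id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  set <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(set)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(set))
  genome(id, seqs)
}

#' Write a genome to a FASTA file
#'
#' @param g A [genome()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  set <- Biostrings::DNAStringSet(g$sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param seq Character vector of A/C/G/T/N strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' GC content of a DNA string
#'
#' Fraction of G+C over non-N bases.
#'
#' @param seq Character vector of DNA strings.
#' @return Numeric vector of fractions in \[0,1\] (`NaN` for all-N input).
#' @export
gc_fraction <- function(seq) {
  vapply(toupper(seq), function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- sum(b %in% c("A", "C", "G", "T"))
    if (n == 0) return(NaN)
    sum(b %in% c("G", "C")) / n
  }, numeric(1), USE.NAMES = FALSE)
}
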