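# Independent brute-force oracles. These deliberately avoid Biostrings and
# the package's vectorised one-hot machinery: everything is plain substring
# arithmetic, checked position by position.

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

oracle_pam_match <- function(window, pam) {
  if (nchar(window) != nchar(pam)) return(FALSE)
  for (i in seq_len(nchar(pam))) {
    p <- substr(pam, i, i)
    w <- substr(window, i, i)
    ok <- if (p == "N") w %in% c("A", "C", "G", "T") else w == p
    if (!ok) return(FALSE)
  }
  TRUE
}

# position-by-position scan of one strand; returns 1-based [a, b] spans of
# protospacer+PAM and the protospacer/pam strings, in scan coordinates
oracle_scan_strand <- function(s, enzyme_name) {
  L <- nchar(s)
  if (enzyme_name == "cas9") { pam <- "NGG"; plen <- 20L } else { pam <- "TTTN"; plen <- 20L }
  pamlen <- nchar(pam)
  res <- list()
  for (p in seq_len(max(0L, L - pamlen + 1L))) {
    if (!oracle_pam_match(substr(s, p, p + pamlen - 1L), pam)) next
    if (enzyme_name == "cas9") {
      a <- p - plen; b <- p + pamlen - 1L
      if (a < 1L) next
      proto <- substr(s, a, p - 1L)
    } else {
      a <- p; b <- p + pamlen + plen - 1L
      if (b > L) next
      proto <- substr(s, p + pamlen, b)
    }
    if (grepl("N", proto, fixed = TRUE)) next
    res[[length(res) + 1L]] <- list(a = a, b = b, proto = proto,
                                    pam = substr(s, p, p + pamlen - 1L))
  }
  res
}

# full two-strand oracle scan in forward 0-based half-open coordinates
oracle_scan <- function(seq, enzyme_name) {
  L <- nchar(seq)
  rows <- list()
  for (hit in oracle_scan_strand(seq, enzyme_name)) {
    rows[[length(rows) + 1L]] <- data.frame(
      start = hit$a - 1L, end = hit$b, strand = "+",
      protospacer = hit$proto, pam = hit$pam, stringsAsFactors = FALSE)
  }
  for (hit in oracle_scan_strand(oracle_revcomp(seq), enzyme_name)) {
    rows[[length(rows) + 1L]] <- data.frame(
      start = L - hit$b, end = L - hit$a + 1L, strand = "-",
      protospacer = hit$proto, pam = hit$pam, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), protospacer = character(),
                      pam = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start, match(df$strand, c("+", "-")), df$end), ]
  rownames(df) <- NULL
  df
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

# exhaustive off-target count oracle: Hamming distance of the guide to the
# protospacer of every PAM-valid window on either strand
oracle_offtarget_counts <- function(guide, seq, enzyme_name, max_mm = 5L) {
  sites <- oracle_scan(seq, enzyme_name)
  counts <- integer(max_mm + 1L)
  names(counts) <- paste0("mm", 0:max_mm)
  if (nrow(sites)) {
    d <- vapply(sites$protospacer, oracle_hamming, integer(1), a = guide)
    for (m in 0:max_mm) counts[m + 1L] <- sum(d == m)
  }
  counts
}

random_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# quantile oracle for median/IQR (type-7 interpolation written out by hand)
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}
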