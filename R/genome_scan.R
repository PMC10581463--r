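#' Enzyme specification for PAM-constrained target scanning
#'
#' Two enzymes are supported: SpCas9, which requires the GC-rich
#' 5'-NGG-3' PAM immediately 3' of the 20-nt protospacer, and Cas12a
#' (Cpf1 orthologs), which requires the AT-rich 5'-TTTN-3' PAM
#' immediately 5' of the protospacer.
#'
#' @param name `"cas9"` or `"cas12a"` (case-insensitive).
#' @return An object of class `enzyme_spec`: list with `name`, `pam`
#'   (IUPAC string), `pam_side` (`"three_prime"` or `"five_prime"` of
#'   the protospacer) and `protospacer_length` (20).
#' @examples
#' enzyme_spec("cas12a")
#' @export
enzyme_spec <- function(name = c("cas9", "cas12a")) {
  name <- match.arg(tolower(name), c("cas9", "cas12a"))
  spec <- switch(name,
    cas9   = list(name = "Cas9",   pam = "NGG",  pam_side = "three_prime"),
    cas12a = list(name = "Cas12a", pam = "TTTN", pam_side = "five_prime")
  )
  spec$protospacer_length <- 20L
  structure(spec, class = "enzyme_spec")
}

as_enzyme <- function(enzyme) {
  if (inherits(enzyme, "enzyme_spec")) enzyme else enzyme_spec(enzyme)
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s: PAM %s (%s of protospacer), %d-nt protospacer\n",
              x$name, x$pam, x$pam_side, x$protospacer_length))
  invisible(x)
}

empty_sites <- function() {
  data.frame(guide_id = character(), genome_id = character(),
             contig = character(), start = integer(), end = integer(),
             strand = character(), protospacer = character(),
             pam = character(), context = character(),
             stringsAsFactors = FALSE)
}

# Scan one strand of one contig. `s` is the sequence as read 5'->3' on the
# strand being scanned; returns 1-based [a,b] spans of protospacer+PAM in the
# coordinates of `s`, plus protospacer/pam/context strings.
scan_strand <- function(s, enzyme) {
  L <- nchar(s)
  plen <- enzyme$protospacer_length
  pamlen <- nchar(enzyme$pam)
  if (L < plen + pamlen) {
    return(list(a = integer(), b = integer(), protospacer = character(),
                pam = character(), context = character()))
  }
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(enzyme$pam), Biostrings::DNAString(s),
    fixed = c(pattern = FALSE, subject = TRUE)
  )
  p <- BiocGenerics::start(hits)
  if (!length(p)) {
    return(list(a = integer(), b = integer(), protospacer = character(),
                pam = character(), context = character()))
  }
  if (enzyme$pam_side == "three_prime") {   # Cas9: protospacer 5' of PAM
    a <- p - plen
    b <- p + pamlen - 1L
    keep <- a >= 1L
    ctx_a <- rep(NA_integer_, length(p))    # 34-nt context defined for Cas12a
    ctx_b <- ctx_a
  } else {                                  # Cas12a: protospacer 3' of PAM
    a <- p
    b <- p + pamlen + plen - 1L
    keep <- b <= L
    ctx_a <- p - 4L
    ctx_b <- p + pamlen + plen + 5L
  }
  a <- a[keep]; b <- b[keep]; p <- p[keep]
  ctx_a <- ctx_a[keep]; ctx_b <- ctx_b[keep]
  if (!length(p)) {
    return(list(a = integer(), b = integer(), protospacer = character(),
                pam = character(), context = character()))
  }
  span <- substring(s, a, b)
  # windows containing genomic N are skipped; IUPAC N in the PAM is a
  # wildcard over A/C/G/T only
  ok <- !grepl("N", span, fixed = TRUE)
  a <- a[ok]; b <- b[ok]; p <- p[ok]
  ctx_a <- ctx_a[ok]; ctx_b <- ctx_b[ok]
  if (!length(p)) {
    return(list(a = integer(), b = integer(), protospacer = character(),
                pam = character(), context = character()))
  }
  if (enzyme$pam_side == "three_prime") {
    proto <- substring(s, p - plen, p - 1L)
    pam <- substring(s, p, p + pamlen - 1L)
    ctx <- rep(NA_character_, length(p))
  } else {
    pam <- substring(s, p, p + pamlen - 1L)
    proto <- substring(s, p + pamlen, p + pamlen + plen - 1L)
    ctx <- ifelse(ctx_a >= 1L & ctx_b <= L, substring(s, ctx_a, ctx_b), NA_character_)
    ctx[!is.na(ctx) & grepl("N", ctx, fixed = TRUE)] <- NA_character_
  }
  list(a = a, b = b, protospacer = proto, pam = pam, context = ctx)
}

#' Enumerate guide target sites in a genome
#'
#' Scans both strands of every contig for sites where the enzyme's PAM
#' pattern matches (IUPAC N in the PAM is a wildcard over A/C/G/T only,
#' never genomic N) and a full 20-nt protospacer free of N fits on the
#' correct side of the PAM. Overlapping and nested sites are all
#' reported. Coordinates are 0-based half-open on the forward strand and
#' span protospacer+PAM; the protospacer is reported 5'->3' on the
#' PAM-carrying strand. For Cas12a a 34-nt context
#' (4-nt 5' flank, TTTN PAM, 20-nt protospacer, 6-nt 3' flank) is
#' attached where the flanks fit and are N-free.
#'
#' @param genome A [genome()] object.
#' @param enzyme An [enzyme_spec()] or its name.
#' @return A data.frame with columns `guide_id`, `genome_id`, `contig`,
#'   `start`, `end`, `strand`, `protospacer`, `pam`, `context`, sorted
#'   by contig, ascending start, `+` before `-` at ties.
#' @examples
#' g <- generate_genome(2000, gc = 0.4, seed = 1)
#' head(find_guides(g, "cas12a"))
#' @export
find_guides <- function(genome, enzyme) {
  stopifnot(inherits(genome, "genome"))
  enzyme <- as_enzyme(enzyme)
  out <- list()
  for (ctg in names(genome$sequences)) {
    s <- genome$sequences[[ctg]]
    L <- nchar(s)
    if (L == 0L) next
    fwd <- scan_strand(s, enzyme)
    rev <- scan_strand(revcomp(s), enzyme)
    df <- rbind(
      if (length(fwd$a)) data.frame(
        contig = ctg, start = fwd$a - 1L, end = fwd$b, strand = "+",
        protospacer = fwd$protospacer, pam = fwd$pam, context = fwd$context,
        stringsAsFactors = FALSE),
      if (length(rev$a)) data.frame(
        contig = ctg, start = L - rev$b, end = L - rev$a + 1L, strand = "-",
        protospacer = rev$protospacer, pam = rev$pam, context = rev$context,
        stringsAsFactors = FALSE)
    )
    if (!is.null(df) && nrow(df)) out[[ctg]] <- df
  }
  if (!length(out)) return(empty_sites())
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df <- df[order(df$contig, df$start, match(df$strand, c("+", "-")), df$end), ,
           drop = FALSE]
  rownames(df) <- NULL
  df <- cbind(
    guide_id = sprintf("%s:%s:%d-%d:%s", genome$id, df$contig, df$start,
                       df$end, df$strand),
    genome_id = genome$id, df, stringsAsFactors = FALSE)
  df
}

# one-hot encode 20-nt protospacers as an n x 80 0/1 matrix (position-major)
proto_onehot <- function(protos, plen = 20L) {
  n <- length(protos)
  m <- matrix(0L, n, 4L * plen)
  if (n == 0L) return(m)
  chars <- matrix(unlist(strsplit(protos, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  code <- match(chars, c("A", "C", "G", "T"))
  idx <- cbind(rep(seq_len(n), plen),
               (rep(seq_len(plen), each = n) - 1L) * 4L + as.vector(code))
  m[idx] <- 1L
  m
}

#' Count mismatch-tolerant potential off-targets for guides
#'
#' Candidate sites are all genomic windows (both strands) whose PAM
#' matches the enzyme pattern exactly; mismatches are counted in the
#' 20-nt protospacer only (Hamming distance), and windows containing N
#' are excluded.
#'
#' @param guides Character vector of 20-nt A/C/G/T protospacers.
#' @param genome A [genome()] object.
#' @param enzyme An [enzyme_spec()] or its name.
#' @param max_mm Maximum mismatch count retained (default 5).
#' @return An integer matrix, one row per guide, columns `mm0` ...
#'   `mm<max_mm>`; entry \[i, m\] is the number of genomic sites at
#'   Hamming distance exactly m from guide i.
#' @examples
#' g <- generate_genome(3000, gc = 0.4, seed = 2)
#' sites <- find_guides(g, "cas9")
#' if (nrow(sites)) count_offtargets(sites$protospacer[1], g, "cas9")
#' @export
count_offtargets <- function(guides, genome, enzyme, max_mm = 5L) {
  enzyme <- as_enzyme(enzyme)
  plen <- enzyme$protospacer_length
  stopifnot(max_mm >= 0L, max_mm <= plen)
  if (!is.character(guides) || any(nchar(guides) != plen) ||
      any(grepl("[^ACGT]", guides))) {
    stop("invalid guide: each guide must be a ", plen, "-nt A/C/G/T string")
  }
  sites <- find_guides(genome, enzyme)
  counts <- matrix(0L, length(guides), max_mm + 1L,
                   dimnames = list(guides, paste0("mm", 0:max_mm)))
  if (nrow(sites)) {
    site_oh <- proto_onehot(sites$protospacer, plen)
    guide_oh <- proto_onehot(guides, plen)
    matches <- site_oh %*% t(guide_oh)       # sites x guides match counts
    mism <- plen - matches
    for (m in 0:max_mm) counts[, m + 1L] <- as.integer(colSums(mism == m))
  }
  counts
}

#' Guide target density of a genome
#'
#' @param genome A [genome()] object (non-zero length).
#' @param enzyme An [enzyme_spec()] or its name.
#' @return Guides per bp: `nrow(find_guides(...)) / genome$length`.
#' @export
target_density <- function(genome, enzyme) {
  stopifnot(inherits(genome, "genome"))
  if (genome$length == 0L) stop("zero-length genome")
  nrow(find_guides(genome, enzyme)) / genome$length
}

#' Cas9:Cas12a target availability ratio
#'
#' Ratio of Cas9 to Cas12a target densities for one genome; reported as
#' `NA` when the genome has no Cas12a target.
#'
#' @param genome A [genome()] object.
#' @return List with `cas9_density`, `cas12a_density`, `ratio`.
#' @export
cas9_to_cas12a_ratio <- function(genome) {
  d9 <- target_density(genome, "cas9")
  d12 <- target_density(genome, "cas12a")
  list(cas9_density = d9, cas12a_density = d12,
       ratio = if (d12 > 0) d9 / d12 else NA_real_)
}

#' Per-guide Cas9:Cas12a off-target ratios for one genome
#'
#' Off-target counts are normalised by genome size; each Cas9 guide's
#' normalised count at a mismatch level is divided by the median
#' normalised Cas12a count at the same level, giving one ratio per Cas9
#' guide per level (a ratio > 1 indicates more predicted Cas9
#' off-targets). Levels where the Cas12a median is zero are dropped.
#'
#' @param cas9_counts,cas12a_counts Integer matrices from
#'   [count_offtargets()] (same mismatch columns).
#' @param genome_id Genome identifier for the output rows.
#' @param genome_length Genome length in bp used for normalisation.
#' @return Data.frame with columns `genome_id`, `mm_level`, `ratio`.
#' @export
per_guide_offtarget_ratios <- function(cas9_counts, cas12a_counts,
                                       genome_id, genome_length) {
  stopifnot(ncol(cas9_counts) == ncol(cas12a_counts), genome_length > 0)
  mm <- as.integer(sub("^mm", "", colnames(cas9_counts)))
  out <- list()
  for (j in seq_along(mm)) {
    med12 <- stats::median(cas12a_counts[, j] / genome_length)
    if (med12 == 0) next
    out[[j]] <- data.frame(
      genome_id = genome_id, mm_level = mm[j],
      ratio = (cas9_counts[, j] / genome_length) / med12,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(out)) {
    return(data.frame(genome_id = character(), mm_level = integer(),
                      ratio = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Aggregate off-target ratios and compare mismatch levels
#'
#' Per-guide Cas9:Cas12a off-target ratios are aggregated per genome
#' (median), summarised per mismatch level (median and 25/75 percentile
#' IQR of the per-genome medians) and compared across levels with a
#' Kruskal-Wallis rank test (mid-ranks for ties); pairwise levels are
#' compared with rank-sum tests, corrected by multiplying each p by the
#' number of comparisons, capped at 1 (Bonferroni).
#'
#' @param ratios Data.frame with columns `genome_id`, `mm_level`,
#'   `ratio` (one row per guide), e.g. rbind-ed output of
#'   [per_guide_offtarget_ratios()] over genomes.
#' @return List with elements `table` (genome_id, mm_level,
#'   median_ratio, iqr_lo, iqr_hi, n_guides), `kruskal` (statistic, df,
#'   p_value; NULL with fewer than 2 levels) and `pairwise` (mm_a, mm_b,
#'   p_raw, p_bonferroni).
#' @export
offtarget_ratio_table <- function(ratios) {
  stopifnot(all(c("genome_id", "mm_level", "ratio") %in% names(ratios)))
  key <- interaction(ratios$genome_id, ratios$mm_level, drop = TRUE)
  tab <- do.call(rbind, lapply(split(ratios, key), function(d) {
    q <- stats::quantile(d$ratio, c(0.25, 0.75), names = FALSE)
    data.frame(genome_id = d$genome_id[1L], mm_level = d$mm_level[1L],
               median_ratio = stats::median(d$ratio),
               iqr_lo = q[1L], iqr_hi = q[2L], n_guides = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab <- tab[order(tab$mm_level, tab$genome_id), , drop = FALSE]
  rownames(tab) <- NULL

  levels_present <- sort(unique(tab$mm_level))
  kruskal <- NULL
  pairwise <- data.frame(mm_a = integer(), mm_b = integer(),
                         p_raw = numeric(), p_bonferroni = numeric())
  if (length(levels_present) >= 2L) {
    vals <- tab$median_ratio
    grp <- factor(tab$mm_level)
    if (length(unique(vals)) == 1L) {
      kruskal <- list(statistic = 0, df = length(levels_present) - 1L,
                      p_value = 1)
    } else {
      kt <- stats::kruskal.test(vals, grp)
      kruskal <- list(statistic = unname(kt$statistic),
                      df = unname(kt$parameter), p_value = kt$p.value)
    }
    pairs <- utils::combn(levels_present, 2L)
    ncomp <- ncol(pairs)
    pw <- apply(pairs, 2L, function(pr) {
      x <- vals[tab$mm_level == pr[1L]]
      y <- vals[tab$mm_level == pr[2L]]
      p <- if (length(unique(c(x, y))) == 1L) 1 else
        suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
      c(pr, p)
    })
    pairwise <- data.frame(mm_a = as.integer(pw[1L, ]),
                           mm_b = as.integer(pw[2L, ]),
                           p_raw = pw[3L, ],
                           p_bonferroni = pmin(1, pw[3L, ] * ncomp))
  }
  list(table = tab, kruskal = kruskal, pairwise = pairwise)
}
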