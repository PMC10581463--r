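#' Log-fold changes from pooled-screen read counts
#'
#' Counts are normalised to counts-per-million within each timepoint's
#' library; the per-guide LFC of a timepoint against the reference is
#' `log2((cpm_t + 1) / (cpm_ref + 1))` (pseudocount 1 on cpm).
#'
#' @param counts Data.frame with a `guide_id` column, a reference count
#'   column and one count column per post-reference timepoint.
#' @param ref_col Name of the reference count column (default
#'   `"count_ref"`).
#' @param timepoint_cols Names of post-reference count columns; default
#'   every column matching `^count_` other than `ref_col`.
#' @return Data.frame with `guide_id` and one `lfc_*` column per
#'   timepoint (suffix taken from the count column name).
#' @export
screen_lfc <- function(counts, ref_col = "count_ref", timepoint_cols = NULL) {
  stopifnot("guide_id" %in% names(counts), ref_col %in% names(counts))
  if (is.null(timepoint_cols)) {
    timepoint_cols <- setdiff(grep("^count_", names(counts), value = TRUE),
                              ref_col)
  }
  if (!length(timepoint_cols)) stop("no post-reference timepoint columns")
  if (any(counts[[ref_col]] < 0)) stop("negative reference counts")
  ref_total <- sum(counts[[ref_col]])
  if (ref_total == 0) stop("reference library total is zero")
  cpm_ref <- 1e6 * counts[[ref_col]] / ref_total
  out <- data.frame(guide_id = counts$guide_id, stringsAsFactors = FALSE)
  for (col in timepoint_cols) {
    tot <- sum(counts[[col]])
    if (tot == 0) stop("library total is zero for ", col)
    cpm_t <- 1e6 * counts[[col]] / tot
    out[[sub("^count_", "lfc_", col)]] <- log2((cpm_t + 1) / (cpm_ref + 1))
  }
  out
}

#' Infer guide efficiency from an LFC trajectory
#'
#' Guides cutting essential genes deplete over time, so efficiency is
#' proxied by the negative mean LFC across post-reference timepoints
#' (higher score = more depleted = more efficient). An alternative
#' `"slope"` method uses the negated slope of LFC against timepoint
#' index.
#'
#' @param lfc Data.frame from [screen_lfc()] (columns `guide_id` and
#'   `lfc_*`), or a numeric matrix of LFCs (guides x timepoints).
#' @param method `"mean"` (default) or `"slope"`.
#' @return Named numeric vector of efficiency scores.
#' @export
infer_efficiency <- function(lfc, method = c("mean", "slope")) {
  method <- match.arg(method)
  if (is.data.frame(lfc)) {
    cols <- grep("^lfc_", names(lfc), value = TRUE)
    if (!length(cols)) stop("no lfc_* columns / post-reference timepoints")
    m <- as.matrix(lfc[cols])
    rownames(m) <- lfc$guide_id
  } else {
    m <- as.matrix(lfc)
    if (!ncol(m)) stop("no post-reference timepoints")
  }
  if (method == "mean") {
    score <- -rowMeans(m)
  } else {
    t_idx <- seq_len(ncol(m))
    tc <- t_idx - mean(t_idx)
    score <- -as.numeric((m %*% tc) / sum(tc^2))
  }
  stats::setNames(as.numeric(score), rownames(m))
}

#' Convert an efficiency score to percent scale
#'
#' Under an exponential depletion model (expected count multiplied by
#' `2^(-t * k * efficiency/100)` at week t) the mean-LFC score equals
#' `mean(weeks) * k * efficiency / 100`; this inverts that map and clips
#' to \[0, 100\].
#'
#' @param score Numeric scores from [infer_efficiency()].
#' @param k Depletion rate constant per week per unit efficiency
#'   (default 0.75, the generator's default: a fully efficient guide on
#'   an essential gene loses 3 log2 units of abundance by week 4).
#' @param weeks Post-reference timepoints (default 1:4).
#' @return Numeric vector of efficiencies in \[0, 100\].
#' @export
score_to_percent <- function(score, k = 0.75, weeks = 1:4) {
  pmin(100, pmax(0, 100 * score / (k * mean(weeks))))
}

#' Filter guides by gene essentiality
#'
#' Retains guides whose gene has a Bayes Factor at or above the
#' threshold, so that depletion reflects cutting efficiency rather than
#' gene dispensability. Gene symbols are joined case-insensitively;
#' guides whose gene has no Bayes-Factor row are dropped with a message
#' reporting the count.
#'
#' @param guides Data.frame with a `gene` column.
#' @param bf_table Data.frame with columns `gene`, `bf` (one row per
#'   gene).
#' @param bf_threshold Minimum Bayes Factor (default 6, a conventional
#'   high-confidence essentiality cutoff).
#' @return The retained rows of `guides`.
#' @export
essentiality_filter <- function(guides, bf_table, bf_threshold = 6) {
  stopifnot("gene" %in% names(guides),
            all(c("gene", "bf") %in% names(bf_table)))
  if (!nrow(bf_table)) {
    warning("empty Bayes-Factor table; all guides dropped")
    return(guides[integer(), , drop = FALSE])
  }
  idx <- match(toupper(guides$gene), toupper(bf_table$gene))
  n_unmatched <- sum(is.na(idx))
  if (n_unmatched) {
    message(n_unmatched, " guide(s) dropped: gene has no Bayes-Factor row")
  }
  keep <- !is.na(idx) & bf_table$bf[idx] >= bf_threshold
  guides[keep, , drop = FALSE]
}

#' Read a narrowPeak BED file
#'
#' Standard ENCODE narrowPeak: 10 tab-separated columns, 0-based
#' half-open intervals.
#'
#' @param path Path to a narrowPeak file.
#' @return Data.frame with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand`, `signal`, `p_value`, `q_value`, `peak`.
#' @export
read_narrowpeak <- function(path) {
  cols <- c("contig", "start", "end", "name", "score", "strand",
            "signal", "p_value", "q_value", "peak")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("narrowPeak file needs at least 3 columns")
  df <- df[, seq_len(min(ncol(df), 10L)), drop = FALSE]
  names(df) <- cols[seq_len(ncol(df))]
  if (any(df$start >= df$end)) stop("narrowPeak intervals must have start < end")
  df
}

#' Annotate guides with chromatin accessibility
#'
#' A guide is labelled accessible (1) iff its \[start, end) interval
#' overlaps any DNase-hypersensitive peak by at least 1 bp (half-open
#' abutment does not count). Guides on contigs absent from the peak set
#' are labelled 0 and counted in a message.
#'
#' @param guides Data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open).
#' @param peaks Data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open), e.g. from [read_narrowpeak()].
#' @return Integer vector of 0/1 labels, one per guide row.
#' @export
annotate_accessibility <- function(guides, peaks) {
  stopifnot(all(c("contig", "start", "end") %in% names(guides)),
            all(c("contig", "start", "end") %in% names(peaks)))
  n_off <- sum(!guides$contig %in% peaks$contig)
  if (n_off) {
    message(n_off, " guide(s) on contigs absent from the peak set (label 0)")
  }
  if (!nrow(peaks)) return(rep(0L, nrow(guides)))
  # convert half-open to the 1-based closed convention of GRanges
  gr_g <- GenomicRanges::GRanges(
    guides$contig, IRanges::IRanges(guides$start + 1L, guides$end))
  gr_p <- GenomicRanges::GRanges(
    peaks$contig, IRanges::IRanges(peaks$start + 1L, peaks$end))
  hits <- GenomicRanges::countOverlaps(gr_g, gr_p, minoverlap = 1L)
  as.integer(hits > 0L)
}

#' Two-group summary with Welch's t test
#'
#' @param x,y Numeric vectors (each n >= 2), e.g. cleavage efficiencies
#'   of two cohorts.
#' @return List with `mean_x`, `sd_x`, `n_x`, `mean_y`, `sd_y`, `n_y`,
#'   `welch_t`, `welch_df`, `p` (two-sided).
#' @export
cohort_stats <- function(x, y) {
  wt <- welch_t(x, y)
  list(mean_x = mean(x), sd_x = stats::sd(x), n_x = length(x),
       mean_y = mean(y), sd_y = stats::sd(y), n_y = length(y),
       welch_t = wt$t, welch_df = wt$df, p = wt$p)
}

#' Build a labelled guide-efficiency training table
#'
#' Full pre-processing path of the pooled-screen pipeline: read counts
#' -> per-timepoint LFC -> efficiency score and percent label ->
#' essentiality (Bayes-Factor) filter -> chromatin-accessibility
#' annotation -> join of 34-nt context sequences.
#'
#' @param counts Data.frame as for [screen_lfc()], plus `gene`,
#'   `contig`, `start`, `end` columns.
#' @param contexts Data.frame with `guide_id`, `context` (34-nt).
#' @param bf_table Data.frame with `gene`, `bf`.
#' @param peaks narrowPeak data.frame (may have 0 rows).
#' @param bf_threshold Passed to [essentiality_filter()].
#' @param k,weeks Passed to [score_to_percent()].
#' @return Data.frame with `guide_id`, `gene`, `context`, `efficiency`
#'   (percent), `score`, `accessible`.
#' @export
build_training_table <- function(counts, contexts, bf_table, peaks,
                                 bf_threshold = 6, k = 0.75, weeks = 1:4) {
  lfc <- screen_lfc(counts)
  score <- infer_efficiency(lfc)
  eff <- score_to_percent(score, k = k, weeks = weeks)
  tab <- data.frame(guide_id = counts$guide_id, gene = counts$gene,
                    contig = counts$contig, start = counts$start,
                    end = counts$end, score = score, efficiency = eff,
                    stringsAsFactors = FALSE)
  tab <- essentiality_filter(tab, bf_table, bf_threshold)
  tab$accessible <- annotate_accessibility(tab, peaks)
  tab$context <- contexts$context[match(tab$guide_id, contexts$guide_id)]
  if (anyNA(tab$context)) stop("missing context sequence for some guides")
  tab[, c("guide_id", "gene", "context", "efficiency", "score", "accessible")]
}
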