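#' Validate an allele table
#'
#' Allele tables describe per-target editing outcomes, one row per
#' observed allele: `target_id`, `variant_type` (one of `insertion`,
#' `deletion`, `SNV`, `WT`), `length` (nt; >= 1 for indels, 1 for SNV,
#' 0 for WT), `position` (0-based offset within the analysis window on
#' the PAM-carrying strand), `outcome_base` (A/C/G/T for SNV, NA
#' otherwise) and `read_count`.
#'
#' @param records Data.frame in the allele-table layout.
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validate_allele_table <- function(records) {
  req <- c("target_id", "variant_type", "length", "position",
           "outcome_base", "read_count")
  missing <- setdiff(req, names(records))
  if (length(missing)) stop("allele table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (!all(records$variant_type %in% c("insertion", "deletion", "SNV", "WT"))) {
    stop("variant_type must be insertion/deletion/SNV/WT")
  }
  if (any(records$read_count < 0)) stop("negative read_count")
  indel <- records$variant_type %in% c("insertion", "deletion")
  if (any(records$length[indel] < 1)) stop("indel length must be >= 1")
  records
}

#' Indel spectrum: read-weighted frequencies by type and length
#'
#' @param records Allele table (see [validate_allele_table()]); only
#'   insertion and deletion rows contribute.
#' @return Data.frame with `variant_type`, `length`, `reads`,
#'   `frequency` (read-count-weighted, summing to 1 over indel classes);
#'   empty input gives an empty table.
#' @export
indel_spectrum <- function(records) {
  records <- validate_allele_table(records)
  ind <- records[records$variant_type %in% c("insertion", "deletion"), ,
                 drop = FALSE]
  if (!nrow(ind) || sum(ind$read_count) == 0) {
    return(data.frame(variant_type = character(), length = integer(),
                      reads = numeric(), frequency = numeric()))
  }
  agg <- stats::aggregate(read_count ~ variant_type + length, data = ind, sum)
  agg <- agg[agg$read_count > 0, , drop = FALSE]
  agg <- agg[order(agg$variant_type, agg$length), , drop = FALSE]
  rownames(agg) <- NULL
  data.frame(variant_type = agg$variant_type, length = as.integer(agg$length),
             reads = agg$read_count,
             frequency = agg$read_count / sum(agg$read_count))
}

# per-target read-fraction of one variant type (fraction of all reads at
# that target, WT included)
per_target_type_freq <- function(records, type) {
  tot <- tapply(records$read_count, records$target_id, sum)
  sel <- records[records$variant_type == type, , drop = FALSE]
  typ <- tapply(sel$read_count, factor(sel$target_id, levels = names(tot)), sum)
  typ[is.na(typ)] <- 0
  as.numeric(typ) / as.numeric(tot)
}

#' Deletion/insertion statistics
#'
#' Pooled deletion:insertion read ratio, plus a Welch t test and
#' Cohen's d (pooled-SD standardised mean difference) on the per-target
#' deletion vs insertion read fractions.
#'
#' @param records Allele table.
#' @return List with `ratio` (sum of deletion reads / sum of insertion
#'   reads; `Inf` when there are deletions but no insertion reads),
#'   `welch_t`, `welch_df`, `welch_p`, `cohens_d`, `n_targets`.
#' @export
del_ins_stats <- function(records) {
  records <- validate_allele_table(records)
  del_reads <- sum(records$read_count[records$variant_type == "deletion"])
  ins_reads <- sum(records$read_count[records$variant_type == "insertion"])
  ratio <- if (ins_reads > 0) del_reads / ins_reads else
    if (del_reads > 0) Inf else NaN
  d_freq <- per_target_type_freq(records, "deletion")
  i_freq <- per_target_type_freq(records, "insertion")
  if (length(d_freq) >= 2L) {
    wt <- welch_t(d_freq, i_freq)
    d <- cohens_d(d_freq, i_freq)
  } else {  # t/d need per-target replication
    wt <- list(t = NA_real_, df = NA_real_, p = NA_real_)
    d <- NA_real_
  }
  list(ratio = ratio, welch_t = wt$t, welch_df = wt$df, welch_p = wt$p,
       cohens_d = d, n_targets = length(d_freq))
}

#' Welch's unequal-variance t test
#'
#' @param x,y Numeric vectors (each n >= 2). Degenerate input with zero
#'   variance in both groups and equal means yields `t = 0, p = 1`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  tt <- stats::t.test(x, y)  # Welch by default
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(x) - mean(y)) / s_pooled`,
#' `s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`.
#'
#' @param x,y Numeric vectors.
#' @return Numeric scalar (0 when both groups are constant and equal).
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) return(if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Positional distribution of SNV reads
#'
#' Percentage of SNV reads at each 0-based position of the analysis
#' window, together with the uniform expectation `100 / window_length`
#' (2.56% for the default 39-nt window).
#'
#' @param records Allele table; only SNV rows contribute. Rows with a
#'   position outside `[0, window_length)` are rejected (dropped with a
#'   warning).
#' @param window_length Analysis-window length in nt (default 39).
#' @return List with `distribution` (data.frame `position`, `reads`,
#'   `pct`; percentages sum to 100 when any SNV read exists) and
#'   `uniform_expectation_pct`.
#' @export
snv_positional_distribution <- function(records, window_length = 39L) {
  stopifnot(window_length >= 1L)
  records <- validate_allele_table(records)
  snv <- records[records$variant_type == "SNV", , drop = FALSE]
  bad <- snv$position < 0L | snv$position >= window_length
  if (any(bad)) {
    warning(sum(bad), " SNV record(s) outside [0, ", window_length,
            ") rejected")
    snv <- snv[!bad, , drop = FALSE]
  }
  reads <- vapply(0:(window_length - 1L), function(p)
    sum(snv$read_count[snv$position == p]), numeric(1))
  tot <- sum(reads)
  data_frame <- data.frame(
    position = 0:(window_length - 1L), reads = reads,
    pct = if (tot > 0) 100 * reads / tot else rep(NA_real_, window_length))
  list(distribution = data_frame,
       uniform_expectation_pct = 100 / window_length)
}

#' Filter SNV outcomes by read fraction
#'
#' Retains a target's SNV outcome iff its SNV reads exceed the given
#' fraction of total target reads (strictly greater than; the default
#' 1% threshold drops outcomes at exactly 1%). Targets with zero total
#' reads are skipped.
#'
#' @param summaries Data.frame with columns `target_id`, `snv_reads`,
#'   `total_reads`.
#' @param threshold Fraction (default 0.01).
#' @return The retained rows of `summaries`.
#' @export
snv_read_fraction_filter <- function(summaries, threshold = 0.01) {
  stopifnot(all(c("target_id", "snv_reads", "total_reads") %in% names(summaries)))
  ok <- summaries$total_reads > 0 &
    summaries$snv_reads / summaries$total_reads > threshold
  ok[is.na(ok)] <- FALSE
  summaries[ok, , drop = FALSE]
}

#' SNV share of short-variant reads
#'
#' @param records Allele table.
#' @return `100 * SNV reads / (SNV + insertion + deletion reads)`;
#'   `NA` (with a message) when there are no variant reads.
#' @export
snv_fraction_of_variants <- function(records) {
  records <- validate_allele_table(records)
  snv <- sum(records$read_count[records$variant_type == "SNV"])
  indel <- sum(records$read_count[records$variant_type %in%
                                    c("insertion", "deletion")])
  if (snv + indel == 0) {
    message("no variant reads; SNV fraction undefined")
    return(NA_real_)
  }
  100 * snv / (snv + indel)
}
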