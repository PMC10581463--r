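#' Relative off-target cleavage efficiencies for one guide
#'
#' GUIDE-seq-style observations are expressed relative to the guide's
#' on-target read count: each site's efficiency is
#' `100 * read_count / on-target read_count` (the on-target site itself
#' is reported at mismatch level 0 with 100%).
#'
#' @param observations Data.frame for a single guide with columns
#'   `site_id`, `mismatches`, `read_count`, `is_on_target` (logical or
#'   0/1); exactly one row must be flagged on-target.
#' @return Data.frame with columns `site_id`, `mismatches`,
#'   `relative_pct`, or `NULL` (with a warning) when the on-target read
#'   count is zero.
#' @export
relative_cleavage <- function(observations) {
  stopifnot(all(c("site_id", "mismatches", "read_count", "is_on_target")
                %in% names(observations)))
  on <- observations[as.logical(observations$is_on_target), , drop = FALSE]
  if (nrow(on) != 1L) {
    stop("expected exactly one on-target record, found ", nrow(on))
  }
  if (on$mismatches != 0L) stop("on-target record must have 0 mismatches")
  if (any(observations$read_count < 0)) stop("negative read counts")
  if (on$read_count == 0) {
    warning("on-target read count is zero; guide excluded")
    return(NULL)
  }
  out <- data.frame(
    site_id = observations$site_id,
    mismatches = as.integer(observations$mismatches),
    relative_pct = 100 * observations$read_count / on$read_count,
    stringsAsFactors = FALSE)
  out[order(out$mismatches, out$site_id), , drop = FALSE]
}

#' Relative cleavage pooled over guides
#'
#' Applies [relative_cleavage()] per guide; guides with zero on-target
#' reads are excluded with a warning.
#'
#' @param observations Data.frame with a `guide_id` column plus the
#'   columns required by [relative_cleavage()].
#' @return Data.frame with `guide_id`, `site_id`, `mismatches`,
#'   `relative_pct`.
#' @export
relative_cleavage_all <- function(observations) {
  stopifnot("guide_id" %in% names(observations))
  parts <- lapply(split(observations, observations$guide_id), function(d) {
    r <- withCallingHandlers(
      relative_cleavage(d[setdiff(names(d), "guide_id")]),
      warning = function(w) {
        warning("guide ", d$guide_id[1L], ": ", conditionMessage(w),
                call. = FALSE)
        invokeRestart("muffleWarning")
      })
    if (is.null(r)) return(NULL)
    cbind(guide_id = d$guide_id[1L], r, stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) {
    return(data.frame(guide_id = character(), site_id = character(),
                      mismatches = integer(), relative_pct = numeric()))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Fraction of predicted off-targets observed cleaved
#'
#' A predicted site counts as cleaved iff it carries at least one read.
#'
#' @param predicted Named integer vector or data.frame
#'   (`mismatches`, `n_sites`) giving the number of predicted sites per
#'   mismatch level (vector names `mm0`.. or bare levels).
#' @param observations Data.frame of observed sites with columns
#'   `mismatches` and `read_count` (one row per site).
#' @return Data.frame with `mismatches`, `n_predicted`, `n_cleaved`,
#'   `cleaved_pct` (`NA` where no sites are predicted).
#' @export
cleaved_fraction <- function(predicted, observations) {
  if (is.data.frame(predicted)) {
    stopifnot(all(c("mismatches", "n_sites") %in% names(predicted)))
    mm <- as.integer(predicted$mismatches)
    n_pred <- as.integer(predicted$n_sites)
  } else {
    mm <- as.integer(sub("^mm", "", names(predicted)))
    n_pred <- as.integer(predicted)
  }
  stopifnot(all(c("mismatches", "read_count") %in% names(observations)))
  cleaved <- observations[observations$read_count > 0, , drop = FALSE]
  n_cl <- vapply(mm, function(m) sum(cleaved$mismatches == m), integer(1))
  if (any(n_cl > n_pred)) {
    stop("observed cleaved sites exceed predicted sites at mismatch level ",
         mm[which(n_cl > n_pred)[1L]])
  }
  data.frame(mismatches = mm, n_predicted = n_pred, n_cleaved = n_cl,
             cleaved_pct = ifelse(n_pred > 0, 100 * n_cl / n_pred, NA_real_))
}
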