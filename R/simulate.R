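#' Generate a random genome of controlled GC content
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1-gc)/2, giving an empirical GC within about 0.02 of the target
#' from 10 kb up. Deterministic given the seed.
#'
#' @param length Genome length in bp (>= 100).
#' @param gc Target GC fraction in \[0, 1\] (default 0.5).
#' @param seed Integer RNG seed (required).
#' @param id Genome identifier.
#' @return A [genome()] object with one contig.
#' @examples
#' generate_genome(1000, gc = 0.3, seed = 7)
#' @export
generate_genome <- function(length, gc = 0.5, seed, id = "synthetic") {
  stopifnot(length >= 100L)
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  set.seed(seed)
  seq <- paste(sample(BASES, length, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
               collapse = "")
  genome(id, c(contig1 = seq))
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
}

# default planted sequence-feature -> efficiency weights, applied to the
# tokenized 20-nt protospacer (GC-rich protospacers cut better, TT runs hurt)
DEFAULT_EFFICIENCY_WEIGHTS <- c(glob_A = -1, glob_C = 1, glob_G = 1,
                                glob_T = -1, glob_GG = 0.5, glob_TT = -0.5)

planted_efficiency <- function(protospacers, weights, effect_scale) {
  feats <- featurize_sequences(protospacers,
                               families = c("global_mono", "global_di"))
  w <- stats::setNames(numeric(ncol(feats)), colnames(feats))
  w[names(weights)] <- weights
  s <- as.numeric(feats %*% w)
  z <- (s - mean(s)) / stats::sd(s)
  100 * stats::plogis(effect_scale * z)
}

#' Simulate a pooled knockout screen with planted guide efficiencies
#'
#' Emulates a mini-human-style screen: guides over genes, a reference
#' library and weekly timepoints. Each guide gets a 34-nt Cas12a
#' context; its planted efficiency is a logistic transform of a
#' weighted sum of protospacer sequence features, scaled to \[0, 100\].
#' Guides of essential genes deplete exponentially — expected count at
#' week t is `depth * 2^(-t * k * efficiency/100)` (a fully efficient
#' guide loses ~3 log2 units by week 4 at the default k) — while
#' non-essential genes stay flat regardless of efficiency. Per-guide
#' library-composition skew is log-normal and shared across all
#' libraries (so it cancels in fold changes, as plasmid-abundance skew
#' does in real screens); each library additionally gets independent
#' multiplicative log-normal noise emulating PCR/counting
#' overdispersion, and counts are Poisson-sampled.
#' Bayes Factors are drawn so that essential genes exceed the default
#' filter threshold and non-essential genes fall well below it. A
#' DNase-peak table covering a configurable fraction of guides is also
#' produced.
#'
#' @param n_genes Number of genes (default 687).
#' @param guides_per_gene Guides per gene (default 3; 687 x 3 = 2061).
#' @param essential_fraction Fraction of genes that are essential
#'   (default 0.15, leaving roughly 300 guides after the Bayes-Factor
#'   filter).
#' @param depth Mean reference read depth per guide (default 500).
#' @param weeks Post-reference timepoints (default 1:4).
#' @param k Depletion rate constant (default 0.75; see
#'   [score_to_percent()]).
#' @param skew_sd SD (natural log) of the shared per-guide abundance
#'   skew (default 0.5).
#' @param noise_sd SD (natural log) of independent per-library noise
#'   (default 0.1).
#' @param accessible_fraction Fraction of guides inside DNase peaks
#'   (default 0.34).
#' @param weights Named planted feature weights on the tokenized
#'   protospacer (see `DEFAULT_EFFICIENCY_WEIGHTS`).
#' @param effect_scale Logistic slope of the planted efficiency
#'   (default 1.5).
#' @param seed Integer RNG seed (required).
#' @return List with `counts` (guide_id, gene, contig, start, end,
#'   strand, count_ref, count_w1..), `contexts` (guide_id, context),
#'   `bf` (gene, bf), `peaks` (narrowPeak-style data.frame) and `truth`
#'   (guide_id, gene, essential, efficiency_true, accessible).
#' @export
generate_screen <- function(n_genes = 687L, guides_per_gene = 3L,
                            essential_fraction = 0.15, depth = 500,
                            weeks = 1:4, k = 0.75, skew_sd = 0.5,
                            noise_sd = 0.1,
                            accessible_fraction = 0.34,
                            weights = DEFAULT_EFFICIENCY_WEIGHTS,
                            effect_scale = 1.5, seed) {
  stopifnot(n_genes >= 1L, guides_per_gene >= 1L)
  if (depth <= 0) stop("depth must be positive")
  stopifnot(essential_fraction >= 0, essential_fraction <= 1,
            accessible_fraction >= 0, accessible_fraction <= 1)
  set.seed(seed)
  n <- n_genes * guides_per_gene
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  essential <- stats::rbinom(n_genes, 1L, essential_fraction) == 1L
  gene_of <- rep(genes, each = guides_per_gene)
  ess_of <- rep(essential, each = guides_per_gene)
  guide_id <- sprintf("guide%05d", seq_len(n))

  contexts <- paste0(random_seq(n, 4L), "TTT", random_seq(n, 1L),
                     random_seq(n, 20L), random_seq(n, 6L))
  protos <- substr(contexts, 9L, 28L)
  eff <- planted_efficiency(protos, weights, effect_scale)

  start <- (seq_len(n) - 1L) * 50L
  end <- start + 24L
  accessible <- stats::rbinom(n, 1L, accessible_fraction)

  counts <- data.frame(guide_id = guide_id, gene = gene_of,
                       contig = "chrS", start = start, end = end,
                       strand = "+", stringsAsFactors = FALSE)
  abundance <- exp(stats::rnorm(n, 0, skew_sd))   # shared across libraries
  noise <- function() exp(stats::rnorm(n, 0, noise_sd))
  counts$count_ref <- stats::rpois(n, depth * abundance * noise())
  for (t in weeks) {
    depletion <- ifelse(ess_of, 2^(-t * k * eff / 100), 1)
    counts[[paste0("count_w", t)]] <-
      stats::rpois(n, depth * abundance * depletion * noise())
  }

  bf <- data.frame(
    gene = genes,
    bf = ifelse(essential,
                6 + stats::rgamma(n_genes, shape = 4, rate = 0.5),
                stats::rnorm(n_genes, -5, 3)))

  acc_idx <- which(accessible == 1L)
  peaks <- if (length(acc_idx)) {
    data.frame(contig = "chrS", start = pmax(0L, start[acc_idx] - 10L),
               end = end[acc_idx] + 10L,
               name = sprintf("peak%05d", seq_along(acc_idx)),
               score = 0L, strand = ".", signal = 1, p_value = -1,
               q_value = -1, peak = -1L, stringsAsFactors = FALSE)
  } else {
    data.frame(contig = character(), start = integer(), end = integer())
  }

  list(counts = counts,
       contexts = data.frame(guide_id = guide_id, context = contexts,
                             stringsAsFactors = FALSE),
       bf = bf, peaks = peaks,
       truth = data.frame(guide_id = guide_id, gene = gene_of,
                          essential = ess_of, efficiency_true = eff,
                          accessible = accessible,
                          stringsAsFactors = FALSE))
}

#' Simulate editing-outcome allele tables with planted structure
#'
#' Per target, reads are drawn as WT or variant; variants split into
#' SNVs and indels with configured shares, indels into deletions and
#' insertions at the planted deletion:insertion ratio. Indel lengths
#' are geometric (monotone decay); an optional deletion-length cap
#' emulates alignment-truncation artifacts. SNV positions are
#' multinomial over the analysis window with a single-position hotspot
#' enrichment; SNV outcome bases are uniform over the 3 non-reference
#' bases unless a planted outcome rule (`snv_rule_offset`) ties the
#' hotspot outcome to the complement of the base at another offset.
#'
#' @param n_targets Number of targets (default 55).
#' @param reads_per_target Reads per target (default 2000).
#' @param window_length Analysis-window length in nt (default 39).
#' @param edited_fraction Fraction of reads carrying a variant
#'   (default 0.41).
#' @param snv_share Share of variant reads that are SNVs (default
#'   0.634).
#' @param del_ins_ratio Planted deletion:insertion read ratio (default
#'   1.91).
#' @param del_geom_p,ins_geom_p Geometric length parameters (defaults
#'   0.38 and 0.6).
#' @param max_del_cap Optional cap on deletion length (e.g. 5 to
#'   emulate a truncated dataset); `NULL` for no cap.
#' @param hotspot_position 0-based hotspot position of SNV reads
#'   (default 17).
#' @param hotspot_enrichment Multinomial weight of the hotspot relative
#'   to other positions (default 3).
#' @param snv_rule_offset Optional 0-based offset; when set, hotspot
#'   SNV outcomes equal the complement of the reference base at this
#'   offset instead of a uniform draw.
#' @param seed Integer RNG seed (required).
#' @return List with `records` (allele table: target_id, variant_type,
#'   length, position, outcome_base, read_count), `targets` (target_id,
#'   window) and `config`.
#' @export
generate_outcomes <- function(n_targets = 55L, reads_per_target = 2000L,
                              window_length = 39L, edited_fraction = 0.41,
                              snv_share = 0.634, del_ins_ratio = 1.91,
                              del_geom_p = 0.38, ins_geom_p = 0.6,
                              max_del_cap = NULL, hotspot_position = 17L,
                              hotspot_enrichment = 3,
                              snv_rule_offset = NULL, seed) {
  stopifnot(n_targets >= 1L, reads_per_target >= 1L, window_length >= 1L)
  if (edited_fraction < 0 || edited_fraction > 1 ||
      snv_share < 0 || snv_share > 1) {
    stop("edited_fraction and snv_share must lie in [0, 1]")
  }
  stopifnot(hotspot_position >= 0L, hotspot_position < window_length)
  set.seed(seed)
  windows <- random_seq(n_targets, window_length)
  target_id <- sprintf("target%03d", seq_len(n_targets))
  p_del <- del_ins_ratio / (1 + del_ins_ratio)
  pos_w <- rep(1, window_length)
  pos_w[hotspot_position + 1L] <- hotspot_enrichment
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  rows <- list()
  for (i in seq_len(n_targets)) {
    win <- strsplit(windows[i], "", fixed = TRUE)[[1L]]
    nr <- reads_per_target
    n_var <- stats::rbinom(1L, nr, edited_fraction)
    n_snv <- stats::rbinom(1L, n_var, snv_share)
    n_del <- stats::rbinom(1L, n_var - n_snv, p_del)
    n_ins <- n_var - n_snv - n_del

    part <- list(data.frame(target_id = target_id[i], variant_type = "WT",
                            length = 0L, position = 0L,
                            outcome_base = NA_character_,
                            read_count = nr - n_var,
                            stringsAsFactors = FALSE))
    if (n_del > 0L) {
      len <- stats::rgeom(n_del, del_geom_p) + 1L
      if (!is.null(max_del_cap)) len <- pmin(len, as.integer(max_del_cap))
      pos <- vapply(len, function(l)
        sample.int(max(1L, window_length - l + 1L), 1L) - 1L, integer(1))
      part <- c(part, list(data.frame(
        target_id = target_id[i], variant_type = "deletion", length = len,
        position = pos, outcome_base = NA_character_, read_count = 1L,
        stringsAsFactors = FALSE)))
    }
    if (n_ins > 0L) {
      len <- stats::rgeom(n_ins, ins_geom_p) + 1L
      pos <- sample.int(window_length, n_ins, replace = TRUE) - 1L
      part <- c(part, list(data.frame(
        target_id = target_id[i], variant_type = "insertion", length = len,
        position = pos, outcome_base = NA_character_, read_count = 1L,
        stringsAsFactors = FALSE)))
    }
    if (n_snv > 0L) {
      pos <- sample.int(window_length, n_snv, replace = TRUE,
                        prob = pos_w) - 1L
      ref <- win[pos + 1L]
      outcome <- vapply(seq_len(n_snv), function(j) {
        if (!is.null(snv_rule_offset) && pos[j] == hotspot_position) {
          comp[[win[snv_rule_offset + 1L]]]
        } else {
          sample(setdiff(BASES, ref[j]), 1L)
        }
      }, character(1))
      # planted rule can coincide with the reference base; re-draw those
      clash <- outcome == ref
      if (any(clash)) {
        outcome[clash] <- vapply(which(clash), function(j)
          sample(setdiff(BASES, ref[j]), 1L), character(1))
      }
      part <- c(part, list(data.frame(
        target_id = target_id[i], variant_type = "SNV", length = 1L,
        position = pos, outcome_base = outcome, read_count = 1L,
        stringsAsFactors = FALSE)))
    }
    rows[[i]] <- do.call(rbind, part)
  }
  records <- do.call(rbind, rows)
  records$outcome_base[is.na(records$outcome_base)] <- "."
  agg <- stats::aggregate(
    read_count ~ target_id + variant_type + length + position +
      outcome_base, data = records, sum)
  agg$outcome_base[agg$outcome_base == "."] <- NA_character_
  agg <- agg[agg$read_count > 0, , drop = FALSE]
  agg <- agg[order(agg$target_id, agg$variant_type, agg$length,
                   agg$position), , drop = FALSE]
  rownames(agg) <- NULL
  list(records = agg[, c("target_id", "variant_type", "length", "position",
                         "outcome_base", "read_count")],
       targets = data.frame(target_id = target_id, window = windows,
                            stringsAsFactors = FALSE),
       config = list(n_targets = n_targets,
                     reads_per_target = reads_per_target,
                     window_length = window_length,
                     edited_fraction = edited_fraction,
                     snv_share = snv_share, del_ins_ratio = del_ins_ratio,
                     hotspot_position = hotspot_position,
                     hotspot_enrichment = hotspot_enrichment, seed = seed))
}

#' Simulate GUIDE-seq-style observation and prediction tables
#'
#' Per guide and mismatch level m, a configurable number of predicted
#' sites exists; each is cleaved with probability `cleavage_prob[m+1]`,
#' and cleaved sites get expected reads
#' `on_target_reads * decay^m`.
#'
#' @param n_guides Number of guides (default 18).
#' @param on_target_reads On-target read count (default 1000).
#' @param decay Per-mismatch relative-cleavage decay in (0, 1\]
#'   (default 0.5).
#' @param cleavage_prob Probability a predicted site is cleaved, by
#'   mismatch level 0..5 (default `c(1, .9, .6, .3, .15, .08)`).
#' @param n_predicted Predicted sites per mismatch level 0..5 (default
#'   `c(1, 4, 16, 64, 256, 1024)`).
#' @param read_noise Poisson-sample read counts (default TRUE); FALSE
#'   gives deterministic expected counts.
#' @param seed Integer RNG seed (required).
#' @return List with `observations` (guide_id, site_id, mismatches,
#'   read_count, is_on_target; cleaved sites only) and `predicted`
#'   (guide_id, mismatches, n_sites).
#' @export
generate_guideseq <- function(n_guides = 18L, on_target_reads = 1000L,
                              decay = 0.5,
                              cleavage_prob = c(1, 0.9, 0.6, 0.3, 0.15, 0.08),
                              n_predicted = c(1L, 4L, 16L, 64L, 256L, 1024L),
                              read_noise = TRUE, seed) {
  if (decay <= 0 || decay > 1) stop("decay must lie in (0, 1]")
  stopifnot(length(cleavage_prob) == length(n_predicted),
            all(cleavage_prob >= 0 & cleavage_prob <= 1),
            n_predicted[1L] == 1L)
  set.seed(seed)
  mm_levels <- seq_along(n_predicted) - 1L
  obs <- list()
  pred <- list()
  for (g in seq_len(n_guides)) {
    gid <- sprintf("gRNA%02d", g)
    pred[[g]] <- data.frame(guide_id = gid, mismatches = mm_levels,
                            n_sites = as.integer(n_predicted),
                            stringsAsFactors = FALSE)
    rows <- list(data.frame(guide_id = gid, site_id = paste0(gid, "_on"),
                            mismatches = 0L,
                            read_count = as.integer(on_target_reads),
                            is_on_target = TRUE, stringsAsFactors = FALSE))
    for (m in mm_levels[-1L]) {
      n_m <- n_predicted[m + 1L]
      cleaved <- which(stats::runif(n_m) < cleavage_prob[m + 1L])
      if (!length(cleaved)) next
      mu <- on_target_reads * decay^m
      reads <- if (read_noise) {
        pmax(1L, stats::rpois(length(cleaved), mu))
      } else {
        rep(as.integer(round(mu)), length(cleaved))
      }
      rows <- c(rows, list(data.frame(
        guide_id = gid, site_id = sprintf("%s_mm%d_%03d", gid, m, cleaved),
        mismatches = m, read_count = reads, is_on_target = FALSE,
        stringsAsFactors = FALSE)))
    }
    obs[[g]] <- do.call(rbind, rows)
  }
  list(observations = do.call(rbind, obs),
       predicted = do.call(rbind, pred))
}
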