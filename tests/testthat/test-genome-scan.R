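test_that("no Cas9 guides exist without a GG dinucleotide", {
  g <- genome("polyA", paste(rep("A", 100), collapse = ""))
  expect_identical(nrow(find_guides(g, "cas9")), 0L)
})

test_that("sequences shorter than protospacer+PAM yield no guides", {
  g <- genome("tiny", "TTTACCCGGGTTTAAACCCGG")  # 21 nt < 24
  expect_identical(nrow(find_guides(g, "cas12a")), 0L)
})

test_that("guide enumeration equals the brute-force oracle on a toy genome", {
  seq <- "TTTACCCGGGTTTAAACCCGGGTTTAAACCCGGGACGTACGTAGCTAGCTAGGATCCGAT"
  g <- genome("toy", seq)
  for (enz in c("cas9", "cas12a")) {
    got <- find_guides(g, enz)
    exp <- oracle_scan(seq, enz)
    expect_identical(got$start, exp$start)
    expect_identical(got$end, exp$end)
    expect_identical(got$strand, exp$strand)
    expect_identical(got$protospacer, exp$protospacer)
    expect_identical(got$pam, exp$pam)
  }
})

test_that("guides on a genome mirror guides on its reverse complement", {
  set.seed(401)
  seq <- random_dna(800, gc = 0.45)
  g_fwd <- genome("fwd", seq)
  g_rev <- genome("rev", oracle_revcomp(seq))
  L <- nchar(seq)
  for (enz in c("cas9", "cas12a")) {
    a <- find_guides(g_fwd, enz)
    b <- find_guides(g_rev, enz)
    expect_equal(nrow(a), nrow(b))
    # reflect b onto forward coordinates and swap strands
    b$rstart <- L - b$end
    b$rend <- L - b$start
    b$rstrand <- ifelse(b$strand == "+", "-", "+")
    key_a <- sort(paste(a$start, a$end, a$strand, a$protospacer))
    key_b <- sort(paste(b$rstart, b$rend, b$rstrand, b$protospacer))
    expect_identical(key_a, key_b)
  }
})

test_that("enumeration matches the oracle on random genomes (property)", {
  for (seed in 1:25) {
    set.seed(seed)
    seq <- random_dna(sample(200:1200, 1), gc = runif(1, 0.2, 0.7))
    g <- genome(paste0("rg", seed), seq)
    enz <- if (seed %% 2) "cas9" else "cas12a"
    got <- find_guides(g, enz)
    exp <- oracle_scan(seq, enz)
    expect_identical(got$start, exp$start, label = paste("seed", seed))
    expect_identical(got$protospacer, exp$protospacer,
                     label = paste("seed", seed))
  }
})

test_that("windows containing genomic N are skipped, never matched by PAM N", {
  # N inside the protospacer region and N at the PAM wildcard position
  seq <- paste0("TTTA", "ACGTACGTACNGTACGTACG", strrep("C", 10))
  g <- genome("withN", seq)
  s <- find_guides(g, "cas12a")
  expect_false(any(grepl("N", s$protospacer)))
  g2 <- genome("pamN", paste0("TTTN", strrep("ACGT", 5), strrep("C", 6)))
  expect_identical(nrow(find_guides(g2, "cas12a")), 0L)
})

test_that("planted off-targets are recovered at their exact mismatch level", {
  guide <- "ACCACAACCACCACAACCAC"             # A/C only
  # A/T background has no G (no NGG PAM on + or -) except planted casettes
  set.seed(402)
  bg <- function(n) paste(sample(c("A", "T"), n, replace = TRUE), collapse = "")
  mm2 <- guide
  substr(mm2, 3, 3) <- "T"; substr(mm2, 18, 18) <- "G"
  seq <- paste0(bg(120), guide, "AGG", bg(90), mm2, "TGG", bg(100))
  g <- genome("planted", seq)
  counts <- count_offtargets(guide, g, "cas9")
  oracle <- oracle_offtarget_counts(guide, seq, "cas9")
  expect_identical(counts[1, ], oracle)
  expect_identical(unname(counts[1, c("mm0", "mm1", "mm2", "mm3")]),
                   c(1L, 0L, 1L, 0L))
})

test_that("off-target counts match the exhaustive Hamming oracle (property)", {
  for (seed in 1:12) {
    set.seed(100 + seed)
    seq <- random_dna(sample(400:1500, 1), gc = runif(1, 0.25, 0.65))
    g <- genome(paste0("og", seed), seq)
    enz <- if (seed %% 2) "cas9" else "cas12a"
    sites <- find_guides(g, enz)
    if (!nrow(sites)) next
    pick <- sites$protospacer[sample.int(nrow(sites), min(3, nrow(sites)))]
    got <- count_offtargets(pick, g, enz)
    for (i in seq_along(pick)) {
      expect_identical(got[i, ], oracle_offtarget_counts(pick[i], seq, enz),
                       label = paste("seed", seed, "guide", i))
    }
  }
})

test_that("a guide from the scanned genome always hits itself", {
  set.seed(403)
  seq <- random_dna(1000, gc = 0.5)
  g <- genome("self", seq)
  sites <- find_guides(g, "cas12a")
  skip_if(nrow(sites) == 0)
  counts <- count_offtargets(sites$protospacer[1], g, "cas12a")
  expect_gte(counts[1, "mm0"], 1L)
})

test_that("cumulative off-target counts are monotone in max_mm and bounded", {
  set.seed(404)
  seq <- random_dna(1200, gc = 0.5)
  g <- genome("mono", seq)
  sites <- find_guides(g, "cas9")
  guide <- sites$protospacer[1]
  counts <- count_offtargets(guide, g, "cas9", max_mm = 5)
  cum <- cumsum(counts[1, ])
  expect_true(all(diff(cum) >= 0))
  expect_lte(sum(counts), nrow(sites))   # <= number of PAM-valid windows
})

test_that("invalid guides are rejected", {
  g <- genome("g", "TTTAACGTACGTACGTACGTACGTAA")
  expect_error(count_offtargets("ACGT", g, "cas9"), "invalid guide")
  expect_error(count_offtargets(paste(rep("N", 20), collapse = ""), g, "cas9"),
               "invalid guide")
})

test_that("target density and ratio are simple arithmetic on counts", {
  seq <- "TTTACCCGGGTTTAAACCCGGGTTTAAACCCGGGACGTACGTAGCTAGCTAGGATCCGAT"
  g <- genome("dens", seq)
  n9 <- nrow(find_guides(g, "cas9"))
  n12 <- nrow(find_guides(g, "cas12a"))
  expect_equal(target_density(g, "cas9"), n9 / nchar(seq))
  r <- cas9_to_cas12a_ratio(g)
  expect_equal(r$ratio, (n9 / nchar(seq)) / (n12 / nchar(seq)))
  g_flat <- genome("noCas12a", paste(rep("C", 200), collapse = ""))
  expect_true(is.na(cas9_to_cas12a_ratio(g_flat)$ratio))
})

test_that("concatenating genomes changes counts only near the junction", {
  set.seed(405)
  s1 <- random_dna(600, 0.5); s2 <- random_dna(600, 0.5)
  n_parts <- nrow(find_guides(genome("a", s1), "cas9")) +
    nrow(find_guides(genome("b", s2), "cas9"))
  n_cat <- nrow(find_guides(genome("ab", paste0(s1, s2)), "cas9"))
  expect_lte(abs(n_cat - n_parts), 44)  # <= 22 junction windows per strand
})

test_that("Cas9:Cas12a target ratio rises with GC on a synthetic panel", {
  gcs <- seq(0.15, 0.70, length.out = 12)
  ratios <- vapply(seq_along(gcs), function(i) {
    g <- generate_genome(20000, gc = gcs[i], seed = 500 + i)
    cas9_to_cas12a_ratio(g)$ratio
  }, numeric(1))
  expect_false(anyNA(ratios))
  expect_gt(cor(gcs, ratios, method = "spearman"), 0)
})

test_that("ratio table medians and IQRs match order statistics", {
  ratios <- data.frame(
    genome_id = "G1",
    mm_level = rep(0:2, each = 5),
    ratio = c(1.0, 1.1, 0.9, 1.3, 1.05,   # mm0
              0.8, 0.85, 1.2, 0.95, 0.7,  # mm1
              0.5, 0.55, 0.6, 0.45, 0.4)) # mm2
  res <- offtarget_ratio_table(ratios)
  for (m in 0:2) {
    x <- ratios$ratio[ratios$mm_level == m]
    row <- res$table[res$table$mm_level == m, ]
    expect_equal(row$median_ratio, sort(x)[3])
    expect_equal(row$iqr_lo, oracle_quantile7(x, 0.25))
    expect_equal(row$iqr_hi, oracle_quantile7(x, 0.75))
  }
  expect_true(all(res$pairwise$p_bonferroni >= res$pairwise$p_raw))
})

test_that("identical ratios across groups give a null test", {
  ratios <- data.frame(genome_id = rep(paste0("G", 1:4), 3),
                       mm_level = rep(0:2, each = 4), ratio = 1)
  res <- offtarget_ratio_table(ratios)
  expect_equal(res$kruskal$statistic, 0)
  expect_equal(res$kruskal$p_value, 1)
  expect_true(all(res$pairwise$p_bonferroni == 1))
})

test_that("fewer than two mismatch groups yields descriptives only", {
  ratios <- data.frame(genome_id = "G1", mm_level = 0, ratio = c(1, 2, 3))
  res <- offtarget_ratio_table(ratios)
  expect_null(res$kruskal)
  expect_identical(nrow(res$pairwise), 0L)
})
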