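# small planted-signal regression fixture: one informative column among noise
planted_regression <- function(n, p_noise = 8, noise_sd = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * (p_noise + 1)), n,
              dimnames = list(NULL, c("signal", paste0("noise", seq_len(p_noise)))))
  y <- pmin(100, pmax(0, 100 * x[, "signal"] + rnorm(n, 0, noise_sd)))
  list(x = x, y = y)
}

test_that("constant labels give constant predictions and zero training MSE", {
  set.seed(2)
  x <- matrix(runif(200), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  m <- suppressWarnings(train_regressor(x, rep(42, 20), n_trees = 50, seed = 3))
  p <- predict(m, x)
  expect_equal(p, rep(42, 20))
  expect_equal(mean((p - 42)^2), 0)
})

test_that("a noiseless planted signal is learned almost perfectly", {
  d <- planted_regression(500, seed = 11)
  train <- 1:400; test <- 401:500
  m <- train_regressor(d$x[train, ], d$y[train], seed = 12)
  p <- predict(m, d$x[test, ])
  expect_gte(cor(p, d$y[test]), 0.95)
  expect_true(all(p >= 0 & p <= 100))
})

test_that("training and prediction are bit-reproducible under a fixed seed", {
  d <- planted_regression(80, seed = 21)
  m1 <- train_regressor(d$x, d$y, n_trees = 100, seed = 7)
  m2 <- train_regressor(d$x, d$y, n_trees = 100, seed = 7)
  expect_identical(predict(m1, d$x), predict(m2, d$x))
  expect_identical(m1$oob_error, m2$oob_error)
})

test_that("schema mismatches are refused at prediction time", {
  d <- planted_regression(40, seed = 31)
  m <- train_regressor(d$x, d$y, n_trees = 20, seed = 1)
  x_bad <- d$x
  colnames(x_bad)[2] <- "renamed"
  expect_error(predict(m, x_bad), "schema mismatch")
})

test_that("labels outside [0, 100] are rejected", {
  d <- planted_regression(40, seed = 41)
  expect_error(train_regressor(d$x, d$y - 200, seed = 1), "0, 100")
})

test_that("fold assignment partitions the samples", {
  f <- make_folds(103, k = 5, seed = 9)
  expect_identical(length(f), 103L)
  expect_identical(sort(unique(f)), 1:5)
  expect_true(all(table(f) %in% c(20L, 21L)))
})

test_that("stratified folds preserve class proportions exactly at 30/10", {
  y <- rep(c("hi", "lo"), c(30, 10))
  f <- make_folds(k = 5, seed = 13, y = y)
  tab <- table(f, y)
  expect_true(all(tab[, "hi"] == 6L))
  expect_true(all(tab[, "lo"] == 2L))
  expect_error(make_folds(k = 5, seed = 1, y = c("a", "a", "b")),
               "fewer members")
})

test_that("cross-validation recovers a strong planted signal", {
  d <- planted_regression(300, noise_sd = 5, seed = 51)
  cv <- cross_validate(d$x, d$y, task = "regression", folds = 5,
                       n_trees = 150, seed = 5)
  expect_identical(sort(unique(cv$fold_id)), 1:5)
  expect_gte(cv$mean[["pearson_r"]], 0.9)
  expect_identical(nrow(cv$predictions), 300L)
})

test_that("the validation report matches formula-by-hand evaluation", {
  pred <- c(10, 30, 22, 55, 70)
  truth <- c(12, 25, 30, 50, 80)
  rep <- validate(pred, truth, task = "regression")
  expect_equal(rep$mse, mean((pred - truth)^2), tolerance = 1e-12)
  r_hand <- sum((pred - mean(pred)) * (truth - mean(truth))) /
    sqrt(sum((pred - mean(pred))^2) * sum((truth - mean(truth))^2))
  expect_equal(rep$pearson_r, r_hand, tolerance = 1e-12)
  ident <- validate(truth, truth, task = "regression")
  expect_equal(ident$mse, 0)
  expect_equal(ident$pearson_r, 1)
  anti <- validate(-truth, truth, task = "regression")
  expect_equal(anti$pearson_r, -1)
})

test_that("zero-variance inputs leave correlations missing", {
  expect_message(rep <- validate(rep(5, 4), c(1, 2, 3, 4), "regression"),
                 "zero variance")
  expect_true(is.na(rep$pearson_r))
  expect_equal(rep$mse, mean((5 - c(1, 2, 3, 4))^2))
})

test_that("percentile ranks follow the mean-of-strict-and-weak convention", {
  expect_equal(percentile_ranks(c(7, 7, 7)), rep(50, 3))
  v <- c(10, 20, 20, 30, 40, 50)
  # hand computation: e.g. the tied 20s have 1 strict-below, 3 weak-below
  expect_equal(percentile_ranks(v),
               c(100 * (0 + 1) / 12, 100 * (1 + 3) / 12, 100 * (1 + 3) / 12,
                 100 * (3 + 4) / 12, 100 * (4 + 5) / 12, 100 * (5 + 6) / 12))
  expect_true(!is.unsorted(percentile_ranks(sort(v))))
})

test_that("feature importances are normalised, sorted, and equivariant", {
  d <- planted_regression(200, seed = 61)
  m <- train_regressor(d$x, d$y, n_trees = 100, seed = 6)
  imp <- feature_importance(m)
  expect_identical(imp$feature[1], "signal")
  expect_equal(sum(imp$weight), 1, tolerance = 1e-9)
  expect_true(all(diff(imp$weight) <= 0))
  # permuting feature columns permutes importances identically
  perm <- c(5, 1, 3, 2, 4, 6, 7, 8, 9)
  m2 <- train_regressor(d$x[, perm], d$y, n_trees = 100, seed = 6)
  imp2 <- feature_importance(m2)
  expect_identical(imp2$feature[1], "signal")
})

test_that("the SNV classifier learns a planted complement rule", {
  set.seed(71)
  n <- 240
  windows <- vapply(seq_len(n), function(i) random_dna(39), character(1))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  labels <- comp[substr(windows, 3, 3)]   # outcome = complement of offset 2
  feats <- featurize_sequences(windows, families = c("positional_mono"))
  train <- 1:190; test <- 191:240
  m <- train_snv_classifier(feats[train, ], labels[train], n_trees = 150,
                            seed = 8)
  acc <- mean(as.character(predict(m, feats[test, ])) == labels[test])
  expect_gte(acc, 0.9)
  imp <- feature_importance(m)
  expect_true(any(grepl("^pos2_", imp$feature[1:5])))
  expect_equal(m$chance_accuracy, 1 / 3)
})

test_that("rows whose label equals the reference base are rejected", {
  feats <- matrix(runif(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  labels <- rep(c("A", "C"), 5)
  expect_error(train_snv_classifier(feats, labels, ref_base = "A"),
               "reference base")
})

test_that("classification validation counts and confusion add up", {
  truth <- c("A", "A", "C", "G", "G", "G")
  pred <- c("A", "C", "C", "G", "A", "G")
  rep <- validate(pred, truth, task = "classification")
  expect_equal(sum(diag(rep$confusion)), sum(pred == truth))
  expect_equal(rowSums(rep$confusion),
               c(A = 2, C = 1, G = 3))  # row sums = truth counts
  expect_equal(rep$accuracy, 4 / 6)
})

test_that("one-vs-all AUC of random scores on balanced classes is ~0.5", {
  set.seed(81)
  n <- 1000
  truth <- sample(c("A", "C", "G"), n, replace = TRUE)
  raw <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, c("A", "C", "G")))
  prob <- raw / rowSums(raw)
  rocs <- roc_one_vs_all(truth, prob)
  for (cl in names(rocs)) {
    expect_gte(rocs[[cl]]$auc, 0.45)
    expect_lte(rocs[[cl]]$auc, 0.55)
  }
})

test_that("a permutation test flags real association and not noise", {
  set.seed(91)
  x <- rnorm(120)
  y <- x + rnorm(120, 0, 0.5)
  real <- permutation_cor_test(x, y, n_perm = 999, seed = 2)
  expect_lt(real$p, 0.01)
  nul <- permutation_cor_test(x, rnorm(120), n_perm = 999, seed = 2)
  expect_gt(nul$p, 0.01)
})

test_that("planted-signal OOB beats its label-permuted twin (paired)", {
  wins <- 0L
  for (s in 1:10) {
    d <- planted_regression(120, noise_sd = 5, seed = 700 + s)
    m_true <- train_regressor(d$x, d$y, n_trees = 100, seed = s)
    set.seed(9000 + s)
    m_perm <- train_regressor(d$x, sample(d$y), n_trees = 100, seed = s)
    wins <- wins + (m_true$oob_error < m_perm$oob_error)
  }
  expect_gte(wins, 9L)
})

test_that("models round-trip through disk with their metadata sidecar", {
  d <- planted_regression(60, seed = 101)
  m <- train_regressor(d$x, d$y, n_trees = 40, seed = 4)
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$task, "regression")
  expect_identical(meta$n_trees, 40L)
  m2 <- load_model(path)
  expect_identical(predict(m2, d$x), predict(m, d$x))
})
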