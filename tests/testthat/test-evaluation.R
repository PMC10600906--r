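test_that("confusion tabulates the standard 2x2 cases", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cc2 <- confusion(c(1, 0), c(0, 1))
  expect_equal(c(cc2$TP, cc2$TN, cc2$FP, cc2$FN), c(0L, 0L, 1L, 1L))
  cc3 <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(c(cc3$TP, cc3$FN, cc3$FP, cc3$TN), c(1L, 1L, 1L, 1L))
  expect_error(confusion(c(1, 0), c(1)), "dimension error")
})

test_that("metrics computes the closed forms with degenerate flags", {
  perfect <- metrics(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(unlist(perfect[c("Acc", "Sens", "Spec", "MCC")]),
               c(Acc = 1, Sens = 1, Spec = 1, MCC = 1))
  anti <- metrics(confusion(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(anti$Acc, 0)
  expect_equal(anti$MCC, -1)
  chance <- metrics(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_equal(chance$Acc, 0.5)
  expect_equal(chance$MCC, 0)

  deg <- metrics(confusion(c(0, 0), c(0, 0)))  # no positives at all
  expect_equal(deg$Sens, 0)
  expect_true(all(c("Sens", "MCC") %in% deg$degenerate))
})

test_that("metric identities hold on exhaustive 2x2 tables (total <= 30)", {
  grid <- expand.grid(TP = 0:30, TN = 0:30, FP = 0:30, FN = 0:30)
  grid <- grid[rowSums(grid) >= 1 & rowSums(grid) <= 30, ]
  tp <- grid$TP; tn <- grid$TN; fp <- grid$FP; fn <- grid$FN
  acc <- (tp + tn) / (tp + tn + fp + fn)
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- ifelse(denom > 0, (tp * tn - fp * fn) / sqrt(denom), 0)

  # spot-check the vectorized forms against the package on a subsample,
  # then assert the identities over the full enumeration
  idx <- seq(1, nrow(grid), by = 997)
  for (i in idx) {
    cc <- structure(list(TP = tp[i], TN = tn[i], FP = fp[i], FN = fn[i]),
                    class = "confusion_counts")
    m <- metrics(cc)
    expect_equal(c(m$Acc, m$Sens, m$Spec, m$MCC),
                 c(acc[i], sens[i], spec[i], mcc[i]))
  }
  P <- tp + fn
  N <- tn + fp
  defined <- P > 0 & N > 0
  expect_true(all(abs(acc[defined] -
                        (sens[defined] * P[defined] + spec[defined] * N[defined]) /
                        (P + N)[defined]) < 1e-12))
  expect_true(all(mcc >= -1 - 1e-12 & mcc <= 1 + 1e-12))
  is_one <- abs(mcc - 1) < 1e-12
  expect_true(all(is_one == (fp == 0 & fn == 0 & tp > 0 & tn > 0)))
  is_neg1 <- abs(mcc + 1) < 1e-12
  expect_true(all(is_neg1 == (tp == 0 & tn == 0 & fp > 0 & fn > 0)))
})

test_that("auc equals the all-pairs oracle and handles ties and swaps", {
  expect_equal(auc(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(auc(c(1, 0), c(0.1, 0.9)), 0)
  expect_equal(auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  expect_error(auc(c(1, 1), c(0.5, 0.4)), "undefined-AUC")

  set.seed(77)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 1)  # coarse scores force ties
    expect_equal(auc(y, s), oracle_auc(y, s))
    expect_equal(auc(1 - y, -s), oracle_auc(y, s))   # label/score swap
    expect_equal(auc(y, -s), 1 - oracle_auc(y, s))   # score inversion
  }
})

test_that("swapping the class encoding maps Sens to Spec", {
  y <- c(1, 1, 1, 0, 0, 0, 0)
  p <- c(1, 0, 1, 0, 1, 0, 0)
  m <- metrics(confusion(y, p))
  m_swap <- metrics(confusion(1 - y, 1 - p))
  expect_equal(m_swap$Sens, m$Spec)
  expect_equal(m_swap$Spec, m$Sens)
  expect_equal(m_swap$MCC, m$MCC)
})

test_that("stratified_kfold balances classes across folds", {
  y <- rep(c(1L, 0L), each = 100)
  f <- stratified_kfold(y, k = 5, seed = 1)
  for (i in 1:5) {
    expect_equal(sum(y[f == i] == 1), 20L)
    expect_equal(sum(y[f == i] == 0), 20L)
  }
  y2 <- rep(c(1L, 0L), each = 11)
  f2 <- stratified_kfold(y2, k = 5, seed = 1)
  counts <- table(f2, y2)
  expect_true(all(counts %in% 2:3))
  expect_equal(sort(unique(f2)), 1:5)
  expect_length(f2, 22L)
  expect_identical(stratified_kfold(y2, 5, seed = 1), f2)
  expect_error(stratified_kfold(rep(c(1L, 0L), c(3, 20)), k = 5),
               "stratification")
})

test_that("cross_validate is deterministic and tiles the data across folds", {
  recs <- generate_benchmark(fixture_config(n_pos = 40, n_neg = 40,
                                            length = 21, seed = 8))
  spec <- make_spec("logistic_regression", seed = 2L)
  rep1 <- cross_validate(recs, encoding_scheme("kmer", 2), spec, seed = 4L)
  rep2 <- cross_validate(recs, encoding_scheme("kmer", 2), spec, seed = 4L)
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_equal(nrow(rep1$per_fold), 5L)
  # per-fold test sets tile the dataset exactly once
  expect_equal(sum(rep1$per_fold$TP + rep1$per_fold$TN +
                     rep1$per_fold$FP + rep1$per_fold$FN), 80)
  expect_equal(rep1$aggregate$Acc, mean(rep1$per_fold$Acc))
  expect_true(all(unlist(rep1$aggregate[c("Acc", "Sens", "Spec", "AUC")]) >= 0))

  pooled <- cross_validate(recs, encoding_scheme("kmer", 2), spec, seed = 4L,
                           aggregate = "pooled")
  total <- with(pooled$per_fold, sum(TP + TN))
  expect_equal(pooled$aggregate$Acc, total / 80)

  row <- report_to_csv_row(rep1, "synthetic")
  expect_equal(names(row),
               c("species", "scheme", "param", "model", "tuned", "protocol",
                 "Acc", "Sens", "Spec", "MCC", "AUC", "seed"))
  js <- report_to_json(rep1)
  expect_true(jsonlite::validate(js))
})

test_that("cross_species transfers across alphabets and checks lengths", {
  pair <- generate_species_pair(
    fixture_config(n_pos = 60, n_neg = 60, length = 21, seed = 5,
                   species = "a"),
    fixture_config(n_pos = 60, n_neg = 60, length = 21, seed = 6,
                   species = "b"),
    divergence = 0)
  spec <- make_spec("logistic_regression", seed = 3L)
  scheme <- encoding_scheme("binary")
  rep_dna <- cross_species(pair$a, pair$b, scheme, spec)
  expect_equal(rep_dna$protocol, "transfer")
  expect_equal(nrow(rep_dna$per_fold), 1L)

  # RNA-alphabet test set gives identical results after normalization
  rep_rna <- cross_species(pair$a, normalize_alphabet(pair$b, "RNA"),
                           scheme, spec)
  expect_identical(rep_rna$per_fold, rep_dna$per_fold)

  # matched train/test distributions: transfer Acc close to CV Acc
  cv <- cross_validate(pair$b, scheme, spec, k = 5, seed = 3L)
  expect_lt(abs(rep_dna$aggregate$Acc - cv$aggregate$Acc), 0.05)

  short <- generate_benchmark(fixture_config(n_pos = 30, n_neg = 30,
                                             length = 15, seed = 7))
  expect_error(cross_species(pair$a, short, scheme, spec),
               "incompatible-length")
  # non-positional scheme tolerates unequal lengths
  rep_k <- cross_species(pair$a, short, encoding_scheme("kmer", 2), spec)
  expect_equal(rep_k$protocol, "transfer")

  # single-class test set: AUC flagged degenerate, not an error
  one_class <- pair$b[pair$b$label == 1, ]
  rep_one <- cross_species(pair$a, one_class, scheme, spec)
  expect_match(rep_one$per_fold$degenerate, "AUC")
})
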