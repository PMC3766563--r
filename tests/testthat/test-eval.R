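test_that("confusion metrics reproduce the defining identities", {
  # TP=9 FN=1 TN=8 FP=2
  truth <- rep(c(1, 0), c(10, 10))
  pred <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm[c("TP", "FN", "TN", "FP")],
               list(TP = 9L, FN = 1L, TN = 8L, FP = 2L))
  expect_equal(cm$Sn, 0.90)
  expect_equal(cm$Sp, 0.80)
  expect_equal(cm$Acc, 0.85)

  perfect <- confusion_metrics(truth, truth)
  expect_equal(c(perfect$Sn, perfect$Sp, perfect$Acc), c(1, 1, 1))

  all_pos <- confusion_metrics(rep(1, 20), truth)
  expect_equal(c(all_pos$Sn, all_pos$Sp), c(1, 0))
})

test_that("confusion identities hold exactly over enumerated tables", {
  for (tp in 0:3) for (fn in 0:3) for (tn in 0:3) for (fp in 0:3) {
    n <- tp + fn + tn + fp
    if (n == 0) next
    truth <- rep(c(1, 1, 0, 0), c(tp, fn, tn, fp))
    pred <- rep(c(1, 0, 0, 1), c(tp, fn, tn, fp))
    cm <- confusion_metrics(pred, truth)
    expect_equal(cm$TP + cm$FN, sum(truth == 1))
    expect_equal(cm$TN + cm$FP, sum(truth == 0))
    if (tp + fn > 0) expect_equal(cm$Sn, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(cm$Sp, tn / (tn + fp))
    expect_equal(cm$Acc, (tp + tn) / n)
  }
})

test_that("a missing class yields NA rates with an explicit note", {
  cm <- confusion_metrics(c(1, 0, 1), c(1, 1, 1))
  expect_true(is.na(cm$Sp))
  expect_match(cm$notes, "Sp undefined")
  expect_equal(cm$Sn, 2 / 3)
})

test_that("ROC endpoints, monotonicity and canonical auROC values", {
  # perfect separation
  r <- roc_auroc(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_equal(r$auroc, 1)
  # all scores tied: random-guess diagonal
  r2 <- roc_auroc(rep(1, 10), rep(c(0, 1), 5))
  expect_equal(r2$auroc, 0.5)
  # brute-force over the 4 pairs: 3 wins, 1 loss
  r3 <- roc_auroc(c(2, 3, 1, 2.5), c(1, 1, 0, 0))
  expect_equal(r3$auroc, 0.75)

  expect_equal(r3$points$fpr[1], 0)
  expect_equal(r3$points$tpr[1], 0)
  expect_equal(r3$points$fpr[nrow(r3$points)], 1)
  expect_equal(r3$points$tpr[nrow(r3$points)], 1)
  expect_true(all(diff(r3$points$fpr) >= 0))
  expect_true(all(diff(r3$points$tpr) >= 0))

  expect_error(roc_auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("trapezoidal auROC equals the pairwise-rank oracle on random score sets", {
  set.seed(19)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    expect_equal(roc_auroc(scores, truth)$auroc, rank_auroc(scores, truth))
  }
})

test_that("auROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  truth <- sample(0:1, 60, replace = TRUE, prob = c(0.6, 0.4))
  truth[1:2] <- 0:1
  scores <- rnorm(60) + truth
  ref <- suppressMessages(as.numeric(pROC::auc(truth, scores)))
  expect_equal(roc_auroc(scores, truth)$auroc, ref)
})

test_that("jackknife on separable data is perfect, deterministic, complete", {
  ds <- separable_dataset(4)
  fm <- encode_dataset(ds)
  r1 <- jackknife(fm, ds$labels)
  expect_equal(r1$Acc, 1)
  expect_equal(r1$auroc, 1)
  expect_equal(nrow(r1$per_sample), nrow(fm))
  expect_setequal(r1$per_sample$id, ds$records$id)

  r2 <- jackknife(fm, ds$labels)
  expect_identical(r1$per_sample, r2$per_sample)
})

test_that("jackknife is permutation invariant up to row order", {
  blobs <- gauss_blobs(10, p = 3, sep = 2, seed = 31)
  r <- jackknife(blobs$X, blobs$y)
  set.seed(1)
  perm <- sample(nrow(blobs$X))
  rp <- jackknife(blobs$X[perm, ], blobs$y[perm])
  o1 <- r$per_sample[order(r$per_sample$id), ]
  o2 <- rp$per_sample[order(rp$per_sample$id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_equal(r$auroc, rp$auroc)
})

test_that("fast leave-one-out path equals explicit per-fold refitting", {
  blobs <- gauss_blobs(8, p = 5, sep = 1.5, seed = 13)
  fast <- jackknife(blobs$X, blobs$y)
  slow <- jackknife(blobs$X, blobs$y,
                    trainer = function(X, y) nb_fit(X, y))
  expect_equal(fast$per_sample$score, slow$per_sample$score,
               tolerance = 1e-10)
  expect_equal(fast$Acc, slow$Acc)
})

test_that("duplicated samples score identically and keep the ranking consistent", {
  # at this n the leave-one-out parameter shift is small, so the duplicated
  # dataset's scores should track the original ranking closely
  blobs <- gauss_blobs(30, p = 3, sep = 2, seed = 17)
  r1 <- jackknife(blobs$X, blobs$y)
  X2 <- rbind(blobs$X, blobs$X)
  rownames(X2) <- paste0("r", seq_len(nrow(X2)))
  r2 <- jackknife(X2, c(blobs$y, blobs$y))
  n <- nrow(blobs$X)
  first_copy <- r2$per_sample$score[seq_len(n)]
  second_copy <- r2$per_sample$score[n + seq_len(n)]
  # exact symmetry: the two copies of a sample get identical held-out scores
  expect_equal(first_copy, second_copy)
  # and the score ranking stays in step with the original dataset's
  expect_gt(stats::cor(r1$per_sample$score, first_copy,
                       method = "spearman"), 0.9)
})

test_that("raising theta trades sensitivity for specificity monotonically", {
  blobs <- gauss_blobs(20, p = 3, sep = 2, seed = 41)
  scores <- jackknife(blobs$X, blobs$y)$per_sample$score
  grid <- sort(c(-Inf, scores, Inf))
  sn <- sp <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cm <- confusion_metrics(as.integer(scores >= grid[i]), blobs$y)
    sn[i] <- cm$Sn
    sp[i] <- cm$Sp
  }
  expect_true(all(diff(sn) <= 0))
  expect_true(all(diff(sp) >= 0))
})

test_that("stratified folds balance both classes and obey the seed", {
  y <- rep(c(1, 0), c(23, 57))
  f1 <- stratified_folds(y, 10, seed = 3)
  f2 <- stratified_folds(y, 10, seed = 3)
  expect_identical(f1, f2)
  for (cls in 0:1) {
    sizes <- table(f1[y == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_false(identical(f1, stratified_folds(y, 10, seed = 4)))
})

test_that("k-fold with k = n reduces to the jackknife", {
  blobs <- gauss_blobs(6, p = 3, sep = 2, seed = 29)
  jk <- jackknife(blobs$X, blobs$y)
  kf <- kfold(blobs$X, blobs$y, k = nrow(blobs$X), seed = 2)
  o <- order(kf$per_sample$id)
  expect_equal(kf$per_sample$score[o],
               jk$per_sample$score[order(jk$per_sample$id)],
               tolerance = 1e-10)

  # determinism of the full report
  expect_identical(kfold(blobs$X, blobs$y, k = 4, seed = 7),
                   kfold(blobs$X, blobs$y, k = 4, seed = 7))
})

test_that("independent test reports calls, correct count, and NA for absent class", {
  ds <- separable_dataset(5)
  fm <- encode_dataset(ds)
  model <- nb_fit(fm, ds$labels)
  pos_only <- fm[ds$labels == 1, , drop = FALSE]
  r <- independent_test(model, pos_only)
  expect_equal(r$n_correct, r$TP)
  expect_true(is.na(r$Sp))
  expect_true(all(r$calls %in% c("Antioxidant", "Nonantioxidant")))
  expect_equal(nrow(r$per_sample), nrow(pos_only))
  expect_error(independent_test(model, fm[0, , drop = FALSE]), "empty")
})
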