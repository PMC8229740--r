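# signature training stages and the fitted model object

test_that("Z-score normalisation freezes training parameters", {
  tr <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  p <- zscore_fit(tr)
  zt <- zscore_apply(p, tr)
  expect_equal(unname(zt[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(zt)), c(0, 0))
  expect_equal(unname(apply(zt, 2, sd)), c(1, 1))

  te <- cbind(a = c(4, 5), b = c(0, 100))
  zte <- zscore_apply(p, te)
  expect_equal(unname(zte[, "a"]), (c(4, 5) - 2) / 1)   # train mean/sd only
  # reapplying the frozen parameters reproduces the training transform
  expect_equal(zscore_apply(p, tr), zt)
  # zero-variance columns are dropped, not normalised
  p2 <- suppressMessages(zscore_fit(cbind(a = c(1, 2, 3), c = c(4, 4, 4))))
  expect_identical(p2$dropped, "c")
})

test_that("redundancy pruning keeps the pair member with lower mean
          correlation and deduplicates exact copies", {
  set.seed(5)
  n <- 500
  S <- matrix(c(1, .92, .2, .92, 1, .5, .2, .5, 1), 3, 3)
  L <- chol(S)
  x <- matrix(rnorm(n * 3), n, 3) %*% L
  colnames(x) <- c("A", "B", "C")
  rho <- abs(cor(apply(x, 2, rank)))
  # premise of the worked example: only (A,B) exceeds the threshold
  expect_gt(rho["A", "B"], 0.85)
  expect_lt(rho["A", "C"], 0.85); expect_lt(rho["B", "C"], 0.85)
  expect_lt(rho["A", "C"], rho["B", "C"])  # A has the lower mean correlation
  expect_identical(prune_redundant(x), c("A", "C"))

  dup <- cbind(x, A2 = x[, "A"])
  kept <- prune_redundant(dup)
  expect_equal(sum(kept %in% c("A", "A2")), 1)  # exactly one copy survives
})

test_that("the AUC filter is orientation corrected and strict", {
  set.seed(6)
  y <- rep(c(0, 1), each = 100)
  x <- cbind(same = y + rnorm(200, 0, 1e-3),
             anti = -y + rnorm(200, 0, 1e-3),
             noise = rnorm(200))
  kept <- auc_filter(x, y)
  expect_true(all(c("same", "anti") %in% kept))
  expect_false("noise" %in% kept)
  aucs <- attr(kept, "auc")
  expect_equal(unname(aucs["same"]), 1)
  expect_equal(unname(aucs["anti"]), 1)          # perfectly anti-ordered
  expect_gt(unname(aucs["noise"]), 0.3)
  expect_lt(unname(aucs["noise"]), 0.7)
  expect_error(auc_filter(x[, "noise", drop = FALSE], y), "no feature")
})

test_that("SMOTE balances classes with convex-combination synthetics", {
  set.seed(10)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c(0, 1), each = 10)
  out <- smote(x, y)                  # already balanced: unchanged
  expect_identical(out$x, x); expect_identical(out$labels, as.integer(y))

  y2 <- rep(c(0, 1), c(16, 4))
  out2 <- smote(x, y2)
  expect_equal(sum(out2$labels == 1), sum(out2$labels == 0))
  syn <- out2$x[-seq_len(20), , drop = FALSE]
  mino <- x[y2 == 1, , drop = FALSE]
  for (j in 1:2) {                    # synthetic points stay in the hull box
    expect_true(all(syn[, j] >= min(mino[, j]) - 1e-12))
    expect_true(all(syn[, j] <= max(mino[, j]) + 1e-12))
  }

  # a minority of two identical points can only synthesise that point
  x3 <- rbind(matrix(rnorm(20), 10, 2), c(1, 2), c(1, 2))
  colnames(x3) <- c("f1", "f2")
  y3 <- rep(c(0, 1), c(10, 2))
  out3 <- suppressMessages(smote(x3, y3))
  syn3 <- out3$x[-seq_len(12), , drop = FALSE]
  expect_true(all(apply(syn3, 1, function(r) all(r == c(1, 2)))))

  # hull property across 100 seeded draws
  set.seed(77)
  for (q in 1:100) {
    xx <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("f1", "f2")))
    yy <- rep(c(0, 1), c(9, 6))
    oo <- smote(xx, yy)
    ss <- oo$x[-seq_len(15), , drop = FALSE]
    mm <- xx[yy == 1, , drop = FALSE]
    expect_true(all(ss[, 1] >= min(mm[, 1]) & ss[, 1] <= max(mm[, 1])))
    expect_true(all(ss[, 2] >= min(mm[, 2]) & ss[, 2] <= max(mm[, 2])))
  }
})

test_that("LASSO: sparsity is monotone along an orthogonal-design path and a
          planted feature is recovered among noise", {
  # orthogonal design: the lasso path is exact soft-thresholding, so the
  # active-set size is non-increasing in lambda (ties allowed)
  set.seed(19)
  q <- qr.Q(qr(matrix(rnorm(64 * 8), 64, 8)))
  colnames(q) <- paste0("o", 1:8)
  yq <- as.integer(q[, 1] + 0.5 * q[, 2] + rnorm(64, 0, 0.2) > 0)
  selq <- lasso_select(q, yq, n_folds = 4)
  expect_equal(selq$n_nonzero[1], 0)             # full-shrinkage limit
  expect_true(all(diff(selq$n_nonzero) >= 0))    # grid decreases in lambda

  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  hits <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    x <- cbind(signal = y + rnorm(n, 0, 0.3),
               matrix(rnorm(n * 50), n,
                      dimnames = list(NULL, paste0("n", 1:50))))
    sel <- lasso_select(x, y)
    if ("signal" %in% sel$features) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("the cubic SVM separates a separable fixture and mirrors under
          label flips", {
  set.seed(30)
  x <- rbind(matrix(rnorm(60, -3, 0.5), 30, 2),
             matrix(rnorm(60, 3, 0.5), 30, 2))
  colnames(x) <- c("u", "v")
  y <- rep(c(0, 1), each = 30)
  fit <- train_svm(x, y)
  expect_equal(fit$degree, 3)
  sc <- svm_decision(fit, x)
  expect_equal(mean((sc > 0) == (y == 1)), 1)      # training accuracy 1

  fit_flip <- train_svm(x, 1 - y)
  sc_flip <- svm_decision(fit_flip, x)
  a1 <- roc_auc(sc, y)$auc
  a2 <- roc_auc(sc_flip, y)$auc
  expect_equal(a2, 1 - a1, tolerance = 1e-9)
})

test_that("the ROC threshold lands at the closest-to-corner operating
          point", {
  # perfectly separated: the chosen point is the ideal corner
  thr <- choose_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(thr, 0.5)
  sens <- mean(c(0.8, 0.9) > thr); fpr <- mean(c(0.1, 0.2) > thr)
  expect_equal(c(sens, fpr), c(1, 0))

  set.seed(40)
  sc <- c(rnorm(30, 0), rnorm(30, 1.2)); y <- rep(c(0, 1), each = 30)
  thr2 <- choose_threshold(sc, y)
  # exhaustive check: no candidate threshold is closer to (sens 1, fpr 0)
  cand <- sort(unique(c(sc - 1e-9, sc + 1e-9)))
  dd <- vapply(cand, function(t)
    sqrt((1 - mean(sc[y == 1] > t))^2 + mean(sc[y == 0] > t)^2), 0)
  d_at <- sqrt((1 - mean(sc[y == 1] > thr2))^2 + mean(sc[y == 0] > thr2)^2)
  expect_lte(d_at, min(dd) + 1e-12)

  expect_warning(choose_threshold(rep(1, 4), c(0, 1, 0, 1)), "degenerate")
})

test_that("fit_signature nests its feature lists, is deterministic, and is
          reproduced exactly by its JSON serialisation", {
  set.seed(55)
  n <- 60
  y <- rep(c(0, 1), c(38, 22))
  x <- cbind(matrix(rnorm(n * 8), n, dimnames = list(
    sprintf("P%02d", 1:n), paste0("f", 1:8))))
  x[, "f1"] <- y + rnorm(n, 0, 0.4)
  x[, "f2"] <- x[, "f1"] * 2 + rnorm(n, 0, 0.01)    # redundant with f1
  m <- suppressMessages(fit_signature(x, y, seed = 3))

  expect_true(all(m$lasso_features %in% m$auc_features))
  expect_true(all(m$auc_features %in% m$pruned_features))
  expect_true(all(m$pruned_features %in% m$stable_features))

  m2 <- suppressMessages(fit_signature(x, y, seed = 3))
  expect_identical(as.character(signature_to_json(m)),
                   as.character(signature_to_json(m2)))

  # applying the model to its own training set is deterministic
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1, p2)

  mj <- signature_from_json(signature_to_json(m))
  expect_lt(max(abs(predict(mj, x)$score - p1$score)), 1e-12)

  # a test matrix missing model features fails loudly, naming them
  expect_error(predict(m, x[, -1]), "f1")
})
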