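test_that("fold plans partition, stratify and reproduce deterministically", {
  y <- factor(rep(c("a", "b", "c", "d"), each = 81))   # 324 trials
  fp <- make_folds(y, k = 9, runs = 3, seed = 7)
  for (r in 1:3) {
    f <- fp$assignments[[r]]
    expect_equal(sort(unique(f)), 1:9)
    expect_length(f, 324)
    # class-stratified within +-1
    tab <- table(f, y)
    expect_lte(max(tab) - min(tab), 1)
  }
  # same seed -> identical plan; different runs -> different permutations
  fp2 <- make_folds(y, k = 9, runs = 3, seed = 7)
  expect_identical(fp$assignments, fp2$assignments)
  expect_false(identical(fp$assignments[[1]], fp$assignments[[2]]))
  expect_error(make_folds(y[1:5], k = 9), "exceeds")
  expect_error(make_folds(y, k = 1), "at least 2")
})

test_that("fold sizes reproduce the canonical 2592/9 geometry", {
  y <- factor(rep(1:4, each = 648))
  fp <- make_folds(y, k = 9, runs = 1, seed = 1)
  expect_equal(unname(table(fp$assignments[[1]])), rep(288L, 9),
               ignore_attr = TRUE)
})

test_that("perfect and degenerate predictions hit the metric identities", {
  y <- factor(rep(c("a", "b", "c", "d"), 25))
  m <- compute_metrics(y, y)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1_macro, 1)
  expect_equal(m$f1_micro, 1)
  expect_equal(m$precision_macro, 1)
})

test_that("micro F1 and micro precision equal accuracy for any prediction", {
  set.seed(21)
  for (i in 1:20) {
    y <- factor(sample(letters[1:4], 60, replace = TRUE), levels = letters[1:4])
    p <- factor(sample(letters[1:4], 60, replace = TRUE), levels = letters[1:4])
    m <- compute_metrics(y, p)
    expect_identical(m$f1_micro, m$accuracy)
    expect_identical(m$precision_micro, m$accuracy)
    expect_true(all(unlist(m[c("accuracy", "f1_macro", "f1_micro",
                               "precision_macro", "precision_micro")]) >= 0))
  }
})

test_that("macro F1 matches a brute-force confusion-table oracle", {
  # hand-computed 4x4 example
  y <- factor(c(rep("a", 10), rep("b", 10), rep("c", 10), rep("d", 10)))
  p <- factor(c(rep("a", 8), "b", "c",         # a: 8 right
                rep("b", 6), rep("a", 4),      # b: 6 right
                rep("c", 10),                  # c: all right
                rep("d", 5), rep("a", 5)),     # d: 5 right
              levels = levels(y))
  m <- compute_metrics(y, p)
  brute <- local({
    f1s <- numeric(4)
    for (k in 1:4) {
      cl <- levels(y)[k]
      tp <- sum(y == cl & p == cl)
      prec <- ifelse(sum(p == cl) > 0, tp / sum(p == cl), 0)
      rec <- tp / sum(y == cl)
      f1s[k] <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    }
    mean(f1s)
  })
  expect_equal(m$f1_macro, brute, tolerance = 1e-12)
  expect_equal(m$accuracy, 29 / 40)
})

test_that("uniform random scores give chance-level ROC-AUC", {
  set.seed(31)
  n <- 10000
  y <- factor(sample(letters[1:4], n, replace = TRUE))
  sc <- matrix(stats::runif(n * 4), n)
  sc <- sc / rowSums(sc)
  m <- compute_metrics(y, factor(letters[max.col(sc)], levels(y)), sc)
  expect_equal(m$auc_macro, 0.5, tolerance = 0.02)
  expect_equal(m$auc_micro, 0.5, tolerance = 0.02)
  expect_true(m$auc_defined)
})

test_that("AUC agrees with a pair-counting oracle and flags absent classes", {
  set.seed(33)
  y <- factor(c(rep("a", 30), rep("b", 70)), levels = c("a", "b"))
  sc <- cbind(a = stats::rnorm(100, ifelse(y == "a", 1, 0)), b = 0)
  sc[, "b"] <- 1 - sc[, "a"]
  m <- compute_metrics(y, y, sc)
  pos <- sc[y == "a", "a"]; neg <- sc[y != "a", "a"]
  pairs <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  expect_equal(m$auc_macro, mean(pairs), tolerance = 1e-12)
  y1 <- factor(rep("a", 10), levels = c("a", "b"))
  expect_warning(m1 <- compute_metrics(y1, y1, cbind(a = runif(10), b = 0)),
                 "undefined")
  expect_false(m1$auc_defined)
})

test_that("cross-validation wires training, prediction and reporting together", {
  set.seed(41)
  n <- 90
  x <- array(rnorm(8 * 8 * n, sd = 0.2), c(n, 8, 8))
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  x[y == "b", 1:4, 1:4] <- x[y == "b", 1:4, 1:4] + 3
  x[y == "c", 5:8, 5:8] <- x[y == "c", 5:8, 5:8] + 3
  fp <- make_folds(y, k = 3, runs = 2, seed = 3)
  rep_ <- run_cv(x, function(s, k) build_plv_cnnm(s, k, filters = c(4, 8)),
                 train_config(max_epochs = 30, batch_size = 10, seed = 1),
                 fp, y = y)
  expect_s3_class(rep_, "eval_report")
  expect_equal(nrow(rep_$per_fold), 6)        # 3 folds x 2 runs
  expect_identical(rep_$per_fold$f1_micro, rep_$per_fold$accuracy)
  expect_identical(rep_$per_fold$precision_micro, rep_$per_fold$accuracy)
  expect_gt(rep_$aggregate$accuracy, 0.8)     # easy planted means
  expect_equal(rep_$aggregate$accuracy_sd, sd(rep_$per_fold$accuracy))
  row <- report_row(rep_)
  expect_equal(row$accuracy, rep_$aggregate$accuracy)
})

test_that("grid harness sweeps rows, flags the best and survives bad rows", {
  set.seed(43)
  n <- 60
  x <- array(rnorm(8 * 8 * n, sd = 0.2), c(n, 8, 8))
  y <- factor(rep(c("a", "b"), each = n / 2))
  x[y == "b", 1:4, ] <- x[y == "b", 1:4, ] + 1.2
  fp <- make_folds(y, k = 2, runs = 1, seed = 5)
  grid <- data.frame(filters1 = c(2L, 4L, 64L), filters2 = c(4L, 8L, 128L),
                     kernel = c(2L, 3L, 20L))   # kernel 20 cannot fit 8x8
  out <- hyperparameter_grid(x, grid, model = "plv",
                             config = train_config(max_epochs = 6,
                                                   batch_size = 20, seed = 1),
                             fold_plan = fp, y = y)
  expect_equal(nrow(out), 3)
  expect_true(out$failed[3])
  expect_true(is.na(out$accuracy[3]))
  expect_equal(sum(out$best, na.rm = TRUE), 1)
  expect_false(out$best[3])
})

test_that("packaged grids mirror the canonical tuning tables", {
  g1 <- default_grid("adj_filters")
  expect_equal(g1$filters, c(32L, 64L, 128L, 256L))
  expect_true(all(g1$kernel_w == 45L))
  g2 <- default_grid("adj_kernels")
  expect_equal(g2$kernel_w, c(22L, 45L, 65L, 85L))
  g3 <- default_grid("plv")
  expect_equal(nrow(g3), 8)
  expect_setequal(paste(g3$filters1, g3$filters2),
                  paste(c(8, 32, 128, 256), c(16, 64, 256, 512)))
  expect_setequal(unique(g3$kernel), c(2L, 3L))
})
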