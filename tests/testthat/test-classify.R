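# small synthetic feature tables used across blocks
separable_xy <- function(n_per_class = 20, k = 6, gap = 8, seed = 101) {
  with_seed_local(seed, {
    classes <- c("0", "1+", "2+", "3+")
    x <- do.call(rbind, lapply(seq_along(classes), function(i)
      matrix(rnorm(n_per_class * k, mean = gap * i), n_per_class)))
    list(x = x, y = factor(rep(classes, each = n_per_class), levels = classes))
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

test_that("both learners separate well-separated classes perfectly", {
  d <- separable_xy()
  for (learner in c("logreg", "svm")) {
    fit <- her2_ova(d$x, d$y, learner = learner)
    expect_equal(mean(predict(fit, d$x) == d$y), 1)
    sc <- predict(fit, d$x, type = "score")
    expect_equal(dim(sc), c(length(d$y), 4))
  }
})

test_that("held-out accuracy sits at chance when labels are independent of features", {
  with_seed_local(102, {
    x <- matrix(rnorm(400 * 8), 400)
    y <- rep(c("0", "1+", "2+", "3+"), each = 100)
  })
  acc <- vapply(1:20, function(r) {
    sp <- holdout_split(data.frame(label = y, x), train_frac = 0.7, seed = r)
    fit <- her2_ova(as.matrix(sp$train[, -1]), sp$train$label)
    mean(predict(fit, as.matrix(sp$test[, -1])) == sp$test$label)
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.25), 0.05)
})

test_that("degenerate inputs raise informative errors", {
  d <- separable_xy(n_per_class = 5)
  expect_error(her2_ova(d$x, rep("2+", nrow(d$x))), "at least 2 classes")
  y <- as.character(d$y); y[y == "0"] <- "1+"; y[1] <- "0"
  expect_error(her2_ova(d$x, y), "class '0'")
})

test_that("holdout splits are stratified, seeded and reproduce the 70/30 sample counts", {
  # class sizes chosen to total 4019 tiles
  sizes <- c(1033, 850, 997, 1139)
  df <- data.frame(label = rep(c("0", "1+", "2+", "3+"), sizes),
                   f = seq_len(sum(sizes)))
  sp <- holdout_split(df, train_frac = 0.70, seed = 5)
  expect_equal(nrow(sp$train), 2813)
  expect_equal(nrow(sp$test), 1206)
  for (cl in unique(df$label)) {
    n_tr <- sum(sp$train$label == cl)
    expect_equal(n_tr, round(0.7 * sum(df$label == cl)))
  }
  sp2 <- holdout_split(df, train_frac = 0.70, seed = 5)
  expect_identical(sp$train$f, sp2$train$f)
  sp3 <- holdout_split(df, train_frac = 0.70, seed = 6)
  expect_false(identical(sp$train$f, sp3$train$f))
})

test_that("evaluation reproduces confusion-derived metrics", {
  d <- separable_xy()
  fit <- her2_ova(d$x, d$y)
  rep_ <- evaluate(fit, list(x = d$x, y = d$y))
  expect_equal(unname(diag(rep_$confusion)), rep(20, 4))
  expect_equal(unname(rep_$f1), rep(1, 4))
  expect_equal(rep_$accuracy, 1)

  # hand-checkable row: recall = diagonal / row sum
  conf <- matrix(c(299, 11, 0, 0,
                   42, 206, 7, 0,
                   5, 1, 286, 7,
                   0, 0, 1, 341), 4, 4, byrow = TRUE,
                 dimnames = list(actual = c("0", "1+", "2+", "3+"),
                                 predicted = c("0", "1+", "2+", "3+")))
  r <- her2feat:::confusion_report(conf)
  expect_equal(unname(r$recall["0"]), 299 / 310, tolerance = 1e-12)
  expect_equal(round(unname(r$recall["0"]), 2), 0.96)
  expect_equal(unname(r$precision["0"]), 299 / (299 + 42 + 5))
  expect_equal(r$accuracy, (299 + 206 + 286 + 341) / sum(conf))

  # unseen test label is an error
  expect_error(evaluate(fit, list(x = d$x[1:2, ], y = c("0", "4+"))),
               "unseen")
})

test_that("repeated cross-validation is stratified, deterministic and reports per-trial accuracies", {
  d <- separable_xy(n_per_class = 15)
  df <- data.frame(label = as.character(d$y), d$x)
  r1 <- repeated_cv(df, folds = 5, repeats = 3, seed = 7)
  r2 <- repeated_cv(df, folds = 5, repeats = 3, seed = 7)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_length(r1$accuracies, 3)
  expect_equal(r1$mean_accuracy, 1)
  expect_equal(sum(r1$confusion), 3 * nrow(df))

  expect_error(repeated_cv(df[c(1:4, 16:60), ], folds = 5, repeats = 1),
               "fewer samples")

  # on non-separable data, different seeds shuffle folds differently
  with_seed_local(103, {
    dfn <- data.frame(label = rep(c("0", "1+", "2+", "3+"), each = 20),
                      matrix(rnorm(80 * 4), 80))
  })
  n1 <- repeated_cv(dfn, folds = 4, repeats = 3, seed = 7)
  n2 <- repeated_cv(dfn, folds = 4, repeats = 3, seed = 7)
  n3 <- repeated_cv(dfn, folds = 4, repeats = 3, seed = 8)
  expect_identical(n1$accuracies, n2$accuracies)
  expect_false(identical(n1$accuracies, n3$accuracies))
})

test_that("stratified CV folds keep class proportions within one sample", {
  y <- factor(rep(c("0", "1+", "2+", "3+"), c(40, 37, 23, 55)))
  fold_of <- integer(length(y))
  her2feat:::with_seed(99, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold_of[idx] <- rep_len(1:5, length(idx))
    }
  })
  for (f in 1:5) for (cl in levels(y)) {
    in_fold <- sum(y[fold_of == f] == cl)
    expect_lte(abs(in_fold - sum(y == cl) / 5), 1)
  }
})

test_that("leave-one-out on trivially separable samples is perfect", {
  x <- matrix(c(0, 0, 0, 0, 10, 10, 10, 10), ncol = 1)
  x <- cbind(x, x)
  df <- data.frame(label = rep(c("0", "3+"), each = 4), x)
  r <- repeated_cv(df, folds = 4, repeats = 1, seed = 1)
  expect_equal(r$accuracy, 1)
})

test_that("logreg and svm produce comparable report structures on pipeline features", {
  dat <- generate_dataset(n_per_class = 12, seed = 2, size = 64)
  feats <- suppressMessages(extract_dataset(dat$tiles, dat$labels))
  reports <- lapply(c("logreg", "svm"), function(ln)
    repeated_cv(feats, learner = ln, folds = 3, repeats = 2, seed = 3))
  cmp <- data.frame(learner = c("logreg", "svm"),
                    mean = vapply(reports, `[[`, numeric(1), "mean_accuracy"),
                    sd = vapply(reports, `[[`, numeric(1), "sd_accuracy"))
  expect_equal(dim(cmp), c(2, 3))
  expect_true(all(cmp$mean >= 0 & cmp$mean <= 1))
  for (r in reports) {
    expect_s3_class(r, "her2_report")
    expect_equal(rownames(r$confusion), c("0", "1+", "2+", "3+"))
  }
})
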