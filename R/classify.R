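# --- seeding helpers ---------------------------------------------------------

# Derive a child seed (< 2^31) from a master seed and up to two indices, so
# that every randomised step is reproducible from a single documented seed.
derive_seed <- function(master, a = 0, b = 0) {
  as.integer((abs(as.numeric(master)) %% 1e6 * 1009 +
                as.numeric(a) * 7919 + as.numeric(b) * 131) %% 2147483647)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Stratified train/test indices: round(n_c * frac) per class (clamped so
# neither side is empty for classes with >= 2 samples).
stratified_split_idx <- function(labels, train_frac, seed) {
  labels <- factor(labels)
  with_seed(seed, {
    train <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      k <- round(length(idx) * train_frac)
      k <- max(1L, min(k, max(length(idx) - 1L, 1L)))
      train <- c(train, sample(idx, k))
    }
    list(train = sort(train),
         test = setdiff(seq_along(labels), train))
  })
}

#' Stratified holdout split of a feature table
#'
#' Random class-stratified split into a training and a test portion
#' (default 70/30); class proportions are preserved within rounding.
#'
#' @param features a feature table with a `label` column.
#' @param train_frac training fraction in (0, 1).
#' @param seed split seed; the same seed reproduces the same split.
#' @return list with data frames `train` and `test`.
#' @export
holdout_split <- function(features, train_frac = 0.70, seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1, "label" %in% names(features))
  sp <- stratified_split_idx(features$label, train_frac, seed)
  list(train = features[sp$train, , drop = FALSE],
       test = features[sp$test, , drop = FALSE])
}

# --- one-vs-all model --------------------------------------------------------

#' Fit a one-vs-all HER2 classifier
#'
#' Fits one binary classifier per class on z-scored features (the
#' standardisation parameters are learned from the training data only) and
#' predicts by the maximal decision score.  Two learners are available:
#' ridge-penalised logistic regression (via \pkg{glmnet}; penalty
#' `lambda = 1 / (n * C)` with inverse strength `C` from the config) and a
#' support vector machine (via \pkg{e1071}; RBF kernel by default, kernel
#' width by the median heuristic unless set in the config).
#'
#' @param x numeric feature matrix (or a feature table, in which case `y`
#'   defaults to its `label` column).
#' @param y class labels; at least two classes, each with >= 2 samples.
#' @param learner `"logreg"` or `"svm"`.
#' @param config a [her2_config()] supplying the hyperparameters.
#' @return object of class `her2_ova` with `print`, `summary`, `coef` and
#'   `predict` methods.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' y <- rep(c("0", "3+"), each = 20)
#' fit <- her2_ova(x, y)
#' table(predict(fit, x), y)
her2_ova <- function(x, y = NULL, learner = c("logreg", "svm"),
                     config = her2_config()) {
  learner <- match.arg(learner)
  if (is.data.frame(x) && "label" %in% names(x) && is.null(y)) {
    xy <- features_xy(x)
    x <- xy$x; y <- xy$y
  }
  x <- as.matrix(x)
  y <- factor(y, levels = intersect(c(HER2_LEVELS, levels(factor(y))),
                                    unique(as.character(y))))
  if (nlevels(y) < 2) stop("need at least 2 classes to train")
  cnt <- table(y)
  if (any(cnt < 2))
    stop("degenerate class count for class '",
         names(cnt)[which(cnt < 2)[1]], "' (need >= 2 samples)")
  stopifnot(nrow(x) == length(y))

  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  sigma[sigma == 0] <- 1
  xs <- scale(x, center = mu, scale = sigma)

  gamma <- config$learner.svm_gamma
  if (learner == "svm" && is.na(gamma)) gamma <- median_heuristic_gamma(xs)

  models <- list()
  flips <- logical(nlevels(y))
  for (k in seq_len(nlevels(y))) {
    cl <- levels(y)[k]
    ybin <- y == cl
    if (learner == "logreg") {
      lambda <- 1 / (nrow(xs) * config$learner.logreg_C)
      models[[cl]] <- withCallingHandlers(
        glmnet::glmnet(xs, factor(ybin, levels = c(FALSE, TRUE)),
                       family = "binomial", alpha = 0,
                       lambda = lambda, standardize = FALSE),
        warning = function(w) {
          # small-class advisory; ridge keeps the fit well-defined
          if (grepl("fewer than 8", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    } else {
      fit <- e1071::svm(xs, factor(ifelse(ybin, "pos", "neg"),
                                   levels = c("pos", "neg")),
                        kernel = config$learner.svm_kernel,
                        cost = config$learner.svm_cost,
                        gamma = gamma, scale = FALSE)
      dv <- attr(predict(fit, xs, decision.values = TRUE),
                 "decision.values")[, 1]
      flips[k] <- mean(dv[ybin]) < mean(dv[!ybin])
      models[[cl]] <- fit
    }
  }
  structure(list(learner = learner, classes = levels(y), models = models,
                 mu = mu, sigma = sigma, flips = flips, gamma = gamma,
                 n_train = nrow(x), config_hash = config_hash(config)),
            class = "her2_ova")
}

# Median-heuristic RBF kernel width on standardized features.
median_heuristic_gamma <- function(xs, max_n = 500) {
  if (nrow(xs) > max_n) xs <- xs[seq(1, nrow(xs), length.out = max_n), ]
  d2 <- stats::dist(xs)^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med == 0) 1 / ncol(xs) else 1 / (2 * med)
}

#' Decision scores and class predictions
#'
#' @param object a fitted [her2_ova()] model.
#' @param newdata feature matrix or feature table.
#' @param type `"class"` (default) for the argmax label, `"score"` for the
#'   n x K matrix of per-class decision scores.
#' @param ... unused.
#' @return factor of predicted labels, or a score matrix.
#' @export
predict.her2_ova <- function(object, newdata, type = c("class", "score"),
                             ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata))
    newdata <- features_xy(newdata, require_labels = FALSE)$x
  newdata <- as.matrix(newdata)
  xs <- scale(newdata, center = object$mu, scale = object$sigma)
  scores <- sapply(seq_along(object$classes), function(k) {
    cl <- object$classes[k]
    if (object$learner == "logreg") {
      as.numeric(predict(object$models[[cl]], xs, type = "link"))
    } else {
      dv <- attr(predict(object$models[[cl]], xs, decision.values = TRUE),
                 "decision.values")[, 1]
      if (object$flips[k]) -dv else dv
    }
  })
  scores <- matrix(scores, nrow = nrow(xs),
                   dimnames = list(NULL, object$classes))
  if (type == "score") return(scores)
  top <- max.col(scores, ties.method = "first")  # ties: lowest class index
  n_tied <- sum(apply(scores, 1, function(s) sum(s == max(s)) > 1))
  if (n_tied > 0)
    message(n_tied, " tie(s) in decision scores broken toward the lower class")
  factor(object$classes[top], levels = object$classes)
}

#' @export
print.her2_ova <- function(x, ...) {
  cat(sprintf("one-vs-all %s model: %d classes (%s), %d training samples\n",
              if (x$learner == "logreg") "logistic regression" else "SVM",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$n_train))
  invisible(x)
}

#' @export
summary.her2_ova <- function(object, ...) {
  print(object)
  if (object$learner == "logreg") {
    cat("per-class coefficient L2 norms (standardized scale):\n")
    print(vapply(coef(object), function(b) sqrt(sum(b[-1]^2)), numeric(1)))
  } else {
    cat(sprintf("RBF gamma = %.4g; support vectors per class: %s\n",
                object$gamma,
                paste(vapply(object$models, function(m) m$tot.nSV,
                             numeric(1)), collapse = ", ")))
  }
  invisible(object)
}

#' @export
coef.her2_ova <- function(object, ...) {
  if (object$learner != "logreg")
    stop("coefficients are only available for the logistic-regression learner")
  lapply(object$models, function(m) {
    b <- as.matrix(coef(m))
    setNames(b[, 1], rownames(b))
  })
}

# --- evaluation --------------------------------------------------------------

# Build a her2_report from a confusion matrix (rows actual, cols predicted).
confusion_report <- function(conf, accuracies = NULL) {
  tp <- diag(conf)
  precision <- tp / colSums(conf)
  recall <- tp / rowSums(conf)
  f1 <- 2 * precision * recall / (precision + recall)
  structure(list(
    confusion = conf,
    precision = precision, recall = recall, f1 = f1,
    accuracy = sum(tp) / sum(conf),
    accuracies = accuracies,
    mean_accuracy = if (!is.null(accuracies)) mean(accuracies),
    sd_accuracy = if (!is.null(accuracies) && length(accuracies) > 1)
      sd(accuracies)
  ), class = "her2_report")
}

#' @export
print.her2_report <- function(x, digits = 3, ...) {
  cat(sprintf("accuracy = %.2f%%\n", 100 * x$accuracy))
  if (!is.null(x$mean_accuracy))
    cat(sprintf("over %d trials: mean %.2f%%, sd %.2f%%\n",
                length(x$accuracies), 100 * x$mean_accuracy,
                100 * (x$sd_accuracy %||% 0)))
  cat("confusion matrix (rows = actual, columns = predicted):\n")
  print(x$confusion)
  print(round(data.frame(precision = x$precision, recall = x$recall,
                         f1 = x$f1), digits))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a fitted model on a test set
#'
#' Computes the confusion matrix (rows = actual, columns = predicted),
#' per-class precision (column-wise), recall (row-wise), F1, and overall
#' accuracy.
#'
#' @param model a fitted [her2_ova()].
#' @param test feature table with labels, or a list `list(x =, y =)`.
#' @return object of class `her2_report`.
#' @export
evaluate <- function(model, test) {
  if (is.data.frame(test)) test <- features_xy(test)
  y <- factor(test$y)
  if (!length(y)) stop("empty test set")
  unseen <- setdiff(levels(droplevels(y)), model$classes)
  if (length(unseen))
    stop("test set contains label(s) unseen at training: ",
         paste(unseen, collapse = ", "))
  pred <- predict(model, test$x)
  y <- factor(as.character(y), levels = model$classes)
  conf <- table(actual = y, predicted = pred)
  confusion_report(unclass(conf))
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs stratified k-fold cross-validation with fresh shuffles per repeat,
#' pooling held-out predictions within each repeat into one accuracy per
#' trial.  Reports the per-trial accuracies, their mean and standard
#' deviation, and the confusion matrix summed over all held-out predictions.
#'
#' @param features feature table with labels.
#' @param learner `"logreg"` or `"svm"`.
#' @param folds number of folds (>= 2); every class must have at least
#'   `folds` samples.
#' @param repeats number of repeated CV passes.
#' @param seed master seed; per-repeat shuffles derive from it.
#' @param config a [her2_config()].
#' @return a `her2_report` with the per-trial `accuracies` field set.
#' @export
repeated_cv <- function(features, learner = c("logreg", "svm"), folds = 5,
                        repeats = 50, seed = 1, config = her2_config()) {
  learner <- match.arg(learner)
  stopifnot(folds >= 2, repeats >= 1)
  xy <- features_xy(features)
  y <- droplevels(xy$y)
  cnt <- table(y)
  if (any(cnt < folds))
    stop("class '", names(cnt)[which(cnt < folds)[1]],
         "' has fewer samples (", min(cnt), ") than folds (", folds, ")")
  classes <- levels(y)
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(actual = classes, predicted = classes))
  accuracies <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold_of <- integer(length(y))
    with_seed(derive_seed(seed, r), {
      for (cl in classes) {
        idx <- sample(which(y == cl))
        fold_of[idx] <- rep_len(seq_len(folds), length(idx))
      }
    })
    pred <- factor(rep(NA_character_, length(y)), levels = classes)
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      fit <- her2_ova(xy$x[tr, , drop = FALSE], y[tr], learner = learner,
                      config = config)
      pred[!tr] <- predict(fit, xy$x[!tr, , drop = FALSE])
    }
    accuracies[r] <- mean(pred == y)
    conf <- conf + unclass(table(actual = y, predicted = pred))
  }
  confusion_report(conf, accuracies = accuracies)
}
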