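#' Baseline classifier specification
#'
#' The four classical models run on utterance-level MFCC statistics:
#' linear-kernel SVM (C = 1), linear discriminant analysis, k-nearest
#' neighbours (k = 5, Euclidean) and random forest (100 trees, Gini
#' impurity). Features are z-scored with statistics fitted on the training
#' data only (disable with `standardize = FALSE`).
#'
#' @param kind one of `"svm_linear"`, `"lda"`, `"knn"`, `"rf"`
#' @param cost SVM regularization parameter
#' @param k neighbourhood size for kNN
#' @param n_trees number of random-forest trees
#' @param standardize z-score features on training statistics
#' @param seed integer seed for the stochastic models
#' @return a `baseline_spec` list
#' @export
baseline_spec <- function(kind = c("svm_linear", "lda", "knn", "rf"),
                          cost = 1, k = 5, n_trees = 100,
                          standardize = TRUE, seed = 1L) {
  structure(list(kind = match.arg(kind), cost = cost, k = k,
                 n_trees = n_trees, standardize = standardize,
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

#' Fit a baseline classifier
#'
#' @param spec a [baseline_spec()]
#' @param features numeric matrix (rows = utterances)
#' @param labels 0/1 vector (1 = MDD)
#' @return a `baseline_model` usable with [predict_baseline()]
#' @export
fit_baseline <- function(spec, features, labels) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2)
    stop("invalid input: training data must contain both classes")
  if (min(table(labels)) < 2)
    stop("invalid input: need at least 2 samples per class")
  ctr <- rep(0, ncol(features)); scl <- rep(1, ncol(features))
  if (spec$standardize) {
    ctr <- colMeans(features)
    scl <- apply(features, 2, sd)
    scl[scl == 0] <- 1
    features <- scale(features, ctr, scl)
  }
  y <- factor(labels, levels = c(0, 1))
  fit <- switch(spec$kind,
    svm_linear = e1071::svm(features, y, kernel = "linear", cost = spec$cost,
                            scale = FALSE, probability = FALSE),
    lda = MASS::lda(features, grouping = y),
    knn = list(train = features, y = y, k = spec$k),
    rf = with_seed(spec$seed,
      randomForest::randomForest(features, y, ntree = spec$n_trees)))
  structure(list(spec = spec, fit = fit, center = ctr, scale = scl),
            class = "baseline_model")
}

#' Predict with a fitted baseline classifier
#'
#' @param model a `baseline_model` from [fit_baseline()]
#' @param features numeric matrix with the training feature width
#' @return list with `label` (0/1 vector) and `score` (decision value or
#'   class-1 probability, usable for ROC analysis)
#' @export
predict_baseline <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(model$center))
    stop("invalid input: feature width differs from the training data")
  if (model$spec$standardize)
    features <- scale(features, model$center, model$scale)
  kind <- model$spec$kind
  if (kind == "svm_linear") {
    pred <- predict(model$fit, features, decision.values = TRUE)
    dvm <- attr(pred, "decision.values")
    dv <- as.numeric(dvm)
    # e1071 names the decision column "a/b" with positive values favouring
    # class a; orient so that larger = class 1
    first <- strsplit(colnames(dvm)[1], "/")[[1]][1]
    if (identical(first, "0")) dv <- -dv
    list(label = as.numeric(as.character(pred)), score = dv)
  } else if (kind == "lda") {
    pr <- predict(model$fit, features)
    list(label = as.numeric(as.character(pr$class)),
         score = pr$posterior[, "1"])
  } else if (kind == "knn") {
    pr <- class::knn(model$fit$train, features, model$fit$y,
                     k = model$fit$k, prob = TRUE)
    win <- attr(pr, "prob")
    lab <- as.numeric(as.character(pr))
    score <- ifelse(lab == 1, win, 1 - win)
    list(label = lab, score = score)
  } else {
    pr <- predict(model$fit, features, type = "prob")[, "1"]
    list(label = as.numeric(pr >= 0.5), score = as.numeric(pr))
  }
}
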