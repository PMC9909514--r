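#' Participant-independent stratified splits
#'
#' Builds `n_folds` independently seeded participant-level splits. Sizes
#' follow a fixed rounding rule: `train = floor(ratio[1] * N)`; the
#' remainder is divided equally between validation and test, an odd
#' remainder giving the extra participant to validation. Class proportions
#' in every set match the cohort's within one participant. A cohort of 318
#' participants (153/165) yields 254/32/32.
#'
#' @param manifest data frame with `participant_id` and `group` columns
#'   (one or more rows per participant)
#' @param n_folds number of independent splits
#' @param ratios `(train, val, test)` proportions
#' @param stratified preserve class proportions per set
#' @param seed integer root seed; fold `i` uses a derived stream
#' @return list of `split_plan`s, each with `fold_index`, `train_ids`,
#'   `val_ids`, `test_ids`
#' @export
make_splits <- function(manifest, n_folds = 10, ratios = c(0.8, 0.1, 0.1),
                        stratified = TRUE, seed = 1L) {
  pt <- unique(manifest[, c("participant_id", "group")])
  if (anyDuplicated(pt$participant_id))
    stop("invalid input: a participant appears with more than one group")
  N <- nrow(pt)
  sizes <- split_sizes(N, ratios)
  cls <- split(pt$participant_id, pt$group)
  if (stratified && any(vapply(cls, length, integer(1)) < n_folds))
    stop("invalid input: a class has fewer members than folds require")
  class_sizes <- vapply(cls, length, integer(1))
  alloc <- stratified_allocation(class_sizes, sizes)
  lapply(seq_len(n_folds), function(f) {
    with_seed(derive_seed(seed, 1000L + f), {
      train <- character(0); val <- character(0); test <- character(0)
      for (g in names(cls)) {
        ids <- sample(cls[[g]])
        a <- alloc[[g]]
        train <- c(train, ids[seq_len(a[1])])
        val <- c(val, ids[a[1] + seq_len(a[2])])
        test <- c(test, ids[a[1] + a[2] + seq_len(a[3])])
      }
      structure(list(fold_index = f, train_ids = sort(train),
                     val_ids = sort(val), test_ids = sort(test),
                     ratios = ratios, stratified = stratified, seed = seed),
                class = "split_plan")
    })
  })
}

# total (train, val, test) counts under the documented rounding rule
split_sizes <- function(N, ratios = c(0.8, 0.1, 0.1)) {
  train <- floor(ratios[1] * N)
  rem <- N - train
  val <- ceiling(rem / 2)
  test <- rem - val
  c(train = train, val = val, test = test)
}

# per-class (train, val, test) counts: largest-remainder apportionment of
# each set's total across classes
stratified_allocation <- function(class_sizes, sizes) {
  K <- length(class_sizes)
  alloc <- matrix(0L, K, 3, dimnames = list(names(class_sizes), NULL))
  remaining <- class_sizes
  left <- sizes
  for (s in 1:2) {
    quota <- left[s] * remaining / sum(remaining)
    base <- floor(quota)
    short <- left[s] - sum(base)
    if (short > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
      base[extra] <- base[extra] + 1
    }
    alloc[, s] <- as.integer(base)
    remaining <- remaining - base
  }
  alloc[, 3] <- as.integer(remaining)
  lapply(setNames(seq_len(K), names(class_sizes)), function(i) alloc[i, ])
}

#' Average segment probabilities to one participant probability
#'
#' Arithmetic mean of the segment scores; predicted label is 1 when the
#' mean is at least 0.5.
#'
#' @param probs numeric vector of segment probabilities
#' @param participant_ids parallel vector of participant ids
#' @return data frame with `participant_id`, `prob`, `label`
#' @export
aggregate_to_participant <- function(probs, participant_ids) {
  if (length(probs) == 0 || length(probs) != length(participant_ids))
    stop("invalid input: empty or mismatched probability vector")
  agg <- aggregate(list(prob = probs), list(participant_id = participant_ids),
                   mean)
  agg$label <- as.numeric(agg$prob >= 0.5)
  agg
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 (`2PR/(P+R)`) with MDD as the
#' positive class, a score-threshold ROC sweep and the trapezoid-rule AUC.
#' Zero-division cases yield 0 with `zero_division = TRUE` flagged.
#'
#' @param y_true 0/1 truth vector
#' @param y_pred 0/1 predicted labels
#' @param y_score real-valued scores (larger = more MDD-like); optional
#' @return list with scalar metrics, the confusion counts, and (when
#'   scores and both classes are present) `roc` (data frame of FPR/TPR
#'   points) and `auc`
#' @export
compute_metrics <- function(y_true, y_pred, y_score = NULL) {
  if (length(y_true) != length(y_pred))
    stop("invalid input: length mismatch")
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  tn <- sum(y_true == 0 & y_pred == 0)
  zero_division <- FALSE
  prec <- if (tp + fp > 0) tp / (tp + fp) else { zero_division <- TRUE; 0 }
  rec <- if (tp + fn > 0) tp / (tp + fn) else { zero_division <- TRUE; 0 }
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else {
    zero_division <- TRUE; 0
  }
  out <- list(accuracy = (tp + tn) / length(y_true), precision = prec,
              recall = rec, f1 = f1,
              confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
              zero_division = zero_division)
  if (!is.null(y_score)) {
    if (length(unique(y_true)) < 2) {
      out$auc <- NA_real_
      out$auc_flag <- "single-class truth; AUC omitted"
    } else {
      r <- roc_curve(y_true, y_score)
      out$roc <- r
      out$auc <- trapezoid_auc(r$fpr, r$tpr)
    }
  }
  out
}

# ROC by threshold sweep over the distinct scores (ties grouped)
roc_curve <- function(y_true, y_score) {
  o <- order(y_score, decreasing = TRUE)
  y <- y_true[o]; s <- y_score[o]
  P <- sum(y_true == 1); Nn <- sum(y_true == 0)
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / Nn),
             tpr = c(0, tp[last] / P))
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Run the full cross-validated experiment
#'
#' For every fold and task: split participants, fit the requested models on
#' the training participants (SpecAugment expansion applied to the CNN's
#' training segments only), early-stop on the validation participants, and
#' evaluate on the test participants at both segment and participant level.
#'
#' @param dataset a prepared dataset from [prepare_dataset()]
#' @param models character vector among `"cnn"`, `"svm_linear"`, `"lda"`,
#'   `"knn"`, `"rf"`
#' @param n_folds number of independent splits
#' @param seed root seed (splits, model seeds, augmentation)
#' @param train train-phase configuration, a [train_config()]
#' @param augment_cfg SpecAugment settings, an [augment_config()], or
#'   `NULL` to disable expansion
#' @param ratios split proportions
#' @return an `evaluation_report`: data frame `fold_metrics` plus
#'   aggregates from [report_table()]
#' @export
run_experiment <- function(dataset, models = c("cnn", "svm_linear", "lda",
                                               "knn", "rf"),
                           n_folds = 10, seed = 1L, train = train_config(),
                           augment_cfg = augment_config(),
                           ratios = c(0.8, 0.1, 0.1)) {
  models <- match.arg(models, several.ok = TRUE)
  rows <- list()
  failures <- 0L
  all_splits <- list()
  for (task in unique(dataset$manifest$task)) {
    man_t <- dataset$manifest[dataset$manifest$task == task, ]
    splits <- make_splits(man_t, n_folds, ratios,
                          seed = derive_seed(seed, match(task, c(
                            "vowel", "digit", "passage"))))
    all_splits[[task]] <- splits
    for (sp in splits) {
      res <- tryCatch(
        run_fold(dataset, task, sp, models, seed, train, augment_cfg),
        error = function(e) {
          warning(sprintf("fold %d/%s failed: %s", sp$fold_index, task,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(res)) { failures <- failures + 1L; next }
      rows <- c(rows, res)
    }
  }
  fold_metrics <- do.call(rbind, lapply(rows, function(r) r$row))
  roc_points <- do.call(rbind, lapply(rows, function(r) r$roc))
  structure(list(fold_metrics = fold_metrics,
                 summary = report_table(fold_metrics),
                 roc_points = roc_points,
                 splits = all_splits,
                 n_failures = failures, seed = seed, models = models),
            class = "evaluation_report")
}

run_fold <- function(dataset, task, sp, models, seed, train, augment_cfg) {
  man <- dataset$manifest
  key <- function(ids) man$task == task & man$participant_id %in% ids
  rows <- list()
  truth_of <- function(ids)
    as.numeric(man$group[match(ids, man$participant_id)] == "MDD")
  if (any(models != "cnn")) {
    feat <- dataset$features
    ftr <- feat[key(sp$train_ids), , drop = FALSE]
    fte <- feat[key(sp$test_ids), , drop = FALSE]
    ytr <- as.numeric(man$group[key(sp$train_ids)] == "MDD")
    yte <- as.numeric(man$group[key(sp$test_ids)] == "MDD")
    for (m in setdiff(models, "cnn")) {
      spec <- baseline_spec(m, seed = derive_seed(seed, 7000L + sp$fold_index))
      fit <- fit_baseline(spec, ftr, ytr)
      pr <- predict_baseline(fit, fte)
      met <- compute_metrics(yte, pr$label, pr$score)
      rows[[length(rows) + 1L]] <-
        metric_row(task, m, sp$fold_index, "participant", met,
                   length(yte))
    }
  }
  if ("cnn" %in% models) {
    seg_of <- function(ids, cap = Inf) {
      keys <- paste(ids, task, sep = "|")
      lst <- dataset$segments[names(dataset$segments) %in% keys]
      if (is.finite(cap))
        lst <- lapply(lst, function(s) {
          if (length(s) <= cap) s
          else s[unique(round(seq(1, length(s), length.out = cap)))]
        })
      unlist(lst, recursive = FALSE, use.names = FALSE)
    }
    tr_segs <- seg_of(sp$train_ids, dataset$train_segment_cap %||% Inf)
    va_segs <- seg_of(sp$val_ids)
    te_segs <- seg_of(sp$test_ids)
    if (!is.null(augment_cfg)) {
      augment_cfg$seed <- derive_seed(seed, 8000L + sp$fold_index)
      tr_segs <- specaugment_expand(tr_segs, augment_cfg)
    }
    tcfg <- train
    tcfg$seed <- derive_seed(seed, 9000L + sp$fold_index)
    model <- build_cnn(dataset$arch %||% cnn_architecture(),
                       seed = tcfg$seed)
    model <- train_cnn(model, tr_segs, va_segs, tcfg)
    probs <- predict_segments(model, te_segs)
    seg_ids <- vapply(te_segs, attr, character(1), which = "participant_id")
    yseg <- segment_labels(te_segs)
    met_seg <- compute_metrics(yseg, as.numeric(probs >= 0.5), probs)
    rows[[length(rows) + 1L]] <-
      metric_row(task, "cnn", sp$fold_index, "segment", met_seg,
                 length(yseg))
    agg <- aggregate_to_participant(probs, seg_ids)
    ytrue <- truth_of(agg$participant_id)
    met_part <- compute_metrics(ytrue, agg$label, agg$prob)
    rows[[length(rows) + 1L]] <-
      metric_row(task, "cnn", sp$fold_index, "participant", met_part,
                 nrow(agg))
  }
  rows
}

metric_row <- function(task, model, fold, level, met, n) {
  row <- data.frame(task = task, model = model, fold = fold, level = level,
                    n = n, accuracy = met$accuracy,
                    precision = met$precision,
                    recall = met$recall, f1 = met$f1,
                    auc = if (is.null(met$auc)) NA_real_ else met$auc,
                    stringsAsFactors = FALSE)
  roc <- NULL
  if (!is.null(met$roc))
    roc <- cbind(task = task, model = model, fold = fold, level = level,
                 met$roc, stringsAsFactors = FALSE)
  list(row = row, roc = roc)
}

#' Aggregate fold-level metrics into a mean (SD) table
#'
#' @param fold_metrics data frame as produced by [run_experiment()]
#' @return data frame with one row per task x model x level carrying the
#'   mean and SD over folds of each metric
#' @export
report_table <- function(fold_metrics) {
  if (is.null(fold_metrics) || nrow(fold_metrics) == 0) {
    return(data.frame(task = character(0), model = character(0),
                      level = character(0)))
  }
  metrics <- c("accuracy", "precision", "recall", "f1", "auc")
  groups <- unique(fold_metrics[, c("task", "model", "level")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- fold_metrics[fold_metrics$task == g$task &
                          fold_metrics$model == g$model &
                          fold_metrics$level == g$level, ]
    row <- g
    row$n_folds <- nrow(sub)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(sub[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- if (nrow(sub) > 1) sd(sub[[m]], na.rm = TRUE)
        else NA_real_
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  s <- x$summary
  if (nrow(s)) {
    disp <- s[, c("task", "model", "level", "n_folds", "accuracy_mean",
                  "accuracy_sd", "auc_mean")]
    disp$accuracy_mean <- round(disp$accuracy_mean, 3)
    disp$accuracy_sd <- round(disp$accuracy_sd, 3)
    disp$auc_mean <- round(disp$auc_mean, 3)
    print(disp, row.names = FALSE)
  }
  if (x$n_failures > 0) cat(x$n_failures, "fold(s) failed\n")
  invisible(x)
}
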