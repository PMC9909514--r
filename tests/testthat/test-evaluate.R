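fake_manifest <- function(n_mdd, n_hc, task = "passage") {
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n_mdd + n_hc)),
    group = rep(c("MDD", "HC"), c(n_mdd, n_hc)),
    task = task, duration_s = 60, stringsAsFactors = FALSE)
}

test_that("the study-sized cohort splits into 254/32/32", {
  man <- fake_manifest(153, 165)
  splits <- make_splits(man, n_folds = 10, seed = 4)
  expect_length(splits, 10)
  for (sp in splits) {
    expect_length(sp$train_ids, 254)
    expect_length(sp$val_ids, 32)
    expect_length(sp$test_ids, 32)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_length(intersect(sp$train_ids, sp$val_ids), 0)
    expect_length(intersect(sp$val_ids, sp$test_ids), 0)
    expect_setequal(c(sp$train_ids, sp$val_ids, sp$test_ids),
                    man$participant_id)
  }
})

test_that("stratified sets track the cohort's class balance", {
  man <- fake_manifest(153, 165)
  sp <- make_splits(man, n_folds = 1, seed = 5)[[1]]
  grp <- setNames(man$group, man$participant_id)
  global <- 153 / 318
  for (ids in list(sp$train_ids, sp$val_ids, sp$test_ids)) {
    n_mdd <- sum(grp[ids] == "MDD")
    expect_lte(abs(n_mdd - global * length(ids)), 1)
  }
})

test_that("small cohorts follow the rounding rule", {
  man <- fake_manifest(5, 5)
  sp <- make_splits(man, n_folds = 2, seed = 6)[[1]]
  expect_length(sp$train_ids, 8)
  expect_length(sp$val_ids, 1)
  expect_length(sp$test_ids, 1)
  # odd remainder gives validation the extra participant
  man2 <- fake_manifest(6, 5)
  sp2 <- make_splits(man2, n_folds = 2, seed = 6)[[1]]
  expect_length(sp2$train_ids, 8)
  expect_length(sp2$val_ids, 2)
  expect_length(sp2$test_ids, 1)
  expect_error(make_splits(fake_manifest(3, 8), n_folds = 5),
               "fewer members")
})

test_that("splits are deterministic per seed and differ across folds", {
  man <- fake_manifest(20, 20)
  a <- make_splits(man, n_folds = 3, seed = 9)
  b <- make_splits(man, n_folds = 3, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a[[1]]$test_ids, a[[2]]$test_ids))
})

test_that("participant aggregation averages segment probabilities", {
  expect_equal(aggregate_to_participant(0.7, "A")$prob, 0.7)
  agg <- aggregate_to_participant(c(0.2, 0.4, 0.9), c("A", "A", "A"))
  expect_equal(agg$prob, 0.5)
  expect_equal(agg$label, 1)   # >= 0.5 ties to the positive class
  probs <- c(0.1, 0.9, 0.4, 0.8, 0.3)
  ids <- c("A", "B", "A", "B", "A")
  perm <- c(4, 1, 5, 3, 2)
  expect_equal(aggregate_to_participant(probs, ids),
               aggregate_to_participant(probs[perm], ids[perm]))
  expect_error(aggregate_to_participant(numeric(0), character(0)), "empty")
})

test_that("metrics match hand-computed confusion arithmetic", {
  y_true <- rep(c(1, 0), c(40, 60))
  y_pred <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 50))
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m$confusion, c(tp = 30, fp = 10, fn = 10, tn = 50))
  expect_equal(m$accuracy, 0.80)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  ident <- compute_metrics(y_true, y_true)
  expect_equal(unlist(ident[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  expect_error(compute_metrics(c(0, 1), c(0)), "length")
  z <- compute_metrics(c(0, 0, 1), c(0, 0, 0))
  expect_equal(z$precision, 0)
  expect_true(z$zero_division)
})

test_that("perfectly ranked scores give AUC 1 and reversal gives 0", {
  y <- rep(c(0, 1), each = 10)
  s <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  m <- compute_metrics(y, as.numeric(s >= 0.5), s)
  expect_equal(m$auc, 1)
  rev <- compute_metrics(y, as.numeric(s >= 0.5), -s)
  expect_equal(rev$auc, 0)
})

test_that("trapezoid AUC equals the Mann-Whitney statistic", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y <- c(y[-(1:2)], 0, 1)
    s <- round(rnorm(length(y)), sample(c(1, 2, 8), 1))  # force ties
    m <- compute_metrics(y, as.numeric(s >= 0), s)
    expect_equal(m$auc, oracle_auc(y, s), tolerance = 1e-9)
    expect_equal(compute_metrics(y, as.numeric(s >= 0), -s)$auc,
                 1 - m$auc, tolerance = 1e-9)
  }
})

test_that("our AUC agrees with an established ROC implementation", {
  set.seed(21)
  y <- sample(c(0, 1), 60, replace = TRUE)
  y[1:2] <- c(0, 1)
  s <- rnorm(60) + y
  ours <- compute_metrics(y, as.numeric(s >= 0.5), s)$auc
  ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("single-class truth omits the AUC with a flag", {
  m <- compute_metrics(c(1, 1, 1), c(1, 0, 1), c(0.9, 0.2, 0.8))
  expect_true(is.na(m$auc))
  expect_match(m$auc_flag, "single-class")
})

test_that("report aggregation is internally consistent", {
  fm <- data.frame(task = "vowel", model = rep(c("svm_linear", "rf"), each = 3),
                   fold = rep(1:3, 2), level = "participant", n = 5,
                   accuracy = c(0.8, 0.9, 1, 0.6, 0.7, 0.65),
                   precision = 0.5, recall = 0.5, f1 = 0.5, auc = 0.75)
  tab <- report_table(fm)
  expect_equal(nrow(tab), 2)
  svm_row <- tab[tab$model == "svm_linear", ]
  expect_equal(svm_row$accuracy_mean, 0.9, tolerance = 1e-12)
  expect_equal(svm_row$accuracy_sd, 0.1, tolerance = 1e-12)
  expect_equal(report_table(fm[0, ])$task, character(0))
})
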