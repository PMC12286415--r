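# Dataset splitting, supervised training contracts, and the metric suite.

test_that("stratified 70:10:20 split uses largest-remainder sizes", {
  # the study's own composition: 466 + 524 = 990 tiles
  man <- data.frame(class_label = rep(c("recurrent", "non_recurrent"),
                                      c(466, 524)))
  sp <- split_dataset(man, train_config(seed = 4))
  expect_equal(nrow(sp$train), 693)
  expect_equal(nrow(sp$val), 99)
  expect_equal(nrow(sp$test), 198)
  # disjoint and exhaustive
  all_rows <- c(sp$train$.row, sp$val$.row, sp$test$.row)
  expect_equal(sort(all_rows), 1:990)
  # per-class proportions within one tile of the global ones
  for (part in sp) {
    n_rec <- sum(part$class_label == "recurrent")
    expect_lte(abs(n_rec - nrow(part) * 466 / 990), 1)
  }
  # reproducible under the seed
  sp2 <- split_dataset(man, train_config(seed = 4))
  expect_identical(sp$train$.row, sp2$train$.row)
  # a missing class is an error
  expect_error(
    split_dataset(data.frame(class_label = rep("recurrent", 30))),
    "both classes"
  )
})

test_that("split sizes follow largest-remainder rounding across sizes", {
  lr <- slidewise:::largest_remainder
  for (n in c(10, 17, 99, 101, 990)) {
    sizes <- lr(n, c(0.7, 0.1, 0.2))
    expect_equal(sum(sizes), n)
    expect_true(all(abs(sizes - n * c(0.7, 0.1, 0.2)) < 1))
  }
})

test_that("training honours the epoch contract and is seed-reproducible", {
  train <- small_feature_set(8, seed = 501)
  val <- small_feature_set(3, seed = 502)
  cfg <- train_config(epochs = 3, batch_size = 5, seed = 31)
  m1 <- train_classifier(build_classifier(small_cfg(seed = 3)), train, val, cfg)
  expect_equal(nrow(m1$history), 3)
  expect_true(all(c("train_loss", "val_loss", "train_acc", "val_acc")
                  %in% names(m1$history)))
  expect_false(anyNA(m1$history))
  m2 <- train_classifier(build_classifier(small_cfg(seed = 3)), train, val, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_error(
    train_classifier(build_classifier(small_cfg()),
                     list(features = list(), labels = character(0)), val, cfg),
    "empty"
  )
})

test_that("confusion metrics reproduce the worked examples", {
  # the test-set composition implied by recall 0.96 / precision 1.0 on
  # 100 + 100 tiles
  m <- confusion_metrics(c(tp = 96, fp = 0, fn = 4, tn = 100))
  expect_equal(m$precision, 1.0)
  expect_equal(m$recall, 0.96)
  expect_equal(m$accuracy, 0.98)
  expect_equal(m$f1, 2 * 0.96 / 1.96)

  perfect <- confusion_metrics(c(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(unlist(perfect[c("recall", "precision", "f1", "accuracy")]),
               c(recall = 1, precision = 1, f1 = 1, accuracy = 1))

  sym <- confusion_metrics(c(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(unlist(sym[c("recall", "precision", "f1", "accuracy")]),
               c(recall = 0.5, precision = 0.5, f1 = 0.5, accuracy = 0.5))

  expect_error(confusion_metrics(c(tp = -1, fp = 0, fn = 0, tn = 1)),
               "negative")
  expect_warning(z <- confusion_metrics(c(tp = 0, fp = 0, fn = 0, tn = 4)),
                 "0/0")
  expect_true(z$degenerate)
  expect_equal(z$recall, 0)
})

test_that("accuracy decomposes into class-weighted recall and specificity", {
  set.seed(13)
  for (i in 1:20) {
    cm <- c(tp = sample(0:30, 1), fp = sample(0:30, 1),
            fn = sample(0:30, 1), tn = sample(1:30, 1))
    if (cm["tp"] + cm["fn"] == 0 || cm["tn"] + cm["fp"] == 0) next
    m <- suppressWarnings(confusion_metrics(cm))
    P <- cm["tp"] + cm["fn"]
    N <- cm["tn"] + cm["fp"]
    expect_equal(m$accuracy,
                 unname((m$recall * P + m$specificity * N) / (P + N)))
  }
})

test_that("AUC matches closed forms and the pair-counting oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(roc_auc(c(0.2, 0.8), c(1, 1)), "both classes")

  set.seed(99)
  for (i in 1:30) {
    n <- sample(6:25, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)  # duplicates force tie handling
    r <- roc_auc(s, y)
    expect_equal(r$auc, oracle_auc_pairs(s, y), tolerance = 1e-9)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(123)
  y <- sample(0:1, 40, replace = TRUE, prob = c(0.5, 0.5))
  y[1:2] <- 0:1
  s <- runif(40)
  ours <- roc_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("evaluation report ties predictions, confusion and AUC together", {
  fit <- small_fit()
  test_set <- small_feature_set(6, seed = 603)
  ev <- evaluate_classifier(fit$model, test_set)
  expect_equal(sum(ev$confusion), 12)
  expect_gte(ev$auc, 0.5)
  scores <- predict_classifier(fit$model, test_set$features)
  expect_equal(ev$scores, scores)
  cm <- confusion_matrix(as.numeric(scores > 0.5), test_set$labels)
  expect_equal(ev$confusion, cm)
})
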