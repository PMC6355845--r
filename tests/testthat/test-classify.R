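# toy feature tables -----------------------------------------------------
separable_toy <- function(n_per = 40, seed = 5) {
  scheme <- class_scheme()
  set.seed(seed)
  k <- length(scheme$codes)
  centers <- matrix(seq(0, 100, length.out = k * 3), k, 3)
  feats <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(matrix(rep(centers[i, ], each = n_per), n_per, 3) +
            matrix(rnorm(n_per * 3, sd = 0.5), n_per, 3))))
  dt <- data.table::data.table(segment_id = seq_len(k * n_per),
                               f1 = feats[, 1], f2 = feats[, 2], f3 = feats[, 3])
  list(table = dt, labels = rep(scheme$codes, each = n_per))
}

test_that("training pool sampling honours per-class counts, replacement and seeds", {
  toy <- separable_toy(n_per = 200)
  set_ <- make_training_set(toy$table, toy$labels, per_class = 150, seed = 3)
  expect_equal(length(set_$labels), 7 * 150)
  expect_true(all(table(set_$labels) == 150))
  # deficient class: replacement with warning
  toy2 <- separable_toy(n_per = 80)
  w <- capture_warnings(
    set2 <- make_training_set(toy2$table, toy2$labels, per_class = 150, seed = 3))
  expect_true(all(grepl("replacement", w)))
  expect_length(w, 7)   # one per deficient class
  expect_true(all(table(set2$labels) == 150))
  # determinism
  s_a <- make_training_set(toy$table, toy$labels, per_class = 150, seed = 9)
  s_b <- make_training_set(toy$table, toy$labels, per_class = 150, seed = 9)
  expect_identical(s_a$segment_id, s_b$segment_id)
  # OTHER rows dropped, zero-count class errors
  labs3 <- toy$labels; labs3[labs3 == "PEB"] <- "OTHER"
  expect_error(make_training_set(toy$table, labs3, 10, 1), "zero labelled")
})

test_that("stratified split is an exact partition at the requested fraction", {
  toy <- separable_toy(n_per = 100)
  set_ <- make_training_set(toy$table, toy$labels, per_class = 100, seed = 1)
  sp <- split_train_test(set_, train_fraction = 0.15, seed = 2)
  expect_equal(length(sp$train$labels), 7 * 15)
  expect_equal(length(sp$test$labels), 7 * 85)
  expect_true(all(table(sp$train$labels) == 15))
  ids <- sort(c(seq_along(set_$labels)))
  got <- sort(c(match(sp$train$segment_id, set_$segment_id)))
  # no overlap, union = input (by row index bookkeeping)
  n_tr <- length(sp$train$labels); n_te <- length(sp$test$labels)
  expect_equal(n_tr + n_te, length(set_$labels))
  sp_b <- split_train_test(set_, train_fraction = 0.15, seed = 2)
  expect_identical(sp_b$train$segment_id, sp$train$segment_id)
  expect_error(split_train_test(set_, 0), "train_fraction")
})

test_that("all three model kinds separate two distant clusters perfectly", {
  sch <- toy_scheme(c("LCN", "HEMS"))
  set.seed(5)
  n <- 40
  dt <- data.table::data.table(
    segment_id = seq_len(2 * n),
    f1 = c(rnorm(n, 0, 1), rnorm(n, 30, 1)),
    f2 = c(rnorm(n, 0, 1), rnorm(n, -30, 1)))
  labels <- rep(c("LCN", "HEMS"), each = n)
  set_ <- make_training_set(dt, labels, per_class = n, seed = 1, scheme = sch)
  for (mk in c("LR", "RF", "DNN")) {
    mdl <- train_classifier(mk, set_, seed = 4, scheme = sch)
    pred <- predict_classes(mdl, set_$features)
    expect_equal(pred$class, set_$labels, info = mk)
    # probability rows sum to 1
    pm <- as.matrix(pred[, grep("^prob_", names(pred)), with = FALSE])
    expect_equal(unname(rowSums(pm)), rep(1, nrow(pm)), tolerance = 1e-6)
    # determinism: identical predictions run-to-run
    mdl2 <- train_classifier(mk, set_, seed = 4, scheme = sch)
    pred2 <- predict_classes(mdl2, set_$features)
    expect_identical(pred$class, pred2$class, info = mk)
  }
})

test_that("a single depth-1 tree recovers the brute-force optimal split", {
  # 1-feature threshold problem with two classes from the scheme
  scheme <- class_scheme()
  set.seed(10)
  x <- c(runif(60, 0, 1), runif(60, 2, 3))
  y <- rep(scheme$codes[1:2], each = 60)
  # shuffle in some hard cases
  x[1:5] <- runif(5, 1.4, 1.6)
  dt <- data.table::data.table(segment_id = seq_along(x), f1 = x)
  set_ <- structure(list(features = dt, labels = y,
                         segment_id = dt$segment_id), class = "labelled_set")
  sch2 <- toy_scheme(scheme$codes[1:2])
  mdl <- train_classifier("RF", set_,
                          hyper = list(num_trees = 1L, max_depth = 1L,
                                       mtry = 1L, sample_fraction = 1,
                                       replace = FALSE), seed = 1,
                          scheme = sch2)
  pred <- predict_classes(mdl, dt)$class
  # brute-force best single split by Gini impurity
  z <- (x - mean(x)) / sd(x)
  cands <- sort(unique(z))
  best <- NULL; best_g <- Inf
  for (t in (head(cands, -1) + diff(cands) / 2)) {
    for (side in c(TRUE, FALSE)) {
      left <- if (side) z <= t else z > t
      gini <- function(v) { p <- table(v) / length(v); 1 - sum(p^2) }
      g <- (sum(left) * gini(y[left]) + sum(!left) * gini(y[!left])) / length(y)
      if (g < best_g) { best_g <- g; best <- t }
    }
  }
  # labels implied by the optimal split
  left <- z <= best
  lab_left <- names(which.max(table(y[left])))
  lab_right <- names(which.max(table(y[!left])))
  want <- ifelse(left, lab_left, lab_right)
  expect_equal(pred, unname(want))
})

test_that("softmax argmax of hand-set network weights matches closed form", {
  # 2 features -> hidden identity-ish -> 3 outputs with known weights
  X <- matrix(c(1, 0, -1, 2, 0.5, -0.5), 3, 2)
  W1 <- diag(2); b1 <- c(0, 0)
  W2 <- matrix(c(1, 0, 0, 1, -1, 0.5), 2, 3)
  b2 <- c(0.1, -0.2, 0)
  fit <- list(par = list(W = list(W1, W2), b = list(b1, b2)), sizes = c(2, 2, 3))
  probs <- mobia:::mlp_predict(fit, X)
  H <- pmax(X %*% W1 + matrix(b1, 3, 2, byrow = TRUE), 0)
  Z <- H %*% W2 + matrix(b2, 3, 3, byrow = TRUE)
  want <- exp(Z) / rowSums(exp(Z))
  expect_equal(probs, want, tolerance = 1e-12)
  expect_equal(apply(probs, 1, which.max), apply(Z, 1, which.max))
})

test_that("evaluation metrics match hand computation on a 2-class matrix", {
  sch <- toy_scheme(c("A", "B"))
  truth <- c(rep("A", 50), rep("B", 50))
  pred <- c(rep("A", 40), rep("B", 10), rep("A", 20), rep("B", 30))
  ev <- evaluate_classification(pred, truth, sch)
  expect_equal(unname(ev$confusion), matrix(c(40, 20, 10, 30), 2, 2))
  expect_equal(ev$metrics$overall_accuracy, 0.70)
  expect_equal(ev$metrics$macro_precision, (40 / 60 + 30 / 40) / 2)
  expect_equal(ev$metrics$macro_recall, (0.8 + 0.6) / 2)
  expect_equal(ev$metrics$average_accuracy, 0.70)
  expect_equal(ev$metrics$micro_precision, 0.70)
  # against the independent tally oracle
  om <- oracle_metrics(pred, truth, sch$codes)
  expect_equal(ev$metrics[names(om)], om)
})

test_that("perfect prediction scores 1 on all six metrics", {
  scheme <- class_scheme()
  labs <- rep(scheme$codes, times = 3)
  ev <- evaluate_classification(labs, labs, scheme)
  for (m in ev$metrics) expect_equal(m, 1)
})

test_that("micro precision = micro recall = overall accuracy on random labelings", {
  scheme <- class_scheme()
  set.seed(20)
  for (case in 1:10) {
    n <- 200
    truth <- sample(scheme$codes, n, replace = TRUE)
    pred <- sample(scheme$codes, n, replace = TRUE)
    ev <- evaluate_classification(pred, truth, scheme)
    expect_equal(ev$metrics$micro_precision, ev$metrics$overall_accuracy)
    expect_equal(ev$metrics$micro_recall, ev$metrics$overall_accuracy)
    om <- oracle_metrics(pred, truth, scheme$codes)
    expect_equal(ev$metrics[names(om)], om)
    for (m in ev$metrics) { expect_gte(m, 0); expect_lte(m, 1) }
  }
})

test_that("undefined precision is zero-filled and flagged", {
  sch <- toy_scheme(c("A", "B", "C"))
  truth <- c("A", "B", "C", "A")
  pred <- c("A", "A", "A", "A")   # B and C never predicted
  ev <- evaluate_classification(pred, truth, sch)
  expect_setequal(ev$flagged_precision, c("B", "C"))
  expect_equal(ev$per_class$precision[2:3], c(0, 0))
  expect_error(evaluate_classification(c("A", "Z"), c("A", "B"), sch),
               "outside")
})
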