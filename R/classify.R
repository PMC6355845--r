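#' Facies class scheme
#'
#' Ordered mapped classes (LCN, DC, SPG, HEMS, HESDR, CRUB, PEB) plus the
#' excluded OTHER code; OTHER never enters training or metrics.
#'
#' @return object of class `class_scheme` with `codes` (the 7 mapped
#'   codes), `codes_all` (including OTHER, indexed by raster id), `names`,
#'   `hierarchy`.
#' @export
class_scheme <- function() {
  ct <- class_table()
  structure(list(
    codes = ct$code[ct$code != "OTHER"],
    codes_all = ct$code,
    names = stats::setNames(ct$name, ct$code),
    hierarchy = stats::setNames(ct$hierarchy, ct$code)
  ), class = "class_scheme")
}

#' Build a labelled training pool
#'
#' Seeded sampling of `per_class` objects per mapped class, without
#' replacement when the class has enough labelled objects and with
#' replacement (plus a warning) otherwise. OTHER-labelled rows are dropped
#' beforehand.
#'
#' @param table feature table (data.frame/data.table with segment_id and
#'   feature columns).
#' @param labels character class codes aligned with `table` rows.
#' @param per_class samples per class (default 150).
#' @param seed integer seed.
#' @param scheme a [class_scheme()].
#' @return `labelled_set`: list(features data.table, labels character,
#'   segment_id).
#' @export
make_training_set <- function(table, labels, per_class = 150L, seed = 1L,
                              scheme = class_scheme()) {
  stopifnot(nrow(table) == length(labels))
  keep <- labels %in% scheme$codes
  table <- as.data.table(table)[keep]
  labels <- labels[keep]
  counts <- table(factor(labels, levels = scheme$codes))
  if (any(counts == 0))
    stop("class(es) with zero labelled objects: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  idx <- with_seed(seed, {
    unlist(lapply(scheme$codes, function(cl) {
      i <- which(labels == cl)
      if (length(i) < per_class) {
        warning(sprintf("class %s has %d labelled objects < %d; sampling with replacement",
                        cl, length(i), per_class))
        sample(i, per_class, replace = TRUE)
      } else sample(i, per_class)
    }))
  })
  structure(list(features = table[idx], labels = labels[idx],
                 segment_id = table$segment_id[idx]),
            class = "labelled_set")
}

#' Stratified train/test split
#'
#' Random split stratified by class: for each class,
#' `round(train_fraction * n)` objects (at least 1) go to training, the
#' rest to test; the two parts partition the input exactly.
#'
#' @param set a `labelled_set`.
#' @param train_fraction fraction in (0, 1); default 0.15 (the unusual
#'   15/85 train/test convention this workflow follows).
#' @param seed integer seed.
#' @return list(train, test), both `labelled_set`s.
#' @export
split_train_test <- function(set, train_fraction = 0.15, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  lab <- set$labels
  if (any(table(lab) < 2)) stop("every class needs >= 2 members to stratify")
  tr_idx <- with_seed(seed, {
    unlist(lapply(unique(lab), function(cl) {
      i <- which(lab == cl)
      k <- max(1L, round(train_fraction * length(i)))
      sample(i, k)
    }))
  })
  subset_set <- function(i) structure(
    list(features = set$features[i], labels = set$labels[i],
         segment_id = set$segment_id[i]), class = "labelled_set")
  list(train = subset_set(sort(tr_idx)),
       test = subset_set(sort(setdiff(seq_along(lab), tr_idx))))
}

# numeric feature matrix (drops segment_id / non-numeric / all-NA columns)
feature_matrix <- function(features) {
  df <- as.data.frame(features)
  df$segment_id <- NULL
  num <- vapply(df, is.numeric, TRUE)
  m <- as.matrix(df[, num, drop = FALSE])
  m
}

# z-score standardization statistics from training data; NA -> 0 after
# scaling (aspect of flat segments)
std_stats <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  sg <- apply(m, 2, stats::sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  mu[!is.finite(mu)] <- 0
  list(mu = mu, sg = sg)
}

apply_std <- function(m, st) {
  z <- sweep(sweep(m, 2, st$mu), 2, st$sg, "/")
  z[!is.finite(z)] <- 0
  z
}

#' Train a facies classifier
#'
#' Three model kinds: `"LR"` — multinomial logistic regression with an L2
#' (weight-decay) penalty; `"RF"` — bootstrap-aggregated decision-tree
#' ensemble (majority/probability voting, `num_trees` trees, sqrt(p)
#' candidate features per split); `"DNN"` — fully connected network with
#' two hidden ReLU layers, softmax output and cross-entropy loss trained
#' with Adam for a fixed epoch budget. Features are z-scored with training
#' statistics stored in the model; all fits are seeded.
#'
#' @param model_kind "LR", "RF" or "DNN".
#' @param train a `labelled_set`.
#' @param hyper list of hyperparameters; recognised entries:
#'   `decay` (LR, default 1), `num_trees` (RF, 100), `max_depth` (RF, 0 =
#'   unlimited), `mtry` (RF, sqrt(p)), `sample_fraction` (RF, 1 with
#'   replacement), `hidden` (DNN, c(64, 64)), `epochs` (DNN, 200),
#'   `batch` (DNN, 32), `lr` (DNN, 1e-3).
#' @param seed integer seed.
#' @param scheme a [class_scheme()].
#' @return object of class `mobia_classifier`.
#' @export
train_classifier <- function(model_kind = c("LR", "RF", "DNN"), train,
                             hyper = list(), seed = 1L,
                             scheme = class_scheme()) {
  model_kind <- match.arg(model_kind)
  m <- feature_matrix(train$features)
  if (!all(is.finite(m[, colnames(m) != "aspect"])))
    stop("non-finite feature values in training data")
  st <- std_stats(m)
  z <- apply_std(m, st)
  y <- factor(train$labels, levels = scheme$codes)
  fit <- switch(model_kind,
    LR = {
      decay <- hyper$decay %||% 1
      with_seed(seed, nnet::multinom(
        y ~ ., data = data.frame(y = y, z, check.names = FALSE),
        decay = decay, maxit = 500, MaxNWts = 1e5, trace = FALSE))
    },
    RF = {
      ranger::ranger(
        x = as.data.frame(z), y = y,
        num.trees = hyper$num_trees %||% 100L,
        mtry = hyper$mtry %||% max(1L, floor(sqrt(ncol(z)))),
        max.depth = hyper$max_depth %||% 0L,
        sample.fraction = hyper$sample_fraction %||% 1,
        replace = hyper$replace %||% TRUE,
        probability = TRUE, seed = seed, num.threads = 1L)
    },
    DNN = mlp_train(z, as.integer(y), nlevels(y),
                    hidden = hyper$hidden %||% c(64L, 64L),
                    epochs = hyper$epochs %||% 200L,
                    batch = hyper$batch %||% 32L,
                    lr = hyper$lr %||% 1e-3, seed = seed))
  structure(list(kind = model_kind, fit = fit, std = st,
                 feature_names = colnames(m), scheme = scheme, seed = seed),
            class = "mobia_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict facies classes for a feature table
#'
#' Per-object class probabilities (rows sum to 1) and the argmax class,
#' ties broken by class-scheme order.
#'
#' @param model a `mobia_classifier`.
#' @param table feature table with the training schema's columns.
#' @return data.table: segment_id (if present), class, prob_<code> columns.
#' @export
predict_classes <- function(model, table) {
  m <- feature_matrix(table)
  missing_cols <- setdiff(model$feature_names, colnames(m))
  if (length(missing_cols))
    stop("feature schema mismatch; missing: ", paste(missing_cols, collapse = ", "))
  m <- m[, model$feature_names, drop = FALSE]
  z <- apply_std(m, model$std)
  codes <- model$scheme$codes
  probs <- switch(model$kind,
    LR = {
      p <- stats::predict(model$fit, newdata = data.frame(z, check.names = FALSE),
                          type = "probs")
      # two-class multinom returns P(second level) as a vector
      if (is.null(dim(p))) p <- cbind(1 - p, p)
      p
    },
    RF = stats::predict(model$fit, data = as.data.frame(z),
                        num.threads = 1L)$predictions,
    DNN = mlp_predict(model$fit, z))
  if (ncol(probs) == length(codes)) {
    colnames(probs) <- codes
  } else {
    # a backend dropped empty classes: realign by its column names
    full <- matrix(0, nrow(probs), length(codes), dimnames = list(NULL, codes))
    full[, colnames(probs)] <- probs
    probs <- full
  }
  probs <- probs[, codes, drop = FALSE]
  probs <- probs / rowSums(probs)
  cls <- codes[apply(probs, 1, which.max)]   # which.max: first max = scheme order
  out <- data.table::data.table(class = cls)
  if (!is.null(table$segment_id)) out <- cbind(
    data.table::data.table(segment_id = table$segment_id), out)
  pcols <- data.table::as.data.table(probs)
  names(pcols) <- paste0("prob_", codes)
  cbind(out, pcols)
}

#' Confusion matrix and accuracy metrics
#'
#' Rows are true classes, columns predicted, ordered by the scheme.
#' Metrics: overall accuracy (trace/total), average accuracy (mean
#' one-vs-rest binary accuracy), micro- and macro-averaged precision and
#' recall. Per-class precision with no predicted instances is counted as 0
#' and flagged, keeping macro averages comparable. For single-label
#' multiclass data micro precision = micro recall = overall accuracy.
#'
#' @param pred,truth character class codes (equal length, within scheme).
#' @param scheme a [class_scheme()].
#' @return list(confusion = K x K matrix, metrics = named list,
#'   per_class = data.table, flagged_precision = codes with no predictions).
#' @export
evaluate_classification <- function(pred, truth, scheme = class_scheme()) {
  codes <- scheme$codes
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (!all(pred %in% codes) || !all(truth %in% codes))
    stop("labels outside the class scheme")
  cm <- table(factor(truth, codes), factor(pred, codes))
  cm <- matrix(as.integer(cm), nrow = length(codes),
               dimnames = list(true = codes, predicted = codes))
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  flagged <- codes[tp + fp == 0]
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  metrics <- list(
    overall_accuracy = sum(tp) / total,
    average_accuracy = mean((tp + tn) / total),
    micro_precision = sum(tp) / (sum(tp) + sum(fp)),
    macro_precision = mean(prec),
    micro_recall = sum(tp) / (sum(tp) + sum(fn)),
    macro_recall = mean(rec))
  per_class <- data.table::data.table(
    class = codes, tp = tp, fp = fp, fn = fn, tn = tn,
    precision = prec, recall = rec,
    binary_accuracy = (tp + tn) / total)
  list(confusion = cm, metrics = metrics, per_class = per_class,
       flagged_precision = flagged)
}

# ---- minimal multilayer perceptron (softmax output, cross-entropy, Adam) ---

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    W <- list(); b <- list()
    for (i in seq_len(length(sizes) - 1)) {
      W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1],
                                    sd = sqrt(2 / sizes[i])),
                       sizes[i], sizes[i + 1])
      b[[i]] <- rep(0, sizes[i + 1])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  acts <- list(X)
  for (i in seq_len(L)) {
    z <- acts[[i]] %*% par$W[[i]]
    z <- sweep(z, 2, par$b[[i]], "+")
    acts[[i + 1]] <- if (i < L) pmax(z, 0) else z
  }
  acts
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_train <- function(X, y_int, K, hidden = c(64L, 64L), epochs = 200L,
                      batch = 32L, lr = 1e-3, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  sizes <- c(p, hidden, K)
  par <- mlp_init(sizes, derive_seed(seed, "mlp_init"))
  L <- length(par$W)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y_int)] <- 1
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  with_seed(derive_seed(seed, "mlp_sgd"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = batch)) {
        idx <- ord[s:min(s + batch - 1, n)]
        acts <- mlp_forward(par, X[idx, , drop = FALSE])
        probs <- softmax_rows(acts[[L + 1]])
        delta <- (probs - Y[idx, , drop = FALSE]) / length(idx)
        t <- t + 1
        for (i in L:1) {
          gW <- crossprod(acts[[i]], delta)
          gb <- colSums(delta)
          if (i > 1) {
            delta <- (delta %*% t(par$W[[i]])) * (acts[[i]] > 0)
          }
          mW[[i]] <- b1 * mW[[i]] + (1 - b1) * gW
          vW[[i]] <- b2 * vW[[i]] + (1 - b2) * gW^2
          mb[[i]] <- b1 * mb[[i]] + (1 - b1) * gb
          vb[[i]] <- b2 * vb[[i]] + (1 - b2) * gb^2
          par$W[[i]] <- par$W[[i]] - lr * (mW[[i]] / (1 - b1^t)) /
            (sqrt(vW[[i]] / (1 - b2^t)) + eps)
          par$b[[i]] <- par$b[[i]] - lr * (mb[[i]] / (1 - b1^t)) /
            (sqrt(vb[[i]] / (1 - b2^t)) + eps)
        }
      }
    }
  })
  list(par = par, sizes = sizes)
}

mlp_predict <- function(fit, X) {
  acts <- mlp_forward(fit$par, X)
  softmax_rows(acts[[length(acts)]])
}
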