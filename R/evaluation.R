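# Evaluation protocol: grouped train/validation/test splitting, minority
# oversampling, ROC-AUC via pair counting, the shared 5-epoch training loop
# with validation-based snapshot selection, and bootstrap model comparison.

#' Specify a dataset split
#'
#' Default fractions are 75% training, 10% validation (development) and 15%
#' test.  Records sharing a `group_by` value are always assigned to the same
#' partition, which prevents leakage between partitions when several records
#' derive from the same admission or summary.
#'
#' @param train,validation,test Positive fractions summing to 1.
#' @param seed Integer seed controlling the (group-level) shuffle.
#' @param group_by Column used for leakage control (default `"group_id"`).
#' @return A list of class `"split_spec"`.
#' @export
split_spec <- function(train = 0.75, validation = 0.10, test = 0.15,
                       seed = 1L, group_by = "group_id") {
  fr <- c(train, validation, test)
  if (any(fr <= 0) || abs(sum(fr) - 1) > 1e-8) {
    stop("split fractions must be positive and sum to 1")
  }
  structure(list(train = train, validation = validation, test = test,
                 seed = as.integer(seed), group_by = group_by),
            class = "split_spec")
}

#' Split a dataset into train / validation / test partitions
#'
#' Groups are shuffled under the spec's seed and assigned greedily so that
#' cumulative record counts match the requested fractions as closely as group
#' granularity allows; with singleton groups the sizes are exact.
#'
#' @param dataset A data frame containing the `group_by` column.
#' @param spec A [split_spec()].
#' @return Named list `train`, `validation`, `test` of row-subsets of
#'   `dataset`.
#' @export
split_dataset <- function(dataset, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"), nrow(dataset) > 0L)
  groups <- as.character(dataset[[spec$group_by]])
  ug <- unique(groups)
  ord <- with_local_seed(spec$seed, sample(ug))
  sizes <- as.numeric(table(groups)[ord])
  n <- nrow(dataset)
  cum <- cumsum(sizes)
  # group g goes to the partition whose quota its midpoint falls in
  b1 <- spec$train * n
  b2 <- (spec$train + spec$validation) * n
  mid <- cum - sizes / 2
  part <- ifelse(mid <= b1, 1L, ifelse(mid <= b2, 2L, 3L))
  assign_of <- part[match(groups, ord)]
  list(train = dataset[assign_of == 1L, , drop = FALSE],
       validation = dataset[assign_of == 2L, , drop = FALSE],
       test = dataset[assign_of == 3L, , drop = FALSE])
}

#' Balance a training set by oversampling the minority class
#'
#' The minority class is duplicated by repeated full passes through the
#' minority pool (each pass drawn without replacement) until the class counts
#' are equal; the final partial pass is a without-replacement sample.  Only
#' ever applied to the training partition — validation and test stay at their
#' natural class balance.
#'
#' @param train A data frame with a binary `label` column.
#' @param seed Seed for the partial-pass draw.
#' @return The balanced data frame (rows of the minority class repeated).
#' @export
oversample_minority <- function(train, seed = 1L) {
  y <- train$label
  if (length(unique(y)) < 2L) stop("both classes required for oversampling")
  tab <- table(y)
  if (tab[["0"]] == tab[["1"]]) return(train)
  minority <- as.integer(names(tab)[which.min(tab)])
  min_rows <- which(y == minority)
  n_min <- length(min_rows)
  n_maj <- max(tab)
  deficit <- n_maj - n_min
  full <- deficit %/% n_min
  rest <- deficit %% n_min
  extra <- c(rep(min_rows, full),
             with_local_seed(seed, sample(min_rows, rest)))
  out <- rbind(train, train[extra, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve by pair counting
#'
#' The Mann–Whitney formulation: the fraction of (positive, negative) pairs
#' the score ranks correctly, with half credit for ties.  Ranges from 0
#' (worst) to 1 (best); random guessing gives 0.5.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (0/1); both classes must be present.
#' @return A list of class `"roc_result"` with `auc`, `n_pos`, `n_neg`,
#'   `scores`, `labels`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("AUC undefined: one class absent")
  r <- rank(scores, ties.method = "average")
  a <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(auc = a, n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f  (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Shared training configuration
#'
#' All models are trained for a fixed number of epochs (default 5) and the
#' epoch snapshot with the highest validation AUC is kept.
#'
#' @param epochs Number of passes over the training data.
#' @param lr Optimiser step size (Adam).
#' @param seed Seed controlling initialisation and data shuffling.
#' @param oversample Balance the training partition first?
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 5L, lr = 1e-2, seed = 1L, oversample = TRUE) {
  stopifnot(epochs >= 1L)
  structure(list(epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
                 oversample = isTRUE(oversample)),
            class = "train_config")
}

#' Train a model under the shared protocol
#'
#' A model specification is a list of three closures:
#' \describe{
#'   \item{`init(seed)`}{returns the initial model state;}
#'   \item{`epoch(state, train, lr, epoch)`}{runs one training pass and
#'     returns the updated state;}
#'   \item{`score(state, data)`}{returns one probability per row of `data`.}
#' }
#' The training partition is (optionally) balanced by
#' [oversample_minority()]; validation AUC is measured after every epoch; the
#' snapshot with the highest validation AUC is returned, and the test AUC is
#' computed once on that snapshot.  Fully reproducible given the seed.
#'
#' @param model_spec The closure triple described above (each built-in model
#'   exposes a `*_spec()` constructor returning one).
#' @param splits Named list `train`, `validation`, `test` from
#'   [split_dataset()].
#' @param config A [train_config()].
#' @return List of class `"trained_model"` with `state` (best snapshot),
#'   `val_trace` (per-epoch validation AUC), `best_epoch`, `test_roc`,
#'   `config`.
#' @export
train_model <- function(model_spec, splits, config = train_config()) {
  stopifnot(all(c("init", "epoch", "score") %in% names(model_spec)))
  train <- splits$train
  if (config$oversample && length(unique(train$label)) == 2L &&
      sum(train$label == 0L) != sum(train$label == 1L)) {
    train <- oversample_minority(train, seed = config$seed)
  }
  state <- model_spec$init(config$seed)
  val_trace <- numeric(config$epochs)
  best <- NULL
  best_auc <- -Inf
  for (e in seq_len(config$epochs)) {
    state <- model_spec$epoch(state, train, config$lr, e)
    v <- auc(model_spec$score(state, splits$validation),
             splits$validation$label)$auc
    val_trace[e] <- v
    if (v > best_auc) {
      best_auc <- v
      best <- state
    }
  }
  test_roc <- auc(model_spec$score(best, splits$test), splits$test$label)
  structure(list(state = best, val_trace = val_trace,
                 best_epoch = which.max(val_trace), test_roc = test_roc,
                 config = config),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained model: best epoch %d/%d, val AUC %.4f, test AUC %.4f>\n",
              x$best_epoch, length(x$val_trace), max(x$val_trace),
              x$test_roc$auc))
  invisible(x)
}

#' Score a dataset with a trained model
#'
#' @param model A [train_model()] result.
#' @param model_spec The spec the model was trained with.
#' @param data A document data frame.
#' @return Numeric probability per row.
#' @export
score_dataset <- function(model, model_spec, data) {
  model_spec$score(model$state, data)
}

#' Compare two models' scores by paired stratified bootstrap
#'
#' Resamples the test set (stratified by class, preserving the pairing of the
#' two score vectors) and computes the AUC difference in each replicate; the
#' two-sided p-value is the symmetrised tail fraction of the difference
#' distribution around zero.
#'
#' @param scores_a,scores_b Paired score vectors on the same test records.
#' @param labels Shared binary labels.
#' @param reps Bootstrap replicates (default 2000).
#' @param seed Seed for resampling.
#' @return List with `p_value`, `auc_a`, `auc_b`, `delta` (observed
#'   difference) and `reps`.
#' @export
compare_models <- function(scores_a, scores_b, labels, reps = 2000L,
                           seed = 1L) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("score vectors and labels must describe the same test set")
  }
  labels <- as.integer(labels)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  obs_a <- auc(scores_a, labels)$auc
  obs_b <- auc(scores_b, labels)$auc
  deltas <- with_local_seed(seed, {
    vapply(seq_len(reps), function(i) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      lb <- labels[idx]
      auc(scores_a[idx], lb)$auc - auc(scores_b[idx], lb)$auc
    }, 0)
  })
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  list(p_value = min(p, 1), auc_a = obs_a, auc_b = obs_b,
       delta = obs_a - obs_b, reps = reps)
}
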