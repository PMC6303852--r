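#' Confusion matrix over a canonical label order
#'
#' @param true_labels Character vector of gold labels.
#' @param predicted_labels Character vector of predictions, same length.
#' @param label_order Canonical label order; rows are true labels, columns
#'   predictions.
#' @return k x k integer matrix of counts with `dimnames(true, predicted)`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             label_order = rct_labels()) {
  stopifnot(length(true_labels) == length(predicted_labels))
  ti <- match(true_labels, label_order)
  pi <- match(predicted_labels, label_order)
  if (anyNA(ti) || anyNA(pi)) stop("labels outside label_order")
  k <- length(label_order)
  cm <- matrix(0L, k, k, dimnames = list(true = label_order,
                                         predicted = label_order))
  for (i in seq_along(ti)) cm[ti[i], pi[i]] <- cm[ti[i], pi[i]] + 1L
  cm
}

#' Per-class precision, recall, F1 and support from a confusion matrix
#'
#' `recall_i = cm[i,i] / rowsum_i`, `precision_i = cm[i,i] / colsum_i`, F1
#' their harmonic mean; any 0/0 is defined as 0.
#'
#' @param cm Square non-negative count matrix, rows = true labels.
#' @return A [tibble::tibble] with columns `label`, `precision`, `recall`,
#'   `f1`, `support`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  diag_ <- diag(cm)
  support <- rowSums(cm)
  pred <- colSums(cm)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  recall <- safe_div(diag_, support)
  precision <- safe_div(diag_, pred)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  tibble::tibble(label = if (!is.null(rownames(cm))) rownames(cm)
                         else as.character(seq_len(nrow(cm))),
                 precision = unname(precision), recall = unname(recall),
                 f1 = unname(f1), support = unname(support))
}

#' Support-weighted F1 score
#'
#' `sum_i (support_i / N) * F1_i` over the label order — per-class F1
#' weighted by how frequent each label is in the evaluation set.
#'
#' @inheritParams confusion_matrix
#' @return Scalar in `[0, 1]`.
#' @export
weighted_f1 <- function(true_labels, predicted_labels,
                        label_order = rct_labels()) {
  if (length(true_labels) == 0L) stop("empty evaluation set")
  cm <- confusion_matrix(true_labels, predicted_labels, label_order)
  m <- per_class_metrics(cm)
  sum(m$support / sum(m$support) * m$f1)
}

#' Evaluate a trained model on a labeled sentence set
#'
#' @param model A `section_model`.
#' @param x A labeled `sentence_set` or `rct_corpus` (augmented the same way
#'   as the training data).
#' @return An object of class `eval_report`: confusion matrix, per-class
#'   metrics, supports and weighted F1.
#' @export
evaluate_model <- function(model, x) {
  ss <- as_sentence_set(x)
  if (anyNA(ss$labels)) stop("evaluation requires labeled sentences")
  pred <- predict(model, ss)
  eval_report(ss$labels, pred, model$label_order)
}

#' Build an evaluation report from label vectors
#'
#' @inheritParams confusion_matrix
#' @return An `eval_report`.
#' @export
eval_report <- function(true_labels, predicted_labels,
                        label_order = rct_labels()) {
  cm <- confusion_matrix(true_labels, predicted_labels, label_order)
  m <- per_class_metrics(cm)
  structure(list(confusion = cm, metrics = m,
                 weighted_f1 = sum(m$support / sum(m$support) * m$f1)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  disp <- x$confusion
  pct <- round(100 * diag(disp) / pmax(rowSums(disp), 1))
  print(disp)
  cat("\nPer-class recall (%):",
      paste(sprintf("%s %d%%", rownames(disp), pct), collapse = ", "), "\n")
  cat(sprintf("Weighted F1: %.3f\n", x$weighted_f1))
  invisible(x)
}

#' Exhaustive hyperparameter grid search
#'
#' Trains one model per (dim, n_max, epochs) cell on the training set,
#' scores support-weighted F1 on the validation set, and returns the best
#' configuration (ties resolved towards smaller dim, then smaller n_max,
#' then fewer epochs) together with the full results table.
#'
#' @param train,valid Labeled sentence sets or corpora (pre-augmented as
#'   desired); must be disjoint.
#' @param dims,n_maxs,epochss Grid axes (defaults: dims 10/20/50, n-grams
#'   1..4, epochs 1..8).
#' @param config Base [train_config()] supplying the remaining settings.
#' @return A list with `best` (a `train_config`), `best_f1`, and `results`
#'   (tibble: dim, n_max, epochs, f1).
#' @export
grid_search <- function(train, valid, dims = c(10L, 20L, 50L),
                        n_maxs = 1:4, epochss = 1:8,
                        config = train_config()) {
  if (length(dims) == 0L || length(n_maxs) == 0L || length(epochss) == 0L)
    stop("empty grid")
  valid_ss <- as_sentence_set(valid)
  grid <- expand.grid(dim = dims, n_max = n_maxs, epochs = epochss,
                      KEEP.OUT.ATTRS = FALSE)
  f1 <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- train_config(dim = grid$dim[i], n_max = grid$n_max[i],
                        epochs = grid$epochs[i], lr = config$lr,
                        buckets = config$buckets,
                        min_count = config$min_count, seed = config$seed)
    model <- train_supervised(train, cfg)
    f1[i] <- evaluate_model(model, valid_ss)$weighted_f1
  }
  results <- tibble::tibble(dim = grid$dim, n_max = grid$n_max,
                            epochs = grid$epochs, f1 = f1)
  ord <- order(-results$f1, results$dim, results$n_max, results$epochs)
  best_row <- results[ord[1L], ]
  best <- train_config(dim = best_row$dim, n_max = best_row$n_max,
                       epochs = best_row$epochs, lr = config$lr,
                       buckets = config$buckets, min_count = config$min_count,
                       seed = config$seed)
  list(best = best, best_f1 = best_row$f1, results = results)
}

#' Semi-supervised learning curves
#'
#' For each training-set size and replicate, samples labeled training
#' sentences without replacement and a disjoint test set, runs every setup
#' on byte-identical splits, and records the support-weighted test F1.
#' Sampling is at the sentence level, ignoring abstract boundaries; no
#' augmentation is applied (single-sentence regime).
#'
#' @param source A labeled `rct_corpus` or `sentence_set` to sample from.
#' @param sizes Increasing integer vector of training-set sizes.
#' @param replicates Replicates per size (train and test both resampled).
#' @param setups Subset of `"supervised"` (scratch), `"pretrained"`
#'   (transfer of `pretrained` vectors), `"sent2vec_mlp"` (frozen
#'   [sent2vec_embed()] vectors + perceptron head).
#' @param pretrained [pretrain_vectors()] output; required by the
#'   `"pretrained"` and `"sent2vec_mlp"` setups. Pre-train it on the full
#'   source with labels ignored.
#' @param test_size Test sentences per replicate.
#' @param config Supervised [train_config()] shared by all setups.
#' @param mlp_hidden Hidden layer size of the perceptron setup.
#' @param seed Master seed; each (size, replicate) derives its own split
#'   seed.
#' @return A list with `results` (tibble: size, setup, replicate, f1),
#'   `medians` (tibble: size, setup, median_f1) and `splits` (the sampled
#'   train/test index pairs per size and replicate).
#' @export
learning_curve <- function(source, sizes, replicates = 5L,
                           setups = c("supervised", "pretrained"),
                           pretrained = NULL, test_size = 20000L,
                           config = train_config(), mlp_hidden = 100L,
                           seed = 1L) {
  ss <- as_sentence_set(source)
  N <- length(ss)
  sizes <- sort(as.integer(sizes))
  if (max(sizes) + test_size > N)
    stop("source corpus too small: need ", max(sizes) + test_size,
         " sentences, have ", N)
  if (any(c("pretrained", "sent2vec_mlp") %in% setups) && is.null(pretrained))
    stop("setups using pre-trained vectors require `pretrained`")

  rows <- list()
  splits <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (si in seq_along(sizes)) {
    n <- sizes[si]
    for (r in seq_len(replicates)) {
      set.seed(seed * 10000L + si * 100L + r)
      train_idx <- sample.int(N, n)
      test_idx <- sample(setdiff(seq_len(N), train_idx), test_size)
      splits[[sprintf("size%d_rep%d", n, r)]] <-
        list(size = n, replicate = r, train = train_idx, test = test_idx)
      train_ss <- ss[train_idx]
      test_ss <- ss[test_idx]
      for (setup in setups) {
        f1 <- run_setup(setup, train_ss, test_ss, pretrained, config,
                        mlp_hidden, seed = seed + r)
        rows[[length(rows) + 1L]] <-
          tibble::tibble(size = n, setup = setup, replicate = r, f1 = f1)
      }
    }
  }
  results <- do.call(rbind, rows)
  med <- aggregate(f1 ~ size + setup, data = results, FUN = median)
  medians <- tibble::tibble(size = med$size, setup = med$setup,
                            median_f1 = med$f1)
  medians <- medians[order(medians$size, medians$setup), ]
  list(results = results, medians = medians, splits = splits)
}

run_setup <- function(setup, train_ss, test_ss, pretrained, config,
                      mlp_hidden, seed) {
  cfg <- train_config(dim = config$dim, n_max = config$n_max,
                      epochs = config$epochs, lr = config$lr,
                      buckets = config$buckets, min_count = config$min_count,
                      seed = seed)
  if (setup == "supervised") {
    model <- train_supervised(train_ss, cfg)
    evaluate_model(model, test_ss)$weighted_f1
  } else if (setup == "pretrained") {
    model <- train_supervised(train_ss, cfg, init_vectors = pretrained)
    evaluate_model(model, test_ss)$weighted_f1
  } else if (setup == "sent2vec_mlp") {
    emb_tr <- t(vapply(train_ss$tokens, sent2vec_embed,
                       numeric(pretrained$h), pretrained = pretrained))
    emb_te <- t(vapply(test_ss$tokens, sent2vec_embed,
                       numeric(pretrained$h), pretrained = pretrained))
    head_ <- train_mlp_head(emb_tr, train_ss$labels, hidden = mlp_hidden,
                            seed = seed, label_order = train_ss$label_set)
    pred <- mlp_predict(head_, emb_te)
    weighted_f1(test_ss$labels, pred, train_ss$label_set)
  } else stop("unknown setup: ", setup)
}
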