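#' Training configuration for the embedding classifier
#'
#' @param dim Embedding dimension h (the grid explored is 10, 20, 50).
#' @param n_max Maximum word n-gram order (1..4).
#' @param epochs Number of SGD passes over the training data.
#' @param lr Initial learning rate; decays linearly to zero over all updates.
#' @param buckets Hash buckets for n-grams of order 2+. Ignored (treated as
#'   0) when `n_max = 1`.
#' @param min_count Vocabulary frequency threshold.
#' @param seed Integer seed controlling initialization and example shuffling;
#'   single-threaded training is bit-reproducible for a fixed seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(dim = 20L, n_max = 2L, epochs = 5L, lr = 0.1,
                         buckets = 2e6, min_count = 1L, seed = 1L) {
  stopifnot(dim >= 1L, n_max >= 1L, epochs >= 1L, lr > 0, buckets >= 1,
            min_count >= 1L)
  structure(list(dim = as.integer(dim), n_max = as.integer(n_max),
                 epochs = as.integer(epochs), lr = lr,
                 buckets = as.integer(buckets),
                 min_count = as.integer(min_count), seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize an embedding model
#'
#' The input table V (one h-vector per feature, stored as columns) is drawn
#' i.i.d. uniform on `[-1/h, 1/h]`; the output table U (k x h) starts at
#' zero, so an untrained model predicts the uniform distribution.
#'
#' @param n_features Number of input features (vocabulary size + buckets).
#' @param h Embedding dimension.
#' @param k Number of outputs (labels in supervised mode; vocabulary words
#'   in unsupervised mode).
#' @param seed Integer seed.
#' @return A list with `V` (h x n_features), `U` (k x h), `h`, `k`.
#' @export
init_model <- function(n_features, h, k, seed = 1L) {
  stopifnot(n_features >= 1L, h >= 1L, k >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  V <- matrix(runif(as.double(n_features) * h, -1 / h, 1 / h),
              nrow = h, ncol = n_features)
  U <- matrix(0, nrow = k, ncol = h)
  list(V = V, U = U, h = as.integer(h), k = as.integer(k))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Sentence vector of a feature bag
#'
#' The weighted average of the feature embeddings: `sum_f w_f V[, f]`. Since
#' bag weights sum to 1, this is the average-of-embeddings hidden layer of
#' the model. An empty bag yields the zero vector.
#'
#' @param model A model with a `V` table (h x n_features).
#' @param bag A feature bag from [encode_bag()].
#' @return Numeric vector of length h.
#' @export
sentence_vector <- function(model, bag) {
  if (length(bag$ids) == 0L) return(numeric(model$h))
  if (any(bag$ids < 1L) || any(bag$ids > ncol(model$V)))
    stop("feature id out of range")
  as.numeric(model$V[, bag$ids, drop = FALSE] %*% bag$weights)
}

#' Class probabilities for one feature bag
#'
#' Softmax of `U %*% sentence_vector(model, bag)`, computed with log-sum-exp
#' stabilization. An empty bag gives the zero sentence vector and hence the
#' uniform distribution.
#'
#' @param model A supervised model (k = number of labels).
#' @param bag A feature bag.
#' @return Probability vector of length k (named with the label order when
#'   the model carries one); entries positive and summing to 1.
#' @export
predict_proba <- function(model, bag) {
  z <- as.numeric(model$U %*% sentence_vector(model, bag))
  p <- softmax(z)
  if (!is.null(model$label_order)) names(p) <- model$label_order
  p
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Predicted label for one feature bag
#'
#' Argmax of [predict_proba()]; ties are broken in favour of the lowest
#' label index in the canonical order.
#'
#' @inheritParams predict_proba
#' @return The predicted label (character if the model carries a label
#'   order, otherwise the 1-based output index).
#' @export
predict_label <- function(model, bag) {
  p <- predict_proba(model, bag)
  i <- which.max(p)
  if (!is.null(model$label_order)) model$label_order[i] else i
}

#' Mean negative log-likelihood on a labeled dataset
#'
#' `(1/N) sum -log p(y_S | S)` over the dataset — the objective minimized by
#' supervised training.
#'
#' @param model A supervised model.
#' @param bags List of feature bags.
#' @param labels Integer vector of 1-based label indices (or characters
#'   matched against the model's label order).
#' @return Non-negative scalar.
#' @export
supervised_loss <- function(model, bags, labels) {
  if (length(bags) == 0L) stop("empty dataset")
  if (is.character(labels)) labels <- match(labels, model$label_order)
  stopifnot(length(bags) == length(labels), !anyNA(labels))
  nll <- vapply(seq_along(bags), function(i) {
    -log(predict_proba(model, bags[[i]])[labels[i]])
  }, numeric(1))
  mean(nll)
}

# Analytic gradient of the single-example negative log-likelihood with
# respect to U and to the touched columns of V. Used by the trainer's
# correctness tests (finite-difference comparison) and to verify that one
# SGD step of the compiled trainer applies exactly this gradient.
supervised_grad <- function(model, bag, label) {
  hvec <- sentence_vector(model, bag)
  p <- softmax(as.numeric(model$U %*% hvec))
  g <- p
  g[label] <- g[label] - 1
  dU <- outer(g, hvec)
  ghid <- as.numeric(t(model$U) %*% g)
  dV <- outer(ghid, bag$weights)  # h x m, column j = d loss / d V[, ids[j]]
  list(dU = dU, ids = bag$ids, dV = dV)
}

#' Train the supervised embedding classifier
#'
#' Plain per-example SGD on the softmax negative log-likelihood over
#' normalized bags of n-grams, with example order reshuffled each epoch and
#' the learning rate decaying linearly to zero. Only the embedding columns
#' of a sentence's own features are updated by its step, so cost is linear
#' in total token count.
#'
#' @param x A labeled `rct_corpus` or `sentence_set` (e.g. the output of
#'   [augment_corpus()]).
#' @param config A [train_config()].
#' @param init_vectors Optional pre-trained vectors from
#'   [pretrain_vectors()]; embeddings of shared features are copied in via
#'   [transfer_init()] before training (semi-supervised mode).
#' @return An object of class `section_model`: label order, vocabulary,
#'   config, tables `V`/`U`, and `epoch_loss` (mean online NLL per epoch).
#' @export
train_supervised <- function(x, config = train_config(), init_vectors = NULL) {
  ss <- as_sentence_set(x)
  if (length(ss) == 0L) stop("empty training set")
  if (anyNA(ss$labels)) stop("supervised training requires labeled sentences")
  label_order <- ss$label_set
  y <- match(ss$labels, label_order)
  if (anyNA(y)) stop("labels outside the corpus label set")

  vocab <- build_vocab(ss, config$min_count)
  buckets_eff <- if (config$n_max >= 2L) config$buckets else 0L
  feats <- encode_sentences(ss, vocab, config$n_max,
                            max(buckets_eff, 1L))
  n_features <- nrow(vocab) + buckets_eff
  k <- length(label_order)

  if (is.null(init_vectors)) {
    m0 <- init_model(n_features, config$dim, k, config$seed)
    V0 <- m0$V
  } else {
    V0 <- transfer_init(init_vectors, vocab, config)
  }
  U0 <- matrix(0, nrow = k, ncol = config$dim)

  fit <- train_supervised_cpp(feats, y, config$dim, k, config$epochs,
                              config$lr, config$seed, V0, U0)
  structure(list(V = fit$V, U = fit$U, h = config$dim, k = k,
                 label_order = label_order, vocab = vocab, config = config,
                 buckets = buckets_eff, epoch_loss = as.numeric(fit$epoch_loss)),
            class = "section_model")
}

#' @export
print.section_model <- function(x, ...) {
  cat(sprintf(paste0("<section_model: h = %d, k = %d, |V| = %d, buckets = %d,",
                     " n_max = %d>\n"),
              x$h, x$k, nrow(x$vocab), x$buckets, x$config$n_max))
  invisible(x)
}

# Encode a sentence set in a trained model's feature space.
model_encode <- function(model, ss) {
  encode_sentences(ss, model$vocab, model$config$n_max,
                   max(model$buckets, 1L))
}

#' Predict rhetorical labels for new sentences
#'
#' @param object A `section_model`.
#' @param newdata A `sentence_set` (augment it the same way the training
#'   data were augmented), an `rct_corpus`, or a list of token vectors.
#' @param type `"label"` for predicted labels, `"prob"` for the N x k matrix
#'   of class probabilities.
#' @param ... Ignored.
#' @return Character vector of labels, or a probability matrix.
#' @export
predict.section_model <- function(object, newdata, type = c("label", "prob"),
                                  ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !inherits(newdata, c("sentence_set", "rct_corpus")))
    newdata <- structure(list(tokens = newdata,
                              labels = rep(NA_character_, length(newdata)),
                              label_set = object$label_order),
                         class = "sentence_set")
  ss <- as_sentence_set(newdata)
  feats <- model_encode(object, ss)
  probs <- predict_proba_cpp(feats, object$V, object$U)
  colnames(probs) <- object$label_order
  if (type == "prob") return(probs)
  object$label_order[max.col(probs, ties.method = "first")]
}
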