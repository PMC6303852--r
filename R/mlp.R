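#' Train a single-hidden-layer perceptron on frozen sentence embeddings
#'
#' The downstream classifier of the sent2vec setup: sentence vectors are
#' computed once with [sent2vec_embed()] and held fixed; a multilayer
#' perceptron with one hidden layer (100 neurons by default) is fit on them
#' by penalized cross-entropy via [nnet::nnet()]. The embeddings are never
#' modified.
#'
#' @param embeddings Numeric matrix, one row per sentence (or a list of
#'   equal-length vectors).
#' @param labels Character labels (or a factor) aligned with the rows.
#' @param hidden Hidden layer size.
#' @param seed Integer seed; training is deterministic for a fixed seed.
#' @param label_order Canonical label order for the output layer.
#' @param maxit Maximum optimizer iterations.
#' @param decay Weight decay of the cross-entropy fit.
#' @return An object of class `mlp_head` wrapping the fitted network and the
#'   label order.
#' @export
train_mlp_head <- function(embeddings, labels, hidden = 100L, seed = 1L,
                           label_order = rct_labels(), maxit = 200L,
                           decay = 1e-4) {
  if (is.list(embeddings)) embeddings <- do.call(rbind, embeddings)
  if (nrow(embeddings) != length(labels))
    stop("embeddings and labels have different lengths")
  stopifnot(hidden >= 1L)
  label_order <- label_order[label_order %in% unique(as.character(labels))]
  y <- factor(as.character(labels), levels = label_order)
  if (anyNA(y)) stop("labels outside label_order")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ymat <- nnet::class.ind(y)
  fit <- nnet::nnet(x = embeddings, y = ymat, size = hidden, softmax = TRUE,
                    decay = decay, maxit = maxit, trace = FALSE,
                    MaxNWts = 100000L)
  structure(list(fit = fit, label_order = label_order,
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "mlp_head")
}

#' Predict with a trained perceptron head
#'
#' @param head An [train_mlp_head()] object.
#' @param embeddings Matrix (or list) of sentence vectors.
#' @param type `"label"` or `"prob"`.
#' @return Character labels (ties broken towards the lowest label index) or
#'   an N x k probability matrix with rows summing to 1.
#' @export
mlp_predict <- function(head, embeddings, type = c("label", "prob")) {
  type <- match.arg(type)
  if (is.list(embeddings)) embeddings <- do.call(rbind, embeddings)
  if (ncol(embeddings) != head$fit$n[1L])
    stop("embedding dimension mismatch: head expects ", head$fit$n[1L])
  probs <- predict(head$fit, embeddings, type = "raw")
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  colnames(probs) <- head$label_order
  if (type == "prob") return(probs)
  head$label_order[max.col(probs, ties.method = "first")]
}
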