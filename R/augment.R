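#' Configuration for sentence-context augmentation
#'
#' Controls the preprocessing step that lets a bag-of-n-grams classifier see
#' sentence order: a numeric position token and prefix-tagged copies of the
#' tokens of neighbouring sentences are added to each sentence's token
#' sequence.
#'
#' @param window Non-negative number of context sentences taken on each side
#'   (2 reproduces the full model; 0 disables context).
#' @param include_position Add a `pos_<i>` token with the 1-based sentence
#'   position.
#' @param include_context Add prefix-tagged context tokens (`-1_`, `+2_`, ...).
#' @param relative_position Use a length-relative position bucket
#'   (`pos_<i>of<n>`) instead of the raw index. Off by default.
#' @return An object of class `augment_config`.
#' @export
#' @examples
#' augment_config(window = 2)                      # full augmentation
#' augment_config(window = 0, include_position = FALSE)  # single-sentence
augment_config <- function(window = 2L, include_position = TRUE,
                           include_context = TRUE, relative_position = FALSE) {
  window <- as.integer(window)
  stopifnot(window >= 0L)
  structure(list(window = window,
                 include_position = isTRUE(include_position),
                 include_context = isTRUE(include_context),
                 relative_position = isTRUE(relative_position)),
            class = "augment_config")
}

position_token <- function(index, n_sentences, config) {
  if (config$relative_position)
    sprintf("pos_%dof%d", index + 1L, n_sentences)
  else
    sprintf("pos_%d", index + 1L)
}

#' Augment one sentence with position and context tokens
#'
#' Produces the enhanced token sequence fed to the classifier: the tokens of
#' up to `window` preceding sentences (most distant first, each token
#' prefixed with its offset, e.g. `-1_` for the directly preceding sentence),
#' then the position token, then the target sentence's tokens unmodified,
#' then the trailing context tokens (`+1_`, `+2_`, ...). Context sentences
#' falling outside the abstract are omitted. Labels of context sentences are
#' never used.
#'
#' @param abstract One abstract (an element of `corpus$abstracts`).
#' @param index 0-based index of the target sentence within the abstract.
#' @param config An [augment_config()].
#' @return A list with `tokens`, `label` (copied from the target sentence)
#'   and `source` (abstract id, sentence index).
#' @export
augment_sentence <- function(abstract, index, config = augment_config()) {
  n <- length(abstract$sentences)
  if (index < 0L || index >= n) stop("sentence index out of range: ", index)
  target <- abstract$sentences[[index + 1L]]
  toks <- character(0)
  if (config$include_context && config$window > 0L) {
    for (off in seq(-config$window, -1L)) {
      j <- index + off
      if (j < 0L) next
      toks <- c(toks, paste0(sprintf("%+d_", off),
                             abstract$sentences[[j + 1L]]$tokens))
    }
  }
  if (config$include_position)
    toks <- c(toks, position_token(index, n, config))
  toks <- c(toks, target$tokens)
  if (config$include_context && config$window > 0L) {
    for (off in seq_len(config$window)) {
      j <- index + off
      if (j >= n) break
      toks <- c(toks, paste0(sprintf("%+d_", off),
                             abstract$sentences[[j + 1L]]$tokens))
    }
  }
  list(tokens = toks,
       label = if (is.null(target$label)) NA_character_ else target$label,
       source = list(abstract = abstract$id, index = index))
}

#' Augment every sentence of a corpus
#'
#' Applies [augment_sentence()] to each sentence, in corpus order, and
#' returns a flat [as_sentence_set()]-style object. With `window = 0` and
#' `include_position = FALSE` the output token sequences equal the input
#' (the single-sentence ablation).
#'
#' @param corpus An `rct_corpus`.
#' @param config An [augment_config()].
#' @return A `sentence_set` of augmented sentences.
#' @export
augment_corpus <- function(corpus, config = augment_config()) {
  stopifnot(inherits(corpus, "rct_corpus"))
  total <- sum(vapply(corpus$abstracts, function(a) length(a$sentences),
                      integer(1)))
  tokens <- vector("list", total)
  labels <- character(total); absid <- character(total); idx <- integer(total)
  pos <- 0L
  for (a in corpus$abstracts) {
    for (i in seq_along(a$sentences) - 1L) {
      s <- augment_sentence(a, i, config)
      pos <- pos + 1L
      tokens[[pos]] <- s$tokens
      labels[pos] <- s$label
      absid[pos] <- a$id
      idx[pos] <- i
    }
  }
  structure(list(tokens = tokens, labels = labels, abstract = absid,
                 index = idx, label_set = corpus$label_set),
            class = "sentence_set")
}
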