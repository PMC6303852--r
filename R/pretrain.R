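#' Smoothed unigram noise distribution for negative sampling
#'
#' `p(w) ~ freq(w)^power`, normalized over the vocabulary. `power = 0.75`
#' is the conventional smoothing; `power = 0` gives the uniform
#' distribution.
#'
#' @param vocab A [build_vocab()] vocabulary.
#' @param power Smoothing exponent.
#' @return An object of class `noise_distribution`: a list with `prob`
#'   (per-word probabilities aligned to vocabulary ids, summing to 1) and
#'   `cum` (cumulative probabilities used by the sampler).
#' @export
build_noise_distribution <- function(vocab, power = 0.75) {
  stopifnot(nrow(vocab) >= 1L)
  w <- vocab$count^power
  p <- w / sum(w)
  structure(list(prob = p, cum = cumsum(p)), class = "noise_distribution")
}

#' Draw negative words from a noise distribution
#'
#' Draws `count` word ids from the distribution, resampling any draw equal
#' to `exclude` (the positive target), so the conditional law is the noise
#' distribution renormalized without the excluded word.
#'
#' @param dist A [build_noise_distribution()].
#' @param count Number of negatives.
#' @param exclude 1-based word id never to return.
#' @param seed Optional integer seed (uses the current R RNG state when
#'   `NULL`).
#' @return Integer vector of `count` word ids.
#' @export
sample_negatives <- function(dist, count, exclude = 0L, seed = NULL) {
  stopifnot(count >= 1L)
  n <- length(dist$prob)
  if (n == 1L && exclude == 1L)
    stop("cannot sample negatives: vocabulary of size 1 equals the excluded word")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  out <- integer(count)
  for (i in seq_len(count)) {
    repeat {
      w <- findInterval(runif(1), dist$cum) + 1L
      if (w != exclude) break
    }
    out[i] <- w
  }
  out
}

#' Enumerate (target, context) pairs of a sentence
#'
#' One pair per in-vocabulary token position. In `"cbow"` (fixed-window)
#' mode the context is the up-to-`window` in-vocabulary tokens on each side;
#' in `"sent2vec"` (whole-sentence) mode it is every other token of the
#' sentence plus, for `n_max >= 2`, the hashed n-grams of the sentence with
#' the target position spliced out. Out-of-vocabulary tokens are removed
#' from the sentence before pairing.
#'
#' @param tokens Character vector of (normalized) sentence tokens.
#' @param vocab A [build_vocab()] vocabulary.
#' @param mode `"cbow"` or `"sent2vec"`.
#' @param window Context half-width in fixed-window mode.
#' @param n_max Maximum n-gram order in whole-sentence mode.
#' @param buckets Hash buckets for n-grams.
#' @return List of pairs, each a list with `target` (word id) and `context`
#'   (integer vector of context feature ids, with multiplicity). Sentences
#'   with fewer than 2 in-vocabulary tokens yield an empty list.
#' @export
make_context_pairs <- function(tokens, vocab, mode = c("sent2vec", "cbow"),
                               window = 5L, n_max = 1L, buckets = 2e6) {
  mode <- match.arg(mode)
  ids <- match(tokens, vocab$token)
  keep <- !is.na(ids)
  ids <- ids[keep]
  toks <- tokens[keep]
  L <- length(ids)
  if (L < 2L) return(list())
  lapply(seq_len(L), function(t) {
    if (mode == "cbow") {
      j <- setdiff(max(1L, t - window):min(L, t + window), t)
      ctx <- ids[j]
    } else {
      ctx <- ids[-t]
      if (n_max >= 2L && L >= 3L) {
        spl <- toks[-t]
        for (n in 2:n_max) {
          if (length(spl) < n) break
          for (j in seq_len(length(spl) - n + 1L))
            ctx <- c(ctx, nrow(vocab) +
                       hash_ngram(spl[j:(j + n - 1L)], buckets) + 1L)
        }
      }
    }
    list(target = ids[t], context = ctx)
  })
}

#' Negative-sampling loss of one (target, context) pair
#'
#' With `v_ctx` the average embedding of the context features, the loss is
#' `log(1 + exp(-u_t . v_ctx)) + sum_neg log(1 + exp(+u_neg . v_ctx))`: the
#' observed target is pushed towards the context vector and the sampled
#' negatives away from it.
#'
#' @param model A list with `V` (h x n_features) and `U` (h x |V|, output
#'   word vectors as columns).
#' @param pair A pair from [make_context_pairs()].
#' @param negatives Integer vector of negative word ids.
#' @return Non-negative scalar; `(1 + length(negatives)) * log(2)` exactly
#'   for an all-zero model.
#' @export
unsupervised_loss <- function(model, pair, negatives) {
  vctx <- context_vector(model, pair)
  s_pos <- sum(model$U[, pair$target] * vctx)
  s_neg <- as.numeric(crossprod(model$U[, negatives, drop = FALSE], vctx))
  log1pexp(-s_pos) + sum(log1pexp(s_neg))
}

context_vector <- function(model, pair) {
  if (length(pair$context) == 0L) return(numeric(nrow(model$V)))
  rowMeans(model$V[, pair$context, drop = FALSE])
}

log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(x)))

# Analytic gradient of the pair loss w.r.t. the touched columns of U
# (target + negatives) and of V (context features). For the
# finite-difference correctness tests.
unsupervised_grad <- function(model, pair, negatives) {
  vctx <- context_vector(model, pair)
  m <- length(pair$context)
  sig <- function(x) 1 / (1 + exp(-x))
  gU <- matrix(0, nrow = nrow(model$U), ncol = 1 + length(negatives))
  g_pos <- sig(sum(model$U[, pair$target] * vctx)) - 1
  gU[, 1] <- g_pos * vctx
  gctx <- g_pos * model$U[, pair$target]
  for (i in seq_along(negatives)) {
    g <- sig(sum(model$U[, negatives[i]] * vctx))
    gU[, i + 1] <- g * vctx
    gctx <- gctx + g * model$U[, negatives[i]]
  }
  list(u_ids = c(pair$target, negatives), dU = gU,
       v_ids = pair$context, dV = matrix(gctx / m, nrow = length(gctx),
                                         ncol = m))
}

#' Pre-train n-gram vectors without labels
#'
#' SGD with negative sampling over (target, context) pairs, shuffling
#' sentence order each epoch with a linearly decaying learning rate. Labels
#' are discarded before any processing. Tokens below `min_count` are removed
#' from sentences before pairing.
#'
#' @param x An `rct_corpus` or `sentence_set`; labels, if present, are
#'   ignored.
#' @param config A [train_config()]; `dim`, `n_max`, `epochs`, `buckets`,
#'   `min_count` and `seed` are used (`lr` below overrides the supervised
#'   default).
#' @param mode `"sent2vec"` (whole-sentence contexts, with n-grams) or
#'   `"cbow"` (fixed-window unigram contexts).
#' @param window Context half-width for `"cbow"` mode.
#' @param negatives Negative samples per positive.
#' @param power Noise-distribution smoothing exponent.
#' @param lr Initial learning rate for unsupervised training.
#' @param subsample Frequent-word subsampling threshold (0 disables it, the
#'   default); occurrences of word w are dropped with probability
#'   `1 - sqrt(subsample / f_w)` where `f_w` is w's corpus frequency share.
#' @return An object of class `pretrained_vectors`: `V` (h x n_features),
#'   `vocab`, `h`, `mode`, `n_max`, `buckets`, `epoch_loss` (mean pair loss
#'   per epoch).
#' @export
pretrain_vectors <- function(x, config = train_config(min_count = 5L),
                             mode = c("sent2vec", "cbow"), window = 5L,
                             negatives = 5L, power = 0.75, lr = 0.05,
                             subsample = 0) {
  mode <- match.arg(mode)
  ss <- as_sentence_set(x)
  ss$labels <- rep(NA_character_, length(ss))  # labels are never read
  vocab <- build_vocab(ss, config$min_count)
  dist <- build_noise_distribution(vocab, power)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  total_tokens <- sum(vocab$count)
  sents <- vector("list", length(ss))
  stoks <- vector("list", length(ss))
  for (i in seq_along(ss$tokens)) {
    toks <- ss$tokens[[i]]
    ids <- match(toks, vocab$token)
    keep <- !is.na(ids)
    if (subsample > 0) {
      f <- vocab$count[ids[keep]] / total_tokens
      p_keep <- pmin(1, sqrt(subsample / f))
      keep[keep] <- runif(sum(keep)) < p_keep
    }
    sents[[i]] <- ids[keep]
    stoks[[i]] <- toks[keep]
  }
  nonempty <- lengths(sents) >= 2L
  sents <- sents[nonempty]
  stoks <- stoks[nonempty]
  if (length(sents) == 0L) stop("no sentences with >= 2 in-vocabulary tokens")

  ngram_mode <- mode == "sent2vec" && config$n_max >= 2L
  buckets_eff <- if (ngram_mode) config$buckets else 0L
  n_features <- nrow(vocab) + buckets_eff
  m0 <- init_model(n_features, config$dim, 1L, config$seed)
  U0 <- matrix(0, nrow = config$dim, ncol = nrow(vocab))

  fit <- pretrain_cpp(sents, stoks, if (mode == "cbow") 0L else 1L,
                      as.integer(window),
                      if (mode == "cbow") 1L else config$n_max,
                      max(buckets_eff, 1L), nrow(vocab), config$dim,
                      config$epochs, lr, as.integer(negatives), dist$cum,
                      config$seed, m0$V, U0)
  structure(list(V = fit$V, U = fit$U, vocab = vocab, h = config$dim,
                 mode = mode,
                 n_max = if (mode == "cbow") 1L else config$n_max,
                 buckets = buckets_eff, window = as.integer(window),
                 negatives = as.integer(negatives),
                 epoch_loss = as.numeric(fit$epoch_loss), config = config),
            class = "pretrained_vectors")
}

#' @export
print.pretrained_vectors <- function(x, ...) {
  cat(sprintf("<pretrained_vectors: %s, h = %d, |V| = %d, buckets = %d>\n",
              x$mode, x$h, nrow(x$vocab), x$buckets))
  invisible(x)
}

#' Additive sentence embedding from pre-trained vectors
#'
#' The arithmetic mean of the embeddings of the sentence's in-vocabulary
#' unigrams and (for `n_max >= 2`) hashed n-grams over the in-vocabulary
#' token sequence. Sentences with no such features map to the zero vector.
#'
#' @param pretrained A [pretrain_vectors()] object.
#' @param tokens Character vector of sentence tokens.
#' @param n_max N-gram order; defaults to the order used at pre-training.
#' @return Numeric vector of length h.
#' @export
sent2vec_embed <- function(pretrained, tokens, n_max = pretrained$n_max) {
  toks <- tokens[tokens %in% pretrained$vocab$token]
  occ <- encode_occurrences(toks, pretrained$vocab, n_max,
                            max(pretrained$buckets, 1L))
  occ <- occ[occ <= ncol(pretrained$V)]
  if (length(occ) == 0L) return(numeric(pretrained$h))
  rowMeans(pretrained$V[, occ, drop = FALSE])
}

#' Transfer pre-trained vectors into a supervised initialization
#'
#' Builds the supervised model's initial input table: embeddings of
#' vocabulary tokens shared with the pre-trained vocabulary are copied in;
#' the n-gram bucket block is copied wholesale when both models use the same
#' bucket count (bucket ids are vocabulary-independent); everything else is
#' freshly initialized.
#'
#' @param pretrained A [pretrain_vectors()] object.
#' @param vocab The supervised model's vocabulary.
#' @param config The supervised [train_config()]; `dim` must equal the
#'   pre-trained dimension.
#' @return An h x n_features initialization matrix for [train_supervised()].
#' @export
transfer_init <- function(pretrained, vocab, config) {
  if (pretrained$h != config$dim)
    stop("dimension mismatch: pretrained h = ", pretrained$h,
         ", config dim = ", config$dim)
  buckets_sup <- if (config$n_max >= 2L) config$buckets else 0L
  n_features <- nrow(vocab) + buckets_sup
  V0 <- init_model(n_features, config$dim, 1L, config$seed)$V
  shared <- match(vocab$token, pretrained$vocab$token)
  hit <- which(!is.na(shared))
  if (length(hit) > 0L)
    V0[, hit] <- pretrained$V[, shared[hit], drop = FALSE]
  if (buckets_sup > 0L && pretrained$buckets > 0L) {
    if (pretrained$buckets != buckets_sup)
      stop("bucket count mismatch between pre-trained vectors and config")
    V0[, nrow(vocab) + seq_len(buckets_sup)] <-
      pretrained$V[, nrow(pretrained$vocab) + seq_len(buckets_sup),
                   drop = FALSE]
  }
  V0
}
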