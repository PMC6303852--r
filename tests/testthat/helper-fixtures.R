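# Fixtures are built in code; nothing is read from disk.

# A tiny hand-written corpus with known counts: 2 abstracts, 3 + 2 sentences.
tiny_corpus <- function() {
  new_corpus(list(
    list(id = "a1", sentences = list(
      list(tokens = c("aspirin", "reduced", "pain", "."), label = "OBJECTIVE"),
      list(tokens = c("we", "randomized", "200", "patients", "."),
           label = "METHODS"),
      list(tokens = c("pain", "scores", "fell", "."), label = "RESULTS")
    )),
    list(id = "a2", sentences = list(
      list(tokens = c("migraine", "is", "common", "."), label = "BACKGROUND"),
      list(tokens = c("treatment", "works", "."), label = "CONCLUSIONS")
    ))
  ))
}

# An abstract with one distinct token per sentence, for augmentation checks.
letters_abstract <- function(n = 5L) {
  toks <- c("aaa", "bbb", "ccc", "ddd", "eee", "fff")[seq_len(n)]
  list(id = "abs1",
       sentences = lapply(seq_len(n), function(i)
         list(tokens = rep(toks[i], 3L), label = rct_labels()[min(i, 5L)])))
}

# 50-sentence corpus where each label carries a unique marker token:
# linearly separable, so the classifier must fit it exactly.
marker_corpus <- function() {
  labs <- rep(rct_labels(), each = 10L)
  markers <- setNames(paste0("mk_", tolower(rct_labels())), rct_labels())
  abstracts <- lapply(seq_along(labs), function(i)
    list(id = sprintf("m%02d", i),
         sentences = list(list(tokens = c(markers[[labs[i]]], "filler_a",
                                          "filler_b"),
                               label = labs[i]))))
  new_corpus(abstracts)
}

# A vocabulary object built directly from token counts.
vocab_from_counts <- function(counts) {
  vocab <- data.frame(token = names(counts), count = as.integer(counts),
                      stringsAsFactors = FALSE)
  ord <- order(-vocab$count, vocab$token, method = "radix")
  vocab <- vocab[ord, , drop = FALSE]
  rownames(vocab) <- NULL
  attr(vocab, "min_count") <- 1L
  class(vocab) <- c("vocabulary", "data.frame")
  vocab
}

# Random feature bag over a given feature space.
random_bag <- function(n_features, m, seed) {
  set.seed(seed)
  ids <- sort(sample.int(n_features, m))
  w <- runif(m)
  list(ids = ids, weights = w / sum(w), n_features = n_features)
}

expect_rel_equal <- function(actual, expected, rel_tol, abs_floor = 1e-8) {
  denom <- pmax(abs(expected), abs_floor)
  expect_true(all(abs(actual - expected) / denom < rel_tol),
              label = sprintf("max rel err %.3g < %.3g",
                              max(abs(actual - expected) / denom), rel_tol))
}

# Central finite differences of f at x (scalar-output f, vector x).
numeric_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
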