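#' Build a vocabulary from a corpus or sentence set
#'
#' Counts token frequencies and keeps tokens occurring at least `min_count`
#' times. Ids are dense (1..|V|) and deterministic: tokens are ordered by
#' decreasing frequency with alphabetical tie-break, so re-building from the
#' same corpus always yields the identical mapping.
#'
#' @param x An `rct_corpus` or `sentence_set`.
#' @param min_count Minimum token frequency to be retained (1 for supervised
#'   training; 5 is the usual choice for unsupervised pre-training).
#' @return An object of class `vocabulary`: a data frame with columns
#'   `token` and `count` (row number = token id), with attributes
#'   `min_count`.
#' @export
build_vocab <- function(x, min_count = 1L) {
  ss <- as_sentence_set(x)
  if (length(ss$tokens) == 0L) stop("cannot build a vocabulary from an empty corpus")
  tab <- table(unlist(ss$tokens, use.names = FALSE))
  tab <- tab[tab >= min_count]
  if (length(tab) == 0L) stop("no tokens survive min_count = ", min_count)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  vocab <- data.frame(token = names(tab)[ord],
                      count = as.integer(tab)[ord],
                      stringsAsFactors = FALSE)
  attr(vocab, "min_count") <- as.integer(min_count)
  class(vocab) <- c("vocabulary", "data.frame")
  vocab
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary: %d tokens, min_count = %d>\n",
              nrow(x), attr(x, "min_count")))
  invisible(x)
}

#' Hash a word n-gram into a bucket
#'
#' FNV-1a (64-bit) over the n-gram's token bytes (with a separator byte
#' between tokens), reduced modulo the bucket count. Deterministic and
#' independent of any vocabulary, so models sharing a bucket count share
#' bucket assignments — the property that makes pre-trained n-gram vectors
#' transferable.
#'
#' @param tokens Character vector, the n-gram's tokens in order.
#' @param buckets Positive number of hash buckets.
#' @return Integer bucket id in `[0, buckets)`.
#' @export
#' @examples
#' hash_ngram(c("randomized", "controlled"), 2e6)
hash_ngram <- function(tokens, buckets) {
  stopifnot(length(tokens) >= 1L, buckets >= 1)
  hash_ngram_cpp(as.character(tokens), as.integer(buckets))
}

#' Encode a token sequence as a normalized feature bag
#'
#' Features are in-vocabulary unigram ids (1..|V|) plus hashed bucket ids
#' (|V|+1..|V|+buckets) for every n-gram of 2..`n_max` consecutive tokens.
#' Out-of-vocabulary unigrams contribute no unigram feature but still occupy
#' their positions inside n-grams. Duplicate features keep their
#' multiplicity; weights are occurrence counts normalized to sum to 1.
#'
#' @param tokens Character vector of (already normalized) tokens.
#' @param vocab A [build_vocab()] vocabulary.
#' @param n_max Maximum n-gram order (1 = pure bag of words).
#' @param buckets Number of hash buckets for n-grams of order 2 and above.
#' @return A list with `ids` (unique feature ids), `weights` (matching,
#'   summing to 1 when non-empty) and `n_features` (= |V| + buckets). An
#'   empty or all-out-of-vocabulary unigram-only input yields an empty bag.
#' @export
encode_bag <- function(tokens, vocab, n_max = 1L, buckets = 2e6) {
  occ <- encode_occurrences(tokens, vocab, n_max, buckets)
  if (length(occ) == 0L)
    return(list(ids = integer(0), weights = numeric(0),
                n_features = nrow(vocab) + as.integer(buckets)))
  tab <- table(occ)
  list(ids = as.integer(names(tab)),
       weights = as.numeric(tab) / length(occ),
       n_features = nrow(vocab) + as.integer(buckets))
}

# Occurrence-level feature ids (with multiplicity), 1-based.
encode_occurrences <- function(tokens, vocab, n_max, buckets) {
  uni <- match(tokens, vocab$token)
  encode_features_cpp(as.character(tokens), as.integer(uni),
                      as.integer(n_max), as.integer(buckets), nrow(vocab))
}

# Batch-encode a sentence set into a list of occurrence-id vectors.
encode_sentences <- function(ss, vocab, n_max, buckets) {
  lapply(ss$tokens, encode_occurrences, vocab = vocab, n_max = n_max,
         buckets = buckets)
}

#' Serialize a vocabulary as a two-column text table
#'
#' @param vocab A [build_vocab()] vocabulary.
#' @param path Output file path (tab-separated `token<TAB>count`, id = line
#'   number).
#' @return Invisibly, `path`.
#' @export
write_vocab <- function(vocab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(vocab$token, vocab$count, sep = "\t"), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocab
#' @param min_count The threshold recorded with the vocabulary on reading.
#' @return `read_vocab` returns the `vocabulary` object.
#' @export
read_vocab <- function(path, min_count = 1L) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vocab <- data.frame(token = vapply(parts, `[[`, "", 1L),
                      count = as.integer(vapply(parts, `[[`, "", 2L)),
                      stringsAsFactors = FALSE)
  attr(vocab, "min_count") <- as.integer(min_count)
  class(vocab) <- c("vocabulary", "data.frame")
  vocab
}
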