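#' Canonical rhetorical label set
#'
#' The five rhetorical section labels of structured randomized-controlled-trial
#' abstracts, in the fixed order used for confusion matrices and model output
#' layers throughout the package.
#'
#' @return Character vector of the five labels.
#' @export
#' @examples
#' rct_labels()
rct_labels <- function() {
  c("OBJECTIVE", "BACKGROUND", "METHODS", "RESULTS", "CONCLUSIONS")
}

#' Normalize raw sentence text into tokens
#'
#' Lower-cases the text, pads every ASCII punctuation character with
#' whitespace so that it becomes its own token, and splits on whitespace.
#' Decimal numbers are split at the period; no stemming or stop-word removal
#' is performed. Non-ASCII characters are treated as ordinary word
#' characters.
#'
#' @param raw Character vector of raw sentence strings.
#' @return For a single input string, a character vector of tokens; for a
#'   vector input, a list of token vectors.
#' @export
#' @examples
#' normalize_text("Aspirin reduced pain.")
normalize_text <- function(raw) {
  padded <- gsub("([][!\"#$%&'()*+,./:;<=>?@\\^_`{|}~-])", " \\1 ",
                 tolower(raw), perl = TRUE)
  toks <- strsplit(trimws(padded), "[[:space:]]+")
  toks <- lapply(toks, function(x) x[nzchar(x)])
  if (length(raw) == 1L) toks[[1L]] else toks
}

#' Construct a corpus of labeled abstracts
#'
#' A corpus is an ordered list of abstracts; each abstract is a list with an
#' `id` and a list of `sentences`, each sentence a list with normalized
#' `tokens` and a `label` (`NA` for unlabeled corpora).
#'
#' @param abstracts List of abstracts as described above.
#' @param label_set Ordered character vector of admissible labels. Defaults
#'   to the canonical five-label set.
#' @return An object of class `rct_corpus`.
#' @export
new_corpus <- function(abstracts, label_set = rct_labels()) {
  structure(list(abstracts = abstracts, label_set = label_set),
            class = "rct_corpus")
}

#' @export
print.rct_corpus <- function(x, ...) {
  ns <- sum(vapply(x$abstracts, function(a) length(a$sentences), integer(1)))
  cat(sprintf("<rct_corpus: %d abstracts, %d sentences, labels: %s>\n",
              length(x$abstracts), ns, paste(x$label_set, collapse = ", ")))
  invisible(x)
}

#' Flatten a corpus into a sentence set
#'
#' A sentence set is the flat representation the classifier consumes: a list
#' with parallel `tokens` (list of token vectors), `labels` (character, `NA`
#' when unlabeled), `abstract` (abstract ids) and `index` (0-based position
#' within the abstract), plus the corpus `label_set`.
#'
#' @param corpus An `rct_corpus` or an existing sentence set (returned
#'   unchanged).
#' @return An object of class `sentence_set`.
#' @export
as_sentence_set <- function(corpus) {
  if (inherits(corpus, "sentence_set")) return(corpus)
  stopifnot(inherits(corpus, "rct_corpus"))
  ns <- vapply(corpus$abstracts, function(a) length(a$sentences), integer(1))
  total <- sum(ns)
  tokens <- vector("list", total)
  labels <- character(total); absid <- character(total); idx <- integer(total)
  pos <- 0L
  for (a in corpus$abstracts) {
    for (i in seq_along(a$sentences)) {
      s <- a$sentences[[i]]
      pos <- pos + 1L
      tokens[[pos]] <- s$tokens
      labels[pos] <- if (is.null(s$label)) NA_character_ else s$label
      absid[pos] <- a$id
      idx[pos] <- i - 1L
    }
  }
  structure(list(tokens = tokens, labels = labels, abstract = absid,
                 index = idx, label_set = corpus$label_set),
            class = "sentence_set")
}

#' @export
print.sentence_set <- function(x, ...) {
  cat(sprintf("<sentence_set: %d sentences (%d labeled)>\n",
              length(x$tokens), sum(!is.na(x$labels))))
  invisible(x)
}

#' Subset a sentence set by sentence position
#' @param x A `sentence_set`.
#' @param i Integer indices of sentences to keep.
#' @param ... Ignored.
#' @return A `sentence_set` with the selected sentences.
#' @export
`[.sentence_set` <- function(x, i, ...) {
  structure(list(tokens = x$tokens[i], labels = x$labels[i],
                 abstract = x$abstract[i], index = x$index[i],
                 label_set = x$label_set),
            class = "sentence_set")
}

#' @export
length.sentence_set <- function(x) length(x$tokens)

validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "rct_corpus"))
  for (a in corpus$abstracts) {
    if (length(a$sentences) < 1L)
      stop("abstract '", a$id, "' has no sentences")
    for (s in a$sentences) {
      if (length(s$tokens) == 0L)
        stop("abstract '", a$id, "' contains an empty sentence")
      if (!is.null(s$label) && !is.na(s$label) &&
          !(s$label %in% corpus$label_set))
        stop("label '", s$label, "' not in corpus label set")
    }
  }
  invisible(corpus)
}
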