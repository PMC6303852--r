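#' Read a corpus in the PubMed-RCT plain-text dialect
#'
#' The dialect stores one abstract per block: a header line `###<id>`,
#' followed by one sentence per line as `LABEL<TAB>text`, with a blank line
#' between abstracts. In unlabeled mode, sentence lines are plain text with
#' no label column (for pre-training corpora). All sentence text is passed
#' through [normalize_text()]; sentences that normalize to zero tokens are
#' dropped.
#'
#' @param path Path to the corpus file (UTF-8).
#' @param labeled Logical; if `FALSE`, sentence lines carry no label column.
#' @param label_set Canonical label order. Labels found in the file that are
#'   not in this set raise an error.
#' @return An [new_corpus()] object.
#' @export
read_rct_corpus <- function(path, labeled = TRUE, label_set = rct_labels()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  abstracts <- list()
  cur_id <- NULL
  cur_sent <- list()
  flush <- function() {
    if (!is.null(cur_id) && length(cur_sent) > 0L)
      abstracts[[length(abstracts) + 1L]] <<- list(id = cur_id,
                                                   sentences = cur_sent)
    cur_id <<- NULL
    cur_sent <<- list()
  }
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) { flush(); next }
    if (startsWith(line, "###")) {
      flush()
      cur_id <- sub("^###", "", line)
      next
    }
    if (is.null(cur_id)) cur_id <- sprintf("block%d", length(abstracts) + 1L)
    if (labeled) {
      tab <- regexpr("\t", line, fixed = TRUE)
      if (tab < 0L)
        stop("parse error at line ", ln, ": expected LABEL<TAB>text")
      label <- substr(line, 1L, tab - 1L)
      if (!(label %in% label_set))
        stop("labeling error at line ", ln, ": unknown label '", label, "'")
      text <- substr(line, tab + 1L, nchar(line))
    } else {
      label <- NA_character_
      text <- line
    }
    toks <- normalize_text(text)
    if (length(toks) == 0L) next
    cur_sent[[length(cur_sent) + 1L]] <- list(tokens = toks, label = label)
  }
  flush()
  new_corpus(abstracts, label_set)
}

#' Write a corpus in the PubMed-RCT plain-text dialect
#'
#' Tokens are joined with single spaces; re-reading the emitted file yields
#' an identical corpus (normalization is idempotent on normalized text).
#'
#' @param corpus An `rct_corpus`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_rct_corpus <- function(corpus, path) {
  validate_corpus_light(corpus)
  out <- character(0)
  for (a in corpus$abstracts) {
    out <- c(out, paste0("###", a$id))
    for (s in a$sentences) {
      text <- paste(s$tokens, collapse = " ")
      line <- if (is.null(s$label) || is.na(s$label)) text
              else paste(s$label, text, sep = "\t")
      out <- c(out, line)
    }
    out <- c(out, "")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}

validate_corpus_light <- function(corpus) {
  stopifnot(inherits(corpus, "rct_corpus"))
  invisible(corpus)
}

#' Write word vectors in the plain-text `.vec` format
#'
#' Standard word-vector interchange format: a header line `"<count> <dim>"`,
#' then one line per token with the token followed by its vector components.
#' Only vocabulary unigram vectors are written (hashed n-gram buckets have no
#' printable name).
#'
#' @param pretrained A pre-trained vector object from [pretrain_vectors()],
#'   or a list with elements `V` (h x n_features matrix) and `vocab`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vectors <- function(pretrained, path) {
  V <- pretrained$V
  vocab <- pretrained$vocab
  nw <- nrow(vocab)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nw, nrow(V)), con, useBytes = TRUE)
  for (i in seq_len(nw)) {
    writeLines(paste(vocab$token[i],
                     paste(sprintf("%.8g", V[, i]), collapse = " ")),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read word vectors from the plain-text `.vec` format
#'
#' @param path Path to a `.vec` file as written by [write_vectors()].
#' @return A list with `tokens` (character) and `V` (h x count matrix, one
#'   column per token).
#' @export
read_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  nw <- hdr[1L]; h <- hdr[2L]
  tokens <- character(nw)
  V <- matrix(0, nrow = h, ncol = nw)
  for (i in seq_len(nw)) {
    parts <- strsplit(lines[i + 1L], " ", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts)]
    tokens[i] <- parts[1L]
    V[, i] <- as.numeric(parts[-1L])
  }
  list(tokens = tokens, V = V)
}

#' Save / load a trained model
#'
#' Models are stored with R's native serialization together with a format
#' version tag, the label order, the vocabulary and both embedding tables.
#'
#' @param model A model from [train_supervised()] or vectors from
#'   [pretrain_vectors()].
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "sectionseer-1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sectionseer-1"))
    stop("not a sectionseer model file: ", path)
  obj$model
}
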