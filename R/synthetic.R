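#' Specification for a synthetic structured-abstract corpus
#'
#' The simulator emulates the statistical structure that rhetorical sentence
#' classification exploits: sections appear in a canonical order
#' (background/objective block, then methods, results, conclusions), each
#' label has its own discriminative token pool, background and objective
#' draw part of their discriminative mass from a shared confusable pool
#' (these two classes are genuinely mixed up in real abstracts), and class
#' supports are skewed towards methods and results. Token draws within each
#' pool follow a 1/rank (Zipf-like) law so that frequency thresholds and
#' noise distributions have realistic tails.
#'
#' @param n_abstracts Number of abstracts.
#' @param sections Data frame with columns `label`, `presence` (probability
#'   the section occurs in an abstract), `min_sent`, `max_sent` (uniform
#'   sentence count when present), rows in canonical abstract order.
#' @param sent_len Length-2 integer range of tokens per sentence.
#' @param shared_size,disc_size,conf_size Sizes of the shared pool, each
#'   label's discriminative pool, and the background/objective confusable
#'   pool. Pools are disjoint by construction.
#' @param delta Probability that a token is drawn from a discriminative pool
#'   rather than the shared pool.
#' @param epsilon Fraction of background/objective discriminative draws
#'   taken from the common confusable pool instead of the label's own pool.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_abstracts = 500L,
                           sections = default_sections(),
                           sent_len = c(4L, 9L),
                           shared_size = 1000L, disc_size = 300L,
                           conf_size = 300L, delta = 0.3, epsilon = 0.5) {
  stopifnot(n_abstracts >= 1L, delta >= 0, delta <= 1, epsilon >= 0,
            epsilon <= 1, sent_len[1L] >= 1L, sent_len[2L] >= sent_len[1L])
  structure(list(n_abstracts = as.integer(n_abstracts), sections = sections,
                 sent_len = as.integer(sent_len),
                 shared_size = as.integer(shared_size),
                 disc_size = as.integer(disc_size),
                 conf_size = as.integer(conf_size),
                 delta = delta, epsilon = epsilon),
            class = "synthetic_spec")
}

default_sections <- function() {
  data.frame(
    label = c("BACKGROUND", "OBJECTIVE", "METHODS", "RESULTS", "CONCLUSIONS"),
    presence = c(0.7, 0.9, 1.0, 1.0, 0.9),
    min_sent = c(1L, 1L, 2L, 2L, 1L),
    max_sent = c(2L, 2L, 5L, 5L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic corpus scales
#'
#' `"small"` (500 abstracts) sizes unit tests; `"medium"` (5000 abstracts,
#' roughly 54k sentences) sizes the package's benchmark experiments. Both
#' use `delta = 0.3`, `epsilon = 0.5`.
#'
#' @param scale `"small"` or `"medium"`.
#' @return A [synthetic_spec()].
#' @export
default_spec <- function(scale = c("small", "medium")) {
  scale <- match.arg(scale)
  synthetic_spec(n_abstracts = if (scale == "small") 500L else 5000L)
}

disc_prefixes <- function() {
  c(OBJECTIVE = "obj", BACKGROUND = "bkg", METHODS = "met", RESULTS = "res",
    CONCLUSIONS = "con")
}

#' Generate a synthetic structured-abstract corpus
#'
#' Each sentence's tokens are drawn from a mixture: with probability `delta`
#' from the sentence label's discriminative pool (background/objective
#' redirect a fraction `epsilon` of those draws to the shared confusable
#' pool), otherwise from the shared pool. Sections appear in canonical order
#' with the presence probabilities and sentence counts of the spec, so
#' sentence position carries (noisy) label information, exactly as in real
#' structured abstracts.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the same spec and seed always give the
#'   identical corpus.
#' @return An `rct_corpus`.
#' @export
generate_corpus <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  sec <- spec$sections
  # plan: one row per sentence
  plan_label <- character(0); plan_abs <- integer(0)
  for (a in seq_len(spec$n_abstracts)) {
    labs <- character(0)
    for (j in seq_len(nrow(sec))) {
      if (runif(1) <= sec$presence[j]) {
        cnt <- if (sec$min_sent[j] == sec$max_sent[j]) sec$min_sent[j]
               else sample(sec$min_sent[j]:sec$max_sent[j], 1L)
        labs <- c(labs, rep(sec$label[j], cnt))
      }
    }
    if (length(labs) == 0L) labs <- "METHODS"
    plan_label <- c(plan_label, labs)
    plan_abs <- c(plan_abs, rep(a, length(labs)))
  }
  ns <- length(plan_label)
  lens <- if (spec$sent_len[1L] == spec$sent_len[2L])
            rep(spec$sent_len[1L], ns)
          else sample(spec$sent_len[1L]:spec$sent_len[2L], ns, replace = TRUE)

  # token-level mixture, drawn pool by pool for speed
  tok_label <- rep(plan_label, lens)
  total <- length(tok_label)
  is_disc <- runif(total) < spec$delta
  pool <- ifelse(is_disc, unname(disc_prefixes()[tok_label]), "w")
  confusable <- is_disc & tok_label %in% c("OBJECTIVE", "BACKGROUND") &
    runif(total) < spec$epsilon
  pool[confusable] <- "cnf"

  pool_sizes <- c(w = spec$shared_size, cnf = spec$conf_size,
                  setNames(rep(spec$disc_size, 5L), unname(disc_prefixes())))
  tokens <- character(total)
  for (p in names(pool_sizes)) {
    sel <- which(pool == p)
    if (length(sel) == 0L) next
    sz <- pool_sizes[[p]]
    zipf <- (1 / seq_len(sz)) / sum(1 / seq_len(sz))
    tokens[sel] <- sprintf("%s%d", p, sample.int(sz, length(sel),
                                                 replace = TRUE, prob = zipf))
  }

  sent_id <- rep(seq_len(ns), lens)
  sent_tokens <- split(tokens, sent_id)
  abstracts <- vector("list", spec$n_abstracts)
  for (a in seq_len(spec$n_abstracts)) {
    rows <- which(plan_abs == a)
    abstracts[[a]] <- list(
      id = sprintf("synth%05d", a),
      sentences = lapply(rows, function(r)
        list(tokens = unname(sent_tokens[[r]]), label = plan_label[r]))
    )
  }
  new_corpus(abstracts, rct_labels())
}
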