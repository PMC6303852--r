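test_that("noise distribution applies the smoothing exponent", {
  vocab <- vocab_from_counts(c(hot = 81, cold = 16))
  d <- build_noise_distribution(vocab, power = 0.75)
  expect_equal(d$prob, c(27 / 35, 8 / 35), tolerance = 1e-15)
  d0 <- build_noise_distribution(vocab, power = 0)
  expect_equal(d0$prob, c(0.5, 0.5))
  expect_equal(sum(d$prob), 1, tolerance = 1e-15)
})

test_that("negative sampling excludes the target and renormalizes", {
  vocab <- vocab_from_counts(c(a = 50, b = 30, c = 20))
  d <- build_noise_distribution(vocab, power = 1)
  draws <- sample_negatives(d, 20000L, exclude = 1L, seed = 13)
  expect_length(draws, 20000L)
  expect_false(any(draws == 1L))
  # conditional law = noise distribution renormalized without the excluded word
  cond <- d$prob[2:3] / sum(d$prob[2:3])
  emp <- tabulate(draws, 3)[2:3] / 20000
  se <- sqrt(cond * (1 - cond) / 20000)
  expect_true(all(abs(emp - cond) < 4 * se))
  expect_identical(sample_negatives(d, 5L, exclude = 2L, seed = 3),
                   sample_negatives(d, 5L, exclude = 2L, seed = 3))
  v1 <- vocab_from_counts(c(only = 4))
  expect_error(sample_negatives(build_noise_distribution(v1), 2L,
                                exclude = 1L), "size 1")
})

test_that("context pairs enumerate fixed-window and whole-sentence modes", {
  vocab <- vocab_from_counts(c(a = 3, b = 2, c = 1))
  id <- function(tok) match(tok, vocab$token)
  pairs <- make_context_pairs(c("a", "b", "c"), vocab, mode = "cbow",
                              window = 1)
  expect_length(pairs, 3L)
  expect_equal(pairs[[1]], list(target = id("a"), context = id("b")))
  expect_setequal(pairs[[2]]$context, id(c("a", "c")))
  expect_equal(pairs[[3]]$context, id("b"))

  s2v <- make_context_pairs(c("a", "b", "c"), vocab, mode = "sent2vec",
                            n_max = 1)
  expect_length(s2v, 3L)
  expect_setequal(s2v[[2]]$context, id(c("a", "c")))

  # pair count equals in-vocabulary token count in both modes
  toks <- c("a", "b", "a", "c", "b", "zzz")
  expect_length(make_context_pairs(toks, vocab, "cbow", window = 2), 5L)
  expect_length(make_context_pairs(toks, vocab, "sent2vec", n_max = 2,
                                   buckets = 100), 5L)
  # whole-sentence contexts include spliced n-grams
  p <- make_context_pairs(c("a", "b", "c"), vocab, "sent2vec", n_max = 2,
                          buckets = 100)
  expect_true(any(p[[2]]$context > nrow(vocab)))  # the (a,c) bridge bigram
  expect_equal(sum(p[[2]]$context > nrow(vocab)), 1L)
  expect_length(make_context_pairs(c("a", "zzz"), vocab, "cbow"), 0L)
})

test_that("pair loss is (1+negatives) ln 2 at zero parameters and vanishes in the limit", {
  model <- list(V = matrix(0, 3, 10), U = matrix(0, 3, 6))
  pair <- list(target = 2L, context = c(1L, 4L, 7L))
  expect_equal(unsupervised_loss(model, pair, negatives = c(3L, 5L)),
               3 * log(2), tolerance = 1e-15)
  # strong fit: target aligned, negatives anti-aligned
  model$V[, pair$context] <- 1
  model$U[, 2] <- 50
  model$U[, c(3, 5)] <- -50
  expect_lt(unsupervised_loss(model, pair, c(3L, 5L)), 1e-12)
})

test_that("unsupervised gradients match central finite differences", {
  set.seed(123)
  for (draw in 1:20) {
    h <- 3; nv <- 5
    model <- list(V = matrix(rnorm(h * nv), h, nv),
                  U = matrix(rnorm(h * nv), h, nv))
    pair <- list(target = sample.int(nv, 1),
                 context = sample.int(nv, sample(2:3, 1), replace = TRUE))
    negs <- sample(setdiff(seq_len(nv), pair$target), 2)
    g <- sectionseer:::unsupervised_grad(model, pair, negs)
    # U columns (accumulate duplicates per unique id)
    for (u in unique(g$u_ids)) {
      fd <- numeric_grad(function(col) {
        m2 <- model; m2$U[, u] <- col
        unsupervised_loss(m2, pair, negs)
      }, model$U[, u])
      an <- rowSums(g$dU[, g$u_ids == u, drop = FALSE])
      expect_rel_equal(an, fd, 1e-5, abs_floor = 1e-6)
    }
    for (v in unique(g$v_ids)) {
      fd <- numeric_grad(function(col) {
        m2 <- model; m2$V[, v] <- col
        unsupervised_loss(m2, pair, negs)
      }, model$V[, v])
      an <- rowSums(g$dV[, g$v_ids == v, drop = FALSE])
      expect_rel_equal(an, fd, 1e-5, abs_floor = 1e-6)
    }
  }
})

test_that("pre-training is deterministic and never reads labels", {
  corpus <- generate_corpus(synthetic_spec(n_abstracts = 40L), seed = 21)
  cfg <- train_config(dim = 6, n_max = 2, epochs = 2, buckets = 1e4,
                      min_count = 2, seed = 31)
  p1 <- pretrain_vectors(corpus, cfg)
  p2 <- pretrain_vectors(corpus, cfg)
  expect_identical(p1$V, p2$V)
  stripped <- as_sentence_set(corpus)
  stripped$labels <- rep(NA_character_, length(stripped))
  p3 <- pretrain_vectors(stripped, cfg)
  expect_identical(p1$V, p3$V)
})

test_that("vectors learn two-block co-occurrence structure", {
  # words co-occur only within two disjoint topic blocks
  set.seed(55)
  words_a <- sprintf("alpha%d", 1:15)
  words_b <- sprintf("beta%d", 1:15)
  sent <- function(pool) list(tokens = sample(pool, 6, replace = TRUE),
                              label = "METHODS")
  abstracts <- lapply(1:150, function(i)
    list(id = sprintf("t%03d", i),
         sentences = list(sent(if (i %% 2) words_a else words_b))))
  corpus <- new_corpus(abstracts)
  pre <- pretrain_vectors(corpus, train_config(dim = 10, n_max = 1,
                                               epochs = 10, min_count = 1,
                                               seed = 2),
                          mode = "sent2vec", lr = 0.1)
  ia <- match(intersect(words_a, pre$vocab$token), pre$vocab$token)
  ib <- match(intersect(words_b, pre$vocab$token), pre$vocab$token)
  cosmat <- function(idx1, idx2) {
    M <- pre$V
    norms <- sqrt(colSums(M^2))
    (t(M[, idx1]) %*% M[, idx2]) / outer(norms[idx1], norms[idx2])
  }
  within_ <- (mean(cosmat(ia, ia)) + mean(cosmat(ib, ib))) / 2
  across <- mean(cosmat(ia, ib))
  expect_gt(within_, across)
})

test_that("sentence embeddings are exact means of constituent vectors", {
  corpus <- generate_corpus(synthetic_spec(n_abstracts = 30L), seed = 14)
  pre <- pretrain_vectors(corpus, train_config(dim = 8, n_max = 2,
                                               buckets = 1e4, epochs = 1,
                                               min_count = 1, seed = 6))
  w1 <- pre$vocab$token[1]; w2 <- pre$vocab$token[2]
  expect_equal(sent2vec_embed(pre, w1, n_max = 1), as.numeric(pre$V[, 1]))
  expect_equal(sent2vec_embed(pre, c(w1, w2), n_max = 1),
               as.numeric((pre$V[, 1] + pre$V[, 2]) / 2), tolerance = 1e-14)
  expect_equal(sent2vec_embed(pre, "notinthevocab"), rep(0, 8))
  # brute-force mean over the enumerated feature list R(S)
  ss <- as_sentence_set(corpus)
  for (i in 1:10) {
    toks <- ss$tokens[[i]]
    iv <- toks[toks %in% pre$vocab$token]
    occ <- sectionseer:::encode_occurrences(iv, pre$vocab, 2, 1e4)
    brute <- rowMeans(pre$V[, occ, drop = FALSE])
    expect_equal(sent2vec_embed(pre, toks), brute, tolerance = 1e-14)
  }
})

test_that("transfer copies shared features and leaves the rest freshly initialized", {
  corpus <- generate_corpus(synthetic_spec(n_abstracts = 40L), seed = 33)
  pre <- pretrain_vectors(corpus, train_config(dim = 7, n_max = 2,
                                               buckets = 5e3, min_count = 2,
                                               epochs = 1, seed = 3))
  sup_ss <- as_sentence_set(corpus)[1:50]
  vocab <- build_vocab(sup_ss, 1)
  cfg <- train_config(dim = 7, n_max = 2, buckets = 5e3, seed = 44)
  V0 <- transfer_init(pre, vocab, cfg)
  expect_equal(ncol(V0), nrow(vocab) + 5e3)
  shared <- which(vocab$token %in% pre$vocab$token)
  for (i in shared)
    expect_equal(V0[, i],
                 pre$V[, match(vocab$token[i], pre$vocab$token)])
  # bucket block is copied wholesale
  expect_equal(V0[, nrow(vocab) + 1:10], pre$V[, nrow(pre$vocab) + 1:10])
  # unseen unigrams equal a fresh seeded initialization
  fresh <- init_model(ncol(V0), 7, 1, seed = 44)$V
  unseen <- setdiff(seq_len(nrow(vocab)), shared)
  if (length(unseen) > 0)
    expect_identical(V0[, unseen], fresh[, unseen])
  # disjoint vocabularies: transfer of unigrams is a no-op
  other <- vocab_from_counts(c(zzz1 = 5, zzz2 = 4))
  cfg1 <- train_config(dim = 7, n_max = 1, seed = 44)
  expect_identical(transfer_init(pre, other, cfg1),
                   init_model(2, 7, 1, seed = 44)$V)
  expect_error(transfer_init(pre, vocab, train_config(dim = 9, n_max = 1)),
               "dimension mismatch")
})
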