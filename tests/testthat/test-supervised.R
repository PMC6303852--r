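test_that("initialization is seeded and bounded; zero U predicts uniform", {
  m1 <- init_model(50, 8, 5, seed = 42)
  m2 <- init_model(50, 8, 5, seed = 42)
  expect_identical(m1, m2)
  expect_true(all(abs(m1$V) <= 1 / 8))
  expect_true(all(m1$U == 0))
  bag <- random_bag(50, 7, seed = 1)
  expect_equal(unname(predict_proba(m1, bag)), rep(1 / 5, 5),
               tolerance = 1e-15)
  expect_error(init_model(0, 8, 5))
})

test_that("V entries are centred (CLT bound over many draws)", {
  m <- init_model(10000, 10, 2, seed = 7)   # 1e5 draws on [-1/h, 1/h]
  sigma <- (2 / 10) / sqrt(12)
  expect_lt(abs(mean(m$V)), 3 * sigma / sqrt(length(m$V)))
})

test_that("sentence vectors are the weighted feature-embedding averages", {
  m <- init_model(30, 6, 5, seed = 3)
  one <- list(ids = 17L, weights = 1)
  expect_equal(sentence_vector(m, one), as.numeric(m$V[, 17]))
  empty <- list(ids = integer(0), weights = numeric(0))
  expect_equal(sentence_vector(m, empty), rep(0, 6))
  bag <- random_bag(30, 9, seed = 4)
  brute <- rep(0, 6)
  for (j in seq_along(bag$ids))
    brute <- brute + bag$weights[j] * m$V[, bag$ids[j]]
  expect_equal(sentence_vector(m, bag), brute, tolerance = 1e-14)
  expect_error(sentence_vector(m, list(ids = 31L, weights = 1)),
               "out of range")
})

test_that("probabilities match the stabilized softmax and normalize exactly", {
  set.seed(11)
  for (rep in 1:20) {
    h <- sample(2:4, 1); k <- sample(2:5, 1)
    m <- init_model(20, h, k, seed = rep)
    m$U <- matrix(rnorm(k * h, sd = 3), k, h)
    bag <- random_bag(20, 5, seed = rep + 100)
    p <- predict_proba(m, bag)
    z <- as.numeric(m$U %*% sentence_vector(m, bag))
    ref <- exp(z - max(z) - log(sum(exp(z - max(z)))))
    expect_equal(unname(p), ref, tolerance = 1e-12)
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
  # two-class closed form: logits (z, -z) -> (sigma(2z), 1 - sigma(2z))
  m <- init_model(4, 2, 2, seed = 1)
  m$V[, 1] <- c(1, 0)
  m$U <- matrix(c(1.3, -1.3, 0, 0), nrow = 2)
  p <- predict_proba(m, list(ids = 1L, weights = 1))
  expect_equal(unname(p[1]), 1 / (1 + exp(-2 * 1.3)), tolerance = 1e-12)
})

test_that("label prediction takes the argmax with lowest-index ties", {
  m <- init_model(10, 3, 5, seed = 2)
  m$label_order <- rct_labels()
  empty <- list(ids = integer(0), weights = numeric(0))
  expect_equal(predict_label(m, empty), "OBJECTIVE")  # uniform -> first label
  set.seed(21)
  for (rep in 1:50) {
    bag <- random_bag(10, 4, seed = rep)
    p <- predict_proba(m, bag)
    expect_equal(predict_label(m, bag), rct_labels()[which.max(p)])
  }
})

test_that("loss equals ln k at zero parameters and 0 for perfect predictions", {
  m <- init_model(10, 4, 5, seed = 1)
  bags <- lapply(1:6, function(s) random_bag(10, 3, seed = s))
  expect_equal(supervised_loss(m, bags, rep(1L, 6)), log(5), tolerance = 1e-12)
  # near-one-hot model: huge margins drive the loss to ~0
  m$U <- matrix(0, 5, 4)
  m$V[] <- 0
  m$V[1, 1] <- 1
  m$U[2, 1] <- 1e4
  expect_lt(supervised_loss(m, list(list(ids = 1L, weights = 1)), 2L), 1e-12)
  expect_error(supervised_loss(m, list(), integer(0)), "empty")
})

test_that("analytic gradients match central finite differences", {
  set.seed(99)
  for (draw in 1:20) {
    h <- sample(2:3, 1); k <- sample(2:5, 1); nf <- sample(4:10, 1)
    m <- init_model(nf, h, k, seed = draw)
    m$U <- matrix(rnorm(k * h), k, h)
    m$V <- matrix(rnorm(h * nf), h, nf)
    bag <- random_bag(nf, sample(2:4, 1), seed = draw + 500)
    y <- sample.int(k, 1)
    g <- sectionseer:::supervised_grad(m, bag, y)
    loss_at <- function(m2) -log(predict_proba(m2, bag)[y])
    fdU <- numeric_grad(function(u) {
      m2 <- m; m2$U <- matrix(u, k, h); loss_at(m2)
    }, as.numeric(m$U))
    expect_rel_equal(as.numeric(g$dU), fdU, 1e-5, abs_floor = 1e-6)
    fdV <- numeric_grad(function(vcols) {
      m2 <- m; m2$V[, bag$ids] <- matrix(vcols, h); loss_at(m2)
    }, as.numeric(m$V[, bag$ids]))
    expect_rel_equal(as.numeric(g$dV), fdV, 1e-5, abs_floor = 1e-6)
  }
})

test_that("one SGD step of the trainer applies exactly the analytic gradient", {
  vocab_tokens <- c("t1", "t2", "t3", "t4")
  corpus <- new_corpus(list(list(id = "a", sentences = list(
    list(tokens = c("t1", "t2", "t3"), label = "METHODS")))))
  cfg <- train_config(dim = 3, n_max = 1, epochs = 1, lr = 0.25, seed = 5)
  model <- train_supervised(corpus, cfg)
  vocab <- model$vocab
  init <- init_model(nrow(vocab), 3, 5, seed = 5)
  bag <- encode_bag(c("t1", "t2", "t3"), vocab, n_max = 1)
  g <- sectionseer:::supervised_grad(
    list(V = init$V, U = init$U, h = 3L), bag, match("METHODS", rct_labels()))
  expect_equal(model$U, init$U - 0.25 * g$dU, tolerance = 1e-12)
  V_exp <- init$V
  V_exp[, g$ids] <- V_exp[, g$ids] - 0.25 * g$dV
  expect_equal(model$V, V_exp, tolerance = 1e-12)
})

test_that("training fits a linearly separable marker corpus exactly", {
  corpus <- marker_corpus()
  cfg <- train_config(dim = 10, n_max = 1, epochs = 5, seed = 3)
  model <- train_supervised(corpus, cfg)
  ss <- as_sentence_set(corpus)
  pred <- predict(model, ss)
  expect_equal(mean(pred == ss$labels), 1.0)
  # training loss decreases over epochs on separable data
  expect_true(model$epoch_loss[length(model$epoch_loss)] <
                model$epoch_loss[1])
})

test_that("training is bit-reproducible under a fixed seed", {
  corpus <- generate_corpus(synthetic_spec(n_abstracts = 30L), seed = 12)
  cfg <- train_config(dim = 8, n_max = 2, epochs = 2, buckets = 1e4,
                      seed = 77)
  m1 <- train_supervised(corpus, cfg)
  m2 <- train_supervised(corpus, cfg)
  expect_identical(m1$V, m2$V)
  expect_identical(m1$U, m2$U)
  m3 <- train_supervised(corpus, train_config(dim = 8, n_max = 2, epochs = 2,
                                              buckets = 1e4, seed = 78))
  expect_false(identical(m1$V, m3$V))
})

test_that("only feature columns touched by training examples are updated", {
  corpus <- marker_corpus()
  cfg <- train_config(dim = 6, n_max = 1, epochs = 3, seed = 9)
  model <- train_supervised(corpus, cfg)
  ss <- as_sentence_set(corpus)
  # features of a held-in vocabulary never seen: append unused token via vocab
  seen <- unique(unlist(ss$tokens))
  expect_setequal(model$vocab$token, seen)
  init <- init_model(nrow(model$vocab), 6, 5, seed = 9)
  # every unigram occurs in some sentence, so sparsity is visible on the
  # hashed bigram block: bucket columns no training bigram maps to must stay
  # at their seeded initialization (two epochs: with U starting at zero, the
  # first step leaves V unchanged).
  cfg2 <- train_config(dim = 6, n_max = 2, epochs = 2, buckets = 1000,
                       seed = 9)
  m2 <- train_supervised(corpus, cfg2)
  nuni <- nrow(m2$vocab)
  init2 <- init_model(ncol(m2$V), 6, 5, seed = 9)
  hit <- unique(unlist(lapply(ss$tokens, function(tk)
    encode_bag(tk, m2$vocab, n_max = 2, buckets = 1000)$ids)))
  unused <- setdiff(nuni + seq_len(1000), hit)
  expect_gt(length(unused), 0L)
  expect_identical(m2$V[, unused], init2$V[, unused])
  used_buckets <- setdiff(hit, seq_len(nuni))
  expect_false(identical(m2$V[, used_buckets], init2$V[, used_buckets]))
})

test_that("empty or all-OOV sentences predict the uniform fallback", {
  corpus <- marker_corpus()
  model <- train_supervised(corpus, train_config(dim = 6, n_max = 1,
                                                 epochs = 2, seed = 1))
  probs <- predict(model, list(c("unseen_token_xyz")), type = "prob")
  expect_equal(as.numeric(probs), rep(1 / 5, 5), tolerance = 1e-12)
})

test_that("models survive a save/load round-trip", {
  corpus <- marker_corpus()
  model <- train_supervised(corpus, train_config(dim = 4, n_max = 1,
                                                 epochs = 1, seed = 2))
  f <- withr::local_tempfile(fileext = ".bin")
  save_model(model, f)
  back <- load_model(f)
  expect_equal(back$V, model$V)
  expect_equal(back$label_order, model$label_order)
})
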