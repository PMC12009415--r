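test_that("attention pooling matches a brute-force oracle", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      H <- matrix(rnorm(5 * 4), 5, 4)
      omega <- rnorm(4)
      mask <- c(TRUE, TRUE, TRUE, rep(sample(c(TRUE, FALSE), 1), 2))
      got <- attention_pool(H, omega, mask)
      want <- oracle_attention(H, omega, mask)
      expect_equal(got$alpha, want$alpha, tolerance = 1e-8)
      expect_equal(got$c, want$c, tolerance = 1e-8)
    }
  })
})

test_that("attention weights form a simplex over unmasked positions", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      L <- sample(3:8, 1)
      H <- matrix(rnorm(L * 6, sd = 2), L, 6)
      mask <- c(rep(TRUE, 2), sample(c(TRUE, FALSE), L - 2, replace = TRUE))
      got <- attention_pool(H, rnorm(6), mask)
      expect_true(all(got$alpha >= 0))
      expect_equal(sum(got$alpha), 1, tolerance = 1e-9)
      expect_true(all(got$alpha[!mask] == 0))
      # c is a convex combination of unmasked rows
      sub <- H[mask, , drop = FALSE]
      expect_true(all(got$c >= apply(sub, 2, min) - 1e-9))
      expect_true(all(got$c <= apply(sub, 2, max) + 1e-9))
    }
  })
  expect_error(attention_pool(matrix(0, 3, 2), c(0, 0), c(FALSE, FALSE,
                                                          FALSE)),
               "degenerate")
})

test_that("identical rows or zero omega give uniform attention", {
  H <- matrix(rep(c(1, -2, 0.5), each = 4), 4, 3)
  got <- attention_pool(H, rnorm(3), rep(TRUE, 4))
  expect_equal(got$alpha, rep(0.25, 4), tolerance = 1e-9)
  expect_equal(got$c, H[1, ], tolerance = 1e-9)
  H2 <- matrix(rnorm(12), 4, 3)
  mask <- c(TRUE, TRUE, TRUE, FALSE)
  got2 <- attention_pool(H2, rep(0, 3), mask)
  expect_equal(got2$alpha[1:3], rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(got2$c, colMeans(H2[1:3, ]), tolerance = 1e-9)
})

test_that("softmax classification follows the closed form", {
  got <- classify(c(0, 0), matrix(0, 4, 2), rep(0, 4))
  expect_equal(got$probs, rep(0.25, 4), tolerance = 1e-12)
  expect_identical(got$predicted, "DS")  # tie broken to the lowest index
  two <- classify(1, matrix(c(1, 0), 2, 1), c(0, 0), labels = c("a", "b"))
  expect_equal(two$probs, c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)
  withr::with_seed(13, {
    for (rep in 1:10) {
      got <- classify(rnorm(6), matrix(rnorm(24), 4, 6), rnorm(4))
      expect_equal(sum(got$probs), 1, tolerance = 1e-6)
      expect_identical(got$predicted,
                       RELATION_LABELS[which.max(got$probs)])
    }
  })
  expect_error(classify(Inf, matrix(1, 2, 1), c(0, 0)), "numeric-error")
})

test_that("the BiGRU emits L x 2u with zero rows on padding", {
  vocab <- build_vocab(list(c("#", "*", "a", "b")))
  enc <- lookup_encoder(vocab, D = 6, L = 10, seed = 2)
  params <- rehabminer:::init_params(6, 3, 4, seed = 5)
  H <- bigru_forward(encode(enc, "# a b *"), params)
  expect_identical(dim(H), c(10L, 6L))
  expect_true(all(H[5:10, ] == 0))
  expect_true(any(H[1:4, ] != 0))
  # all-masked input gives an all-zero H
  H0 <- bigru_forward(encode(enc, ""), params)
  expect_true(all(H0 == 0))
})

test_that("reversing the tokens swaps the directional blocks", {
  vocab <- build_vocab(list(c("x", "y", "z", "w")))
  enc <- lookup_encoder(vocab, D = 5, L = 4, seed = 3)
  params <- rehabminer:::init_params(5, 3, 4, seed = 7)
  mirrored <- params
  mirrored$f <- params$b
  mirrored$b <- params$f
  H1 <- bigru_forward(encode(enc, "x y z w"), params)
  H2 <- bigru_forward(encode(enc, "w z y x"), mirrored)
  expect_equal(H1[, 1:3], H2[4:1, 4:6], tolerance = 1e-12)
  expect_equal(H1[, 4:6], H2[4:1, 1:3], tolerance = 1e-12)
})

test_that("analytic gradients match numeric differentiation", {
  withr::with_seed(31, {
    B <- 3; L <- 5; D <- 4; u <- 3; nl <- 3
    V <- 6
    ids <- matrix(sample(seq_len(V), B * L, replace = TRUE), B, L)
    mask <- matrix(TRUE, B, L); mask[1, 4:5] <- FALSE; mask[2, 5] <- FALSE
    y <- c(1L, 2L, 3L)
    for (pooling in c("attention", "mean")) {
      cfg <- model_config(hidden_units = u, n_labels = nl, dropout = 0,
                          pooling = pooling, seed = 2)
      params <- rehabminer:::init_params(D, u, nl, seed = 3)
      params$E <- matrix(rnorm(V * D, sd = 0.3), V, D)
      loss_of <- function(p)
        rehabminer:::batch_forward(p, p$E, ids, mask, cfg, y = y)$loss
      fw <- rehabminer:::batch_forward(params, params$E, ids, mask, cfg,
                                       y = y, training = TRUE,
                                       keep_cache = TRUE)
      gr <- rehabminer:::batch_backward(params, params$E, ids, mask, cfg,
                                        y, fw)
      eps <- 1e-6
      perturb <- function(p, path, i, delta) {
        if (length(path) == 1) p[[path]][i] <- p[[path]][i] + delta
        else p[[path[1]]][[path[2]]][i] <- p[[path[1]]][[path[2]]][i] + delta
        p
      }
      cases <- list(list("omega", 1), list("Wout", 2), list("bout", 1),
                    list("E", 5), list(c("f", "Wz"), 3),
                    list(c("f", "Un"), 4), list(c("b", "Wn"), 2),
                    list(c("b", "Ur"), 1), list(c("f", "bn"), 2))
      for (cs in cases) {
        if (pooling == "mean" && identical(cs[[1]], "omega")) next
        ng <- (loss_of(perturb(params, cs[[1]], cs[[2]], eps)) -
                 loss_of(perturb(params, cs[[1]], cs[[2]], -eps))) /
          (2 * eps)
        ag <- if (length(cs[[1]]) == 1) gr[[cs[[1]]]][cs[[2]]]
              else gr[[cs[[1]][1]]][[cs[[1]][2]]][cs[[2]]]
        expect_equal(ag, ng, tolerance = 1e-4)
      }
    }
  })
})

tiny_separable_set <- function(n_per = 10) {
  mk <- function(lab, cue, i)
    relation_instance(lab, "d", "v", paste("start #", cue, "* end", i))
  c(lapply(seq_len(n_per), function(i) mk("DS", "alpha", i)),
    lapply(seq_len(n_per), function(i) mk("SFD", "beta", i)))
}

test_that("loss decreases on a tiny separable dataset", {
  insts <- tiny_separable_set(10)
  toks <- lapply(insts, function(i) tokenize(i$marked_text))
  enc <- lookup_encoder(build_vocab(toks), D = 8, L = 16, seed = 4)
  cfg <- model_config(hidden_units = 4, dropout = 0, epochs = 30,
                      batch_size = 4, learning_rate = 5e-3, seed = 4)
  m <- train_relation_model(insts, insts, enc, cfg)
  loss <- m$trace$loss
  expect_lt(loss[length(loss)], loss[1])
  expect_true(all(diff(loss) < 0.05))  # monotone descent to tolerance
  expect_equal(m$trace$val_F1[nrow(m$trace)], 1, tolerance = 1e-9)
})

test_that("zero learning rate leaves parameters and loss unchanged", {
  insts <- tiny_separable_set(5)
  toks <- lapply(insts, function(i) tokenize(i$marked_text))
  enc <- lookup_encoder(build_vocab(toks), D = 8, L = 16, seed = 4)
  cfg <- model_config(hidden_units = 4, dropout = 0, epochs = 4,
                      learning_rate = 0, seed = 4)
  m <- train_relation_model(insts, insts, enc, cfg)
  init <- rehabminer:::init_params(8, 4, 4, seed = 4)
  expect_equal(m$params$f$Wz, init$f$Wz, tolerance = 1e-12)
  expect_equal(max(abs(diff(m$trace$loss))), 0, tolerance = 1e-9)
})

test_that("training is deterministic under a fixed seed", {
  insts <- tiny_separable_set(6)
  toks <- lapply(insts, function(i) tokenize(i$marked_text))
  enc <- lookup_encoder(build_vocab(toks), D = 8, L = 16, seed = 9)
  cfg <- model_config(hidden_units = 4, epochs = 5, batch_size = 4,
                      seed = 9)
  m1 <- train_relation_model(insts, insts, enc, cfg)
  m2 <- train_relation_model(insts, insts, enc, cfg)
  expect_identical(m1$trace$val_F1, m2$trace$val_F1)
  expect_equal(m1$params$omega, m2$params$omega, tolerance = 1e-15)
})

test_that("empty training sets are rejected", {
  enc <- lookup_encoder(build_vocab(list("a")), D = 4, L = 8, seed = 1)
  expect_error(train_relation_model(list(), list(), enc, model_config()),
               "empty training set")
})

test_that("predicted triples come from enumerated candidate pairs", {
  g <- generate_corpus(generator_config(n_records = 120,
                                        noise_sentence_rate = 0,
                                        seed = 14, max_len = 64))
  sp <- stratified_split(g$gold, seed = 14)
  toks <- lapply(sp$train, function(i) tokenize(i$marked_text))
  enc <- lookup_encoder(build_vocab(toks), D = 16, L = 64, seed = 14)
  cfg <- model_config(hidden_units = 8, epochs = 8, seed = 14)
  m <- train_relation_model(sp$train, sp$validation, enc, cfg)
  triples <- predict_triples(g$records[1:20], m)
  expect_true(all(c("record_id", "entity1", "entity2", "relation",
                    "prob") %in% names(triples)))
  expect_true(all(triples$relation %in% RELATION_LABELS))
  expect_true(all(startsWith(triples$entity1, "dis")))
  # records without DIS mentions yield no triples
  no_dis <- qa_record("x", "t", "sym1 hurts", "rest well",
                      data.frame(surface = "sym1", etype = "SYM",
                                 start = 2, end = 6))
  expect_identical(nrow(predict_triples(list(no_dis), m)), 0L)
})

test_that("test F1 degrades as noise sentences are added", {
  f1_at <- function(noise, seeds = 1:2) {
    mean(vapply(seeds, function(s) {
      cfg <- generator_config(n_records = 300,
                              noise_sentence_rate = noise,
                              seed = s, max_len = 64)
      res <- run_extraction_experiment(cfg,
        model_cfg = model_config(epochs = 25, seed = s))
      res$report$f1[res$report$class == "Total"]
    }, numeric(1)))
  }
  expect_gte(f1_at(0) + 1e-6, f1_at(0.8))
})
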