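test_that("vocabulary respects min_count and empty vocabularies are fatal", {
  fx <- toy_model()
  n_tokens <- length(unique(unlist(fx$sentences)))
  expect_lte(length(fx$model$vocab), n_tokens)
  expect_true(all(fx$model$freq >= fx$model$hp$min_count))
  expect_error(
    train_embedding(fx$sentences, embedding_hp(dim = 8, min_count = 10000L)),
    "min_count", class = "triscreen_empty_error")
})

test_that("training is bit-reproducible under a fixed seed and differs across seeds", {
  fx <- toy_model()
  hp <- embedding_hp(dim = 16, epochs = 2, window = 5, seed = 42)
  m2 <- train_embedding(fx$sentences, hp)
  expect_identical(fx$model$vectors, m2$vectors)
  m3 <- train_embedding(fx$sentences, embedding_hp(dim = 16, epochs = 2,
                                                   window = 5, seed = 43))
  expect_false(identical(fx$model$vectors, m3$vectors))
})

test_that("molecule vectors are token-vector sums with OOV skipped", {
  fx <- toy_model()
  model <- fx$model
  toks <- rownames(model$vectors)
  # [a, b] -> va + vb
  v <- embed_molecule(model, toks[1:2])
  expect_equal(v, model$vectors[1, ] + model$vectors[2, ],
               ignore_attr = TRUE, tolerance = 1e-12)
  # [a, a] -> 2 va, against one-token-at-a-time accumulation
  v2 <- embed_molecule(model, c(toks[1], toks[1]))
  expect_equal(v2, 2 * model$vectors[1, ], ignore_attr = TRUE,
               tolerance = 1e-12)
  # OOV tokens contribute nothing
  v3 <- embed_molecule(model, c(toks[1], "no-such-token"))
  expect_equal(v3, model$vectors[1, ], ignore_attr = TRUE, tolerance = 1e-12)
  # all-OOV sentence: zero vector with a warning
  expect_warning(v4 <- embed_molecule(model, c("nope1", "nope2")),
                 "no in-vocabulary")
  expect_identical(v4, numeric(model$hp$dim))
})

test_that("model serialisation round-trips bit-for-bit", {
  fx <- toy_model()
  dir <- withr::local_tempdir()
  save_embedding(fx$model, dir)
  expect_true(all(file.exists(file.path(dir, c("vocab.tsv", "vectors.bin",
                                               "hyperparameters.json",
                                               "model-card.txt")))))
  back <- load_embedding(dir)
  expect_identical(back$vectors, fx$model$vectors)
  expect_identical(back$vocab, fx$model$vocab)
  expect_identical(back$hp$dim, fx$model$hp$dim)
  expect_identical(back$hp$seed, fx$model$hp$seed)
})

test_that("hyperparameter validation rejects degenerate settings", {
  expect_error(embedding_hp(dim = 1), "dim", class = "triscreen_config_error")
  expect_error(embedding_hp(epochs = 0), "epochs",
               class = "triscreen_config_error")
  fx <- toy_model()
  expect_error(train_embedding(list()), "empty",
               class = "triscreen_input_error")
})
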