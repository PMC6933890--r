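make_params <- function(config) {
  vocab <- list(words = c("mother", "<UNK>"), chars = c(letters, "<UNK>"),
                pos = c(default_pos_backend()$tagset, "<UNK>"),
                cuis = c("NONE", "<UNK>"))
  set.seed(config$seed)
  famhx:::init_params(vocab, 5L, config)
}

test_that("the character CNN yields fixed-length deterministic vectors", {
  cfg <- small_labeler_config(epochs = 1, seed = 2)
  params <- make_params(cfg)
  enc <- function(w) match(strsplit(w, "")[[1]], c(letters, "<UNK>"))
  r1 <- famhx:::nn_char_repr_cpp(params, enc("a"), 0, FALSE, 1)
  r2 <- famhx:::nn_char_repr_cpp(params, enc("grandmother"), 0, FALSE, 1)
  expect_length(r1, cfg$char_filters)
  expect_length(r2, cfg$char_filters)
  # evaluation mode is deterministic under fixed weights
  expect_identical(r2, famhx:::nn_char_repr_cpp(params, enc("grandmother"),
                                                0.5, FALSE, 99))
  # empty word maps to the zero vector
  expect_equal(as.numeric(famhx:::nn_char_repr_cpp(params, integer(), 0,
                                                   FALSE, 1)),
               rep(0, cfg$char_filters))
})

test_that("the published dimensions concatenate to a 471-long input vector", {
  cfg <- labeler_config(seed = 1)
  expect_equal(cfg$word_dim + cfg$char_filters + cfg$pos_dim + 1 + cfg$cui_dim,
               471)
  params <- make_params(cfg)
  expect_equal(ncol(params$Wf), 471)  # the LSTM consumes the concatenation
  expect_equal(ncol(params$Wb), 471)
})

test_that("training reduces the loss, is seed-deterministic and serializable", {
  fx <- synthetic_sentences(8, 101)
  cfg <- small_labeler_config(epochs = 8, seed = 5)
  m1 <- train_labeler(fx$sentences, fx$scheme, cfg)
  expect_lt(utils::tail(m1$loss_log$mean_loss, 1), m1$loss_log$mean_loss[1])
  # same seed, same loss curve
  m2 <- train_labeler(fx$sentences, fx$scheme, cfg)
  expect_identical(m1$loss_log, m2$loss_log)
  # save -> load -> predict equals predict before save
  p1 <- predict_labeler(m1, fx$sentences)
  path <- withr::local_tempfile()
  save_labeler(m1, path)
  m3 <- load_labeler(path)
  expect_identical(predict_labeler(m3, fx$sentences), p1)
  # predictions come from the scheme inventory and are IOB2-valid
  expect_true(all(unlist(p1) %in% fx$scheme$labels))
  for (lab in p1) expect_true(iob2_valid(lab))
  expect_identical(predict_labeler(m1, list()), list())
  expect_error(train_labeler(list(), fx$scheme, cfg), "empty")
})

test_that("a sufficiently trained model memorizes a small corpus", {
  # overfit sanity run: dropout off so the network can interpolate
  fx <- synthetic_sentences(10, 103, scheme = standard_scheme())
  cfg <- labeler_config(word_dim = 24, char_dim = 12, char_filters = 12,
                        pos_dim = 8, cui_dim = 8, hidden_dim = 24,
                        epochs = 100, dropout = 0, seed = 6)
  model <- train_labeler(fx$sentences, standard_scheme(), cfg)
  pred <- predict_labeler(model, fx$sentences)
  gold <- lapply(fx$sentences, `[[`, "labels")
  expect_gte(token_f1(pred, gold), 0.95)
})

test_that("pre-trained word vectors seed the embedding table", {
  fx <- synthetic_sentences(4, 104)
  cfg <- small_labeler_config(epochs = 1, seed = 7)
  emb <- matrix(0.5, 2, cfg$word_dim,
                dimnames = list(c("mother", "diabetes"), NULL))
  model <- train_labeler(fx$sentences, fx$scheme, cfg, word_embeddings = emb)
  expect_true("mother" %in% model$vocab$words)
  # rows were seeded before training; after one epoch they moved only slightly
  i <- match("mother", model$vocab$words)
  expect_lt(max(abs(model$params$Ew[i, ] - 0.5)), 0.3)
})

test_that("the classical CRF baseline fits a separable corpus exactly", {
  fx <- synthetic_sentences(10, 105, scheme = standard_scheme())
  bl <- train_crf_baseline(fx$sentences, standard_scheme(), epochs = 15,
                           seed = 8)
  pred <- predict_labeler(bl, fx$sentences)
  gold <- lapply(fx$sentences, `[[`, "labels")
  expect_equal(mean(unlist(pred) == unlist(gold)), 1)
  # same scheme machinery and output structure as the neural model
  side_fx <- synthetic_sentences(6, 106)
  bl2 <- train_crf_baseline(side_fx$sentences, side_fx$scheme, epochs = 5,
                            seed = 8)
  p2 <- predict_labeler(bl2, side_fx$sentences)
  expect_type(p2, "list")
  expect_true(all(unlist(p2) %in% side_fx$scheme$labels))
  for (lab in p2) expect_true(iob2_valid(lab))
})
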