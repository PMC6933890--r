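test_that("the F1 formula reproduces hand-checked values", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(0.5, 1), 2 / 3)
  # harmonic-mean identity on a grid
  p <- seq(0.05, 1, by = 0.05)
  r <- rev(p)
  expect_equal(f1_score(p, r), 2 * p * r / (p + r))
})

test_that("partial observation matching honors the four-token budget", {
  expect_true(match_observation("diabetes", "type 2 diabetes"))
  expect_true(match_observation("type 2 diabetes", "type 2 diabetes"))
  expect_false(match_observation("asthma",
                                 "late onset pelvic cancer heart disease"))
  # budget arithmetic: shared run of 1, leftovers on both sides
  expect_true(match_observation("severe heart problems",
                                "heart disease history"))   # 2 + 2 leftovers
  expect_false(match_observation("severe acute heart problems",
                                 "heart disease history x")) # 3 + 3 leftovers
  # containment always matches
  expect_true(match_observation("cancer",
                                "late onset pelvic cancer of some kind"))
  # gold-side-only counting is more permissive
  expect_true(match_observation("severe acute heart problems",
                                "heart disease history x",
                                count_sides = "gold"))
  # punctuation and case are ignored
  expect_true(match_observation("Heart disease.", "heart disease"))
  # symmetry under the default both-sides counting
  set.seed(20)
  vocab <- c("type", "2", "diabetes", "heart", "disease", "cancer", "late")
  for (i in 1:50) {
    a <- paste(sample(vocab, sample(1:5, 1), replace = TRUE), collapse = " ")
    b <- paste(sample(vocab, sample(1:5, 1), replace = TRUE), collapse = " ")
    expect_identical(match_observation(a, b), match_observation(b, a))
  }
})

test_that("document aggregation deduplicates records", {
  docs <- data.frame(doc_id = "d",
                     text = "His mother is sick. His mother has diabetes.",
                     stringsAsFactors = FALSE)
  tokens <- preprocess_documents(docs)
  mentions <- data.frame(
    doc_id = "d", sent_index = c(1L, 2L, 2L),
    first = c(2L, 2L, 4L), last = c(2L, 2L, 4L),
    etype = c("FamilyMember", "FamilyMember", "Observation"),
    fm = c("Mother", "Mother", NA), sf = c("NA", "NA", NA),
    stringsAsFactors = FALSE)
  agg <- aggregate_document(mentions, tokens)
  expect_equal(nrow(agg), 2)  # two (Mother, NA) mentions collapse to one
  expect_equal(agg$obs_text[agg$type == "Observation"], "diabetes")
  # distinct sides stay distinct
  m2 <- mentions[1:2, ]
  m2$sf <- c("Maternal", "Paternal")
  m2$fm <- "Cousin"
  expect_equal(nrow(aggregate_document(m2, tokens)), 2)
  expect_equal(nrow(aggregate_document(mentions[0, ], tokens)), 0)
})

test_that("scoring counts exact family pairs and partial observations", {
  gold <- data.frame(
    doc_id = c("a", "a", "b"),
    type = c("FamilyMember", "Observation", "FamilyMember"),
    fm = c("Cousin", NA, "Mother"), sf = c("Maternal", NA, "NA"),
    obs_text = c(NA, "type 2 diabetes", NA), stringsAsFactors = FALSE)
  # perfect predictions
  perfect <- score_predictions(gold, gold)
  expect_equal(perfect["Overall", "f1"], 1)
  expect_equal(perfect["Overall", "precision"], 1)
  # wrong side: one FP and one FN
  wrong <- gold
  wrong$sf[1] <- "Paternal"
  r <- score_predictions(wrong, gold)
  expect_equal(r["FamilyMember", "fp"], 1)
  expect_equal(r["FamilyMember", "fn"], 1)
  # partial observation still a TP
  part <- gold
  part$obs_text[2] <- "diabetes"
  expect_equal(score_predictions(part, gold)["Observation", "f1"], 1)
  # unknown doc_id in predictions: all its records are FPs
  extra <- rbind(gold, data.frame(doc_id = "zz", type = "FamilyMember",
                                  fm = "Aunt", sf = "NA", obs_text = NA))
  r2 <- score_predictions(extra, gold)
  expect_equal(r2["FamilyMember", "fp"], 1)
})

test_that("score conservation and document-order invariance hold", {
  set.seed(21)
  fams <- family_base_names()$name
  mk_list <- function(n) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      d <- sample(c("a", "b", "c"), 1)
      if (runif(1) < 0.5) {
        data.frame(doc_id = d, type = "FamilyMember",
                   fm = sample(fams, 1),
                   sf = sample(c("NA", "Maternal", "Paternal"), 1),
                   obs_text = NA_character_, stringsAsFactors = FALSE)
      } else {
        data.frame(doc_id = d, type = "Observation", fm = NA_character_,
                   sf = NA_character_,
                   obs_text = paste(sample(c("heart", "disease", "cancer",
                                             "type", "2"),
                                           sample(1:3, 1), replace = TRUE),
                                    collapse = " "),
                   stringsAsFactors = FALSE)
      }
    }))
  }
  for (i in 1:10) {
    pred <- unique(mk_list(8))
    gold <- unique(mk_list(8))
    r <- score_predictions(pred, gold)
    expect_equal(r["FamilyMember", "tp"] + r["FamilyMember", "fn"],
                 sum(gold$type == "FamilyMember"))
    expect_equal(r["Observation", "tp"] + r["Observation", "fp"],
                 sum(pred$type == "Observation"))
    expect_equal(r["Overall", "tp"] + r["Overall", "fp"], nrow(pred))
    # reordering documents (keeping within-document record order, which the
    # greedy observation matcher honors) does not change the report
    blocks <- lapply(sample(unique(pred$doc_id)),
                     function(d) pred[pred$doc_id == d, , drop = FALSE])
    shuffled <- do.call(rbind, blocks)
    expect_equal(as.data.frame(score_predictions(shuffled, gold)),
                 as.data.frame(r))
  }
})

test_that("token and entity F1 agree with hand-counted examples", {
  gold <- list(c("B-FM", "O", "B-Ob", "I-Ob"))
  pred <- list(c("B-FM", "O", "B-Ob", "O"))
  # tokens: tp 2, fp 0, fn 1 -> P 1, R 2/3
  expect_equal(token_f1(pred, gold), f1_score(1, 2 / 3))
  # entities: the truncated observation span no longer matches
  expect_equal(entity_f1(pred, gold, standard_scheme()), 0.5)
  expect_equal(entity_f1(gold, gold, standard_scheme()), 1)
})
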