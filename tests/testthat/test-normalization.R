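lex <- load_family_lexicon()

test_that("the lexicon covers exactly the normalized vocabulary", {
  expect_equal(nrow(lex$base_names), 15)
  expect_setequal(lex$base_names$name[lex$base_names$degree == 1],
                  c("Father", "Mother", "Parent", "Sister", "Brother",
                    "Daughter", "Son", "Child"))
  expect_true(all(lex$variants %in% lex$base_names$name))
  expect_equal(unname(lex$side_terms[c("maternal", "paternal")]),
               c("Maternal", "Paternal"))
})

test_that("mention normalization maps variants, plurals and modifiers", {
  expect_equal(normalize_fm("mom", lexicon = lex), "Mother")
  expect_equal(normalize_fm("mommy", lexicon = lex), "Mother")
  expect_equal(normalize_fm("sisters", lexicon = lex), "Sister")
  expect_equal(normalize_fm(c("older", "brother"), lexicon = lex), "Brother")
  expect_equal(normalize_fm("children", lexicon = lex), "Child")
  expect_equal(normalize_fm("grandpa", lexicon = lex), "Grandfather")
  # adjective-tagged tokens are removed before matching
  expect_equal(normalize_fm(c("maternal", "aunt"), pos = c("JJ", "NN"),
                            lexicon = lex), "Aunt")
  expect_equal(normalize_fm("gentleman", lexicon = lex), "UNRESOLVED")
  expect_error(normalize_fm(character(), lexicon = lex), "empty")
})

test_that("normalization is case-insensitive and fixes base names", {
  for (nm in family_base_names()$name) {
    expect_equal(normalize_fm(nm, lexicon = lex), nm)
    expect_equal(normalize_fm(toupper(nm), lexicon = lex), nm)
  }
})

test_that("side priors count training occurrences exactly", {
  ann <- data.frame(
    etype = c(rep("FamilyMember", 6), "Observation"),
    fm = c("Cousin", "Cousin", "Cousin", "Cousin", "Mother", "Mother", NA),
    sf = c("Maternal", "Maternal", "Maternal", "NA", "NA", "NA", NA),
    stringsAsFactors = FALSE)
  prior <- build_side_prior(ann)
  expect_equal(prior$Cousin, c("NA" = 1, Maternal = 3, Paternal = 0))
  expect_equal(sum(prior$Mother), sum(ann$fm == "Mother", na.rm = TRUE))
  empty <- build_side_prior(ann[0, ])
  expect_true(all(vapply(empty, sum, numeric(1)) == 0))
})

test_that("side resolution prefers the lookbehind term over the prior", {
  prior <- build_side_prior(data.frame(
    etype = "FamilyMember", fm = rep("Cousin", 4),
    sf = c("Maternal", "Maternal", "Maternal", "NA"), stringsAsFactors = FALSE))
  # no preceding side term: modal value from the prior
  expect_equal(resolve_sf("Cousin", c("a"), prior, lex), "Maternal")
  # explicit side term overrides any prior
  expect_equal(resolve_sf("Aunt", c("a", "maternal"), prior, lex), "Maternal")
  expect_equal(resolve_sf("Cousin", c("his", "paternal"), prior, lex), "Paternal")
  # term outside the window does not fire
  expect_equal(resolve_sf("Cousin", c("paternal", "x", "y"), prior, lex),
               "Maternal")
  # ties and empty priors fall back to NA
  expect_equal(resolve_sf("Uncle", character(), prior, lex), "NA")
  expect_equal(resolve_sf("UNRESOLVED", character(), prior, lex), "NA")
})

test_that("property finalization composes rules per scheme", {
  docs <- data.frame(doc_id = "d", text = "His maternal cousin has asthma.",
                     stringsAsFactors = FALSE)
  tokens <- preprocess_documents(docs)
  prior <- build_side_prior(data.frame(
    etype = "FamilyMember", fm = "Cousin", sf = "Maternal",
    stringsAsFactors = FALSE))
  base <- data.frame(doc_id = "d", sent_index = 1L, first = 3L, last = 3L,
                     etype = "FamilyMember", fm = NA_character_,
                     sf = NA_character_, stringsAsFactors = FALSE)
  # standard: both properties from rules (lookbehind sees "maternal")
  std <- finalize_properties(base, "standard", tokens, prior, lex)
  expect_equal(std$fm, "Cousin")
  expect_equal(std$sf, "Maternal")
  # side: name from rules, side from tag
  side <- base
  side$sf <- "Paternal"
  out <- finalize_properties(side, "side", tokens, prior, lex)
  expect_equal(out$fm, "Cousin")
  expect_equal(out$sf, "Paternal")
  # relation-side: both from the tag, rules not invoked
  rel <- base
  rel$fm <- "Aunt"
  rel$sf <- "Paternal"
  out2 <- finalize_properties(rel, "relation_side", tokens, prior, lex)
  expect_equal(out2[, c("fm", "sf")], data.frame(fm = "Aunt", sf = "Paternal"),
               ignore_attr = TRUE)
  # unresolvable member mentions are dropped with a warning
  ghost <- base
  ghost$first <- ghost$last <- 4L  # "has"
  expect_warning(out3 <- finalize_properties(ghost, "standard", tokens, prior,
                                             lex), "dropped")
  expect_equal(nrow(out3), 0)
})

test_that("first-degree relatives never receive a side", {
  docs <- data.frame(doc_id = "d", text = "His maternal mother has asthma.",
                     stringsAsFactors = FALSE)
  tokens <- preprocess_documents(docs)
  m <- data.frame(doc_id = "d", sent_index = 1L, first = 3L, last = 3L,
                  etype = "FamilyMember", fm = NA_character_,
                  sf = "Maternal", stringsAsFactors = FALSE)
  out <- finalize_properties(m, "side", tokens, NULL, lex)
  expect_equal(out$fm, "Mother")
  expect_equal(out$sf, "NA")
})
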