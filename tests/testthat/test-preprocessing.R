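test_that("sentence splitting respects clinical abbreviations", {
  t1 <- "His mother has diabetes. His father is healthy."
  s1 <- split_sentences(t1)
  expect_equal(nrow(s1), 2)
  expect_equal(substr(t1, s1$start[2] + 1, s1$end[2]), "His father is healthy.")

  t2 <- "Mrs. Manuela reports a maternal aunt had a child with heart disease."
  expect_equal(nrow(split_sentences(t2)), 1)

  expect_equal(nrow(split_sentences("")), 0)
  expect_equal(nrow(split_sentences("Dr. Smith saw him at 3.5 yrs. of age.")), 1)
})

test_that("tokenization splits punctuation but keeps hyphenated expressions", {
  expect_equal(tokenize("type 2 diabetes")$surface, c("type", "2", "diabetes"))
  expect_equal(tokenize("cousin.")$surface, c("cousin", "."))
  tk <- tokenize("35-year-old gentleman,")
  expect_equal(tk$surface, c("35-year-old", "gentleman", ","))
  # offsets reconstruct the input exactly
  txt <- "A 35-year-old gentleman, otherwise healthy."
  tk2 <- tokenize(txt)
  for (i in seq_len(nrow(tk2))) {
    expect_equal(substr(txt, tk2$start[i] + 1, tk2$end[i]), tk2$surface[i])
  }
})

test_that("numeric normalization reduces digit runs and is idempotent", {
  expect_equal(normalize_numeric("35-year-old"), "0-year-old")
  expect_equal(normalize_numeric("89"), "0")
  expect_equal(normalize_numeric("mother"), "mother")
  expect_equal(normalize_numeric("2018"), "0")
  expect_equal(normalize_numeric("0-yr"), "0-yr")
  x <- c("35-year-old", "89", "mother", "b12", "3.5")
  expect_equal(normalize_numeric(normalize_numeric(x)), normalize_numeric(x))
  expect_equal(normalize_numeric("35-year-old", mode = "whole_token"), "0")
})

test_that("PoS tagging returns one closed-inventory tag per token", {
  be <- default_pos_backend()
  tags <- pos_tag(c("His", "mother", "has", "diabetes"), be)
  expect_length(tags, 4)
  expect_true(all(tags %in% be$tagset))
  expect_equal(pos_tag("maternal", be), "JJ")
  expect_equal(pos_tag(character(), be), character())
  expect_error(pos_tag("x", backend = NULL), "backend")
})

test_that("tokens reconstruct each document (detokenization property)", {
  docs <- tiny_documents()
  tokens <- preprocess_documents(docs)
  for (d in docs$doc_id) {
    txt <- docs$text[docs$doc_id == d]
    tk <- tokens[tokens$doc_id == d, ]
    rebuilt <- ""
    cursor <- 0L
    for (i in seq_len(nrow(tk))) {
      rebuilt <- paste0(rebuilt, substr(txt, cursor + 1, tk$start[i]),
                        tk$surface[i])
      cursor <- tk$end[i]
    }
    rebuilt <- paste0(rebuilt, substr(txt, cursor + 1, nchar(txt)))
    expect_equal(rebuilt, txt)
  }
})

test_that("annotations align to whole-token runs", {
  docs <- tiny_documents()
  ann <- validate_annotations(tiny_annotations(), docs)
  tokens <- preprocess_documents(docs, ann)
  m <- align_annotations(tokens, ann)
  expect_equal(nrow(m), 4)
  expect_null(attr(m, "rejected"))
  # "heart disease" covers a run of two tokens
  hd <- m[m$doc_id == "doc2" & m$etype == "Observation", ]
  expect_equal(hd$last - hd$first + 1L, 2L)
  # sentence counts preserved: alignment adds no/removes no sentences
  expect_equal(length(unique(paste(tokens$doc_id, tokens$sent_index))), 3)

  # a span ending inside a token snaps outward with a warning
  part <- data.frame(doc_id = "doc1", start = 4L, end = 9L,
                     etype = "FamilyMember", fm = "Mother", sf = "NA",
                     stringsAsFactors = FALSE)
  expect_warning(m2 <- align_annotations(tokens, part), "snapping")
  tk <- tokens[tokens$doc_id == "doc1" & tokens$sent_index == m2$sent_index[1], ]
  expect_equal(tk$surface[m2$first[1]], "mother")
})

test_that("annotations crossing a sentence boundary trigger merge repair", {
  docs <- data.frame(doc_id = "d", text = "He has type 2. Diabetes runs deep.",
                     stringsAsFactors = FALSE)
  ann <- data.frame(doc_id = "d", start = 7L, end = 23L, etype = "Observation",
                    fm = "", sf = "", stringsAsFactors = FALSE)
  ann <- validate_annotations(ann, docs)
  expect_equal(ann$text, "type 2. Diabetes")
  expect_warning(tokens <- preprocess_documents(docs, ann), "merging")
  expect_equal(length(unique(tokens$sent_index[tokens$doc_id == "d"])), 1)
  m <- align_annotations(tokens, ann)
  expect_equal(nrow(m), 1)
})

test_that("CoNLL dumps contain one token per line with sentence breaks", {
  docs <- tiny_documents()
  tokens <- preprocess_documents(docs)
  path <- withr::local_tempfile()
  write_conll(tokens, NULL, path)
  lines <- readLines(path)
  body <- lines[nzchar(lines)]
  expect_length(body, nrow(tokens))
  expect_equal(sum(!nzchar(lines)), 3)  # one blank per sentence
  expect_match(body[1], "^His\tHis\t[A-Z$]+\tO$")
})
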