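# Shared fixtures and independent oracles, all built in code.

# --- tiny documents ---------------------------------------------------------

tiny_documents <- function() {
  data.frame(
    doc_id = c("doc1", "doc2"),
    text = c("His mother has diabetes. His father is healthy.",
             "Mrs. Manuela reports a maternal aunt had a child with heart disease."),
    stringsAsFactors = FALSE)
}

tiny_annotations <- function() {
  data.frame(
    doc_id = c("doc1", "doc1", "doc2", "doc2"),
    start = c(4L, 15L, 32L, 54L),
    end = c(10L, 23L, 36L, 67L),
    etype = c("FamilyMember", "Observation", "FamilyMember", "Observation"),
    fm = c("Mother", "", "Aunt", ""),
    sf = c("NA", "", "Maternal", ""),
    stringsAsFactors = FALSE)
}

write_tiny_corpus <- function(dir) {
  notes <- file.path(dir, "notes")
  dir.create(notes, recursive = TRUE, showWarnings = FALSE)
  docs <- tiny_documents()
  for (i in seq_len(nrow(docs))) {
    writeLines(docs$text[i], file.path(notes, paste0(docs$doc_id[i], ".txt")))
  }
  ann_path <- file.path(dir, "annotations.tsv")
  write_annotations(tiny_annotations(), ann_path)
  list(notes = notes, annotations = ann_path)
}

# --- brute-force linear-chain CRF oracle ------------------------------------

# All L^n label paths of length n.
all_paths <- function(n, L) {
  if (n == 0) return(matrix(integer(), 0, 0))
  as.matrix(expand.grid(rep(list(seq_len(L)), n)))
}

brute_path_score <- function(em, trans, start, stop, path) {
  n <- length(path)
  s <- start[path[1]] + em[1, path[1]]
  if (n > 1) {
    for (t in 2:n) s <- s + trans[path[t - 1], path[t]] + em[t, path[t]]
  }
  s + stop[path[n]]
}

brute_log_partition <- function(em, trans, start, stop) {
  paths <- all_paths(nrow(em), ncol(em))
  scores <- apply(paths, 1, function(p) brute_path_score(em, trans, start, stop, p))
  m <- max(scores)
  m + log(sum(exp(scores - m)))
}

brute_viterbi_score <- function(em, trans, start, stop) {
  paths <- all_paths(nrow(em), ncol(em))
  max(apply(paths, 1, function(p) brute_path_score(em, trans, start, stop, p)))
}

random_crf_instance <- function(n, L) {
  list(em = matrix(rnorm(n * L), n, L),
       trans = matrix(rnorm(L * L), L, L),
       start = rnorm(L), stop = rnorm(L))
}

# --- random mention sets for round-trip properties --------------------------

random_mention_set <- function(n_tokens) {
  base <- family_base_names()
  rows <- list()
  pos <- 1L
  while (pos <= n_tokens) {
    len <- sample(1:2, 1)
    if (pos + len - 1L > n_tokens) break
    if (runif(1) < 0.4) {  # gap
      pos <- pos + len
      next
    }
    if (runif(1) < 0.5) {
      nm <- base$name[sample.int(nrow(base), 1)]
      sf <- if (base$degree[match(nm, base$name)] == 1) "NA" else
        sample(c("NA", "Maternal", "Paternal"), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        first = pos, last = pos + len - 1L, etype = "FamilyMember",
        fm = nm, sf = sf, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        first = pos, last = pos + len - 1L, etype = "Observation",
        fm = NA_character_, sf = NA_character_, stringsAsFactors = FALSE)
    }
    pos <- pos + len
  }
  if (!length(rows)) {
    return(data.frame(first = integer(), last = integer(), etype = character(),
                      fm = character(), sf = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# --- small training fixtures -------------------------------------------------

synthetic_sentences <- function(n_documents, corpus_seed, scheme = NULL) {
  corpus <- generate_corpus(default_generator_config(n_documents = n_documents,
                                                     seed = corpus_seed))
  tokens <- preprocess_documents(corpus$documents, corpus$annotations)
  mentions <- align_annotations(tokens, corpus$annotations)
  if (is.null(scheme)) scheme <- build_side_scheme(mentions)
  list(corpus = corpus, tokens = tokens, mentions = mentions, scheme = scheme,
       sentences = prepare_labeled_sentences(tokens, mentions, scheme))
}

small_labeler_config <- function(epochs, seed, inference = "crf") {
  labeler_config(word_dim = 24, char_dim = 12, char_filters = 12, pos_dim = 8,
                 cui_dim = 8, hidden_dim = 24, epochs = epochs,
                 inference = inference, seed = seed)
}
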