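#' Default synthetic-corpus generator configuration
#'
#' Emulates the statistical structure of a family-history section corpus:
#' most mentions are first-degree relatives (which never carry a
#' maternal/paternal side), extended-family members carry a mixed side
#' distribution with Maternal modal for Cousin, observation phrases are 1-5
#' tokens with some numeric tokens, and a fraction of sentences contain no
#' entities at all. About 60% of non-NA sides are textually realized as a
#' `maternal`/`paternal` term before the mention, so side resolution must
#' exercise both the lookbehind rule and the majority-prior fallback.
#'
#' @param n_documents Number of notes to generate.
#' @param sentences_per_document Inclusive range (length-2 integer vector).
#' @param seed Integer seed; generation is byte-identical for a fixed seed.
#' @param hard_mode Also emit kin-of-kin constructions (`"her father's
#'   brother"` annotated as a paternal uncle), which the recognizer is not
#'   expected to resolve; off by default.
#' @return A list of class `fhx_generator_config`.
#' @export
default_generator_config <- function(n_documents = 40,
                                     sentences_per_document = c(3L, 8L),
                                     seed = 1L, hard_mode = FALSE) {
  family_distribution <- c(
    Mother = 0.15, Father = 0.14, Sister = 0.11, Brother = 0.11,
    Daughter = 0.08, Son = 0.08, Child = 0.04, Parent = 0.01,
    Grandmother = 0.04, Grandfather = 0.04, Grandparent = 0.015,
    Aunt = 0.055, Uncle = 0.055, Cousin = 0.05, Sibling = 0.025)
  second <- list(
    Grandmother = c("NA" = 0.10, Maternal = 0.75, Paternal = 0.15),
    Grandfather = c("NA" = 0.10, Maternal = 0.15, Paternal = 0.75),
    Grandparent = c("NA" = 0.70, Maternal = 0.15, Paternal = 0.15),
    Cousin      = c("NA" = 0.10, Maternal = 0.80, Paternal = 0.10),
    Sibling     = c("NA" = 0.80, Maternal = 0.10, Paternal = 0.10),
    Aunt        = c("NA" = 0.10, Maternal = 0.15, Paternal = 0.75),
    Uncle       = c("NA" = 0.10, Maternal = 0.75, Paternal = 0.15))
  first <- family_base_names()$name[family_base_names()$degree == 1]
  side_distribution <- c(
    setNames(lapply(first, function(n) c("NA" = 1, Maternal = 0, Paternal = 0)),
             first),
    second)
  cfg <- list(
    n_documents = n_documents,
    sentences_per_document = as.integer(sentences_per_document),
    family_distribution = family_distribution,
    side_distribution = side_distribution,
    observation_vocabulary = c(
      "diabetes", "type 2 diabetes", "heart disease", "asthma",
      "high blood pressure", "breast cancer", "colon cancer", "stroke",
      "depression", "hypertension", "coronary artery disease",
      "late onset pelvic cancer", "congenital heart disease",
      "myocardial infarction", "skin cancer", "alcohol abuse",
      "unspecified background retinopathy", "liver cancer", "schizophrenia",
      "cystic fibrosis"),
    p_side_term_explicit = 0.6,
    p_variant = 0.2,
    p_plural = 0.15,
    p_modifier = 0.2,
    p_empty_sentence = 0.25,
    hard_mode = hard_mode,
    seed = as.integer(seed))
  class(cfg) <- "fhx_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (abs(sum(cfg$family_distribution) - 1) > 1e-9) {
    stop("family_distribution must sum to 1")
  }
  for (nm in names(cfg$side_distribution)) {
    if (abs(sum(cfg$side_distribution[[nm]]) - 1) > 1e-9) {
      stop("side_distribution for ", nm, " must sum to 1")
    }
  }
  first <- family_base_names()$name[family_base_names()$degree == 1]
  for (nm in intersect(first, names(cfg$side_distribution))) {
    if (cfg$side_distribution[[nm]][["NA"]] != 1) {
      stop("first-degree relative ", nm, " must have side NA")
    }
  }
  probs <- c(cfg$p_side_term_explicit, cfg$p_variant, cfg$p_plural,
             cfg$p_modifier, cfg$p_empty_sentence)
  stopifnot(all(probs >= 0 & probs <= 1))
  invisible(cfg)
}

# Surface variants the generator may use in place of the base name.
generator_variants <- list(
  Mother = c("mom", "mommy"), Father = c("dad", "daddy"),
  Grandmother = c("grandma"), Grandfather = c("grandpa"),
  Aunt = c("auntie"), Child = c("kid"))

#' Generate a synthetic annotated family-history corpus
#'
#' Assembles notes from templated sentences ("His maternal aunt has heart
#' disease.", "The patient's brother died at age 62 of a stroke.", plus
#' entity-free filler), emitting a gold standoff annotation with exact
#' character offsets, the normalized name and the side attribute for every
#' generated mention. Surface variants, plurals, modifiers and numeric
#' tokens are injected at the configured rates so that normalization,
#' adjective removal and digit reduction are all exercised.
#'
#' @param config A generator configuration; see [default_generator_config()].
#' @return A list with `documents` and `annotations` data frames in the
#'   corpus-io formats, plus `mentions_gold` (the sampled `(fm, sf)` pairs,
#'   one row per generated mention).
#' @export
generate_corpus <- function(config = default_generator_config()) {
  validate_generator_config(config)
  set.seed(config$seed)
  docs <- list()
  anns <- list()
  truth <- list()
  fillers <- c(
    "The remainder of the family history was reviewed in detail .",
    "No further information was provided at this visit .",
    "The patient works as a teacher and lives locally .",
    "There were no other significant findings reported today .",
    "Records from the outside clinic were requested for review .")
  for (d in seq_len(config$n_documents)) {
    doc_id <- sprintf("note%03d", d)
    n_sent <- sample(seq(config$sentences_per_document[1],
                         config$sentences_per_document[2]), 1)
    text <- ""
    for (s in seq_len(n_sent)) {
      if (nzchar(text)) text <- paste0(text, " ")
      if (runif(1) < config$p_empty_sentence) {
        words <- strsplit(sample(fillers, 1), " ", fixed = TRUE)[[1]]
        text <- append_words(text, words)$text
        next
      }
      built <- build_entity_sentence(text, doc_id, config)
      text <- built$text
      anns <- c(anns, built$anns)
      truth <- c(truth, built$truth)
    }
    docs[[d]] <- data.frame(doc_id = doc_id, text = text,
                            stringsAsFactors = FALSE)
  }
  documents <- do.call(rbind, docs)
  annotations <- do.call(rbind, anns)
  rownames(annotations) <- NULL
  annotations <- validate_annotations(annotations, documents)
  list(documents = documents, annotations = annotations,
       mentions_gold = do.call(rbind, truth))
}

# Append space-separated words to a buffer; returns the new buffer plus the
# start/end offsets of each word.
append_words <- function(text, words) {
  starts <- integer(length(words))
  ends <- integer(length(words))
  for (i in seq_along(words)) {
    if (nzchar(text) && !grepl("\\s$", text)) text <- paste0(text, " ")
    starts[i] <- nchar(text)
    text <- paste0(text, words[i])
    ends[i] <- nchar(text)
  }
  list(text = text, starts = starts, ends = ends)
}

sample_member <- function(config) {
  fm <- sample(names(config$family_distribution), 1,
               prob = config$family_distribution)
  sf <- sample(names(config$side_distribution[[fm]]), 1,
               prob = config$side_distribution[[fm]])
  surface <- tolower(fm)
  plural <- FALSE
  if (!is.null(generator_variants[[fm]]) && runif(1) < config$p_variant) {
    surface <- sample(generator_variants[[fm]], 1)
  } else if (runif(1) < config$p_plural) {
    surface <- if (fm == "Child") "children" else paste0(surface, "s")
    plural <- TRUE
  }
  prefix <- character()
  if (sf != "NA" && runif(1) < config$p_side_term_explicit) {
    prefix <- c(prefix, tolower(sf))
  }
  if (runif(1) < config$p_modifier) {
    prefix <- c(prefix, sample(c("older", "younger", "twin"), 1))
  }
  list(fm = fm, sf = sf, surface = surface, prefix = prefix, plural = plural)
}

build_entity_sentence <- function(text, doc_id, config) {
  anns <- list()
  truth <- list()
  obs <- sample(config$observation_vocabulary, 1)
  obs_words <- strsplit(obs, " ", fixed = TRUE)[[1]]
  m <- sample_member(config)
  age <- as.character(sample(20:95, 1))
  templates <- c("has", "died", "diagnosed", "with", "healthy")
  if (isTRUE(config$hard_mode)) templates <- c(templates, "kin_of_kin")
  tpl <- sample(templates, 1)
  poss <- sample(c("His", "Her"), 1)

  emit_member <- function(state, mm) {
    state <- append_words(state$text, mm$prefix)
    st <- append_words(state$text, mm$surface)
    list(text = st$text, start = st$starts[1], end = st$ends[1])
  }
  emit_obs <- function(text) {
    st <- append_words(text, obs_words)
    list(text = st$text, start = st$starts[1], end = st$ends[length(obs_words)])
  }
  add_fam <- function(mm, span) {
    anns[[length(anns) + 1L]] <<- data.frame(
      doc_id = doc_id, start = span$start, end = span$end,
      etype = "FamilyMember", fm = mm$fm, sf = mm$sf, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      fm = mm$fm, sf = mm$sf, stringsAsFactors = FALSE)
  }
  add_obs <- function(span) {
    anns[[length(anns) + 1L]] <<- data.frame(
      doc_id = doc_id, start = span$start, end = span$end,
      etype = "Observation", fm = "", sf = "", stringsAsFactors = FALSE)
  }

  if (tpl == "has") {
    state <- append_words(text, poss)
    span <- emit_member(list(text = state$text), m)
    add_fam(m, span)
    verb <- if (m$plural) "have" else "has"
    state <- append_words(span$text, verb)
    ospan <- emit_obs(state$text)
    add_obs(ospan)
    text <- append_words(ospan$text, ".")$text
  } else if (tpl == "died") {
    state <- append_words(text, c("The", "patient's"))
    span <- emit_member(list(text = state$text), m)
    add_fam(m, span)
    state <- append_words(span$text, c("died", "at", "age", age, "of"))
    ospan <- emit_obs(state$text)
    add_obs(ospan)
    text <- append_words(ospan$text, ".")$text
  } else if (tpl == "diagnosed") {
    state <- append_words(text, poss)
    span <- emit_member(list(text = state$text), m)
    add_fam(m, span)
    state <- append_words(span$text, c("was", "diagnosed", "with"))
    ospan <- emit_obs(state$text)
    add_obs(ospan)
    state <- append_words(ospan$text, c("at", "age", age, "."))
    text <- state$text
  } else if (tpl == "with") {
    state <- append_words(text, c("The", "patient", "has", "a"))
    span <- emit_member(list(text = state$text), m)
    add_fam(m, span)
    state <- append_words(span$text, "with")
    ospan <- emit_obs(state$text)
    add_obs(ospan)
    text <- append_words(ospan$text, ".")$text
  } else if (tpl == "healthy") {
    state <- append_words(text, "A")
    span <- emit_member(list(text = state$text), m)
    add_fam(m, span)
    text <- append_words(span$text, c("is", "healthy", "."))$text
  } else {  # kin_of_kin (hard mode)
    kin <- sample(c("brother", "sister", "mother"), 1)
    kin_fm <- c(brother = "Uncle", sister = "Aunt", mother = "Grandmother")[[kin]]
    state <- append_words(text, c(poss, "father's"))
    st <- append_words(state$text, kin)
    mm <- list(fm = kin_fm, sf = "Paternal")
    add_fam(mm, list(start = st$starts[1], end = st$ends[1]))
    state <- append_words(st$text, c("had"))
    ospan <- emit_obs(state$text)
    add_obs(ospan)
    text <- append_words(ospan$text, ".")$text
  }
  list(text = text, anns = anns, truth = truth)
}
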