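#' Normalize the numeric parts of a token
#'
#' Every maximal run of digit characters collapses to the single character
#' `"0"`, so `"35-year-old"` becomes `"0-year-old"` and `"2018"` becomes
#' `"0"`. This is the form used for embedding lookup, which keeps the many
#' surface variants of ages and years from fragmenting the vocabulary. The
#' operation is idempotent. `mode = "whole_token"` instead maps any
#' digit-bearing token wholly to `"0"`.
#'
#' @param x Character vector of token surfaces.
#' @param mode `"run"` (default) or `"whole_token"`.
#' @return Character vector of normalized forms.
#' @examples
#' normalize_numeric(c("35-year-old", "89", "mother"))
#' @export
normalize_numeric <- function(x, mode = c("run", "whole_token")) {
  mode <- match.arg(mode)
  if (mode == "run") {
    gsub("[0-9]+", "0", x)
  } else {
    ifelse(grepl("[0-9]", x), "0", x)
  }
}

# Trailing-period abbreviations that must not end a sentence.
sentence_abbreviations <- function() {
  c("mr", "mrs", "ms", "dr", "prof", "st", "jr", "sr", "vs", "no",
    "yr", "yrs", "mo", "mos", "wk", "wks", "approx", "etc", "e.g", "i.e")
}

#' Split a document into sentences
#'
#' Rule-based splitter: a run of `.`, `!` or `?` followed by whitespace (or
#' end of text) ends a sentence, unless the word before the period is a
#' common clinical abbreviation (`Mrs.`, `Dr.`, `yrs.`, ...) or a single
#' initial. Deterministic by construction; no models are loaded.
#'
#' @param text Document text (newlines already normalized to `"\n"`).
#' @return A `data.frame` with columns `sent_index`, `start`, `end`
#'   (0-based, half-open character offsets of each sentence).
#' @export
split_sentences <- function(text) {
  empty <- data.frame(sent_index = integer(), start = integer(), end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  abbrev <- sentence_abbreviations()
  m <- gregexpr("[.!?]+", text)[[1]]
  boundaries <- integer()
  if (m[1] != -1) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      nxt <- if (e < nchar(text)) substr(text, e + 1L, e + 1L) else " "
      if (!grepl("\\s", nxt)) next
      # word immediately before the punctuation run
      pre <- sub(".*?([A-Za-z.]+)$", "\\1",
                 substr(text, max(1L, e - 20L), e - 1L))
      w <- tolower(sub("\\.$", "", pre))
      if (w %in% abbrev || grepl("^[A-Za-z]$", w)) next
      boundaries <- c(boundaries, e)
    }
  }
  cuts <- c(0L, boundaries, nchar(text))
  out <- list()
  k <- 0L
  for (i in seq_len(length(cuts) - 1L)) {
    s <- cuts[i]
    e <- cuts[i + 1L]
    seg <- substr(text, s + 1L, e)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s2 <- s + lead
    e2 <- e - trail
    if (e2 <= s2) next
    k <- k + 1L
    out[[k]] <- data.frame(sent_index = k, start = s2, end = e2)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Tokenize a text span
#'
#' Splits words from punctuation while keeping hyphenated and apostrophized
#' words (such as age expressions like `35-year-old`) as single tokens, so
#' that numeric normalization can act on the whole expression. Offsets are
#' exact: `substr(text, start + 1, end)` reproduces each surface.
#'
#' @param text Text to tokenize.
#' @param offset Character offset of `text` within its document (added to the
#'   reported token offsets).
#' @return A `data.frame` with columns `surface`, `start`, `end`.
#' @export
tokenize <- function(text, offset = 0L) {
  empty <- data.frame(surface = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[A-Za-z0-9]+(?:['-][A-Za-z0-9]+)*|[^A-Za-z0-9[:space:]]",
                text, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  data.frame(
    surface = substring(text, starts, starts + lens - 1L),
    start = offset + starts - 1L,
    end = offset + starts + lens - 1L,
    stringsAsFactors = FALSE
  )
}

#' Default rule-based part-of-speech backend
#'
#' A deterministic lexicon-plus-suffix tagger with a closed, MedPost-like tag
#' inventory. PoS tagging is a pluggable interface: any backend providing a
#' `tagset` and a vectorized `tag(surfaces)` function can replace it (for
#' example an adapter over an external biomedical tagger).
#'
#' @return An object of class `fhx_pos_backend`.
#' @export
default_pos_backend <- function() {
  adj <- c("maternal", "paternal", "older", "younger", "old", "young",
           "healthy", "twin", "half", "step", "late", "chronic", "congenital",
           "high", "unspecified", "elder", "eldest", "oldest", "youngest",
           "next", "previous", "unknown", "alcoholic", "dysmorphic", "severe",
           "mild", "little", "big", "first", "second", "third", "fourth",
           "full-term", "male", "female", "additional", "further", "pelvic",
           "obstructive", "coronary")
  det <- c("the", "a", "an", "this", "that", "these", "those", "no", "any",
           "some", "each", "both", "all", "several", "five")
  prp <- c("he", "she", "it", "they", "i", "we", "you", "him", "them", "who")
  prp_dollar <- c("his", "her", "their", "my", "our", "its", "your")
  vb <- c("be", "been", "have", "die", "deny", "report", "smoke", "drink",
          "work", "exercise", "develop", "diagnose", "describe", "live",
          "suffer", "pass", "carry", "review", "provide")
  vbd <- c("was", "were", "had", "died", "developed", "diagnosed", "described",
           "reported", "suffered", "passed", "revealed", "resulted", "provided",
           "reviewed")
  vbz <- c("is", "has", "denies", "reports", "smokes", "drinks", "works",
           "exercises", "lives", "describes", "carries", "are")
  inp <- c("of", "at", "in", "on", "with", "for", "from", "by", "about",
           "after", "before", "during", "through", "as")
  cc <- c("and", "or", "but", "nor")
  rb <- c("not", "also", "currently", "regularly", "never", "ever", "still")
  tag_one <- function(s) {
    lc <- tolower(s)
    if (grepl("^[^A-Za-z0-9]+$", s)) return("PUNCT")
    if (grepl("^[0-9]+$", lc)) return("CD")
    if (lc == "to") return("TO")
    if (lc %in% adj) return("JJ")
    if (grepl("^[0-9]", lc) && grepl("-", lc)) return("JJ")  # 35-year-old
    if (lc %in% det) return("DT")
    if (lc %in% prp) return("PRP")
    if (lc %in% prp_dollar) return("PRP$")
    if (lc %in% vbz) return("VBZ")
    if (lc %in% vbd) return("VBD")
    if (lc %in% vb) return("VB")
    if (lc %in% inp) return("IN")
    if (lc %in% cc) return("CC")
    if (lc %in% rb) return("RB")
    if (grepl("(al|ic|ous|ful|ive)$", lc) && nchar(lc) > 4) return("JJ")
    if (grepl("[^s]s$", lc) && nchar(lc) > 3) return("NNS")
    "NN"
  }
  structure(list(
    name = "famhx-rules",
    tagset = c("CC", "CD", "DT", "IN", "JJ", "NN", "NNS", "PRP", "PRP$",
               "PUNCT", "RB", "TO", "VB", "VBD", "VBZ"),
    tag = function(surfaces) vapply(surfaces, tag_one, character(1),
                                    USE.NAMES = FALSE)
  ), class = "fhx_pos_backend")
}

#' Tag a tokenized sentence with parts of speech
#'
#' @param surfaces Character vector of token surfaces (one sentence).
#' @param backend A PoS backend; see [default_pos_backend()].
#' @return Character vector of tags, one per token, drawn from
#'   `backend$tagset`.
#' @export
pos_tag <- function(surfaces, backend = default_pos_backend()) {
  if (is.null(backend) || !inherits(backend, "fhx_pos_backend")) {
    stop("no PoS backend registered")
  }
  if (length(surfaces) == 0) return(character())
  tags <- backend$tag(surfaces)
  stopifnot(length(tags) == length(surfaces), all(tags %in% backend$tagset))
  tags
}

#' Preprocess documents into a token table
#'
#' Runs sentence segmentation, tokenization, numeric normalization and PoS
#' tagging for each document. When gold annotations are supplied, sentence
#' boundaries falling inside an annotation are repaired by merging the two
#' sentences (with a warning), so that every annotation lies within one
#' sentence.
#'
#' @param documents Document table from [read_documents()].
#' @param annotations Optional annotation table used for boundary repair.
#' @param backend PoS backend.
#' @param numeric_mode Passed to [normalize_numeric()].
#' @return A token table: `doc_id`, `sent_index`, `tok_index`, `surface`,
#'   `norm`, `start`, `end`, `pos`.
#' @export
preprocess_documents <- function(documents, annotations = NULL,
                                 backend = default_pos_backend(),
                                 numeric_mode = "run") {
  out <- vector("list", nrow(documents))
  for (i in seq_len(nrow(documents))) {
    doc_id <- documents$doc_id[i]
    text <- documents$text[i]
    sents <- split_sentences(text)
    if (!is.null(annotations)) {
      ann <- annotations[annotations$doc_id == doc_id, , drop = FALSE]
      sents <- repair_sentence_boundaries(sents, ann, doc_id)
    }
    if (nrow(sents) == 0) next
    toks <- lapply(seq_len(nrow(sents)), function(k) {
      tk <- tokenize(substr(text, sents$start[k] + 1L, sents$end[k]),
                     offset = sents$start[k])
      if (nrow(tk) == 0) return(NULL)
      tk$doc_id <- doc_id
      tk$sent_index <- sents$sent_index[k]
      tk$tok_index <- seq_len(nrow(tk))
      tk$norm <- normalize_numeric(tk$surface, mode = numeric_mode)
      tk$pos <- pos_tag(tk$surface, backend)
      tk
    })
    out[[i]] <- do.call(rbind, toks)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(surface = character(), start = integer(), end = integer(),
                      doc_id = character(), sent_index = integer(),
                      tok_index = integer(), norm = character(),
                      pos = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res[, c("doc_id", "sent_index", "tok_index", "surface", "norm",
          "start", "end", "pos")]
}

# Merge sentences whose boundary cuts through an annotation span.
repair_sentence_boundaries <- function(sents, ann, doc_id) {
  if (nrow(sents) <= 1 || nrow(ann) == 0) return(sents)
  repeat {
    merged <- FALSE
    for (j in seq_len(nrow(ann))) {
      hits <- which(sents$start < ann$end[j] & sents$end > ann$start[j])
      if (length(hits) > 1) {
        warning("annotation crosses a sentence boundary in ", doc_id,
                "; merging sentences", call. = FALSE)
        lo <- min(hits); hi <- max(hits)
        sents$end[lo] <- sents$end[hi]
        sents <- sents[-seq(lo + 1L, hi), , drop = FALSE]
        sents$sent_index <- seq_len(nrow(sents))
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  rownames(sents) <- NULL
  sents
}

#' Project character-offset annotations onto token spans
#'
#' Each annotation is mapped to the maximal contiguous token run overlapping
#' its character span. Boundaries falling inside a token snap outward to the
#' whole token with a warning. Annotations that still overlap two sentences
#' are rejected into the `"rejected"` attribute. Sentences without
#' annotations are unaffected: this function only adds mention records.
#'
#' @param tokens Token table from [preprocess_documents()].
#' @param annotations Annotation table.
#' @return A mention table: `doc_id`, `sent_index`, `first`, `last` (token
#'   indices within the sentence, inclusive), `etype`, `fm`, `sf`.
#' @export
align_annotations <- function(tokens, annotations) {
  rows <- list()
  rejected <- list()
  for (j in seq_len(nrow(annotations))) {
    a <- annotations[j, ]
    tk <- tokens[tokens$doc_id == a$doc_id &
                   tokens$start < a$end & tokens$end > a$start, , drop = FALSE]
    if (nrow(tk) == 0) {
      rejected[[length(rejected) + 1L]] <-
        cbind(a, data.frame(reason = "no overlapping tokens"))
      next
    }
    if (length(unique(tk$sent_index)) > 1) {
      rejected[[length(rejected) + 1L]] <-
        cbind(a, data.frame(reason = "annotation overlaps two sentences"))
      next
    }
    if (min(tk$start) < a$start || max(tk$end) > a$end) {
      warning("annotation boundary inside a token in ", a$doc_id,
              "; snapping to whole tokens", call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      doc_id = a$doc_id, sent_index = tk$sent_index[1],
      first = min(tk$tok_index), last = max(tk$tok_index),
      etype = a$etype, fm = a$fm, sf = a$sf, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(doc_id = character(), sent_index = integer(), first = integer(),
               last = integer(), etype = character(), fm = character(),
               sf = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else NULL
  out
}

#' Write a token/label table in CoNLL style
#'
#' One token per line, `surface<TAB>norm<TAB>pos<TAB>label`, blank line
#' between sentences.
#'
#' @param tokens Token table.
#' @param labels Character vector of labels parallel to `tokens` rows (or
#'   `NULL` for `O` everywhere).
#' @param path Output file.
#' @export
write_conll <- function(tokens, labels = NULL, path) {
  if (is.null(labels)) labels <- rep("O", nrow(tokens))
  stopifnot(length(labels) == nrow(tokens))
  lines <- character()
  key <- paste(tokens$doc_id, tokens$sent_index)
  for (k in unique(key)) {
    idx <- which(key == k)
    lines <- c(lines, paste(tokens$surface[idx], tokens$norm[idx],
                            tokens$pos[idx], labels[idx], sep = "\t"), "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
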