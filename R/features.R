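#' Allowed UMLS semantic types
#'
#' The 60 semantic-type abbreviations whose concepts are kept by the concept
#' recognizer filter, shipped verbatim as a resource file so the filter is
#' auditable.
#'
#' @return Character vector of abbreviations (includes e.g. `dsyn`, `neop`,
#'   `famg`).
#' @export
allowed_semantic_types <- function() {
  readLines(system.file("extdata", "semantic_types.txt", package = "famhx"))
}

#' Family-dictionary flag
#'
#' Binary indicator of whether a token refers to a family member: its
#' lowercase surface, or the singular form, is a base name or a known
#' variant.
#'
#' @param surfaces Character vector of token surfaces.
#' @param lexicon Family lexicon.
#' @return Integer vector of 0/1.
#' @export
family_flag <- function(surfaces, lexicon = load_family_lexicon()) {
  known <- c(tolower(lexicon$base_names$name), names(lexicon$variants))
  lc <- tolower(surfaces)
  as.integer(lc %in% known | singularize(lc) %in% known)
}

#' Dictionary-based concept recognizer backend
#'
#' A small exact-match concept recognizer over a term-to-CUI table, bundled
#' so the concept feature channel works offline. It implements the same
#' contract an adapter over a full concept recognizer (such as MetaMap)
#' would: given a token sequence, return non-overlapping concept matches
#' with CUIs and semantic types. The bundled table is a synthetic toy
#' dictionary, not a UMLS excerpt.
#'
#' @param path Optional TSV `term<TAB>cui<TAB>semtype[,semtype...]`; defaults
#'   to the bundled dictionary.
#' @return An object of class `fhx_concept_backend`.
#' @export
dictionary_concept_backend <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "concept_dictionary.tsv", package = "famhx")
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  key <- tolower(d$term)
  entries <- setNames(lapply(seq_len(nrow(d)), function(i) {
    list(cui = d$cui[i], semtypes = strsplit(d$semtypes[i], ",")[[1]])
  }), key)
  structure(list(
    name = "dictionary",
    max_len = max(lengths(strsplit(key, " ", fixed = TRUE))),
    lookup = function(phrase) entries[[phrase]]
  ), class = "fhx_concept_backend")
}

#' Recognize concepts in a tokenized sentence
#'
#' Longest-match, left-to-right, non-overlapping matching against the
#' backend, keeping only matches with at least one semantic type in
#' `allowed_types`. Both the raw and the digit-normalized token forms are
#' tried, so `type 2 diabetes` matches regardless of numeric normalization.
#' A backend failure degrades gracefully to zero matches with a warning.
#'
#' @param surfaces Character vector of token surfaces (one sentence).
#' @param backend Concept backend; see [dictionary_concept_backend()].
#' @param allowed_types Character vector of admissible semantic types.
#' @param norms Optional parallel vector of normalized token forms.
#' @return A `data.frame` with columns `first`, `last`, `cui`.
#' @export
recognize_concepts <- function(surfaces, backend = dictionary_concept_backend(),
                               allowed_types = allowed_semantic_types(),
                               norms = NULL) {
  empty <- data.frame(first = integer(), last = integer(), cui = character(),
                      stringsAsFactors = FALSE)
  n <- length(surfaces)
  if (n == 0 || length(allowed_types) == 0) return(empty)
  lc <- tolower(surfaces)
  lcn <- if (is.null(norms)) lc else tolower(norms)
  rows <- list()
  res <- tryCatch({
    i <- 1L
    while (i <= n) {
      hit <- NULL
      for (len in seq(min(backend$max_len, n - i + 1L), 1L)) {
        phrase <- paste(lc[i:(i + len - 1L)], collapse = " ")
        e <- backend$lookup(phrase)
        if (is.null(e)) {
          phrase_n <- paste(lcn[i:(i + len - 1L)], collapse = " ")
          e <- backend$lookup(phrase_n)
        }
        if (!is.null(e) && length(intersect(e$semtypes, allowed_types)) > 0) {
          hit <- list(first = i, last = i + len - 1L, cui = e$cui)
          break
        }
      }
      if (!is.null(hit)) {
        rows[[length(rows) + 1L]] <- as.data.frame(hit, stringsAsFactors = FALSE)
        i <- hit$last + 1L
      } else {
        i <- i + 1L
      }
    }
    TRUE
  }, error = function(e) {
    warning("concept backend failed (", conditionMessage(e),
            "); concept features disabled for this sentence", call. = FALSE)
    FALSE
  })
  if (!isTRUE(res) || !length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Assemble per-token handcrafted feature vectors
#'
#' One feature record per token: the PoS index into the tagger's inventory
#' (unknown tags map to a reserved UNK index), the binary family-dictionary
#' flag, and the CUI of the covering concept match (`"NONE"` outside any
#' match; every token inside a match span shares the match's CUI).
#'
#' @param surfaces,pos Token surfaces and PoS tags of one sentence.
#' @param matches Concept matches from [recognize_concepts()].
#' @param lexicon Family lexicon.
#' @param pos_inventory Closed PoS inventory (from the backend).
#' @return A `data.frame` with columns `pos_index`, `family_flag`, `cui`.
#' @export
assemble_features <- function(surfaces, pos, matches = NULL,
                              lexicon = load_family_lexicon(),
                              pos_inventory = default_pos_backend()$tagset) {
  n <- length(surfaces)
  pos_index <- match(pos, pos_inventory)
  pos_index[is.na(pos_index)] <- length(pos_inventory) + 1L  # UNK
  cui <- rep("NONE", n)
  if (!is.null(matches) && nrow(matches) > 0) {
    for (i in seq_len(nrow(matches))) {
      cui[matches$first[i]:matches$last[i]] <- matches$cui[i]
    }
  }
  data.frame(pos_index = pos_index,
             family_flag = family_flag(surfaces, lexicon),
             cui = cui, stringsAsFactors = FALSE)
}
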