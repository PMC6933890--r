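#' Normalize a family-member mention to its base name
#'
#' Rule-based normalization of a recognized mention: (1) drop tokens whose
#' PoS is adjectival or numeral and tokens on the modifier stop list
#' (`older`, `twin`, `step`, ...); (2) lowercase the remainder, map surface
#' variants (`mom`, `grandpa`, ...) and reduce regular plurals to base forms;
#' (3) match the final head token against the 15 normalized names.
#' Case-insensitive by construction.
#'
#' @param surfaces Character vector: the mention's token surfaces (non-empty).
#' @param pos Optional character vector of PoS tags parallel to `surfaces`.
#' @param lexicon A family lexicon from [load_family_lexicon()].
#' @return One of the 15 normalized names, or `"UNRESOLVED"` when no token
#'   matches.
#' @examples
#' lex <- load_family_lexicon()
#' normalize_fm("mom", lexicon = lex)
#' normalize_fm(c("older", "brother"), lexicon = lex)
#' @export
normalize_fm <- function(surfaces, pos = NULL, lexicon = load_family_lexicon()) {
  if (length(surfaces) == 0) stop("empty mention")
  keep <- rep(TRUE, length(surfaces))
  if (!is.null(pos)) {
    stopifnot(length(pos) == length(surfaces))
    keep <- keep & !(startsWith(pos, "JJ") | pos == "CD" | pos == "PUNCT")
  }
  keep <- keep & !(tolower(surfaces) %in% lexicon$modifiers)
  rest <- tolower(surfaces[keep])
  if (length(rest) == 0) return("UNRESOLVED")
  canon <- vapply(rest, function(w) {
    if (w %in% names(lexicon$variants)) return(lexicon$variants[[w]])
    s <- singularize(w)
    if (s %in% names(lexicon$variants)) return(lexicon$variants[[s]])
    hit <- match(s, tolower(lexicon$base_names$name))
    if (!is.na(hit)) return(lexicon$base_names$name[hit])
    "UNRESOLVED"
  }, character(1), USE.NAMES = FALSE)
  head_tok <- canon[length(canon)]
  if (head_tok != "UNRESOLVED") head_tok else "UNRESOLVED"
}

#' Count side-of-family occurrences per member type in training data
#'
#' The counts feed the majority-vote fallback of [resolve_sf()]: when a
#' mention is not preceded by an explicit side term, it receives the side
#' value most frequently observed for its member type in training.
#'
#' @param annotations Gold annotation (or mention) table with `etype`, `fm`,
#'   `sf` columns.
#' @return An object of class `fhx_side_prior`: a named list of
#'   `c(NA, Maternal, Paternal)` count vectors, one per member name.
#' @export
build_side_prior <- function(annotations) {
  fam <- annotations[annotations$etype == "FamilyMember", , drop = FALSE]
  values <- c("NA", "Maternal", "Paternal")
  counts <- lapply(family_base_names()$name, function(nm) {
    sfs <- fam$sf[fam$fm == nm]
    setNames(vapply(values, function(v) sum(sfs == v), numeric(1)), values)
  })
  structure(setNames(counts, family_base_names()$name),
            class = "fhx_side_prior")
}

#' Resolve the side-of-family attribute of a mention
#'
#' If a side term (`maternal` / `paternal`) occurs within the lookbehind
#' window immediately preceding the mention in the same sentence, its value
#' wins regardless of the prior. Otherwise the most frequent side for the
#' member type in training is used; ties and all-zero counts resolve to the
#' least committal value in the order `NA > Maternal > Paternal`.
#'
#' @param fm Normalized member name (or `"UNRESOLVED"`).
#' @param preceding Character vector of the token surfaces before the mention
#'   in its sentence (any length; only the last `window` are inspected).
#' @param prior A side prior from [build_side_prior()].
#' @param lexicon Family lexicon (for the side-term table).
#' @param window Lookbehind window in tokens (default 2, wide enough for
#'   "maternal half aunt" while staying inside the clause).
#' @return `"NA"`, `"Maternal"` or `"Paternal"`.
#' @export
resolve_sf <- function(fm, preceding = character(), prior = NULL,
                       lexicon = load_family_lexicon(), window = 2) {
  look <- tolower(utils::tail(preceding, window))
  for (w in rev(look)) {
    if (w %in% names(lexicon$side_terms)) return(lexicon$side_terms[[w]])
  }
  if (is.null(prior) || is.na(fm) || !fm %in% names(prior)) return("NA")
  counts <- prior[[fm]]
  order_pref <- c("NA", "Maternal", "Paternal")
  counts <- counts[order_pref]
  if (all(counts == 0)) return("NA")
  order_pref[which.max(counts)]
}

#' Fill in the fm and sf properties of decoded mentions
#'
#' Applies the scheme-appropriate combination of rules: under `standard` both
#' properties come from the rules ([normalize_fm()] then [resolve_sf()]);
#' under `side` the side is already in the tag and only the name is resolved;
#' under `relation_side` both come from the tag. Family-member mentions whose
#' name cannot be resolved are dropped (with a warning) since they cannot
#' appear in the normalized document list. First-degree relatives always
#' carry side `NA`.
#'
#' @param mentions Mention table from decoding (`doc_id`, `sent_index`,
#'   `first`, `last`, `etype`, plus scheme-dependent `fm`, `sf`).
#' @param scheme_name `"standard"`, `"side"` or `"relation_side"`.
#' @param tokens Token table for the same documents.
#' @param prior Side prior (used by the `standard` scheme).
#' @param lexicon Family lexicon.
#' @param window Lookbehind window for [resolve_sf()].
#' @return The mention table with `fm` and `sf` resolved.
#' @export
finalize_properties <- function(mentions, scheme_name, tokens, prior = NULL,
                                lexicon = load_family_lexicon(), window = 2) {
  if (nrow(mentions) == 0) return(mentions)
  out <- mentions
  for (i in seq_len(nrow(out))) {
    if (out$etype[i] != "FamilyMember") next
    sent <- tokens[tokens$doc_id == out$doc_id[i] &
                     tokens$sent_index == out$sent_index[i], , drop = FALSE]
    sent <- sent[order(sent$tok_index), , drop = FALSE]
    span <- out$first[i]:out$last[i]
    if (scheme_name %in% c("standard", "side")) {
      out$fm[i] <- normalize_fm(sent$surface[span], sent$pos[span], lexicon)
    }
    if (scheme_name == "standard") {
      out$sf[i] <- resolve_sf(out$fm[i],
                              preceding = sent$surface[seq_len(out$first[i] - 1)],
                              prior = prior, lexicon = lexicon, window = window)
    }
  }
  unresolved <- out$etype == "FamilyMember" & out$fm == "UNRESOLVED"
  if (any(unresolved)) {
    warning(sum(unresolved), " family mention(s) could not be normalized; dropped",
            call. = FALSE)
    out <- out[!unresolved, , drop = FALSE]
  }
  # first-degree relatives never carry a maternal/paternal side
  first_degree <- family_base_names()$name[family_base_names()$degree == 1]
  fixup <- out$etype == "FamilyMember" & out$fm %in% first_degree
  out$sf[fixup] <- "NA"
  rownames(out) <- NULL
  out
}
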