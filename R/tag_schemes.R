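#' IOB2 tag schemes for family-history extraction
#'
#' Three reversible encodings between annotated token runs and per-token
#' label sequences. All three use plain `B/I-Ob` for observations; they
#' differ in how much of the family-member properties they push into the
#' labels:
#'
#' * `standard`: members are just `B/I-FM`; the normalized name and the side
#'   of family are recovered afterwards by rules.
#' * `side`: the side-of-family attribute is encoded in the tag
#'   (`B/I-FM_SIDE_Maternal`, ...). Member types never observed with any
#'   side value in training keep a dedicated `B/I-FM_NA` tag.
#' * `relation_side`: both the normalized name and the side are encoded
#'   (`B/I-FM_Cousin_Maternal`, ...), over exactly the (name, side)
#'   combinations observed in training.
#'
#' @param side_eligible For `side_scheme()`: character vector of member names
#'   observed with at least one non-NA side in training; all other members
#'   encode as `FM_NA`.
#' @return An object of class `fhx_scheme` with elements `name`, `labels`
#'   and scheme-specific metadata.
#' @name tag_schemes
NULL

#' @rdname tag_schemes
#' @export
standard_scheme <- function() {
  structure(list(name = "standard",
                 labels = c("B-FM", "I-FM", "B-Ob", "I-Ob", "O")),
            class = "fhx_scheme")
}

#' @rdname tag_schemes
#' @export
side_scheme <- function(side_eligible = character()) {
  types <- c("FM_NA", "FM_SIDE_NA", "FM_SIDE_Paternal", "FM_SIDE_Maternal", "Ob")
  structure(list(name = "side",
                 labels = c(as.vector(rbind(paste0("B-", types),
                                            paste0("I-", types))), "O"),
                 side_eligible = sort(unique(side_eligible))),
            class = "fhx_scheme")
}

#' Derive the side scheme's eligibility table from training mentions
#'
#' A member name is side-eligible when it is observed with at least one
#' non-NA side anywhere in the training mentions.
#'
#' @param mentions Mention table carrying gold `fm` and `sf`.
#' @return A `side` scheme whose `side_eligible` reflects the training data.
#' @export
build_side_scheme <- function(mentions) {
  fam <- mentions[mentions$etype == "FamilyMember", , drop = FALSE]
  eligible <- unique(fam$fm[fam$sf %in% c("Maternal", "Paternal")])
  side_scheme(side_eligible = eligible)
}

#' Build the relation-side inventory from training mentions
#'
#' The inventory is data-driven by construction: one `B/I-FM_<name>_<side>`
#' pair per (name, side) combination observed in training, ordered
#' lexicographically, plus `B/I-Ob` and `O`.
#'
#' @param mentions Mention table carrying gold `fm` and `sf`.
#' @return A `relation_side` scheme.
#' @export
build_relation_side_scheme <- function(mentions) {
  fam <- mentions[mentions$etype == "FamilyMember", , drop = FALSE]
  pairs <- unique(data.frame(fm = fam$fm, sf = fam$sf, stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$fm, pairs$sf), , drop = FALSE]
  if (nrow(pairs) == 0) {
    warning("empty training mention set; relation-side inventory has only ",
            "observation labels", call. = FALSE)
  }
  types <- c(if (nrow(pairs)) sort(paste0("FM_", pairs$fm, "_", pairs$sf)), "Ob")
  structure(list(name = "relation_side",
                 labels = c(as.vector(rbind(paste0("B-", types),
                                            paste0("I-", types))), "O"),
                 pairs = pairs),
            class = "fhx_scheme")
}

# Entity-type part of a label under a scheme, e.g. "FM_SIDE_Maternal".
scheme_entity_type <- function(mention, scheme) {
  if (mention$etype == "Observation") return("Ob")
  switch(scheme$name,
    standard = "FM",
    side = if (mention$fm %in% scheme$side_eligible) {
      paste0("FM_SIDE_", mention$sf)
    } else {
      "FM_NA"
    },
    relation_side = {
      tag <- paste0("FM_", mention$fm, "_", mention$sf)
      if (!paste0("B-", tag) %in% scheme$labels) {
        stop("(", mention$fm, ", ", mention$sf,
             ") is not in the relation-side inventory")
      }
      tag
    },
    stop("unknown scheme: ", scheme$name))
}

#' Encode mentions of one sentence as an IOB2 label sequence
#'
#' @param mentions Mention table rows for one sentence (`first`, `last`,
#'   `etype`, `fm`, `sf`). Must be non-overlapping.
#' @param n_tokens Sentence length.
#' @param scheme A tag scheme.
#' @return Character vector of `n_tokens` labels from the scheme inventory.
#' @examples
#' sc <- build_relation_side_scheme(
#'   data.frame(etype = "FamilyMember", fm = "Cousin", sf = "Maternal"))
#' encode_labels(data.frame(first = 1, last = 1, etype = "FamilyMember",
#'                          fm = "Cousin", sf = "Maternal"), 1, sc)
#' @export
encode_labels <- function(mentions, n_tokens, scheme) {
  labels <- rep("O", n_tokens)
  if (is.null(mentions) || nrow(mentions) == 0) return(labels)
  m <- mentions[order(mentions$first), , drop = FALSE]
  if (any(m$first < 1 | m$last > n_tokens | m$first > m$last)) {
    stop("mention token span outside sentence bounds")
  }
  if (nrow(m) > 1 && any(m$first[-1] <= m$last[-nrow(m)])) {
    i <- which(m$first[-1] <= m$last[-nrow(m)])[1]
    stop("overlapping mentions: tokens ", m$first[i], "-", m$last[i],
         " and ", m$first[i + 1], "-", m$last[i + 1])
  }
  for (i in seq_len(nrow(m))) {
    tag <- scheme_entity_type(m[i, ], scheme)
    labels[m$first[i]] <- paste0("B-", tag)
    if (m$last[i] > m$first[i]) {
      labels[(m$first[i] + 1):m$last[i]] <- paste0("I-", tag)
    }
  }
  labels
}

#' Decode an IOB2 label sequence into mentions
#'
#' Maximal `B-X (I-X)*` runs become mentions. Under the `side` scheme the
#' side attribute is filled from the tag suffix (`FM_NA` and `FM_SIDE_NA`
#' both yield `NA`); under `relation_side` both the name and the side come
#' from the tag; under `standard` both are left unset.
#'
#' @param labels Character vector of labels from the scheme inventory.
#' @param scheme A tag scheme.
#' @return Mention table with columns `first`, `last`, `etype`, `fm`, `sf`.
#' @export
decode_labels <- function(labels, scheme) {
  stopifnot(all(labels %in% scheme$labels))
  rows <- list()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (startsWith(labels[i], "B-")) {
      tag <- substring(labels[i], 3)
      j <- i
      while (j < n && labels[j + 1] == paste0("I-", tag)) j <- j + 1L
      if (tag == "Ob") {
        rows[[length(rows) + 1L]] <- data.frame(
          first = i, last = j, etype = "Observation",
          fm = NA_character_, sf = NA_character_, stringsAsFactors = FALSE)
      } else {
        fm <- NA_character_
        sf <- NA_character_
        if (scheme$name == "side") {
          sf <- if (tag %in% c("FM_NA", "FM_SIDE_NA")) "NA" else
            sub("^FM_SIDE_", "", tag)
        } else if (scheme$name == "relation_side") {
          parts <- strsplit(tag, "_", fixed = TRUE)[[1]]
          fm <- parts[2]
          sf <- parts[3]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          first = i, last = j, etype = "FamilyMember", fm = fm, sf = sf,
          stringsAsFactors = FALSE)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(rows)) {
    return(data.frame(first = integer(), last = integer(), etype = character(),
                      fm = character(), sf = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Repair an invalid IOB2 sequence
#'
#' Rewrites any `I-X` that is not preceded by `B-X` or `I-X` of the same type
#' to `B-X`. Valid sequences are returned unchanged; the operation is
#' idempotent.
#'
#' @param labels Character vector of labels.
#' @return An IOB2-valid character vector.
#' @export
repair_iob2 <- function(labels) {
  out <- labels
  for (i in seq_along(out)) {
    if (startsWith(out[i], "I-")) {
      tag <- substring(out[i], 3)
      prev_ok <- i > 1 && out[i - 1] %in% paste0(c("B-", "I-"), tag)
      if (!prev_ok) out[i] <- paste0("B-", tag)
    }
  }
  out
}

#' Check IOB2 validity
#' @param labels Character vector of labels.
#' @return `TRUE` iff every `I-X` follows `B-X` or `I-X` of the same type.
#' @export
iob2_valid <- function(labels) {
  identical(labels, repair_iob2(labels))
}

#' Transition constraints implied by IOB2
#'
#' Builds the 0/1 masks used for constrained Viterbi decoding: `I-X` may only
#' follow `B-X` or `I-X` of the same type, and may not start a sentence.
#'
#' @param scheme A tag scheme.
#' @return A list with an `L x L` `trans` matrix and a length-`L` `start`
#'   vector (1 = allowed).
#' @export
iob2_constraints <- function(scheme) {
  L <- length(scheme$labels)
  labels <- scheme$labels
  trans <- matrix(1, L, L, dimnames = list(labels, labels))
  start <- setNames(rep(1, L), labels)
  for (j in seq_len(L)) {
    if (startsWith(labels[j], "I-")) {
      tag <- substring(labels[j], 3)
      ok <- labels %in% paste0(c("B-", "I-"), tag)
      trans[!ok, j] <- 0
      start[j] <- 0
    }
  }
  list(trans = trans, start = start)
}
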