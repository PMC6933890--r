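#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`, defined as 0 when `P + R = 0`.
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return Numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

# Word tokens used for observation matching: lowercase, punctuation stripped.
obs_tokens <- function(text) {
  toks <- strsplit(tolower(text), "\\s+")[[1]]
  toks <- gsub("[^a-z0-9]", "", toks)
  toks[nzchar(toks)]
}

# Length of the longest common contiguous token run.
lcs_contiguous <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0L)
  best <- 0L
  prev <- integer(length(b))
  for (i in seq_along(a)) {
    cur <- integer(length(b))
    for (j in seq_along(b)) {
      if (a[i] == b[j]) {
        cur[j] <- if (j > 1) prev[j - 1] + 1L else 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

#' Partial matching of observation phrases
#'
#' Two observation phrases match when one contains the other, or when they
#' share a contiguous token run and the number of leftover tokens (outside
#' the shared run) does not exceed the mismatch budget of 4. So predicting
#' `"diabetes"` against gold `"type 2 diabetes"` is a true positive (two
#' leftover tokens). Tokens are compared lowercase with punctuation
#' stripped.
#'
#' @param predicted,gold Observation phrases (character strings).
#' @param budget Maximum number of mismatched tokens (default 4).
#' @param count_sides `"both"` (default, stricter: leftovers on both sides
#'   count) or `"gold"` (only gold-side leftovers count).
#' @return `TRUE` or `FALSE`.
#' @export
match_observation <- function(predicted, gold, budget = 4,
                              count_sides = c("both", "gold")) {
  count_sides <- match.arg(count_sides)
  a <- obs_tokens(predicted)
  b <- obs_tokens(gold)
  if (length(a) == 0 || length(b) == 0) return(FALSE)
  k <- lcs_contiguous(a, b)
  if (k == 0) return(FALSE)
  if (k == length(a) || k == length(b)) return(TRUE)  # containment
  leftover <- if (count_sides == "both") {
    (length(a) - k) + (length(b) - k)
  } else {
    length(b) - k
  }
  leftover <= budget
}

#' Aggregate finalized mentions into a document-level prediction list
#'
#' Family-member mentions collapse to unique `(fm, sf)` records per
#' document; observation mentions collapse to unique token sequences
#' (case-insensitive).
#'
#' @param mentions Finalized mention table (from [finalize_properties()]).
#' @param tokens Token table covering the mentions.
#' @return A prediction `data.frame` (`doc_id`, `type`, `fm`, `sf`,
#'   `obs_text`) as consumed by [score_predictions()] and
#'   [write_prediction_list()].
#' @export
aggregate_document <- function(mentions, tokens) {
  empty <- data.frame(doc_id = character(), type = character(), fm = character(),
                      sf = character(), obs_text = character(),
                      stringsAsFactors = FALSE)
  if (is.null(mentions) || nrow(mentions) == 0) return(empty)
  rows <- lapply(seq_len(nrow(mentions)), function(i) {
    m <- mentions[i, ]
    if (m$etype == "FamilyMember") {
      data.frame(doc_id = m$doc_id, type = "FamilyMember", fm = m$fm, sf = m$sf,
                 obs_text = NA_character_, stringsAsFactors = FALSE)
    } else {
      sent <- tokens[tokens$doc_id == m$doc_id &
                       tokens$sent_index == m$sent_index, , drop = FALSE]
      sent <- sent[order(sent$tok_index), , drop = FALSE]
      txt <- paste(tolower(sent$surface[m$first:m$last]), collapse = " ")
      data.frame(doc_id = m$doc_id, type = "Observation", fm = NA_character_,
                 sf = NA_character_, obs_text = txt, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  key <- ifelse(out$type == "FamilyMember",
                paste(out$doc_id, "F", out$fm, out$sf),
                paste(out$doc_id, "O", out$obs_text))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Document-level gold list from annotations
#'
#' Builds the same deduplicated per-document structure as
#' [aggregate_document()], directly from gold standoff annotations.
#'
#' @param annotations Annotation table (with covered `text` as produced by
#'   [read_annotations()]).
#' @return A prediction-list `data.frame`.
#' @export
gold_document_list <- function(annotations) {
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    if (a$etype == "FamilyMember") {
      data.frame(doc_id = a$doc_id, type = "FamilyMember", fm = a$fm, sf = a$sf,
                 obs_text = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(doc_id = a$doc_id, type = "Observation", fm = NA_character_,
                 sf = NA_character_,
                 obs_text = paste(obs_tokens(a$text), collapse = " "),
                 stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(doc_id = character(), type = character(), fm = character(),
               sf = character(), obs_text = character(), stringsAsFactors = FALSE)
  key <- ifelse(out$type == "FamilyMember",
                paste(out$doc_id, "F", out$fm, out$sf),
                paste(out$doc_id, "O", out$obs_text))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score document-level predictions against gold
#'
#' Family records match by exact `(fm, sf)` equality within each document.
#' Observations match one-to-one under the partial-match rule: predictions
#' are processed in document order and each consumes the unmatched gold
#' phrase with the largest contiguous token overlap. Precision, recall and
#' F1 are reported per concept class and overall (micro-average over both
#' classes); zero denominators yield 0.
#'
#' @param predictions,gold Prediction-list `data.frame`s (`doc_id`, `type`,
#'   `fm`, `sf`, `obs_text`).
#' @param budget,count_sides Passed to [match_observation()].
#' @return An `fhx_eval_report`: a `data.frame` with rows `FamilyMember`,
#'   `Observation`, `Overall` and columns `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
score_predictions <- function(predictions, gold, budget = 4,
                              count_sides = "both") {
  counts <- c(FamilyMember = 0, Observation = 0)
  tp <- fp <- fn <- c(FamilyMember = 0, Observation = 0)
  for (d in union(predictions$doc_id, gold$doc_id)) {
    p <- predictions[predictions$doc_id == d, , drop = FALSE]
    g <- gold[gold$doc_id == d, , drop = FALSE]
    # family: exact (fm, sf) pairs
    pf <- paste(p$fm[p$type == "FamilyMember"], p$sf[p$type == "FamilyMember"])
    gf <- paste(g$fm[g$type == "FamilyMember"], g$sf[g$type == "FamilyMember"])
    hit <- sum(pf %in% gf)
    tp["FamilyMember"] <- tp["FamilyMember"] + hit
    fp["FamilyMember"] <- fp["FamilyMember"] + length(pf) - hit
    fn["FamilyMember"] <- fn["FamilyMember"] + length(gf) - sum(gf %in% pf)
    # observations: greedy one-to-one partial matching
    po <- p$obs_text[p$type == "Observation"]
    go <- g$obs_text[g$type == "Observation"]
    used <- rep(FALSE, length(go))
    for (ptxt in po) {
      overlap <- vapply(seq_along(go), function(j) {
        if (used[j] || !match_observation(ptxt, go[j], budget, count_sides)) {
          return(-1L)
        }
        lcs_contiguous(obs_tokens(ptxt), obs_tokens(go[j]))
      }, integer(1))
      if (length(overlap) && max(overlap) > 0) {
        used[which.max(overlap)] <- TRUE
        tp["Observation"] <- tp["Observation"] + 1
      } else {
        fp["Observation"] <- fp["Observation"] + 1
      }
    }
    fn["Observation"] <- fn["Observation"] + sum(!used)
  }
  mk <- function(t, f, n) {
    t <- unname(t); f <- unname(f); n <- unname(n)
    p <- if (t + f > 0) t / (t + f) else 0
    r <- if (t + n > 0) t / (t + n) else 0
    c(tp = t, fp = f, fn = n, precision = p, recall = r, f1 = f1_score(p, r))
  }
  out <- rbind(FamilyMember = mk(tp[1], fp[1], fn[1]),
               Observation = mk(tp[2], fp[2], fn[2]),
               Overall = mk(sum(tp), sum(fp), sum(fn)))
  out <- as.data.frame(out)
  class(out) <- c("fhx_eval_report", "data.frame")
  out
}

#' @export
print.fhx_eval_report <- function(x, ...) {
  cat("Document-level evaluation (partial matching for observations)\n")
  y <- x
  y$precision <- sprintf("%.4f", y$precision)
  y$recall <- sprintf("%.4f", y$recall)
  y$f1 <- sprintf("%.4f", y$f1)
  print.data.frame(y, ...)
  invisible(x)
}

#' Token-level F1 over entity labels
#'
#' Micro-averaged F1 of per-token label assignments, counting only non-`O`
#' labels (a token counts as a true positive when predicted and gold labels
#' are identical and not `O`).
#'
#' @param predicted,gold Lists of character label vectors (parallel).
#' @return A single F1 value.
#' @export
token_f1 <- function(predicted, gold) {
  p <- unlist(predicted)
  g <- unlist(gold)
  stopifnot(length(p) == length(g))
  tp <- sum(p == g & g != "O")
  fp <- sum(p != "O" & p != g)
  fn <- sum(g != "O" & p != g)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1_score(prec, rec)
}

#' Entity-level (span) F1
#'
#' F1 over decoded entity spans: a predicted span counts as correct when its
#' token extent and full label type match a gold span in the same sentence.
#'
#' @param predicted,gold Lists of label vectors (parallel sentences).
#' @param scheme The tag scheme to decode under.
#' @return A single F1 value.
#' @export
entity_f1 <- function(predicted, gold, scheme) {
  tp <- np <- ng <- 0
  for (i in seq_along(gold)) {
    pm <- decode_labels(repair_iob2(predicted[[i]]), scheme)
    gm <- decode_labels(gold[[i]], scheme)
    keyp <- paste(pm$first, pm$last, pm$etype, pm$fm, pm$sf)
    keyg <- paste(gm$first, gm$last, gm$etype, gm$fm, gm$sf)
    tp <- tp + sum(keyp %in% keyg)
    np <- np + length(keyp)
    ng <- ng + length(keyg)
  }
  prec <- if (np > 0) tp / np else 0
  rec <- if (ng > 0) tp / ng else 0
  f1_score(prec, rec)
}
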