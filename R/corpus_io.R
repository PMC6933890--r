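#' Read plain-text patient notes
#'
#' Reads one or more UTF-8 notes into a document table. Each file becomes one
#' document whose `doc_id` is the filename without extension. Newlines are
#' normalized to `"\n"` before any character offsets are computed, so offsets
#' are stable across platforms.
#'
#' @param path A directory containing `.txt` files, or a single file.
#' @return A `data.frame` with columns `doc_id` and `text`, one row per note.
#' @examples
#' d <- tempfile(fileext = ".txt")
#' writeLines("His mother has diabetes.", d)
#' read_documents(d)
#' @export
read_documents <- function(path) {
  if (!file.exists(path)) {
    stop("path does not exist: ", path)
  }
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.txt$", full.names = TRUE)
  } else {
    path
  }
  files <- sort(files)
  docs <- lapply(files, function(f) {
    raw <- readChar(f, file.size(f), useBytes = TRUE)
    Encoding(raw) <- "UTF-8"
    txt <- gsub("\r\n", "\n", raw, fixed = TRUE)
    txt <- gsub("\r", "\n", txt, fixed = TRUE)
    if (!nzchar(txt)) {
      warning("empty document: ", f, call. = FALSE)
    }
    data.frame(doc_id = tools::file_path_sans_ext(basename(f)), text = txt,
               stringsAsFactors = FALSE)
  })
  out <- if (length(docs)) do.call(rbind, docs) else
    data.frame(doc_id = character(), text = character(), stringsAsFactors = FALSE)
  if (anyDuplicated(out$doc_id)) stop("duplicate doc_id in corpus")
  rownames(out) <- NULL
  out
}

#' Read standoff annotations
#'
#' Reads gold annotations from a tab-separated standoff file with one record
#' per line: `doc_id  start  end  etype  fm  sf` (the last two fields are
#' empty for observations). Offsets are validated against the document text;
#' invalid records are collected into an error report attached as the
#' `"rejected"` attribute rather than aborting the whole read.
#'
#' @param path Annotation file.
#' @param documents Document table from [read_documents()].
#' @param offset_base Character-offset convention of the file: 0 (default,
#'   half-open `[start, end)`) or 1 (inclusive 1-based, as some exporters
#'   use). Offsets are normalized internally to 0-based half-open.
#' @return A `data.frame` with columns `doc_id`, `start`, `end`, `etype`,
#'   `fm`, `sf` and `text` (the covered text). Rejected records, with a
#'   `reason` column, are in `attr(x, "rejected")`.
#' @export
read_annotations <- function(path, documents, offset_base = 0) {
  stopifnot(offset_base %in% c(0, 1))
  raw <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = character(),
                    col.names = c("doc_id", "start", "end", "etype", "fm", "sf"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "character", "character"))
  if (offset_base == 1) {
    raw$start <- raw$start - 1L  # 1-based inclusive -> 0-based half-open
  }
  validate_annotations(raw, documents)
}

#' @keywords internal
validate_annotations <- function(ann, documents) {
  txt <- setNames(documents$text, documents$doc_id)
  ann$fm[is.na(ann$fm)] <- ""
  ann$sf[is.na(ann$sf)] <- ""
  reason <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    r <- ann[i, ]
    if (!r$doc_id %in% names(txt)) {
      reason[i] <- "unknown doc_id"
    } else if (!r$etype %in% c("FamilyMember", "Observation")) {
      reason[i] <- paste0("unknown etype: ", r$etype)
    } else if (is.na(r$start) || is.na(r$end) || r$start < 0 || r$start >= r$end ||
               r$end > nchar(txt[[r$doc_id]])) {
      reason[i] <- "offsets out of range"
    } else if (r$etype == "FamilyMember" &&
               !(r$fm %in% family_base_names()$name &&
                 r$sf %in% c("NA", "Maternal", "Paternal"))) {
      reason[i] <- "invalid fm/sf for FamilyMember"
    } else if (r$etype == "Observation" && (nzchar(r$fm) || nzchar(r$sf))) {
      reason[i] <- "fm/sf set on Observation"
    }
  }
  ok <- !nzchar(reason)
  rejected <- cbind(ann[!ok, , drop = FALSE],
                    data.frame(reason = reason[!ok], stringsAsFactors = FALSE))
  out <- ann[ok, , drop = FALSE]
  out$fm[out$etype == "Observation"] <- NA_character_
  out$sf[out$etype == "Observation"] <- NA_character_
  out$text <- vapply(seq_len(nrow(out)), function(i) {
    substr(txt[[out$doc_id[i]]], out$start[i] + 1L, out$end[i])
  }, character(1))
  rownames(out) <- NULL
  if (nrow(rejected)) {
    warning(nrow(rejected), " annotation record(s) rejected", call. = FALSE)
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write standoff annotations
#'
#' Inverse of [read_annotations()]: writes the 0-based half-open TSV dialect.
#'
#' @param annotations Annotation table (columns `doc_id`, `start`, `end`,
#'   `etype`, `fm`, `sf`).
#' @param path Output file.
#' @export
write_annotations <- function(annotations, path) {
  df <- annotations[, c("doc_id", "start", "end", "etype", "fm", "sf")]
  df$fm[is.na(df$fm)] <- ""
  df$sf[is.na(df$sf)] <- ""
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a document-level prediction list
#'
#' Writes the deduplicated per-document output of the extractor as TSV lines
#' `doc_id<TAB>FamilyMember<TAB><fm><TAB><sf>` and
#' `doc_id<TAB>Observation<TAB><text>`, sorted by `doc_id` then record type.
#' The format round-trips through [read_prediction_list()].
#'
#' @param predictions A `data.frame` with columns `doc_id`, `type`
#'   (`"FamilyMember"` or `"Observation"`), `fm`, `sf`, `obs_text`.
#' @param path Output file.
#' @export
write_prediction_list <- function(predictions, path) {
  p <- predictions
  if (nrow(p) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  p <- p[order(p$doc_id, p$type, p$fm, p$sf, p$obs_text, na.last = TRUE), ]
  lines <- vapply(seq_len(nrow(p)), function(i) {
    if (p$type[i] == "FamilyMember") {
      paste(p$doc_id[i], "FamilyMember", p$fm[i], p$sf[i], sep = "\t")
    } else {
      paste(p$doc_id[i], "Observation", p$obs_text[i], sep = "\t")
    }
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a document-level prediction list
#'
#' @param path File written by [write_prediction_list()] (or the gold list in
#'   the same format).
#' @return A `data.frame` with columns `doc_id`, `type`, `fm`, `sf`,
#'   `obs_text`.
#' @export
read_prediction_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed prediction line ", i, ": ", lines[i])
    if (f[2] == "FamilyMember") {
      if (length(f) != 4) stop("malformed FamilyMember line ", i)
      data.frame(doc_id = f[1], type = "FamilyMember", fm = f[3], sf = f[4],
                 obs_text = NA_character_, stringsAsFactors = FALSE)
    } else if (f[2] == "Observation") {
      data.frame(doc_id = f[1], type = "Observation", fm = NA_character_,
                 sf = NA_character_, obs_text = paste(f[-(1:2)], collapse = "\t"),
                 stringsAsFactors = FALSE)
    } else {
      stop("unknown record type on line ", i, ": ", f[2])
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(doc_id = character(), type = character(), fm = character(),
               sf = character(), obs_text = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read an embedding table in word2vec text format
#'
#' Each line is `token v1 ... v_dim`, space separated. An optional first
#' header line `count dim` is tolerated and skipped. Duplicate tokens keep the
#' first occurrence with a warning; a line whose vector length differs from
#' `dim` aborts with the offending line number.
#'
#' @param path Embedding file.
#' @param dim Expected vector dimension.
#' @return A numeric matrix with one row per token; rownames are the tokens.
#' @export
read_embeddings <- function(path, dim) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(matrix(numeric(), nrow = 0, ncol = dim))
  }
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  skip <- length(first) == 2 && !anyNA(suppressWarnings(as.numeric(first)))
  idx <- if (skip) seq_along(lines)[-1] else seq_along(lines)
  toks <- character(length(idx))
  vecs <- matrix(NA_real_, nrow = length(idx), ncol = dim)
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != dim + 1) {
      stop("embedding dimension mismatch on line ", i, ": expected ", dim,
           " values, got ", length(f) - 1)
    }
    toks[k] <- f[1]
    vecs[k, ] <- as.numeric(f[-1])
  }
  dup <- duplicated(toks)
  if (any(dup)) {
    warning(sum(dup), " duplicate embedding token(s); keeping first occurrence",
            call. = FALSE)
    vecs <- vecs[!dup, , drop = FALSE]
    toks <- toks[!dup]
  }
  rownames(vecs) <- toks
  vecs
}
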