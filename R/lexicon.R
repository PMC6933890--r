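#' The 15 normalized family names
#'
#' The closed vocabulary every recognized family-member mention must be
#' normalized to, with the degree of kinship (1 = immediate family, 2 =
#' extended). First-degree relatives never carry a maternal/paternal side.
#'
#' @return A `data.frame` with columns `name` and `degree`.
#' @export
family_base_names <- function() {
  data.frame(
    name = c("Father", "Mother", "Parent", "Sister", "Brother", "Daughter",
             "Son", "Child",
             "Grandmother", "Grandfather", "Grandparent", "Cousin", "Sibling",
             "Aunt", "Uncle"),
    degree = c(rep(1L, 8), rep(2L, 7)),
    stringsAsFactors = FALSE
  )
}

#' Load the family-member lexicon
#'
#' Bundles the base-name vocabulary with an editable table of surface
#' variants (`mom`, `mommy`, `grandpa`, ...), the side-of-family trigger
#' terms (`maternal`, `paternal`) and a modifier stop list used during
#' mention normalization. The shipped variant list is a reconstruction:
#' it extends the documented `mom`/`mommy` example by analogy.
#'
#' @param variants_path,side_terms_path,modifiers_path Optional overrides for
#'   the bundled TSV resources.
#' @return An object of class `fhx_lexicon`.
#' @export
load_family_lexicon <- function(variants_path = NULL, side_terms_path = NULL,
                                modifiers_path = NULL) {
  variants_path <- variants_path %||%
    system.file("extdata", "family_lexicon.tsv", package = "famhx")
  side_terms_path <- side_terms_path %||%
    system.file("extdata", "side_terms.tsv", package = "famhx")
  modifiers_path <- modifiers_path %||%
    system.file("extdata", "modifier_stoplist.txt", package = "famhx")
  v <- read.delim(variants_path, sep = "\t", stringsAsFactors = FALSE)
  base <- family_base_names()
  if (!all(v$base_name %in% base$name)) {
    stop("lexicon variant maps to a name outside the normalized vocabulary: ",
         paste(setdiff(v$base_name, base$name), collapse = ", "))
  }
  s <- read.delim(side_terms_path, sep = "\t", stringsAsFactors = FALSE)
  structure(list(
    base_names = base,
    variants = setNames(v$base_name, tolower(v$surface)),
    side_terms = setNames(s$side, tolower(s$surface)),
    modifiers = tolower(readLines(modifiers_path))
  ), class = "fhx_lexicon")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reduce a regular English plural to its singular form
#'
#' Rule-based: `-ies` to `-y`, trailing `-s` dropped unless the word ends in
#' `-ss`. Irregular plurals (`children`) are handled by the variant table,
#' not here.
#'
#' @param x Character vector of lowercase tokens.
#' @return Character vector of the same length.
#' @export
singularize <- function(x) {
  out <- x
  ies <- grepl("ies$", out) & nchar(out) > 4
  out[ies] <- sub("ies$", "y", out[ies])
  plain <- !ies & grepl("[^s]s$", out) & nchar(out) > 2
  out[plain] <- sub("s$", "", out[plain])
  out
}
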