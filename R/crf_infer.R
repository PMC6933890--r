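#' Linear-chain CRF log likelihood
#'
#' Log probability of a gold label path given per-token emission scores and
#' label-transition scores: `score(gold) - log sum over all paths of
#' exp(score)`, with the partition function computed by the forward
#' algorithm in log space. Always `<= 0`.
#'
#' @param emissions Numeric `n x L` matrix of per-token label scores.
#' @param trans Numeric `L x L` transition score matrix (`trans[i, j]` scores
#'   a move from label `i` to label `j`).
#' @param start,stop Length-`L` boundary score vectors.
#' @param gold Integer vector of gold label indices (1-based), length `n`.
#' @return The log likelihood (a single non-positive number).
#' @export
crf_log_likelihood <- function(emissions, trans, start, stop, gold) {
  stopifnot(nrow(emissions) == length(gold), ncol(emissions) == nrow(trans),
            nrow(trans) == ncol(trans), length(start) == ncol(emissions),
            length(stop) == ncol(emissions))
  if (length(gold) == 0) return(0)
  if (any(gold < 1 | gold > ncol(emissions))) {
    stop("gold label index outside the inventory")
  }
  crf_path_score_cpp(emissions, trans, start, stop, as.integer(gold)) -
    crf_log_partition_cpp(emissions, trans, start, stop)
}

#' CRF log partition function
#'
#' @inheritParams crf_log_likelihood
#' @return `log` of the sum over all label paths of `exp(path score)`.
#' @export
crf_log_partition <- function(emissions, trans, start, stop) {
  crf_log_partition_cpp(emissions, trans, start, stop)
}

#' Viterbi decoding
#'
#' Returns an argmax-scoring label path. With `constraints` (from
#' [iob2_constraints()]), transitions into IOB2-invalid successors are
#' clamped to effectively minus infinity so the decoded path is IOB2-valid
#' by construction. Ties resolve deterministically to the lowest label
#' index at the first divergence.
#'
#' @inheritParams crf_log_likelihood
#' @param constraints Optional list with 0/1 `trans` matrix and `start`
#'   vector of allowed moves.
#' @return Integer vector of decoded label indices (1-based).
#' @export
viterbi_decode <- function(emissions, trans, start, stop, constraints = NULL) {
  if (nrow(emissions) == 0) return(integer())
  ct <- if (is.null(constraints)) NULL else constraints$trans
  cs <- if (is.null(constraints)) NULL else as.numeric(constraints$start)
  as.integer(crf_viterbi_cpp(emissions, trans, start, stop, ct, cs))
}

#' Per-token softmax decoding
#'
#' The no-CRF ablation: per-token argmax over emission scores, followed by
#' IOB2 repair of the resulting label strings. Equivalent to Viterbi in the
#' zero-transition, no-tie limit.
#'
#' @param emissions Numeric `n x L` matrix of per-token label scores.
#' @param labels Character vector naming the `L` columns (a scheme
#'   inventory). When supplied, the decoded sequence is IOB2-repaired and
#'   returned as indices into `labels`.
#' @return Integer vector of decoded label indices (1-based).
#' @export
softmax_decode <- function(emissions, labels = NULL) {
  if (nrow(emissions) == 0) return(integer())
  idx <- apply(emissions, 1, which.max)
  if (!is.null(labels)) {
    idx <- match(repair_iob2(labels[idx]), labels)
  }
  as.integer(idx)
}
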