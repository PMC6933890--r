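# Classical feature-based linear-chain CRF baseline. Shares the tag schemes,
# the compiled forward-backward/Viterbi core, the property-resolution rules
# and the evaluator with the neural model; only the emission model differs
# (sparse indicator features with one weight per (feature, label) pair).

# Feature templates: token/norm identity, lowercase surface, PoS, family
# flag, CUI presence and character prefixes/suffixes (length <= 3) at the
# current position, plus identity/PoS/flag at offsets -2..+2; label bigrams
# are the CRF transition weights. The templates are a reconstruction in the
# spirit of standard NER baselines.
crf_features_sentence <- function(s, window = 2) {
  n <- length(s$surface)
  low <- tolower(s$surface)
  lapply(seq_len(n), function(t) {
    f <- c(paste0("w0=", s$norm[t]),
           paste0("l0=", low[t]),
           paste0("p0=", s$pos[t]),
           paste0("fl0=", s$flag[t]),
           paste0("cui0=", as.integer(s$cui[t] != "NONE")))
    for (k in 1:3) {
      if (nchar(low[t]) >= k) {
        f <- c(f, paste0("pre", k, "=", substring(low[t], 1, k)),
               paste0("suf", k, "=", substring(low[t], nchar(low[t]) - k + 1)))
      }
    }
    for (o in setdiff(-window:window, 0)) {
      u <- t + o
      if (u >= 1 && u <= n) {
        f <- c(f, paste0("w", o, "=", s$norm[u]),
               paste0("p", o, "=", s$pos[u]),
               paste0("fl", o, "=", s$flag[u]))
      } else {
        f <- c(f, paste0("w", o, "=<pad>"))
      }
    }
    f
  })
}

#' Train the classical CRF baseline
#'
#' A feature-based linear-chain CRF trained by SGD on the regularized
#' negative log likelihood, using the same compiled forward-backward core,
#' tag schemes and decoding as the neural labeler.
#'
#' @param sentences Labeled sentences from [prepare_labeled_sentences()].
#' @param scheme The tag scheme the labels were encoded under.
#' @param epochs,learning_rate,l2 SGD settings (learning rate decays as
#'   `lr / (1 + 0.05 (epoch - 1))`).
#' @param window Feature context window (offsets `-window..window`).
#' @param seed Integer seed for shuffling.
#' @param constrained_decode Clamp IOB2-invalid transitions at decode time.
#' @return A model of class `fhx_labeler` (with `model_type`
#'   `"crf_baseline"`), usable with [predict_labeler()].
#' @export
train_crf_baseline <- function(sentences, scheme, epochs = 40,
                               learning_rate = 0.1, l2 = 1e-6, window = 2,
                               seed = 1L, constrained_decode = TRUE) {
  if (length(sentences) == 0) stop("empty training corpus")
  set.seed(seed)
  L <- length(scheme$labels)
  featl <- lapply(sentences, crf_features_sentence, window = window)
  goldl <- lapply(sentences, function(s) {
    g <- match(s$labels, scheme$labels)
    if (anyNA(g)) stop("label outside the scheme inventory")
    as.integer(g)
  })
  feat_env <- new.env(hash = TRUE, parent = emptyenv())
  nf <- 0L
  idsl <- lapply(featl, function(fs) {
    lapply(fs, function(f) {
      vapply(f, function(x) {
        id <- feat_env[[x]]
        if (is.null(id)) {
          nf <<- nf + 1L
          feat_env[[x]] <- nf
          id <- nf
        }
        id
      }, integer(1), USE.NAMES = FALSE)
    })
  })
  W <- matrix(0, nf, L)
  trans <- matrix(0, L, L)
  start <- rep(0, L)
  stop_ <- rep(0, L)
  n <- length(sentences)
  loss_log <- data.frame(epoch = integer(), lr = numeric(), mean_loss = numeric())
  for (epoch in seq_len(epochs)) {
    lr <- learning_rate / (1 + 0.05 * (epoch - 1))
    total <- 0
    for (si in sample.int(n)) {
      ids <- idsl[[si]]
      len <- length(ids)
      if (len == 0) next
      em <- matrix(0, len, L)
      for (t in seq_len(len)) em[t, ] <- colSums(W[ids[[t]], , drop = FALSE])
      res <- crf_nll_grad_cpp(em, trans, start, stop_, goldl[[si]])
      total <- total + res$nll
      for (t in seq_len(len)) {
        W[ids[[t]], ] <- W[ids[[t]], , drop = FALSE] -
          lr * rep(res$g_em[t, ], each = length(ids[[t]]))
      }
      trans <- trans - lr * (res$g_trans + l2 * trans)
      start <- start - lr * (res$g_start + l2 * start)
      stop_ <- stop_ - lr * (res$g_stop + l2 * stop_)
      W <- W * (1 - lr * l2)
    }
    loss_log <- rbind(loss_log,
                      data.frame(epoch = epoch, lr = lr, mean_loss = total / n))
  }
  structure(list(feat_env = feat_env, W = W, trans = trans, start = start,
                 stop = stop_, scheme = scheme,
                 config = list(window = window, inference = "crf",
                               constrained_decode = constrained_decode,
                               seed = seed),
                 loss_log = loss_log, model_type = "crf_baseline"),
            class = "fhx_labeler")
}

predict_crf_baseline <- function(model, sentences) {
  scheme <- model$scheme
  cons <- if (isTRUE(model$config$constrained_decode)) iob2_constraints(scheme)
          else NULL
  lapply(sentences, function(s) {
    fs <- crf_features_sentence(s, window = model$config$window)
    len <- length(s$surface)
    if (len == 0) return(character())
    em <- matrix(0, len, length(scheme$labels))
    for (t in seq_len(len)) {
      ids <- unlist(lapply(fs[[t]], function(x) model$feat_env[[x]]))
      if (length(ids)) em[t, ] <- colSums(model$W[ids, , drop = FALSE])
    }
    idx <- viterbi_decode(em, model$trans, model$start, model$stop, cons)
    repair_iob2(scheme$labels[idx])
  })
}
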