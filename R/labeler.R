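#' Configuration of the neural sequence labeler
#'
#' Defaults follow the published hyper-parameter table of the architecture:
#' 200-dimensional word embeddings, 30-dimensional character embeddings
#' convolved by 50 kernels of width 3, 20-dimensional PoS embeddings,
#' 200-dimensional concept (CUI) embeddings, SGD with learning rate 0.01
#' decayed as `lr / (1 + 0.05 t)`, batch size 10, dropout 0.5, L2 penalty
#' 1e-8 and 1000 epochs. The recurrent hidden size is not part of that
#' table; the default of 200 units per direction follows the architecture
#' the model is based on. Training at desk scale uses explicitly reduced
#' `epochs` and dimensions.
#'
#' @param word_dim,char_dim,char_kernel,char_filters,pos_dim,cui_dim,hidden_dim
#'   Layer dimensions.
#' @param learning_rate,batch_size,dropout,lr_decay,l2,epochs,clip SGD
#'   settings; `clip` is the global gradient-norm ceiling.
#' @param inference `"crf"` (linear-chain CRF likelihood and Viterbi) or
#'   `"softmax"` (per-token cross-entropy and argmax; the no-CRF ablation).
#' @param constrained_decode Clamp IOB2-invalid transitions at decode time.
#' @param seed Mandatory integer seed; all initialization, shuffling and
#'   dropout derive from it.
#' @return A list of class `fhx_labeler_config`.
#' @export
labeler_config <- function(word_dim = 200, char_dim = 30, char_kernel = 3,
                           char_filters = 50, pos_dim = 20, cui_dim = 200,
                           hidden_dim = 200, learning_rate = 0.01,
                           batch_size = 10, dropout = 0.5, lr_decay = 0.05,
                           l2 = 1e-8, epochs = 1000, clip = 5.0,
                           inference = c("crf", "softmax"),
                           constrained_decode = TRUE, seed) {
  if (missing(seed)) stop("seed is a mandatory configuration field")
  inference <- match.arg(inference)
  stopifnot(word_dim > 0, char_dim > 0, char_kernel >= 1, char_filters > 0,
            pos_dim > 0, cui_dim > 0, hidden_dim > 0,
            dropout >= 0, dropout < 1, epochs >= 1, batch_size >= 1)
  structure(list(word_dim = word_dim, char_dim = char_dim,
                 char_kernel = char_kernel, char_filters = char_filters,
                 pos_dim = pos_dim, cui_dim = cui_dim, hidden_dim = hidden_dim,
                 learning_rate = learning_rate, batch_size = batch_size,
                 dropout = dropout, lr_decay = lr_decay, l2 = l2,
                 epochs = epochs, clip = clip, inference = inference,
                 constrained_decode = constrained_decode,
                 seed = as.integer(seed)),
            class = "fhx_labeler_config")
}

#' Prepare labeled sentences for the sequence labeler
#'
#' Groups a token table into per-sentence records carrying the surfaces,
#' digit-normalized forms, PoS tags, handcrafted feature channels
#' (family-dictionary flag and concept CUI) and, when gold mentions and a
#' scheme are given, the encoded IOB2 labels.
#'
#' @param tokens Token table from [preprocess_documents()].
#' @param mentions Optional gold mention table from [align_annotations()].
#' @param scheme Optional tag scheme used to encode labels.
#' @param lexicon Family lexicon.
#' @param concept_backend Concept recognizer backend (`NULL` disables the
#'   concept channel: every token gets CUI `"NONE"`).
#' @param allowed_types Semantic-type filter for the concept recognizer.
#' @return A list of sentence records (class `fhx_sentences`).
#' @export
prepare_labeled_sentences <- function(tokens, mentions = NULL, scheme = NULL,
                                      lexicon = load_family_lexicon(),
                                      concept_backend = dictionary_concept_backend(),
                                      allowed_types = allowed_semantic_types()) {
  key <- paste(tokens$doc_id, tokens$sent_index, sep = "\r")
  out <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    idx <- idx[order(tokens$tok_index[idx])]
    s <- tokens[idx, , drop = FALSE]
    matches <- if (is.null(concept_backend)) NULL else
      recognize_concepts(s$surface, concept_backend, allowed_types, norms = s$norm)
    feats <- assemble_features(s$surface, s$pos, matches, lexicon)
    labels <- NULL
    if (!is.null(mentions) && !is.null(scheme)) {
      m <- mentions[mentions$doc_id == s$doc_id[1] &
                      mentions$sent_index == s$sent_index[1], , drop = FALSE]
      labels <- encode_labels(m, nrow(s), scheme)
    }
    list(doc_id = s$doc_id[1], sent_index = s$sent_index[1],
         surface = s$surface, norm = s$norm, pos = s$pos,
         flag = feats$family_flag, cui = feats$cui, labels = labels)
  })
  structure(out, class = "fhx_sentences")
}

# Vocabulary over prepared sentences. UNK entries sit at the end of each
# inventory; "NONE" is an ordinary (trainable) concept row.
build_vocab <- function(sentences, pos_inventory = default_pos_backend()$tagset) {
  words <- sort(unique(unlist(lapply(sentences, `[[`, "norm"))))
  chars <- sort(unique(unlist(strsplit(
    unlist(lapply(sentences, `[[`, "surface")), "", fixed = TRUE))))
  cuis <- sort(unique(c("NONE", unlist(lapply(sentences, `[[`, "cui")))))
  list(words = c(words, "<UNK>"), chars = c(chars, "<UNK>"),
       pos = c(pos_inventory, "<UNK>"), cuis = c(cuis, "<UNK>"))
}

# Integer-encode prepared sentences against a vocabulary (1-based; unknowns
# map to the trailing UNK row).
encode_for_nn <- function(sentences, vocab, scheme = NULL) {
  lapply(sentences, function(s) {
    word <- match(s$norm, vocab$words)
    word[is.na(word)] <- length(vocab$words)
    chars <- lapply(strsplit(s$surface, "", fixed = TRUE), function(cs) {
      ci <- match(cs, vocab$chars)
      ci[is.na(ci)] <- length(vocab$chars)
      as.integer(ci)
    })
    pos <- match(s$pos, vocab$pos)
    pos[is.na(pos)] <- length(vocab$pos)
    cui <- match(s$cui, vocab$cuis)
    cui[is.na(cui)] <- length(vocab$cuis)
    gold <- if (!is.null(s$labels) && !is.null(scheme)) {
      g <- match(s$labels, scheme$labels)
      if (anyNA(g)) stop("label outside the scheme inventory: ",
                         paste(unique(s$labels[is.na(g)]), collapse = ", "))
      as.integer(g)
    } else {
      integer()
    }
    list(word = as.integer(word), chars = chars, pos = as.integer(pos),
         cui = as.integer(cui), flag = as.numeric(s$flag), gold = gold)
  })
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

embed_init <- function(v, d) {
  r <- sqrt(3 / d)
  matrix(runif(v * d, -r, r), v, d)
}

# Initialize the parameter list. Pre-trained tables (matrices with token
# rownames) overwrite matching rows and are fine-tuned during training.
init_params <- function(vocab, n_labels, config, word_embeddings = NULL,
                        cui_embeddings = NULL) {
  cfg <- config
  H <- cfg$hidden_dim
  D <- cfg$word_dim + cfg$char_filters + cfg$pos_dim + 1 + cfg$cui_dim
  Ew <- embed_init(length(vocab$words), cfg$word_dim)
  if (!is.null(word_embeddings)) {
    stopifnot(ncol(word_embeddings) == cfg$word_dim)
    hit <- match(vocab$words, rownames(word_embeddings))
    Ew[!is.na(hit), ] <- word_embeddings[hit[!is.na(hit)], , drop = FALSE]
  }
  Eu <- embed_init(length(vocab$cuis), cfg$cui_dim)
  if (!is.null(cui_embeddings)) {
    stopifnot(ncol(cui_embeddings) == cfg$cui_dim)
    hit <- match(vocab$cuis, rownames(cui_embeddings))
    Eu[!is.na(hit), ] <- cui_embeddings[hit[!is.na(hit)], , drop = FALSE]
  }
  bf <- rep(0, 4 * H)
  bf[(H + 1):(2 * H)] <- 1  # forget-gate bias
  list(Ew = Ew,
       Ec = embed_init(length(vocab$chars), cfg$char_dim),
       Ep = embed_init(length(vocab$pos), cfg$pos_dim),
       Eu = Eu,
       Wconv = glorot(cfg$char_filters, cfg$char_kernel * cfg$char_dim),
       bconv = rep(0, cfg$char_filters),
       Wf = glorot(4 * H, D), Uf = glorot(4 * H, H), bf = bf,
       Wb = glorot(4 * H, D), Ub = glorot(4 * H, H), bb = bf,
       Wo = glorot(n_labels, 2 * H), bo = rep(0, n_labels),
       trans = matrix(0, n_labels, n_labels),
       start = rep(0, n_labels), stop = rep(0, n_labels))
}

grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

#' Train the neural sequence labeler
#'
#' Character CNN + bidirectional LSTM + CRF (or softmax) trained by plain
#' SGD on mini-batches, minimizing the mean per-sentence negative log
#' likelihood, with learning rate `lr / (1 + lr_decay * (epoch - 1))`, L2
#' penalty and global gradient-norm clipping. Deterministic given the
#' config seed.
#'
#' @param sentences Labeled sentences from [prepare_labeled_sentences()].
#' @param scheme The tag scheme the labels were encoded under.
#' @param config A [labeler_config()].
#' @param word_embeddings,cui_embeddings Optional pre-trained tables
#'   (matrices with token/CUI rownames) from [read_embeddings()]; matching
#'   rows initialize the corresponding embeddings and are fine-tuned.
#' @param quiet Suppress the per-epoch progress line.
#' @return A trained model of class `fhx_labeler` with a `loss_log`
#'   data.frame (`epoch`, `lr`, `mean_loss`).
#' @export
train_labeler <- function(sentences, scheme, config, word_embeddings = NULL,
                          cui_embeddings = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "fhx_labeler_config"))
  if (length(sentences) == 0) stop("empty training corpus")
  if (any(vapply(sentences, function(s) is.null(s$labels), logical(1)))) {
    stop("all training sentences must carry labels")
  }
  set.seed(config$seed)
  vocab <- build_vocab(sentences)
  enc <- encode_for_nn(sentences, vocab, scheme)
  enc <- enc[vapply(enc, function(s) length(s$word) > 0, logical(1))]
  params <- init_params(vocab, length(scheme$labels), config,
                        word_embeddings, cui_embeddings)
  mode <- if (config$inference == "crf") 0L else 1L
  n <- length(enc)
  loss_log <- data.frame(epoch = integer(), lr = numeric(), mean_loss = numeric())
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate / (1 + config$lr_decay * (epoch - 1))
    ord <- sample.int(n)
    total <- 0
    for (b in seq(1, n, by = config$batch_size)) {
      idx <- ord[b:min(b + config$batch_size - 1, n)]
      res <- nn_batch_grad_cpp(params, enc[idx], config$dropout, mode,
                               sample.int(.Machine$integer.max, 1))
      if (!is.finite(res$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             " (batch starting at ", b, "); reduce the learning rate")
      }
      total <- total + res$loss
      g <- res$grads
      gn <- grad_global_norm(g)
      scale <- if (gn > config$clip) config$clip / gn else 1
      for (nm in names(params)) {
        params[[nm]] <- params[[nm]] -
          lr * (scale * g[[nm]] + config$l2 * params[[nm]])
      }
    }
    loss_log <- rbind(loss_log,
                      data.frame(epoch = epoch, lr = lr, mean_loss = total / n))
    if (!quiet) {
      message(sprintf("epoch %d  lr %.5f  mean loss %.4f", epoch, lr, total / n))
    }
  }
  structure(list(params = params, vocab = vocab, scheme = scheme,
                 config = config, loss_log = loss_log,
                 model_type = "neural"),
            class = "fhx_labeler")
}

#' Predict label sequences
#'
#' Runs the trained network in evaluation mode (dropout disabled) and
#' decodes per the model's inference setting: Viterbi over the learned
#' transitions (optionally IOB2-constrained) or per-token argmax followed by
#' IOB2 repair. Output is always IOB2-valid.
#'
#' @param model A trained `fhx_labeler`.
#' @param sentences Sentences from [prepare_labeled_sentences()] (labels not
#'   required).
#' @return A list of character label vectors, one per sentence.
#' @export
predict_labeler <- function(model, sentences) {
  if (length(sentences) == 0) return(list())
  scheme <- model$scheme
  if (model$model_type == "crf_baseline") {
    return(predict_crf_baseline(model, sentences))
  }
  enc <- encode_for_nn(sentences, model$vocab, scheme = NULL)
  ems <- nn_emissions_cpp(model$params, enc)
  cons <- if (model$config$constrained_decode) iob2_constraints(scheme) else NULL
  lapply(ems, function(e) {
    if (model$config$inference == "crf") {
      idx <- viterbi_decode(e, model$params$trans, model$params$start,
                            model$params$stop, cons)
      repair_iob2(scheme$labels[idx])
    } else {
      scheme$labels[softmax_decode(e, scheme$labels)]
    }
  })
}

#' Save / load a labeler checkpoint
#'
#' The checkpoint is a single self-describing archive holding the config,
#' vocabularies, scheme and weights. Loading verifies the label inventory
#' against the stored hash so a model cannot silently be decoded under a
#' different scheme.
#'
#' @param model A trained `fhx_labeler`.
#' @param path Checkpoint file.
#' @return `save_labeler` returns `path` invisibly; `load_labeler` returns
#'   the model.
#' @export
save_labeler <- function(model, path) {
  model$label_hash <- paste(model$scheme$labels, collapse = "|")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_labeler
#' @export
load_labeler <- function(path) {
  model <- readRDS(path)
  if (!identical(model$label_hash, paste(model$scheme$labels, collapse = "|"))) {
    stop("checkpoint label inventory does not match its scheme")
  }
  model
}
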