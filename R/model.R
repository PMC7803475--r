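# Full STS model: construction, featurization, joint forward/backward and
# prediction.  All trainable parameters (tiny encoder, character CNN,
# entity-type BCNN, entity-II aggregation, MLP head) live in one flat
# named list so a single optimiser updates them jointly; the TransE table
# is a frozen input.

#' Construct a multi-level STS model
#'
#' Builds the tiny encoder vocabulary and the character vocabulary from
#' the training corpus and initialises all parameters deterministically
#' from `seed`.
#'
#' @param corpus Data frame of training pairs (`snippet_a`, `snippet_b`);
#'   used to harvest vocabularies.
#' @param lexicon An `entity_lexicon`; required when either entity
#'   component is enabled.
#' @param kg_table A `kg_table` from [train_transe()]; required when the
#'   knowledge-graph entity component is enabled.
#' @param config A [model_config()].
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `sts_model`.
#' @export
sts_model <- function(corpus, lexicon = NULL, kg_table = NULL,
                      config = model_config(), seed = 1) {
  if (config$encoder != "tiny-random") {
    stop("only the 'tiny-random' encoder is bundled; pretrained encoders ",
         "must be supplied through the encoder contract")
  }
  if ((config$use_entity1 || config$use_entity2) && is.null(lexicon)) {
    stop("an entity lexicon is required when an entity component is enabled")
  }
  if (config$use_entity2) {
    if (is.null(kg_table)) {
      stop("a KG embedding table is required when the entity II component is enabled")
    }
    if (kg_table$d != config$kg_dim) {
      stop("kg_table dimension ", kg_table$d, " differs from configured kg_dim ",
           config$kg_dim)
    }
  }
  texts <- c(corpus$snippet_a, corpus$snippet_b)
  enc <- make_tiny_encoder(texts, hidden = config$hidden,
                           n_layers = config$n_layers, n_heads = config$n_heads,
                           max_len = config$max_len,
                           seed = derive_seed(seed, 1L))
  cvocab <- char_vocab(unlist(lapply(texts, preprocess)))
  params <- enc$params
  input_dim <- config$hidden
  with_seed(derive_seed(seed, 2L), {
    if (config$use_char) {
      params <- c(params, init_char_params(config, length(cvocab$chars)))
      input_dim <- input_dim + config$char_filters
    }
    if (config$use_entity1) {
      params <- c(params, init_bcnn_params(config))
      input_dim <- input_dim + 2L * config$bcnn_filters
    }
    if (config$use_entity2) {
      params <- c(params, init_ent2_params(config))
      input_dim <- input_dim + config$ent2_dim
    }
    params <- c(params, init_head_params(config, input_dim))
  })
  structure(list(params = params, config = config,
                 encoder_cfg = enc$cfg, encoder_vocab = enc$vocab,
                 char_vocab = cvocab, lexicon = lexicon, kg_table = kg_table,
                 input_dim = input_dim, seed = as.integer(seed),
                 train_log = NULL),
            class = "sts_model")
}

#' @export
print.sts_model <- function(x, ...) {
  on <- c("sentence",
          if (x$config$use_char) "char",
          if (x$config$use_entity1) "entity I",
          if (x$config$use_entity2) "entity II")
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("Multi-level STS model (%s): fused dim %d, %d parameters\n",
              paste(on, collapse = " + "), x$input_dim, np))
  if (!is.null(x$train_log)) {
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                nrow(x$train_log), x$train_log$loss[nrow(x$train_log)]))
  }
  invisible(x)
}

# Precompute everything static about a pair: encoder inputs, per-token
# character indices, entity-type labels and frozen pooled KG vectors.
featurize_pairs <- function(model, pairs) {
  cfg <- model$config
  lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$snippet_a[i]; b <- pairs$snippet_b[i]
    ft <- list(enc = encoder_inputs(a, b, model$encoder_vocab, cfg$max_len))
    toks_a <- preprocess(a); toks_b <- preprocess(b)
    if (cfg$use_char) {
      ft$chars_a <- lapply(toks_a, char_ids, vocab = model$char_vocab)
      ft$chars_b <- lapply(toks_b, char_ids, vocab = model$char_vocab)
    }
    if (cfg$use_entity1 || cfg$use_entity2) {
      la <- tag_entities(toks_a, model$lexicon)
      lb <- tag_entities(toks_b, model$lexicon)
      if (cfg$use_entity1) { ft$labels_a <- la; ft$labels_b <- lb }
      if (cfg$use_entity2) {
        ft$eg_a <- pool_entities(kg_entity_ids(la, toks_a, model$lexicon),
                                 model$kg_table)
        ft$eg_b <- pool_entities(kg_entity_ids(lb, toks_b, model$lexicon),
                                 model$kg_table)
      }
    }
    ft$g <- if (!is.null(pairs$g_score)) pairs$g_score[i] else NA_real_
    ft
  })
}

# Forward one featurized pair; returns raw prediction and all caches.
model_forward <- function(params, model, ft) {
  cfg <- model$config
  encf <- encoder_forward(params, model$encoder_cfg, ft$enc$ids, ft$enc$seg)
  C <- NULL; charf <- NULL
  if (cfg$use_char) {
    charf <- char_pair_forward(ft$chars_a, ft$chars_b, params, cfg)
    C <- charf$C
  }
  E1 <- NULL; bcnnf <- NULL
  if (cfg$use_entity1) {
    bcnnf <- bcnn_pair_forward(ft$labels_a, ft$labels_b, params, cfg)
    E1 <- bcnnf$E
  }
  E2 <- NULL; ent2_pre <- NULL
  if (cfg$use_entity2) {
    x2 <- c(ft$eg_a - ft$eg_b, ft$eg_a * ft$eg_b)
    ent2_pre <- as.numeric(params[["ent2.We"]] %*% x2) +
      as.numeric(params[["ent2.be"]])
    E2 <- tanh(ent2_pre)
  }
  f <- fuse(encf$S, C, E1, E2)
  hf <- head_forward(f, params)
  list(p = hf$p, encf = encf, charf = charf, bcnnf = bcnnf,
       E2 = E2, x2 = if (cfg$use_entity2) c(ft$eg_a - ft$eg_b, ft$eg_a * ft$eg_b),
       hf = hf)
}

# Backward one pair given dL/dp; accumulates into the environment gacc.
model_backward <- function(params, model, ft, fw, dp, gacc) {
  cfg <- model$config
  df <- head_backward(fw$hf, dp, params, gacc)
  off <- cfg$hidden
  dS <- df[seq_len(cfg$hidden)]
  if (cfg$use_char) {
    dC <- df[off + seq_len(cfg$char_filters)]
    off <- off + cfg$char_filters
    char_pair_backward(fw$charf, dC, params, cfg, gacc)
  }
  if (cfg$use_entity1) {
    dE1 <- df[off + seq_len(2L * cfg$bcnn_filters)]
    off <- off + 2L * cfg$bcnn_filters
    bcnn_pair_backward(fw$bcnnf, dE1, params, cfg, gacc)
  }
  if (cfg$use_entity2) {
    dE2 <- df[off + seq_len(cfg$ent2_dim)]
    dpre <- dE2 * (1 - fw$E2^2)
    gacc$`ent2.be` <- gacc$`ent2.be` + matrix(dpre, ncol = 1)
    gacc$`ent2.We` <- gacc$`ent2.We` + dpre %o% fw$x2
    # pooled KG vectors are frozen inputs: no gradient beyond W_e, b_e
  }
  encoder_backward(params, model$encoder_cfg, fw$encf$cache, dS, gacc)
  invisible()
}

# Loss and gradients over a batch of featurized pairs (mean-MSE scaling).
model_loss_grads <- function(params, model, feats) {
  B <- length(feats)
  gacc <- new.env(parent = emptyenv())
  for (nm in names(params)) assign(nm, zeros_like(params[[nm]]), envir = gacc)
  loss <- 0
  for (ft in feats) {
    fw <- model_forward(params, model, ft)
    err <- fw$p - ft$g
    loss <- loss + err^2 / B
    model_backward(params, model, ft, fw, 2 * err / B, gacc)
  }
  list(loss = loss, grads = as.list(gacc))
}

#' Predict similarity scores for snippet pairs
#'
#' Runs the fused model on each pair and clips predictions to the 0-5
#' scale.
#'
#' @param object A trained (or freshly initialised) `sts_model`.
#' @param pairs Data frame with `snippet_a`, `snippet_b`.
#' @param ... Unused.
#' @return Numeric vector of predicted scores in `[0, 5]`.
#' @export
predict.sts_model <- function(object, pairs, ...) {
  feats <- featurize_pairs(object, pairs)
  raw <- vapply(feats, function(ft) model_forward(object$params, object, ft)$p, 0)
  clip_scores(raw)
}
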