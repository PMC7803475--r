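# Checkpoint serialization: one versioned JSON archive holding the model
# configuration, vocabularies, all parameter tensors, the entity lexicon
# and (when present) the frozen KG embedding table.

#' Save a model checkpoint
#'
#' @param model An `sts_model`.
#' @param path Output path (JSON).
#' @export
save_checkpoint <- function(model, path) {
  ser_mat <- function(m) list(dim = dim(m), data = as.vector(m))
  ck <- list(
    format = "stsfuse-checkpoint", version = 1L,
    config = unclass(model$config),
    encoder_cfg = model$encoder_cfg,
    encoder_vocab = model$encoder_vocab$tokens,
    char_vocab = model$char_vocab$chars,
    input_dim = model$input_dim,
    seed = model$seed,
    params = lapply(model$params, ser_mat),
    lexicon = if (!is.null(model$lexicon)) unclass(model$lexicon),
    kg_table = if (!is.null(model$kg_table)) {
      list(d = model$kg_table$d,
           entity_ids = rownames(model$kg_table$entities),
           entities = as.vector(model$kg_table$entities),
           relation_ids = rownames(model$kg_table$relations),
           relations = as.vector(model$kg_table$relations))
    },
    train_log = model$train_log
  )
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path Path to the checkpoint JSON.
#' @return An `sts_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                 error = function(e) {
                   stop("not a model checkpoint (unparseable JSON): ", path)
                 })
  if (!identical(ck$format, "stsfuse-checkpoint")) {
    stop("not a model checkpoint: ", path)
  }
  params <- lapply(ck$params, function(p) matrix(p$data, p$dim[1], p$dim[2]))
  lexicon <- NULL
  if (!is.null(ck$lexicon)) {
    lexicon <- entity_lexicon(ck$lexicon$surface, ck$lexicon$type,
                              ck$lexicon$kg_id %||% NA_character_)
  }
  kg_table <- NULL
  if (!is.null(ck$kg_table)) {
    E <- matrix(ck$kg_table$entities, ncol = ck$kg_table$d)
    rownames(E) <- ck$kg_table$entity_ids
    R <- matrix(ck$kg_table$relations, ncol = ck$kg_table$d)
    rownames(R) <- ck$kg_table$relation_ids
    kg_table <- structure(list(entities = E, relations = R,
                               d = as.integer(ck$kg_table$d),
                               margin = NA_real_, lr = NA_real_,
                               epochs = NA_integer_, seed = NA_integer_),
                          class = "kg_table")
  }
  cfg <- do.call(model_config, ck$config)
  enc_cfg <- ck$encoder_cfg
  enc_cfg$hidden <- as.integer(enc_cfg$hidden)
  enc_cfg$n_layers <- as.integer(enc_cfg$n_layers)
  enc_cfg$n_heads <- as.integer(enc_cfg$n_heads)
  enc_cfg$max_len <- as.integer(enc_cfg$max_len)
  structure(list(params = params, config = cfg,
                 encoder_cfg = enc_cfg,
                 encoder_vocab = list(tokens = ck$encoder_vocab,
                                      index = stats::setNames(
                                        seq_along(ck$encoder_vocab),
                                        ck$encoder_vocab)),
                 char_vocab = list(chars = ck$char_vocab,
                                   index = stats::setNames(
                                     seq_along(ck$char_vocab), ck$char_vocab)),
                 lexicon = lexicon, kg_table = kg_table,
                 input_dim = as.integer(ck$input_dim),
                 seed = as.integer(ck$seed),
                 train_log = ck$train_log),
            class = "sts_model")
}
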