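# Fusion of the three representations and the regression head.
#
# The fused vector is the ordered concatenation f = [S; C; E_I; E_II] of
# whichever components are enabled (the sentence representation S is
# always present; the "sentence only" ablation uses S alone).  A
# multilayer perceptron maps f to the predicted similarity p_score; the
# training loss is mean squared error against the gold score, and at
# inference predictions are clipped to the [0, 5] scale.

#' Model configuration with the standard hyperparameters
#'
#' Defaults follow the reference hyperparameter set: sequence length 380,
#' knowledge-graph embedding dimension 100, character-level kernel size 3,
#' 50 BCNN convolution kernels of size 3, entity-type embedding dimension
#' 50.  Sizes with no reference value (character embedding dimension and
#' filter count, MLP layout, tiny-encoder hidden size) have explicit,
#' configurable defaults.
#'
#' @param encoder Encoder identifier; `"tiny-random"` is the bundled
#'   desk-scale encoder (pretrained checkpoints are a deployment concern
#'   and not shipped).
#' @param hidden Tiny-encoder hidden size.
#' @param n_layers,n_heads Tiny-encoder depth and head count.
#' @param max_len Maximum encoded sequence length.
#' @param char_dim,char_filters,char_kernel Character CNN sizes.
#' @param label_dim Entity-type embedding dimension.
#' @param bcnn_filters,bcnn_kernel BCNN convolution sizes.
#' @param kg_dim Knowledge-graph embedding dimension d.
#' @param ent2_dim Output dimension of the entity-II aggregation.
#' @param mlp_hidden Width of the MLP hidden layer.
#' @param use_char,use_entity1,use_entity2 Component flags.
#' @return A named list of class `sts_model_config`.
#' @export
model_config <- function(encoder = "tiny-random",
                         hidden = 16, n_layers = 2, n_heads = 2,
                         max_len = 380,
                         char_dim = 25, char_filters = 50, char_kernel = 3,
                         label_dim = 50, bcnn_filters = 50, bcnn_kernel = 3,
                         kg_dim = 100, ent2_dim = kg_dim,
                         mlp_hidden = 128,
                         use_char = TRUE, use_entity1 = TRUE,
                         use_entity2 = TRUE) {
  structure(list(encoder = encoder, hidden = as.integer(hidden),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 max_len = as.integer(max_len),
                 char_dim = as.integer(char_dim),
                 char_filters = as.integer(char_filters),
                 char_kernel = as.integer(char_kernel),
                 label_dim = as.integer(label_dim),
                 bcnn_filters = as.integer(bcnn_filters),
                 bcnn_kernel = as.integer(bcnn_kernel),
                 kg_dim = as.integer(kg_dim), ent2_dim = as.integer(ent2_dim),
                 mlp_hidden = as.integer(mlp_hidden),
                 use_char = isTRUE(use_char), use_entity1 = isTRUE(use_entity1),
                 use_entity2 = isTRUE(use_entity2)),
            class = "sts_model_config")
}

#' Training configuration with the standard hyperparameters
#'
#' Defaults are the reference values: learning rate 2e-5, 12 epochs,
#' batch size 20.  Desk-scale runs with the randomly initialised tiny
#' encoder typically override the learning rate (2e-5 is a fine-tuning
#' rate for a pretrained encoder; 0.01 is the conventional Adam rate for
#' training small models from scratch).
#'
#' @param lr Learning rate (one rate for all modules).
#' @param epochs Number of training epochs; the last epoch's parameters
#'   are the final model (no best-epoch selection).
#' @param batch_size Minibatch size.
#' @param seed Master seed for shuffling and initialisation streams.
#' @return A named list of class `sts_train_config`.
#' @export
train_config <- function(lr = 2e-5, epochs = 12, batch_size = 20, seed = 1) {
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "sts_train_config")
}

#' Concatenate enabled representations into the fused vector
#'
#' Component order is fixed: sentence, character, entity I, entity II;
#' absent (`NULL`) components are skipped.  The sentence representation
#' must be present.
#'
#' @param S Sentence-pair representation (required).
#' @param C Character-level representation or `NULL`.
#' @param E1 Entity-type sequence representation or `NULL`.
#' @param E2 Knowledge-graph entity representation or `NULL`.
#' @return Numeric vector `f`.
#' @export
fuse <- function(S, C = NULL, E1 = NULL, E2 = NULL) {
  if (is.null(S)) stop("the sentence representation S must be present")
  c(S, C, E1, E2)
}

#' Mean squared error loss
#'
#' @param p_scores Predicted scores.
#' @param g_scores Gold scores.
#' @return Mean of squared differences.
#' @export
mse_loss <- function(p_scores, g_scores) {
  if (length(p_scores) != length(g_scores)) {
    stop("length mismatch: ", length(p_scores), " predictions vs ",
         length(g_scores), " gold scores")
  }
  if (length(p_scores) == 0L) stop("empty score vectors")
  mean((p_scores - g_scores)^2)
}

#' Clip predicted scores to the 0-5 similarity scale
#' @param p Numeric vector of raw predictions.
#' @return Predictions clipped to `[0, 5]`.
#' @export
clip_scores <- function(p) pmin(pmax(p, 0), 5)

init_head_params <- function(cfg, input_dim) {
  list(`head.W1` = xavier_init(cfg$mlp_hidden, input_dim),
       `head.b1` = matrix(0, cfg$mlp_hidden, 1),
       `head.w2` = xavier_init(1, cfg$mlp_hidden),
       `head.b2` = matrix(2.5, 1, 1))   # start at the scale midpoint
}

# MLP head forward: f -> scalar (unclipped).
head_forward <- function(f, params) {
  W1 <- params[["head.W1"]]
  if (ncol(W1) != length(f)) {
    stop("fused vector has length ", length(f),
         " but the head expects ", ncol(W1))
  }
  z1 <- as.numeric(W1 %*% f) + as.numeric(params[["head.b1"]])
  h1 <- tanh(z1)
  p <- sum(as.numeric(params[["head.w2"]]) * h1) + params[["head.b2"]][1, 1]
  list(p = p, f = f, h1 = h1)
}

head_backward <- function(cache, dp, params, gacc) {
  w2 <- as.numeric(params[["head.w2"]])
  gacc$`head.b2`[1, 1] <- gacc$`head.b2`[1, 1] + dp
  gacc$`head.w2` <- gacc$`head.w2` + dp * matrix(cache$h1, 1)
  dz1 <- dp * w2 * (1 - cache$h1^2)
  gacc$`head.b1` <- gacc$`head.b1` + matrix(dz1, ncol = 1)
  gacc$`head.W1` <- gacc$`head.W1` + dz1 %o% cache$f
  as.numeric(t(params[["head.W1"]]) %*% dz1)   # df
}

init_ent2_params <- function(cfg) {
  list(`ent2.We` = xavier_init(cfg$ent2_dim, 2L * cfg$kg_dim),
       `ent2.be` = matrix(0, cfg$ent2_dim, 1))
}
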