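# Character-level representation module.
#
# Each token is encoded by a 1-D convolution (kernel size 3 by default)
# over its character embeddings with tanh activation and max pooling over
# character positions; the pair representation C is the element-wise max
# over the token vectors of ALL tokens of both snippets.  One shared
# convolution serves both snippets.  Global max pooling makes C invariant
# to token order and to duplicated tokens, and monotone under adding
# tokens.

#' Build a character vocabulary from a token collection
#'
#' Index 1 is reserved for padding and index 2 for unknown characters;
#' the observed characters follow in sorted order.
#'
#' @param tokens Character vector of tokens whose characters the
#'   vocabulary should cover.
#' @return A list with `chars` (character vector) and `index` (named
#'   integer lookup including `"<pad>"` and `"<unk>"`).
#' @export
char_vocab <- function(tokens) {
  chars <- sort_c(unique(unlist(strsplit(tokens, "", fixed = TRUE))))
  all <- c("<pad>", "<unk>", chars)
  list(chars = all, index = stats::setNames(seq_along(all), all))
}

# Map one token to character indices (unknown characters -> <unk>).
char_ids <- function(token, vocab) {
  cs <- strsplit(token, "", fixed = TRUE)[[1]]
  ids <- vocab$index[cs]
  ids[is.na(ids)] <- vocab$index[["<unk>"]]
  as.integer(ids)
}

init_char_params <- function(cfg, vocab_size) {
  list(`char.emb` = gauss_init(vocab_size, cfg$char_dim),
       `char.W` = xavier_init(cfg$char_filters, cfg$char_kernel * cfg$char_dim),
       `char.b` = matrix(0, cfg$char_filters, 1))
}

# Forward pass for one token: returns the pooled vector plus the cache
# needed for backprop.  `ids` are character indices (the padding row of
# the embedding table is never used: padding contributes zero vectors).
char_token_forward <- function(ids, params, cfg) {
  if (length(ids) == 0L) stop("empty token")
  k <- cfg$char_kernel
  dc <- cfg$char_dim
  X <- params[["char.emb"]][ids, , drop = FALSE]
  L <- nrow(X)
  pl <- 0L; pr <- 0L
  if (L < k) {                      # symmetric zero-padding up to kernel size
    pl <- (k - L) %/% 2L
    pr <- k - L - pl
    X <- rbind(matrix(0, pl, dc), X, matrix(0, pr, dc))
  }
  Lp <- nrow(X)
  nw <- Lp - k + 1L
  Win <- matrix(0, nw, k * dc)
  for (s in seq_len(k)) {
    Win[, ((s - 1L) * dc + 1L):(s * dc)] <- X[s:(s + nw - 1L), , drop = FALSE]
  }
  Z <- Win %*% t(params[["char.W"]]) +
    matrix(params[["char.b"]], nw, cfg$char_filters, byrow = TRUE)
  H <- tanh(Z)
  amax <- max.col(t(H), ties.method = "first")   # argmax window per filter
  v <- H[cbind(amax, seq_len(cfg$char_filters))]
  list(v = v, H = H, Win = Win, amax = amax, ids = ids, pl = pl, nw = nw)
}

# Backward for one token given dL/dv; accumulates into the gradient
# environment `gacc` (names char.W, char.b, char.emb).
char_token_backward <- function(cache, dv, params, cfg, gacc) {
  k <- cfg$char_kernel
  dc <- cfg$char_dim
  nf <- cfg$char_filters
  act <- which(dv != 0)
  if (length(act) == 0L) return(invisible())
  W <- params[["char.W"]]
  L <- length(cache$ids)
  for (f in act) {
    j <- cache$amax[f]
    dz <- dv[f] * (1 - cache$H[j, f]^2)
    gacc$`char.b`[f, 1] <- gacc$`char.b`[f, 1] + dz
    gacc$`char.W`[f, ] <- gacc$`char.W`[f, ] + dz * cache$Win[j, ]
    # route into the character embeddings under the window
    dwin <- dz * W[f, ]
    for (s in seq_len(k)) {
      pos <- j + s - 1L - cache$pl      # position in the unpadded token
      if (pos >= 1L && pos <= L) {
        row <- cache$ids[pos]
        gacc$`char.emb`[row, ] <- gacc$`char.emb`[row, ] +
          dwin[((s - 1L) * dc + 1L):(s * dc)]
      }
    }
  }
  invisible()
}

#' Character-level representation of a snippet pair
#'
#' Applies the shared character CNN to every token of both snippets and
#' max-pools element-wise over all token vectors.
#'
#' @param chars_a,chars_b Lists of integer character-index vectors, one
#'   per token (see [char_ids()]).
#' @param params Flat named parameter list holding `char.emb`, `char.W`,
#'   `char.b`.
#' @param cfg Model configuration (see [model_config()]).
#' @return List with the pooled vector `C` (length `char_filters`) and the
#'   per-token caches used for backprop.
#' @export
char_pair_forward <- function(chars_a, chars_b, params, cfg) {
  all_tok <- c(chars_a, chars_b)
  if (length(all_tok) == 0L) stop("both snippets are empty")
  caches <- lapply(all_tok, char_token_forward, params = params, cfg = cfg)
  V <- do.call(rbind, lapply(caches, `[[`, "v"))
  atok <- max.col(t(V), ties.method = "first")
  C <- V[cbind(atok, seq_len(cfg$char_filters))]
  list(C = C, caches = caches, atok = atok)
}

char_pair_backward <- function(cache, dC, params, cfg, gacc) {
  nf <- cfg$char_filters
  # group gradient routing by winning token
  for (t in unique(cache$atok)) {
    dv <- numeric(nf)
    sel <- cache$atok == t
    dv[sel] <- dC[sel]
    char_token_backward(cache$caches[[t]], dv, params, cfg, gacc)
  }
  invisible()
}
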