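# Sentence-level pair encoder.
#
# The model consumes the pair representation S produced by a transformer
# encoder run on the jointly encoded snippet pair:
#
#   [CLS] tokens(a) [SEP] tokens(b) [SEP]
#
# with segment embeddings distinguishing the two snippets; S is the hidden
# state at the [CLS] position.  The encoder is a contract: a production
# configuration would load a pretrained uncased checkpoint, while
# `make_tiny_encoder()` builds a small randomly initialised 2-layer,
# 2-head transformer with a word-piece-style vocabulary harvested from the
# training corpus, so every experiment runs self-contained and
# deterministically.  The encoder applies its own subword tokenization to
# raw text, independent of the rule-based corpus preprocessing.

ENC_SPECIALS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]")

# Word-piece-style vocabulary: whole words seen in the corpus, plus every
# single character, so any input can be encoded (OOV words back off to
# characters; unknown characters map to [UNK]).
build_encoder_vocab <- function(texts) {
  pieces <- unlist(lapply(tolower(texts), function(x)
    regmatches(x, gregexpr("[a-z0-9]+|[^a-z0-9[:space:]]", x))[[1]]))
  words <- sort_c(unique(pieces))
  chars <- sort_c(unique(unlist(strsplit(words, "", fixed = TRUE))))
  toks <- c(ENC_SPECIALS, union(words, chars))
  list(tokens = toks, index = stats::setNames(seq_along(toks), toks))
}

# Encode raw text to vocabulary ids (no specials).
encoder_tokenize <- function(text, vocab) {
  pieces <- regmatches(tolower(text),
                       gregexpr("[a-z0-9]+|[^a-z0-9[:space:]]", tolower(text)))[[1]]
  ids <- integer(0)
  unk <- vocab$index[["[UNK]"]]
  for (p in pieces) {
    id <- vocab$index[p]
    if (!is.na(id)) {
      ids <- c(ids, id)
    } else {
      cs <- vocab$index[strsplit(p, "", fixed = TRUE)[[1]]]
      cs[is.na(cs)] <- unk
      ids <- c(ids, cs)
    }
  }
  as.integer(ids)
}

# Build [CLS] a [SEP] b [SEP] ids + segment ids, truncating the longer
# segment first until the pair fits in max_len positions.
encoder_inputs <- function(a, b, vocab, max_len) {
  if (!nzchar(trimws(a)) || !nzchar(trimws(b))) stop("empty snippet")
  ia <- encoder_tokenize(a, vocab)
  ib <- encoder_tokenize(b, vocab)
  budget <- max_len - 3L
  while (length(ia) + length(ib) > budget) {
    if (length(ia) >= length(ib)) ia <- ia[-length(ia)] else ib <- ib[-length(ib)]
  }
  cls <- vocab$index[["[CLS]"]]; sep <- vocab$index[["[SEP]"]]
  ids <- c(cls, ia, sep, ib, sep)
  seg <- c(rep(1L, length(ia) + 2L), rep(2L, length(ib) + 1L))
  list(ids = as.integer(ids), seg = seg)
}

init_encoder_params <- function(cfg, vocab_size) {
  h <- cfg$hidden
  ff <- 4L * h
  p <- list(
    `enc.tok_emb` = gauss_init(vocab_size, h),
    `enc.pos_emb` = gauss_init(cfg$max_len, h),
    `enc.seg_emb` = gauss_init(2L, h)
  )
  for (l in seq_len(cfg$n_layers)) {
    pf <- sprintf("enc.l%d.", l)
    p[[paste0(pf, "Wq")]] <- gauss_init(h, h)
    p[[paste0(pf, "Wk")]] <- gauss_init(h, h)
    p[[paste0(pf, "Wv")]] <- gauss_init(h, h)
    p[[paste0(pf, "Wo")]] <- gauss_init(h, h)
    p[[paste0(pf, "bq")]] <- matrix(0, 1, h)
    p[[paste0(pf, "bk")]] <- matrix(0, 1, h)
    p[[paste0(pf, "bv")]] <- matrix(0, 1, h)
    p[[paste0(pf, "bo")]] <- matrix(0, 1, h)
    p[[paste0(pf, "ln1.g")]] <- matrix(1, 1, h)
    p[[paste0(pf, "ln1.b")]] <- matrix(0, 1, h)
    p[[paste0(pf, "W1")]] <- gauss_init(h, ff)
    p[[paste0(pf, "b1")]] <- matrix(0, 1, ff)
    p[[paste0(pf, "W2")]] <- gauss_init(ff, h)
    p[[paste0(pf, "b2")]] <- matrix(0, 1, h)
    p[[paste0(pf, "ln2.g")]] <- matrix(1, 1, h)
    p[[paste0(pf, "ln2.b")]] <- matrix(0, 1, h)
  }
  p
}

#' Build a tiny random transformer pair encoder
#'
#' A deterministic, desk-scale stand-in for a pretrained checkpoint: a
#' 2-layer, 2-head transformer whose vocabulary (whole words plus a full
#' character back-off) is harvested from the supplied corpus, with all
#' weights drawn from a seeded Gaussian.
#'
#' @param texts Character vector of corpus texts the vocabulary must cover.
#' @param hidden Hidden size (even, at least 4).
#' @param n_layers,n_heads Transformer depth and head count.
#' @param max_len Maximum number of encoded positions (default 380).
#' @param seed Integer seed; identical seeds give bit-identical weights.
#' @return A list with `cfg` (encoder configuration), `vocab` and `params`
#'   (flat named list, `enc.*`).
#' @export
make_tiny_encoder <- function(texts, hidden = 16, n_layers = 2, n_heads = 2,
                              max_len = 380, seed = 1) {
  if (hidden < 4 || hidden %% n_heads != 0) {
    stop("hidden size must be at least 4 and divisible by the head count")
  }
  if (max_len < 3) stop("max_len must allow [CLS] plus two separators")
  vocab <- build_encoder_vocab(texts)
  cfg <- list(id = "tiny-random", hidden = as.integer(hidden),
              n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
              max_len = as.integer(max_len))
  params <- with_seed(seed, init_encoder_params(cfg, length(vocab$tokens)))
  list(cfg = cfg, vocab = vocab, params = params)
}

# Row-wise layer norm; returns output and cache.
layernorm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  sd <- sqrt(v + eps)
  xhat <- xc / sd
  Y <- sweep(xhat, 2, as.numeric(g), `*`)
  Y <- sweep(Y, 2, as.numeric(b), `+`)
  list(Y = Y, xhat = xhat, sd = sd)
}

layernorm_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, as.numeric(g), `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) / cache$sd
  dg <- matrix(colSums(dY * xhat), 1)
  db <- matrix(colSums(dY), 1)
  list(dX = dX, dg = dg, db = db)
}

# Full encoder forward.  Returns S (hidden at [CLS]) and a cache.
encoder_forward <- function(params, cfg, ids, seg) {
  h <- cfg$hidden
  nh <- cfg$n_heads
  dh <- h %/% nh
  T <- length(ids)
  X <- params[["enc.tok_emb"]][ids, , drop = FALSE] +
    params[["enc.pos_emb"]][seq_len(T), , drop = FALSE] +
    params[["enc.seg_emb"]][seg, , drop = FALSE]
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pf <- sprintf("enc.l%d.", l)
    Xin <- X
    Q <- Xin %*% params[[paste0(pf, "Wq")]]
    Q <- sweep(Q, 2, as.numeric(params[[paste0(pf, "bq")]]), `+`)
    K <- Xin %*% params[[paste0(pf, "Wk")]]
    K <- sweep(K, 2, as.numeric(params[[paste0(pf, "bk")]]), `+`)
    V <- Xin %*% params[[paste0(pf, "Wv")]]
    V <- sweep(V, 2, as.numeric(params[[paste0(pf, "bv")]]), `+`)
    A <- vector("list", nh)
    Opre <- matrix(0, T, h)
    for (k in seq_len(nh)) {
      cols <- ((k - 1L) * dh + 1L):(k * dh)
      Sc <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
      A[[k]] <- softmax_rows(Sc)
      Opre[, cols] <- A[[k]] %*% V[, cols, drop = FALSE]
    }
    O <- Opre %*% params[[paste0(pf, "Wo")]]
    O <- sweep(O, 2, as.numeric(params[[paste0(pf, "bo")]]), `+`)
    R1 <- Xin + O
    ln1 <- layernorm_forward(R1, params[[paste0(pf, "ln1.g")]],
                             params[[paste0(pf, "ln1.b")]])
    X1 <- ln1$Y
    Zf <- X1 %*% params[[paste0(pf, "W1")]]
    Zf <- sweep(Zf, 2, as.numeric(params[[paste0(pf, "b1")]]), `+`)
    Hf <- Zf * (Zf > 0)                 # ReLU
    F2 <- Hf %*% params[[paste0(pf, "W2")]]
    F2 <- sweep(F2, 2, as.numeric(params[[paste0(pf, "b2")]]), `+`)
    R2 <- X1 + F2
    ln2 <- layernorm_forward(R2, params[[paste0(pf, "ln2.g")]],
                             params[[paste0(pf, "ln2.b")]])
    layers[[l]] <- list(Xin = Xin, Q = Q, K = K, V = V, A = A, Opre = Opre,
                        ln1 = ln1, X1 = X1, Zf = Zf, Hf = Hf, ln2 = ln2)
    X <- ln2$Y
  }
  list(S = X[1, ], cache = list(ids = ids, seg = seg, layers = layers, T = T))
}

# Encoder backward: dS is dL/dS (length hidden).  Accumulates into gacc.
encoder_backward <- function(params, cfg, cache, dS, gacc) {
  h <- cfg$hidden
  nh <- cfg$n_heads
  dh <- h %/% nh
  T <- cache$T
  dX <- matrix(0, T, h)
  dX[1, ] <- dS
  for (l in rev(seq_len(cfg$n_layers))) {
    pf <- sprintf("enc.l%d.", l)
    lc <- cache$layers[[l]]
    # layer norm 2
    b2 <- layernorm_backward(dX, lc$ln2, params[[paste0(pf, "ln2.g")]])
    gacc[[paste0(pf, "ln2.g")]] <- gacc[[paste0(pf, "ln2.g")]] + b2$dg
    gacc[[paste0(pf, "ln2.b")]] <- gacc[[paste0(pf, "ln2.b")]] + b2$db
    dR2 <- b2$dX
    dX1 <- dR2
    dF2 <- dR2
    gacc[[paste0(pf, "W2")]] <- gacc[[paste0(pf, "W2")]] + t(lc$Hf) %*% dF2
    gacc[[paste0(pf, "b2")]] <- gacc[[paste0(pf, "b2")]] + matrix(colSums(dF2), 1)
    dHf <- dF2 %*% t(params[[paste0(pf, "W2")]])
    dZf <- dHf * (lc$Zf > 0)
    gacc[[paste0(pf, "W1")]] <- gacc[[paste0(pf, "W1")]] + t(lc$X1) %*% dZf
    gacc[[paste0(pf, "b1")]] <- gacc[[paste0(pf, "b1")]] + matrix(colSums(dZf), 1)
    dX1 <- dX1 + dZf %*% t(params[[paste0(pf, "W1")]])
    # layer norm 1
    b1 <- layernorm_backward(dX1, lc$ln1, params[[paste0(pf, "ln1.g")]])
    gacc[[paste0(pf, "ln1.g")]] <- gacc[[paste0(pf, "ln1.g")]] + b1$dg
    gacc[[paste0(pf, "ln1.b")]] <- gacc[[paste0(pf, "ln1.b")]] + b1$db
    dR1 <- b1$dX
    dXin <- dR1
    dO <- dR1
    gacc[[paste0(pf, "Wo")]] <- gacc[[paste0(pf, "Wo")]] + t(lc$Opre) %*% dO
    gacc[[paste0(pf, "bo")]] <- gacc[[paste0(pf, "bo")]] + matrix(colSums(dO), 1)
    dOpre <- dO %*% t(params[[paste0(pf, "Wo")]])
    dQ <- matrix(0, T, h); dK <- matrix(0, T, h); dV <- matrix(0, T, h)
    for (k in seq_len(nh)) {
      cols <- ((k - 1L) * dh + 1L):(k * dh)
      A <- lc$A[[k]]
      dOk <- dOpre[, cols, drop = FALSE]
      dA <- dOk %*% t(lc$V[, cols, drop = FALSE])
      dV[, cols] <- t(A) %*% dOk
      dSc <- softmax_rows_backward(dA, A)
      dQ[, cols] <- (dSc %*% lc$K[, cols, drop = FALSE]) / sqrt(dh)
      dK[, cols] <- (t(dSc) %*% lc$Q[, cols, drop = FALSE]) / sqrt(dh)
    }
    gacc[[paste0(pf, "Wq")]] <- gacc[[paste0(pf, "Wq")]] + t(lc$Xin) %*% dQ
    gacc[[paste0(pf, "bq")]] <- gacc[[paste0(pf, "bq")]] + matrix(colSums(dQ), 1)
    gacc[[paste0(pf, "Wk")]] <- gacc[[paste0(pf, "Wk")]] + t(lc$Xin) %*% dK
    gacc[[paste0(pf, "bk")]] <- gacc[[paste0(pf, "bk")]] + matrix(colSums(dK), 1)
    gacc[[paste0(pf, "Wv")]] <- gacc[[paste0(pf, "Wv")]] + t(lc$Xin) %*% dV
    gacc[[paste0(pf, "bv")]] <- gacc[[paste0(pf, "bv")]] + matrix(colSums(dV), 1)
    dXin <- dXin + dQ %*% t(params[[paste0(pf, "Wq")]]) +
      dK %*% t(params[[paste0(pf, "Wk")]]) +
      dV %*% t(params[[paste0(pf, "Wv")]])
    dX <- dXin
  }
  # embeddings
  for (t in seq_len(T)) {
    gacc$`enc.tok_emb`[cache$ids[t], ] <- gacc$`enc.tok_emb`[cache$ids[t], ] + dX[t, ]
    gacc$`enc.seg_emb`[cache$seg[t], ] <- gacc$`enc.seg_emb`[cache$seg[t], ] + dX[t, ]
  }
  gacc$`enc.pos_emb`[seq_len(T), ] <- gacc$`enc.pos_emb`[seq_len(T), , drop = FALSE] + dX
  invisible()
}

#' Encode a snippet pair with a tiny encoder
#'
#' Convenience wrapper running the joint two-segment encoding of the pair
#' and returning the hidden state at the sequence-start marker.
#'
#' @param a,b Raw snippet texts (non-empty).
#' @param encoder An encoder built by [make_tiny_encoder()].
#' @return Numeric vector S of length `encoder$cfg$hidden`.
#' @export
encode_pair <- function(a, b, encoder) {
  inp <- encoder_inputs(a, b, encoder$vocab, encoder$cfg$max_len)
  encoder_forward(encoder$params, encoder$cfg, inp$ids, inp$seg)$S
}
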