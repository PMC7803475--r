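# Parameters for a hand-checkable character CNN: 2 filters, kernel 3,
# 2-dim character embeddings over the vocabulary {<pad>, <unk>, a, b}.
toy_char_setup <- function() {
  cfg <- model_config(char_dim = 2, char_filters = 2, char_kernel = 3)
  vocab <- char_vocab(c("ab", "ba"))
  params <- list(
    `char.emb` = matrix(c(0, 0, 0.5, -0.5, 0.1, 0.2, -0.3, 0.4),
                        nrow = 4, byrow = TRUE),
    `char.W` = matrix(c(0.2, -0.1, 0.4, 0.3, -0.2, 0.1,
                        -0.5, 0.2, 0.1, -0.4, 0.3, 0.2),
                      nrow = 2, byrow = TRUE),
    `char.b` = matrix(c(0.05, -0.05), 2, 1))
  list(cfg = cfg, vocab = vocab, params = params)
}

test_that("token convolution matches the sliding-window oracle", {
  s <- toy_char_setup()
  for (tok in c("ab", "ba", "a", "abab", "b")) {
    ids <- stsfuse:::char_ids(tok, s$vocab)
    got <- stsfuse:::char_token_forward(ids, s$params, s$cfg)$v
    want <- oracle_char_conv(s$params$`char.emb`[ids, , drop = FALSE],
                             s$params$`char.W`, s$params$`char.b`, 3)
    expect_equal(got, want, tolerance = 1e-12, info = tok)
  }
})

test_that("degenerate tokens and zero weights behave as specified", {
  s <- toy_char_setup()
  # 1-character token: defined output via symmetric padding
  v1 <- stsfuse:::char_token_forward(stsfuse:::char_ids("a", s$vocab),
                                     s$params, s$cfg)$v
  expect_length(v1, 2L)
  expect_true(all(is.finite(v1)))
  # all-zero weights and bias give the zero vector
  p0 <- s$params
  p0$`char.W`[] <- 0; p0$`char.b`[] <- 0
  v0 <- stsfuse:::char_token_forward(stsfuse:::char_ids("ab", s$vocab),
                                     p0, s$cfg)$v
  expect_equal(v0, c(0, 0))
  expect_error(stsfuse:::char_token_forward(integer(), s$params, s$cfg),
               "empty")
})

test_that("pair pooling is the element-wise max over all token vectors", {
  s <- toy_char_setup()
  ids <- function(tok) stsfuse:::char_ids(tok, s$vocab)
  v <- function(tok) stsfuse:::char_token_forward(ids(tok), s$params, s$cfg)$v
  # two single-token snippets: element-wise max of the two token vectors
  C <- char_pair_forward(list(ids("ab")), list(ids("ba")), s$params, s$cfg)$C
  expect_equal(C, pmax(v("ab"), v("ba")), tolerance = 1e-12)
  # b's tokens a subset of a's: C equals pooling over a alone
  Ca <- char_pair_forward(list(ids("ab"), ids("ba")), list(ids("ba")),
                          s$params, s$cfg)$C
  Cb <- char_pair_forward(list(ids("ab"), ids("ba")),
                          list(ids("ab"), ids("ba")), s$params, s$cfg)$C
  expect_equal(Ca, Cb, tolerance = 1e-12)
  # duplicating a token leaves C unchanged
  Cd <- char_pair_forward(list(ids("ab"), ids("ab"), ids("ba")),
                          list(ids("ba")), s$params, s$cfg)$C
  expect_equal(Cd, Ca, tolerance = 1e-12)
})

test_that("pooled representation is permutation-invariant and monotone", {
  s <- toy_char_setup()
  ids <- function(tok) stsfuse:::char_ids(tok, s$vocab)
  toks <- c("ab", "ba", "a", "abab", "b", "aa")
  set.seed(3)
  base <- char_pair_forward(lapply(toks[1:3], ids), lapply(toks[4:6], ids),
                            s$params, s$cfg)$C
  for (rep in 1:10) {
    perm <- sample(toks)
    cut <- sample(1:5, 1)
    C <- char_pair_forward(lapply(perm[1:cut], ids),
                           lapply(perm[-(1:cut)], ids), s$params, s$cfg)$C
    expect_equal(C, base, tolerance = 1e-12)
  }
  # adding a token can only keep coordinates equal or larger
  Cplus <- char_pair_forward(lapply(c(toks, "bb"), ids), list(ids("a")),
                             s$params, s$cfg)$C
  expect_true(all(Cplus >= base - 1e-12))
  expect_length(base, s$cfg$char_filters)
})
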