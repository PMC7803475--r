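# Independent oracles and shared tiny fixtures for the test suite.
# The oracles deliberately use a different formulation from the package
# code (explicit character scans, sliding-window loops, recursive search)
# so they check the implementation rather than mirror it.

# Regex-free character-scanner tokenizer implementing the preprocessing
# rules directly: lowercase, split on whitespace and on [ ] / , . with
# the symbols emitted standalone, except a period flanked by digits.
oracle_tokenize <- function(x) {
  chars <- strsplit(tolower(x), "", fixed = TRUE)[[1]]
  isdig <- function(c) length(c) == 1 && c >= "0" && c <= "9"
  toks <- character()
  cur <- ""
  flush <- function() {
    if (nzchar(cur)) toks <<- c(toks, cur)
    cur <<- ""
  }
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c %in% c(" ", "\t", "\n")) {
      flush()
    } else if (c %in% c("[", "]", "/", ",")) {
      flush(); toks <- c(toks, c)
    } else if (c == ".") {
      prev <- if (i > 1) chars[i - 1] else ""
      nxt <- if (i < length(chars)) chars[i + 1] else ""
      if (isdig(prev) && isdig(nxt)) {
        cur <- paste0(cur, c)
      } else {
        flush(); toks <- c(toks, ".")
      }
    } else {
      cur <- paste0(cur, c)
    }
  }
  flush()
  toks
}

# Recursive longest-match oracle: find the earliest position with any
# lexicon match, take the longest match there, recurse on the remainder.
oracle_tag <- function(tokens, lexicon) {
  labels <- rep("O", length(tokens))
  surf <- strsplit(lexicon$surface, " ", fixed = TRUE)
  matches_at <- function(i) {
    lens <- integer(0); types <- character(0)
    for (j in seq_along(surf)) {
      n <- length(surf[[j]])
      if (i + n - 1 <= length(tokens) &&
          identical(tolower(tokens[i:(i + n - 1)]), surf[[j]])) {
        lens <- c(lens, n); types <- c(types, lexicon$type[j])
      }
    }
    if (length(lens)) list(n = max(lens), type = types[which.max(lens)]) else NULL
  }
  i <- 1
  while (i <= length(tokens)) {
    m <- matches_at(i)
    if (!is.null(m)) {
      labels[i:(i + m$n - 1)] <- m$type
      i <- i + m$n
    } else {
      i <- i + 1
    }
  }
  labels
}

# Sliding-window character-convolution oracle: embeddings X (L x dc),
# symmetric zero padding to >= k, per-window linear map + tanh, max pool.
oracle_char_conv <- function(X, W, b, k) {
  dc <- ncol(X)
  L <- nrow(X)
  if (L < k) {
    pl <- (k - L) %/% 2
    X <- rbind(matrix(0, pl, dc), X, matrix(0, k - L - pl, dc))
  }
  nw <- nrow(X) - k + 1
  out <- rep(-Inf, nrow(W))
  for (j in seq_len(nw)) {
    win <- as.vector(t(X[j:(j + k - 1), , drop = FALSE]))
    h <- tanh(as.vector(W %*% win) + as.vector(b))
    out <- pmax(out, h)
  }
  out
}

# Wide-convolution + mean oracle for one BCNN branch: explicit windows
# over a zero-padded sequence, linear conv, average over input length,
# bias then tanh.
oracle_bcnn_branch <- function(X, W, b, k) {
  dl <- ncol(X)
  L <- nrow(X)
  Xp <- rbind(matrix(0, k - 1, dl), X, matrix(0, k - 1, dl))
  s <- numeric(nrow(W))
  for (j in seq_len(L + k - 1)) {
    win <- as.vector(t(Xp[j:(j + k - 1), , drop = FALSE]))
    s <- s + as.vector(W %*% win)
  }
  tanh(s / L + as.vector(b))
}

# The printed medication-line example and its fixture lexicon.
fig_sentence <- "Zocor 40 mg tablet 1 tablet by mouth one time daily."
fig_lexicon <- function() {
  entity_lexicon(c("zocor", "tablet", "mouth"),
                 c("MedicationMention", "MedicationMention",
                   "AnatomicalSiteMention"),
                 kg_id = c("M0001", NA, NA))
}

# Small shared model configuration for desk-scale training tests.
tiny_cfg <- function(...) {
  model_config(hidden = 16, max_len = 64, char_dim = 8, char_filters = 16,
               label_dim = 8, bcnn_filters = 8, kg_dim = 16, ent2_dim = 16,
               mlp_hidden = 32, ...)
}

# A tiny labeled bundle (corpus + lexicon + KG table) for training tests.
tiny_bundle <- function(n_pairs = 16, seed = 7, kg_fraction = 1,
                        kg_epochs = 50) {
  b <- generate_corpus(generator_spec(n_pairs = n_pairs, seed = seed,
                                      kg_fraction = kg_fraction))
  b$kg <- train_transe(b$triples, d = 16, epochs = kg_epochs, seed = seed)
  b
}

# Exhaustive TransE separation check: every true triple must score
# strictly better than every corruption (head or tail replaced by any
# other entity, skipping corruptions that are true triples).
transe_separates <- function(tab, triples, tails_only = FALSE) {
  ents <- rownames(tab$entities)
  score <- function(h, r, t) {
    v <- tab$entities[h, ] + tab$relations[r, ] - tab$entities[t, ]
    sum(v * v)
  }
  truth <- paste(triples$head, triples$relation, triples$tail)
  for (i in seq_len(nrow(triples))) {
    h <- triples$head[i]; r <- triples$relation[i]; t <- triples$tail[i]
    sp <- score(h, r, t)
    for (e in ents) {
      if (e != t && !(paste(h, r, e) %in% truth) && sp >= score(h, r, e)) {
        return(FALSE)
      }
      if (!tails_only && e != h && !(paste(e, r, t) %in% truth) &&
          sp >= score(e, r, t)) {
        return(FALSE)
      }
    }
  }
  TRUE
}
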