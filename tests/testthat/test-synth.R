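test_that("generator specs validate their fields", {
  expect_error(generator_spec(mixture = rep(0.2, 6)), "summing to 1")
  expect_error(generator_spec(mixture = rep(1 / 5, 5)), "6")
  expect_error(generator_spec(kg_fraction = 1.5), "cannot map more")
  expect_error(generator_spec(n_pairs = 0), "positive")
  expect_error(generator_spec(n_entities = 5), "15")
})

test_that("generation is byte-identical under a fixed seed", {
  b1 <- generate_corpus(generator_spec(n_pairs = 30, seed = 5))
  b2 <- generate_corpus(generator_spec(n_pairs = 30, seed = 5))
  expect_identical(b1, b2)
  b3 <- generate_corpus(generator_spec(n_pairs = 30, seed = 6))
  expect_false(identical(b1$pairs$snippet_a, b3$pairs$snippet_a))
})

test_that("score-5 pairs are paraphrases sharing all entity mentions", {
  spec <- generator_spec(n_pairs = 40, mixture = c(0, 0, 0, 0, 0, 1), seed = 8)
  b <- generate_corpus(spec)
  expect_true(all(b$pairs$g_score == 5))
  for (i in seq_len(nrow(b$pairs))) {
    ta <- preprocess(b$pairs$snippet_a[i])
    tb <- preprocess(b$pairs$snippet_b[i])
    ma <- entity_mentions(tag_entities(ta, b$lexicon), ta)
    mb <- entity_mentions(tag_entities(tb, b$lexicon), tb)
    expect_equal(sort(ma$surface), sort(mb$surface), info = i)
    expect_false(identical(b$pairs$snippet_a[i], b$pairs$snippet_b[i]))
  }
})

test_that("lexical overlap separates the similarity extremes", {
  spec <- generator_spec(n_pairs = 200, mixture = c(0.5, 0, 0, 0, 0, 0.5),
                         seed = 9)
  b <- generate_corpus(spec)
  jac <- function(a, b_) {
    ta <- unique(preprocess(a)); tb <- unique(preprocess(b_))
    length(intersect(ta, tb)) / length(union(ta, tb))
  }
  j <- mapply(jac, b$pairs$snippet_a, b$pairs$snippet_b)
  expect_gt(mean(j[b$pairs$g_score == 5]), mean(j[b$pairs$g_score == 0]))
})

test_that("mention-level KG coverage recovers the requested fraction", {
  spec <- generator_spec(n_pairs = 250, seed = 11, kg_fraction = 0.2)
  b <- generate_corpus(spec)
  cov <- kg_coverage(b$pairs, b$lexicon)
  expect_gte(cov$n_mentions, 1000L)
  expect_lt(abs(cov$coverage - 0.2), 0.02)
  b5 <- generate_corpus(generator_spec(n_pairs = 250, seed = 12,
                                       kg_fraction = 0.5))
  expect_lt(abs(kg_coverage(b5$pairs, b5$lexicon)$coverage - 0.5), 0.02)
})

test_that("generated corpora round-trip through the corpus format", {
  b <- generate_corpus(generator_spec(n_pairs = 25, seed = 13))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_sts_tsv(b$pairs, tf)
  back <- read_sts_tsv(tf)
  expect_equal(back$snippet_a, b$pairs$snippet_a)
  expect_equal(back$snippet_b, b$pairs$snippet_b)
  expect_equal(back$g_score, b$pairs$g_score)
})

test_that("the toy knowledge graph is closed and connected over mapped entities", {
  b <- generate_corpus(generator_spec(n_pairs = 60, seed = 14,
                                      kg_fraction = 0.5))
  mapped <- b$lexicon$kg_id[!is.na(b$lexicon$kg_id)]
  expect_gte(length(mapped), 2L)
  expect_gte(nrow(b$triples), 1L)
  # closure: every identifier in the triples resolves in the lexicon
  expect_true(all(c(b$triples$head, b$triples$tail) %in% mapped))
  # connectivity: breadth-first search reaches every mapped entity
  adj <- split(c(b$triples$tail, b$triples$head),
               c(b$triples$head, b$triples$tail))
  seen <- mapped[1]; frontier <- mapped[1]
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  expect_setequal(seen, mapped)
  # a lexicon with fewer than 2 mapped entries is rejected
  lex1 <- entity_lexicon("zocor", "MedicationMention", "M1")
  expect_error(generate_kg(lex1, generator_spec()), "at least 2")
})

test_that("generated scores reproduce a requested interval distribution", {
  mix <- c(0.05, 0.15, 0.2, 0.3, 0.2, 0.1)
  b <- generate_corpus(generator_spec(n_pairs = 2000, mixture = mix, seed = 15))
  h <- score_histogram(b$pairs)
  expect_true(all(abs(as.numeric(h) / 2000 - mix) < 0.03))
})
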