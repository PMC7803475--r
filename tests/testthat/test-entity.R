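test_that("the printed medication line is tagged with the expected labels", {
  toks <- preprocess(fig_sentence)
  labs <- tag_entities(toks, fig_lexicon())
  expect_equal(labs,
               c("MedicationMention", "O", "O", "MedicationMention", "O",
                 "MedicationMention", "O", "AnatomicalSiteMention", "O", "O",
                 "O", "O"))
  m <- entity_mentions(labs, toks)
  expect_equal(sum(m$type == "MedicationMention"), 3L)
  expect_equal(sum(m$type == "AnatomicalSiteMention"), 1L)
  expect_equal(m$surface[m$type == "MedicationMention"],
               c("zocor", "tablet", "tablet"))
})

test_that("tagging is greedy longest-match, leftmost-first", {
  lex <- entity_lexicon(c("heart attack", "heart"),
                        c("DiseaseDisorderMention", "AnatomicalSiteMention"))
  expect_equal(tag_entities(c("heart", "attack"), lex),
               rep("DiseaseDisorderMention", 2))
  # the multi-token match must win even when a shorter match also starts there
  expect_equal(tag_entities(c("heart", "rate"), lex),
               c("AnatomicalSiteMention", "O"))
})

test_that("tagging matches a recursive search oracle on random inputs", {
  lex <- entity_lexicon(
    c("chest", "chest pain", "pain", "left knee", "knee", "mri scan"),
    c("AnatomicalSiteMention", "SignSymptomMention", "SignSymptomMention",
      "AnatomicalSiteMention", "AnatomicalSiteMention", "ProcedureMention"))
  vocabulary <- c("chest", "pain", "left", "knee", "mri", "scan", "the", "no")
  set.seed(42)
  for (rep in 1:25) {
    toks <- sample(vocabulary, sample(2:9, 1), replace = TRUE)
    expect_equal(tag_entities(toks, lex), oracle_tag(toks, lex),
                 info = paste(toks, collapse = " "))
  }
})

test_that("tagging preserves length, is deterministic, and handles empties", {
  lex <- fig_lexicon()
  toks <- preprocess(fig_sentence)
  expect_length(tag_entities(toks, lex), length(toks))
  expect_identical(tag_entities(toks, lex), tag_entities(toks, lex))
  expect_equal(tag_entities(c("anything", "here"), entity_lexicon(character(), character())),
               c("O", "O"))
  expect_error(tag_entities(character(), lex), "empty")
})

test_that("mentions are maximal same-type runs", {
  expect_equal(nrow(entity_mentions(rep("O", 5))), 0L)
  m <- entity_mentions(c("MedicationMention", "MedicationMention", "O",
                         "MedicationMention"))
  expect_equal(nrow(m), 2L)
  expect_equal(m$start, c(1L, 4L))
  # adjacent runs of different types are distinct mentions
  m2 <- entity_mentions(c("MedicationMention", "DiseaseDisorderMention"))
  expect_equal(nrow(m2), 2L)
})

test_that("kg_entity_ids emits identifiers in mention order, skipping unmapped", {
  lex <- fig_lexicon()
  toks <- preprocess(fig_sentence)
  labs <- tag_entities(toks, lex)
  expect_equal(kg_entity_ids(labs, toks, lex), "M0001")
  expect_equal(kg_entity_ids(rep("O", 3), c("a", "b", "c"), lex), character())
  # repeated mentions of the same mapped surface repeat the identifier
  toks2 <- c("zocor", "then", "zocor")
  labs2 <- tag_entities(toks2, lex)
  expect_equal(kg_entity_ids(labs2, toks2, lex), c("M0001", "M0001"))
})

test_that("lexica round-trip through the TSV format", {
  lex <- entity_lexicon(c("zocor", "left knee"),
                        c("MedicationMention", "AnatomicalSiteMention"),
                        c("M1", NA))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, tf)
  back <- read_lexicon(tf)
  expect_equal(back$surface, lex$surface)
  expect_equal(back$type, lex$type)
  expect_equal(back$kg_id, lex$kg_id)
  expect_error(entity_lexicon("x", "NotAType"), "unknown entity type")
})
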