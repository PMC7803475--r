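chain3 <- data.frame(head = c("A", "B"), relation = "r", tail = c("B", "C"),
                     stringsAsFactors = FALSE)

test_that("training is deterministic and validates its inputs", {
  t1 <- train_transe(chain3, d = 4, epochs = 20, seed = 3)
  t2 <- train_transe(chain3, d = 4, epochs = 20, seed = 3)
  expect_identical(t1$entities, t2$entities)
  expect_identical(t1$relations, t2$relations)
  expect_error(train_transe(chain3[0, ], d = 4), "empty")
  expect_error(train_transe(chain3, d = 1), "at least 2")
})

test_that("entity norms are unit after every epoch's normalization", {
  tab <- train_transe(chain3, d = 4, epochs = 30, seed = 3)
  expect_lt(max(attr(tab, "epoch_norm_dev")), 1e-6)
  expect_equal(unname(sqrt(rowSums(tab$entities^2))), rep(1, 3),
               tolerance = 1e-6)
})

test_that("a trained toy chain ranks true tails above all corruptions", {
  # margin scaled to the unit-norm embedding geometry of a tiny graph
  tab <- train_transe(chain3, d = 4, margin = 0.5, lr = 0.05,
                      epochs = 200, seed = 1)
  expect_true(transe_separates(tab, chain3, tails_only = TRUE))
})

test_that("trained embeddings beat random embeddings at link prediction", {
  drugs <- sprintf("drug%02d", 1:5)
  dis <- sprintf("dis%02d", 1:5)
  tri <- data.frame(head = drugs, relation = "treats", tail = dis,
                    stringsAsFactors = FALSE)
  trained <- train_transe(tri, d = 8, epochs = 200, lr = 0.05, seed = 4)
  random <- train_transe(tri, d = 8, epochs = 0, seed = 4)
  mr_trained <- mean(as.matrix(kg_ranks(trained, tri)))
  mr_random <- mean(as.matrix(kg_ranks(random, tri)))
  expect_lt(mr_trained, mr_random)
  expect_equal(mr_trained, 1)
})

test_that("pool_entities averages, skips unknowns, and zero-fills empties", {
  tab <- train_transe(chain3, d = 4, epochs = 5, seed = 3)
  expect_equal(pool_entities("A", tab), unname(tab$entities["A", ]))
  expect_equal(pool_entities(c("A", "A"), tab), unname(tab$entities["A", ]))
  expect_equal(pool_entities(c("A", "C"), tab),
               unname((tab$entities["A", ] + tab$entities["C", ]) / 2),
               tolerance = 1e-12)
  expect_equal(pool_entities(character(), tab), numeric(4))
  expect_warning(out <- pool_entities(c("A", "nope"), tab), "nope")
  expect_equal(out, unname(tab$entities["A", ]))
  expect_equal(suppressWarnings(pool_entities("nope", tab)), numeric(4))
})

test_that("aggregation computes tanh(W [diff; prod] + b) with bounded output", {
  # hand-set example: eg_a = (1,0), eg_b = (0,1), identity-like 4x4 W
  E <- aggregate_entities(c(1, 0), c(0, 1), diag(4), rep(0, 4))
  expect_equal(E, tanh(c(1, -1, 0, 0)), tolerance = 1e-12)
  # eg_a == eg_b with zero weights gives exactly zero
  expect_equal(aggregate_entities(c(0.3, -0.2), c(0.3, -0.2),
                                  matrix(0, 2, 4), c(0, 0)), c(0, 0))
  expect_error(aggregate_entities(c(1, 0), c(1, 0, 0), diag(4), rep(0, 4)),
               "dimension")
  set.seed(8)
  for (rep in 1:10) {
    # bounded coordinate-wise; tanh saturates to 1 at machine precision
    E <- aggregate_entities(rnorm(3, sd = 5), rnorm(3, sd = 5),
                            matrix(rnorm(12), 2, 6), rnorm(2))
    expect_true(all(abs(E) <= 1))
    E2 <- aggregate_entities(rnorm(3, sd = 0.3), rnorm(3, sd = 0.3),
                             matrix(rnorm(12, sd = 0.3), 2, 6),
                             rnorm(2, sd = 0.3))
    expect_true(all(abs(E2) < 1))
  }
})

test_that("embedding tables round-trip through the text format", {
  tab <- train_transe(chain3, d = 4, epochs = 10, seed = 3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_kg_table(tab, tf)
  back <- read_kg_table(tf)
  expect_equal(back$entities, tab$entities, tolerance = 1e-9)
  expect_equal(back$relations, tab$relations, tolerance = 1e-9)
  expect_equal(back$d, 4L)
})
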