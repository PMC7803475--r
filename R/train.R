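# End-to-end training loop, Pearson-correlation evaluation, fivefold
# cross-validation and the component ablation runner.

#' Pearson correlation coefficient
#'
#' The evaluation metric for STS: sample Pearson correlation between
#' predicted and gold scores (delegates to [stats::cor()] after input
#' validation).
#'
#' @param p,g Numeric vectors of equal length at least 2.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(p, g) {
  if (length(p) != length(g)) stop("length mismatch")
  if (length(p) < 2L) stop("at least two observations are required")
  if (stats::sd(p) == 0) stop("zero variance in the predicted scores")
  if (stats::sd(g) == 0) stop("zero variance in the gold scores")
  stats::cor(p, g)
}

#' Train the fused STS model
#'
#' Jointly optimises every enabled component with Adam for exactly
#' `config$epochs` epochs over seeded shuffled minibatches; the last
#' epoch's parameters are the final model (no best-epoch selection).
#' Deterministic given the seed under single-threaded execution.
#'
#' @param model An `sts_model` from [sts_model()].
#' @param pairs Labeled training pairs (`snippet_a`, `snippet_b`,
#'   `g_score`).
#' @param config A [train_config()].
#' @return The trained model, with `train_log` (one MSE entry per epoch).
#' @export
train_sts <- function(model, pairs, config = train_config()) {
  if (nrow(pairs) == 0L) stop("empty training corpus")
  if (is.null(pairs$g_score) || anyNA(pairs$g_score)) {
    stop("training requires a fully labeled corpus")
  }
  feats <- featurize_pairs(model, pairs)
  n <- length(feats)
  params <- model$params
  state <- adam_init()
  log_loss <- numeric(config$epochs)
  with_seed(derive_seed(config$seed, 3L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        lg <- model_loss_grads(params, model, feats[idx])
        upd <- adam_step(params, lg$grads, state, config$lr)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      log_loss[ep] <- ep_loss / n
    }
  })
  model$params <- params
  model$train_log <- data.frame(epoch = seq_len(config$epochs), loss = log_loss)
  model$train_config <- config
  model
}

#' Evaluate a model by Pearson correlation on a labeled set
#'
#' Predictions are clipped to the 0-5 scale before the correlation is
#' computed, matching what a challenge submission would contain.
#'
#' @param model A trained `sts_model`.
#' @param pairs Labeled pairs.
#' @return List with `pcc` and the per-pair `predictions` data frame.
#' @export
evaluate_sts <- function(model, pairs) {
  if (is.null(pairs$g_score)) stop("evaluation requires gold scores")
  p <- predict(model, pairs)
  list(pcc = pearson_cor(p, pairs$g_score),
       predictions = data.frame(pair_id = pairs$pair_id,
                                g_score = pairs$g_score, p_score = p,
                                stringsAsFactors = FALSE))
}

#' Partition a corpus into k cross-validation folds
#'
#' Seeded shuffle followed by a near-equal split; the folds are disjoint
#' and their union is the corpus.
#'
#' @param n Corpus size.
#' @param k Number of folds (at least 2, at most n).
#' @param seed Integer seed.
#' @return List of k integer index vectors.
#' @export
make_folds <- function(n, k = 5, seed = 1) {
  if (k < 2L) stop("at least 2 folds are required")
  if (n < k) stop("corpus smaller than the number of folds")
  idx <- with_seed(seed, sample.int(n))
  sizes <- diff(floor(seq(0, n, length.out = k + 1)))
  split(idx, rep(seq_len(k), times = sizes))
}

#' Fivefold cross-validation of the fused model
#'
#' Trains on k-1 folds and evaluates on the held-out fold in rotation.
#'
#' A fold whose held-out gold scores are constant has no defined
#' correlation; such folds are reported as `NA` with a warning rather
#' than aborting the rotation (this only arises on very small corpora).
#'
#' @param pairs Labeled corpus.
#' @param lexicon,kg_table Entity resources passed to [sts_model()].
#' @param k Number of folds (default 5).
#' @param config A [model_config()].
#' @param train A [train_config()]; its seed also fixes the fold split.
#' @return List with `fold_pcc`, `mean_pcc` and the fold index list.
#' @export
crossvalidate <- function(pairs, lexicon = NULL, kg_table = NULL, k = 5,
                          config = model_config(), train = train_config()) {
  folds <- make_folds(nrow(pairs), k, train$seed)
  fold_pcc <- numeric(k)
  for (i in seq_len(k)) {
    tr <- pairs[-folds[[i]], , drop = FALSE]
    te <- pairs[folds[[i]], , drop = FALSE]
    m <- sts_model(tr, lexicon, kg_table, config, seed = train$seed)
    m <- train_sts(m, tr, train)
    fold_pcc[i] <- tryCatch(evaluate_sts(m, te)$pcc, error = function(e) {
      warning("fold ", i, ": ", conditionMessage(e))
      NA_real_
    })
  }
  list(fold_pcc = fold_pcc, mean_pcc = mean(fold_pcc), folds = folds)
}

#' The seven standard ablation configurations
#'
#' Component-flag combinations covering: each entity variant (and both)
#' with the character representation, each entity variant without it, the
#' entity-free model, and the sentence-only model.
#'
#' @return Data frame with `configuration` and the three component flags.
#' @export
ablation_configs <- function() {
  data.frame(
    configuration = c("entity I", "entity II", "entity I + entity II",
                      "entity I, no char", "entity II, no char",
                      "no entity", "sentence only"),
    use_char = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    use_entity1 = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    use_entity2 = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Component ablation study
#'
#' Trains and evaluates the seven configurations of [ablation_configs()]
#' with the same seed and reports one Pearson correlation per row.
#'
#' @param train_pairs,test_pairs Labeled train and test sets.
#' @param lexicon,kg_table Entity resources.
#' @param config Base [model_config()]; component flags are overridden per
#'   row.
#' @param train A [train_config()].
#' @return [ablation_configs()] with an extra `pcc` column.
#' @export
ablate <- function(train_pairs, test_pairs, lexicon = NULL, kg_table = NULL,
                   config = model_config(), train = train_config()) {
  rows <- ablation_configs()
  rows$pcc <- NA_real_
  for (i in seq_len(nrow(rows))) {
    cfg <- config
    cfg$use_char <- rows$use_char[i]
    cfg$use_entity1 <- rows$use_entity1[i]
    cfg$use_entity2 <- rows$use_entity2[i]
    m <- sts_model(train_pairs,
                   lexicon = if (cfg$use_entity1 || cfg$use_entity2) lexicon,
                   kg_table = if (cfg$use_entity2) kg_table,
                   config = cfg, seed = train$seed)
    m <- train_sts(m, train_pairs, train)
    rows$pcc[i] <- evaluate_sts(m, test_pairs)$pcc
  }
  rows
}

#' Histogram of gold scores over the standard similarity intervals
#'
#' Counts pairs per interval `[0,0.5), [0.5,1.5), [1.5,2.5), [2.5,3.5),
#' [3.5,4.5), [4.5,5]`.
#'
#' @param pairs Labeled corpus (zero rows allowed).
#' @return Named integer vector of six counts.
#' @export
score_histogram <- function(pairs) {
  labs <- c("[0,0.5)", "[0.5,1.5)", "[1.5,2.5)", "[2.5,3.5)", "[3.5,4.5)",
            "[4.5,5]")
  counts <- stats::setNames(integer(6), labs)
  g <- pairs$g_score
  if (!is.null(g) && length(g)) {
    bin <- findInterval(g, c(0.5, 1.5, 2.5, 3.5, 4.5)) + 1L
    tab <- table(factor(bin, levels = 1:6))
    counts[] <- as.integer(tab)
  }
  counts
}
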