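# Entity-level representation II: translation-based knowledge-graph
# embeddings.  Entities and relations are embedded in R^d (d = 100 by
# default) by TransE: a true triple (h, r, t) should satisfy h + r ~ t,
# trained with the margin ranking loss
#
#   max(0, margin + d(h, r, t) - d(h', r, t'))
#
# over uniformly corrupted negatives (head or tail replaced), with
# squared-L2 dissimilarity d and entity vectors projected to the unit
# sphere after every epoch.  The learned table is FROZEN during STS
# training; only the aggregation weights W_e, b_e are trained with the
# model.

#' Read knowledge-graph triples from a TSV file
#'
#' Format: `head<TAB>relation<TAB>tail`, one triple per line.
#'
#' @param path Path to the triples file.
#' @return Data frame with columns `head`, `relation`, `tail`.
#' @export
read_triples <- function(path) {
  if (!file.exists(path)) stop("triples file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 3L)) {
    stop("triples line ", which(lengths(fields) != 3L)[1], ": expected 3 fields")
  }
  data.frame(head = vapply(fields, `[`, "", 1L),
             relation = vapply(fields, `[`, "", 2L),
             tail = vapply(fields, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Write knowledge-graph triples to a TSV file
#' @param triples Data frame with `head`, `relation`, `tail`.
#' @param path Output path.
#' @export
write_triples <- function(triples, path) {
  writeLines(paste(triples$head, triples$relation, triples$tail, sep = "\t"), path)
  invisible(path)
}

#' Train TransE embeddings on a triple collection
#'
#' Stochastic gradient descent on the margin ranking loss with uniform
#' negative sampling; entity vectors are L2-normalized after every epoch.
#' Fully deterministic given `seed`.
#'
#' @param triples Data frame with `head`, `relation`, `tail` columns (or a
#'   path readable by [read_triples()]).
#' @param d Embedding dimension (default 100).
#' @param margin Ranking margin (default 1).
#' @param lr SGD learning rate.
#' @param epochs Number of passes over the triples.
#' @param seed Integer seed.
#' @return A `kg_table` list: `entities` and `relations` matrices with
#'   identifier rownames, plus the training configuration.  The attribute
#'   `epoch_norm_dev` records the maximum deviation of any entity norm
#'   from 1 after each epoch's normalization.
#' @export
train_transe <- function(triples, d = 100, margin = 1, lr = 0.01,
                         epochs = 100, seed = 1) {
  if (is.character(triples)) triples <- read_triples(triples)
  if (nrow(triples) == 0L) stop("empty triple set")
  if (d < 2) stop("embedding dimension must be at least 2")
  if (any(!nzchar(triples$head) | !nzchar(triples$relation) | !nzchar(triples$tail))) {
    stop("triple identifiers must be non-empty")
  }
  ents <- sort_c(unique(c(triples$head, triples$tail)))
  rels <- sort_c(unique(triples$relation))
  hi <- match(triples$head, ents)
  ri <- match(triples$relation, rels)
  ti <- match(triples$tail, ents)
  n <- nrow(triples); ne <- length(ents)
  truth <- new.env(parent = emptyenv())
  for (i in seq_len(n)) assign(paste(hi[i], ri[i], ti[i]), TRUE, envir = truth)
  is_true <- function(h, r, t) !is.null(truth[[paste(h, r, t)]])
  with_seed(seed, {
    lim <- 6 / sqrt(d)
    E <- matrix(stats::runif(ne * d, -lim, lim), ne, d)
    R <- matrix(stats::runif(length(rels) * d, -lim, lim), length(rels), d)
    R <- R / sqrt(rowSums(R * R))           # relations normalized at init
    norm_dev <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      E <- E / sqrt(rowSums(E * E))         # project before the epoch's updates
      ord <- sample.int(n)
      corrupt_head <- stats::runif(n) < 0.5
      for (j in seq_len(n)) {
        i <- ord[j]
        h <- E[hi[i], ]; r <- R[ri[i], ]; t <- E[ti[i], ]
        # corrupted negative: head or tail replaced uniformly, rejecting
        # the original entity and corruptions that are true triples
        hn_i <- hi[i]; tn_i <- ti[i]
        for (try in 1:25) {
          cand <- sample.int(ne, 1L)
          if (corrupt_head[i]) {
            if (cand != hi[i] && !is_true(cand, ri[i], ti[i])) { hn_i <- cand; break }
          } else {
            if (cand != ti[i] && !is_true(hi[i], ri[i], cand)) { tn_i <- cand; break }
          }
        }
        if (hn_i == hi[i] && tn_i == ti[i]) next
        hn <- E[hn_i, ]; tn <- E[tn_i, ]
        dp <- h + r - t
        dn <- hn + r - tn
        viol <- margin + sum(dp * dp) - sum(dn * dn)
        if (viol > 0) {
          gp <- 2 * dp; gn <- 2 * dn
          E[hi[i], ] <- E[hi[i], ] - lr * gp
          E[ti[i], ] <- E[ti[i], ] + lr * gp
          R[ri[i], ] <- R[ri[i], ] - lr * (gp - gn)
          E[hn_i, ] <- E[hn_i, ] + lr * gn
          E[tn_i, ] <- E[tn_i, ] - lr * gn
        }
      }
      E <- E / sqrt(rowSums(E * E))         # normalize after the epoch
      norm_dev[ep] <- max(abs(sqrt(rowSums(E * E)) - 1))
    }
    rownames(E) <- ents
    rownames(R) <- rels
    out <- structure(list(entities = E, relations = R, d = as.integer(d),
                          margin = margin, lr = lr, epochs = as.integer(epochs),
                          seed = as.integer(seed)),
                     class = "kg_table")
    attr(out, "epoch_norm_dev") <- norm_dev
    out
  })
}

#' @export
print.kg_table <- function(x, ...) {
  cat(sprintf("TransE embedding table: %d entities, %d relations, d = %d\n",
              nrow(x$entities), nrow(x$relations), x$d))
  invisible(x)
}

# Squared-L2 TransE dissimilarity for index triples against a table.
transe_score <- function(table, h, r, t) {
  dvec <- table$entities[h, ] + table$relations[r, ] - table$entities[t, ]
  sum(dvec * dvec)
}

#' Link-prediction ranks of the true tails (and heads) of a triple set
#'
#' For each triple, ranks the true tail among all entities substituted in
#' tail position by the TransE dissimilarity (and likewise the true head),
#' optionally filtering substitutions that themselves form a true triple.
#'
#' @param table A `kg_table` from [train_transe()].
#' @param triples Data frame of triples to rank.
#' @param filtered Drop corruptions that are themselves true triples.
#' @return Data frame with columns `tail_rank` and `head_rank`.
#' @export
kg_ranks <- function(table, triples, filtered = TRUE) {
  ents <- rownames(table$entities)
  truth <- paste(triples$head, triples$relation, triples$tail, sep = "\r")
  tr <- integer(nrow(triples)); hr <- integer(nrow(triples))
  for (i in seq_len(nrow(triples))) {
    h <- triples$head[i]; r <- triples$relation[i]; t <- triples$tail[i]
    base <- table$entities[h, ] + table$relations[r, ]
    diffs <- sweep(table$entities, 2, base, `-`)
    sc_t <- rowSums(diffs * diffs)                 # score of every tail candidate
    cand <- ents
    if (filtered) {
      ok <- !(paste(h, r, cand, sep = "\r") %in% truth) | cand == t
      sc <- sc_t[ok]; cd <- cand[ok]
    } else { sc <- sc_t; cd <- cand }
    tr[i] <- sum(sc < sc[cd == t]) + 1L
    base2 <- table$entities[t, ] - table$relations[r, ]
    diffs2 <- sweep(table$entities, 2, base2, `-`)
    sc_h <- rowSums(diffs2 * diffs2)
    if (filtered) {
      ok <- !(paste(cand, r, t, sep = "\r") %in% truth) | cand == h
      sc <- sc_h[ok]; cd <- cand[ok]
    } else { sc <- sc_h; cd <- cand }
    hr[i] <- sum(sc < sc[cd == h]) + 1L
  }
  data.frame(tail_rank = tr, head_rank = hr)
}

#' Average-pool the KG embeddings of a snippet's entities
#'
#' @param entity_ids Character vector of KG entity identifiers (possibly
#'   empty) in mention order, e.g. from [kg_entity_ids()].
#' @param table A `kg_table`.
#' @return Numeric vector of length `table$d`: the arithmetic mean of the
#'   listed entity vectors; the zero vector when no listed entity is
#'   available.  Identifiers absent from the table are skipped with a
#'   warning.
#' @export
pool_entities <- function(entity_ids, table) {
  present <- entity_ids %in% rownames(table$entities)
  if (any(!present)) {
    warning("skipping entity id(s) absent from the embedding table: ",
            paste(unique(entity_ids[!present]), collapse = ", "))
  }
  ids <- entity_ids[present]
  if (length(ids) == 0L) return(numeric(table$d))
  colMeans(table$entities[ids, , drop = FALSE])
}

#' Aggregate two pooled entity vectors into the entity representation
#'
#' Computes `tanh(W_e [eg_a - eg_b ; eg_a * eg_b] + b_e)`: the
#' difference and element-wise product of the two pooled vectors are
#' concatenated, mapped by a weight matrix and bias, and squashed, so
#' every coordinate lies in (-1, 1).
#'
#' @param eg_a,eg_b Pooled entity vectors of equal length d.
#' @param W_e Weight matrix mapping 2d to the output dimension.
#' @param b_e Bias vector of the output dimension.
#' @return Numeric vector in (-1, 1) coordinate-wise.
#' @export
aggregate_entities <- function(eg_a, eg_b, W_e, b_e) {
  if (length(eg_a) != length(eg_b)) stop("pooled vectors differ in dimension")
  x <- c(eg_a - eg_b, eg_a * eg_b)
  if (ncol(W_e) != length(x)) {
    stop("W_e has ", ncol(W_e), " columns but the concatenated input has length ",
         length(x))
  }
  as.numeric(tanh(W_e %*% x + as.numeric(b_e)))
}

#' Write a TransE embedding table to a plain-text file
#'
#' Versioned format: a header line `#transe-table v1 d=<d>`, then one line
#' per entity `E<TAB>id<TAB>v1..vd` and per relation `R<TAB>id<TAB>v1..vd`,
#' values space-separated.
#'
#' @param table A `kg_table`.
#' @param path Output path.
#' @export
write_kg_table <- function(table, path) {
  fmt <- function(M, tag) {
    vapply(seq_len(nrow(M)), function(i)
      paste(tag, rownames(M)[i],
            paste(format(M[i, ], digits = 10, trim = TRUE, scientific = TRUE),
                  collapse = " "), sep = "\t"), "")
  }
  writeLines(c(sprintf("#transe-table v1 d=%d", table$d),
               fmt(table$entities, "E"), fmt(table$relations, "R")), path)
  invisible(path)
}

#' Read a TransE embedding table written by [write_kg_table()]
#' @param path Path to the table file.
#' @return A `kg_table`.
#' @export
read_kg_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1]
  if (!grepl("^#transe-table v1 d=\\d+$", hdr)) stop("unrecognized table header")
  d <- as.integer(sub("^#transe-table v1 d=", "", hdr))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  tag <- vapply(body, `[`, "", 1L)
  ids <- vapply(body, `[`, "", 2L)
  vals <- lapply(body, function(f) as.numeric(strsplit(f[3], " ", fixed = TRUE)[[1]]))
  E <- do.call(rbind, vals[tag == "E"]); rownames(E) <- ids[tag == "E"]
  R <- do.call(rbind, vals[tag == "R"]); rownames(R) <- ids[tag == "R"]
  structure(list(entities = E, relations = R, d = d,
                 margin = NA_real_, lr = NA_real_, epochs = NA_integer_,
                 seed = NA_integer_),
            class = "kg_table")
}
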