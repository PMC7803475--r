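# Entity-level representation I: the two entity-type label sequences are
# embedded (one shared 10-label table, 50-dimensional by default), passed
# through a shared wide convolution (kernel 3, 50 filters) and
# average-pooled to one vector per sequence; the two pooled vectors are
# combined as [u_a - u_b ; u_a * u_b].
#
# The convolution block is linear before pooling: the wide convolution
# (zero padding of kernel-1 on each side, so every input position falls
# under every kernel slot exactly once) is averaged over the *input*
# length and only then passed through a bias and tanh.  This makes the
# pooled vector of a constant label sequence independent of its length
# and keeps both branches exactly symmetric under shared weights.

label_index <- function(labels) {
  idx <- match(labels, entity_types())
  if (anyNA(idx)) stop("unknown entity label: ",
                       paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}

init_bcnn_params <- function(cfg) {
  list(`ent1.emb` = gauss_init(length(entity_types()), cfg$label_dim),
       `ent1.W` = xavier_init(cfg$bcnn_filters, cfg$bcnn_kernel * cfg$label_dim),
       `ent1.b` = matrix(0, cfg$bcnn_filters, 1))
}

# One branch: label id sequence -> pooled vector u (length bcnn_filters).
bcnn_branch_forward <- function(lab_ids, params, cfg) {
  k <- cfg$bcnn_kernel
  dl <- cfg$label_dim
  L <- length(lab_ids)
  if (L == 0L) stop("empty label sequence")
  X <- params[["ent1.emb"]][lab_ids, , drop = FALSE]
  Xp <- rbind(matrix(0, k - 1L, dl), X, matrix(0, k - 1L, dl))
  nw <- L + k - 1L
  # sum of window vectors; each position contributes once per kernel slot
  wsum <- numeric(k * dl)
  for (s in seq_len(k)) {
    wsum[((s - 1L) * dl + 1L):(s * dl)] <- colSums(Xp[s:(s + nw - 1L), , drop = FALSE])
  }
  z <- as.numeric(params[["ent1.W"]] %*% wsum) / L + as.numeric(params[["ent1.b"]])
  u <- tanh(z)
  list(u = u, wsum = wsum, L = L, lab_ids = lab_ids)
}

bcnn_branch_backward <- function(cache, du, params, cfg, gacc) {
  k <- cfg$bcnn_kernel
  dl <- cfg$label_dim
  dz <- du * (1 - tanh_of(cache)^2)
  gacc$`ent1.b` <- gacc$`ent1.b` + matrix(dz, ncol = 1)
  gacc$`ent1.W` <- gacc$`ent1.W` + (dz %o% cache$wsum) / cache$L
  g <- as.numeric(t(params[["ent1.W"]]) %*% dz) / cache$L
  # every position receives the same embedding gradient (sum over slots)
  demb <- numeric(dl)
  for (s in seq_len(k)) demb <- demb + g[((s - 1L) * dl + 1L):(s * dl)]
  for (id in unique(cache$lab_ids)) {
    gacc$`ent1.emb`[id, ] <- gacc$`ent1.emb`[id, ] +
      demb * sum(cache$lab_ids == id)
  }
  invisible()
}

tanh_of <- function(cache) cache$u

#' Entity-type sequence representation of a snippet pair (siamese CNN)
#'
#' Both label sequences run through the same embedding table and
#' convolution (shared weights); the pooled branch vectors `u_a`, `u_b`
#' are combined as `c(u_a - u_b, u_a * u_b)`, the same
#' difference/product comparison used for the knowledge-graph entity
#' representation, giving a vector of length `2 * bcnn_filters`.
#'
#' @param labels_a,labels_b Entity-type label sequences (character vectors
#'   over [entity_types()]).
#' @param params Flat named parameter list holding `ent1.emb`, `ent1.W`,
#'   `ent1.b`.
#' @param cfg Model configuration.
#' @return List with `E` and the two branch caches.
#' @export
bcnn_pair_forward <- function(labels_a, labels_b, params, cfg) {
  ca <- bcnn_branch_forward(label_index(labels_a), params, cfg)
  cb <- bcnn_branch_forward(label_index(labels_b), params, cfg)
  list(E = c(ca$u - cb$u, ca$u * cb$u), ca = ca, cb = cb)
}

bcnn_pair_backward <- function(cache, dE, params, cfg, gacc) {
  nf <- cfg$bcnn_filters
  dd <- dE[seq_len(nf)]
  dp <- dE[nf + seq_len(nf)]
  du_a <- dd + dp * cache$cb$u
  du_b <- -dd + dp * cache$ca$u
  bcnn_branch_backward(cache$ca, du_a, params, cfg, gacc)
  bcnn_branch_backward(cache$cb, du_b, params, cfg, gacc)
  invisible()
}
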