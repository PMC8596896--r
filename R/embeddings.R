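#' Seeded random word embeddings
#'
#' Rows are drawn i.i.d. uniform on `[-0.5/d_e, 0.5/d_e]` (the customary
#' word2vec initialization range); the padding row is all zeros so that
#' padded positions contribute nothing to the convolution.
#'
#' @param vocab A `swam_vocabulary`.
#' @param d_e Embedding dimension.
#' @param seed Integer seed.
#' @return A numeric matrix `|vocab| x d_e` with tokens as row names and
#'   attributes `provenance = "random"` and `seed`.
#' @export
random_embeddings <- function(vocab, d_e, seed = 1L) {
  stopifnot(d_e > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  v <- vocab_size(vocab)
  E <- matrix(runif(v * d_e, -0.5 / d_e, 0.5 / d_e), nrow = v, ncol = d_e)
  E[PAD_ID, ] <- 0
  rownames(E) <- vocab$tokens
  attr(E, "provenance") <- "random"
  attr(E, "seed") <- seed
  E
}

#' Pretrain CBOW word embeddings on an encoded corpus
#'
#' A continuous-bag-of-words model with negative sampling, trained with
#' per-document mini-batch updates (all centers of one document are processed
#' with shared parameters, then the accumulated update is applied).  This
#' keeps training deterministic under a seed and vectorizable; it departs
#' from token-by-token stochastic updates of classic word2vec but optimizes
#' the same objective.  Negative samples follow the usual unigram^(3/4)
#' distribution.  Tokens that never occur in the corpus (or fall below
#' `min_count`) keep their seeded random initialization; the padding row is
#' all zeros.
#'
#' @param docs_ids A list of integer id vectors (encoded documents; pad ids
#'   are ignored if present).
#' @param vocab A `swam_vocabulary`.
#' @param d_e Embedding dimension (default 100).
#' @param window Context window half-width (default 5).
#' @param min_count Minimum corpus frequency for a token to be trained
#'   (default 0: the vocabulary is assumed already frequency-filtered).
#' @param epochs Training epochs (default 5).
#' @param negative Negative samples per center (default 5).
#' @param lr Learning rate (default 0.05, constant).
#' @param seed Integer seed.
#' @return An embedding matrix as in [random_embeddings()], with
#'   `provenance = "pretrained_cbow"`.
#' @export
pretrain_cbow <- function(docs_ids, vocab, d_e = 100, window = 5,
                          min_count = 0, epochs = 5, negative = 5,
                          lr = 0.05, seed = 1L) {
  if (length(docs_ids) == 0) {
    abort("cannot pretrain embeddings on an empty corpus",
          class = "swam_data_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  v <- vocab_size(vocab)
  counts <- tabulate(unlist(docs_ids), nbins = v)
  counts[PAD_ID] <- 0L
  trainable <- counts >= max(min_count, 1L)

  Win <- matrix(runif(v * d_e, -0.5 / d_e, 0.5 / d_e), nrow = v)
  Wout <- matrix(0, nrow = v, ncol = d_e)

  # unigram^0.75 negative-sampling distribution over trainable tokens
  p_neg <- counts^0.75
  p_neg[!trainable] <- 0
  if (sum(p_neg) == 0) abort("no trainable tokens", class = "swam_data_error")
  p_neg <- p_neg / sum(p_neg)
  neg_pool <- which(p_neg > 0)
  p_pool <- p_neg[neg_pool]

  sigm <- function(x) 1 / (1 + exp(-x))

  for (ep in seq_len(epochs)) {
    for (doc in docs_ids) {
      ids <- doc[doc != PAD_ID & trainable[doc]]
      n <- length(ids)
      if (n < 2) next
      Xd <- Win[ids, , drop = FALSE]
      pref <- apply(Xd, 2, cumsum)
      lo <- pmax(seq_len(n) - window, 1L)
      hi <- pmin(seq_len(n) + window, n)
      csum <- pref[hi, , drop = FALSE] -
        rbind(0, pref[-n, , drop = FALSE])[lo, , drop = FALSE] - Xd
      cnt <- hi - lo  # window size minus the center itself
      ok <- cnt > 0
      if (!any(ok)) next
      H <- csum[ok, , drop = FALSE] / cnt[ok]
      ctr <- ids[ok]
      m <- nrow(H)
      negs <- matrix(neg_pool[sample.int(length(neg_pool), m * negative,
                                         replace = TRUE, prob = p_pool)],
                     nrow = m)
      g_pos <- sigm(rowSums(H * Wout[ctr, , drop = FALSE])) - 1
      dH <- g_pos * Wout[ctr, , drop = FALSE]
      out_rows <- c(ctr)
      out_grad <- list(g_pos * H)
      for (j in seq_len(negative)) {
        nj <- negs[, j]
        g_neg <- sigm(rowSums(H * Wout[nj, , drop = FALSE]))
        dH <- dH + g_neg * Wout[nj, , drop = FALSE]
        out_rows <- c(out_rows, nj)
        out_grad[[j + 1]] <- g_neg * H
      }
      dWout <- rowsum(do.call(rbind, out_grad), group = out_rows)
      ridx <- as.integer(rownames(dWout))
      Wout[ridx, ] <- Wout[ridx, ] - lr * dWout

      # spread dH/cnt back over each center's context window via prefix sums
      dcon <- matrix(0, nrow = n, ncol = d_e)
      dcon[ok, ] <- dH / cnt[ok]
      dpref <- apply(dcon, 2, cumsum)
      dX <- dpref[hi, , drop = FALSE] -
        rbind(0, dpref[-n, , drop = FALSE])[lo, , drop = FALSE] - dcon
      dWin <- rowsum(dX, group = ids)
      ridx <- as.integer(rownames(dWin))
      Win[ridx, ] <- Win[ridx, ] - lr * dWin
    }
  }
  Win[PAD_ID, ] <- 0
  rownames(Win) <- vocab$tokens
  attr(Win, "provenance") <- "pretrained_cbow"
  attr(Win, "seed") <- seed
  Win
}

#' Embedding lookup for one document
#'
#' Gathers the embedding rows of a token-id sequence into the input matrix
#' `X` of the convolution, with one column per token position.
#'
#' @param ids Integer vector of token ids (length N).
#' @param embedding Embedding matrix (`|vocab| x d_e`).
#' @return A `d_e x N` numeric matrix.
#' @export
embed_doc <- function(ids, embedding) {
  t(embedding[ids, , drop = FALSE])
}
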