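#' Model configuration
#'
#' Collects the architectural hyperparameters of the shallow wide attention
#' network: a single convolutional layer of `d_c` filters of width `k` over
#' `d_e`-dimensional word embeddings, followed by either a per-label
#' attention layer (one attention distribution over positions per code) or a
#' global max-pooling layer (the textCNN variant), then one linear + sigmoid
#' classifier per code.
#'
#' @param k Filter width in tokens (default 4, the tuned optimum).
#' @param d_c Number of convolution filters (default 500, the tuned optimum;
#'   width is the point of the architecture).
#' @param d_e Embedding dimension (default 100).
#' @param n_labels Number of codes `|L|`.
#' @param activation `"tanh"` (default) or `"relu"`.
#' @param attention `"per_label"` (default) or `"max_pool"`.
#' @param dropout Dropout probability on the embedded input (default 0.2).
#' @param threshold Decision threshold on predicted probabilities
#'   (default 0.5).
#' @return A `swam_config` list.
#' @export
swam_config <- function(k = 4, d_c = 500, d_e = 100, n_labels,
                        activation = c("tanh", "relu"),
                        attention = c("per_label", "max_pool"),
                        dropout = 0.2, threshold = 0.5) {
  activation <- match.arg(activation)
  attention <- match.arg(attention)
  stopifnot(k >= 1, d_c >= 1, d_e >= 1, n_labels >= 1,
            dropout >= 0, dropout < 1, threshold > 0, threshold < 1)
  structure(
    list(k = as.integer(k), d_c = as.integer(d_c), d_e = as.integer(d_e),
         n_labels = as.integer(n_labels), activation = activation,
         attention = attention, dropout = dropout, threshold = threshold),
    class = "swam_config"
  )
}

#' @export
print.swam_config <- function(x, ...) {
  cat(sprintf(
    "<swam_config> k=%d d_c=%d d_e=%d labels=%d %s/%s dropout=%.2f\n",
    x$k, x$d_c, x$d_e, x$n_labels, x$activation, x$attention, x$dropout))
  invisible(x)
}

# convolution padding: pl zeros on the left, pr on the right, so that the
# base representation keeps the document length for every filter width
conv_pad <- function(k) {
  list(left = (k - 1L) %/% 2L, right = k %/% 2L)
}

#' Initialize model parameters
#'
#' Convolution filters, attention vectors and output weights are drawn from
#' symmetric uniform ranges scaled by fan-in; biases start at zero.
#'
#' @param config A [swam_config()].
#' @param embedding Embedding matrix (`|vocab| x d_e`), copied into the
#'   parameter set (it is fine-tuned during training unless frozen).
#' @param seed Integer seed.
#' @return A `swam_params` list: `E` (vocab x d_e), `W` (`(k*d_e) x d_c`,
#'   rows grouped by window offset), `b_c` (d_c), `U` (d_c x L attention
#'   vectors; `NULL` for the max-pool variant), `B` (d_c x L output weights),
#'   `b` (L offsets).
#' @export
swam_init_params <- function(config, embedding, seed = 1L) {
  stopifnot(ncol(embedding) == config$d_e)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  kde <- config$k * config$d_e
  r_conv <- sqrt(6 / kde)
  r_att <- sqrt(6 / config$d_c)
  params <- list(
    E = unclass_embedding(embedding),
    W = matrix(runif(kde * config$d_c, -r_conv, r_conv), nrow = kde),
    b_c = rep(0, config$d_c),
    U = if (config$attention == "per_label")
      matrix(runif(config$d_c * config$n_labels, -r_att, r_att),
             nrow = config$d_c)
    else NULL,
    B = matrix(runif(config$d_c * config$n_labels, -r_att, r_att),
               nrow = config$d_c),
    b = rep(0, config$n_labels)
  )
  structure(params, class = "swam_params", config = config, seed = seed)
}

unclass_embedding <- function(E) {
  rn <- rownames(E)
  E <- matrix(as.numeric(E), nrow = nrow(E))
  rownames(E) <- rn
  E
}

# W stored as (k*d_e) x d_c; as_filter_array exposes the k x d_e x d_c view
as_filter_array <- function(W, k, d_e) {
  array(aperm(array(W, dim = c(d_e, k, ncol(W))), c(2, 1, 3)),
        dim = c(k, d_e, ncol(W)))
}

as_filter_matrix <- function(W_arr) {
  k <- dim(W_arr)[1]; d_e <- dim(W_arr)[2]; d_c <- dim(W_arr)[3]
  matrix(aperm(W_arr, c(2, 1, 3)), nrow = k * d_e, ncol = d_c)
}

activate <- function(Z, activation) {
  if (activation == "tanh") tanh(Z) else pmax(Z, 0)
}

#' Convolutional layer over a document
#'
#' Computes the base representation `H`: at each position n the filters see
#' the window of `k` adjacent embeddings, the document being zero-padded on
#' both sides so `H` keeps the same number of columns as `X` (for even `k`
#' the padding is one column heavier on the right).
#'
#' @param X Input matrix `d_e x N` (one column per token position).
#' @param W_c Filter tensor `k x d_e x d_c`.
#' @param b_c Bias vector of length `d_c`.
#' @param activation `"tanh"`, `"relu"` or `"identity"`.
#' @return The base representation `H`, a `d_c x N` matrix.
#' @export
conv_forward <- function(X, W_c, b_c, activation = "tanh") {
  stopifnot(is.matrix(X), ncol(X) >= 1)
  if (!all(is.finite(X))) abort("non-finite input to conv_forward",
                                class = "swam_numeric_error")
  k <- dim(W_c)[1]; d_e <- dim(W_c)[2]; d_c <- dim(W_c)[3]
  stopifnot(nrow(X) == d_e, length(b_c) == d_c)
  n <- ncol(X)
  pad <- conv_pad(k)
  Xp <- cbind(matrix(0, d_e, pad$left), X, matrix(0, d_e, pad$right))
  Z <- matrix(rep(b_c, n), nrow = n, byrow = TRUE)
  Xt <- t(Xp)  # (n + k - 1) x d_e
  for (t in seq_len(k)) {
    Wt <- matrix(W_c[t, , ], nrow = d_e, ncol = d_c)
    Z <- Z + Xt[t:(t + n - 1), , drop = FALSE] %*% Wt
  }
  if (activation == "identity") t(Z) else t(activate(Z, activation))
}

#' Per-label attention over document positions
#'
#' Projects the base representation onto a label's attention vector and
#' normalizes with a numerically stable (max-shifted) softmax.  Masked
#' positions (document padding in a batch) are excluded: they receive weight
#' exactly zero.
#'
#' @param H Base representation `d_c x N`.
#' @param u Attention vector of length `d_c` for one label.
#' @param mask Optional logical/0-1 vector of length N; `FALSE`/0 marks
#'   padded positions.
#' @return The attention vector `alpha`, length N, summing to 1 over
#'   unmasked positions.
#' @export
perlabel_attention <- function(H, u, mask = NULL) {
  stopifnot(is.matrix(H), length(u) == nrow(H))
  n <- ncol(H)
  s <- as.vector(crossprod(H, u))
  keep <- if (is.null(mask)) rep(TRUE, n) else as.logical(mask)
  if (!any(keep)) abort("all positions masked", class = "swam_data_error")
  alpha <- numeric(n)
  sk <- s[keep]
  e <- exp(sk - max(sk))
  alpha[keep] <- e / sum(e)
  alpha
}

#' Attention pooling of the base representation
#'
#' The per-label document representation is the attention-weighted sum of
#' the base representation's columns.
#'
#' @param H Base representation `d_c x N`.
#' @param alpha Attention weights of length N (on the simplex).
#' @return A vector of length `d_c`.
#' @export
attend_pool <- function(H, alpha) {
  if (length(alpha) != ncol(H)) {
    abort("attention length does not match document length",
          class = "swam_shape_error")
  }
  as.vector(H %*% alpha)
}

#' Global max-pooling of the base representation
#'
#' The textCNN-style pooling: each filter contributes its maximum activation
#' over unmasked positions.  The argmax position of each filter is recorded
#' (ties broken by earliest position) so the pooled feature can be traced
#' back to a text window.
#'
#' @param H Base representation `d_c x N`.
#' @param mask Optional logical/0-1 vector of length N.
#' @return A list with `v` (length `d_c`) and `argmax` (length `d_c`,
#'   1-based positions in the document).
#' @export
max_pool <- function(H, mask = NULL) {
  n <- ncol(H)
  keep <- if (is.null(mask)) rep(TRUE, n) else as.logical(mask)
  if (!any(keep)) abort("all positions masked", class = "swam_data_error")
  Hk <- H[, keep, drop = FALSE]
  am_local <- max.col(Hk, ties.method = "first")
  v <- Hk[cbind(seq_len(nrow(H)), am_local)]
  list(v = v, argmax = which(keep)[am_local])
}

#' Per-label classification
#'
#' @param v Document representation of length `d_c` (per-label under
#'   attention pooling, shared under max pooling).
#' @param beta Output weight vector of length `d_c`.
#' @param b Scalar offset.
#' @return The predicted probability, a scalar in (0,1).
#' @export
classify <- function(v, beta, b) {
  plogis(sum(beta * v) + b)
}

#' Binary cross-entropy over the label set
#'
#' Summed over labels; batching code averages over documents.  Predicted
#' probabilities are clamped away from 0 and 1 at a machine-epsilon margin
#' (with a warning) so the loss stays finite.
#'
#' @param yhat Predicted probabilities (vector over labels).
#' @param y Binary ground-truth vector of the same length.
#' @return A non-negative scalar.
#' @export
bce_loss <- function(yhat, y) {
  stopifnot(length(yhat) == length(y))
  eps <- .Machine$double.eps
  if (any(yhat <= 0 | yhat >= 1)) {
    warn("probabilities clamped to the open unit interval for the loss")
    yhat <- pmin(pmax(yhat, eps), 1 - eps)
  }
  -sum(y * log(yhat) + (1 - y) * log(1 - yhat))
}

#' Full forward pass over one document
#'
#' Composes embedding lookup, (optional) dropout on the embedded input,
#' convolution, the configured pooling variant and per-label classification,
#' returning every intermediate needed for both prediction and snippet
#' explanation.
#'
#' @param ids Integer token-id vector (an encoded document).
#' @param params A `swam_params` object.
#' @param config A [swam_config()].
#' @param training If `TRUE`, applies dropout to the embedded input (draws
#'   from the current RNG stream).
#' @return A `swam_forward` list: `X` (d_e x N), `H` (d_c x N), `A` (L x N
#'   attention matrix for the per-label variant, `NULL` for max pooling,
#'   which instead records the per-filter `argmax` positions), `V`
#'   (d_c x L), `yhat` (length L).
#' @export
swam_forward <- function(ids, params, config, training = FALSE) {
  stopifnot(length(ids) >= 1)
  X <- embed_doc(ids, params$E)
  if (training && config$dropout > 0) {
    m <- matrix(rbinom(length(X), 1, 1 - config$dropout), nrow = nrow(X))
    X <- X * m / (1 - config$dropout)
  }
  mask <- ids != PAD_ID
  if (!any(mask)) abort("document consists only of padding",
                        class = "swam_data_error")
  W_arr <- as_filter_array(params$W, config$k, config$d_e)
  H <- conv_forward(X, W_arr, params$b_c, activation = config$activation)
  L <- config$n_labels
  n <- ncol(H)
  V <- matrix(0, nrow = config$d_c, ncol = L)
  A <- NULL
  argmax <- NULL
  if (config$attention == "per_label") {
    A <- matrix(0, nrow = L, ncol = n)
    for (l in seq_len(L)) {
      a <- perlabel_attention(H, params$U[, l], mask = mask)
      A[l, ] <- a
      V[, l] <- attend_pool(H, a)
    }
  } else {
    mp <- max_pool(H, mask = mask)
    V[] <- mp$v
    argmax <- mp$argmax
  }
  yhat <- vapply(seq_len(L), function(l) classify(V[, l], params$B[, l],
                                                  params$b[l]), numeric(1))
  structure(list(X = X, H = H, A = A, V = V, yhat = yhat,
                 argmax = argmax, mask = mask),
            class = "swam_forward")
}
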