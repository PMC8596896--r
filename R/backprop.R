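# Batched forward/backward for the shallow wide attention network.
#
# Layout: documents in a batch are padded to the batch maximum length and
# stacked.  The stacked input matrix reserves k-1 zero rows around each
# document so every convolution window that leaves a document reads zeros,
# which is exactly the zero-padding contract that keeps H the same length as
# X.  The convolution (forward, filter gradient, input gradient) then runs as
# k shifted BLAS matrix products over the whole batch; the attention /
# pooling / classification head is cheap and runs per document.

batch_layout <- function(batch_ids, k) {
  lens <- lengths(batch_ids)
  maxlen <- max(lens)
  pad <- conv_pad(k)
  blockh <- maxlen + k - 1L
  nb <- length(batch_ids)
  tok_rows <- unlist(lapply(seq_len(nb), function(i) {
    (i - 1L) * blockh + pad$left + seq_len(lens[i])
  }))
  out_base <- rep((seq_len(nb) - 1L) * blockh, each = maxlen) +
    rep(seq_len(maxlen), nb)
  list(lens = lens, maxlen = maxlen, blockh = blockh, nb = nb,
       tok_rows = tok_rows, out_base = out_base, pad = pad)
}

# Forward pass for a batch; returns caches when `keep` is TRUE.
swam_batch_forward <- function(batch_ids, params, config, training = FALSE,
                               keep = FALSE) {
  k <- config$k; d_e <- config$d_e; d_c <- config$d_c; L <- config$n_labels
  lay <- batch_layout(batch_ids, k)
  allids <- unlist(batch_ids)
  Xtok <- params$E[allids, , drop = FALSE]
  drop_mask <- NULL
  if (training && config$dropout > 0) {
    drop_mask <- matrix(rbinom(length(Xtok), 1, 1 - config$dropout),
                        nrow = nrow(Xtok)) / (1 - config$dropout)
    Xtok <- Xtok * drop_mask
  }
  Xpad <- matrix(0, nrow = lay$nb * lay$blockh, ncol = d_e)
  Xpad[lay$tok_rows, ] <- Xtok

  Z <- matrix(rep(params$b_c, each = lay$nb * lay$maxlen),
              nrow = lay$nb * lay$maxlen)
  for (t in seq_len(k)) {
    rows <- ((t - 1L) * d_e + 1L):(t * d_e)
    Z <- Z + Xpad[lay$out_base + (t - 1L), , drop = FALSE] %*%
      params$W[rows, , drop = FALSE]
  }
  H <- activate(Z, config$activation)

  yhat <- matrix(NA_real_, nrow = lay$nb, ncol = L)
  head_cache <- if (keep) vector("list", lay$nb) else NULL
  for (i in seq_len(lay$nb)) {
    r <- (i - 1L) * lay$maxlen + seq_len(lay$lens[i])
    Hd <- H[r, , drop = FALSE]
    if (config$attention == "per_label") {
      S <- Hd %*% params$U
      cm <- apply(S, 2, max)
      Eo <- exp(sweep(S, 2, cm, "-"))
      A <- sweep(Eo, 2, colSums(Eo), "/")
      V <- crossprod(Hd, A)
      cache <- list(A = A, V = V)
    } else {
      am <- max.col(t(Hd), ties.method = "first")
      V <- matrix(Hd[cbind(am, seq_len(d_c))], nrow = d_c, ncol = L)
      cache <- list(am = am, V = V)
    }
    logits <- colSums(V * params$B) + params$b
    yhat[i, ] <- plogis(logits)
    if (keep) head_cache[[i]] <- cache
  }
  res <- list(yhat = yhat)
  if (keep) {
    res$lay <- lay; res$allids <- allids; res$Xpad <- Xpad
    res$Z <- Z; res$H <- H; res$head <- head_cache
    res$drop_mask <- drop_mask
  }
  res
}

# Mean-over-batch BCE loss, no gradients (used by the finite-difference
# checks and validation).
swam_batch_loss <- function(params, batch_ids, Y, config) {
  fw <- swam_batch_forward(batch_ids, params, config, training = FALSE)
  eps <- 1e-12
  yh <- pmin(pmax(fw$yhat, eps), 1 - eps)
  -sum(Y * log(yh) + (1 - Y) * log(1 - yh)) / length(batch_ids)
}

# Loss and analytic gradients for one batch (mean over the batch of the
# label-summed BCE).  `training` enables dropout on the embedded input.
swam_batch_grad <- function(params, batch_ids, Y, config, training = FALSE) {
  k <- config$k; d_e <- config$d_e; d_c <- config$d_c; L <- config$n_labels
  fw <- swam_batch_forward(batch_ids, params, config, training = training,
                           keep = TRUE)
  lay <- fw$lay
  nb <- lay$nb
  eps <- 1e-12
  yh <- pmin(pmax(fw$yhat, eps), 1 - eps)
  loss <- -sum(Y * log(yh) + (1 - Y) * log(1 - yh)) / nb

  dH <- matrix(0, nrow = nrow(fw$H), ncol = d_c)
  gU <- if (!is.null(params$U)) matrix(0, d_c, L) else NULL
  gB <- matrix(0, d_c, L)
  gb <- numeric(L)
  per_label <- config$attention == "per_label"
  for (i in seq_len(nb)) {
    r <- (i - 1L) * lay$maxlen + seq_len(lay$lens[i])
    Hd <- fw$H[r, , drop = FALSE]
    cache <- fw$head[[i]]
    dlog <- fw$yhat[i, ] - Y[i, ]
    gB <- gB + sweep(cache$V, 2, dlog, "*")
    gb <- gb + dlog
    if (per_label) {
      dV <- sweep(params$B, 2, dlog, "*")
      A <- cache$A
      dA <- Hd %*% dV
      dHd <- A %*% t(dV)
      dS <- A * sweep(dA, 2, colSums(A * dA), "-")
      gU <- gU + crossprod(Hd, dS)
      dHd <- dHd + dS %*% t(params$U)
      dH[r, ] <- dHd
    } else {
      dv <- as.vector(params$B %*% dlog)
      dHd <- matrix(0, nrow = length(r), ncol = d_c)
      dHd[cbind(cache$am, seq_len(d_c))] <- dv
      dH[r, ] <- dHd
    }
  }

  dZ <- if (config$activation == "tanh") dH * (1 - fw$H^2) else dH * (fw$Z > 0)
  gb_c <- colSums(dZ)
  gW <- matrix(0, nrow = k * d_e, ncol = d_c)
  dXpad <- matrix(0, nrow = nrow(fw$Xpad), ncol = d_e)
  for (t in seq_len(k)) {
    rows <- ((t - 1L) * d_e + 1L):(t * d_e)
    idx <- lay$out_base + (t - 1L)
    Xg <- fw$Xpad[idx, , drop = FALSE]
    gW[rows, ] <- crossprod(Xg, dZ)
    dXpad[idx, ] <- dXpad[idx, ] + dZ %*% t(params$W[rows, , drop = FALSE])
  }
  dXtok <- dXpad[lay$tok_rows, , drop = FALSE]
  if (!is.null(fw$drop_mask)) dXtok <- dXtok * fw$drop_mask
  agg <- rowsum(dXtok, group = fw$allids)
  gE <- matrix(0, nrow = nrow(params$E), ncol = d_e)
  gE[as.integer(rownames(agg)), ] <- agg
  gE[PAD_ID, ] <- 0  # padding embedding stays fixed at zero

  grads <- list(E = gE / nb, W = gW / nb, b_c = gb_c / nb,
                U = if (per_label) gU / nb else NULL,
                B = gB / nb, b = gb / nb)
  list(loss = loss, grads = grads, yhat = fw$yhat)
}

# Predicted probabilities for a list of encoded documents, in batches.
swam_predict_ids <- function(docs_ids, params, config, batch_size = 64L) {
  n <- length(docs_ids)
  out <- matrix(NA_real_, nrow = n, ncol = config$n_labels)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1L, n)
    out[s:e, ] <- swam_batch_forward(docs_ids[s:e], params, config)$yhat
  }
  out
}
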