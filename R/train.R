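#' Training configuration
#'
#' @param lr Learning rate for the Adam optimizer (default 0.001, the tuned
#'   optimum).
#' @param batch_size Mini-batch size (default 16).
#' @param max_epochs Hard cap on epochs (default 200; early stopping usually
#'   fires first).
#' @param patience Early-stopping patience: training stops when validation
#'   macro-F1 fails to improve for this many consecutive epochs (default 10).
#'   "Improve" means strictly greater.
#' @param data_seed Seed controlling the per-epoch shuffling of training
#'   documents (and dropout draws).
#' @param param_seed Seed for parameter initialization.
#' @param freeze_embeddings If `TRUE`, the embedding matrix is not updated.
#' @return A `swam_train_config` list.
#' @export
swam_train_config <- function(lr = 0.001, batch_size = 16, max_epochs = 200,
                              patience = 10, data_seed = 1L, param_seed = 1L,
                              freeze_embeddings = FALSE) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(
    list(lr = lr, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         data_seed = as.integer(data_seed), param_seed = as.integer(param_seed),
         freeze_embeddings = freeze_embeddings),
    class = "swam_train_config"
  )
}

# Early-stopping state machine: strictly-greater improvements reset the
# counter; `stop` turns TRUE once `patience` consecutive epochs fail.
es_init <- function(patience) {
  list(best = -Inf, best_epoch = 0L, since = 0L, patience = patience,
       stop = FALSE)
}

es_update <- function(state, epoch, value) {
  if (value > state$best) {
    state$best <- value
    state$best_epoch <- epoch
    state$since <- 0L
  } else {
    state$since <- state$since + 1L
  }
  state$stop <- state$since >= state$patience
  state
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) NULL else list(m = p * 0, v = p * 0)
  })
}

adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8, skip = NULL) {
  for (nm in names(params)) {
    if (is.null(params[[nm]]) || nm %in% skip) next
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

dataset_split_ids <- function(dataset, split) {
  sel <- dataset$docs$split == split
  list(ids = dataset$docs$token_ids[sel],
       labels = dataset$labels[sel, , drop = FALSE],
       doc_id = dataset$docs$doc_id[sel])
}

# Macro-F1 over a decision matrix, zero-denominator convention = 0.
f1_macro_fast <- function(decisions, truth) {
  tp <- colSums(decisions == 1 & truth == 1)
  fp <- colSums(decisions == 1 & truth == 0)
  fn <- colSums(decisions == 0 & truth == 1)
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  mean(f)
}

#' Train a shallow wide attention model
#'
#' Minimizes the label-summed binary cross-entropy by mini-batch Adam,
#' evaluating validation macro-F1 (decisions at the configured threshold)
#' after every epoch and stopping early when it fails to improve for
#' `patience` consecutive epochs.  The returned parameters are those of the
#' best validation epoch.  The run is deterministic given the two seeds and
#' single-threaded numerics.
#'
#' @param dataset A `swam_dataset` (see [prepare_dataset()]) with non-empty
#'   train and validation splits.
#' @param embedding Initial embedding matrix (`|vocab| x d_e`), e.g. from
#'   [pretrain_cbow()] or [random_embeddings()].
#' @param model_config A [swam_config()]; its `n_labels` and `d_e` must match
#'   the dataset and embedding.
#' @param train_config A [swam_train_config()].
#' @param verbose Print one line per epoch.
#' @return A `swam_fit`: `params` (best epoch), `model_config`,
#'   `train_config`, `log` (tibble: epoch, train_loss, val_f1_macro,
#'   seconds), `best_epoch`, `stop_reason` (`"patience_exhausted"` or
#'   `"max_epochs"`), plus the dataset's `vocab` and `label_space`.
#' @export
swam_train <- function(dataset, embedding, model_config, train_config,
                       verbose = FALSE) {
  tr <- dataset_split_ids(dataset, "train")
  va <- dataset_split_ids(dataset, "valid")
  if (length(tr$ids) == 0 || length(va$ids) == 0) {
    abort("train and validation splits must be non-empty",
          class = "swam_data_error")
  }
  stopifnot(model_config$n_labels == ncol(dataset$labels),
            model_config$d_e == ncol(embedding))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  params <- swam_init_params(model_config, embedding,
                             seed = train_config$param_seed)
  opt <- adam_init(params)
  skip <- if (train_config$freeze_embeddings) "E" else NULL
  es <- es_init(train_config$patience)
  best_params <- params
  log <- vector("list", train_config$max_epochs)
  step <- 0L
  stop_reason <- "max_epochs"
  n_tr <- length(tr$ids)

  for (epoch in seq_len(train_config$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    set.seed((train_config$data_seed %% 100000L) * 10000L + epoch)
    perm <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = train_config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      sel <- perm[s:min(s + train_config$batch_size - 1L, n_tr)]
      bg <- swam_batch_grad(params, tr$ids[sel],
                            tr$labels[sel, , drop = FALSE],
                            model_config, training = TRUE)
      if (!is.finite(bg$loss)) {
        abort(sprintf("training diverged (non-finite loss at epoch %d)", epoch),
              class = "swam_numeric_error")
      }
      epoch_loss <- epoch_loss + bg$loss * length(sel)
      step <- step + 1L
      upd <- adam_step(params, bg$grads, opt, step, train_config$lr,
                       skip = skip)
      params <- upd$params
      opt <- upd$state
    }
    epoch_loss <- epoch_loss / n_tr
    val_scores <- swam_predict_ids(va$ids, params, model_config)
    val_dec <- (val_scores >= model_config$threshold) * 1L
    val_f1 <- f1_macro_fast(val_dec, va$labels)
    es <- es_update(es, epoch, val_f1)
    if (es$best_epoch == epoch) best_params <- params
    secs <- proc.time()[["elapsed"]] - t0
    log[[epoch]] <- tibble(epoch = epoch, train_loss = epoch_loss,
                           val_f1_macro = val_f1, seconds = secs)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val macro-F1 %.4f  (%.1fs)",
                      epoch, epoch_loss, val_f1, secs))
    }
    if (es$stop) {
      stop_reason <- "patience_exhausted"
      break
    }
  }

  structure(
    list(params = best_params, model_config = model_config,
         train_config = train_config,
         log = bind_rows(log[!vapply(log, is.null, logical(1))]),
         best_epoch = es$best_epoch, best_val_f1 = es$best,
         stop_reason = stop_reason,
         vocab = dataset$vocab, label_space = dataset$label_space),
    class = "swam_fit"
  )
}

#' @export
print.swam_fit <- function(x, ...) {
  cat(sprintf(
    "<swam_fit> %s/%s d_c=%d k=%d | best epoch %d (val macro-F1 %.3f), %s after %d epochs\n",
    x$model_config$activation, x$model_config$attention, x$model_config$d_c,
    x$model_config$k, x$best_epoch, x$best_val_f1, x$stop_reason,
    nrow(x$log)))
  invisible(x)
}

#' Predicted probabilities for one split of a dataset
#'
#' @param fit A `swam_fit`.
#' @param dataset A `swam_dataset` preprocessed with the same vocabulary and
#'   label space.
#' @param split `"test"` (default), `"valid"` or `"train"`.
#' @return A numeric matrix, documents by codes, with dimnames.
#' @export
predict_matrix <- function(fit, dataset, split = "test") {
  part <- dataset_split_ids(dataset, split)
  scores <- swam_predict_ids(part$ids, fit$params, fit$model_config)
  dimnames(scores) <- list(part$doc_id, fit$label_space$codes)
  scores
}

#' @describeIn swam_train Tidy per-document predictions: a long tibble with
#'   `doc_id`, `code`, `score` and `decision` at the configured threshold.
#' @param object,newdata,... A `swam_fit`, a `swam_dataset`, and unused
#'   arguments (the split is passed as `split`).
#' @param split Which split of `newdata` to score.
#' @export
predict.swam_fit <- function(object, newdata, split = "test", ...) {
  scores <- predict_matrix(object, newdata, split = split)
  tibble(
    doc_id = rep(rownames(scores), times = ncol(scores)),
    code = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores),
    decision = as.integer(as.vector(scores) >= object$model_config$threshold)
  ) |> arrange(.data$doc_id, .data$code)
}

#' @export
tidy.swam_fit <- function(x, ...) x$log

#' @export
glance.swam_fit <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) if (is.null(p)) 0L else length(p),
                      integer(1)))
  tibble(
    epochs_run = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_f1_macro = x$best_val_f1,
    stop_reason = x$stop_reason,
    n_parameters = n_par,
    d_c = x$model_config$d_c,
    k = x$model_config$k,
    attention = x$model_config$attention
  )
}

#' @export
autoplot.swam_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_f1_macro"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training loss and validation macro-F1") +
    ggplot2::theme_minimal()
}

#' Grid search over the tuning ranges
#'
#' Trains one model per grid point (all seeds held fixed across points so
#' points differ only in the tuned values) and ranks configurations by
#' validation macro-F1.
#'
#' @param dataset A `swam_dataset`.
#' @param embedding_fn A function `d_e -> embedding matrix` (the embedding
#'   depends on `d_e`, which may be constant over the grid); or a single
#'   embedding matrix if `d_e` is not tuned.
#' @param grid A named list of vectors over any of `lr`, `k`, `d_c`,
#'   `dropout`; the full tuning ranges are available as
#'   [swam_default_grid()].
#' @param model_config,train_config Base configurations supplying every
#'   field not in the grid.
#' @param verbose Print one line per grid point.
#' @return A tibble with one row per configuration (`lr`, `k`, `d_c`,
#'   `dropout`, `val_f1_macro`, `best_epoch`), sorted by `val_f1_macro`
#'   descending; the fitted best model is attached as attribute `best_fit`.
#' @export
grid_search <- function(dataset, embedding_fn, grid, model_config,
                        train_config, verbose = FALSE) {
  defaults <- list(lr = train_config$lr, k = model_config$k,
                   d_c = model_config$d_c, dropout = model_config$dropout)
  grid <- modifyList(defaults, grid)
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  get_emb <- if (is.function(embedding_fn)) embedding_fn else {
    force(embedding_fn); function(d_e) embedding_fn
  }
  rows <- vector("list", nrow(cells))
  best <- NULL; best_f1 <- -Inf
  for (i in seq_len(nrow(cells))) {
    mc <- model_config
    mc$k <- as.integer(cells$k[i]); mc$d_c <- as.integer(cells$d_c[i])
    mc$dropout <- cells$dropout[i]
    tc <- train_config
    tc$lr <- cells$lr[i]
    fit <- swam_train(dataset, get_emb(mc$d_e), mc, tc)
    rows[[i]] <- tibble(lr = tc$lr, k = mc$k, d_c = mc$d_c,
                        dropout = mc$dropout,
                        val_f1_macro = fit$best_val_f1,
                        best_epoch = fit$best_epoch)
    if (fit$best_val_f1 > best_f1) { best_f1 <- fit$best_val_f1; best <- fit }
    if (verbose) {
      message(sprintf("grid %d/%d: lr=%g k=%d d_c=%d q=%.1f -> %.4f",
                      i, nrow(cells), tc$lr, mc$k, mc$d_c, mc$dropout,
                      fit$best_val_f1))
    }
  }
  out <- bind_rows(rows) |> arrange(desc(.data$val_f1_macro))
  attr(out, "best_fit") <- best
  out
}

#' The published tuning ranges
#'
#' Learning rate in \{1e-4, 3e-4, 1e-3, 3e-3\}, filter width 1..10, filter
#' count 50..500 in steps of 50, dropout 0.2..0.8; the tuned optima are
#' lr = 0.001, k = 4, d_c = 500, dropout = 0.2.
#'
#' @return A named list of vectors suitable for [grid_search()].
#' @export
swam_default_grid <- function() {
  list(lr = c(1e-4, 3e-4, 1e-3, 3e-3),
       k = 1:10,
       d_c = seq(50L, 500L, by = 50L),
       dropout = seq(0.2, 0.8, by = 0.1))
}

#' Retrain with a different data-order seed
#'
#' Re-runs training with an identical configuration except for the seed that
#' controls the order training documents are visited in, which is the lever
#' behind the data-shuffle experiment: a capacity-starved model converges to
#' a different local optimum, abandoning a different subset of labels.
#'
#' @param dataset,embedding,model_config,train_config As in [swam_train()].
#' @param data_seed The new data-order seed.
#' @return A `swam_fit`.
#' @export
reshuffle_and_retrain <- function(dataset, embedding, model_config,
                                  train_config, data_seed) {
  train_config$data_seed <- as.integer(data_seed)
  swam_train(dataset, embedding, model_config, train_config)
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single-file archive of the model configuration and
#' all named parameter tensors together with the vocabulary and label space;
#' reloading reproduces the fit bit-exactly.
#'
#' @param fit A `swam_fit`.
#' @param path File path.
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` the restored `swam_fit`.
#' @export
write_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)
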