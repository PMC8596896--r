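#' Extract the most informative snippet for one (document, code) pair
#'
#' Under per-label attention the most informative location is the argmax of
#' the label's attention vector (ties broken by earliest position); the
#' snippet is the k-token convolution window anchored there, offset
#' `floor((k-1)/2)` to the left to mirror the convolution padding and
#' clipped at the document edges.  Under max pooling, which weighs input
#' without an explicit attention vector, the location is the pooled argmax
#' of the most influential filter — the filter with the largest
#' `|beta_lj * v_j|` contribution to the label's logit — and the reported
#' weight is that filter's share of the total absolute contribution.
#'
#' @param state A `swam_forward` (see [swam_forward()]).
#' @param tokens Character vector: the document's tokens, aligned with the
#'   encoded ids the state was computed from (truncated identically).
#' @param label Label index (1-based) of the code to explain.
#' @param config The [swam_config()] used for the forward pass.
#' @param beta The label's output weight vector (length `d_c`); required for
#'   the max-pool variant, ignored under per-label attention.
#' @return A one-row tibble: `label` (the 1-based index; callers with a
#'   label space substitute the code string), `snippet`, `center` (0-based
#'   token index), `weight`, `score`.
#' @export
extract_snippet <- function(state, tokens, label, config, beta = NULL) {
  n <- length(tokens)
  if (config$attention == "per_label") {
    a <- state$A[label, ]
    pos <- which.max(a)  # ties: earliest
    weight <- a[pos]
  } else {
    if (is.null(beta)) {
      abort("the max-pool variant needs the label's output weights `beta`",
            class = "swam_shape_error")
    }
    contrib <- abs(beta * state$V[, label])
    jstar <- which.max(contrib)
    pos <- state$argmax[jstar]
    weight <- contrib[jstar] / max(sum(contrib), .Machine$double.eps)
  }
  window <- snippet_window(pos, config$k, n)
  tibble(label = as.integer(label),
         snippet = paste(tokens[window], collapse = " "),
         center = pos - 1L, weight = unname(weight),
         score = state$yhat[label])
}

# k-token window anchored at `pos`, left offset floor((k-1)/2), clipped.
snippet_window <- function(pos, k, n) {
  if (n <= k) return(seq_len(n))
  pad <- conv_pad(k)
  lo <- pos - pad$left
  hi <- pos + pad$right
  if (lo < 1) { hi <- hi + (1 - lo); lo <- 1 }
  if (hi > n) { lo <- lo - (hi - n); hi <- n }
  lo:hi
}

#' Snippet explanations for a fitted model
#'
#' Runs the forward pass over the requested documents and extracts, for each
#' (document, code) pair, the snippet whose attention weight drove the
#' prediction.  By default only codes predicted positive (score at or above
#' the decision threshold) are explained.
#'
#' @param fit A `swam_fit`.
#' @param dataset A `swam_dataset`.
#' @param split Which split to explain (default `"test"`).
#' @param doc_ids Optional character vector restricting the documents.
#' @param codes Optional character vector restricting the codes; `NULL`
#'   (default) explains predicted-positive codes only; `"all"` explains
#'   every code.
#' @return A tibble: `doc_id`, `code`, `snippet`, `center` (0-based token
#'   index in the truncated document), `weight` (attention weight at the
#'   center), `score`.
#' @export
extract_snippets <- function(fit, dataset, split = "test", doc_ids = NULL,
                             codes = NULL) {
  sel <- dataset$docs$split == split
  if (!is.null(doc_ids)) sel <- sel & dataset$docs$doc_id %in% doc_ids
  docs <- dataset$docs[sel, ]
  cfg <- fit$model_config
  all_codes <- fit$label_space$codes
  rows <- list()
  for (i in seq_len(nrow(docs))) {
    ids <- docs$token_ids[[i]]
    tokens <- decode_doc(ids, dataset$vocab)
    st <- swam_forward(ids, fit$params, cfg)
    labs <- if (is.null(codes)) {
      which(st$yhat >= cfg$threshold)
    } else if (identical(codes, "all")) {
      seq_along(all_codes)
    } else {
      match(codes, all_codes)
    }
    for (l in labs) {
      if (cfg$attention == "per_label") {
        a <- st$A[l, ]
        pos <- which.max(a)
        weight <- a[pos]
      } else {
        contrib <- abs(fit$params$B[, l] * st$V[, l])
        jstar <- which.max(contrib)
        pos <- st$argmax[jstar]
        weight <- contrib[jstar] / max(sum(contrib), .Machine$double.eps)
      }
      window <- snippet_window(pos, cfg$k, length(tokens))
      rows[[length(rows) + 1L]] <- tibble(
        doc_id = docs$doc_id[i], code = all_codes[l],
        snippet = paste(tokens[window], collapse = " "),
        center = pos - 1L, weight = unname(weight),
        score = st$yhat[l])
    }
  }
  if (length(rows) == 0) {
    return(tibble(doc_id = character(), code = character(),
                  snippet = character(), center = integer(),
                  weight = double(), score = double()))
  }
  bind_rows(rows)
}

#' Top activating windows per convolution filter
#'
#' For each of the `d_c` filters, finds the `top_m` document windows with
#' the highest activation anywhere in the requested split.  This is the
#' division-of-labor audit: after training on planted-snippet data, filters
#' dedicated to a label's snippet should be maximally activated by
#' occurrences of that same snippet.
#'
#' @param fit A `swam_fit`.
#' @param dataset A `swam_dataset`.
#' @param top_m Windows to keep per filter (default 5; 0 gives an empty
#'   table).
#' @param split Split to scan (default `"train"`).
#' @param max_docs Optional cap on the number of documents scanned (in split
#'   order), to bound runtime on large corpora.
#' @return A tibble: `filter` (1-based index), `rank`, `doc_id`, `center`
#'   (0-based), `activation`, `snippet`.
#' @export
filter_snippet_map <- function(fit, dataset, top_m = 5, split = "train",
                               max_docs = NULL) {
  cfg <- fit$model_config
  if (top_m == 0) {
    return(tibble(filter = integer(), rank = integer(), doc_id = character(),
                  center = integer(), activation = double(),
                  snippet = character()))
  }
  docs <- dataset$docs[dataset$docs$split == split, ]
  if (!is.null(max_docs)) docs <- docs[seq_len(min(max_docs, nrow(docs))), ]
  d_c <- cfg$d_c
  vals <- matrix(-Inf, nrow = d_c, ncol = top_m)
  meta_doc <- matrix(NA_character_, nrow = d_c, ncol = top_m)
  meta_pos <- matrix(NA_integer_, nrow = d_c, ncol = top_m)
  W_arr <- as_filter_array(fit$params$W, cfg$k, cfg$d_e)
  for (i in seq_len(nrow(docs))) {
    ids <- docs$token_ids[[i]]
    X <- embed_doc(ids, fit$params$E)
    H <- conv_forward(X, W_arr, fit$params$b_c, activation = cfg$activation)
    len <- ncol(H)
    m_here <- min(top_m, len)
    for (j in seq_len(d_c)) {
      ord <- order(-H[j, ], seq_len(len))[seq_len(m_here)]
      cand_v <- c(vals[j, ], H[j, ord])
      cand_d <- c(meta_doc[j, ], rep(docs$doc_id[i], m_here))
      cand_p <- c(meta_pos[j, ], ord)
      keep <- order(-cand_v)[seq_len(top_m)]
      vals[j, ] <- cand_v[keep]
      meta_doc[j, ] <- cand_d[keep]
      meta_pos[j, ] <- cand_p[keep]
    }
  }
  rows <- list()
  tok_cache <- new.env(parent = emptyenv())
  get_tokens <- function(did) {
    if (is.null(tok_cache[[did]])) {
      ids <- docs$token_ids[[match(did, docs$doc_id)]]
      tok_cache[[did]] <- decode_doc(ids, dataset$vocab)
    }
    tok_cache[[did]]
  }
  for (j in seq_len(d_c)) {
    for (r in seq_len(top_m)) {
      if (!is.finite(vals[j, r])) next
      toks <- get_tokens(meta_doc[j, r])
      window <- snippet_window(meta_pos[j, r], cfg$k, length(toks))
      rows[[length(rows) + 1L]] <- tibble(
        filter = j, rank = r, doc_id = meta_doc[j, r],
        center = meta_pos[j, r] - 1L, activation = vals[j, r],
        snippet = paste(toks[window], collapse = " "))
    }
  }
  bind_rows(rows)
}
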