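#' Specification of a planted-snippet synthetic corpus
#'
#' The generator emulates the statistical structure the shallow wide
#' attention architecture assumes: documents are mostly noise, and each true
#' code is signalled by a short label-specific ("non-generic") snippet
#' planted at a random position, optionally alongside "generic" snippets
#' shared between labels.  Noise tokens follow a Zipf-like long-tail
#' distribution so the document-frequency vocabulary filter is exercised.
#'
#' @param n_labels Number of codes L (default 10).
#' @param snippets_per_label Non-generic snippet phrases per code
#'   (default 2; the architecture is motivated by codes having several).
#' @param snippet_len Tokens per snippet phrase (default 3, at most the
#'   filter width for single-window learnability).
#' @param n_generic Number of generic snippets, each shared by exactly two
#'   labels (default 3).
#' @param vocab_noise Size of the noise vocabulary (default 5000).
#' @param doc_len Mean document length in tokens; lengths are Poisson
#'   (default 300).
#' @param label_prob Marginal probability of each label (default 0.3;
#'   label sets are resampled if empty).
#' @param plant_prob Probability that a true label's snippet actually
#'   appears (default 1, a fully separable corpus).
#' @param n_docs Number of documents (default 2000).
#' @param n_patients Number of patients; documents are assigned round-robin
#'   (default 1000).
#' @param zipf_s Zipf exponent of the noise distribution (default 1.1).
#' @param hard_mode If `TRUE`, snippet phrases are built from the noise
#'   vocabulary instead of a reserved one, so snippet tokens also occur as
#'   noise (default `FALSE`, which keeps ground-truth audits unambiguous).
#' @param seed Integer seed.
#' @return A `swam_synthetic_spec` list; `$phrases` tabulates every snippet
#'   phrase with its owning code(s).
#' @export
synthetic_spec <- function(n_labels = 10, snippets_per_label = 2,
                           snippet_len = 3, n_generic = 3,
                           vocab_noise = 5000, doc_len = 300,
                           label_prob = 0.3, plant_prob = 1.0,
                           n_docs = 2000, n_patients = 1000,
                           zipf_s = 1.1, hard_mode = FALSE, seed = 1L) {
  stopifnot(n_labels >= 1, snippets_per_label >= 1, snippet_len >= 1,
            n_generic >= 0, vocab_noise >= 10, doc_len > snippet_len * 3,
            label_prob > 0, label_prob < 1, plant_prob > 0, plant_prob <= 1,
            n_docs >= 1, n_patients >= 1)
  codes <- sprintf("c%02d", seq_len(n_labels))
  noise_tokens <- sprintf("w%05d", seq_len(vocab_noise))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mk_phrase <- function(prefix) {
    if (hard_mode) {
      paste(sample(noise_tokens, snippet_len), collapse = " ")
    } else {
      paste(sprintf("%st%02d", prefix, seq_len(snippet_len)), collapse = " ")
    }
  }
  ng <- purrr::map(seq_len(n_labels), function(l) {
    vapply(seq_len(snippets_per_label),
           function(s) mk_phrase(sprintf("lab%02ds%d", l, s)), character(1))
  })
  gen_owners <- if (n_generic > 0) {
    purrr::map(seq_len(n_generic), function(g) {
      a <- ((g - 1L) %% n_labels) + 1L
      b <- (g %% n_labels) + 1L
      if (a == b) b <- (b %% n_labels) + 1L
      codes[c(a, b)]
    })
  } else list()
  gen <- vapply(seq_len(n_generic),
                function(g) mk_phrase(sprintf("gen%02d", g)), character(1))
  phrases <- bind_rows(
    tibble(phrase = unlist(ng),
           code = rep(codes, each = snippets_per_label),
           generic = FALSE),
    if (n_generic > 0)
      tibble(phrase = rep(gen, lengths(gen_owners)),
             code = unlist(gen_owners), generic = TRUE)
  )
  if (!hard_mode && anyDuplicated(unique(phrases$phrase)) > 0) {
    abort("snippet phrases must be distinct", class = "swam_data_error")
  }
  structure(
    list(n_labels = n_labels, codes = codes,
         snippets_per_label = snippets_per_label, snippet_len = snippet_len,
         n_generic = n_generic, vocab_noise = vocab_noise,
         noise_tokens = noise_tokens, doc_len = doc_len,
         label_prob = label_prob, plant_prob = plant_prob,
         n_docs = n_docs, n_patients = n_patients, zipf_s = zipf_s,
         hard_mode = hard_mode, seed = seed,
         nongeneric = ng, generic = gen, generic_owners = gen_owners,
         phrases = phrases),
    class = "swam_synthetic_spec"
  )
}

#' @export
print.swam_synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<swam_synthetic_spec> %d labels x %d snippets (+%d generic), %d docs / %d patients, plant_prob=%.2f, seed=%d\n",
    x$n_labels, x$snippets_per_label, x$n_generic, x$n_docs, x$n_patients,
    x$plant_prob, x$seed))
  invisible(x)
}

#' Generate a planted-snippet corpus
#'
#' For each document: labels are sampled as independent Bernoulli draws
#' (resampled while empty); each true label plants one of its non-generic
#' phrases with probability `plant_prob`, as does each generic snippet
#' owned by a true label; snippets land at uniform random non-overlapping
#' positions (positions are re-drawn on collision) and every remaining
#' position is filled with a Zipf-distributed noise token.  Documents are
#' assigned to patients round-robin.  Fully deterministic under the spec's
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `corpus` (a corpus tibble as from [read_corpus()]) and
#'   `truth` (tibble: `doc_id`, `code` — `NA` for generic snippets —,
#'   `phrase`, `start` 1-based token position, `length`, `generic`).
#' @export
generate_corpus <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 1L)
  zipf_p <- seq_len(spec$vocab_noise)^(-spec$zipf_s)
  zipf_p <- zipf_p / sum(zipf_p)
  L <- spec$n_labels
  slen <- spec$snippet_len

  docs <- vector("list", spec$n_docs)
  truth <- vector("list", spec$n_docs)
  for (i in seq_len(spec$n_docs)) {
    y <- rbinom(L, 1, spec$label_prob)
    while (sum(y) == 0) y <- rbinom(L, 1, spec$label_prob)
    plants <- list()
    for (l in which(y == 1)) {
      if (runif(1) <= spec$plant_prob) {
        ph <- spec$nongeneric[[l]][sample.int(spec$snippets_per_label, 1)]
        plants[[length(plants) + 1L]] <-
          list(code = spec$codes[l], phrase = ph, generic = FALSE)
      }
    }
    if (spec$n_generic > 0) {
      for (g in seq_len(spec$n_generic)) {
        if (any(spec$generic_owners[[g]] %in% spec$codes[y == 1]) &&
            runif(1) <= spec$plant_prob) {
          plants[[length(plants) + 1L]] <-
            list(code = NA_character_, phrase = spec$generic[g],
                 generic = TRUE)
        }
      }
    }
    len <- max(rpois(1, spec$doc_len), (length(plants) + 2L) * (slen + 1L))
    tokens <- spec$noise_tokens[sample.int(spec$vocab_noise, len,
                                           replace = TRUE, prob = zipf_p)]
    occupied <- rep(FALSE, len)
    doc_truth <- vector("list", length(plants))
    for (pi in seq_along(plants)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        start <- sample.int(len - slen + 1L, 1)
        span <- start:(start + slen - 1L)
        if (!any(occupied[span])) {
          occupied[span] <- TRUE
          tokens[span] <- strsplit(plants[[pi]]$phrase, " ", fixed = TRUE)[[1]]
          doc_truth[[pi]] <- tibble(
            doc_id = sprintf("d%05d", i), code = plants[[pi]]$code,
            phrase = plants[[pi]]$phrase, start = start,
            length = slen, generic = plants[[pi]]$generic)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort("could not place snippets without overlap; document too short",
              class = "swam_data_error")
      }
    }
    docs[[i]] <- tibble(
      patient_id = sprintf("p%05d", ((i - 1L) %% spec$n_patients) + 1L),
      doc_id = sprintf("d%05d", i),
      text = paste(tokens, collapse = " "),
      codes = list(spec$codes[y == 1]))
    truth[[i]] <- bind_rows(doc_truth)
  }
  list(corpus = bind_rows(docs), truth = bind_rows(truth))
}

#' String-matching reference classifier for a synthetic corpus
#'
#' Predicts a code if and only if one of its non-generic snippet phrases
#' occurs verbatim in the document.  On a corpus with `plant_prob = 1` this
#' achieves macro-F1 of 1 by construction, giving the ceiling trained models
#' are compared against; at `plant_prob < 1` its per-label recall is about
#' `plant_prob` with precision 1 (without `hard_mode`).
#'
#' @param spec The [synthetic_spec()] that generated the corpus.
#' @param corpus The corpus tibble.
#' @return A list: `report` (a `swam_metrics`), `scores` (0/1 matrix).
#' @export
bayes_optimal_reference <- function(spec, corpus) {
  if (nrow(corpus) == 0) abort("empty corpus", class = "swam_data_error")
  toks <- tokenize(corpus$text)
  L <- spec$n_labels
  phrase_tokens <- purrr::map(spec$nongeneric,
                              ~ purrr::map(.x, strsplit, split = " ",
                                           fixed = TRUE) |>
                                purrr::map(1))
  has_phrase <- function(tokens, ph) {
    hits <- which(tokens == ph[1])
    if (length(ph) == 1) return(length(hits) > 0)
    for (h in hits) {
      if (h + length(ph) - 1L <= length(tokens) &&
          all(tokens[h:(h + length(ph) - 1L)] == ph)) return(TRUE)
    }
    FALSE
  }
  scores <- matrix(0, nrow = nrow(corpus), ncol = L,
                   dimnames = list(corpus$doc_id, spec$codes))
  for (i in seq_len(nrow(corpus))) {
    for (l in seq_len(L)) {
      if (any(vapply(phrase_tokens[[l]], has_phrase, logical(1),
                     tokens = toks[[i]]))) {
        scores[i, l] <- 1
      }
    }
  }
  ls <- structure(list(codes = spec$codes, frequencies = NULL, k = L),
                  class = "swam_label_space")
  truth <- label_matrix(corpus, ls)
  list(report = metrics_report(scores, truth), scores = scores)
}
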