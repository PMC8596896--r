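PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"
PAD_ID <- 1L
UNK_ID <- 2L

#' Tokenize clinical text
#'
#' Lowercases, splits on maximal runs of non-alphanumeric characters, and
#' drops tokens containing no alphabetic character.  Dose-like tokens such as
#' `"100ml"` survive; bare numbers such as `"100"` do not.  "Alphabetic"
#' means ASCII `[a-z]` after lowercasing, so the result is locale-independent.
#'
#' @param text Character vector of raw documents.
#' @return A list of character vectors, one per input document (a document
#'   with no surviving tokens yields `character(0)`).
#' @export
#' @examples
#' tokenize("Gave 100 ml")   # "gave", "ml"
#' tokenize("100ml saline")  # "100ml", "saline"
tokenize <- function(text) {
  text <- tolower(as.character(text))
  toks <- stringr::str_split(text, "[^a-z0-9]+")
  purrr::map(toks, function(x) {
    x <- x[nzchar(x)]
    x[stringr::str_detect(x, "[a-z]")]
  })
}

#' Build a vocabulary from training documents
#'
#' Tokens are retained only if they appear in at least `min_doc_freq`
#' *training* documents (counting each document once).  Two special ids are
#' reserved: a padding token used for batching and an unknown token that
#' absorbs all out-of-vocabulary tokens at encode time.
#'
#' @param train_docs A list of token character vectors (training split only).
#' @param min_doc_freq Minimum number of training documents a token must
#'   appear in (default 3).
#' @return A `swam_vocabulary`: list with `tokens` (id -> token, ids 1 and 2
#'   reserved for pad/unk), `min_doc_freq`, and `stats` (tokens seen, dropped
#'   by the alphabetic filter upstream is zero by construction here, dropped
#'   by frequency).
#' @export
build_vocabulary <- function(train_docs, min_doc_freq = 3) {
  if (length(train_docs) == 0) {
    abort("cannot build a vocabulary from an empty training set",
          class = "swam_data_error")
  }
  stopifnot(min_doc_freq >= 1)
  per_doc <- purrr::map(train_docs, unique)
  df <- table(unlist(per_doc))
  seen <- names(df)
  keep <- seen[as.vector(df) >= min_doc_freq]
  keep <- sort(keep)
  tokens <- c(PAD_TOKEN, UNK_TOKEN, keep)
  structure(
    list(
      tokens = tokens,
      min_doc_freq = min_doc_freq,
      stats = list(
        tokens_seen = length(seen),
        dropped_by_freq = length(seen) - length(keep),
        n_train_docs = length(train_docs)
      )
    ),
    class = "swam_vocabulary"
  )
}

#' @export
print.swam_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<swam_vocabulary> %d tokens (+pad/unk), min_doc_freq=%d, built from %d docs\n",
    length(x$tokens) - 2L, x$min_doc_freq, x$stats$n_train_docs))
  invisible(x)
}

#' Number of entries in a vocabulary (including pad and unk)
#' @param vocab A `swam_vocabulary`.
#' @return Integer vocabulary size.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Encode tokens as integer ids
#'
#' Out-of-vocabulary tokens map to the unknown id; documents are truncated to
#' their first `max_len` tokens.
#'
#' @param tokens A character vector of tokens (one document), or a list of
#'   such vectors for `encode_docs()`.
#' @param vocab A `swam_vocabulary`.
#' @param max_len Maximum document length in tokens (default 2500).
#' @return An integer vector of ids (or a list of them).
#' @export
encode_doc <- function(tokens, vocab, max_len = 2500) {
  if (length(tokens) > max_len) tokens <- tokens[seq_len(max_len)]
  ids <- match(tokens, vocab$tokens)
  ids[is.na(ids)] <- UNK_ID
  as.integer(ids)
}

#' @rdname encode_doc
#' @export
encode_docs <- function(tokens, vocab, max_len = 2500) {
  purrr::map(tokens, encode_doc, vocab = vocab, max_len = max_len)
}

#' Decode integer ids back to token strings
#' @param ids Integer vector of token ids.
#' @param vocab A `swam_vocabulary`.
#' @return Character vector of tokens (`"<unk>"` where the id is unknown).
#' @export
decode_doc <- function(ids, vocab) vocab$tokens[ids]

#' Restrict a corpus to its k most frequent codes
#'
#' Code frequencies are counted over the full corpus (one count per document
#' the code appears on).  The k most frequent codes form the label space,
#' ordered by descending frequency with ties broken by code string; documents
#' carrying none of the retained codes are dropped, and the remaining
#' documents' code sets are intersected with the label space.
#'
#' @param corpus A corpus tibble (see [read_corpus()]).
#' @param k Number of codes to retain (default 50).
#' @return A list with `label_space` (a `swam_label_space`: `codes` in rank
#'   order plus `frequencies`) and `corpus` (the filtered tibble).
#' @export
select_top_labels <- function(corpus, k = 50) {
  freqs <- table(unlist(purrr::map(corpus$codes, unique)))
  if (length(freqs) < k) {
    abort(sprintf("corpus has %d distinct codes, fewer than k=%d",
                  length(freqs), k), class = "swam_data_error")
  }
  ord <- order(-as.vector(freqs), names(freqs))
  codes <- names(freqs)[ord][seq_len(k)]
  label_space <- structure(
    list(codes = codes, frequencies = as.vector(freqs)[ord][seq_len(k)], k = k),
    class = "swam_label_space"
  )
  new_codes <- purrr::map(corpus$codes, intersect, y = codes)
  keep <- lengths(new_codes) > 0
  filtered <- corpus[keep, ]
  filtered$codes <- new_codes[keep]
  list(label_space = label_space, corpus = filtered)
}

#' @export
print.swam_label_space <- function(x, ...) {
  cat(sprintf("<swam_label_space> %d codes: %s%s\n", x$k,
              paste(head(x$codes, 5), collapse = ", "),
              if (x$k > 5) ", ..." else ""))
  invisible(x)
}

#' Binary label matrix for a corpus under a label space
#' @param corpus A corpus tibble.
#' @param label_space A `swam_label_space`.
#' @return A 0/1 matrix, documents by codes, with dimnames.
#' @export
label_matrix <- function(corpus, label_space) {
  L <- length(label_space$codes)
  m <- matrix(0L, nrow = nrow(corpus), ncol = L,
              dimnames = list(corpus$doc_id, label_space$codes))
  for (i in seq_len(nrow(corpus))) {
    j <- match(intersect(corpus$codes[[i]], label_space$codes), label_space$codes)
    m[i, j] <- 1L
  }
  m
}

#' Split a corpus by patient
#'
#' Patients (not documents) are randomly partitioned into train/validation/
#' test so that no patient contributes documents to two partitions.  Patients
#' are shuffled under `seed` and cut at the cumulative fractions, giving
#' partition sizes within one patient of the exact proportions.
#'
#' @param corpus A corpus tibble.
#' @param fractions Numeric length-3 vector `(train, valid, test)` summing
#'   to 1 (default `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed.
#' @return A tibble `patient_id`, `split` (factor train/valid/test), with the
#'   fractions and seed as attributes.
#' @export
split_by_patient <- function(corpus, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            all(fractions > 0))
  patients <- sort(unique(corpus$patient_id))
  if (length(patients) < 3) {
    abort("need at least 3 patients to form 3 partitions",
          class = "swam_data_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shuffled <- sample(patients)
  n <- length(patients)
  cuts <- round(cumsum(fractions) * n)
  cuts[3] <- n
  split <- rep(c("train", "valid", "test"),
               times = c(cuts[1], cuts[2] - cuts[1], n - cuts[2]))
  out <- tibble(patient_id = shuffled,
                split = factor(split, levels = c("train", "valid", "test")))
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- seed
  out
}

#' Prepare a modeling dataset from a raw corpus
#'
#' Runs the full preprocessing pipeline: top-k label selection on the whole
#' corpus, patient-level split, tokenization, vocabulary construction on the
#' training split only, and integer encoding with truncation.
#'
#' @param corpus A corpus tibble.
#' @param k_labels Number of codes to retain (default 50).
#' @param min_doc_freq Vocabulary document-frequency threshold (default 3).
#' @param max_len Truncation length in tokens (default 2500).
#' @param fractions Train/valid/test fractions (default `c(0.7, 0.15, 0.15)`).
#' @param seed Seed for the patient split.
#' @return A `swam_dataset`: list with `docs` (tibble: `doc_id`, `patient_id`,
#'   `split`, `token_ids` list-column), `labels` (binary doc x code matrix
#'   aligned with `docs`), `vocab`, `label_space`, `max_len` and the split
#'   metadata.
#' @export
prepare_dataset <- function(corpus, k_labels = 50, min_doc_freq = 3,
                            max_len = 2500, fractions = c(0.70, 0.15, 0.15),
                            seed = 1L) {
  sel <- select_top_labels(corpus, k = k_labels)
  corpus <- sel$corpus
  assign_tbl <- split_by_patient(corpus, fractions = fractions, seed = seed)
  split <- assign_tbl$split[match(corpus$patient_id, assign_tbl$patient_id)]
  toks <- tokenize(corpus$text)
  vocab <- build_vocabulary(toks[split == "train"], min_doc_freq = min_doc_freq)
  ids <- encode_docs(toks, vocab, max_len = max_len)
  docs <- tibble(
    doc_id = corpus$doc_id,
    patient_id = corpus$patient_id,
    split = split,
    token_ids = ids
  )
  structure(
    list(
      docs = docs,
      labels = label_matrix(corpus, sel$label_space),
      vocab = vocab,
      label_space = sel$label_space,
      max_len = max_len,
      split_fractions = fractions,
      split_seed = seed
    ),
    class = "swam_dataset"
  )
}

#' @export
print.swam_dataset <- function(x, ...) {
  cat(sprintf(
    "<swam_dataset> %d docs (%d train / %d valid / %d test), %d labels, vocab %d\n",
    nrow(x$docs), sum(x$docs$split == "train"), sum(x$docs$split == "valid"),
    sum(x$docs$split == "test"), length(x$label_space$codes),
    vocab_size(x$vocab)))
  invisible(x)
}

#' Serialize a vocabulary or label space to plain text
#'
#' The vocabulary is written as a two-column TSV (token, id) plus a JSON
#' sidecar (`<path>.stats.json`) with the build statistics; the label space
#' as an ordered one-code-per-line file.
#'
#' @param vocab,label_space Objects to write.
#' @param path Output path.
#' @return `path` invisibly (writers); the reconstructed object (readers).
#' @export
write_vocabulary <- function(vocab, path) {
  readr::write_tsv(tibble(token = vocab$tokens, id = seq_along(vocab$tokens)),
                   path, progress = FALSE)
  jsonlite::write_json(c(vocab$stats, list(min_doc_freq = vocab$min_doc_freq)),
                       paste0(path, ".stats.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tb <- readr::read_tsv(path, col_types = "ci", progress = FALSE)
  stats <- jsonlite::fromJSON(paste0(path, ".stats.json"))
  structure(
    list(tokens = tb$token[order(tb$id)],
         min_doc_freq = stats$min_doc_freq,
         stats = stats[setdiff(names(stats), "min_doc_freq")]),
    class = "swam_vocabulary"
  )
}

#' @rdname write_vocabulary
#' @export
write_label_space <- function(label_space, path) {
  writeLines(label_space$codes, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_label_space <- function(path) {
  codes <- readLines(path, warn = FALSE)
  structure(list(codes = codes, frequencies = NULL, k = length(codes)),
            class = "swam_label_space")
}

#' Serialize encoded documents as JSON-lines
#'
#' One object per document: `doc_id`, `patient_id`, `split`, `token_ids`
#' (integer id sequence) and `codes` (the document's true codes under the
#' label space).  Together with the vocabulary and label-space files this is
#' a complete plain-text representation of a prepared dataset.
#'
#' @param dataset A `swam_dataset`.
#' @param path Output path.
#' @return `path` invisibly (writer); a tibble mirroring `dataset$docs` with
#'   a `codes` list-column (reader).
#' @export
write_encoded <- function(dataset, path) {
  codes <- apply(dataset$labels, 1,
                 function(r) dataset$label_space$codes[r == 1],
                 simplify = FALSE)
  lines <- vapply(seq_len(nrow(dataset$docs)), function(i) {
    jsonlite::toJSON(
      list(doc_id = dataset$docs$doc_id[i],
           patient_id = dataset$docs$patient_id[i],
           split = as.character(dataset$docs$split[i]),
           token_ids = dataset$docs$token_ids[[i]],
           codes = codes[[i]]),
      auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_encoded
#' @export
read_encoded <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- purrr::map(lines, jsonlite::fromJSON)
  tibble(
    doc_id = purrr::map_chr(recs, "doc_id"),
    patient_id = purrr::map_chr(recs, "patient_id"),
    split = factor(purrr::map_chr(recs, "split"),
                   levels = c("train", "valid", "test")),
    token_ids = purrr::map(recs, ~ as.integer(.x$token_ids)),
    codes = purrr::map(recs, ~ as.character(.x$codes))
  )
}

# Save/restore the global RNG state so seeded helpers don't disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
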