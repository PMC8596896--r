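#' Read a labeled document corpus
#'
#' Reads a corpus of clinical documents with their code labels.  The canonical
#' on-disk format is JSON-lines (one object per document with fields
#' `patient_id`, `doc_id`, `text` and `codes` as a JSON array), because
#' clinical free text routinely contains every delimiter a flat format could
#' choose.  A CSV dialect is also supported in which `codes` is a single
#' `";"`-joined string.
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` (default) or `"csv"`.
#'
#' @return A tibble with columns `patient_id` (character), `doc_id`
#'   (character), `text` (character) and `codes` (list of character vectors,
#'   deduplicated). Rows preserve file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".jsonl")
#' writeLines(c(
#'   '{"patient_id":"p1","doc_id":"d1","text":"chest pain","codes":["276.1","285.9"]}'
#' ), tf)
#' read_corpus(tf)
read_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("corpus file not found: ", path), class = "swam_io_error")
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- purrr::map(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    needed <- c("patient_id", "doc_id", "text", "codes")
    for (r in recs) {
      missing <- setdiff(needed, names(r))
      if (length(missing) > 0) {
        abort(paste0("corpus record missing field(s): ",
                     paste(missing, collapse = ", ")),
              class = "swam_format_error")
      }
    }
    out <- tibble(
      patient_id = purrr::map_chr(recs, ~ as.character(.x$patient_id)),
      doc_id     = purrr::map_chr(recs, ~ as.character(.x$doc_id)),
      text       = purrr::map_chr(recs, ~ as.character(.x$text)),
      codes      = purrr::map(recs, ~ unique(as.character(unlist(.x$codes))))
    )
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    needed <- c("patient_id", "doc_id", "text", "codes")
    missing <- setdiff(needed, names(df))
    if (length(missing) > 0) {
      abort(paste0("corpus file missing column(s): ",
                   paste(missing, collapse = ", ")),
            class = "swam_format_error")
    }
    df$text[is.na(df$text)] <- ""
    df$codes[is.na(df$codes)] <- ""
    out <- tibble(
      patient_id = df$patient_id,
      doc_id     = df$doc_id,
      text       = df$text,
      codes      = purrr::map(df$codes, function(s) {
        cs <- strsplit(s, ";", fixed = TRUE)[[1]]
        unique(cs[nzchar(cs)])
      })
    )
  }
  if (anyDuplicated(out$doc_id) > 0) {
    dup <- out$doc_id[duplicated(out$doc_id)][1]
    abort(paste0("duplicate doc_id in corpus: ", dup), class = "swam_format_error")
  }
  out
}

#' Write a labeled document corpus
#'
#' @param corpus A tibble as returned by [read_corpus()].
#' @param path Output path.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- purrr::pmap_chr(
      list(corpus$patient_id, corpus$doc_id, corpus$text, corpus$codes),
      function(p, d, t, cs) {
        jsonlite::toJSON(list(patient_id = p, doc_id = d, text = t,
                              codes = as.character(cs)),
                         auto_unbox = TRUE)
      }
    )
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- tibble(
      patient_id = corpus$patient_id,
      doc_id = corpus$doc_id,
      text = corpus$text,
      codes = purrr::map_chr(corpus$codes, paste, collapse = ";")
    )
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read word vectors in word2vec text format
#'
#' The word2vec text format has a header line `"V D"` followed by one line per
#' token: the token then D floats, space-separated.
#'
#' @param path Path to the embedding file.
#' @return A numeric matrix of dimension V x D with tokens as row names.
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 1) abort("empty embedding file", class = "swam_format_error")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2) {
    abort("word2vec header must be 'V D'", class = "swam_format_error")
  }
  v <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != v) {
    abort(sprintf("header declares %d rows, found %d", v, length(body)),
          class = "swam_format_error")
  }
  toks <- character(v)
  mat <- matrix(NA_real_, nrow = v, ncol = d)
  for (i in seq_len(v)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(parts) != d + 1) {
      abort(sprintf("row %d has %d values, expected %d", i, length(parts) - 1, d),
            class = "swam_format_error")
    }
    toks[i] <- parts[1]
    mat[i, ] <- as.numeric(parts[-1])
  }
  rownames(mat) <- toks
  mat
}

#' Write word vectors in word2vec text format
#'
#' @param embedding A numeric matrix with tokens as row names.
#' @param path Output path.
#' @param digits Significant digits to write (default 8).
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(embedding, path, digits = 8) {
  stopifnot(is.matrix(embedding), !is.null(rownames(embedding)))
  hdr <- paste(nrow(embedding), ncol(embedding))
  rows <- vapply(seq_len(nrow(embedding)), function(i) {
    paste(rownames(embedding)[i],
          paste(formatC(embedding[i, ], digits = digits, format = "g"),
                collapse = " "))
  }, character(1))
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read or write per-document code predictions
#'
#' Predictions are stored as TSV with columns `doc_id`, `code`, `score`
#' (probability in \[0,1\]) and `decision` (0/1 at the configured threshold).
#'
#' @param predictions A tibble with columns `doc_id`, `code`, `score`,
#'   `decision`.
#' @param path File path.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` returns the tibble.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("doc_id", "code", "score", "decision") %in% names(predictions)))
  if (any(predictions$score < 0 | predictions$score > 1)) {
    abort("prediction scores must lie in [0,1]", class = "swam_format_error")
  }
  readr::write_tsv(predictions[, c("doc_id", "code", "score", "decision")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    doc_id = readr::col_character(),
    code = readr::col_character(),
    score = readr::col_double(),
    decision = readr::col_integer()
  ), progress = FALSE)
}

#' Read or write snippet explanations
#'
#' Explanations are stored as JSON-lines, one object per (document, code)
#' pair with the extracted snippet, its center position (0-based token index
#' into the truncated document), the attention weight at the center and the
#' predicted probability.
#'
#' @param explanations A tibble as returned by [extract_snippets()].
#' @param path File path.
#' @return `write_explanations()` returns `path` invisibly;
#'   `read_explanations()` returns the tibble (rows in file order).
#' @export
write_explanations <- function(explanations, path) {
  if (nrow(explanations) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- purrr::pmap_chr(
    list(explanations$doc_id, explanations$code, explanations$snippet,
         explanations$center, explanations$weight, explanations$score),
    function(d, cd, sn, ce, w, sc) {
      jsonlite::toJSON(list(doc_id = d, code = cd, snippet = sn,
                            center = ce, weight = w, score = sc),
                       auto_unbox = TRUE, digits = NA)
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_explanations
#' @export
read_explanations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(doc_id = character(), code = character(),
                  snippet = character(), center = integer(),
                  weight = double(), score = double()))
  }
  recs <- purrr::map(lines, jsonlite::fromJSON)
  tibble(
    doc_id = purrr::map_chr(recs, "doc_id"),
    code = purrr::map_chr(recs, "code"),
    snippet = purrr::map_chr(recs, "snippet"),
    center = purrr::map_int(recs, ~ as.integer(.x$center)),
    weight = purrr::map_dbl(recs, "weight"),
    score = purrr::map_dbl(recs, "score")
  )
}
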