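test_that("tokenizer lowercases, keeps dose-like tokens and drops bare numbers", {
  expect_equal(tokenize("Gave 100 ml")[[1]], c("gave", "ml"))
  expect_equal(tokenize("100ml saline")[[1]], c("100ml", "saline"))
  expect_equal(tokenize("")[[1]], character(0))
  expect_equal(tokenize("3.5% NaCl IV-drip!")[[1]], c("nacl", "iv", "drip"))
  expect_equal(tokenize("A1c 7.2 , mg/dL")[[1]], c("a1c", "mg", "dl"))
})

test_that("vocabulary honors the document-frequency threshold", {
  docs <- list(c("fever", "cough"), c("fever", "night"), c("fever", "cough"),
               c("cough", "rare"), c("fever", "wheeze"))
  v3 <- build_vocabulary(docs, min_doc_freq = 3)
  expect_true(all(c("fever", "cough") %in% v3$tokens))
  expect_false(any(c("night", "rare", "wheeze") %in% v3$tokens))
  v1 <- build_vocabulary(docs, min_doc_freq = 1)
  expect_true(all(c("night", "rare", "wheeze") %in% v1$tokens))
  expect_error(build_vocabulary(list()), class = "swam_data_error")
  # pad/unk reserved and distinct
  expect_equal(v3$tokens[1:2], c("<pad>", "<unk>"))
  # repeated occurrences in one doc count once
  docs2 <- list(rep("fever", 10), "cough")
  expect_false("fever" %in% build_vocabulary(docs2, min_doc_freq = 2)$tokens)
})

test_that("hand-countable toy corpus yields the hand-derived vocabulary", {
  corpus <- toy_corpus()
  toks <- tokenize(corpus$text)
  vocab <- build_vocabulary(toks, min_doc_freq = 3)
  # by hand: doc frequencies over all 10 docs
  # and=6, with=4, fever=3, cough=3, noted=3, chills=3; everything else <3
  hand <- sort(c("and", "with", "fever", "cough", "noted", "chills"))
  expect_equal(sort(setdiff(vocab$tokens, c("<pad>", "<unk>"))), hand)
  expect_equal(vocab$stats$dropped_by_freq,
               vocab$stats$tokens_seen - length(hand))
})

test_that("encoding maps OOV to unk, truncates, and decodes back", {
  vocab <- build_vocabulary(list(c("a1", "b1"), c("a1", "b1"), c("a1", "c1")),
                            min_doc_freq = 2)
  ids <- encode_doc(c("a1", "zzz", "b1"), vocab)
  expect_equal(decode_doc(ids, vocab), c("a1", "<unk>", "b1"))
  long <- rep("a1", 3000)
  expect_length(encode_doc(long, vocab, max_len = 2500), 2500)
  all_oov <- encode_doc(c("x", "y", "z"), vocab)
  expect_equal(all_oov, rep(2L, 3))
  expect_true(all(encode_doc(c("a1", "b1", "q"), vocab) <= vocab_size(vocab)))
})

test_that("top-k label selection ranks, drops and restricts correctly", {
  corpus <- tibble::tibble(
    patient_id = paste0("p", 1:30), doc_id = paste0("d", 1:30),
    text = "x",
    codes = c(rep(list("l1"), 10), rep(list("l2"), 8), rep(list("l3"), 6),
              rep(list(c("l1", "l4")), 4), rep(list("l5"), 2)))
  sel <- select_top_labels(corpus, k = 3)
  expect_equal(sel$label_space$codes, c("l1", "l2", "l3"))
  # docs with only l5 dropped; docs with l1+l4 kept with label restricted
  expect_equal(nrow(sel$corpus), 28)
  expect_equal(sel$corpus$codes[[25]], "l1")
  m <- label_matrix(sel$corpus, sel$label_space)
  expect_equal(sum(m[25, ]), 1)
  expect_error(select_top_labels(corpus, k = 10), class = "swam_data_error")
})

test_that("patient split keeps patients intact, is seeded, and hits fractions", {
  corpus <- tibble::tibble(
    patient_id = rep(sprintf("p%04d", 1:1000), each = 2),
    doc_id = sprintf("d%04d", 1:2000), text = "x", codes = list("a"))
  s1 <- split_by_patient(corpus, seed = 42)
  s2 <- split_by_patient(corpus, seed = 42)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 1000)
  tab <- table(s1$split)
  expect_lt(abs(tab[["train"]] / 1000 - 0.70), 0.02)
  expect_lt(abs(tab[["valid"]] / 1000 - 0.15), 0.02)
  expect_lt(abs(tab[["test"]] / 1000 - 0.15), 0.02)
  # no patient in two partitions by construction: assignment is per patient
  expect_equal(anyDuplicated(s1$patient_id), 0)
  # a single patient's documents all land together
  one <- tibble::tibble(patient_id = rep("p1", 3),
                        doc_id = c("d1", "d2", "d3"), text = "x",
                        codes = list("a"))
  expect_error(split_by_patient(one), class = "swam_data_error")
})

test_that("prepare_dataset is deterministic and leak-free end to end", {
  prob <- small_training_problem()
  ds <- prob$dataset
  ds2 <- prepare_dataset(prob$gen$corpus, k_labels = 2, min_doc_freq = 3,
                         seed = 5)
  expect_identical(ds$docs$token_ids, ds2$docs$token_ids)
  expect_identical(ds$labels, ds2$labels)
  # no patient leakage across partitions
  by_split <- split(ds$docs$patient_id, ds$docs$split)
  expect_length(intersect(by_split$train, by_split$test), 0)
  expect_length(intersect(by_split$train, by_split$valid), 0)
  expect_length(intersect(by_split$valid, by_split$test), 0)
  # every encoded id is a valid vocabulary index
  expect_true(all(unlist(ds$docs$token_ids) >= 1))
  expect_true(all(unlist(ds$docs$token_ids) <= vocab_size(ds$vocab)))
  # every kept doc has at least one label
  expect_true(all(rowSums(ds$labels) >= 1))
})

test_that("vocabulary and label space serialize to text and back", {
  vocab <- build_vocabulary(list(c("aa", "bb"), c("aa", "bb"), "aa"),
                            min_doc_freq = 2)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(vocab, tf)
  back <- read_vocabulary(tf)
  expect_equal(back$tokens, vocab$tokens)
  expect_equal(back$min_doc_freq, vocab$min_doc_freq)
  ls <- structure(list(codes = c("b", "a"), frequencies = NULL, k = 2),
                  class = "swam_label_space")
  tf2 <- withr::local_tempfile(fileext = ".txt")
  write_label_space(ls, tf2)
  expect_equal(read_label_space(tf2)$codes, c("b", "a"))
})

test_that("encoded datasets round-trip through json-lines", {
  prob <- small_training_problem(seed = 59)
  ds <- prob$dataset
  tf <- withr::local_tempfile(fileext = ".jsonl")
  write_encoded(ds, tf)
  back <- read_encoded(tf)
  expect_equal(back$doc_id, ds$docs$doc_id)
  expect_identical(back$token_ids, ds$docs$token_ids)
  expect_equal(back$split, ds$docs$split)
  # codes reconstruct the label matrix exactly
  ls <- ds$label_space
  m <- matrix(0L, nrow(back), length(ls$codes),
              dimnames = list(back$doc_id, ls$codes))
  for (i in seq_len(nrow(back))) m[i, match(back$codes[[i]], ls$codes)] <- 1L
  expect_equal(m, ds$labels)
})
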