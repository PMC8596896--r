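# Small corpora and model fixtures built in code, plus a lazy cache for the
# expensive study-scale objects shared by the acceptance tests.

toy_corpus <- function() {
  tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p3", "p4", "p5", "p6", "p7", "p8", "p9"),
    doc_id = sprintf("d%02d", 1:10),
    text = c(
      "fever and cough with fever again",
      "cough at night and wheeze",
      "fever with chills and rigors",
      "night sweats and fever",
      "cough with sputum 100ml noted",
      "wheeze and stridor heard",
      "chills with rigors overnight",
      "sputum sample 100 ml taken",
      "stridor noted on exam",
      "sweats and chills noted"
    ),
    codes = list(c("a", "b"), "a", c("a", "c"), "b", "a",
                 "c", "b", "a", "c", c("a", "b"))
  )
}

micro_embedding <- function(v, d_e, seed = 1) {
  set.seed(seed)
  E <- matrix(rnorm(v * d_e, sd = 0.3), nrow = v)
  E[1, ] <- 0
  rownames(E) <- c("<pad>", "<unk>", sprintf("t%03d", seq_len(v - 2)))
  E
}

random_params <- function(config, v = 20, seed = 1) {
  swam_init_params(config, micro_embedding(v, config$d_e, seed = seed),
                   seed = seed + 1)
}

small_training_problem <- function(seed = 11) {
  sp <- synthetic_spec(n_labels = 2, snippets_per_label = 1, snippet_len = 2,
                       n_generic = 0, vocab_noise = 300, doc_len = 60,
                       label_prob = 0.4, n_docs = 240, n_patients = 120,
                       seed = seed)
  g <- generate_corpus(sp)
  ds <- prepare_dataset(g$corpus, k_labels = 2, min_doc_freq = 3, seed = 5)
  list(spec = sp, gen = g, dataset = ds)
}

# ---- study-scale fixtures (shared across acceptance tests, built once) ----

.study_cache <- new.env(parent = emptyenv())

study_fixture <- function(name) {
  if (!is.null(.study_cache[[name]])) return(.study_cache[[name]])
  val <- switch(name,
    spec = synthetic_spec(seed = 20240601),
    gen = generate_corpus(study_fixture("spec")),
    dataset = prepare_dataset(study_fixture("gen")$corpus, k_labels = 10,
                              min_doc_freq = 3, seed = 101),
    embedding = random_embeddings(study_fixture("dataset")$vocab, 32,
                                  seed = 7),
    wide_config = swam_config(k = 4, d_c = 80, d_e = 32, n_labels = 10,
                              dropout = 0.2),
    narrow_config = swam_config(k = 4, d_c = 4, d_e = 32, n_labels = 10,
                                dropout = 0.2),
    train_config = swam_train_config(lr = 0.001, max_epochs = 25,
                                     patience = 10, data_seed = 1,
                                     param_seed = 1),
    test_truth = {
      ds <- study_fixture("dataset")
      ds$labels[ds$docs$split == "test", , drop = FALSE]
    },
    wide_fit = swam_train(study_fixture("dataset"),
                          study_fixture("embedding"),
                          study_fixture("wide_config"),
                          study_fixture("train_config")),
    wide_scores = predict_matrix(study_fixture("wide_fit"),
                                 study_fixture("dataset"), "test"),
    narrow_fits = {
      ds <- study_fixture("dataset"); emb <- study_fixture("embedding")
      nc <- study_fixture("narrow_config"); tc <- study_fixture("train_config")
      setNames(
        lapply(1:5, function(sd) reshuffle_and_retrain(ds, emb, nc, tc, sd)),
        as.character(1:5))
    },
    narrow_reports = {
      ds <- study_fixture("dataset"); truth <- study_fixture("test_truth")
      lapply(study_fixture("narrow_fits"), function(f) {
        metrics_report(predict_matrix(f, ds, "test"), truth)
      })
    },
    wide_fit_seed2 = reshuffle_and_retrain(study_fixture("dataset"),
                                           study_fixture("embedding"),
                                           study_fixture("wide_config"),
                                           study_fixture("train_config"), 2),
    stop("unknown fixture: ", name)
  )
  .study_cache[[name]] <- val
  val
}

zero_precision_of <- function(report) {
  report$per_label$code[report$per_label$precision == 0 &
                          report$per_label$support > 0]
}

# O(n^2) pair-counting AUC oracle (Mann-Whitney), ties count 1/2.
auc_pair_oracle <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
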