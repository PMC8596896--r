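test_that("per-label P/R/F1 follows hand counts and the zero conventions", {
  truth <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0), c = c(1, 1, 1, 1))
  dec <- cbind(a = c(1, 0, 1, 0), b = c(0, 0, 0, 0), c = c(1, 1, 1, 1))
  per <- per_label_prf(dec, truth)
  # label a: TP=1 FP=1 FN=1 -> P=R=F1=0.5
  expect_equal(per$precision[per$code == "a"], 0.5)
  expect_equal(per$recall[per$code == "a"], 0.5)
  expect_equal(per$f1[per$code == "a"], 0.5)
  # label b never predicted: precision 0 by convention, recall 0
  expect_equal(per$precision[per$code == "b"], 0)
  expect_equal(per$recall[per$code == "b"], 0)
  # perfect label c
  expect_equal(per$f1[per$code == "c"], 1)
})

test_that("macro F1 averages labels; micro F1 flattens pairs (hand example)", {
  # 3 docs x 2 labels, traced by enumerating all 6 (doc, label) pairs
  truth <- cbind(l1 = c(1, 0, 1), l2 = c(0, 1, 1))
  dec <- cbind(l1 = c(1, 1, 1), l2 = c(0, 0, 0))
  # l1: TP=2 FP=1 FN=0 -> P=2/3 R=1 F1=0.8 ; l2: never predicted -> 0
  mm <- macro_micro_f1(dec, truth)
  expect_equal(mm$f1_macro, 0.4)
  # flattened: TP=2, FP=1, FN=2 -> P=2/3, R=1/2, F1=4/7
  expect_equal(mm$f1_micro, 4 / 7)
  # two labels with F1 1 and 0 -> macro 0.5 (contained above); all-correct:
  expect_equal(macro_micro_f1(truth, truth)$f1_macro, 1)
  expect_equal(macro_micro_f1(truth, truth)$f1_micro, 1)
})

test_that("micro F1 via flattened pairs equals the TP/FP/FN aggregate route", {
  set.seed(61)
  for (rep in 1:20) {
    nd <- sample(3:20, 1); L <- sample(2:6, 1)
    truth <- matrix(rbinom(nd * L, 1, 0.4), nd)
    dec <- matrix(rbinom(nd * L, 1, 0.4), nd)
    # independent aggregate-formula implementation
    tp <- sum(dec & truth); fp <- sum(dec & !truth); fn <- sum(!dec & truth)
    agg <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    expect_equal(macro_micro_f1(dec, truth)$f1_micro, agg)
  }
})

test_that("ROC-AUC matches the pair-counting oracle and tie conventions", {
  y <- c(1, 1, 0, 0, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  expect_equal(swam:::auc_one(s, y), auc_pair_oracle(s, y), tolerance = 1e-9)
  # perfect separation
  expect_equal(swam:::auc_one(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # constant scores: 0.5 by tie convention
  expect_equal(swam:::auc_one(rep(0.5, 6), y), 0.5)
  set.seed(62)
  for (rep in 1:20) {
    n <- sample(6:25, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # rounded to force some ties
    expect_equal(swam:::auc_one(s, y), auc_pair_oracle(s, y), tolerance = 1e-9)
  }
})

test_that("random scores give AUC near 0.5 and degenerate labels are skipped", {
  set.seed(63)
  n <- 4000
  s <- runif(n); y <- rbinom(n, 1, 0.5)
  expect_lt(abs(auc_pair_oracle(s[1:500], y[1:500]) - 0.5), 0.08)
  truth <- cbind(ok = y[1:100], allpos = rep(1, 100))
  scores <- cbind(ok = s[1:100], allpos = runif(100))
  expect_message(res <- auc_macro_micro(scores, truth), "skipped")
  expect_equal(attr(res, "skipped"), "allpos")
})

test_that("precision at n follows hand counts, brute force, tie policy and
           monotone invariance", {
  truth <- rbind(c(1, 1, 1, 0, 0), c(1, 0, 0, 0, 0))
  scores <- rbind(c(0.9, 0.8, 0.7, 0.6, 0.5), c(0.9, 0.8, 0.7, 0.6, 0.5))
  # doc1 top-3 all true -> 1 ; doc2 top-3 has 1 true -> 1/3
  expect_equal(precision_at_n(scores, truth, n = 3), mean(c(1, 1 / 3)))
  # brute-force oracle on random scores
  set.seed(64)
  for (rep in 1:10) {
    nd <- 3; L <- 6; n <- 4
    sc <- matrix(runif(nd * L), nd)
    tr <- matrix(rbinom(nd * L, 1, 0.5), nd)
    brute <- mean(vapply(seq_len(nd), function(i) {
      ord <- order(-sc[i, ], seq_len(L))
      mean(tr[i, ord[seq_len(n)]])
    }, numeric(1)))
    expect_equal(precision_at_n(sc, tr, n = n), brute)
  }
  # ties broken by ascending label index
  sc_tie <- matrix(c(0.5, 0.5, 0.5, 0.2), 1)
  tr_tie <- matrix(c(1, 0, 0, 1), 1)
  expect_equal(precision_at_n(sc_tie, tr_tie, n = 1), 1)
  # invariant under strictly monotone transforms
  sc <- matrix(runif(12), 3)
  tr <- matrix(rbinom(12, 1, 0.5), 3)
  expect_equal(precision_at_n(plogis(5 * sc), tr, n = 2),
               precision_at_n(sc, tr, n = 2))
  expect_equal(precision_at_n(sc^3, tr, n = 2),
               precision_at_n(sc, tr, n = 2))
})

test_that("all metrics are invariant under document permutation", {
  set.seed(65)
  sc <- matrix(runif(40), 10)
  tr <- matrix(rbinom(40, 1, 0.5), 10)
  tr[1, ] <- 1 - tr[2, ]  # ensure both classes somewhere
  r1 <- metrics_report(sc, tr)
  perm <- sample(10)
  r2 <- metrics_report(sc[perm, ], tr[perm, ])
  expect_equal(glance(r1), glance(r2))
})

test_that("metrics report prints, tidies and serializes", {
  set.seed(66)
  sc <- matrix(runif(30), 10)
  tr <- matrix(rbinom(30, 1, 0.5), 10,
               dimnames = list(NULL, c("x", "y", "z")))
  tr[1:2, ] <- rbind(rep(1, 3), rep(0, 3))
  rep_ <- metrics_report(sc, tr, n = 2)
  expect_s3_class(glance(rep_), "tbl_df")
  expect_equal(nrow(tidy(rep_)), 3)
  tf <- withr::local_tempfile(fileext = ".json")
  write_metrics(rep_, tf)
  js <- jsonlite::fromJSON(tf)
  expect_equal(js$f1_macro, rep_$f1_macro)
  expect_true(file.exists(paste0(tf, ".per_label.tsv")))
})

test_that("paired bootstrap is symmetric, directional and deterministic", {
  set.seed(67)
  tr <- matrix(rbinom(200, 1, 0.5), 50)
  good <- tr * 0.8 + 0.1              # scores tracking the truth
  bad <- matrix(runif(200), 50)       # uninformative scores
  # identical models: every resample ties, split half-and-half -> exactly 0.5
  p_same <- paired_bootstrap(good, good, tr, metric = "f1_macro", B = 200,
                             seed = 3)
  expect_equal(as.numeric(p_same), 0.5)
  # A strictly dominates B
  p_dom <- paired_bootstrap(good, bad, tr, metric = "f1_macro", B = 200,
                            seed = 3)
  expect_lt(as.numeric(p_dom), 0.05)
  # deterministic under seed
  p2 <- paired_bootstrap(good, bad, tr, metric = "f1_macro", B = 200, seed = 3)
  expect_identical(as.numeric(p_dom), as.numeric(p2))
  expect_warning(paired_bootstrap(good, bad, tr, B = 50, seed = 1), "100")
})

test_that("bag-of-words baseline separates a planted-snippet corpus", {
  prob <- small_training_problem()
  bl <- bow_logreg_baseline(prob$dataset)
  expect_gt(bl$report$f1_macro, 0.5)
  bl2 <- bow_logreg_baseline(prob$dataset)
  expect_identical(bl$scores, bl2$scores)
})
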