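zero_precision_codes <- function(per_label) {
  per_label$code[per_label$precision == 0 & per_label$support > 0]
}

configs_differ_only_in <- function(configs, field) {
  ref <- configs[[1]]
  for (cfg in configs[-1]) {
    other <- setdiff(names(ref), field)
    if (!identical(ref[other], cfg[other])) return(FALSE)
  }
  TRUE
}

experiment_manifest <- function(name, model_configs, train_configs) {
  list(
    experiment = name,
    package_version = as.character(utils::packageVersion("swam")),
    cells = purrr::map2(model_configs, train_configs, function(mc, tc) {
      list(model = unclass(mc), train = unclass(tc))
    })
  )
}

#' Write an experiment manifest
#'
#' Serializes the configurations and seeds of an ablation or shuffle run as
#' JSON, sufficient to re-run it bit-identically.
#'
#' @param result A `swam_ablation` or `swam_shuffle` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path) {
  jsonlite::write_json(result$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Network-width ablation
#'
#' Trains models that are identical except for the number of convolution
#' filters `d_c` and compares their per-label test precision.  The expected
#' signature of capacity starvation is that the narrow model abandons some
#' labels entirely (precision 0) while the wide model does not, since every
#' label-specific snippet needs a filter of its own.
#'
#' @param dataset A `swam_dataset`.
#' @param embedding Initial embedding matrix shared by all cells.
#' @param model_configs A list of two or more [swam_config()]s differing
#'   *only* in `d_c`; anything else differing is refused.
#' @param train_config A [swam_train_config()] shared by all cells.
#' @param split Evaluation split (default `"test"`).
#' @param verbose Passed to [swam_train()].
#' @return A `swam_ablation`: `summary` (tibble: `d_c`, `f1_macro`,
#'   `f1_micro`, `auc_macro`, `p_at_n`, `n_zero_precision`),
#'   `per_label` (long tibble: `d_c`, `code`, `precision`, `recall`, `f1`,
#'   `support`), `zero_precision` (named list of code sets), `fits`,
#'   `reports`, `manifest`.
#' @export
run_width_ablation <- function(dataset, embedding, model_configs,
                               train_config, split = "test",
                               verbose = FALSE) {
  stopifnot(length(model_configs) >= 2)
  if (!configs_differ_only_in(model_configs, "d_c")) {
    abort("ablation cells must differ only in d_c", class = "swam_config_error")
  }
  widths <- vapply(model_configs, function(c) c$d_c, integer(1))
  names(model_configs) <- paste0("d_c=", widths)
  fits <- purrr::map(model_configs, function(mc) {
    swam_train(dataset, embedding, mc, train_config, verbose = verbose)
  })
  truth <- dataset_split_ids(dataset, split)$labels
  reports <- purrr::map(fits, function(f) {
    metrics_report(predict_matrix(f, dataset, split = split), truth)
  })
  per_label <- purrr::imap(reports, function(r, nm) {
    mutate(r$per_label, d_c = as.integer(sub("d_c=", "", nm)), .before = 1)
  }) |> bind_rows()
  zp <- purrr::map(reports, ~ zero_precision_codes(.x$per_label))
  summary <- tibble(
    d_c = widths,
    f1_macro = purrr::map_dbl(reports, "f1_macro"),
    f1_micro = purrr::map_dbl(reports, "f1_micro"),
    auc_macro = purrr::map_dbl(reports, "auc_macro"),
    p_at_n = purrr::map_dbl(reports, "p_at_n"),
    n_zero_precision = lengths(zp)
  )
  structure(
    list(summary = summary, per_label = per_label, zero_precision = zp,
         fits = fits, reports = reports,
         manifest = experiment_manifest(
           "ablation_width", model_configs,
           rep(list(train_config), length(model_configs)))),
    class = "swam_ablation"
  )
}

#' @export
print.swam_ablation <- function(x, ...) {
  cat("<swam_ablation>\n")
  print(x$summary)
  for (nm in names(x$zero_precision)) {
    cat(sprintf("  %s zero-precision: {%s}\n", nm,
                paste(x$zero_precision[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
autoplot.swam_ablation <- function(object, ...) {
  df <- mutate(object$per_label, width = factor(.data$d_c))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$code, y = .data$precision,
                                   fill = .data$width)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "code", y = "test precision", fill = "filters",
                  title = "Per-label precision by network width") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Data-order shuffle study
#'
#' Retrains each configuration under several data-order seeds and tracks
#' which labels end with zero test precision.  A capacity-starved (narrow)
#' model converges to a different local optimum per ordering, so the
#' identity of its abandoned labels changes with the seed; a sufficiently
#' wide model on separable data abandons none regardless of ordering.
#'
#' @param dataset A `swam_dataset`.
#' @param embedding Initial embedding matrix.
#' @param model_configs Named list of [swam_config()]s (e.g. narrow and
#'   wide).
#' @param train_config Base [swam_train_config()]; only its `data_seed`
#'   varies.
#' @param data_seeds Integer vector of two or more data-order seeds.
#' @param split Evaluation split (default `"test"`).
#' @param fits Optional pre-computed fits, a named list
#'   `fits[[model]][[as.character(seed)]]`, reused instead of retraining.
#' @return A `swam_shuffle`: `results` (tibble: `model`, `d_c`,
#'   `data_seed`, `f1_macro`, `zero_precision` list-column), `changed`
#'   (tibble per model: whether the zero-precision set differs across any
#'   seed pair), `manifest`.
#' @export
run_shuffle_study <- function(dataset, embedding, model_configs,
                              train_config, data_seeds, split = "test",
                              fits = NULL) {
  stopifnot(length(data_seeds) >= 2 || length(unique(data_seeds)) >= 1)
  if (is.null(names(model_configs))) {
    names(model_configs) <- paste0("d_c=", vapply(model_configs,
                                                  function(c) c$d_c,
                                                  integer(1)))
  }
  truth <- dataset_split_ids(dataset, split)$labels
  rows <- list()
  for (nm in names(model_configs)) {
    mc <- model_configs[[nm]]
    for (sd in data_seeds) {
      fit <- fits[[nm]][[as.character(sd)]]
      if (is.null(fit)) {
        fit <- reshuffle_and_retrain(dataset, embedding, mc, train_config, sd)
      }
      rep <- metrics_report(predict_matrix(fit, dataset, split = split), truth)
      rows[[length(rows) + 1L]] <- tibble(
        model = nm, d_c = mc$d_c, data_seed = as.integer(sd),
        f1_macro = rep$f1_macro,
        zero_precision = list(zero_precision_codes(rep$per_label)))
    }
  }
  results <- bind_rows(rows)
  changed <- results |>
    group_by(.data$model) |>
    summarise(
      n_seeds = n(),
      sets_change = length(unique(purrr::map_chr(
        .data$zero_precision, ~ paste(sort(.x), collapse = "|")))) > 1,
      always_empty = all(lengths(.data$zero_precision) == 0),
      .groups = "drop")
  structure(
    list(results = results, changed = changed,
         manifest = experiment_manifest(
           "shuffle", model_configs,
           purrr::map(data_seeds, function(sd) {
             tc <- train_config; tc$data_seed <- as.integer(sd); tc
           }))),
    class = "swam_shuffle"
  )
}

#' @export
print.swam_shuffle <- function(x, ...) {
  cat("<swam_shuffle>\n")
  df <- mutate(x$results, zero_precision = purrr::map_chr(
    .data$zero_precision, ~ paste(.x, collapse = ",")))
  print(df)
  invisible(x)
}
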