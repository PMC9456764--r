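#' Restrict a feature table to labeled, hyperconserved TLs
#'
#' Keeps rows flagged hyperconserved whose label is `active` or
#' `nonactive` — the modeling subset of an assayed cohort. Retained counts
#' per label are reported as a message; an empty result is an error. The
#' operation is idempotent.
#'
#' @param table Feature-table tibble with `label` and `hyperconserved`
#'   columns.
#' @return The filtered tibble.
#' @export
filter_labeled_hyperconserved <- function(table) {
  if (!all(c("label", "hyperconserved") %in% names(table))) {
    abort("filter_labeled_hyperconserved: need 'label' and 'hyperconserved' columns")
  }
  out <- table |>
    filter(!is.na(.data$hyperconserved), .data$hyperconserved,
           .data$label %in% c("active", "nonactive"))
  if (nrow(out) == 0) abort("filter_labeled_hyperconserved: no rows retained")
  message(sprintf("retained %d TLs (%d active, %d nonactive)",
                  nrow(out), sum(out$label == "active"),
                  sum(out$label == "nonactive")))
  out
}

#' Run the full TL audit pipeline
#'
#' Orchestrates feature extraction, the enrichment battery, and the repeated
#' classifier evaluation over a cohort of TLs plus evidence layers — either
#' a synthetic `tl_cohort` from [generate_cohort()] or a list with the same
#' elements built from real files (`tls`, and optionally `promoters`,
#' `splice3`, `cds`, `cage_peaks`, `rnaseq`). Layers may be omitted:
#' CAGE-less cohorts get missing CAGE features, which the classifier
#' mean-imputes. Results are deterministic given the inputs and
#' `spec$seed`.
#'
#' @param cohort A `tl_cohort` or compatible list of layers.
#' @param spec A [model_spec()] for the classifier stage.
#' @param window_nt,pseudocount Feature-extraction parameters (see
#'   [cage_features()], [rnaseq_bias()]).
#' @param out_dir Optional directory; when given, the feature table,
#'   enrichment table, per-repeat accuracies, coefficients, and a run
#'   report (seed, version, stage record counts) are written there.
#' @return A list of class `tl_audit`: `features`, `modeled` (filtered
#'   table), `enrichment`, `model`.
#' @export
run_audit <- function(cohort, spec = model_spec(), window_nt = 10,
                      pseudocount = 1, out_dir = NULL) {
  stopifnot(is.list(cohort), !is.null(cohort$tls))
  features <- build_feature_table(
    cohort$tls, promoters = cohort$promoters, splice3 = cohort$splice3,
    cds = cohort$cds, cage_peaks = cohort$cage_peaks, rnaseq = cohort$rnaseq,
    window_nt = window_nt, pseudocount = pseudocount
  )
  modeled <- if ("hyperconserved" %in% names(features)) {
    suppressMessages(filter_labeled_hyperconserved(features))
  } else {
    features |> filter(.data$label %in% c("active", "nonactive"))
  }
  enrichment <- enrichment_battery(modeled)
  model <- evaluate_repeated(modeled, spec)
  out <- structure(list(features = features, modeled = modeled,
                        enrichment = enrichment, model = model, spec = spec),
                   class = "tl_audit")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(out_dir, x)
    write_feature_table(features, fp("features.tsv"))
    readr::write_tsv(enrichment, fp("enrichment.tsv"))
    readr::write_tsv(model$repeats, fp("accuracies.tsv"))
    readr::write_tsv(as_tibble(model$coefficients), fp("coefficients.tsv"))
    writeLines(c(
      sprintf("tlaudit %s", as.character(utils::packageVersion("tlaudit"))),
      sprintf("seed: %d", spec$seed),
      sprintf("features: %d TLs x %d columns", nrow(features), ncol(features)),
      sprintf("stats: %d features tested", nrow(enrichment)),
      sprintf("classify: %d repeats, mean accuracy %.4f, max %.4f",
              nrow(model$repeats), model$mean_accuracy, model$max_accuracy)
    ), fp("report.txt"))
  }
  out
}

#' @export
print.tl_audit <- function(x, ...) {
  cat(sprintf("TL audit: %d TLs (%d modeled)\n", nrow(x$features),
              nrow(x$modeled)))
  cat("Top enrichment results:\n")
  print(head(x$enrichment, 5))
  print(x$model)
  invisible(x)
}
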