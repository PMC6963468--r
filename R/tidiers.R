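# broom-style tidiers for the fitted-result objects.

#' Tidy an evaluation report
#'
#' One row per fold with the fold-level metrics; pooled values are available
#' via [glance.eval_report()].
#'
#' @param x An `eval_report` from [cross_validate()] or [nested_select()].
#' @param ... Unused.
#' @return Tibble with `fold` and the per-fold metric columns.
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::select(x$per_fold, -"undefined")
}

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble: pooled accuracy, sensitivity, specificity,
#'   precision, F1, AUC, counts, and fold count.
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(
    dplyr::select(x$metrics, -"undefined"),
    tibble::tibble(auc = x$auc, folds = x$folds))
}

#' Tidy a feature-selection result
#'
#' The full evaluation trace, one row per scored subset, in evaluation order.
#'
#' @param x An `fs_result` from [best_first_search()] or [random_search()].
#' @param ... Unused.
#' @return Tibble with `subset` (list-column), `size`, `objective`, and
#'   `selected` flag.
#' @export
tidy.fs_result <- function(x, ...) {
  dplyr::mutate(
    x$trace,
    step = dplyr::row_number(),
    selected = purrr::map_lgl(.data$subset, identical, as.character(x$selected)))
}

#' One-row summary of a feature-selection result
#'
#' @param x An `fs_result`.
#' @param ... Unused.
#' @return One-row tibble: method, selected subset (comma separated), its
#'   size, objective, and evaluation count.
#' @export
glance.fs_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    selected = paste(x$selected, collapse = ","),
    size = length(x$selected),
    objective = x$objective,
    n_evaluated = x$n_evaluated)
}
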