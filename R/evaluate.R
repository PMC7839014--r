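#' Fold-error classification of prediction ratios
#'
#' A prediction ratio (predicted/observed) within 0.5- to 2-fold is the
#' conventional acceptance window for interspecies clearance prediction.
#' Boundaries are inclusive: a ratio of exactly 0.5 or 2.0 classifies as
#' `"within"`. Classification always uses unrounded ratios.
#'
#' @param ratio Numeric vector of prediction ratios.
#' @return Character vector: `"under"` (< 0.5), `"within"` (\[0.5, 2\]) or
#'   `"over"` (> 2); `NA` propagates.
#' @export
classify_fold_error <- function(ratio) {
  dplyr::case_when(
    is.na(ratio) ~ NA_character_,
    ratio < 0.5 ~ "under",
    ratio <= 2.0 ~ "within",
    TRUE ~ "over"
  )
}

#' Evaluate predictions against observed human clearance
#'
#' Fills the `ratio` (= `predicted_cl / observed_cl`) and `classification`
#' columns of a prediction tibble wherever an observed value is available.
#' The percent prediction error is `(ratio - 1) * 100`.
#'
#' @param predictions Prediction tibble with columns `predicted_cl` and
#'   `observed_cl` (see [scale_three_species()] and friends).
#' @param observed Optional numeric vector overriding the `observed_cl`
#'   column (recycled per row); must be strictly positive.
#' @return `predictions` with `ratio` and `classification` columns filled.
#' @export
evaluate_predictions <- function(predictions, observed = NULL) {
  if (!is.null(observed)) {
    predictions$observed_cl <- rep(observed, length.out = nrow(predictions))
  }
  obs <- predictions$observed_cl
  if (any(!is.na(obs) & obs <= 0)) {
    abort("Observed clearance must be strictly positive")
  }
  predictions$ratio <- predictions$predicted_cl / obs
  predictions$classification <- classify_fold_error(predictions$ratio)
  predictions
}

#' Summarise fold-error performance of prediction strategies
#'
#' Counts predictions falling under, within and over the 0.5-2-fold window,
#' per strategy group. Input order does not affect the result.
#'
#' @param predictions Evaluated prediction tibble (every row must carry a
#'   `ratio`; see [evaluate_predictions()]).
#' @param group Character vector of grouping columns; defaults to
#'   `strategy` and `detail`, falling back to whichever are present.
#' @return A tibble with one row per group: `n_observations`, `n_under`,
#'   `n_within`, `n_over`, `pct_within` (0-100), `ratio_min`, `ratio_max`.
#' @examples
#' adc_clearance_data() |>
#'   dplyr::filter(n_animal_species >= 3) |>
#'   scale_three_species(strategy = "sa") |>
#'   summarize_strategy()
#' @export
summarize_strategy <- function(predictions,
                               group = intersect(c("strategy", "detail", "exponent_b"),
                                                 names(predictions))) {
  if (nrow(predictions) == 0) {
    abort("Cannot summarise an empty prediction set")
  }
  if (any(is.na(predictions$ratio))) {
    abort("All predictions must be evaluated (non-missing ratio); see evaluate_predictions()")
  }
  if ("exponent_b" %in% group && !all(predictions$strategy %in%
                                      c("one_species_fixed"))) {
    group <- setdiff(group, "exponent_b")
  }
  predictions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n_observations = dplyr::n(),
      n_under = sum(.data$classification == "under"),
      n_within = sum(.data$classification == "within"),
      n_over = sum(.data$classification == "over"),
      pct_within = 100 * sum(.data$classification == "within") / dplyr::n(),
      ratio_min = min(.data$ratio),
      ratio_max = max(.data$ratio),
      .groups = "drop"
    )
}
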