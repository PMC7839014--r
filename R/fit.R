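#' Fit an allometric power law
#'
#' Fits `value = a * weight^b` by ordinary least squares of `log(value)` on
#' `log(weight)`: `a = exp(intercept)`, `b = slope`. This is the standard
#' log-log regression behind allometric scaling (equivalent to a spreadsheet
#' power trendline); with exactly two points the fitted line passes through
#' both transformed points.
#'
#' @param points Data frame with numeric columns `weight` (kg) and `value`
#'   (the quantity being scaled: clearance in mL/day, or a clearance x
#'   correction-factor product). At least two rows with distinct weights and
#'   strictly positive values.
#' @param method Method tag recorded on the fit: `"simple"`,
#'   `"mlp_product"` or `"brain_weight_product"`.
#' @param species Optional character vector of species identifiers, recorded
#'   on the fit.
#' @return An object of class `allometric_fit`: a list with elements
#'   `coefficient_a`, `exponent_b`, `method`, `n_species`, `species_used`,
#'   `points` and the underlying `lm` fit (`model`). Supports [tidy()],
#'   [glance()], [autoplot()], [print()] and [predict_human()].
#' @examples
#' pts <- data.frame(weight = c(0.02, 0.25, 3.5), value = c(0.20, 2.37, 46.9))
#' fit <- fit_power_law(pts)
#' glance(fit)
#' predict_human(fit)
#' @export
fit_power_law <- function(points,
                          method = c("simple", "mlp_product",
                                     "brain_weight_product"),
                          species = NULL) {
  method <- match.arg(method)
  if (!is.data.frame(points) || !all(c("weight", "value") %in% names(points))) {
    abort("`points` must be a data frame with columns `weight` and `value`")
  }
  w <- points$weight
  v <- points$value
  if (length(w) < 2) {
    abort("At least two (weight, value) points are required to fit a power law")
  }
  if (any(!is.finite(w) | w <= 0)) {
    abort("All weights must be finite and strictly positive")
  }
  if (anyDuplicated(w)) {
    abort("Weights must be distinct; repeated body weights give a degenerate fit")
  }
  if (any(!is.finite(v) | v <= 0)) {
    abort("All values must be finite and strictly positive (log transform)")
  }
  model <- lm(log(v) ~ log(w))
  cf <- coef(model)
  structure(
    list(
      coefficient_a = exp(cf[[1]]),
      exponent_b = cf[[2]],
      method = method,
      n_species = length(w),
      species_used = species %||% rep(NA_character_, length(w)),
      points = tibble::tibble(weight = w, value = v),
      model = model
    ),
    class = "allometric_fit"
  )
}

#' Fit a series with an optional correction factor
#'
#' Applies [fit_power_law()] to one drug x analyte series. For the corrected
#' methods each animal clearance is first multiplied by the species'
#' correction constant: MLP in years (`"mlp_product"`) or brain weight in g
#' (`"brain_weight_product"`). With all correction constants equal the
#' corrected fit reduces to simple allometry.
#'
#' @param animals Tibble of animal observations with columns `species`,
#'   `body_weight_kg`, `clearance_ml_per_day` (the `animals` element of a
#'   series table row, see [read_clearance_data()]).
#' @inheritParams read_clearance_data
#' @param method `"simple"`, `"mlp_product"` or `"brain_weight_product"`.
#' @return An `allometric_fit`, see [fit_power_law()].
#' @export
fit_series <- function(animals, constants = species_constants(),
                       method = c("simple", "mlp_product",
                                  "brain_weight_product")) {
  method <- match.arg(method)
  sp <- resolve_species(animals$species, constants)
  idx <- match(sp, constants$species)
  correction <- switch(method,
    simple = rep(1, length(sp)),
    mlp_product = constants$mlp_years[idx],
    brain_weight_product = constants$brain_weight_g[idx]
  )
  fit_power_law(
    data.frame(
      weight = constants$body_weight_kg[idx],
      value = animals$clearance_ml_per_day * correction
    ),
    method = method,
    species = sp
  )
}

#' Predict human clearance from an allometric fit
#'
#' Evaluates the fitted power law at the human body weight, using unrounded
#' fit parameters. For corrected fits the evaluated product is divided by the
#' corresponding human constant: MLP 93.4 years for `"mlp_product"`, brain
#' weight 1400 g for `"brain_weight_product"` (taken from `constants`).
#'
#' @param fit An `allometric_fit`, see [fit_power_law()].
#' @inheritParams read_clearance_data
#' @return Predicted human clearance in mL/day (a single number).
#' @export
predict_human <- function(fit, constants = species_constants()) {
  stopifnot(inherits(fit, "allometric_fit"))
  human <- constants[constants$species == "human", , drop = FALSE]
  if (nrow(human) != 1) {
    abort("Constants registry must contain exactly one 'human' entry")
  }
  denom <- switch(fit$method,
    simple = 1,
    mlp_product = human$mlp_years,
    brain_weight_product = human$brain_weight_g
  )
  fit$coefficient_a * human$body_weight_kg^fit$exponent_b / denom
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf(
    "Allometric fit (%s): a = %.4g, b = %.4g  [%d species%s]\n",
    x$method, x$coefficient_a, x$exponent_b, x$n_species,
    if (all(is.na(x$species_used))) "" else
      paste0(": ", paste(x$species_used, collapse = ", "))
  ))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x An `allometric_fit`.
#' @param ... Unused.
#' @method tidy allometric_fit
#' @export
tidy.allometric_fit <- function(x, ...) {
  se <- tryCatch(sqrt(diag(stats::vcov(x$model))), error = function(e) rep(NA_real_, 2))
  if (x$n_species < 3) se <- rep(NA_real_, 2)
  tibble::tibble(
    term = c("coefficient_a", "exponent_b"),
    estimate = c(x$coefficient_a, x$exponent_b),
    # the coefficient is estimated on the log scale; its standard error is
    # reported there (delta-method back-transform would hide the asymmetry)
    std.error = c(se[1], se[2]),
    scale = c("log", "identity")
  )
}

#' @rdname fit_power_law
#' @method glance allometric_fit
#' @export
glance.allometric_fit <- function(x, ...) {
  r2 <- if (x$n_species > 2) summary(x$model)$r.squared else NA_real_
  tibble::tibble(
    coefficient_a = x$coefficient_a,
    exponent_b = x$exponent_b,
    method = x$method,
    n_species = x$n_species,
    r.squared = r2
  )
}

#' @rdname fit_power_law
#' @param object An `allometric_fit`.
#' @method autoplot allometric_fit
#' @export
autoplot.allometric_fit <- function(object, ...) {
  grid <- tibble::tibble(
    weight = exp(seq(log(min(object$points$weight)),
                     log(max(object$points$weight)), length.out = 50))
  )
  grid$value <- object$coefficient_a * grid$weight^object$exponent_b
  ggplot2::ggplot(object$points, ggplot2::aes(.data$weight, .data$value)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Body weight (kg)", y = "Fitted quantity",
      title = sprintf("%s fit: a = %.3g, b = %.3g",
                      object$method, object$coefficient_a, object$exponent_b)
    ) +
    ggplot2::theme_minimal()
}
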