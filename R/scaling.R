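#' Human clearance prediction by three-species allometric scaling
#'
#' Runs one of the three-species strategies on every series of a nested
#' series table (see [read_clearance_data()]):
#' \describe{
#'   \item{`"sa"`}{simple allometry only.}
#'   \item{`"roe"`}{Rule of Exponents for biologics: simple fit first, then a
#'     brain-weight-corrected refit when the simple exponent exceeds 1.0
#'     (see [roe_select()]).}
#'   \item{`"mlp"`}{MLP-corrected fit, regardless of the exponent. For ADCs
#'     this systematically under-predicts human clearance; it is provided to
#'     demonstrate that inapplicability.}
#' }
#'
#' @param data Nested series tibble; every series must have at least three
#'   animal species (filter with `dplyr::filter(n_animal_species >= 3)`).
#' @inheritParams read_clearance_data
#' @param strategy `"roe"`, `"sa"` or `"mlp"`.
#' @return A prediction tibble with one row per series: `drug`, `analyte`,
#'   `strategy`, `detail`, `method`, `band`, `coefficient_a`, `exponent_b`,
#'   `exponent_sa`, `predicted_cl`, `observed_cl`, `ratio`,
#'   `classification`. Ratios and fold classifications are filled where the
#'   observed human clearance is available.
#' @examples
#' adc_clearance_data() |>
#'   dplyr::filter(n_animal_species >= 3) |>
#'   scale_three_species(strategy = "roe")
#' @export
scale_three_species <- function(data, constants = species_constants(),
                                strategy = c("roe", "sa", "mlp")) {
  strategy <- match.arg(strategy)
  too_few <- data$n_animal_species < 3
  if (any(too_few)) {
    abort(paste0(
      "Three-species scaling needs >= 3 animal species; series with fewer: ",
      paste(unique(data$drug[too_few]), collapse = ", "),
      ". Use scale_two_species() or scale_one_species() for those."
    ))
  }
  rows <- purrr::pmap_dfr(
    list(data$drug, data$analyte, data$animals, data$human_cl_ml_per_day),
    function(drug, analyte, animals, observed) {
      sa <- fit_series(animals, constants, "simple")
      fit <- sa
      band <- roe_select(sa$exponent_b)$band
      if (strategy == "roe") {
        decision <- roe_select(sa$exponent_b, "biologic")
        if (decision$chosen_method == "brain_weight_product") {
          fit <- fit_series(animals, constants, "brain_weight_product")
        }
      } else if (strategy == "mlp") {
        fit <- fit_series(animals, constants, "mlp_product")
      }
      tibble::tibble(
        drug = drug, analyte = analyte,
        strategy = paste0("three_species_", strategy),
        detail = fit$method,
        method = fit$method,
        band = band,
        coefficient_a = fit$coefficient_a,
        exponent_b = fit$exponent_b,
        exponent_sa = sa$exponent_b,
        predicted_cl = predict_human(fit, constants),
        observed_cl = observed
      )
    }
  )
  evaluate_predictions(rows)
}

#' Human clearance prediction by two-species allometric scaling
#'
#' Fits the exact two-point power law (the line through both log-log points)
#' for each requested species pair and predicts at the human body weight.
#' The Rule of Exponents and correction factors are never applied in
#' two-species scaling.
#'
#' @inheritParams scale_three_species
#' @param pair Optional character vector of two species. When `NULL`, all of
#'   `(mouse, monkey)`, `(mouse, rat)` and `(rat, monkey)` are fitted for
#'   every series in which both members are present. When given, every series
#'   must contain both species.
#' @return A prediction tibble, one row per series x pair, with `detail` set
#'   to `"<species1>,<species2>"`. See [scale_three_species()] for columns.
#' @export
scale_two_species <- function(data, constants = species_constants(),
                              pair = NULL) {
  default_pairs <- list(c("mouse", "monkey"), c("mouse", "rat"),
                        c("rat", "monkey"))
  pairs <- if (is.null(pair)) default_pairs else list(resolve_species(pair, constants))
  if (!is.null(pair) && length(pairs[[1]]) != 2) {
    abort("`pair` must name exactly two species")
  }
  rows <- purrr::pmap_dfr(
    list(data$drug, data$analyte, data$animals, data$human_cl_ml_per_day),
    function(drug, analyte, animals, observed) {
      purrr::map_dfr(pairs, function(p) {
        present <- p %in% animals$species
        if (!all(present)) {
          if (!is.null(pair)) {
            abort(sprintf(
              "Species %s absent from series %s (%s)",
              paste(p[!present], collapse = ", "), drug, analyte
            ))
          }
          return(tibble::tibble())
        }
        sub <- animals[match(p, animals$species), , drop = FALSE]
        fit <- fit_series(sub, constants, "simple")
        tibble::tibble(
          drug = drug, analyte = analyte,
          strategy = "two_species_sa",
          detail = paste(p, collapse = ","),
          method = "simple",
          band = NA_character_,
          coefficient_a = fit$coefficient_a,
          exponent_b = fit$exponent_b,
          exponent_sa = fit$exponent_b,
          predicted_cl = predict_human(fit, constants),
          observed_cl = observed
        )
      })
    }
  )
  evaluate_predictions(rows)
}

#' Human clearance prediction from a single species
#'
#' One-species scaling with a fixed allometric exponent: the species
#' clearance is multiplied by the human/species body-weight ratio raised to
#' the exponent,
#' `CL_human = CL_species * (W_human / W_species)^b`.
#' With `b = 1` this is linear per-kg extrapolation. Common fixed exponents
#' for antibodies are 0.75, 0.80, 0.85 and 1.0.
#'
#' @inheritParams scale_three_species
#' @param species Character vector of source species (never `"human"`).
#'   Series lacking a requested species contribute no rows for it.
#' @param exponents Numeric vector of fixed exponents, all > 0.
#' @return A prediction tibble, one row per series x available species x
#'   exponent; `detail` holds the source species and `exponent_b` the fixed
#'   exponent used.
#' @examples
#' adc_clearance_data() |>
#'   dplyr::filter(drug == "DNIB0600A") |>
#'   scale_one_species(species = "monkey", exponents = 1.0)
#' @export
scale_one_species <- function(data, constants = species_constants(),
                              species = c("mouse", "rat", "monkey"),
                              exponents = c(0.75, 0.80, 0.85, 1.0)) {
  species <- resolve_species(species, constants)
  if ("human" %in% species) {
    abort("One-species scaling predicts human clearance; 'human' cannot be the source species")
  }
  if (length(exponents) == 0 || any(!is.finite(exponents) | exponents <= 0)) {
    abort("`exponents` must be a non-empty vector of positive numbers")
  }
  present_anywhere <- unique(unlist(purrr::map(data$animals, "species")))
  if (!any(species %in% present_anywhere)) {
    abort(paste0("None of the requested species (",
                 paste(species, collapse = ", "),
                 ") occur in the supplied series"))
  }
  w_human <- constants$body_weight_kg[constants$species == "human"]
  rows <- purrr::pmap_dfr(
    list(data$drug, data$analyte, data$animals, data$human_cl_ml_per_day),
    function(drug, analyte, animals, observed) {
      sub <- animals[animals$species %in% species, , drop = FALSE]
      if (nrow(sub) == 0) return(tibble::tibble())
      i <- rep(seq_len(nrow(sub)), each = length(exponents))
      b <- rep(exponents, nrow(sub))
      tibble::tibble(
        drug = drug, analyte = analyte,
        strategy = "one_species_fixed",
        detail = sub$species[i],
        method = "fixed_exponent",
        band = NA_character_,
        coefficient_a = NA_real_,
        exponent_b = b,
        exponent_sa = NA_real_,
        predicted_cl = sub$clearance_ml_per_day[i] *
          (w_human / sub$body_weight_kg[i])^b,
        observed_cl = observed
      )
    }
  )
  evaluate_predictions(rows)
}

#' One-species prediction averaged over several exponents
#'
#' Computes the [scale_one_species()] prediction for each exponent in
#' `exponents` and averages them (arithmetic mean). Averaging over
#' `{0.85, 1.0, 1.1}` was proposed to stabilise mouse-based predictions,
#' which a single exponent of 1.0 tends to under-predict.
#'
#' @inheritParams scale_one_species
#' @param exponents Exponents to average over; default `c(0.85, 1.0, 1.1)`.
#' @return A prediction tibble, one row per series x available species;
#'   `detail` records the source species and exponent list.
#' @export
scale_one_species_average <- function(data, constants = species_constants(),
                                      species = "mouse",
                                      exponents = c(0.85, 1.0, 1.1)) {
  per_exponent <- scale_one_species(data, constants, species, exponents)
  rows <- per_exponent |>
    dplyr::group_by(.data$drug, .data$analyte, .data$detail,
                    .data$observed_cl) |>
    dplyr::summarise(predicted_cl = mean(.data$predicted_cl), .groups = "drop") |>
    dplyr::transmute(
      drug = .data$drug, analyte = .data$analyte,
      strategy = "one_species_average",
      detail = sprintf("%s avg(%s)", .data$detail,
                       paste(format(exponents, trim = TRUE), collapse = ", ")),
      method = "fixed_exponent_average",
      band = NA_character_,
      coefficient_a = NA_real_,
      exponent_b = NA_real_,
      exponent_sa = NA_real_,
      predicted_cl = .data$predicted_cl,
      observed_cl = .data$observed_cl
    ) |>
    dplyr::arrange(.data$drug, .data$analyte)
  evaluate_predictions(rows)
}
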