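#' Rule of Exponents method selection
#'
#' Selects the scaling method from the exponent of the simple-allometry fit.
#' The classical small-molecule rule is: simple allometry for `b` in
#' \[0.56, 0.70\], the MLP product for `b` in (0.70, 1.0), and the
#' brain-weight product for `b` in \[1.0, 1.3\]. For biologics (monoclonal
#' antibodies, ADCs and other therapeutic proteins) the MLP correction
#' systematically under-predicts human clearance and is never selected: the
#' rule reduces to the brain-weight product when `b > 1.0` and simple
#' allometry otherwise.
#'
#' Exponents outside \[0.56, 1.3\] are flagged via the `band` column
#' (`"low"` / `"high"`); no additional correction is invented for them and
#' the class rule above is applied unchanged.
#'
#' @param exponent_b Numeric vector of simple-allometry exponents.
#' @param molecule_class `"biologic"` (default) or `"small_molecule"`.
#' @return A tibble with one row per exponent: `exponent_b`,
#'   `molecule_class`, `band` (`low`, `sa_band`, `mlp_band`, `brain_band`,
#'   `high`), `chosen_method` and `in_band`.
#' @examples
#' roe_select(c(0.89, 1.06))
#' roe_select(0.85, molecule_class = "small_molecule")
#' @export
roe_select <- function(exponent_b,
                       molecule_class = c("biologic", "small_molecule")) {
  molecule_class <- match.arg(molecule_class)
  if (any(!is.finite(exponent_b))) {
    abort("`exponent_b` must be finite")
  }
  band <- dplyr::case_when(
    exponent_b < 0.56 ~ "low",
    exponent_b <= 0.70 ~ "sa_band",
    exponent_b < 1.0 ~ "mlp_band",
    exponent_b <= 1.3 ~ "brain_band",
    TRUE ~ "high"
  )
  chosen <- if (molecule_class == "biologic") {
    ifelse(exponent_b > 1.0, "brain_weight_product", "simple")
  } else {
    dplyr::case_when(
      band == "sa_band" ~ "simple",
      band == "mlp_band" ~ "mlp_product",
      band == "brain_band" ~ "brain_weight_product",
      TRUE ~ "simple"
    )
  }
  tibble::tibble(
    exponent_b = exponent_b,
    molecule_class = molecule_class,
    band = band,
    chosen_method = chosen,
    in_band = band %in% c("sa_band", "mlp_band", "brain_band")
  )
}
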