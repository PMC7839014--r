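#' Write the full reproduction report to disk
#'
#' Runs [run_full_analysis()] and writes every result table as CSV together
#' with an aligned plain-text rendering, a per-strategy summary, and a
#' discrepancy report comparing each computed cell with the published
#' reference value ([compare_published()]). Output is deterministic:
#' rerunning with the same inputs produces byte-identical files (no
#' timestamps inside data files).
#'
#' @param out_dir Output directory; created (recursively) if missing.
#' @inheritParams run_full_analysis
#' @return The `adc_analysis` object, invisibly.
#' @export
reproduce_analysis <- function(out_dir,
                               data = adc_clearance_data(),
                               constants = species_constants(),
                               fixed_exponents = c(0.75, 0.80, 0.85, 1.0),
                               avg_exponents = c(0.85, 1.0, 1.1)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("Could not create output directory '%s'", out_dir))
  }
  analysis <- run_full_analysis(data, constants, fixed_exponents,
                                avg_exponents)
  tables <- list(
    three_species = analysis$three_species,
    mlp_comparison = analysis$mlp_comparison,
    two_species = analysis$two_species,
    one_species = analysis$one_species,
    one_species_average = analysis$one_species_average
  )
  for (nm in names(tables)) {
    tbl <- render_rounding(tables[[nm]])
    readr::write_csv(tbl, file.path(out_dir, paste0(nm, ".csv")))
    writeLines(render_text_table(tbl),
               file.path(out_dir, paste0(nm, ".txt")))
  }
  readr::write_csv(analysis$summary, file.path(out_dir, "summary.csv"))
  writeLines(render_text_table(analysis$summary),
             file.path(out_dir, "summary.txt"))
  disc <- compare_published(analysis) |>
    dplyr::select("table", "drug", "analyte", "detail", "exponent",
                  cell = "quantity", "printed", "computed", "rel_error",
                  "status")
  readr::write_csv(disc, file.path(out_dir, "discrepancy_report.csv"))
  invisible(analysis)
}

# Display rounding for rendered tables: exponents to 2 dp, coefficients at
# mixed precision (1 dp when >= 10, else 2 dp), predictions to whole mL/day,
# ratios to 2 dp. Classification always derives from unrounded ratios
# upstream; this is presentation only.
render_rounding <- function(tbl) {
  r <- tbl
  round_mixed <- function(a) ifelse(a >= 10, round(a, 1), round(a, 2))
  for (col in intersect(c("coefficient_a", "coefficient"), names(r))) {
    r[[col]] <- round_mixed(r[[col]])
  }
  for (col in intersect(c("exponent_b", "exponent_sa"), names(r))) {
    r[[col]] <- round(r[[col]], 2)
  }
  for (col in intersect(c("predicted_cl", "predicted_sa", "predicted_mlp"),
                        names(r))) {
    r[[col]] <- round(r[[col]])
  }
  for (col in intersect(c("ratio", "ratio_sa", "ratio_mlp"), names(r))) {
    r[[col]] <- round(r[[col]], 2)
  }
  r
}

# Fixed-width text rendering of a data frame (right-aligned numerics).
render_text_table <- function(tbl) {
  df <- as.data.frame(tbl)
  cols <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    txt <- if (is.numeric(x)) format(x, trim = TRUE, na.encode = TRUE) else
      as.character(x)
    txt[is.na(x)] <- "-"
    width <- max(nchar(c(nm, txt)), na.rm = TRUE)
    formatC(c(nm, txt), width = width,
            flag = if (is.numeric(x)) "" else "-")
  })
  rows <- do.call(paste, c(cols, sep = "  "))
  c(rows[1], strrep("-", nchar(rows[1])), rows[-1])
}

#' Predict human clearance for one drug series
#'
#' Convenience wrapper running a single strategy on one drug x analyte
#' series of a dataset, with fit diagnostics and the Rule-of-Exponents
#' decision reported as messages.
#'
#' @inheritParams run_full_analysis
#' @param drug Drug name (must match a series in `data`; unknown names error
#'   listing the available series).
#' @param analyte `"total"` or `"conjugate"`.
#' @param strategy One of `"three_species_roe"`, `"three_species_sa"`,
#'   `"three_species_mlp"`, `"two_species"`, `"one_species"`,
#'   `"one_species_average"`.
#' @param ... Passed to the underlying scaling function (`pair`, `species`,
#'   `exponents`).
#' @param quiet Suppress diagnostic messages.
#' @return A prediction tibble (see [scale_three_species()]).
#' @examples
#' predict_series(drug = "Thiomab", strategy = "three_species_roe")
#' @export
predict_series <- function(drug, analyte = "total",
                           strategy = c("three_species_roe",
                                        "three_species_sa",
                                        "three_species_mlp",
                                        "two_species", "one_species",
                                        "one_species_average"),
                           data = adc_clearance_data(),
                           constants = species_constants(), ...,
                           quiet = FALSE) {
  strategy <- match.arg(strategy)
  series <- pick_series(data, drug, analyte)
  if (startsWith(strategy, "three_species") && !quiet) {
    sa <- fit_series(series$animals[[1]], constants, "simple")
    decision <- roe_select(sa$exponent_b, "biologic")
    message(sprintf(
      "Simple allometry: a = %.4g, b = %.4g (band %s); ROE selects %s%s",
      sa$coefficient_a, sa$exponent_b, decision$band, decision$chosen_method,
      if (decision$chosen_method == "brain_weight_product")
        sprintf(" (b = %.2f > 1.0)", sa$exponent_b) else ""
    ))
  }
  switch(strategy,
    three_species_roe = scale_three_species(series, constants, "roe"),
    three_species_sa = scale_three_species(series, constants, "sa"),
    three_species_mlp = scale_three_species(series, constants, "mlp"),
    two_species = scale_two_species(series, constants, ...),
    one_species = scale_one_species(series, constants, ...),
    one_species_average = scale_one_species_average(series, constants, ...)
  )
}
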