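#' Read a multi-species clearance dataset
#'
#' Reads a tidy CSV of absolute clearance values (mL/day, not per kg) with
#' header `drug,analyte,species,clearance_ml_per_day` and returns one row per
#' drug x analyte series. Human rows supply the observed human clearance for
#' that series; they are stored in their own column, never among the animal
#' observations, so fitting code cannot accidentally include human data in a
#' fit. Animal observations are ordered by ascending body weight.
#'
#' @param path Path to the CSV file.
#' @param constants Species constants registry, see [species_constants()].
#' @return A nested tibble with columns:
#'   \describe{
#'     \item{drug}{drug name}
#'     \item{analyte}{`"total"` (total antibody) or `"conjugate"`}
#'     \item{animals}{list column; each element a tibble with `species`,
#'       `body_weight_kg`, `clearance_ml_per_day` for the non-human species}
#'     \item{human_cl_ml_per_day}{observed human clearance, `NA` if absent}
#'     \item{n_animal_species}{number of animal species in the series}
#'   }
#' @seealso [adc_clearance_data()] for the bundled dataset,
#'   [write_clearance_data()] for the inverse operation.
#' @export
read_clearance_data <- function(path, constants = species_constants()) {
  x <- readr::read_csv(path, col_types = readr::cols(
    drug = readr::col_character(),
    analyte = readr::col_character(),
    species = readr::col_character(),
    clearance_ml_per_day = readr::col_double()
  ))
  as_series_table(x, constants)
}

#' Assemble a series table from a flat observation data frame
#'
#' Validates and nests a flat data frame of clearance observations (one row
#' per drug x analyte x species) into the per-series form used by the
#' scaling functions.
#'
#' @param x Data frame with columns `drug`, `analyte`, `species`,
#'   `clearance_ml_per_day`.
#' @inheritParams read_clearance_data
#' @return A nested series tibble, see [read_clearance_data()].
#' @export
as_series_table <- function(x, constants = species_constants()) {
  required <- c("drug", "analyte", "species", "clearance_ml_per_day")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("Clearance dataset is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- tibble::as_tibble(x[required])
  x$analyte <- tolower(trimws(x$analyte))
  bad_analyte <- setdiff(unique(x$analyte), c("total", "conjugate"))
  if (length(bad_analyte) > 0) {
    abort(paste0("Analyte must be 'total' or 'conjugate'; found: ",
                 paste(bad_analyte, collapse = ", ")))
  }
  x$species <- resolve_species(x$species, constants)
  bad_cl <- which(!is.finite(x$clearance_ml_per_day) |
                    x$clearance_ml_per_day <= 0)
  if (length(bad_cl) > 0) {
    i <- bad_cl[1]
    abort(sprintf(
      "Non-positive clearance for %s (%s) %s in row %d; the log transform requires CL > 0",
      x$drug[i], x$analyte[i], x$species[i], i
    ))
  }
  key <- paste(x$drug, x$analyte, x$species, sep = " / ")
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate (drug, analyte, species) observation(s): ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }

  x <- dplyr::left_join(
    x,
    dplyr::select(constants, "species", "body_weight_kg"),
    by = "species"
  )
  is_human <- x$species == "human"
  humans <- x[is_human, c("drug", "analyte", "clearance_ml_per_day")]
  names(humans)[3] <- "human_cl_ml_per_day"
  out <- x[!is_human, ] |>
    dplyr::arrange(.data$drug, .data$analyte, .data$body_weight_kg) |>
    tidyr::nest(animals = c("species", "body_weight_kg",
                            "clearance_ml_per_day")) |>
    dplyr::left_join(humans, by = c("drug", "analyte")) |>
    dplyr::mutate(n_animal_species = purrr::map_int(.data$animals, nrow)) |>
    dplyr::arrange(.data$drug, .data$analyte)
  orphan <- dplyr::anti_join(humans, out, by = c("drug", "analyte"))
  if (nrow(orphan) > 0) {
    abort(paste0("Series with no animal observations: ",
                 paste(unique(orphan$drug), collapse = ", ")))
  }
  out
}

#' Write a clearance dataset to CSV
#'
#' Serializes a nested series table back to the flat
#' `drug,analyte,species,clearance_ml_per_day` form; human observed clearance
#' is written as a `species = human` row. Reading the file back with
#' [read_clearance_data()] reproduces the input.
#'
#' @param data Nested series tibble, see [read_clearance_data()].
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_clearance_data <- function(data, path) {
  flat <- flatten_series(data)
  readr::write_csv(flat, path)
  invisible(data)
}

flatten_series <- function(data) {
  purrr::pmap_dfr(
    list(data$drug, data$analyte, data$animals, data$human_cl_ml_per_day),
    function(drug, analyte, animals, human_cl) {
      rows <- tibble::tibble(
        drug = drug, analyte = analyte,
        species = animals$species,
        clearance_ml_per_day = animals$clearance_ml_per_day
      )
      if (is.finite(human_cl)) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          drug = drug, analyte = analyte, species = "human",
          clearance_ml_per_day = human_cl
        ))
      }
      rows
    }
  )
}

#' Bundled multi-species ADC clearance dataset
#'
#' Absolute clearance values (mL/day) of antibody-drug conjugates in mouse,
#' rat, cynomolgus monkey and human, as tabulated in the published reference
#' analysis this package reproduces. The dataset contains 13 drug x analyte
#' series (10 total-antibody, 3 conjugated-antibody): 36 animal observations
#' and 13 observed human clearances. Ten series (covering seven drugs) have
#' all three animal species; DMOT4039A, Pinatuzumab vedotin and ADC1 have
#' mouse and monkey only.
#'
#' @inheritParams read_clearance_data
#' @return A nested series tibble, see [read_clearance_data()].
#' @examples
#' adc_clearance_data()
#' @export
adc_clearance_data <- function(constants = species_constants()) {
  path <- system.file("extdata", "adc_clearance.csv", package = "adcscale",
                      mustWork = TRUE)
  read_clearance_data(path, constants)
}

# Select one series from a nested table; errors list what is available.
pick_series <- function(data, drug, analyte = "total") {
  hit <- data$drug == drug & data$analyte == analyte
  if (!any(hit)) {
    avail <- paste(data$drug, paste0("(", data$analyte, ")"), collapse = ", ")
    abort(sprintf("No series '%s' (%s). Available: %s", drug, analyte, avail))
  }
  data[hit, , drop = FALSE]
}
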