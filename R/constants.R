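#' Species constants registry
#'
#' Body weight, brain weight and maximum life-span potential (MLP) for the
#' species used in allometric scaling. Brain weight (in g) and MLP (in years)
#' are the multiplicative correction factors of the Rule of Exponents; the
#' human entries (1400 g, 93.4 y) are the denominators used when a corrected
#' fit is evaluated at the human body weight.
#'
#' With no `path`, returns the default registry used throughout the ADC
#' analysis: mouse (0.02 kg, 0.36 g, 3 y), rat (0.25 kg, 1.8 g, 4.4 y),
#' cynomolgus monkey (3.5 kg, 63 g, 18 y) and human (70 kg, 1400 g, 93.4 y).
#'
#' @param path Optional path to a CSV file with columns
#'   `species,body_weight_kg,brain_weight_g,mlp_years`. When `NULL` the
#'   built-in four-species registry is returned.
#' @return A tibble with columns `species`, `body_weight_kg`,
#'   `brain_weight_g`, `mlp_years`; one row per species.
#' @examples
#' species_constants()
#' @export
species_constants <- function(path = NULL) {
  if (is.null(path)) {
    return(default_species_constants)
  }
  read_species_constants(path)
}

default_species_constants <- tibble::tibble(
  species        = c("mouse", "rat", "monkey", "human"),
  body_weight_kg = c(0.02, 0.25, 3.5, 70),
  brain_weight_g = c(0.36, 1.8, 63, 1400),
  mlp_years      = c(3, 4.4, 18, 93.4)
)

#' Read a species constants registry from CSV
#'
#' @param path Path to a CSV file with header
#'   `species,body_weight_kg,brain_weight_g,mlp_years`.
#' @return A validated tibble (see [species_constants()]).
#' @export
read_species_constants <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    species = readr::col_character(),
    .default = readr::col_double()
  ))
  validate_species_constants(x)
}

validate_species_constants <- function(x) {
  required <- c("species", "body_weight_kg", "brain_weight_g", "mlp_years")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("Species constants are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- tibble::as_tibble(x[required])
  x$species <- tolower(trimws(x$species))
  if (anyDuplicated(x$species)) {
    dup <- unique(x$species[duplicated(x$species)])
    abort(paste0("Duplicate species in constants registry: ",
                 paste(dup, collapse = ", ")))
  }
  for (col in c("body_weight_kg", "brain_weight_g", "mlp_years")) {
    bad <- which(!is.finite(x[[col]]) | x[[col]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-positive or missing %s for species '%s' (row %d)",
        col, x$species[bad[1]], bad[1]
      ))
    }
  }
  x
}

# Resolve species names against a registry (case-insensitive); errors listing
# every unresolvable name.
resolve_species <- function(species, constants) {
  canon <- tolower(trimws(species))
  unknown <- setdiff(unique(canon), constants$species)
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown species not present in the constants registry: ",
      paste(unknown, collapse = ", "),
      ". Known species: ", paste(constants$species, collapse = ", ")
    ))
  }
  canon
}
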