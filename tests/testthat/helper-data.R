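# In-code fixtures for dataset IO tests.

flat_panel <- function(drug = "drugA", analyte = "total",
                       species = c("mouse", "rat", "monkey", "human"),
                       cl = c(0.1, 1.25, 17.5, 350)) {
  data.frame(drug = drug, analyte = analyte, species = species,
             clearance_ml_per_day = cl)
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

# Noiseless three-species panel following CL = a * W^b exactly.
exact_panel <- function(a, b, drug = "exact", analyte = "total",
                        constants = species_constants()) {
  animals <- constants[constants$species != "human", ]
  flat_panel(
    drug = drug, analyte = analyte,
    species = c(animals$species, "human"),
    cl = a * c(animals$body_weight_kg, 70)^b
  )
}
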