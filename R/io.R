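# Fixed CSV schemas (UTF-8, comma separated, header row, "." decimal, empty
# string = missing) and input validation.

.SCHEMAS <- list(
  mesocosms = c("mesocosm_id", "community_id", "herbivore_treatment",
                "soil_treatment", "replicate", "prop_exotic_planted",
                "prop_woody_planted"),
  plants = c("plant_id", "mesocosm_id", "species", "provenance",
             "functional_group", "alive", "aboveground_biomass_g",
             "belowground_biomass_g", "n_surveys_observed"),
  herbivore_species = c("species", "provenance", "mean_dry_mass_g",
                        "guild", "origin"),
  surveys = c("mesocosm_id", "survey_index", "plant_id",
              "herbivore_species", "count"),
  damage = c("mesocosm_id", "survey_index", "plant_id", "category"))

#' @keywords internal
#' @noRd
.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write a synthetic experiment to the pipeline's CSV schemas
#'
#' Emits `mesocosms.csv`, `plants.csv`, `herbivore_species.csv`,
#' `plant_species.csv`, `surveys.csv` and `damage.csv`, plus a
#' `generator_truth.json` sidecar holding the generator configuration and
#' ground-truth host ranges for parameter-recovery tests.
#'
#' @param experiment A [simulate_mesocosm_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_experiment_csvs <- function(experiment, dir) {
  stopifnot(inherits(experiment, "mesocosm_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- experiment$design
  plants <- merge(d$plant_individuals,
                  experiment$outcomes[, c("plant_id", "alive",
                                          "aboveground_biomass_g",
                                          "belowground_biomass_g",
                                          "n_surveys_observed")],
                  by = "plant_id")
  plants <- plants[order(plants$plant_id), .SCHEMAS$plants]
  files <- c(mesocosms = "mesocosms.csv", plants = "plants.csv",
             herbivore_species = "herbivore_species.csv",
             plant_species = "plant_species.csv", surveys = "surveys.csv",
             damage = "damage.csv")
  .write_csv(d$mesocosms, file.path(dir, files["mesocosms"]))
  .write_csv(plants, file.path(dir, files["plants"]))
  .write_csv(d$herbivores, file.path(dir, files["herbivore_species"]))
  .write_csv(d$plants, file.path(dir, files["plant_species"]))
  .write_csv(experiment$surveys[, .SCHEMAS$surveys],
             file.path(dir, files["surveys"]))
  .write_csv(experiment$damage[, .SCHEMAS$damage],
             file.path(dir, files["damage"]))
  truth <- list(config = unclass(d$config),
                host_ranges = d$host_ranges,
                plant_schedule = attr(experiment$surveys, "plant_schedule"))
  jsonlite::write_json(truth, file.path(dir, "generator_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, c(files, "generator_truth.json")))
}

#' Read pipeline input CSVs
#'
#' Loads the five schema files from a directory and rebuilds the
#' `plant_species` column of the survey table by joining `plants.csv`.
#'
#' @param dir Directory holding `mesocosms.csv`, `plants.csv`,
#'   `herbivore_species.csv`, `surveys.csv`, `damage.csv`.
#' @return List of data frames `mesocosms`, `plants`, `herbivores`,
#'   `surveys`, `damage`.
#' @export
read_experiment_csvs <- function(dir) {
  path <- function(f) file.path(dir, f)
  need <- c("mesocosms.csv", "plants.csv", "herbivore_species.csv",
            "surveys.csv", "damage.csv")
  missing <- need[!file.exists(path(need))]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rd <- function(f) utils::read.csv(path(f), stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8")
  out <- list(mesocosms = rd("mesocosms.csv"), plants = rd("plants.csv"),
              herbivores = rd("herbivore_species.csv"),
              surveys = rd("surveys.csv"), damage = rd("damage.csv"))
  sp <- setNames(out$plants$species, out$plants$plant_id)
  out$surveys$plant_species <- unname(sp[out$surveys$plant_id])
  out
}

#' Validate pipeline input files
#'
#' Checks each schema file for required columns, value constraints (counts
#' and biomasses non-negative, damage categories 0--5, treatments from their
#' enumerated sets) and referential integrity (every survey and damage row
#' must reference a known plant, mesocosm and herbivore). At most the first
#' 10 violations per file are reported.
#'
#' @param dir Directory of input CSVs.
#' @return Data frame of class `validation_report` with columns `file`,
#'   `check`, `status`, `detail`; attribute `valid` is TRUE when all checks
#'   pass.
#' @export
validate_inputs <- function(dir) {
  tabs <- read_experiment_csvs(dir)
  names(tabs)[names(tabs) == "herbivores"] <- "herbivore_species"
  rows <- list()
  note <- function(file, check, status, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(file = file, check = check,
                                             status = status,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  }
  first10 <- function(idx) paste("rows",
                                 paste(utils::head(which(idx), 10),
                                       collapse = ", "))
  for (nm in names(.SCHEMAS)) {
    df <- if (nm == "surveys") tabs$surveys else tabs[[nm]]
    missing <- setdiff(.SCHEMAS[[nm]], names(df))
    note(paste0(nm, ".csv"), "columns",
         if (length(missing)) "fail" else "pass",
         if (length(missing)) paste("missing:",
                                    paste(missing, collapse = ", ")) else "")
  }
  sv <- tabs$surveys
  bad <- !is.na(sv$count) & sv$count < 0
  note("surveys.csv", "count >= 0", if (any(bad)) "fail" else "pass",
       if (any(bad)) first10(bad) else "")
  unknown <- !(sv$plant_id %in% tabs$plants$plant_id)
  note("surveys.csv", "plant_id known",
       if (any(unknown)) "fail" else "pass",
       if (any(unknown))
         paste("unknown:", paste(utils::head(unique(sv$plant_id[unknown]),
                                             10), collapse = ", ")) else "")
  unknown <- !(sv$herbivore_species %in% tabs$herbivore_species$species)
  note("surveys.csv", "herbivore known",
       if (any(unknown)) "fail" else "pass",
       if (any(unknown))
         paste("unknown species:",
               paste(utils::head(unique(sv$herbivore_species[unknown]), 10),
                     collapse = ", ")) else "")
  unknown <- !(sv$mesocosm_id %in% tabs$mesocosms$mesocosm_id)
  note("surveys.csv", "mesocosm known",
       if (any(unknown)) "fail" else "pass",
       if (any(unknown)) first10(unknown) else "")
  dm <- tabs$damage
  bad <- is.na(dm$category) | dm$category < 0 | dm$category > 5 |
    dm$category != as.integer(dm$category)
  note("damage.csv", "category in 0..5", if (any(bad)) "fail" else "pass",
       if (any(bad)) first10(bad) else "")
  unknown <- !(dm$plant_id %in% tabs$plants$plant_id)
  note("damage.csv", "plant_id known", if (any(unknown)) "fail" else "pass",
       if (any(unknown)) first10(unknown) else "")
  pl <- tabs$plants
  bad <- pl$aboveground_biomass_g < 0 | pl$belowground_biomass_g < 0
  note("plants.csv", "biomass >= 0", if (any(bad)) "fail" else "pass",
       if (any(bad)) first10(bad) else "")
  bad <- pl$n_surveys_observed < 1
  note("plants.csv", "n_surveys_observed >= 1",
       if (any(bad)) "fail" else "pass", if (any(bad)) first10(bad) else "")
  bad <- !(pl$provenance %in% c("native", "exotic"))
  note("plants.csv", "provenance enum", if (any(bad)) "fail" else "pass",
       if (any(bad)) first10(bad) else "")
  ms <- tabs$mesocosms
  bad <- !(ms$herbivore_treatment %in% c("plus_H", "minus_H")) |
    !(ms$soil_treatment %in% c("home", "away"))
  note("mesocosms.csv", "treatment enums", if (any(bad)) "fail" else "pass",
       if (any(bad)) first10(bad) else "")
  hs <- tabs$herbivore_species
  bad <- is.na(hs$mean_dry_mass_g) | hs$mean_dry_mass_g <= 0
  note("herbivore_species.csv", "mean_dry_mass_g > 0",
       if (any(bad)) "fail" else "pass", if (any(bad)) first10(bad) else "")

  report <- do.call(rbind, rows)
  attr(report, "valid") <- all(report$status == "pass")
  class(report) <- c("validation_report", class(report))
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Input validation: %s (%d checks, %d failed)\n",
              if (attr(x, "valid")) "PASS" else "FAIL", nrow(x),
              sum(x$status == "fail")))
  print.data.frame(x[x$status == "fail", ], row.names = FALSE)
  invisible(x)
}
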