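# End-to-end pipeline driver: simulate -> validate -> assemble -> pac ->
# dominance, with a reproducible manifest.

#' Pipeline configuration
#'
#' @param generator A [mesocosm_config()] used when simulating inputs
#'   (ignored when `input_dir` is given).
#' @param input_dir Optional directory of existing input CSVs; when `NULL`
#'   the pipeline simulates its own inputs into `<out_dir>/input`.
#' @param out_dir Output directory.
#' @param seed Master seed; overrides the generator's seed so one number
#'   controls the whole run.
#' @param pac_direction Aggregation convention for [aggregate_pac()].
#' @param normalize_mesocosm_per_survey Divide mesocosm-level herbivore
#'   biomass by the number of surveys (default FALSE: totals over surveys).
#' @param ci_method Dominance confidence-interval method (`"t"` or
#'   `"bootstrap"`).
#' @param biomass_partition Biomass partition for the dominance test
#'   (`"total"` or `"aboveground"`).
#' @param write_d_matrices Also write the full pairwise PAC matrices as a
#'   long CSV.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = mesocosm_config(),
                            input_dir = NULL,
                            out_dir = "pacweb_run",
                            seed = generator$seed,
                            pac_direction = c("muller", "transposed"),
                            normalize_mesocosm_per_survey = FALSE,
                            ci_method = c("t", "bootstrap"),
                            biomass_partition = c("total", "aboveground"),
                            write_d_matrices = FALSE) {
  generator$seed <- as.integer(seed)
  validate_mesocosm_config(generator)
  structure(list(generator = generator, input_dir = input_dir,
                 out_dir = out_dir, seed = as.integer(seed),
                 pac_direction = match.arg(pac_direction),
                 normalize_mesocosm_per_survey = normalize_mesocosm_per_survey,
                 ci_method = match.arg(ci_method),
                 biomass_partition = match.arg(biomass_partition),
                 write_d_matrices = write_d_matrices),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Runs the requested stages and writes all stage outputs and a run manifest
#' (config hash, seed, per-file row counts, package version) to
#' `config$out_dir`. A rerun with the same configuration and seed is
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("simulate", "validate", "assemble", "pac", "dominance")`; `"all"`
#'   (default) expands to every applicable stage.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "validate", "assemble", "pac", "dominance")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  input_dir <- config$input_dir
  if ("simulate" %in% stages && is.null(input_dir)) {
    ex <- simulate_mesocosm_experiment(config$generator)
    input_dir <- file.path(config$out_dir, "input")
    write_experiment_csvs(ex, input_dir)
  }
  if (is.null(input_dir))
    stop("no input_dir configured and the simulate stage was not run",
         call. = FALSE)

  if ("validate" %in% stages) {
    report <- validate_inputs(input_dir)
    .write_csv(as.data.frame(report), file.path(config$out_dir,
                                                "validation.csv"))
    counts$validation <- nrow(report)
    if (!attr(report, "valid")) {
      fails <- report[report$status == "fail", ]
      stop("input validation failed: ",
           paste(sprintf("%s [%s] %s", fails$file, fails$check,
                         fails$detail), collapse = "; "), call. = FALSE)
    }
  }

  tabs <- read_experiment_csvs(input_dir)
  std <- standardize_herbivore_biomass(tabs$surveys, tabs$herbivores,
                                       tabs$plants)
  imats <- interaction_matrices(std, tabs$plants)

  if ("assemble" %in% stages) {
    .write_csv(std[, c("mesocosm_id", "plant_id", "herbivore_species",
                       "biomass_g")],
               file.path(config$out_dir, "networks.csv"))
    counts$networks <- nrow(std)

    nd <- unlist(lapply(imats, function(im)
      suppressWarnings(normalized_degree(im))))
    names(nd) <- unlist(lapply(imats, function(im) rownames(im$alpha)))
    dmg <- damage_index(tabs$damage)
    br <- biomass_ratio(std, tabs$plants)
    idx <- tabs$plants[, c("plant_id", "mesocosm_id", "species",
                           "provenance")]
    idx$normalized_degree <- unname(nd[idx$plant_id])
    idx <- merge(idx, dmg, by = "plant_id", all.x = TRUE)
    idx <- merge(idx, br, by = "plant_id", all.x = TRUE)
    idx <- idx[order(idx$plant_id), ]
    .write_csv(idx, file.path(config$out_dir, "plant_indices.csv"))
    counts$plant_indices <- nrow(idx)

    mb <- mesocosm_herbivore_biomass(
      tabs$surveys, tabs$herbivores, by_provenance = TRUE,
      normalize_per_survey = config$normalize_mesocosm_per_survey,
      n_surveys = max(tabs$surveys$survey_index, 1),
      mesocosm_ids = tabs$mesocosms$mesocosm_id)
    .write_csv(mb, file.path(config$out_dir, "mesocosm_biomass.csv"))
    counts$mesocosm_biomass <- nrow(mb)

    mw <- build_metaweb(std, unique(tabs$plants[, c("species", "provenance")]),
                        tabs$herbivores)
    edges <- which(mw > 0, arr.ind = TRUE)
    .write_csv(data.frame(plant_species = rownames(mw)[edges[, 1]],
                          herbivore_species = colnames(mw)[edges[, 2]]),
               file.path(config$out_dir, "metaweb.csv"))
    counts$metaweb <- nrow(edges)
  }

  if ("pac" %in% stages) {
    pr <- compute_pac(imats, direction = config$pac_direction)
    pdf <- pac_table(pr, imats, tabs$mesocosms)
    .write_csv(pdf, file.path(config$out_dir, "pac.csv"))
    counts$pac <- nrow(pdf)
    if (config$write_d_matrices) {
      dd <- do.call(rbind, lapply(names(pr), function(m) {
        d <- pr[[m]]$d
        data.frame(mesocosm_id = m,
                   receiver = rownames(d)[row(d)],
                   donor = colnames(d)[col(d)],
                   d = as.vector(d), stringsAsFactors = FALSE)
      }))
      .write_csv(dd, file.path(config$out_dir, "d_matrices.csv"))
      counts$d_matrices <- nrow(dd)
    }
  }

  if ("dominance" %in% stages) {
    props <- suppressWarnings(exotic_biomass_proportion(
      tabs$plants, partition = config$biomass_partition))
    dom <- dominance_ci_table(props, tabs$mesocosms,
                              method = config$ci_method)
    .write_csv(as.data.frame(dom), file.path(config$out_dir,
                                             "dominance.csv"))
    counts$dominance <- nrow(dom)
  }

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(.config_as_list(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  # hash the configuration minus filesystem paths, so identical runs into
  # different directories yield identical manifests
  canon <- .config_as_list(config)
  canon$out_dir <- canon$input_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(canon, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(config_hash = unname(tools::md5sum(tmp)),
                   seed = config$seed,
                   stages = stages,
                   n_mesocosms = nrow(tabs$mesocosms),
                   rows = counts,
                   package_version =
                     as.character(utils::packageVersion("pacweb")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @keywords internal
#' @noRd
.config_as_list <- function(config) {
  out <- unclass(config)
  out$generator <- unclass(out$generator)
  out
}

#' Command-line entry point
#'
#' Thin wrapper exposing the pipeline as subcommands:
#' `simulate`, `validate`, `assemble`, `pac`, `dominance`, `all`, with flags
#' `--seed`, `--out`, `--input`, `--pac-direction`, `--ci-method`. Invoked by
#' the `pacweb` script in `inst/scripts/`, or directly:
#' `Rscript -e 'pacweb::pacweb_cli()' all --seed 1 --out run1`.
#'
#' @param args Character vector of command-line arguments.
#' @return The pipeline manifest (or validation report), invisibly.
#' @export
pacweb_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: pacweb <simulate|validate|assemble|pac|dominance|all> [options]"
  if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(NULL))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character",
                          default = "pacweb_run"),
    optparse::make_option("--input", type = "character", default = NULL,
                          help = "directory of existing input CSVs"),
    optparse::make_option("--pac-direction", type = "character",
                          default = "muller", dest = "pac_direction"),
    optparse::make_option("--ci-method", type = "character", default = "t",
                          dest = "ci_method")))
  opt <- optparse::parse_args(parser, args = args[-1])
  if (cmd == "validate") {
    if (is.null(opt$input)) stop("validate requires --input", call. = FALSE)
    report <- validate_inputs(opt$input)
    print(report)
    return(invisible(report))
  }
  stages <- switch(cmd,
                   simulate = "simulate",
                   assemble = c("simulate", "assemble"),
                   pac = c("simulate", "assemble", "pac"),
                   dominance = c("simulate", "assemble", "dominance"),
                   all = "all",
                   stop(usage, call. = FALSE))
  if (!is.null(opt$input))
    stages <- setdiff(stages, "simulate")
  cfg <- pipeline_config(generator = mesocosm_config(seed = opt$seed),
                         input_dir = opt$input, out_dir = opt$out,
                         seed = opt$seed,
                         pac_direction = opt$pac_direction,
                         ci_method = opt$ci_method)
  manifest <- run_pipeline(cfg, stages = stages)
  message("pipeline complete; outputs in ", opt$out)
  invisible(manifest)
}
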