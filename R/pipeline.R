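.pipeline_log <- function(verbose, ...) {
  if (verbose) message(...)
}

#' Run the full contamination and risk pipeline
#'
#' Orchestrates the complete analysis on a soil table, a produce table and
#' a config: load + validate, impute censored cells, soil contamination
#' indices (CF, classes, PLI, trigger-value screening), soil-to-plant
#' transfer factors, EU food-limit screening, dietary risk (EDI, HQ, HI,
#' As CR), and area group comparisons. Writes `contamination.csv`,
#' `tf.csv`, `risk.csv`, `stats.csv`, `report.md` and `manifest.json` into
#' `out_dir`. Any stage failure aborts the run, removes partial outputs
#' and re-raises the error with the stage name.
#'
#' @param soil_path,plant_path,config_path input files (see
#'   [load_dataset()]).
#' @param out_dir output directory (created if needed).
#' @param pairing TF pairing mode, see [tf_table()].
#' @param alpha significance level for the group comparisons.
#' @param verbose emit per-stage progress messages.
#' @return The run manifest (list, class `pte_manifest`), invisibly.
#' @export
run_pipeline <- function(soil_path, plant_path, config_path, out_dir,
                         pairing = "per-garden", alpha = 0.05,
                         verbose = FALSE) {
  ds <- load_dataset(soil_path, plant_path, config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  cleanup <- function() unlink(file.path(out_dir, artifacts))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cleanup()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    .write_csv_header(path)
    suppressWarnings(utils::write.table(df, path, sep = ",",
                                        row.names = FALSE, quote = FALSE,
                                        append = TRUE))
    artifacts <<- c(artifacts, file)
    path
  }

  ds <- stage("impute", impute_dataset(ds))

  .pipeline_log(verbose, "stage: soil contamination indices")
  cf_elements <- intersect(
    .default_cf_elements,
    ds$element_params$element[!is.na(ds$element_params$background)])
  cf_elements <- intersect(cf_elements, dataset_elements(ds$soils))
  contam <- NULL
  if (length(cf_elements)) {
    contam <- stage("contamination",
                    contamination_table(ds, elements = cf_elements))
    emit(contam, "contamination.csv")
  } else {
    emit(data.frame(note = "no geochemical backgrounds configured"),
         "contamination.csv")
  }

  .pipeline_log(verbose, "stage: transfer factors")
  tf <- stage("transfer", tf_table(ds$plants, ds$soils, pairing = pairing))
  emit(tf, "tf.csv")

  .pipeline_log(verbose, "stage: dietary risk")
  risk <- stage("risk", risk_table(ds$plants, ds$exposure,
                                   ds$element_params,
                                   area_map = ds$area_map))
  emit(risk, "risk.csv")
  food <- stage("food-limits",
                food_limit_table(ds$plants, ds$element_params,
                                 ds$exposure$fw_factor))

  .pipeline_log(verbose, "stage: group statistics")
  stats_df <- stage("stats", .pipeline_stats(ds, alpha))
  emit(stats_df, "stats.csv")

  report <- stage("report",
                  .pipeline_report(ds, contam, tf, risk, food, stats_df))
  writeLines(report, file.path(out_dir, "report.md"))
  artifacts <- c(artifacts, "report.md")

  inputs <- c(soil = soil_path, plants = plant_path, config = config_path)
  manifest <- list(
    package = "ptegarden",
    version = tryCatch(as.character(utils::packageVersion("ptegarden")),
                       error = function(e) "dev"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_hashes = as.list(tools::md5sum(inputs)),
    config = jsonlite::read_json(config_path),
    artifacts = c(artifacts, "manifest.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  class(manifest) <- "pte_manifest"
  invisible(manifest)
}

# Area comparisons per element for soils and, where replication allows,
# per species for plants; long output with one row per element x group.
.pipeline_stats <- function(ds, alpha) {
  rows <- list()
  add_comparison <- function(stratum, element, values) {
    values <- values[vapply(values, length, 0L) >= 3]
    if (length(values) < 2) return(NULL)
    cmp <- compare_groups(values, alpha = alpha)
    data.frame(stratum = stratum, element = element,
               test_used = cmp$test_used,
               statistic = cmp$statistic, p_value = cmp$p_value,
               group = names(cmp$means), mean = as.numeric(cmp$means),
               letter = unname(cmp$letters[names(cmp$means)]),
               stringsAsFactors = FALSE)
  }
  for (el in dataset_elements(ds$soils)) {
    v <- split(ds$soils[[el]], ds$soils$area)
    v <- lapply(v, function(x) x[!is.na(x)])
    rows[[paste0("soil.", el)]] <- add_comparison("soil", el, v)
  }
  grown <- ds$plants[ds$plants$source != "market", , drop = FALSE]
  if (nrow(grown)) {
    grown$area <- ds$soils$area[match(grown$source, ds$soils$garden_code)]
    for (sp in unique(grown$species)) {
      sub <- grown[grown$species == sp, ]
      for (el in dataset_elements(ds$plants)) {
        v <- split(sub[[el]], sub$area)
        v <- lapply(v, function(x) x[!is.na(x)])
        rows[[paste(sp, el)]] <- add_comparison(sp, el, v)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(stratum = character(), element = character(),
                      test_used = character(), statistic = numeric(),
                      p_value = numeric(), group = character(),
                      mean = numeric(), letter = character())
  rownames(out) <- NULL
  out
}

.pipeline_report <- function(ds, contam, tf, risk, food, stats_df) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "g")
  lines <- c("# Garden contamination and dietary risk report", "")
  lines <- c(lines, sprintf("- soil samples: %d (%d gardens)",
                            nrow(ds$soils),
                            length(unique(ds$soils$garden_code))),
             sprintf("- plant samples: %d (%d species)", nrow(ds$plants),
                     length(unique(ds$plants$species))), "")
  lines <- c(lines, "## Soil contamination", "")
  if (!is.null(contam)) {
    pli <- unique(contam[, c("garden_code", "area", "pli")])
    lines <- c(lines, "Garden pollution load index (PLI > 1 = contaminated):",
               "")
    lines <- c(lines, sprintf("- %s (%s): PLI %s%s", pli$garden_code,
                              pli$area, fmt(pli$pli),
                              ifelse(pli$pli > 1, "  **[> 1]**", "")))
    tv <- contam[!is.na(contam$exceeds_tv) & contam$exceeds_tv, ]
    lines <- c(lines, "", if (nrow(tv))
      c("Trigger-value exceedances:",
        sprintf("- %s: %s mean %s mg/kg above regulatory trigger value",
                tv$garden_code, tv$element, fmt(tv$mean_conc)))
      else "No regulatory trigger value exceeded.")
  } else {
    lines <- c(lines,
               "Not computed: no geochemical backgrounds configured.")
  }
  lines <- c(lines, "", "## Soil-to-plant transfer", "")
  hi_tf <- tf[tf$exceeds_one, ]
  lines <- c(lines, if (nrow(hi_tf))
    c("Transfer factors at or above 1:",
      sprintf("- %s / %s / %s: TF %s", hi_tf$species, hi_tf$area,
              hi_tf$element, fmt(hi_tf$tf)))
    else "All transfer factors below 1 (low edible-part accumulation).")
  lines <- c(lines, "", "## Dietary risk (adult scenario)", "")
  lines <- c(lines, sprintf(
    "- %s (%s): HI %s%s, As CR %s%s", risk$species, risk$area,
    fmt(risk$hi), ifelse(risk$hi_exceeds, " **[HI > 1]**", ""),
    ifelse(is.na(risk$cr_as), "n/a", fmt(risk$cr_as)),
    ifelse(!is.na(risk$cr_unacceptable) & risk$cr_unacceptable,
           " **[CR > 1e-5]**", "")))
  exc <- food[!is.na(food$exceeds) & food$exceeds, ]
  lines <- c(lines, "", "## EU food maximum levels", "")
  lines <- c(lines, if (nrow(exc))
    sprintf("- %s (%s) %s: %s mg/kg fw above limit %s", exc$species,
            exc$source, exc$element, fmt(exc$conc_fw), fmt(exc$limit))
    else "No EU food maximum level exceeded.")
  lines <- c(lines, "", "## Group comparisons", "",
             sprintf("%d element x stratum comparisons; see stats.csv.",
                     length(unique(paste(stats_df$stratum,
                                         stats_df$element)))))
  lines
}

#' Command-line interface
#'
#' Entry point behind the `ptegarden` executable script
#' (`inst/cli/ptegarden`). Subcommands: `run` (full pipeline),
#' `soil-indices`, `tf`, `risk`, `stats`, `simulate`, `calibrate-ir`.
#' Run `ptegarden <subcommand> --help` for options.
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 success, 2 validation/usage
#'   failure, 1 internal stage failure.
#' @export
pte_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: ptegarden <run|soil-indices|tf|risk|stats|",
                 "simulate|calibrate-ir> [options]", sep = "")
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(args)) 0L else 2L))
  }
  sub <- args[1]
  rest <- args[-1]
  run <- function(expr) {
    tryCatch({ expr; invisible(0L) },
             error = function(e) {
               message("error: ", conditionMessage(e))
               invisible(2L)
             })
  }
  opt <- function(...) optparse::parse_args(
    optparse::OptionParser(option_list = list(...)), args = rest)
  o <- optparse::make_option
  switch(sub,
    run = run({
      x <- opt(o("--soil", type = "character"),
               o("--plants", type = "character"),
               o("--config", type = "character"),
               o("--out", type = "character", default = "results"),
               o("--pairing", type = "character", default = "per-garden"),
               o("--verbose", action = "store_true", default = FALSE))
      run_pipeline(x$soil, x$plants, x$config, x$out, pairing = x$pairing,
                   verbose = x$verbose)
    }),
    `soil-indices` = run({
      x <- opt(o("--soil", type = "character"),
               o("--config", type = "character"),
               o("--out", type = "character", default = "contamination.csv"))
      cfg <- read_config(x$config)
      soils <- read_soil_csv(x$soil, area_map = cfg$area_map)
      ds <- structure(list(soils = soils,
                           plants = data.frame(sample_id = character(),
                                               species = character(),
                                               vegetable_group = character(),
                                               source = character()),
                           element_params = cfg$element_params,
                           exposure = cfg$exposure),
                      class = "pte_dataset")
      tab <- contamination_table(ds)
      .write_csv_header(x$out)
      suppressWarnings(utils::write.table(tab, x$out, sep = ",",
                                          row.names = FALSE, quote = FALSE,
                                          append = TRUE))
    }),
    tf = run({
      x <- opt(o("--plants", type = "character"),
               o("--soil", type = "character"),
               o("--config", type = "character", default = NULL),
               o("--pairing", type = "character", default = "per-garden"),
               o("--out", type = "character", default = "tf.csv"))
      amap <- if (!is.null(x$config)) read_config(x$config)$area_map
      soils <- read_soil_csv(x$soil, area_map = amap)
      plants <- read_plant_csv(x$plants, area_map = amap)
      tab <- tf_table(plants, soils, pairing = x$pairing)
      .write_csv_header(x$out)
      suppressWarnings(utils::write.table(tab, x$out, sep = ",",
                                          row.names = FALSE, quote = FALSE,
                                          append = TRUE))
    }),
    risk = run({
      x <- opt(o("--plants", type = "character"),
               o("--config", type = "character", default = NULL),
               o("--profile", type = "character",
                 default = "calibrated"),
               o("--out", type = "character", default = "risk.csv"))
      cfg <- if (!is.null(x$config)) read_config(x$config)
             else if (file.exists(x$profile)) read_config(x$profile)
             else risk_profile(x$profile)
      plants <- read_plant_csv(x$plants, area_map = cfg$area_map)
      tab <- risk_table(plants, cfg$exposure, cfg$element_params,
                        area_map = cfg$area_map)
      .write_csv_header(x$out)
      suppressWarnings(utils::write.table(tab, x$out, sep = ",",
                                          row.names = FALSE, quote = FALSE,
                                          append = TRUE))
    }),
    stats = run({
      x <- opt(o("--plants", type = "character", default = NULL),
               o("--soil", type = "character"),
               o("--config", type = "character"),
               o("--alpha", type = "double", default = 0.05),
               o("--out", type = "character", default = "stats.csv"))
      cfg <- read_config(x$config)
      soils <- read_soil_csv(x$soil, area_map = cfg$area_map)
      plants <- if (!is.null(x$plants))
        read_plant_csv(x$plants, area_map = cfg$area_map,
                       registry = cfg$registry)
      else data.frame(sample_id = character(), species = character(),
                      vegetable_group = character(), source = character())
      ds <- structure(list(soils = soils, plants = plants,
                           element_params = cfg$element_params,
                           exposure = cfg$exposure),
                      class = "pte_dataset")
      tab <- .pipeline_stats(impute_dataset(ds), x$alpha)
      .write_csv_header(x$out)
      suppressWarnings(utils::write.table(tab, x$out, sep = ",",
                                          row.names = FALSE, quote = FALSE,
                                          append = TRUE))
    }),
    simulate = run({
      x <- opt(o("--seed", type = "integer", default = 42),
               o("--out", type = "character", default = "data"))
      ds <- survey_like_fixture(seed = x$seed)
      files <- write_dataset(ds, x$out)
      truth <- attr(ds, "truth")
      jsonlite::write_json(
        list(soil_median = as.data.frame(truth$soil_median),
             true_tf = as.data.frame(truth$true_tf),
             censor_fraction = as.list(truth$censor_fraction),
             seed = truth$seed),
        file.path(x$out, "truth.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    }),
    `calibrate-ir` = run({
      x <- opt(o("--cm", type = "character"),
               o("--hq", type = "character"),
               o("--profile", type = "character", default = "calibrated"),
               o("--out", type = "character", default = "ir.json"))
      cm <- utils::read.csv(x$cm, comment.char = "#")
      hq <- utils::read.csv(x$hq, comment.char = "#")
      cfg <- if (file.exists(x$profile)) read_config(x$profile)
             else risk_profile(x$profile)
      cal <- calibrate_ingestion_rate(cm, hq, cfg$element_params,
                                      cfg$exposure)
      jsonlite::write_json(list(ir_fresh = as.list(cal$ir),
                                flagged = cal$cells[cal$cells$flagged, ]),
                           x$out, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }),
    { message("unknown subcommand: ", sub, "\n", usage); invisible(2L) }
  )
}
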