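# Censoring tokens accepted in concentration cells (case-insensitive,
# internal whitespace ignored): "<LOD", "<LD", "<dl", "nd".
.censor_token_rx <- "^(<\\s*(lod|ld|dl)|nd)$"

.is_censor_token <- function(x) {
  grepl(.censor_token_rx, gsub("[[:space:]]", "", tolower(trimws(x))))
}

#' @noRd
.parse_conc_column <- function(x, col, file) {
  x <- trimws(as.character(x))
  cens <- !is.na(x) & .is_censor_token(x)
  val <- rep(NA_real_, length(x))
  plain <- !cens & !is.na(x) & nzchar(x)
  suppressWarnings(num <- as.numeric(x[plain]))
  if (anyNA(num)) {
    bad <- which(plain)[is.na(num)]
    stop(sprintf("%s: column '%s' has non-numeric value '%s' at data row %d",
                 file, col, x[bad[1]], bad[1]), call. = FALSE)
  }
  if (any(num < 0)) {
    bad <- which(plain)[num < 0][1]
    stop(sprintf("%s: negative concentration in column '%s' at data row %d",
                 file, col, bad), call. = FALSE)
  }
  val[plain] <- num
  list(value = val, censored = cens)
}

.read_csv_raw <- function(path) {
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  comment.char = "#", strip.white = TRUE)
}

.check_columns <- function(df, required, path) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

.element_columns <- function(df, path) {
  known_meta <- c("sample_id", "garden_code", "species", "source", "ph",
                  "conductivity")
  cand <- setdiff(names(df), known_meta)
  cand <- cand[!grepl("_censored$", cand)]
  if (length(cand)) {
    ok <- tolower(cand) %in% tolower(pte_elements)
    if (any(!ok))
      stop(sprintf("%s: unknown column(s) %s; element columns must be among: %s",
                   path, paste(cand[!ok], collapse = ", "),
                   paste(pte_elements, collapse = ", ")), call. = FALSE)
  }
  cand
}

#' Read a soil concentration table
#'
#' Reads a CSV of garden soil observations with columns
#' `sample_id,garden_code,ph,conductivity` plus one column per element
#' (mg/kg dry weight). Cells holding a below-detection token (`<LOD`,
#' `<LD`, `<dl`, `nd`; case-insensitive) are parsed as left-censored: the
#' stored value is `NA` and the matching cell of the `censored` attribute is
#' `TRUE`. An optional `<element>_censored` logical column overrides token
#' detection for that element.
#'
#' @param path CSV file path.
#' @param area_map optional named vector resolving non-built-in garden codes.
#' @return A `data.frame` with numeric element columns, an `area` column,
#'   and a logical `censored` matrix attribute (rows = samples, columns =
#'   element columns present).
#' @export
read_soil_csv <- function(path, area_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- .read_csv_raw(path)
  .check_columns(raw, c("sample_id", "garden_code", "ph"), path)
  elems <- .element_columns(raw, path)
  out <- data.frame(sample_id = raw$sample_id,
                    garden_code = raw$garden_code,
                    stringsAsFactors = FALSE)
  out$area <- assign_area(raw$garden_code, area_map)
  suppressWarnings(out$ph <- as.numeric(raw$ph))
  if (anyNA(out$ph))
    stop(path, ": 'ph' must be numeric and present for every sample",
         call. = FALSE)
  if (any(out$ph <= 0 | out$ph >= 14))
    stop(path, ": 'ph' outside (0, 14)", call. = FALSE)
  if ("conductivity" %in% names(raw)) {
    suppressWarnings(out$conductivity <- as.numeric(raw$conductivity))
    if (any(out$conductivity < 0, na.rm = TRUE))
      stop(path, ": negative conductivity", call. = FALSE)
  } else out$conductivity <- NA_real_
  cens <- matrix(FALSE, nrow(raw), length(elems),
                 dimnames = list(NULL, as_element(elems)))
  for (el in elems) {
    parsed <- .parse_conc_column(raw[[el]], el, path)
    canon <- as_element(el)
    out[[canon]] <- parsed$value
    flag_col <- paste0(el, "_censored")
    if (flag_col %in% names(raw)) {
      cens[, canon] <- toupper(trimws(raw[[flag_col]])) %in%
        c("TRUE", "T", "1", "YES")
    } else cens[, canon] <- parsed$censored
  }
  attr(out, "censored") <- cens
  out
}

#' Read a produce concentration table
#'
#' Reads a CSV of edible-produce observations with columns
#' `sample_id,species,source` plus element columns (mg/kg dry weight unless
#' suffixed `_fw`). `source` is a garden code or the literal `"market"`.
#' Censoring tokens are handled as in [read_soil_csv()]. A
#' `vegetable_group` column is attached from the species registry.
#'
#' @inheritParams read_soil_csv
#' @param registry optional species registry extension (see
#'   [vegetable_group()]).
#' @return A `data.frame` with a `censored` matrix attribute.
#' @export
read_plant_csv <- function(path, area_map = NULL, registry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- .read_csv_raw(path)
  .check_columns(raw, c("sample_id", "species", "source"), path)
  elems <- .element_columns(raw, path)
  out <- data.frame(sample_id = raw$sample_id,
                    species = tolower(raw$species),
                    stringsAsFactors = FALSE)
  out$vegetable_group <- vegetable_group(raw$species, registry)
  out$source <- raw$source
  cens <- matrix(FALSE, nrow(raw), length(elems),
                 dimnames = list(NULL, as_element(elems)))
  for (el in elems) {
    parsed <- .parse_conc_column(raw[[el]], el, path)
    canon <- as_element(el)
    out[[canon]] <- parsed$value
    cens[, canon] <- parsed$censored
  }
  attr(out, "censored") <- cens
  out
}

#' Read an analysis configuration (JSON or YAML)
#'
#' The config carries three blocks: `elements` (per element: `rfd`,
#' `slope_factor`, `background`, `trigger_value`, `lod`, and `food_limits`
#' per vegetable group, mg/kg fresh weight), `exposure` (`ir_fresh` per
#' species in kg fresh weight/day, `bw`, `ef`, `ed`, `at_nc`, `at_c`,
#' `fw_factor`) and optional `areas` (garden-code -> area overrides) and
#' `species` (species -> vegetable-group registry extensions).
#'
#' @param path path to a `.json` (or `.yaml`/`.yml`, if the yaml package is
#'   installed) config file.
#' @return A list with components `element_params` (data.frame),
#'   `exposure` (list), `area_map`, `registry`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  build_config(cfg)
}

#' Build a validated configuration from a list
#'
#' Programmatic equivalent of [read_config()]; accepts the same nested
#' structure as an R list.
#'
#' @param cfg nested list with `elements`, `exposure`, optional `areas` and
#'   `species` blocks.
#' @return As [read_config()].
#' @export
build_config <- function(cfg) {
  if (is.null(cfg$elements) || is.null(cfg$exposure))
    stop("config must contain 'elements' and 'exposure' blocks",
         call. = FALSE)
  els <- as_element(names(cfg$elements))
  num_or_na <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)
  ep <- data.frame(element = els, stringsAsFactors = FALSE)
  for (f in c("rfd", "slope_factor", "background", "trigger_value", "lod"))
    ep[[f]] <- vapply(cfg$elements, function(e) num_or_na(e[[f]]), 0)
  for (g in pte_groups)
    ep[[paste0("food_limit_", g)]] <-
      vapply(cfg$elements, function(e) num_or_na(e$food_limits[[g]]), 0)
  rownames(ep) <- NULL
  bad <- ep$element[!is.na(ep$rfd) & ep$rfd <= 0]
  if (length(bad))
    stop("rfd must be > 0 (element: ", paste(bad, collapse = ", "), ")",
         call. = FALSE)
  ex <- cfg$exposure
  ir <- unlist(ex$ir_fresh)
  if (length(ir)) names(ir) <- tolower(names(ir))
  exposure <- exposure_params(
    ir_fresh = ir,
    bw = num_or_na(ex$bw), ef = num_or_na(ex$ef), ed = num_or_na(ex$ed),
    at_nc = num_or_na(ex$at_nc), at_c = num_or_na(ex$at_c),
    fw_factor = num_or_na(ex$fw_factor))
  area_map <- unlist(cfg$areas)
  registry <- unlist(cfg$species)
  list(element_params = ep, exposure = exposure,
       area_map = area_map, registry = registry)
}

#' Exposure parameter set
#'
#' Bundles the adult dietary exposure scenario: per-species fresh-weight
#' ingestion rates IR (kg/day), body weight BW (kg), exposure frequency Ef
#' (day/year), exposure duration Ed (year), averaging times for
#' non-carcinogenic (`at_nc`) and carcinogenic (`at_c`) effects (days), and
#' the dry-to-fresh weight conversion factor. Defaults follow the adult
#' scenario used throughout the package: BW 70 kg, Ef 365 d/y, Ed 30 y,
#' AT_nc 30 x 365 = 10950 d, AT_c 78 x 365 = 28470 d, fw factor 0.085.
#'
#' @param ir_fresh named numeric vector, species -> kg fresh weight/day.
#' @param bw,ef,ed,at_nc,at_c,fw_factor scalars, see description.
#' @return A list of class `pte_exposure`.
#' @export
exposure_params <- function(ir_fresh = numeric(), bw = 70, ef = 365, ed = 30,
                            at_nc = 10950, at_c = 28470, fw_factor = 0.085) {
  if (is.na(bw)) bw <- 70
  if (is.na(ef)) ef <- 365
  if (is.na(ed)) ed <- 30
  if (is.na(at_nc)) at_nc <- 10950
  if (is.na(at_c)) at_c <- 28470
  if (is.na(fw_factor)) fw_factor <- 0.085
  stopifnot(bw > 0, ed > 0, at_nc > 0)
  if (ef <= 0 || ef > 365) stop("ef must be in (0, 365]", call. = FALSE)
  if (fw_factor <= 0 || fw_factor > 1)
    stop("fw_factor must be in (0, 1]", call. = FALSE)
  if (at_c < at_nc) stop("at_c must be >= at_nc", call. = FALSE)
  if (length(ir_fresh) && any(ir_fresh <= 0))
    stop("ingestion rates must be > 0", call. = FALSE)
  structure(list(ir_fresh = ir_fresh, bw = bw, ef = ef, ed = ed,
                 at_nc = at_nc, at_c = at_c, fw_factor = fw_factor),
            class = "pte_exposure")
}

#' Load a full analysis dataset
#'
#' Reads and cross-validates the soil table, produce table and config into
#' a single dataset object. Every plant source must be `"market"` or a
#' garden code present in the soil table; every element column present in
#' the data must have a parameter entry in the config.
#'
#' @param soil_path,plant_path,config_path file paths (see
#'   [read_soil_csv()], [read_plant_csv()], [read_config()]).
#' @return An object of class `pte_dataset`: list with components `soils`,
#'   `plants` (both carrying `censored` attributes), `element_params`,
#'   `exposure`.
#' @export
load_dataset <- function(soil_path, plant_path, config_path) {
  cfg <- read_config(config_path)
  soils <- read_soil_csv(soil_path, area_map = cfg$area_map)
  plants <- read_plant_csv(plant_path, area_map = cfg$area_map,
                           registry = cfg$registry)
  ds <- structure(list(soils = soils, plants = plants,
                       element_params = cfg$element_params,
                       exposure = cfg$exposure,
                       area_map = cfg$area_map),
                  class = "pte_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a dataset object
#'
#' @param ds a `pte_dataset`.
#' @return `ds`, invisibly; errors describe the first violation found.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "pte_dataset"))
  src <- setdiff(unique(ds$plants$source), "market")
  missing_src <- setdiff(src, unique(ds$soils$garden_code))
  if (length(missing_src))
    stop("plant source garden(s) absent from soil table: ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  present <- union(dataset_elements(ds$soils), dataset_elements(ds$plants))
  uncov <- setdiff(present, ds$element_params$element)
  if (length(uncov))
    stop("element(s) present in data but absent from config: ",
         paste(uncov, collapse = ", "), call. = FALSE)
  invisible(ds)
}

#' Element columns present in a concentration table
#' @param df soil or plant data.frame.
#' @return character vector of element symbols.
#' @export
dataset_elements <- function(df) intersect(pte_elements, names(df))

#' @export
print.pte_dataset <- function(x, ...) {
  cat("<pte_dataset>\n")
  cat(sprintf("  soils : %d samples, %d gardens, elements: %s\n",
              nrow(x$soils), length(unique(x$soils$garden_code)),
              paste(dataset_elements(x$soils), collapse = " ")))
  cat(sprintf("  plants: %d samples, %d species, sources: %s\n",
              nrow(x$plants), length(unique(x$plants$species)),
              paste(utils::head(unique(x$plants$source), 8), collapse = " ")))
  cens <- attr(x$soils, "censored")
  if (!is.null(cens) && any(cens))
    cat(sprintf("  censored soil cells: %d\n", sum(cens)))
  invisible(x)
}

.format_cell <- function(value, censored) {
  out <- vapply(value, function(v)
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE), "")
  out[censored] <- "<LOD"
  out
}

.write_csv_header <- function(path) {
  ver <- tryCatch(as.character(utils::packageVersion("ptegarden")),
                  error = function(e) "dev")
  writeLines(sprintf("# generated_by: ptegarden %s", ver), path)
}

.write_table_csv <- function(df, cens, path) {
  out <- df
  for (el in intersect(colnames(cens), names(out)))
    out[[el]] <- .format_cell(out[[el]], cens[, el])
  .write_csv_header(path)
  suppressWarnings(utils::write.table(out, path, sep = ",", row.names = FALSE,
                                      quote = FALSE, append = TRUE))
  invisible(path)
}

#' Write a dataset back to disk
#'
#' Emits `soil.csv`, `plants.csv` and `config.json` into `dir` in the same
#' schema [load_dataset()] reads, with censored cells rendered as `<LOD`.
#' Round-trips exactly: reloading reproduces every field and censoring flag.
#'
#' @param ds a `pte_dataset`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "pte_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  soil_path <- file.path(dir, "soil.csv")
  plant_path <- file.path(dir, "plants.csv")
  cfg_path <- file.path(dir, "config.json")
  soils_out <- ds$soils[, setdiff(names(ds$soils), "area")]
  .write_table_csv(soils_out, attr(ds$soils, "censored"), soil_path)
  plants_out <- ds$plants[, setdiff(names(ds$plants), "vegetable_group")]
  .write_table_csv(plants_out, attr(ds$plants, "censored"), plant_path)
  write_config(ds, cfg_path)
  invisible(c(soil = soil_path, plants = plant_path, config = cfg_path))
}

#' Serialise the parameter blocks of a dataset to JSON
#' @param ds a `pte_dataset`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_config <- function(ds, path) {
  ep <- ds$element_params
  drop_na <- function(l) l[!vapply(l, function(v) all(is.na(v)), TRUE)]
  elements <- lapply(seq_len(nrow(ep)), function(i) {
    row <- ep[i, ]
    fl <- drop_na(list(leafy = row$food_limit_leafy,
                       bulbous = row$food_limit_bulbous,
                       fruiting = row$food_limit_fruiting))
    out <- drop_na(list(rfd = row$rfd, slope_factor = row$slope_factor,
                        background = row$background,
                        trigger_value = row$trigger_value, lod = row$lod))
    if (length(fl)) out$food_limits <- fl
    out
  })
  names(elements) <- ep$element
  ex <- ds$exposure
  cfg <- list(elements = elements,
              exposure = list(ir_fresh = as.list(ex$ir_fresh), bw = ex$bw,
                              ef = ex$ef, ed = ex$ed, at_nc = ex$at_nc,
                              at_c = ex$at_c, fw_factor = ex$fw_factor))
  # garden codes outside the built-in registry must survive the round trip
  extra <- setdiff(unique(ds$soils$garden_code), names(.garden_area_map))
  if (length(extra)) {
    amap <- ds$soils$area[match(extra, ds$soils$garden_code)]
    cfg$areas <- as.list(stats::setNames(amap, extra))
  }
  extra_sp <- setdiff(unique(ds$plants$species), names(.species_registry))
  if (length(extra_sp)) {
    grp <- ds$plants$vegetable_group[match(extra_sp, ds$plants$species)]
    cfg$species <- as.list(stats::setNames(grp, extra_sp))
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Replace left-censored values by the observed minimum
#'
#' Implements the below-detection replacement rule used for soils: every
#' censored entry of an element is replaced by the lowest uncensored value
#' of that element across the whole dataset. Uncensored entries are never
#' modified, so the operation is idempotent.
#'
#' @param values numeric vector (censored entries may be `NA`).
#' @param censored logical vector, same length.
#' @return Numeric vector with censored entries imputed.
#' @examples
#' impute_censored(c(5, 3, NA), c(FALSE, FALSE, TRUE))
#' @export
impute_censored <- function(values, censored) {
  stopifnot(length(values) == length(censored), is.logical(censored))
  if (all(censored | is.na(values)))
    stop("all values censored: no replacement value exists", call. = FALSE)
  repl <- min(values[!censored], na.rm = TRUE)
  values[censored] <- repl
  values
}

#' Impute all censored cells of a dataset
#'
#' Applies [impute_censored()] element by element, pooling all soil samples
#' (and, separately, all plant samples) in the dataset. The censoring flags
#' are preserved so that imputed cells remain identifiable.
#'
#' @param ds a `pte_dataset`.
#' @return The dataset with censored concentrations filled in.
#' @export
impute_dataset <- function(ds) {
  stopifnot(inherits(ds, "pte_dataset"))
  for (tab in c("soils", "plants")) {
    cens <- attr(ds[[tab]], "censored")
    if (is.null(cens)) next
    for (el in colnames(cens)) {
      if (!any(cens[, el])) next
      ds[[tab]][[el]] <- impute_censored(ds[[tab]][[el]], cens[, el])
    }
  }
  ds
}
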