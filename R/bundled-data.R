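.extdata <- function(file) {
  path <- system.file("extdata", file, package = "ptegarden")
  if (path == "") path <- file.path("inst", "extdata", file)  # dev tree
  path
}

#' Bundled garden-level soil summary statistics
#'
#' Per-garden descriptive statistics (sample size, mean, minimum, maximum)
#' for soil pH and the six elements with regional backgrounds (As, Cr, Cu,
#' Ni, Pb, Zn) across the 15 Andalusian urban gardens the package defaults
#' are tuned to. Minima reported below the detection limit are `NA` with
#' `min_censored = TRUE`.
#'
#' @return data.frame with columns `garden_code`, `area`, `n`, `param`
#'   (`"pH"` or an element symbol), `mean`, `min`, `max`, `min_censored`.
#' @export
garden_soil_summary <- function() {
  df <- utils::read.csv(.extdata("garden_soil_summary.csv"),
                        colClasses = "character", comment.char = "#")
  out <- data.frame(garden_code = df$garden_code,
                    area = assign_area(df$garden_code),
                    n = as.integer(df$n),
                    param = df$param,
                    mean = as.numeric(df$mean),
                    stringsAsFactors = FALSE)
  out$min_censored <- .is_censor_token(df$min)
  suppressWarnings({
    out$min <- ifelse(out$min_censored, NA_real_, as.numeric(df$min))
    out$max <- as.numeric(df$max)
  })
  out[, c("garden_code", "area", "n", "param", "mean", "min", "max",
          "min_censored")]
}

#' Bundled vegetable mean concentrations
#'
#' Mean element concentrations (mg/kg dry weight, with standard
#' deviations) of the seven vegetable species by provenance: mining, city
#' and peri-urban gardens plus local-market purchases. One cell (market
#' tomato As) was below the detection limit and is `NA` with
#' `censored = TRUE`.
#'
#' @return data.frame with columns `species`, `source`, `element`, `mean`,
#'   `sd`, `censored`.
#' @export
vegetable_means <- function() {
  df <- utils::read.csv(.extdata("vegetable_means.csv"),
                        colClasses = "character", comment.char = "#")
  out <- data.frame(species = df$species, source = df$source,
                    element = as_element(df$element),
                    stringsAsFactors = FALSE)
  out$censored <- .is_censor_token(df$mean)
  suppressWarnings({
    out$mean <- ifelse(out$censored, NA_real_, as.numeric(df$mean))
    out$sd <- as.numeric(df$sd)
  })
  out
}

#' Bundled published hazard quotients
#'
#' The hazard-quotient table published for the surveyed vegetables
#' (species x area x element), kept as printed — including a handful of
#' internally inconsistent cells (apparent exponent slips, e.g. the
#' mining-area onion As and Ni entries) that
#' [calibrate_ingestion_rate()]'s residual check is designed to flag.
#'
#' @return data.frame with columns `species`, `area`, `element`, `hq`.
#' @export
vegetable_hazard_quotients <- function() {
  df <- utils::read.csv(.extdata("vegetable_hazard_quotients.csv"),
                        comment.char = "#",
                        colClasses = c("character", "character",
                                       "character", "numeric"))
  df$element <- as_element(df$element)
  df
}

#' Exposure/toxicity profiles for reproducing the survey risk tables
#'
#' Two shipped adult dietary profiles:
#' \describe{
#'   \item{`"calibrated"`}{The profile that reproduces the published
#'     hazard-quotient table: oral reference doses with Pb 2e-3 and
#'     Mo 5e-3 mg/kg-bw/day, plus per-species fresh-weight ingestion rates
#'     back-calculated by [calibrate_ingestion_rate()] (chard 4.94, onion
#'     18.25, tomato 24.9, zucchini 5.60, eggplant 5.09, lettuce 10.54,
#'     pepper 6.63 g/day).}
#'   \item{`"reference"`}{The literature RfD set as stated in the survey
#'     text (Pb 3.5e-3; no Mo value), without ingestion rates.}
#' }
#' Both include the As slope factor (1.5), regional trigger values and the
#' EU food maximum levels for Cd and Pb. Regional geochemical backgrounds
#' are deliberately not shipped: they are site-specific user input.
#'
#' @param name `"calibrated"` (default) or `"reference"`.
#' @return A config list as from [read_config()].
#' @export
risk_profile <- function(name = c("calibrated", "reference")) {
  name <- match.arg(name)
  file <- sprintf("adult_diet_%s.json", name)
  path <- system.file("profiles", file, package = "ptegarden")
  if (path == "") path <- file.path("inst", "profiles", file)
  read_config(path)
}
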