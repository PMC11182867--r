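#' Dry-weight to fresh-weight conversion
#'
#' Converts a dry-weight concentration to a fresh-weight basis by the
#' moisture conversion factor (default 0.085 for garden vegetables, i.e.
#' 8.5 % dry matter).
#'
#' @param c_dw concentration, mg/kg dry weight (>= 0).
#' @param fw_factor unitless factor in (0, 1].
#' @return Concentration in mg/kg fresh weight.
#' @examples
#' dw_to_fw(1.140, 0.085)
#' @export
dw_to_fw <- function(c_dw, fw_factor = 0.085) {
  if (fw_factor <= 0 || fw_factor > 1)
    stop("fw_factor must be in (0, 1]", call. = FALSE)
  if (any(c_dw < 0, na.rm = TRUE)) stop("concentrations must be >= 0", call. = FALSE)
  c_dw * fw_factor
}

#' Fresh-weight to dry-weight conversion (inverse of [dw_to_fw()])
#' @param c_fw concentration, mg/kg fresh weight (>= 0).
#' @inheritParams dw_to_fw
#' @return Concentration in mg/kg dry weight.
#' @export
fw_to_dw <- function(c_fw, fw_factor = 0.085) {
  if (fw_factor <= 0 || fw_factor > 1)
    stop("fw_factor must be in (0, 1]", call. = FALSE)
  if (any(c_fw < 0, na.rm = TRUE)) stop("concentrations must be >= 0", call. = FALSE)
  c_fw / fw_factor
}

#' Screen a produce concentration against its EU food maximum level
#'
#' Compares a fresh-weight concentration with the EU maximum level for the
#' (element, vegetable group) pair. The comparison is strict: a value equal
#' to the limit does not flag. Pairs without a limit return `NA` (skipped).
#'
#' @param c_fw concentration, mg/kg fresh weight.
#' @param element element symbol.
#' @param group vegetable group (`leafy`, `bulbous`, `fruiting`).
#' @param params element parameter data.frame with `food_limit_*` columns.
#' @return `TRUE` if the limit is exceeded, `FALSE` if not, `NA` if no
#'   limit exists for the pair.
#' @examples
#' params <- risk_profile("calibrated")$element_params
#' screen_food_limit(0.21, "Cd", "leafy", params)
#' @export
screen_food_limit <- function(c_fw, element, group, params) {
  element <- as_element(element)
  if (!group %in% pte_groups)
    stop("group must be one of: ", paste(pte_groups, collapse = ", "),
         call. = FALSE)
  lim <- params[[paste0("food_limit_", group)]][
    match(element, params$element)]
  if (is.na(lim)) return(NA)
  c_fw > lim
}

#' Soil-to-plant transfer factor
#'
#' Ratio of the element concentration in the edible plant tissue to the
#' total concentration in the soil the plant grew in, both on a dry-weight
#' basis. Values below 1 indicate the species does not accumulate the
#' element in its edible part relative to soil.
#'
#' @param c_plant_dw plant concentration, mg/kg dry weight (>= 0).
#' @param c_soil soil concentration, mg/kg dry weight (> 0).
#' @return Unitless transfer factor (vectorised).
#' @examples
#' transfer_factor(0.698, 350.2)
#' @export
transfer_factor <- function(c_plant_dw, c_soil) {
  if (any(c_soil <= 0))
    stop("soil concentration must be > 0", call. = FALSE)
  if (any(c_plant_dw < 0))
    stop("plant concentration must be >= 0", call. = FALSE)
  c_plant_dw / c_soil
}

#' Transfer-factor table for a dataset
#'
#' Computes soil-to-plant transfer factors per species x element x area.
#' With `pairing = "per-garden"` each plant sample is divided by the mean
#' soil concentration of the garden it grew in (the paired soil); with
#' `pairing = "per-area-mean"` the denominator is the pooled mean of the
#' area. Plant TFs are then averaged within species x area. Market samples
#' have no soil pairing and are skipped.
#'
#' @param plants plant data.frame ([read_plant_csv()]).
#' @param soils soil data.frame ([read_soil_csv()]), censored values
#'   imputed.
#' @param pairing `"per-garden"` (default) or `"per-area-mean"`.
#' @param elements element set; defaults to elements shared by both tables.
#' @return data.frame with columns `species`, `area`, `element`, `tf`,
#'   `soil_conc` (mean denominator, for audit), `n`, `exceeds_one`.
#' @export
tf_table <- function(plants, soils, pairing = c("per-garden", "per-area-mean"),
                     elements = NULL) {
  pairing <- match.arg(pairing)
  if (is.null(elements))
    elements <- intersect(dataset_elements(plants), dataset_elements(soils))
  elements <- as_element(elements)
  grown <- plants[plants$source != "market", , drop = FALSE]
  if (nrow(grown) == 0) stop("no garden-grown plant samples", call. = FALSE)
  unmatched <- setdiff(unique(grown$source), unique(soils$garden_code))
  if (length(unmatched))
    stop("no soil data for garden(s): ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  grown$area <- soils$area[match(grown$source, soils$garden_code)]
  soil_mean <- function(sub, el) mean(sub[[el]], na.rm = TRUE)
  rows <- list()
  for (el in elements) {
    if (pairing == "per-garden") {
      denom_by <- tapply(soils[[el]], soils$garden_code, mean, na.rm = TRUE)
      denom <- denom_by[grown$source]
    } else {
      denom_by <- tapply(soils[[el]], soils$area, mean, na.rm = TRUE)
      denom <- denom_by[grown$area]
    }
    tf <- transfer_factor(grown[[el]], as.numeric(denom))
    agg <- stats::aggregate(
      cbind(tf = tf, soil_conc = as.numeric(denom)),
      by = list(species = grown$species, area = grown$area), FUN = mean)
    agg$n <- stats::aggregate(tf, by = list(grown$species, grown$area),
                              FUN = length)$x
    agg$element <- el
    rows[[el]] <- agg
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$exceeds_one <- out$tf >= 1
  out[, c("species", "area", "element", "tf", "soil_conc", "n",
          "exceeds_one")]
}

#' Food-limit screening table for a dataset
#'
#' Converts species x area mean dry-weight concentrations to fresh weight
#' and screens them against the EU maximum levels for the elements that
#' have them.
#'
#' @param plants plant data.frame.
#' @param params element parameter data.frame.
#' @param fw_factor dry-to-fresh conversion factor.
#' @return data.frame with columns `species`, `source`, `element`,
#'   `conc_fw`, `limit`, `exceeds`.
#' @export
food_limit_table <- function(plants, params, fw_factor = 0.085) {
  elements <- dataset_elements(plants)
  has_limit <- params$element[
    !is.na(params$food_limit_leafy) | !is.na(params$food_limit_bulbous) |
      !is.na(params$food_limit_fruiting)]
  elements <- intersect(elements, has_limit)
  rows <- list()
  for (el in elements) {
    agg <- stats::aggregate(plants[[el]],
                            by = list(species = plants$species,
                                      source = plants$source),
                            FUN = mean, na.rm = TRUE)
    grp <- vegetable_group(agg$species)
    lim <- params[[1]][0]
    conc_fw <- dw_to_fw(agg$x, fw_factor)
    lim <- vapply(grp, function(g)
      params[[paste0("food_limit_", g)]][match(el, params$element)], 0)
    rows[[el]] <- data.frame(species = agg$species, source = agg$source,
                             element = el, conc_fw = conc_fw, limit = lim,
                             exceeds = ifelse(is.na(lim), NA, conc_fw > lim))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
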