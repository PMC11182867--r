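#' Element symbols handled by the package
#'
#' The eleven potentially toxic elements (PTEs) the package knows about:
#' As, B, Ba, Cd, Co, Cr, Cu, Mo, Ni, Pb and Zn. All concentration tables,
#' parameter maps and results are keyed by these symbols.
#'
#' @format Character vector of length 11.
#' @export
pte_elements <- c("As", "B", "Ba", "Cd", "Co", "Cr", "Cu", "Mo", "Ni",
                  "Pb", "Zn")

#' Normalise and validate element symbols
#'
#' Case-normalises element symbols (`"AS"`, `"as"` -> `"As"`) and errors on
#' anything outside the eleven supported elements.
#'
#' @param x character vector of element symbols.
#' @return Character vector of canonical symbols, same length as `x`.
#' @examples
#' as_element(c("as", "PB"))
#' @export
as_element <- function(x) {
  if (!is.character(x)) stop("element symbols must be character", call. = FALSE)
  idx <- match(tolower(x), tolower(pte_elements))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         "; accepted symbols are: ", paste(pte_elements, collapse = ", "),
         call. = FALSE)
  }
  pte_elements[idx]
}

#' Vegetable groups
#' @keywords internal
pte_groups <- c("leafy", "bulbous", "fruiting")

# Built-in species registry: species -> vegetable group.
.species_registry <- c(
  lettuce  = "leafy",
  chard    = "leafy",
  onion    = "bulbous",
  tomato   = "fruiting",
  pepper   = "fruiting",
  zucchini = "fruiting",
  eggplant = "fruiting"
)

#' Vegetable group of a species
#'
#' Maps a species name to its vegetable group (`leafy`, `bulbous` or
#' `fruiting`). The built-in registry covers the seven species commonly
#' grown in the surveyed gardens (lettuce, chard, onion, tomato, pepper,
#' zucchini, eggplant); additional species can be supplied through
#' `registry`. Unknown species fail loudly: silent misclassification would
#' corrupt group statistics and food-limit screening.
#'
#' @param species character vector of species names (case-insensitive).
#' @param registry optional named character vector extending/overriding the
#'   built-in registry, e.g. `c(kale = "leafy")`. Values must be one of
#'   `leafy`, `bulbous`, `fruiting`.
#' @return Character vector of groups, same length as `species`.
#' @examples
#' vegetable_group(c("chard", "onion", "tomato"))
#' vegetable_group("kale", registry = c(kale = "leafy"))
#' @export
vegetable_group <- function(species, registry = NULL) {
  reg <- .species_registry
  if (!is.null(registry)) {
    if (is.null(names(registry)) || any(!registry %in% pte_groups))
      stop("registry must be a named vector with values in: ",
           paste(pte_groups, collapse = ", "), call. = FALSE)
    reg[tolower(names(registry))] <- unname(registry)
  }
  out <- unname(reg[tolower(species)])
  if (anyNA(out)) {
    bad <- unique(species[is.na(out)])
    stop("unknown species: ", paste(bad, collapse = ", "),
         "; extend the registry via config to classify them", call. = FALSE)
  }
  out
}

#' Survey area types
#' @keywords internal
pte_areas <- c("peri-urban", "city", "mining")

# Built-in garden-code -> area map for the 15 surveyed gardens.
# NER and TIN sit in the Iberian Pyrite Belt mining district; UTR is the
# peri-urban reference garden; the remainder are city gardens (Seville,
# Cordoba, Huelva, Alcala de Guadaira).
.garden_area_map <- c(
  UTR = "peri-urban",
  LUC = "city", ALA = "city", ALC = "city", GUA = "city", ELE = "city",
  HER = "city", MI2 = "city", TRI = "city", TOR = "city", ASO = "city",
  LEV = "city", MOR = "city",
  NER = "mining", TIN = "mining"
)

#' Built-in garden codes and their areas
#'
#' @return Named character vector mapping the 15 built-in garden codes to
#'   their area type.
#' @export
garden_area_codes <- function() .garden_area_map

#' Assign an area type to a garden code
#'
#' Resolves garden codes to area types (`peri-urban`, `city`, `mining`).
#' The 15 surveyed garden codes are built in; unknown codes must be resolved
#' through `area_map`, otherwise an error is raised (defaulting would
#' silently corrupt area-level statistics).
#'
#' @param garden_code character vector of garden codes.
#' @param area_map optional named character vector of additional
#'   code -> area entries; overrides built-ins on collision.
#' @return Character vector of areas, same length as `garden_code`.
#' @examples
#' assign_area(c("NER", "UTR", "GUA"))
#' assign_area("XYZ", area_map = c(XYZ = "city"))
#' @export
assign_area <- function(garden_code, area_map = NULL) {
  if (any(!nzchar(garden_code)))
    stop("garden_code must be non-empty", call. = FALSE)
  map <- .garden_area_map
  if (!is.null(area_map)) {
    if (is.null(names(area_map)) || any(!area_map %in% pte_areas))
      stop("area_map must be a named vector with values in: ",
           paste(pte_areas, collapse = ", "), call. = FALSE)
    map[names(area_map)] <- unname(area_map)
  }
  out <- unname(map[garden_code])
  if (anyNA(out)) {
    bad <- unique(garden_code[is.na(out)])
    stop("cannot resolve area for garden code(s): ",
         paste(bad, collapse = ", "),
         "; supply them via the areas block of the config", call. = FALSE)
  }
  out
}
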