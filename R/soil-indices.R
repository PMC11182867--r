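#' Contamination factor
#'
#' Ratio of the measured soil concentration to the regional geochemical
#' background, `CF = C_soil / C_bk`. Values above 1 indicate enrichment
#' over the natural background.
#'
#' @param c_soil soil concentration, mg/kg dry weight (> 0).
#' @param c_bk regional background concentration, mg/kg (> 0).
#' @return Unitless contamination factor (vectorised).
#' @examples
#' contamination_factor(30, 10)
#' @export
contamination_factor <- function(c_soil, c_bk) {
  if (any(c_soil <= 0) || any(c_bk <= 0))
    stop("contamination_factor requires positive concentrations",
         call. = FALSE)
  c_soil / c_bk
}

.cf_classes <- c("low", "moderate", "considerable", "very high")

#' Hakanson contamination class of a CF value
#'
#' `cf < 1` low; `1 <= cf < 3` moderate; `3 <= cf < 6` considerable;
#' `cf >= 6` very high. Boundary values are assigned to the upper class
#' (conservative for screening).
#'
#' @param cf unitless contamination factor (> 0), vectorised.
#' @return Character vector of classes.
#' @export
classify_cf <- function(cf) {
  if (any(cf <= 0)) stop("cf must be > 0", call. = FALSE)
  .cf_classes[findInterval(cf, c(1, 3, 6)) + 1L]
}

#' Pollution load index
#'
#' Geometric mean of the contamination factors: the nth root of the product
#' of n CF values. Values above 1 indicate overall soil contamination.
#'
#' @param cfs numeric vector of contamination factors (> 0, non-empty).
#' @return Unitless PLI.
#' @examples
#' pollution_load_index(c(2, 8)) # 4
#' @export
pollution_load_index <- function(cfs) {
  if (length(cfs) == 0) stop("cfs must be non-empty", call. = FALSE)
  if (any(cfs <= 0)) stop("cfs must be > 0", call. = FALSE)
  # computed in log space: stable against under/overflow of the raw product
  exp(mean(log(cfs)))
}

#' Screen soil concentrations against regulatory trigger values
#'
#' Flags elements whose concentration strictly exceeds the regional trigger
#' (action) value for agricultural use. Elements lacking a trigger value
#' are reported as `NA` (not screened), never as an error.
#'
#' @param conc named numeric vector, element -> mg/kg.
#' @param params element parameter data.frame (column `trigger_value`).
#' @return Named logical vector (`NA` where no trigger value exists).
#' @export
screen_soil_regulatory <- function(conc, params) {
  tv <- params$trigger_value[match(names(conc), params$element)]
  out <- ifelse(is.na(tv), NA, conc > tv)
  names(out) <- names(conc)
  out
}

# Default CF/PLI element set: the six elements with regional backgrounds.
.default_cf_elements <- c("As", "Cr", "Cu", "Ni", "Pb", "Zn")

#' Contamination summary for one garden
#'
#' Computes, from the soil samples of a single garden, the per-element mean
#' concentration, contamination factor, Hakanson class, trigger-value flag,
#' and the pollution load index over the requested element set. Censored
#' values must have been imputed first (see [impute_dataset()]).
#'
#' @param soils soil data.frame for one garden (as from [read_soil_csv()]).
#' @param params element parameter data.frame with `background` present for
#'   every requested CF element.
#' @param elements element set for CF/PLI; defaults to the six elements
#'   with regional backgrounds (As, Cr, Cu, Ni, Pb, Zn).
#' @param per_sample if `TRUE`, CFs (and PLI) are computed per sample and
#'   returned in the `samples` component instead of on garden means.
#' @return A list of class `pte_contamination`: `garden_code`, `area`,
#'   `mean_conc`, `cf`, `cf_class`, `exceeds_tv`, `pli` (and `samples` when
#'   `per_sample = TRUE`).
#' @export
garden_contamination <- function(soils, params,
                                 elements = .default_cf_elements,
                                 per_sample = FALSE) {
  gc <- unique(soils$garden_code)
  if (length(gc) != 1)
    stop("garden_contamination expects samples from a single garden",
         call. = FALSE)
  elements <- as_element(elements)
  bk <- params$background[match(elements, params$element)]
  if (anyNA(bk)) {
    miss <- elements[is.na(bk)]
    stop("background value missing for element(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  have <- intersect(elements, names(soils))
  if (length(have) < length(elements))
    stop("soil table lacks element column(s): ",
         paste(setdiff(elements, have), collapse = ", "), call. = FALSE)
  conc <- vapply(elements, function(el) mean(soils[[el]]), 0)
  if (anyNA(conc))
    stop("NA concentrations present; impute censored values first",
         call. = FALSE)
  cf <- contamination_factor(conc, bk)
  res <- list(garden_code = gc,
              area = unique(soils$area)[1],
              mean_conc = conc,
              cf = cf,
              cf_class = stats::setNames(classify_cf(cf), elements),
              exceeds_tv = screen_soil_regulatory(conc, params),
              pli = pollution_load_index(cf))
  if (per_sample) {
    names(bk) <- elements
    res$samples <- t(apply(soils[, elements, drop = FALSE], 1,
                           function(row) contamination_factor(row, bk)))
    rownames(res$samples) <- soils$sample_id
  }
  structure(res, class = "pte_contamination")
}

#' @export
print.pte_contamination <- function(x, ...) {
  cat(sprintf("<pte_contamination> garden %s (%s), PLI = %.3g\n",
              x$garden_code, x$area, x$pli))
  print(data.frame(mean_conc = x$mean_conc, cf = x$cf, class = x$cf_class,
                   exceeds_tv = x$exceeds_tv))
  invisible(x)
}

#' Contamination table for every garden in a dataset
#'
#' Runs [garden_contamination()] per garden and returns a long table, one
#' row per garden x element, with the garden PLI repeated on each row.
#'
#' @param ds a `pte_dataset` (censored values are imputed internally).
#' @inheritParams garden_contamination
#' @return data.frame with columns `garden_code`, `area`, `element`,
#'   `mean_conc`, `cf`, `cf_class`, `exceeds_tv`, `pli`.
#' @export
contamination_table <- function(ds, elements = .default_cf_elements) {
  ds <- impute_dataset(ds)
  gardens <- unique(ds$soils$garden_code)
  rows <- lapply(gardens, function(g) {
    res <- garden_contamination(ds$soils[ds$soils$garden_code == g, ],
                                ds$element_params, elements)
    data.frame(garden_code = g, area = res$area, element = names(res$cf),
               mean_conc = unname(res$mean_conc), cf = unname(res$cf),
               cf_class = unname(res$cf_class),
               exceeds_tv = unname(res$exceeds_tv[names(res$cf)]),
               pli = res$pli, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
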