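.get_ir <- function(species, exposure) {
  ir <- exposure$ir_fresh[tolower(species)]
  if (is.null(ir) || anyNA(ir))
    stop("no ingestion rate for species: ",
         paste(unique(species[is.na(ir)]), collapse = ", "), call. = FALSE)
  unname(ir)
}

#' Estimated daily intake of an element through one vegetable
#'
#' `EDI = Cm x IR x Ef x Ed x f_fw / (BW x AT_nc)` in mg per kg body weight
#' per day, where Cm is the dry-weight concentration of the element in the
#' vegetable, IR the fresh-weight ingestion rate, and f_fw the dry/fresh
#' conversion factor (the ingestion rate refers to fresh produce while Cm
#' is measured on dried tissue). With the default exposure scenario
#' (Ef = 365 d/y, Ed = 30 y, AT_nc = 30 x 365 d) the time terms cancel.
#'
#' @param cm_dw concentration in the vegetable, mg/kg dry weight (>= 0).
#' @param species species name (must have an ingestion rate in `exposure`).
#' @param exposure a [exposure_params()] object.
#' @return EDI in mg/kg-bw/day (vectorised over `cm_dw`).
#' @examples
#' ex <- exposure_params(ir_fresh = c(chard = 4.94e-3))
#' estimated_daily_intake(0.272, "chard", ex)
#' @export
estimated_daily_intake <- function(cm_dw, species, exposure) {
  if (any(cm_dw < 0, na.rm = TRUE)) stop("cm_dw must be >= 0", call. = FALSE)
  ir <- .get_ir(species, exposure)
  cm_dw * ir * exposure$ef * exposure$ed * exposure$fw_factor /
    (exposure$bw * exposure$at_nc)
}

#' Hazard quotient
#'
#' Ratio of the estimated daily intake to the oral reference dose (RfD).
#' Values above 1 indicate possible adverse non-carcinogenic effects.
#'
#' @param edi estimated daily intake, mg/kg-bw/day.
#' @param rfd oral reference dose, mg/kg-bw/day (> 0).
#' @return Unitless hazard quotient, with attribute `flagged` marking
#'   values > 1.
#' @export
hazard_quotient <- function(edi, rfd) {
  if (any(rfd <= 0)) stop("rfd must be > 0", call. = FALSE)
  hq <- edi / rfd
  attr(hq, "flagged") <- hq > 1
  hq
}

#' Hazard index
#'
#' Sum of the per-element hazard quotients for one vegetable; values above
#' 1 indicate potential for adverse non-carcinogenic health effects.
#'
#' @param hqs numeric vector (usually named by element) of hazard
#'   quotients; must be non-empty.
#' @return Unitless hazard index with attribute `flagged` (`TRUE` if > 1).
#' @export
hazard_index <- function(hqs) {
  if (length(hqs) == 0) stop("at least one hazard quotient required",
                             call. = FALSE)
  hi <- sum(hqs)
  attr(hi, "flagged") <- hi > 1
  hi
}

#' Carcinogenic risk from dietary arsenic
#'
#' Lifetime excess cancer risk
#' `CR = Cm x IR x f_fw x Ef x Ed x SF / (BW x AT_c)`, with the averaging
#' time `AT_c` taken over a 78-year lifetime (28470 days) and SF the oral
#' slope factor (1.5 (mg/kg-bw/day)^-1 for As). Risks above 1e-5 are
#' deemed unacceptable.
#'
#' @inheritParams estimated_daily_intake
#' @param sf oral slope factor, (mg/kg-bw/day)^-1 (> 0).
#' @return CR (vectorised), with attribute `unacceptable` marking values
#'   above 1e-5.
#' @examples
#' ex <- exposure_params(ir_fresh = c(chard = 4.94e-3))
#' carcinogenic_risk(0.272, "chard", ex, sf = 1.5)
#' @export
carcinogenic_risk <- function(cm_dw, species, exposure, sf) {
  if (is.null(sf) || is.na(sf) || sf <= 0)
    stop("slope factor missing or non-positive", call. = FALSE)
  if (any(cm_dw < 0, na.rm = TRUE)) stop("cm_dw must be >= 0", call. = FALSE)
  ir <- .get_ir(species, exposure)
  cr <- cm_dw * ir * exposure$fw_factor * exposure$ef * exposure$ed * sf /
    (exposure$bw * exposure$at_c)
  attr(cr, "unacceptable") <- cr > 1e-5
  cr
}

#' Back-calculate ingestion rates from a hazard-quotient table
#'
#' Given species x area x element mean concentrations and the matching
#' hazard quotients, each cell implies an ingestion rate
#' `IR = RfD x HQ x BW / (f_fw x Cm)` (the time terms cancel under the
#' default scenario). The per-species IR is the median over cells; cells
#' whose implied IR deviates more than `flag_threshold` from that median
#' are flagged — this catches transcription errors (e.g. exponent slips)
#' in published tables.
#'
#' @param cm_table data.frame `species, area, element, cm` (mg/kg dw).
#' @param hq_table data.frame `species, area, element, hq`.
#' @param params element parameter data.frame with `rfd`.
#' @param exposure a [exposure_params()] object (BW and fw factor used;
#'   ingestion rates in it are ignored).
#' @param flag_threshold relative deviation above which a cell is flagged
#'   (default 0.25).
#' @return List with `ir` (named numeric, kg fresh weight/day per species)
#'   and `cells` (data.frame with per-cell `implied_ir`, `residual`,
#'   `flagged`).
#' @export
calibrate_ingestion_rate <- function(cm_table, hq_table, params,
                                     exposure = exposure_params(),
                                     flag_threshold = 0.25) {
  need <- c("species", "area", "element")
  stopifnot(all(c(need, "cm") %in% names(cm_table)),
            all(c(need, "hq") %in% names(hq_table)))
  m <- merge(cm_table, hq_table, by = need)
  m$rfd <- params$rfd[match(m$element, params$element)]
  usable <- !is.na(m$rfd) & !is.na(m$cm) & !is.na(m$hq) & m$cm > 0
  m <- m[usable, , drop = FALSE]
  # Ef x Ed / AT_nc is assumed to cancel (Ef 365, AT_nc = Ed x 365)
  m$implied_ir <- m$rfd * m$hq * exposure$bw / (exposure$fw_factor * m$cm)
  counts <- table(m$species)
  if (any(counts < 3))
    stop("fewer than 3 usable cells for species: ",
         paste(names(counts)[counts < 3], collapse = ", "), call. = FALSE)
  med <- tapply(m$implied_ir, m$species, stats::median)
  m$residual <- m$implied_ir / med[m$species] - 1
  m$flagged <- abs(m$residual) > flag_threshold
  list(ir = stats::setNames(as.numeric(med), names(med)),
       cells = m[, c(need, "cm", "hq", "implied_ir", "residual", "flagged")])
}

#' Risk table from a table of mean concentrations
#'
#' Variant of [risk_table()] that starts from already-aggregated mean
#' dry-weight concentrations (species x area x element), as when
#' reproducing published summary tables.
#'
#' @param means data.frame with columns `species`, `area`, `element` and a
#'   concentration column `cm` (or `mean`), mg/kg dry weight.
#' @inheritParams risk_table
#' @return As [risk_table()]: one row per species x area with `hq_*`
#'   columns, `hi`, `cr_as` and exceedance flags.
#' @export
risk_from_means <- function(means, exposure, params) {
  cm_col <- if ("cm" %in% names(means)) "cm" else "mean"
  stopifnot(all(c("species", "area", "element", cm_col) %in% names(means)))
  means$element <- as_element(means$element)
  elements <- intersect(pte_elements, unique(means$element))
  wide <- data.frame(species = means$species, area = means$area)
  wide <- unique(wide)
  fake <- wide
  fake$sample_id <- paste(wide$species, wide$area, sep = "|")
  for (el in elements) {
    sub <- means[means$element == el, ]
    key <- paste(sub$species, sub$area, sep = "|")
    fake[[el]] <- sub[[cm_col]][match(fake$sample_id, key)]
  }
  fake$source <- "market"   # placeholder; area reassigned below
  out <- risk_table(fake, exposure, params, per_sample = TRUE)
  out$area <- wide$area[match(out$sample_id, paste(wide$species, wide$area,
                                                   sep = "|"))]
  out$sample_id <- NULL
  out
}

#' Full risk table for a dataset of produce concentrations
#'
#' Computes, per species x area, mean dry-weight concentrations, then the
#' hazard quotient per element, the hazard index, and the carcinogenic
#' risk of As (when an As concentration and slope factor are available).
#' This is the table-shaped output of the non-carcinogenic and
#' carcinogenic screening.
#'
#' @param plants plant data.frame ([read_plant_csv()]); censored cells
#'   should be imputed beforehand.
#' @param exposure a [exposure_params()] object covering every species.
#' @param params element parameter data.frame (rfd per element;
#'   slope_factor for As).
#' @param area_map optional extra garden-code -> area entries.
#' @param per_sample if `TRUE`, rows are per plant sample instead of
#'   species x area means.
#' @return data.frame, one row per species x area: `hq_<element>` columns,
#'   `hi`, `cr_as`, and the flags `hi_exceeds` (HI > 1) and
#'   `cr_unacceptable` (CR > 1e-5).
#' @export
risk_table <- function(plants, exposure, params, area_map = NULL,
                       per_sample = FALSE) {
  elements <- dataset_elements(plants)
  rfd <- stats::setNames(params$rfd[match(elements, params$element)],
                         elements)
  no_rfd <- elements[is.na(rfd)]
  if (length(no_rfd)) {
    warning("no RfD for element(s) ", paste(no_rfd, collapse = ", "),
            "; excluded from HQ/HI", call. = FALSE)
    elements <- setdiff(elements, no_rfd)
  }
  area <- plants$source
  grown <- area != "market"
  area[grown] <- assign_area(area[grown], area_map)
  if (per_sample) {
    key <- data.frame(species = plants$species, area = area,
                      sample_id = plants$sample_id)
    cm <- plants[, elements, drop = FALSE]
  } else {
    agg <- stats::aggregate(plants[, elements, drop = FALSE],
                            by = list(species = plants$species, area = area),
                            FUN = mean, na.rm = TRUE)
    key <- agg[, c("species", "area")]
    cm <- agg[, elements, drop = FALSE]
  }
  sf_as <- params$slope_factor[match("As", params$element)]
  out <- key
  hq_mat <- matrix(NA_real_, nrow(cm), length(elements),
                   dimnames = list(NULL, elements))
  for (el in elements) {
    edi <- estimated_daily_intake(cm[[el]], out$species, exposure)
    hq_mat[, el] <- as.numeric(hazard_quotient(edi, rfd[[el]]))
  }
  colnames(hq_mat) <- paste0("hq_", elements)
  out <- cbind(out, as.data.frame(hq_mat))
  out$hi <- rowSums(hq_mat)
  out$hi_exceeds <- out$hi > 1
  if ("As" %in% names(cm) && !is.na(sf_as)) {
    out$cr_as <- as.numeric(carcinogenic_risk(cm[["As"]], out$species,
                                              exposure, sf_as))
    out$cr_unacceptable <- out$cr_as > 1e-5
  } else {
    out$cr_as <- NA_real_
    out$cr_unacceptable <- NA
  }
  out
}
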