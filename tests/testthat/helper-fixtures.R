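# Shared fixture builders: tiny in-code datasets and on-disk CSV/config
# trios written to a temp dir.

minimal_config_list <- function(ir = c(chard = 4.94e-3, tomato = 2.49e-2),
                                backgrounds = NULL) {
  elements <- list(
    As = list(rfd = 3e-4, slope_factor = 1.5, trigger_value = 36),
    Cu = list(rfd = 0.04, trigger_value = 595),
    Pb = list(rfd = 2e-3, trigger_value = 275,
              food_limits = list(leafy = 0.3, bulbous = 0.1,
                                 fruiting = 0.05)),
    Cd = list(rfd = 1e-3,
              food_limits = list(leafy = 0.20, bulbous = 0.05,
                                 fruiting = 0.05)))
  if (!is.null(backgrounds))
    for (el in names(backgrounds))
      elements[[el]]$background <- backgrounds[[el]]
  list(elements = elements,
       exposure = list(ir_fresh = as.list(ir), bw = 70, ef = 365, ed = 30,
                       at_nc = 10950, at_c = 28470, fw_factor = 0.085))
}

write_fixture_files <- function(dir = tempfile("fx"),
                                soil_lines = NULL, plant_lines = NULL,
                                config = minimal_config_list(
                                  backgrounds = list(As = 10, Cu = 20,
                                                     Pb = 20))) {
  if (is.null(soil_lines))
    soil_lines <- c(
      "sample_id,garden_code,ph,conductivity,As,Cu,Pb",
      "s1,UTR,7.8,0.2,12.4,25.0,14.0",
      "s2,UTR,7.9,0.3,<LOD,30.0,16.0",
      "s3,NER,6.5,0.4,87.2,333.1,359.6")
  if (is.null(plant_lines))
    plant_lines <- c(
      "sample_id,species,source,As,Cu,Pb",
      "p1,chard,UTR,0.027,9.07,0.278",
      "p2,chard,NER,0.272,10.95,0.698",
      "p3,tomato,market,0.017,9.35,0.166")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  soil <- file.path(dir, "soil.csv")
  plants <- file.path(dir, "plants.csv")
  cfg <- file.path(dir, "config.json")
  writeLines(soil_lines, soil)
  writeLines(plant_lines, plants)
  jsonlite::write_json(config, cfg, auto_unbox = TRUE, digits = NA)
  list(dir = dir, soil = soil, plants = plants, config = cfg)
}

# Small noiseless synthetic configuration used by several tests.
noiseless_synth_config <- function(seed = 1234, lod = NULL) {
  synthetic_config(
    areas = data.frame(name = c("peri-urban", "mining"), n_gardens = 2,
                       samples_per_garden = 3),
    soil_median = rbind(`peri-urban` = c(As = 6, Pb = 14, Zn = 36),
                        mining = c(As = 66, Pb = 190, Zn = 228)),
    soil_gsd = 1, lod = lod,
    true_tf = rbind(chard = c(As = 0.01, Pb = 0.01, Zn = 0.6),
                    tomato = c(As = 0.002, Pb = 0.004, Zn = 0.4)),
    plant_noise_gsd = 1, plant_reps = 1, seed = seed)
}
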