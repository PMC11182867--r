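test_that("censoring tokens are parsed as left-censored cells", {
  fx <- write_fixture_files(soil_lines = c(
    "sample_id,garden_code,ph,As,Cu,Pb",
    "s1,UTR,7.8,12.4,25.0,14.0",
    "s2,UTR,7.9,<LOD,< LD,nd",
    "s3,UTR,7.7,<dl,30.0,16.0"))
  soils <- read_soil_csv(fx$soil)
  cens <- attr(soils, "censored")
  expect_equal(unname(cens[, "As"]), c(FALSE, TRUE, TRUE))
  expect_equal(unname(cens[, "Cu"]), c(FALSE, TRUE, FALSE))
  expect_equal(unname(cens[, "Pb"]), c(FALSE, TRUE, FALSE))
  expect_true(is.na(soils$As[2]))
  expect_equal(soils$As[1], 12.4)
})

test_that("schema violations fail loudly with the offending column/row", {
  fx <- write_fixture_files()
  no_ph <- c("sample_id,garden_code,As", "s1,UTR,5.0")
  writeLines(no_ph, file.path(fx$dir, "bad.csv"))
  expect_error(read_soil_csv(file.path(fx$dir, "bad.csv")), "ph")
  neg <- c("sample_id,garden_code,ph,As", "s1,UTR,7.0,-3.0")
  writeLines(neg, file.path(fx$dir, "neg.csv"))
  expect_error(read_soil_csv(file.path(fx$dir, "neg.csv")),
               "negative concentration.*row 1")
  unk <- c("sample_id,garden_code,ph,Fe", "s1,UTR,7.0,3.0")
  writeLines(unk, file.path(fx$dir, "unk.csv"))
  expect_error(read_soil_csv(file.path(fx$dir, "unk.csv")),
               "unknown column.*Fe")
  txt <- c("sample_id,garden_code,ph,As", "s1,UTR,7.0,abc")
  writeLines(txt, file.path(fx$dir, "txt.csv"))
  expect_error(read_soil_csv(file.path(fx$dir, "txt.csv")),
               "non-numeric")
})

test_that("datasets round-trip through write_dataset/load_dataset", {
  fx <- write_fixture_files()
  ds <- load_dataset(fx$soil, fx$plants, fx$config)
  out <- file.path(fx$dir, "roundtrip")
  write_dataset(ds, out)
  ds2 <- load_dataset(file.path(out, "soil.csv"),
                      file.path(out, "plants.csv"),
                      file.path(out, "config.json"))
  expect_equal(ds2$soils, ds$soils)
  expect_equal(attr(ds2$soils, "censored"), attr(ds$soils, "censored"))
  expect_equal(ds2$plants, ds$plants)
  expect_equal(ds2$element_params, ds$element_params)
  expect_equal(unclass(ds2$exposure), unclass(ds$exposure))
})

test_that("cross-validation catches unmatched gardens and elements", {
  fx <- write_fixture_files(plant_lines = c(
    "sample_id,species,source,As,Cu,Pb",
    "p1,chard,ZZZ,0.1,1.0,0.1"))
  expect_error(load_dataset(fx$soil, fx$plants, fx$config),
               "cannot resolve area|absent from soil")
  fx2 <- write_fixture_files(config = minimal_config_list()["exposure"])
  expect_error(load_dataset(fx2$soil, fx2$plants, fx2$config),
               "elements")
})

test_that("area assignment covers the survey codes and user overrides", {
  expect_equal(assign_area("NER"), "mining")
  expect_equal(assign_area("TIN"), "mining")
  expect_equal(assign_area("UTR"), "peri-urban")
  codes <- garden_area_codes()
  expect_length(codes, 15)
  expect_equal(sum(codes == "city"), 12)
  expect_equal(assign_area(names(codes)), unname(codes))
  expect_equal(assign_area("XYZ", area_map = c(XYZ = "city")), "city")
  expect_error(assign_area("XYZ"), "cannot resolve area")
  expect_error(assign_area(""), "non-empty")
})

test_that("species map to their vegetable group, extendable via registry", {
  expect_equal(vegetable_group(c("chard", "lettuce")), c("leafy", "leafy"))
  expect_equal(vegetable_group("onion"), "bulbous")
  expect_equal(vegetable_group(c("tomato", "pepper", "zucchini",
                                 "eggplant")), rep("fruiting", 4))
  expect_equal(vegetable_group("Chard"), "leafy")
  expect_error(vegetable_group("kale"), "unknown species")
  expect_equal(vegetable_group("kale", registry = c(kale = "leafy")),
               "leafy")
})

test_that("element symbols are case-normalised and validated", {
  expect_equal(as_element(c("as", "PB", "Zn")), c("As", "Pb", "Zn"))
  expect_error(as_element("Fe"), "accepted symbols")
})

test_that("impute_censored follows the minimum-replacement rule", {
  expect_equal(impute_censored(c(5, 3, NA), c(FALSE, FALSE, TRUE)),
               c(5, 3, 3))
  v <- c(2.5, 7, 4)
  expect_equal(impute_censored(v, rep(FALSE, 3)), v)
  once <- impute_censored(c(5, 3, NA), c(FALSE, FALSE, TRUE))
  expect_equal(impute_censored(once, c(FALSE, FALSE, TRUE)), once)
  expect_error(impute_censored(c(NA, NA), c(TRUE, TRUE)), "all values")
})

test_that("imputation preserves uncensored values and the dataset minimum", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    v <- rlnorm(n, 1, 0.8)
    cens <- runif(n) < 0.4
    if (all(cens)) cens[1] <- FALSE
    v_in <- replace(v, cens, NA)
    out <- impute_censored(v_in, cens)
    expect_equal(sort(out[!cens]), sort(v[!cens]))
    expect_gte(min(out), min(v[!cens]))
    expect_length(out, n)
  }
})

test_that("impute_dataset pools the minimum across all soil samples", {
  fx <- write_fixture_files(soil_lines = c(
    "sample_id,garden_code,ph,As",
    "s1,UTR,7.8,12.4",
    "s2,NER,6.5,3.1",
    "s3,GUA,7.7,<LOD"))
  ds <- load_dataset(fx$soil, fx$plants, fx$config)
  ds2 <- impute_dataset(ds)
  expect_equal(ds2$soils$As, c(12.4, 3.1, 3.1))
  # flags retained so imputed cells remain identifiable
  expect_true(attr(ds2$soils, "censored")[3, "As"])
})

test_that("config round-trips YAML when available, and rejects bad fields", {
  skip_if_not_installed("yaml")
  cfg <- minimal_config_list()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  parsed <- read_config(path)
  expect_equal(parsed$exposure$bw, 70)
  expect_equal(parsed$element_params$rfd[
    parsed$element_params$element == "As"], 3e-4)
  cfg$exposure$fw_factor <- 1.5
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path2, auto_unbox = TRUE)
  expect_error(read_config(path2), "fw_factor")
})
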