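test_that("contamination factor is the soil/background ratio", {
  expect_equal(contamination_factor(10, 10), 1)
  expect_equal(contamination_factor(30, 10), 3)
  expect_equal(contamination_factor(5.5, 11), 0.5)
  expect_error(contamination_factor(0, 10), "positive")
  expect_error(contamination_factor(10, -1), "positive")
  # homogeneity in the soil concentration
  expect_equal(contamination_factor(7 * 3.3, 1.7),
               7 * contamination_factor(3.3, 1.7))
})

test_that("Hakanson classes: boundaries assigned upward, monotone", {
  expect_equal(classify_cf(0.5), "low")
  expect_equal(classify_cf(1.1), "moderate")
  expect_equal(classify_cf(c(1, 3, 6)),
               c("moderate", "considerable", "very high"))
  expect_equal(classify_cf(12), "very high")
  expect_error(classify_cf(0), "> 0")
  lv <- c("low", "moderate", "considerable", "very high")
  set.seed(7)
  cfs <- sort(rlnorm(50, 0, 1.2))
  ranks <- match(classify_cf(cfs), lv)
  expect_true(all(diff(ranks) >= 0))
})

test_that("PLI is the geometric mean of the CFs", {
  expect_equal(pollution_load_index(rep(1, 6)), 1)
  expect_equal(pollution_load_index(c(2, 8)), 4)
  expect_equal(pollution_load_index(c(1, 1, 1, 1, 1, 16)), 2^(2 / 3),
               tolerance = 1e-12)
  expect_equal(round(pollution_load_index(c(1, 1, 1, 1, 1, 16)), 4),
               1.5874)
  expect_error(pollution_load_index(numeric(0)), "non-empty")
  expect_error(pollution_load_index(c(1, 0)), "> 0")
})

test_that("PLI agrees with a brute-force product oracle and is invariant", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(2:9, 1)
    cfs <- rlnorm(n, 0, 0.9)
    oracle <- prod(cfs)^(1 / n)
    expect_equal(pollution_load_index(cfs), oracle, tolerance = 1e-12)
    expect_equal(pollution_load_index(sample(cfs)),
                 pollution_load_index(cfs), tolerance = 1e-12)
    # constant vector: PLI equals the constant
    expect_equal(pollution_load_index(rep(cfs[1], n)), cfs[1],
                 tolerance = 1e-12)
    # product identity over concatenated vectors
    a <- rlnorm(3); b <- rlnorm(4)
    expect_equal(pollution_load_index(c(a, b))^7,
                 pollution_load_index(a)^3 * pollution_load_index(b)^4,
                 tolerance = 1e-9)
  }
})

test_that("trigger-value screening is strict and skips missing TVs", {
  params <- build_config(minimal_config_list())$element_params
  expect_true(screen_soil_regulatory(c(As = 48.9), params)[["As"]])
  expect_false(screen_soil_regulatory(c(Pb = 92.9), params)[["Pb"]])
  expect_false(screen_soil_regulatory(c(As = 36.0), params)[["As"]])
  expect_true(is.na(screen_soil_regulatory(c(Cd = 5), params)[["Cd"]]))
})

test_that("garden_contamination composes CF, classes, PLI and screening", {
  bk <- list(As = 10, Cu = 20, Pb = 20)
  cfg <- build_config(minimal_config_list(backgrounds = bk))
  soils <- data.frame(sample_id = c("a", "b"), garden_code = "UTR",
                      area = "peri-urban", ph = 7.8,
                      As = c(8, 12), Cu = c(15, 25), Pb = c(18, 22))
  res <- garden_contamination(soils, cfg$element_params,
                              elements = c("As", "Cu", "Pb"))
  expect_s3_class(res, "pte_contamination")
  expect_equal(unname(res$cf), c(1, 1, 1))
  expect_equal(res$pli, 1)
  expect_equal(unname(res$cf_class), rep("moderate", 3))

  # synthetic garden with CFs {1, 1, 2, 8} -> PLI = 16^(1/4) = 2
  soils2 <- soils[1, ]
  soils2$As <- 10; soils2$Cu <- 40; soils2$Pb <- 160
  cfg2 <- build_config(minimal_config_list(
    backgrounds = list(As = 10, Cu = 20, Pb = 20, Cd = 20)))
  soils2$Cd <- 20
  res2 <- garden_contamination(soils2, cfg2$element_params,
                               elements = c("As", "Cd", "Cu", "Pb"))
  expect_equal(sort(unname(res2$cf)), c(1, 1, 2, 8))
  expect_equal(res2$pli, 2, tolerance = 1e-12)

  # doubling backgrounds halves every CF and the PLI
  cfg3 <- build_config(minimal_config_list(
    backgrounds = list(As = 20, Cu = 40, Pb = 40, Cd = 40)))
  res3 <- garden_contamination(soils2, cfg3$element_params,
                               elements = c("As", "Cd", "Cu", "Pb"))
  expect_equal(unname(res3$cf), unname(res2$cf) / 2)
  expect_equal(res3$pli, res2$pli / 2, tolerance = 1e-12)

  expect_error(garden_contamination(soils, cfg$element_params,
                                    elements = c("As", "Zn")),
               "Zn")
})

test_that("contamination_table reports one PLI per garden over the dataset", {
  fx <- write_fixture_files()
  ds <- load_dataset(fx$soil, fx$plants, fx$config)
  tab <- contamination_table(ds, elements = c("As", "Cu", "Pb"))
  expect_setequal(unique(tab$garden_code), c("UTR", "NER"))
  expect_equal(nrow(tab), 6)
  for (g in unique(tab$garden_code)) {
    sub <- tab[tab$garden_code == g, ]
    expect_equal(unique(sub$pli), pollution_load_index(sub$cf),
                 tolerance = 1e-12)
    expect_equal(sub$cf_class, classify_cf(sub$cf))
  }
})
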