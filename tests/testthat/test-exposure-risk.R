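chard_ex <- function() exposure_params(ir_fresh = c(chard = 4.94e-3))

test_that("EDI follows the intake equation and its cancellations", {
  ex <- chard_ex()
  expect_equal(estimated_daily_intake(0, "chard", ex), 0)
  e1 <- estimated_daily_intake(0.272, "chard", ex)
  expect_equal(e1, 0.272 * 4.94e-3 * 0.085 / 70, tolerance = 1e-12)
  expect_equal(round(e1, 9), 1.632e-6)
  # doubling IR doubles EDI
  ex2 <- exposure_params(ir_fresh = c(chard = 2 * 4.94e-3))
  expect_equal(estimated_daily_intake(0.272, "chard", ex2), 2 * e1,
               tolerance = 1e-12)
  # with Ef = 365 and AT_nc = Ed x 365 the EDI is independent of Ed
  for (ed in c(10, 30, 70)) {
    exe <- exposure_params(ir_fresh = c(chard = 4.94e-3), ed = ed,
                           at_nc = ed * 365, at_c = max(28470, ed * 365))
    expect_equal(estimated_daily_intake(0.272, "chard", exe), e1,
                 tolerance = 1e-12)
  }
  expect_error(estimated_daily_intake(0.1, "kale", ex), "kale")
})

test_that("hazard quotient and hazard index", {
  expect_equal(as.numeric(hazard_quotient(3e-4, 3e-4)), 1)
  expect_true(attr(hazard_quotient(4e-4, 3e-4), "flagged"))
  expect_equal(as.numeric(hazard_quotient(0, 5)), 0)
  expect_error(hazard_quotient(1, 0), "rfd")
  hq <- hazard_quotient(estimated_daily_intake(0.272, "chard", chard_ex()),
                        3e-4)
  expect_equal(round(as.numeric(hq), 5), 0.00544)

  hqs <- c(As = 1, B = 1, Ba = 1, Cd = 1, Co = 1, Cr = 1, Cu = 1, Mo = 1,
           Ni = 1, Pb = 1, Zn = 1)
  expect_equal(as.numeric(hazard_index(hqs)), 11)
  expect_true(attr(hazard_index(hqs), "flagged"))
  set.seed(5)
  v <- rlnorm(11, -5, 1)
  expect_equal(as.numeric(hazard_index(sample(v))),
               as.numeric(hazard_index(v)), tolerance = 1e-12)
  expect_error(hazard_index(numeric(0)), "at least one")
})

test_that("carcinogenic risk of As and the CR/HQ closed-form identity", {
  ex <- chard_ex()
  cr0 <- carcinogenic_risk(0, "chard", ex, sf = 1.5)
  expect_equal(as.numeric(cr0), 0)
  expect_false(attr(cr0, "unacceptable"))
  cr <- carcinogenic_risk(0.272, "chard", ex, sf = 1.5)
  expect_equal(as.numeric(cr),
               0.272 * 4.94e-3 * 365 * 30 * 0.085 * 1.5 / (70 * 28470),
               tolerance = 1e-12)
  expect_equal(signif(as.numeric(cr), 3), 9.41e-7)
  expect_error(carcinogenic_risk(0.1, "chard", ex, sf = NA), "slope")

  # CR = HQ_As x RfD_As x SF x (Ed x 365 / AT_c) whenever Ef = 365
  set.seed(11)
  for (i in 1:20) {
    cm <- rlnorm(1, -1, 1)
    hq <- as.numeric(hazard_quotient(
      estimated_daily_intake(cm, "chard", ex), 3e-4))
    lhs <- as.numeric(carcinogenic_risk(cm, "chard", ex, sf = 1.5))
    rhs <- hq * 3e-4 * 1.5 * (30 * 365 / 28470)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("EDI, HQ, HI, CR are degree-1 in Cm and IR, degree -1 in BW", {
  set.seed(21)
  cm <- rlnorm(1); k <- runif(1, 2, 9)
  base <- exposure_params(ir_fresh = c(chard = 4.94e-3))
  ir_k <- exposure_params(ir_fresh = c(chard = k * 4.94e-3))
  bw_k <- exposure_params(ir_fresh = c(chard = 4.94e-3), bw = 70 * k)
  f <- function(ex, cm) c(
    edi = estimated_daily_intake(cm, "chard", ex),
    cr = as.numeric(carcinogenic_risk(cm, "chard", ex, 1.5)))
  expect_equal(f(base, k * cm), k * f(base, cm), tolerance = 1e-12)
  expect_equal(f(ir_k, cm), k * f(base, cm), tolerance = 1e-12)
  expect_equal(f(bw_k, cm), f(base, cm) / k, tolerance = 1e-12)
})

test_that("ingestion-rate calibration recovers a known IR exactly", {
  params <- risk_profile("calibrated")$element_params
  ex <- exposure_params()
  els <- params$element
  true_ir <- c(chard = 4.2e-3, tomato = 1.9e-2)
  set.seed(31)
  cm <- expand.grid(species = names(true_ir),
                    area = c("mining", "city", "peri-urban"),
                    element = els, stringsAsFactors = FALSE)
  cm$cm <- rlnorm(nrow(cm), 0, 1)
  rfd <- params$rfd[match(cm$element, params$element)]
  hq <- cm
  hq$hq <- cm$cm * true_ir[cm$species] * ex$fw_factor / (ex$bw * rfd)
  hq$cm <- NULL
  cal <- calibrate_ingestion_rate(cm, hq, params, ex)
  expect_equal(cal$ir[names(true_ir)], true_ir, tolerance = 1e-10)
  expect_false(any(cal$cells$flagged))

  # a cell corrupted by a factor of 10 is flagged, the median unharmed
  hq2 <- hq
  hq2$hq[1] <- hq2$hq[1] * 10
  cal2 <- calibrate_ingestion_rate(cm, hq2, params, ex)
  expect_true(cal2$cells$flagged[
    cal2$cells$species == hq2$species[1] &
      cal2$cells$area == hq2$area[1] &
      cal2$cells$element == hq2$element[1]])
  expect_equal(cal2$ir[names(true_ir)], true_ir, tolerance = 0.05)

  small <- cm[1:2, ]
  small_hq <- hq[1:2, ]
  expect_error(calibrate_ingestion_rate(small, small_hq, params, ex),
               "fewer than 3")
})

test_that("risk_table scales linearly and handles zero concentrations", {
  prof <- risk_profile("calibrated")
  plants <- data.frame(sample_id = c("p1", "p2"),
                       species = c("chard", "tomato"),
                       vegetable_group = c("leafy", "fruiting"),
                       source = c("NER", "UTR"),
                       As = c(0.272, 0.017), Pb = c(0.698, 0.166))
  rt <- risk_table(plants, prof$exposure, prof$element_params)
  plants10 <- plants
  plants10$As <- 10 * plants10$As
  plants10$Pb <- 10 * plants10$Pb
  rt10 <- risk_table(plants10, prof$exposure, prof$element_params)
  expect_equal(rt10$hi, 10 * rt$hi, tolerance = 1e-12)
  expect_equal(rt10$cr_as, 10 * rt$cr_as, tolerance = 1e-12)
  expect_equal(rt10$hq_As, 10 * rt$hq_As, tolerance = 1e-12)

  zero <- plants
  zero$As <- 0; zero$Pb <- 0
  rt0 <- risk_table(zero, prof$exposure, prof$element_params)
  expect_equal(rt0$hi, c(0, 0))
  expect_equal(rt0$cr_as, c(0, 0))
  expect_false(any(rt0$hi_exceeds))
})

test_that("risk_table warns and drops elements lacking an RfD", {
  prof <- risk_profile("reference")   # no Mo RfD
  plants <- data.frame(sample_id = "p1", species = "chard",
                       vegetable_group = "leafy", source = "NER",
                       As = 0.272, Mo = 1.132)
  ex <- exposure_params(ir_fresh = c(chard = 4.94e-3))
  expect_warning(rt <- risk_table(plants, ex, prof$element_params), "Mo")
  expect_false("hq_Mo" %in% names(rt))
  expect_true("hq_As" %in% names(rt))
})
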