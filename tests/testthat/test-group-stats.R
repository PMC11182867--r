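test_that("pooled descriptives combine garden summaries correctly", {
  gs <- data.frame(garden_code = c("NER", "TIN"), area = "mining",
                   n = c(2, 5), mean = c(87.2, 167.8),
                   min = c(85.5, 48.9), max = c(88.9, 608.9))
  out <- pooled_descriptives(gs)
  expect_equal(out$n, 7L)
  expect_equal(out$mean, (2 * 87.2 + 5 * 167.8) / 7, tolerance = 1e-12)
  expect_equal(out$min, 48.9)
  expect_equal(out$max, 608.9)

  # single garden: area stats equal garden stats
  one <- pooled_descriptives(gs[1, ])
  expect_equal(one$mean, 87.2)
  expect_equal(one$n, 2L)

  # equal-n gardens: simple average of the garden means
  eq <- data.frame(garden_code = c("a", "b"), area = "x", n = 4,
                   mean = c(10, 30))
  expect_equal(pooled_descriptives(eq)$mean, 20)

  expect_error(pooled_descriptives(gs[0, ]), "empty")
  bad <- gs; bad$n[1] <- 0
  expect_error(pooled_descriptives(bad), ">= 1")
})

test_that("weighted pooling equals direct statistics on raw samples", {
  set.seed(13)
  for (i in 1:10) {
    raw <- data.frame(
      area = rep(c("city", "mining"), times = c(20, 12)),
      garden = rep(c("g1", "g2", "g3", "g4"), times = c(12, 8, 5, 7)),
      value = rlnorm(32, 2, 1))
    gs <- do.call(rbind, lapply(split(raw, raw$garden), function(d)
      data.frame(garden_code = d$garden[1], area = d$area[1], n = nrow(d),
                 mean = mean(d$value), min = min(d$value),
                 max = max(d$value))))
    pooled <- pooled_descriptives(gs)
    direct <- pooled_descriptives(raw = raw)
    expect_equal(pooled$mean, direct$mean, tolerance = 1e-12)
    expect_equal(pooled$n, direct$n)
    expect_equal(pooled$min, direct$min)
    expect_equal(pooled$max, direct$max)
    expect_true(all(c("median") %in% names(direct)))
  }
})

test_that("identically distributed groups share a letter", {
  v <- c(1.2, 3.4, 2.2, 5.0, 4.1, 2.8)
  cmp <- compare_groups(list(a = v, b = v, c = v))
  expect_equal(unname(cmp$letters), rep("a", 3))
})

test_that("well-separated normal groups get distinct letters via Tukey", {
  # exact normal quantile scores: the Shapiro gate passes by construction
  g1 <- qnorm(ppoints(20))
  g2 <- qnorm(ppoints(20)) + 10
  cmp <- compare_groups(list(low = g1, high = g2))
  expect_equal(cmp$test_used, "anova_tukey")
  expect_lt(cmp$p_value, 1e-6)
  expect_equal(length(unique(cmp$letters)), 2)
  # letters ordered by descending mean: highest group gets "a"
  expect_equal(unname(cmp$letters["high"]), "a")
  expect_equal(unname(cmp$letters["low"]), "b")
})

test_that("heavy-tailed data are routed to Kruskal-Wallis/Mann-Whitney", {
  set.seed(77)
  g1 <- rlnorm(25, 0, 2)
  g2 <- rlnorm(25, 0, 2)
  # the normality gate must reject at least one group for this seed
  expect_true(any(vapply(list(g1, g2), function(v)
    stats::shapiro.test(v)$p.value <= 0.05, TRUE)))
  cmp <- compare_groups(list(a = g1, b = g2))
  expect_equal(cmp$test_used, "kruskal_mannwhitney")
})

test_that("degenerate alpha bounds behave monotonically", {
  set.seed(55)
  vals <- list(a = rnorm(10, 0), b = rnorm(10, 1), c = rnorm(10, 2))
  none <- compare_groups(vals, alpha = 0)
  expect_equal(length(unique(none$letters)), 1)
  all_sep <- compare_groups(vals, alpha = 1)
  expect_equal(length(unique(all_sep$letters)), 3)
})

test_that("letter display is stable under group relabeling", {
  set.seed(66)
  vals <- list(a = rnorm(15, 0), b = rnorm(15, 0.2), c = rnorm(15, 8))
  cmp1 <- compare_groups(vals)
  cmp2 <- compare_groups(vals[c("c", "a", "b")])
  expect_equal(cmp1$letters[names(cmp2$letters)], cmp2$letters)
})

test_that("insufficient replication errors", {
  expect_error(compare_groups(list(a = c(1, 2), b = c(1, 2, 3))),
               "insufficient replication")
  expect_error(compare_groups(list(a = c(1, 2, 3))), "length")
})

test_that("summarize_by_group computes group means and sds per element", {
  plants <- data.frame(
    sample_id = paste0("p", 1:6),
    species = c("chard", "chard", "lettuce", "onion", "tomato", "tomato"),
    vegetable_group = c("leafy", "leafy", "leafy", "bulbous", "fruiting",
                        "fruiting"),
    source = "UTR",
    As = c(0.3, 0.5, 0.4, 0.1, 0.05, 0.07),
    Zn = c(60, 80, 70, 30, 20, 24))
  out <- summarize_by_group(plants)
  leafy_as <- out[out$vegetable_group == "leafy" & out$element == "As", ]
  expect_equal(leafy_as$mean, 0.4)
  expect_equal(leafy_as$n, 3L)
  bulb_zn <- out[out$vegetable_group == "bulbous" & out$element == "Zn", ]
  expect_true(is.na(bulb_zn$sd))   # singleton group
  # constructed leafy enrichment: leafy > fruiting for every element
  for (el in c("As", "Zn")) {
    sub <- out[out$element == el, ]
    expect_gt(sub$mean[sub$vegetable_group == "leafy"],
              sub$mean[sub$vegetable_group == "fruiting"])
  }
})
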