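test_that("one-way ANOVA handles standard and degenerate inputs", {
  ## identical groups: no between-group variance
  r <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)

  expect_warning(
    r0 <- one_way_anova(list(a = c(0, 0, 0, 0), b = c(1, 1, 1, 1))),
    "zero within-group")
  expect_equal(r0$p, 0)

  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "a")
  expect_error(one_way_anova(list(a = c(1, 2))), "2 groups")
})

test_that("two-group ANOVA equals the pooled t-test (F = t^2)", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(8 + i %% 5); b <- rnorm(12, mean = runif(1))
    r <- one_way_anova(list(a = a, b = b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("ANOVA holds its level on null normal data", {
  set.seed(11)
  rej <- replicate(2000, {
    one_way_anova(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))$p < 0.05
  })
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("the Welch t-test behaves symmetrically and at textbook power", {
  x <- c(1, 2, 3, 4)
  r <- two_sample_ttest(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  set.seed(3)
  a <- rnorm(10); b <- rnorm(15, 1)
  r1 <- two_sample_ttest(a, b); r2 <- two_sample_ttest(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  expect_error(two_sample_ttest(1, c(1, 2)), "2 observations")

  ## power at d = 1, n = 30 per arm is ~0.97
  set.seed(19)
  hits <- replicate(500, two_sample_ttest(rnorm(30), rnorm(30, 1))$p < 0.05)
  expect_gte(mean(hits), 0.95)
})

test_that("significance codes honour the strict thresholds", {
  expect_equal(significance_code(0.0479), "*")
  expect_equal(significance_code(0.0008), "***")
  expect_equal(significance_code(0.05), "ns")
  expect_equal(significance_code(c(0.01, 0.001, 0.0001, 0.00009)),
               c("*", "**", "***", "****"))
  expect_error(significance_code(1.2), "\\[0, 1\\]")
  expect_error(significance_code(-0.1), "\\[0, 1\\]")

  ## property check against an independent cut()-based coding
  set.seed(23)
  p <- c(runif(1e5), 0.05, 0.01, 0.001, 0.0001, 0, 1)
  ref <- as.character(cut(p, c(-Inf, 0.0001, 0.001, 0.01, 0.05, Inf),
                          labels = c("****", "***", "**", "*", "ns"),
                          right = FALSE))
  expect_identical(significance_code(p), ref)
})

test_that("pairwise contrasts have the right structure and handle missing data", {
  set.seed(5)
  mm <- data.frame(pmi_class = rep(1:4, each = 8))
  for (mk in marker_names()) mm[[mk]] <- rnorm(32)
  st <- pairwise_class_contrasts(mm)
  expect_equal(nrow(st), 6 * 3)
  expect_setequal(unique(st$contrast), c("1 vs 2", "1 vs 3", "1 vs 4"))
  expect_true(all(st$n_a == 8 & st$n_b == 8))

  ## NA markers are dropped per marker without contaminating others
  mm$MMR[mm$pmi_class == 3] <- NA
  st2 <- pairwise_class_contrasts(mm)
  expect_equal(sum(st2$marker == "MMR"), 2)
  expect_equal(sum(st2$marker == "amide_I"), 3)

  expect_error(pairwise_class_contrasts(mm, reference_class = 5), "absent")
})

test_that("contrast p-values agree with a direct pooled-variance computation", {
  set.seed(9)
  mm <- data.frame(pmi_class = rep(1:3, times = c(6, 9, 7)),
                   phosphate = rnorm(22))
  st <- pairwise_class_contrasts(mm, markers = "phosphate")
  x <- split(mm$phosphate, mm$pmi_class)
  ns <- lengths(x)
  mse <- sum(vapply(x, function(v) sum((v - mean(v))^2), 0)) / (sum(ns) - 3)
  for (b in 2:3) {
    tt <- (mean(x[[1]]) - mean(x[[b]])) /
      sqrt(mse * (1 / ns[1] + 1 / ns[b]))
    p_manual <- 2 * pt(-abs(tt), sum(ns) - 3)
    expect_equal(st$p_value[st$class_b == b], unname(p_manual),
                 tolerance = 1e-12)
  }
})

test_that("protected LSD gates stars on the omnibus test; Tukey runs", {
  set.seed(13)
  mm <- data.frame(pmi_class = rep(1:3, each = 6), phosphate = rnorm(18))
  st <- pairwise_class_contrasts(mm, markers = "phosphate",
                                 method = "protected-lsd")
  if (all(st$omnibus_p >= 0.05)) expect_true(all(st$significance == "ns"))

  st_tk <- pairwise_class_contrasts(mm, markers = "phosphate",
                                    method = "tukey")
  expect_equal(nrow(st_tk), 2)
  expect_true(all(st_tk$p_value >= 0 & st_tk$p_value <= 1))

  ## Benjamini-Hochberg option adjusts within contrast across markers
  mm2 <- data.frame(pmi_class = rep(1:2, each = 10))
  for (mk in marker_names()) mm2[[mk]] <- rnorm(20)
  raw <- pairwise_class_contrasts(mm2)
  bh <- pairwise_class_contrasts(mm2, p_adjust = "BH")
  expect_equal(bh$p_value, p.adjust(raw$p_value, "BH"), tolerance = 1e-12)
})
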