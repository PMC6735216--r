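test_that("every published summary cell is recomputed from the subject rows", {
  tab <- published_accuracies()
  expect_equal(nrow(tab), 10L)
  gs <- group_summary(tab)
  cell <- function(scope, strategy) {
    r <- gs[gs$scope == scope & gs$strategy == strategy, ]
    c(r$mean, r$sd)
  }
  tol <- 0.005   # printed precision
  expect_equal(cell("overall", "sm1_4"), c(69.50, 8.48), tolerance = tol)
  expect_equal(cell("overall", "sm1_5"), c(71.25, 7.84), tolerance = tol)
  expect_equal(cell("overall", "erd"), c(75.75, 8.98), tolerance = tol)
  expect_equal(cell("proliferation", "sm1_4"), c(70.00, 9.35), tolerance = tol)
  expect_equal(cell("proliferation", "sm1_5"), c(71.25, 8.54), tolerance = tol)
  expect_equal(cell("proliferation", "erd"), c(79.38, 10.28), tolerance = tol)
  expect_equal(cell("SM1", "sm1_4"), c(67.50, 3.54), tolerance = tol)
  expect_equal(cell("SM1", "sm1_5"), c(70.00, 4.56), tolerance = tol)
  expect_equal(cell("SM1", "erd"), c(71.88, 3.75), tolerance = tol)
  expect_equal(cell("others", "sm1_4"), c(72.50, 17.68), tolerance = tol)
  expect_equal(cell("others", "sm1_5"), c(73.75, 15.91), tolerance = tol)
  expect_equal(cell("others", "erd"), c(76.25, 15.91), tolerance = tol)
})

test_that("a single-subject scope reports sd 0 with a flag", {
  one <- as_accuracy_table(tibble::tibble(
    subject = "S1", group = "others", sm1_4 = 70, sm1_5 = 72, erd = 80
  ))
  gs <- group_summary(one)
  expect_true(all(gs$sd == 0))
  expect_true(all(!gs$sd_defined))
  expect_equal(gs$mean[gs$scope == "overall" & gs$strategy == "erd"], 80)
  expect_error(group_summary(one[0, ]), "empty")
})

test_that("the repeated-measures F statistic matches aov and the table", {
  fit <- rm_anova(published_accuracies())
  expect_equal(fit$df_effect, 2L)
  expect_equal(fit$df_error, 18L)
  expect_equal(fit$statistic, 19.442, tolerance = 0.01 / 19.442)
  expect_lt(fit$p_value, 0.0005)

  ## independent route: stats::aov with an Error stratum on a toy table
  toy <- as_accuracy_table(tibble::tibble(
    subject = c("a", "b", "c"), group = "g",
    sm1_4 = c(60, 70, 55), sm1_5 = c(62, 75, 54), erd = c(70, 80, 65)
  ))
  mine <- rm_anova(toy)
  long <- tidyr::pivot_longer(toy[, c("subject", "sm1_4", "sm1_5", "erd")],
                              -subject, names_to = "strategy")
  ref <- summary(stats::aov(value ~ strategy + Error(subject / strategy),
                            data = long))
  ref_tab <- ref[["Error: subject:strategy"]][[1]]
  expect_equal(mine$statistic, ref_tab[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p_value, ref_tab[["Pr(>F)"]][1], tolerance = 1e-10)

  ## identical columns -> F = 0; per-subject offsets do not change F
  flat <- as_accuracy_table(tibble::tibble(
    subject = c("a", "b"), group = "g",
    sm1_4 = c(60, 70), sm1_5 = c(60, 70), erd = c(60, 70)
  ))
  expect_equal(rm_anova(flat)$statistic, 0)
  cols <- c("sm1_4", "sm1_5", "erd")
  shifted <- toy
  shifted[cols] <- toy[cols] + matrix(c(5, -3, 11), nrow = 3, ncol = 3)
  expect_equal(rm_anova(shifted)$statistic, mine$statistic,
               tolerance = 1e-9)
})

test_that("Bonferroni post-hoc ordering matches the independent t statistic", {
  ph <- bonferroni_paired(published_accuracies())
  expect_equal(nrow(ph), 3L)
  expect_true(all(ph$p_adjusted >= ph$p_value))
  p_of <- function(pair) ph$p_adjusted[ph$pair == pair]
  ## SM1-4 vs ERD is the strongest contrast, SM1-4 vs SM1-5 the weakest
  expect_lt(p_of("sm1_4 vs erd"), p_of("sm1_5 vs erd"))
  expect_lt(p_of("sm1_5 vs erd"), p_of("sm1_4 vs sm1_5"))
  expect_lt(p_of("sm1_4 vs erd"), 0.05)
  expect_gt(p_of("sm1_4 vs sm1_5"), 0.05)

  ## independent paired-t computation for one pair
  tab <- published_accuracies()
  d <- tab$sm1_4 - tab$erd
  t_ref <- mean(d) / (sd(d) / sqrt(length(d)))
  p_ref <- 2 * stats::pt(-abs(t_ref), length(d) - 1)
  expect_equal(ph$p_value[ph$pair == "sm1_4 vs erd"], p_ref,
               tolerance = 1e-12)

  ## identical columns are degenerate with adjusted p = 1
  flat <- as_accuracy_table(tibble::tibble(
    subject = c("a", "b", "c"), group = "g",
    sm1_4 = c(60, 70, 80), sm1_5 = c(60, 70, 80), erd = c(60, 70, 80)
  ))
  ph2 <- bonferroni_paired(flat)
  expect_true(all(ph2$degenerate))
  expect_true(all(ph2$p_adjusted == 1))
})

test_that("accuracy tables are validated on the way in", {
  expect_error(as_accuracy_table(tibble::tibble(subject = "a")), "lacks")
  expect_error(as_accuracy_table(tibble::tibble(
    subject = "a", group = "g", sm1_4 = 120, sm1_5 = 70, erd = 70
  )), "percentages")
  expect_error(as_accuracy_table(tibble::tibble(
    subject = "a", group = "g", sm1_4 = NA_real_, sm1_5 = 70, erd = 70
  )), "missing")
})
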