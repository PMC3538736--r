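asl_pc <- function() {
  paired_comparison(1:6, c(295, 456, 191, 289, 374, 269),
                    c(304, 634, 344, 504, 462, 371), method = "ASL",
                    diseased_side = c("none", rep("left", 5)))
}
dce_pc <- function() {
  paired_comparison(1:6, c(535, 321, 313, 566, 504, 330),
                    c(519, 433, 481, 631, 679, 517), method = "DCE",
                    diseased_side = c("none", rep("left", 5)))
}

test_that("group summaries honour the ddof convention", {
  g1 <- group_summary(c(2, 4, 6), ddof = 1)
  expect_equal(g1$mean, 4)
  expect_equal(g1$sd, sd(c(2, 4, 6)))
  g0 <- group_summary(c(2, 4, 6), ddof = 0)
  # population vs sample SD differ by exactly sqrt((n-1)/n)
  expect_equal(g0$sd / g1$sd, sqrt(2 / 3))
  expect_equal(group_summary(c(5, 5, 5))$sd, 0)
  expect_error(group_summary(3), "at least two")
  expect_error(group_summary(c(1, 2), ddof = 2), "ddof")
})

test_that("healthy/diseased grouping follows the all-healthy-subject rule", {
  grp <- split_by_condition(asl_pc())
  expect_equal(sort(grp$diseased), sort(c(456, 191, 289, 374, 269)))
  # the all-healthy subject contributes both kidneys to the healthy group
  expect_equal(sort(grp$healthy), sort(c(295, 304, 634, 344, 504, 462, 371)))
})

test_that("paired differences subtract diseased from healthy per subject", {
  expect_equal(paired_differences(asl_pc()), c(178, 153, 215, 88, 102))
  expect_equal(paired_differences(dce_pc()), c(112, 168, 65, 175, 187))
  pc_eq <- paired_comparison(1:3, c(5, 6, 7), c(5, 6, 7), method = "ASL",
                             diseased_side = rep("left", 3))
  expect_equal(paired_differences(pc_eq), rep(0, 3))
  # right-sided disease flips the subtraction
  pc_r <- paired_comparison(1, 400, 300, method = "ASL", diseased_side = "right")
  expect_equal(paired_differences(pc_r), 100)
  pc_none <- paired_comparison(1, 400, 300, method = "ASL", diseased_side = "none")
  expect_error(paired_differences(pc_none), "no subjects")
})

test_that("paired t-test matches the closed form and is antisymmetric", {
  d <- c(178, 153, 215, 88, 102)
  res <- paired_t_test(d)
  # textbook closed form as the independent oracle
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t_stat, t_oracle)
  expect_equal(res$df, length(d) - 1)
  expect_equal(res$p_two_sided, 2 * stats::pt(-abs(t_oracle), length(d) - 1))

  neg <- paired_t_test(-d)
  expect_equal(neg$t_stat, -res$t_stat)
  expect_equal(neg$p_two_sided, res$p_two_sided)

  expect_error(paired_t_test(c(3, 3, 3)), "zero variance")
  expect_error(paired_t_test(5), "at least two")
})

test_that("Bland-Altman limits use the population SD", {
  d <- c(112, 168, 65, 175, 187)
  ba <- bland_altman(d)
  s0 <- sqrt(mean((d - mean(d))^2))
  expect_equal(ba$sd_diff, s0)
  expect_equal(ba$loa_low, mean(d) - 1.96 * s0)
  expect_equal(ba$loa_high, mean(d) + 1.96 * s0)
  # constant differences collapse the limits onto the mean
  bc <- bland_altman(c(4, 4, 4))
  expect_equal(c(bc$loa_low, bc$loa_high), c(4, 4))
})

test_that("left/right ratios are reported to two decimals", {
  r_asl <- lr_ratio(asl_pc())
  expect_equal(unname(r_asl), c(0.97, 0.72, 0.56, 0.57, 0.81, 0.73))
  r_dce <- lr_ratio(dce_pc())
  expect_equal(unname(r_dce), c(1.03, 0.74, 0.65, 0.90, 0.74, 0.64))
  pc_eq <- paired_comparison(1, 500, 500, method = "ASL", diseased_side = "none")
  expect_equal(unname(lr_ratio(pc_eq)), 1.00)
})

test_that("repeatability summary gives per-kidney mean and population SD", {
  reps <- list(`2.right` = c(634, 615, 651, 650), `4.left` = c(289, 286, 274, 272))
  rs <- repeatability_summary(reps)
  expect_equal(round(rs$mean), c(638, 280))
  expect_equal(round(rs$sd), c(15, 7))
  expect_equal(repeatability_summary(list(k = c(7, 7)))$sd, 0)
  expect_error(repeatability_summary(list(k = 7)), "at least two")
})

test_that("packaged per-animal tables load into paired comparisons", {
  tabs <- read_rbf_table()
  expect_named(tabs, c("ASL", "DCE"))
  expect_equal(nrow(tabs$ASL), 6)
  expect_equal(tabs$ASL$left[tabs$ASL$subject == 2], 456)
  reps <- read_repeats_table()
  expect_length(reps, 4)
  expect_equal(reps[["2.right"]], c(634, 615, 651, 650))
})

test_that("null calibration: rejection rate and LoA coverage are nominal", {
  set.seed(99)
  rej <- mean(replicate(500, paired_t_test(rnorm(5))$p_two_sided < 0.05))
  expect_lt(abs(rej - 0.05), 0.025)
  d <- rnorm(5000)
  ba <- bland_altman(d)
  expect_lt(abs(mean(d >= ba$loa_low & d <= ba$loa_high) - 0.95), 0.01)
})

test_that("plot helpers return ggplot objects", {
  expect_s3_class(plot_bland_altman(asl_pc()), "ggplot")
  expect_s3_class(plot_lr_ratios(list(ASL = asl_pc(), DCE = dce_pc())), "ggplot")
})
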