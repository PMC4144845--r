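test_that("RFI and RC behave as dimensionless indices", {
  expect_equal(rfi(0.8, 0.984), 0.23)
  expect_equal(rfi(0.63, 0.63), 0)
  expect_equal(rfi(0.5, 0.4), -0.2)
  expect_error(rfi(0, 1), "positive")

  # anchor properties: 1 at control-matched fitness, 0 at no improvement
  expect_equal(relative_compensation(0.7, 1.0, 1.0), 1)
  expect_equal(relative_compensation(0.7, 0.7, 1.0), 0)
  expect_equal(relative_compensation(0.6, 0.8, 1.0), 0.5)
  expect_warning(rc <- relative_compensation(1.0, 1.1, 1.0), "undefined")
  expect_true(is.na(rc))

  # rescaling all fitness values leaves both indices unchanged
  for (c_ in c(0.5, 2, 13)) {
    expect_equal(rfi(0.7 * c_, 0.9 * c_), rfi(0.7, 0.9))
    expect_equal(relative_compensation(0.6 * c_, 0.8 * c_, 1.0 * c_),
                 relative_compensation(0.6, 0.8, 1.0))
  }
})

test_that("control improvement cutoff is the normal-fit upper quantile", {
  # vector with sample mean 0.05 and ML standard deviation exactly 0.02
  x <- c(0.03, 0.07, 0.03, 0.07)
  expect_equal(control_improvement_cutoff(x, alpha = 0.05),
               0.05 + qnorm(0.95) * 0.02)
  expect_equal(control_improvement_cutoff(x, alpha = 0.5), 0.05)
  expect_warning(cz <- control_improvement_cutoff(rep(0.04, 5)), "zero")
  expect_equal(cz, 0.04)
  expect_error(control_improvement_cutoff(c(0.1, 0.2)), "3")
})

test_that("compensation calls require both significance and RFI above cutoff", {
  set.seed(3)
  lines <- make_line_tbl(
    genotype = c("gA", "gA", "gB"),
    line = c("l1", "l2", "l1"),
    start = list(rep(0.7, 6), rep(0.7, 6), rep(0.7, 6)),
    end = list(rep(0.98, 6),                       # clean compensation
               0.7 + rnorm(6, 0.15, 0.40),         # high RFI, noisy
               rep(0.71, 6)))                      # below cutoff
  out <- call_compensation(lines, cutoff = 0.08, fdr = 0.05, wt_end = 1.0)
  calls <- out$calls
  expect_true(calls$compensated[1])
  expect_gt(calls$rfi[2], 0.08)
  expect_false(calls$compensated[2])   # fails the significance gate
  expect_false(calls$compensated[3])   # fails the RFI gate
  expect_equal(calls$rc[1], relative_compensation(0.7, 0.98, 1.0))
  # genotype aggregation: one compensated line is enough
  expect_true(out$genotypes$compensated[out$genotypes$genotype == "gA"])
  expect_false(out$genotypes$compensated[out$genotypes$genotype == "gB"])
})

test_that("raising the cutoff never increases the number of calls", {
  set.seed(11)
  n <- 40
  lines <- make_line_tbl(
    genotype = paste0("g", seq_len(n)), line = "l1",
    start = replicate(n, 0.7 + rnorm(6, 0, 0.02), simplify = FALSE),
    end = replicate(n, 0.7 + runif(1, 0, 0.3) + rnorm(6, 0, 0.02),
                    simplify = FALSE))
  counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(cut)
    sum(call_compensation(lines, cut)$calls$compensated), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("missing endpoint data skips the line with a message", {
  lines <- make_line_tbl(genotype = c("g1", "g2"), line = c("l1", "l1"),
                         start = list(rep(0.7, 4), rep(0.7, 4)),
                         end = list(rep(0.9, 4), numeric(0)))
  expect_message(out <- call_compensation(lines, 0.05), "skipped")
  expect_equal(nrow(out$calls), 1L)
})

test_that("trend test detects ordered proportions and reduces to 2x2 chi-square", {
  f <- rep(c(0.55, 0.75, 0.85), each = 10)
  comp <- c(rep(c(TRUE, FALSE), c(9, 1)),
            rep(c(TRUE, FALSE), c(5, 5)),
            rep(c(TRUE, FALSE), c(1, 9)))
  tt <- trend_test(f, comp, c(0.5, 0.7, 0.8, 0.9))
  expect_lt(tt$p, 0.001)
  expect_equal(tt$bins$proportion, c(0.9, 0.5, 0.1))

  flat <- trend_test(f, rep(c(TRUE, FALSE), 15), c(0.5, 0.7, 0.8, 0.9))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p, 1)

  # two extreme bins: the trend statistic equals the 2x2 chi-square
  f2 <- rep(c(0.6, 0.85), each = 10)
  comp2 <- rep(c(FALSE, TRUE), each = 10)
  tt2 <- trend_test(f2, comp2, c(0.5, 0.7, 0.9))
  chi <- chisq.test(rbind(c(0, 10), c(10, 0)), correct = FALSE)
  expect_equal(tt2$statistic, unname(chi$statistic))

  # empty bin merges with its neighbor
  expect_warning(tm <- trend_test(f2, comp2, c(0.5, 0.7, 0.75, 0.9)),
                 "merged")
  expect_equal(nrow(tm$bins), 2L)
})

test_that("genotype ANOVA handles degenerate and clean separations", {
  flat <- genotype_effect_anova(
    data.frame(genotype = rep(c("a", "b"), each = 3), gain = 0.1))
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)

  sep <- genotype_effect_anova(
    data.frame(genotype = rep(c("a", "b"), each = 3),
               gain = rep(c(0, 1), each = 3)))
  expect_equal(sep$F, Inf)
  expect_equal(sep$p, 0)

  expect_error(genotype_effect_anova(
    data.frame(genotype = c("a", "b"), gain = c(0, 1))), "single line")

  # genotype-specific effects are detected at experiment scale
  set.seed(5)
  g <- rep(sprintf("g%03d", 1:90), each = 4)
  eff <- rep(rnorm(90, 0.2, 0.06), each = 4)
  out <- genotype_effect_anova(
    data.frame(genotype = g, gain = eff + rnorm(360, 0, 0.02)))
  expect_lt(out$p, 0.01)
})

test_that("specificity randomization contrasts observed categories with shuffles", {
  # all lines compensated: every shuffle reproduces the same categories
  calls <- data.frame(genotype = rep(c("a", "b", "c"), each = 4),
                      line = rep(1:4, 3), compensated = TRUE)
  out <- genotype_specificity_randomization(calls, n_shuffles = 200, seed = 1)
  expect_equal(unname(out$observed), c(0L, 0L, 3L))
  expect_equal(out$p, 1)
  expect_true(all(rowSums(out$null_counts) == 3))

  # perfectly genotype-clustered calls at 50%: mixed depleted, p small
  calls2 <- data.frame(genotype = rep(sprintf("g%02d", 1:30), each = 4),
                       line = rep(1:4, 30),
                       compensated = rep(c(TRUE, FALSE), each = 60))
  out2 <- genotype_specificity_randomization(calls2, n_shuffles = 500,
                                             seed = 7)
  expect_lt(out2$p, 1e-6)
  expect_equal(unname(out2$observed["mixed"]), 0L)
  expect_gt(out2$null_mean["mixed"], out2$observed["mixed"])

  # reproducibility and degenerate input
  out2b <- genotype_specificity_randomization(calls2, n_shuffles = 500,
                                              seed = 7)
  expect_identical(out2$null_counts, out2b$null_counts)
  expect_error(genotype_specificity_randomization(
    data.frame(genotype = "a", line = 1:4, compensated = TRUE)), "2 genotypes")
})

test_that("saturating trajectories deplete final-interval improvements", {
  # the depletion arithmetic reproduces the strong published-scale example:
  # 8 of 159 single-improvement lines in the last of 4 intervals (~40
  # expected) is a > 5-fold depletion
  dep <- saturation_depletion_test(8, 159, n_intervals = 4)
  expect_equal(dep$expected, 159 / 4)
  expect_lt(dep$p, 1e-8)

  # noise-free saturating construction: all improvement in interval 1
  days <- c(0, 26, 52, 78, 104)
  tbl <- do.call(rbind, lapply(1:24, function(i) {
    f <- c(0.7, rep(0.95, 4))   # jumps once, then flat
    do.call(rbind, lapply(seq_along(days), function(k)
      make_fitness_row(sprintf("g%02d", i), "l1", days[k],
                       f[k] + c(-2:3) * 1e-4)))
  }))
  out <- trajectory_saturation(tbl)
  expect_equal(nrow(out$single), 24L)
  expect_equal(out$depletion$observed, 0)
  expect_equal(out$depletion$expected, 6)
  expect_lt(out$depletion$p, 0.05)
})
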