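toy_design <- function(effect_sex = 0, effect_geno = 0, n = 3, sd = 1,
                       seed = 1) {
  set.seed(seed)
  d <- expand.grid(rep = seq_len(n), sex = c("M", "F"),
                   genotype = c("WT", "KO"))
  d$value <- rnorm(nrow(d), sd = sd) +
    effect_sex * (d$sex == "M") + effect_geno * (d$genotype == "KO")
  d
}

test_that("constant cells give the documented degenerate output", {
  d <- expand.grid(rep = 1:2, sex = c("M", "F"), genotype = c("WT", "KO"))
  d$value <- 5
  out <- two_way_anova(d$value, d$sex, d$genotype)
  expect_equal(out$p, rep(1, 3))
  expect_equal(out$bin, rep("blue", 3))
})

test_that("an injected sex effect is detected and matches hand-computed sums of squares", {
  d <- toy_design(effect_sex = 4, n = 4, sd = 0.8, seed = 123)
  out <- two_way_anova(d$value, d$sex, d$genotype)
  expect_lt(out$p[out$effect == "sex"], 0.05)
  expect_gt(out$p[out$effect == "genotype"], 0.5)
  expect_gt(out$p[out$effect == "sex:genotype"], 0.5)

  # independent oracle: balanced two-way ANOVA from cell means
  cm <- tapply(d$value, list(d$sex, d$genotype), mean)
  n <- 4
  gm <- mean(d$value)
  ss_sex <- 2 * n * sum((rowMeans(cm) - gm)^2)
  ss_geno <- 2 * n * sum((colMeans(cm) - gm)^2)
  ss_int <- n * sum((cm - outer(rowMeans(cm), colMeans(cm), "+") + gm)^2)
  fit_cells <- d$value - cm[cbind(as.character(d$sex),
                                  as.character(d$genotype))]
  ss_res <- sum(fit_cells^2)
  df_res <- nrow(d) - 4
  f_sex <- (ss_sex / 1) / (ss_res / df_res)
  expect_equal(out$F[out$effect == "sex"], f_sex, tolerance = 1e-8)
  expect_equal(out$p[out$effect == "sex"],
               pf(f_sex, 1, df_res, lower.tail = FALSE), tolerance = 1e-8)
  expect_equal(out$F[out$effect == "genotype"],
               (ss_geno / 1) / (ss_res / df_res), tolerance = 1e-8)
  expect_equal(out$F[out$effect == "sex:genotype"],
               (ss_int / 1) / (ss_res / df_res), tolerance = 1e-8)
})

test_that("specimen order does not change the ANOVA", {
  d <- toy_design(effect_geno = 2, n = 5, seed = 11)
  out1 <- two_way_anova(d$value, d$sex, d$genotype)
  set.seed(13)
  perm <- sample(nrow(d))
  out2 <- two_way_anova(d$value[perm], d$sex[perm], d$genotype[perm])
  expect_equal(out1, out2)
})

test_that("design validation names the offending cell", {
  d <- toy_design(n = 3)
  drop <- d$sex == "M" & d$genotype == "KO"
  expect_error(two_way_anova(d$value[!drop], d$sex[!drop],
                             d$genotype[!drop]),
               "sex=M, genotype=KO")
  one <- d[!(drop & duplicated(d[c("sex", "genotype")])), ]
  expect_error(two_way_anova(d$value[-which(drop)[1:2]],
                             d$sex[-which(drop)[1:2]],
                             d$genotype[-which(drop)[1:2]]),
               "at least 2")
})

test_that("paired one-tailed t matches the closed form and its conventions", {
  # identical pairs: boundary convention
  out0 <- paired_one_tailed_t(c(3, 3, 3), c(3, 3, 3))
  expect_equal(out0$t, 0)
  expect_equal(out0$p, 0.5)

  set.seed(17)
  wt <- rnorm(6)
  ko <- wt + 1 + rnorm(6, sd = 0.05)
  out <- paired_one_tailed_t(wt, ko, "ko_gt_wt")
  expect_lt(out$p, 0.01)
  d <- ko - wt
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(out$t, t_hand)
  expect_equal(out$p, pt(t_hand, length(d) - 1, lower.tail = FALSE))
  # reversing the declared direction complements the p-value
  rev <- paired_one_tailed_t(wt, ko, "ko_lt_wt")
  expect_equal(rev$p, 1 - out$p)
  expect_error(paired_one_tailed_t(1:3, 1:4), "equal length")
})

test_that("paired t power grows with effect size", {
  power_at <- function(delta) {
    mean(vapply(1:200, function(s) {
      set.seed(3000 + s)
      wt <- rnorm(5)
      ko <- wt + delta + rnorm(5, sd = 1)
      paired_one_tailed_t(wt, ko, "ko_gt_wt")$p < 0.05
    }, logical(1)))
  }
  p <- vapply(c(0, 1, 2.5), power_at, numeric(1))
  expect_true(all(diff(p) > 0))
  expect_lt(p[1], 0.12) # near nominal alpha under the null
})

test_that("delta-delta-Ct arithmetic follows the definition", {
  # identical Cts everywhere: fold 1
  expect_equal(ddct_fold(rep(20, 4), rep(15, 4), c(TRUE, TRUE, FALSE, FALSE)),
               rep(1, 4))
  # ddCt = -1 doubles, +2 quarters
  ct_t <- c(20, 20, 19, 22)
  ct_r <- rep(15, 4)
  fold <- ddct_fold(ct_t, ct_r, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fold[3], 2)
  expect_equal(fold[4], 0.25)
  # shifting target and reference equally changes nothing
  fold2 <- ddct_fold(ct_t + 3, ct_r + 3, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fold2, fold)
  expect_error(ddct_fold(c(20, NA), c(15, 15), c(TRUE, FALSE)), "target")
  expect_error(ddct_fold(c(20, 20), c(NA, 15), c(TRUE, FALSE)), "reference")
})

test_that("significance bins follow the published thresholds", {
  out <- significance_heatmap(c(0.00005, 0.0001, 0.005, 0.03, 0.05, 0.5),
                              position = 1:6)
  expect_equal(as.character(out$bin),
               c("red", "red", "yellow", "green", "green", "blue"))
  expect_error(significance_heatmap(c(0.5, 1.2)), "0, 1")
  expect_error(significance_heatmap(c(0.5, NA)), "0, 1")
})
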