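test_that("stratified folds partition trials and balance classes", {
  y <- rep(c("left", "relax"), each = 100)
  f <- stratified_kfold(y, k = 5, seed = 3)
  expect_identical(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 40))
  expect_true(all(table(f, y) == 20))
  expect_identical(stratified_kfold(y, 5, 3), f)       # deterministic
  expect_false(identical(stratified_kfold(y, 5, 4), f))
  expect_error(stratified_kfold(y, k = 1), ">= 2")
  expect_error(stratified_kfold(rep(c("a", "b"), c(3, 50)), k = 5),
               "k trials")
})

test_that("Cohen's kappa matches the closed form on canonical fixtures", {
  expect_equal(cohens_kappa(diag(c(50, 50))), 1)
  expect_equal(cohens_kappa(matrix(25, 2, 2)), 0)
  cm <- matrix(c(40, 5, 10, 45), 2, 2)
  po <- 85 / 100
  pe <- (50 * 45 + 50 * 55) / 100^2
  expect_equal(cohens_kappa(cm), (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_warning(k0 <- cohens_kappa(matrix(c(10, 0, 0, 0), 2, 2)),
                 "degenerate")
  expect_identical(k0, 0)
})

test_that("AUC agrees with the concordant-pair count and its null", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.2, 0.9, 0.5)
  y <- factor(c("n", "n", "p", "p", "p", "n", "p", "n"),
              levels = c("n", "p"))
  pos <- scores[y == "p"]; neg <- scores[y == "n"]
  pairs <- outer(pos, neg, function(a, b)
    ifelse(a > b, 1, ifelse(a == b, 0.5, 0)))
  expect_equal(roc_auc(scores, y, positive = "p"), mean(pairs),
               tolerance = 1e-12)
  expect_equal(roc_auc(y == "p", y, positive = "p"), 1)
  set.seed(40)
  yr <- factor(rep(c("n", "p"), 1000))
  expect_lt(abs(roc_auc(rnorm(2000), yr, positive = "p") - 0.5), 0.03)
  expect_error(roc_auc(1:5, rep("p", 5)), "both classes")
})

test_that("macro AUC averages one-vs-rest areas", {
  set.seed(41)
  y <- factor(rep(c("a", "b", "c"), each = 20))
  s <- matrix(rnorm(180), 60, 3, dimnames = list(NULL, c("a", "b", "c"))) +
    2 * diag(3)[as.integer(y), ]
  per_class <- vapply(levels(y), function(cl) {
    roc_auc(s[, cl], factor(ifelse(y == cl, "p", "n"),
                            levels = c("n", "p")), positive = "p")
  }, numeric(1))
  expect_equal(macro_roc_auc(s, y), mean(per_class), tolerance = 1e-12)
})

test_that("t confidence intervals match hand-computed quantile arithmetic", {
  ci <- confidence_interval(c(0, 2))
  expect_equal(as.numeric(ci), c(1 - 12.706 * 1, 1 + 12.706 * 1),
               tolerance = 1e-3)
  const <- confidence_interval(rep(3.3, 5))
  expect_equal(as.numeric(const), c(3.3, 3.3))
  expect_error(confidence_interval(1), "2 values")
  # the published two-class accuracy column: mean 94.83, half-width
  # t(0.975, 15) * s / 4 with the sample SD
  x <- study_table("accuracy", "twoclass")[, "dfbcsp_mlp"]
  ci2 <- confidence_interval(x)
  expect_equal(as.numeric(ci2),
               mean(x) + c(-1, 1) * qt(0.975, 15) * sd(x) / 4,
               tolerance = 1e-12)
})

test_that("repeated-measures ANOVA matches brute-force sums of squares and aov", {
  set.seed(42)
  mat <- matrix(rnorm(12, mean = rep(c(0, 1, 3), each = 4)), 4, 3)
  got <- repeated_measures_anova(mat)
  # independent oracle: stats::aov with a subject error stratum
  df <- data.frame(y = as.vector(mat),
                   subj = factor(rep(1:4, 3)),
                   meth = factor(rep(1:3, each = 4)))
  fit <- summary(aov(y ~ meth + Error(subj), data = df))
  tab <- fit[["Error: Within"]][[1]]
  expect_equal(got$F, tab["meth", "F value"], tolerance = 1e-10)
  expect_equal(got$p, tab["meth", "Pr(>F)"], tolerance = 1e-10)
  # brute-force SS decomposition
  grand <- mean(mat)
  ss_m <- 4 * sum((colMeans(mat) - grand)^2)
  expect_equal(unname(got$ss["method"]), ss_m, tolerance = 1e-10)

  same <- matrix(rep(rnorm(4), 3), 4, 3)
  got0 <- repeated_measures_anova(same)
  expect_identical(got0$F, 0)

  expect_error(repeated_measures_anova(matrix(c(1, NA, 2, 3), 2, 2)),
               "missing")
})

test_that("the two-condition ANOVA equals the squared paired t", {
  set.seed(43)
  mat <- matrix(rnorm(20), 10, 2)
  f <- repeated_measures_anova(mat)$F
  t2 <- bonferroni_paired_t(mat)$t^2
  expect_equal(f, t2, tolerance = 1e-9)
})

test_that("Bonferroni paired t tests cover all pairs with capped p", {
  mat <- study_table("accuracy", "twoclass")
  out <- bonferroni_paired_t(mat)
  expect_identical(nrow(out), 15L)
  expect_true(all(out$df == 15))
  expect_true(all(out$p_bonferroni <= 1))
  expect_true(all(out$p_bonferroni >= out$p_raw))
  oracle <- t.test(mat[, 1], mat[, 2], paired = TRUE)
  expect_equal(out$t[1], unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(out$p_bonferroni[1], min(1, oracle$p.value * 15),
               tolerance = 1e-12)
  same <- cbind(mat[, 1], mat[, 1])
  expect_identical(bonferroni_paired_t(same)$t, 0)
  expect_identical(bonferroni_paired_t(same)$p_bonferroni, 1)
})

test_that("column summaries report both SD conventions", {
  mat <- cbind(a = c(1, 2, 3, 4), b = rep(2.5, 4))
  cs <- column_summary(mat)
  expect_equal(cs$mean, c(2.5, 2.5))
  expect_equal(cs$sd_sample[1], sd(1:4))
  expect_equal(cs$sd_population[1], sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))
  expect_equal(cs$sd_sample[2], 0)
  expect_identical(cs$n, c(4L, 4L))
})

test_that("ERD/ERS curves are null for rest and lateralized for imagery", {
  # fully unmodulated session: every trial is a rest trial
  null_sim <- cached_sim("erdnull", n = 150, seed = 17,
                         erd_depth = 0, ers_gain = 0)$sim
  null_es <- epoch_recording(null_sim$recording, 0, 8)
  tc <- erd_ers_timecourse(null_es, band_hz = c(8, 12),
                           baseline_window_s = c(0, 1), smooth_s = 1)
  expect_true(all(abs(tc$percent) < 15))
  # doubling amplitudes leaves the percent curve unchanged
  null2 <- null_es
  null2$data <- null2$data * 2
  tc2 <- erd_ers_timecourse(null2, band_hz = c(8, 12),
                            baseline_window_s = c(0, 1), smooth_s = 1)
  expect_equal(tc2$percent, tc$percent, tolerance = 1e-9)

  sim <- cached_sim("erd", n = 60, seed = 18)$sim
  es <- epoch_recording(sim$recording, 0, 8)
  left <- dfbcsp:::.subset_epochs(es, which(es$labels == "left"))
  tcl <- erd_ers_timecourse(left, band_hz = c(8, 12),
                            baseline_window_s = c(0, 1))
  win <- tcl$times >= 3.5 & tcl$times <= 5.5
  c3 <- which(tcl$channel_names == "C3")
  c4 <- which(tcl$channel_names == "C4")
  expect_lt(min(tcl$percent[c4, win]), -20)     # contralateral ERD
  expect_gt(max(tcl$percent[c3, win]), 20)      # ipsilateral ERS
})
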