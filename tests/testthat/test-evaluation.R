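# Statistics from first principles, checked against independent oracles,
# and the experiment drivers' structural contracts.

test_that("repeated-measures ANOVA matches brute-force sums of squares", {
  # textbook-style 3-condition data, 5 subjects
  g <- cbind(c(8, 6, 7, 9, 5), c(10, 9, 8, 12, 7), c(12, 11, 10, 14, 9))
  colnames(g) <- c("a", "b", "c")
  res <- rm_anova_bonferroni(g)

  # oracle: explicit cell-by-cell sums of squares
  n <- nrow(g); k <- ncol(g)
  grand <- mean(g)
  ss_cond <- n * sum((colMeans(g) - grand)^2)
  ss_subj <- k * sum((rowMeans(g) - grand)^2)
  ss_err <- 0
  for (i in 1:n) for (j in 1:k) {
    ss_err <- ss_err + (g[i, j] - rowMeans(g)[i] - colMeans(g)[j] + grand)^2
  }
  f_oracle <- unname((ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1))))
  expect_equal(res$F, f_oracle, tolerance = 1e-9)

  # cross-check against stats::aov as an independent implementation
  d <- data.frame(y = as.vector(g),
                  subj = factor(rep(1:n, k)),
                  cond = factor(rep(colnames(g), each = n)))
  av <- summary(stats::aov(y ~ cond + Error(subj), data = d))
  f_aov <- av[["Error: Within"]][[1]]["cond", "F value"]
  expect_equal(res$F, f_aov, tolerance = 1e-9)
  p_aov <- av[["Error: Within"]][[1]]["cond", "Pr(>F)"]
  expect_equal(res$p_value, p_aov, tolerance = 1e-9)

  # Bonferroni post-hoc equals paired t-tests times the number of pairs
  t_ab <- stats::t.test(g[, 1], g[, 2], paired = TRUE)$p.value
  expect_equal(res$pairwise["a vs b", "p_raw"], t_ab, tolerance = 1e-9)
  expect_equal(res$pairwise["a vs b", "p_adjusted"], min(1, 3 * t_ab),
               tolerance = 1e-9)
})

test_that("ANOVA degenerate and separated cases behave as expected", {
  same <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  res <- rm_anova_bonferroni(same)
  expect_equal(res$F, 0)
  expect_equal(res$p_value, 1)
  expect_true(all(res$pairwise$p_adjusted == 1))

  # constant offsets much larger than within-subject noise
  set.seed(5)
  base <- rnorm(6, sd = 0.01)
  sep <- cbind(base, base + 10, base + 20)
  res2 <- rm_anova_bonferroni(sep)
  expect_true(all(res2$pairwise$p_adjusted < 0.05))

  expect_error(rm_anova_bonferroni(cbind(1:2, 3:4)), "3 subjects")
  expect_error(rm_anova_bonferroni(cbind(c(1, NA, 3), 1:3, 1:3)),
               "unbalanced")
})

test_that("two-sample t-test matches stats::t.test and closed forms", {
  a <- c(1.1, 2.3, 0.8, 1.9, 1.4)
  b <- c(2.8, 3.1, 2.2, 3.6)
  res <- independent_t_test(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)

  resw <- independent_t_test(a, b, welch = TRUE)
  refw <- stats::t.test(a, b)
  expect_equal(resw$p_value, refw$p.value, tolerance = 1e-9)

  expect_equal(independent_t_test(a, a)$p_value, 1)
  near <- independent_t_test(c(0, 0, 0, 0), c(10, 10, 10, 10.0001))
  expect_lt(near$p_value, 1e-6)
  expect_equal(independent_t_test(a, b)$p_value,
               independent_t_test(b, a)$p_value, tolerance = 1e-12)
  expect_equal(independent_t_test(c(1, 1), c(1, 1))$p_value, 1)
  expect_error(independent_t_test(1, c(1, 2)), "size")
})

test_that("experiment configuration enforces its invariants", {
  expect_error(experiment_config(n_train_sequences = 0), "at least one")
  expect_error(experiment_config(motion_train_frac = 1), "motion_train_frac")
  expect_error(experiment_config(conditions = data.frame()), "conditions")
  cfg <- experiment_config()
  expect_equal(nrow(cfg$conditions), 10)
  expect_setequal(unique(cfg$conditions$color),
                  c("white", "pink", "brown", "blue", "purple"))
})

test_that("motion split respects the 60/40 design", {
  # 20 pairs -> 12 train, 8 test (checked on the report row)
  cfg <- experiment_config(
    n_motion_pairs = 20, seed = 2,
    tc = train_config(epochs = 1, batch_size = 128, seed = 2))
  tab <- run_motion_experiment(cfg)
  expect_equal(tab$n_train, 12)
  expect_equal(tab$n_test, 8)
  expect_equal(tab$n_seq, 8)
})

test_that("a reduced noise experiment emits one row per condition, reproducibly", {
  conds <- data.frame(color = c("white", "brown"), snr_db = c(-5, -15))
  cfg <- experiment_config(
    n_train_sequences = 2, n_test_sequences = 3, conditions = conds,
    seed = 3, tc = train_config(epochs = 1, batch_size = 128, seed = 3))
  tab <- run_noise_experiment(cfg)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$condition, c("white -5 dB", "brown -15 dB"))
  expect_true(all(c("sens_denoised", "snr_imp_mean", "rop_noisy_mean",
                    "p_rop_noisy_vs_clean") %in% names(tab)))
  expect_true(all(tab$sens_clean == 100))
  tab2 <- run_noise_experiment(cfg)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
})
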