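test_that("significance stars follow the reporting thresholds", {
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.0005), "***")
  expect_equal(significance_stars(0.2), "ns")
  expect_equal(significance_stars(c(0.04, 0.009, 0.00005)),
               c("*", "**", "****"))
  # monotone non-increasing in p
  p <- sort(runif(50))
  ranks <- match(significance_stars(p), c("****", "***", "**", "*", "ns"))
  expect_true(all(diff(ranks) >= 0))
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
})

test_that("the Shapiro-Wilk wrapper matches stats and catches bad input", {
  set.seed(21)
  x <- rnorm(50)
  res <- shapiro_wilk(x)
  ref <- shapiro.test(x)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  # heavily bimodal data are flagged as non-normal
  bim <- c(rep(0, 25), rep(10, 25)) + rnorm(50, 0, 0.01)
  expect_lt(shapiro_wilk(bim)$p, 0.01)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("normal samples rarely fail the normality screen", {
  set.seed(1234)
  w <- replicate(200, shapiro_wilk(rnorm(50))$statistic)
  expect_gte(mean(w > 0.95), 0.95)
})

test_that("paired t-test matches the textbook statistic", {
  set.seed(5)
  a <- rnorm(8); b <- a + 1 + rnorm(8, 0, 0.01)
  res <- paired_t(b, a)
  d <- b - a
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_lt(res$p, 0.001)
  # symmetric differences give t = 0, p = 1
  res0 <- paired_t(c(1, 2), c(2, 1))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero variance")
})

test_that("two-level within factors have epsilon exactly 1", {
  set.seed(10)
  tab <- random_rm_table(n_subj = 5, k_time = 2)
  res <- rm_anova_gg(tab, within = c("side", "time"))
  expect_equal(res$epsilon[res$effect == "side"], 1)
  expect_equal(res$epsilon[res$effect == "time"], 1)
  expect_equal(res$epsilon[res$effect == "side:time"], 1)
  # with eps = 1 the corrected p equals the uncorrected one
  expect_equal(res$p, res$p_uncorrected)
})

test_that("RM ANOVA with GG correction matches car::Anova", {
  skip_if_not_installed("car")
  set.seed(77)
  for (rep_i in 1:25) {
    n <- sample(5:8, 1); k <- sample(3:5, 1)
    tab <- random_rm_table(n_subj = n, k_time = k,
                           effect = runif(1, 0, 0.08))
    res <- rm_anova_gg(tab, within = c("side", "time"))

    wide <- matrix(NA_real_, n, 2 * k)
    cells <- expand.grid(time = sort(unique(tab$time)),
                         side = c("contralateral", "tumor"))
    cells <- cells[order(cells$side, cells$time), ]
    for (j in seq_len(nrow(cells))) {
      sel <- tab$side == cells$side[j] & tab$time == cells$time[j]
      wide[, j] <- tab$value[sel][order(tab$subject[sel])]
    }
    mlm <- lm(wide ~ 1)
    idata <- data.frame(side = factor(cells$side), time = factor(cells$time))
    av <- car::Anova(mlm, idata = idata, idesign = ~ side * time, type = 3)
    # car warns when the Huynh-Feldt epsilon exceeds 1; irrelevant here
    s <- suppressWarnings(summary(av, multivariate = FALSE))
    ut <- s$univariate.tests
    pa <- s$pval.adjustments

    for (eff in c("side", "time", "side:time")) {
      mine <- res[res$effect == eff, ]
      expect_equal(mine$statistic, ut[eff, "F value"], tolerance = 1e-6)
      expect_equal(mine$p_uncorrected, ut[eff, "Pr(>F)"], tolerance = 1e-6)
      if (eff %in% rownames(pa)) {
        expect_equal(mine$epsilon, pa[eff, "GG eps"], tolerance = 1e-6)
        expect_equal(mine$p, pa[eff, "Pr(>F[GG])"], tolerance = 1e-6)
      }
    }
  }
})

test_that("ANOVA rejects unbalanced or single-subject designs", {
  tab <- random_rm_table(n_subj = 4, k_time = 3)
  expect_error(rm_anova_gg(tab[-1, ]), "balanced")
  tab1 <- tab[tab$subject == 1, ]
  expect_error(rm_anova_gg(tab1), "2 subjects")
})

test_that("within-subject Tukey reduces to the paired t-test at 2 levels", {
  set.seed(31)
  tab <- random_rm_table(n_subj = 7, k_time = 2)
  tab <- tab[tab$side == "tumor", ]
  tk <- tukey_posthoc(tab, "time", error = "within")
  expect_equal(nrow(tk), 1L)
  a <- tab$value[tab$time == 1][order(tab$subject[tab$time == 1])]
  b <- tab$value[tab$time == 2][order(tab$subject[tab$time == 2])]
  pt <- paired_t(a, b)
  # q = sqrt(2) |t|, and the k = 2 studentized range equals the paired p
  expect_equal(tk$q, sqrt(2) * abs(pt$statistic), tolerance = 1e-10)
  expect_equal(tk$p, pt$p, tolerance = 1e-10)
})

test_that("between-subject Tukey matches TukeyHSD", {
  skip_if_not_installed("car")  # same suggests tier; base aov suffices
  set.seed(44)
  df <- data.frame(g = rep(c("a", "b", "c", "d"), each = 6),
                   value = rnorm(24) + rep(c(0, 0.5, 0.2, -0.1), each = 6))
  tk <- tukey_posthoc(df, "g", error = "between")
  ref <- TukeyHSD(aov(value ~ g, df))$g
  key <- paste(tk$level_2, tk$level_1, sep = "-")
  expect_equal(tk$diff, unname(ref[key, "diff"]), tolerance = 1e-10)
  expect_equal(tk$p, unname(ref[key, "p adj"]), tolerance = 1e-6)
  # identical level means give adjusted p near 1
  df2 <- data.frame(g = rep(c("a", "b"), each = 5),
                    value = rep(c(1, 2, 3, 4, 5), 2))
  tk2 <- tukey_posthoc(df2, "g", error = "between")
  expect_gt(tk2$p, 0.999)
  expect_error(tukey_posthoc(df[df$g == "a", ], "g"), "2 levels")
})
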