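# Repeated-measures statistics, cross-checked against independent
# implementations (base mauchly.test, car::Anova, aov) and brute-force
# definitions.

random_table <- function(seed, n = 10, k = 7, effect = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n * k), n, k)
  if (!is.null(effect)) m <- m + matrix(rep(effect, each = n), n, k)
  colnames(m) <- paste0("C", seq_len(k))
  m
}

compound_symmetric_table <- function(seed, n = 20, k = 4) {
  set.seed(seed)
  subj <- rnorm(n, 0, 2)
  matrix(subj, n, k) + matrix(rnorm(n * k), n, k)
}

test_that("pooling builds a complete subjects x categories table", {
  asg <- small_subject()$assignments
  tab <- pool_categories(list(S1 = asg, S2 = asg), "median")
  expect_equal(dim(tab), c(2L, 7L))
  expect_equal(colnames(tab), c("Arteriole", "Arteriole-net", "Venule",
                                "Venule-net", "FAZ-net", "FAZ-cp", "Quadrant"))
  expect_false(any(is.na(tab)))
  # pooled cell equals the hand-pooled median for that category
  v <- asg$mean_cov[!is.na(asg[["Quadrant"]])]
  expect_equal(unname(tab[1, "Quadrant"]), median(v))
  iq <- pool_categories(list(S1 = asg, S2 = asg), "IQR")
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(unname(iq[1, "Quadrant"]), q[2] - q[1])

  bad <- asg; bad[["FAZ-cp"]] <- NA_character_
  expect_error(pool_categories(list(S1 = asg, S9 = bad)), "S9")
})

test_that("Shapiro-Wilk wrapper flags degenerate samples and detects bimodality", {
  tab <- random_table(1)
  s <- shapiro_by_category(tab)
  expect_equal(nrow(s), 7L)
  expect_true(all(s$p > 0 & s$p <= 1))

  const <- cbind(tab, K = 5)
  s2 <- shapiro_by_category(const)
  expect_true(s2$degenerate[s2$category == "K"])

  bim <- matrix(c(rep(-10, 5), rep(10, 5)) + rnorm(10, 0, 0.1), ncol = 1)
  expect_lt(shapiro_by_category(cbind(bim, bim))$p[1], 0.05)
  expect_error(shapiro_by_category(tab[1:2, ]), "3 <= n")
})

test_that("normal samples rarely fail the normality check", {
  set.seed(42)
  p <- replicate(100, shapiro.test(rnorm(10))$p.value)
  expect_gte(mean(p > 0.05), 0.9)
})

test_that("Mauchly's W matches the base-R implementation", {
  for (seed in 1:5) {
    tab <- random_table(seed, n = 10, k = sample(3:7, 1))
    mod <- lm(tab ~ 1)
    ref <- mauchly.test(mod, X = ~1)
    got <- mauchly_test(tab)
    expect_equal(got$W, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$p, ref$p.value, tolerance = 1e-6)
  }
  expect_equal(mauchly_test(random_table(1, k = 2))$W, 1)
  expect_error(mauchly_test(random_table(1, n = 5, k = 7)), "n >= k")
})

test_that("compound-symmetric data is spherical: W ~ 1, eps = 1", {
  tab <- compound_symmetric_table(7)
  m <- mauchly_test(tab)
  expect_gt(m$p, 0.05)
  expect_gt(m$W, 0.5)
  expect_equal(huynh_feldt_epsilon(tab), 1)
  a <- rm_anova(tab)
  expect_false(a$sphericity_corrected)
  expect_equal(a$df_effect_corr, a$df_effect)     # corrected == uncorrected
  expect_equal(a$p_corrected, a$p_uncorrected)
})

test_that("epsilon estimates match car and obey the ordering property", {
  for (seed in 1:3) {
    tab <- random_table(seed)
    mod <- lm(tab ~ 1)
    idata <- data.frame(cond = factor(seq_len(ncol(tab))))
    s <- suppressWarnings(summary(car::Anova(mod, idata = idata, idesign = ~cond, type = 3),
                                  multivariate = FALSE))
    e <- epsilons(tab)
    expect_equal(e$gg, unname(s$pval.adjustments[1, "GG eps"]), tolerance = 1e-8)
    expect_equal(e$hf, unname(s$pval.adjustments[1, "HF eps"]), tolerance = 1e-8)
  }
  for (seed in 1:200) {
    n <- sample(8:15, 1); k <- sample(3:7, 1)
    tab <- random_table(seed + 1000, n = n, k = k)
    e <- epsilons(tab)
    expect_gte(e$gg, e$lower_bound - 1e-12)
    expect_lte(e$gg, e$hf_capped + 1e-12)
    expect_lte(e$hf_capped, 1)
  }
})

test_that("RM ANOVA F and SS match aov and brute-force definitions", {
  tab <- random_table(3, n = 6, k = 4)
  long <- data.frame(y = as.vector(tab),
                     subj = factor(rep(seq_len(6), 4)),
                     cond = factor(rep(seq_len(4), each = 6)))
  fit <- summary(aov(y ~ cond + Error(subj / cond), data = long))
  ref_f <- fit[["Error: subj:cond"]][[1]]["cond", "F value"]
  a <- rm_anova(tab)
  expect_equal(a$F, ref_f, tolerance = 1e-10)

  # brute-force SS from definitions
  gm <- mean(tab)
  ss_eff <- 6 * sum((colMeans(tab) - gm)^2)
  ss_subj <- 4 * sum((rowMeans(tab) - gm)^2)
  ss_tot <- sum((tab - gm)^2)
  expect_equal(unname(a$ss["effect"]), ss_eff)
  expect_equal(unname(a$ss["subjects"]), ss_subj)
  expect_equal(unname(a$ss["total"]), ss_tot)
  expect_equal(unname(a$ss["effect"] + a$ss["subjects"] + a$ss["error"]),
               unname(a$ss["total"]), tolerance = 1e-10)
  expect_equal(a$ges, ss_eff / ss_tot)
})

test_that("RM ANOVA null case and degenerate inputs", {
  tab <- matrix(rep(c(1, 3, 2, 5, 4), 4), 5, 4)   # identical columns
  a <- rm_anova(tab)
  expect_equal(a$F, 0)
  expect_equal(a$ges, 0)
  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(rm_anova(matrix(1:3, 3, 1)), "k >= 2")
})

test_that("F, epsilon, ges and post-hoc p are translation invariant", {
  tab <- random_table(11)
  a1 <- rm_anova(tab); a2 <- rm_anova(tab + 100)
  expect_equal(a1$F, a2$F, tolerance = 1e-8)
  expect_equal(a1$epsilon_hf, a2$epsilon_hf, tolerance = 1e-8)
  expect_equal(a1$ges, a2$ges, tolerance = 1e-8)
  p1 <- posthoc_pairwise(tab); p2 <- posthoc_pairwise(tab + 100)
  expect_equal(p1$p_adj, p2$p_adj, tolerance = 1e-8)
})

test_that("post-hoc battery follows the Bonferroni rules", {
  tab <- random_table(5)
  ph <- posthoc_pairwise(tab)
  expect_equal(nrow(ph), 21L)
  expect_equal(attr(ph, "m"), 21)
  expect_equal(attr(ph, "conf_level"), 1 - 0.05 / 21)
  expect_equal(ph$p_adj, pmin(1, 21 * ph$p))
  # cross-check one pair against t.test directly
  d <- tab[, 1] - tab[, 2]
  tt <- t.test(d, conf.level = 1 - 0.05 / 21)
  expect_equal(ph$p[1], tt$p.value)
  expect_equal(ph$ci_lo[1], tt$conf.int[1])

  # identical columns: difference 0, p_adj 1 after correction is impossible,
  # the pair is degenerate (zero variance) and flagged
  tab2 <- cbind(tab, dup = tab[, 1])
  ph2 <- posthoc_pairwise(tab2)
  row <- ph2[ph2$cat1 == "C1" & ph2$cat2 == "dup", ]
  expect_true(row$degenerate)
  expect_equal(row$estimate, 0)

  # near-identical columns: CI contains 0 and p_adj = 1
  tab3 <- tab; tab3[, 2] <- tab3[, 1] + rnorm(10, 0, 1e-3)
  ph3 <- posthoc_pairwise(tab3[, 1:2])
  expect_gte(ph3$p_adj[1], 0.05)
  expect_true(ph3$ci_lo[1] < 0 && ph3$ci_hi[1] > 0)
})

test_that("pairwise matrix reproduces the lower-triangular table layout", {
  tab <- random_table(8, k = 4)
  ph <- posthoc_pairwise(tab)
  m <- pairwise_matrix(ph)
  expect_equal(dim(m), c(3L, 3L))
  expect_true(is.na(m[1, 2]))
  expect_equal(m["C2", "C1"], round(ph$p_adj[ph$cat1 == "C1" & ph$cat2 == "C2"], 2))
})

test_that("category tables round-trip through CSV", {
  tab <- random_table(2)
  colnames(tab) <- c("Arteriole", "Arteriole-net", "Venule", "Venule-net",
                     "FAZ-net", "FAZ-cp", "Quadrant")
  rownames(tab) <- paste0("S", 1:10)
  class(tab) <- c("subject_category_table", "matrix", "array")
  attr(tab, "measure") <- "median"
  td <- withr::local_tempdir()
  p <- file.path(td, "tab.csv")
  write_category_table(tab, p)
  back <- read_category_table(p)
  expect_equal(unclass(back)[, ], unclass(tab)[, ], tolerance = 1e-12)
})
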