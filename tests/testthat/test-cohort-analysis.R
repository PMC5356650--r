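test_that("two-group comparison reproduces the exact rank-sum oracle", {
  # all C(6,3) = 20 rank assignments enumerate to p = 2/20 = 0.1
  r <- compare_groups(c(1, 2, 3, 4, 5, 6),
                      rep(c("a", "b"), each = 3))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "wilcoxon")

  ident <- suppressWarnings(
    compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3)))
  expect_equal(ident$p_value, 1, tolerance = 1e-6)

  expect_error(compare_groups(1:3, c("a", "a", "b")), "fewer than 2")
  expect_error(compare_groups(1:4, rep("a", 4)), "two groups")
})

test_that("three or more groups dispatch to ANOVA, monotone in the shift", {
  set.seed(61)
  base <- stats::rnorm(30, sd = 0.2)
  labels <- rep(c("a", "b", "c"), each = 10)
  ps <- sapply(c(0.2, 0.6, 1.2), function(shift) {
    y <- base + (labels == "c") * shift
    r <- compare_groups(y, labels)
    expect_equal(r$method, "anova")
    r$p_value
  })
  expect_true(all(diff(ps) < 0))
})

test_that("phospho/total ratio is a log difference, location invariant", {
  tab <- matrix(c(1.2, 0.7, 0.9, 0.7), nrow = 2,
                dimnames = list(c("s1", "s2"), c("pAkt", "Akt")))
  r <- phospho_total_ratio(tab, "pAkt", "Akt")
  expect_equal(unname(r), c(0.3, 0))
  shifted <- phospho_total_ratio(tab + 5, "pAkt", "Akt")
  expect_equal(r, shifted)
  raw <- phospho_total_ratio(10^tab, "pAkt", "Akt", log_input = FALSE)
  expect_equal(r, raw)
  expect_error(phospho_total_ratio(tab, "pS6", "Akt"), "pS6")
})

test_that("stratification at zero excludes exact zeros and is antisymmetric", {
  expect_message(g <- stratify_at_zero(c(0.5, -0.3, 0)), "1 sample")
  expect_equal(as.character(g), c("high", "low", NA))
  expect_error(suppressMessages(stratify_at_zero(c(1, 2, 0))), "empty")
  x <- c(0.5, -0.3, 1.2, -2)
  flipped <- stratify_at_zero(-x)
  expect_equal(as.character(flipped) == "high",
               as.character(stratify_at_zero(x)) == "low")
})

test_that("median split sends ties to the low group", {
  expect_message(g <- split_at_median(c(1, 2, 2, 3, 5)), "tie")
  expect_equal(as.character(g), c("low", "low", "low", "high", "high"))
})

test_that("KM/log-rank detects no difference between identical groups", {
  clin <- data.frame(time = rep(c(1, 2, 3, 4), 2),
                     event = rep(c(1, 1, 0, 1), 2))
  groups <- rep(c("a", "b"), each = 4)
  r <- km_logrank(clin, groups)
  expect_equal(r$chisq, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-9)
  # estimator properties: starts at/below 1, nonincreasing within group
  for (gr in unique(r$curves$group)) {
    s <- r$curves$surv[r$curves$group == gr]
    expect_true(all(s <= 1) && all(diff(s) <= 1e-12))
  }
  expect_error(km_logrank(data.frame(time = 1:4, event = 0),
                          rep(c("a", "b"), 2)), "no events")
})

test_that("Cox coefficient rescales as 1/c and converges on clean data", {
  set.seed(71)
  x <- stats::rnorm(120)
  clin <- data.frame(time = stats::rexp(120, 0.2 * exp(0.7 * x)),
                     event = 1L)
  f1 <- cox_univariate(clin, x)
  expect_true(f1$converged)
  expect_gt(f1$coef, 0)
  f10 <- cox_univariate(clin, 10 * x)
  expect_equal(f10$coef, f1$coef / 10, tolerance = 1e-8)
  expect_error(cox_univariate(data.frame(time = 1:3, event = c(1, 0, 0)),
                              1:3), "2 events")
})

test_that("batched Cox adjusts Wald p-values across score columns", {
  set.seed(72)
  x <- stats::rnorm(100)
  clin <- data.frame(time = stats::rexp(100, 0.2 * exp(0.8 * x)), event = 1L)
  scores <- data.frame(signal = x, noise1 = stats::rnorm(100),
                       noise2 = stats::rnorm(100))
  tab <- cox_batch(clin, scores)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$adjusted_p >= tab$p_value - 1e-15))
  expect_lt(tab$adjusted_p[tab$score_id == "signal"], 0.05)
})

test_that("correlation handles both methods and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$estimate, 1)
  expect_equal(correlate(x, exp(-x), "spearman")$estimate, -1)
  expect_error(correlate(x, rep(1, 5)), "zero variance")
  expect_error(correlate(1:2, 1:2), "3 complete")
  # pairwise completeness
  r <- correlate(c(x, NA), c(2 * x, 3), "pearson")
  expect_equal(r$n, 5)
})

test_that("the drug screen selects a monotone drug and tracks bookkeeping", {
  set.seed(81)
  drs <- stats::setNames(stats::rnorm(40), paste0("c", 1:40))
  ic50 <- matrix(stats::rnorm(40 * 6), 40,
                 dimnames = list(names(drs), paste0("null", 1:6)))
  ic50 <- cbind(ic50, mono = exp(drs))       # monotone increasing in DRS
  ic50[1:38, "null1"] <- NA                   # too few pairs -> skipped
  scr <- drug_screen(drs, ic50)
  expect_equal(scr$skipped, "null1")
  mono_row <- scr$results[scr$results$drug_id == "mono", ]
  expect_equal(mono_row$correlation, 1)
  expect_true("mono" %in% scr$positive)
  expect_true(all(scr$results$adjusted_p >= scr$results$p_value - 1e-15))

  sub <- drug_screen(drs, ic50[, "mono", drop = FALSE],
                     subset = paste0("c", 1:10))
  expect_equal(sub$results$n, 10)
  expect_error(drug_screen(drs, ic50[0, , drop = FALSE]), "empty|rownames")
})

test_that("in-package rank AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(91)
  score <- stats::rnorm(80)
  pos <- stats::runif(80) < stats::plogis(score)
  if (length(unique(pos)) < 2) pos[1:2] <- c(TRUE, FALSE)
  a1 <- auc_rank(score, pos)
  a2 <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = score,
                                       quiet = TRUE, direction = "<")))
  expect_equal(a1, a2, tolerance = 1e-12)
  rocp <- roc_points(score, pos)
  expect_equal(rocp$fpr[1], 0)
  expect_equal(rocp$tpr[nrow(rocp)], 1)
  expect_true(all(diff(rocp$fpr) >= 0) && all(diff(rocp$tpr) >= 0))
})

test_that("cross-validated classification separates what is separable", {
  set.seed(92)
  x <- stats::rnorm(80)
  lab <- factor(ifelse(x > stats::median(x), "high", "low"),
                levels = c("low", "high"))
  r <- classify_rcb(x, lab, n_folds = 5, seed = 4, ntree = 100)
  expect_gt(r$auc, 0.95)
  # deterministic under the seed
  r2 <- classify_rcb(x, lab, n_folds = 5, seed = 4, ntree = 100)
  expect_identical(r$auc, r2$auc)
  expect_error(classify_rcb(x, rep("high", 80)), "two levels")
  expect_error(classify_rcb(x, factor(c(rep("high", 78), "low", "low"))),
               "n_folds")
})
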