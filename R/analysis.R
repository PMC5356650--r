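#' Compare a score between clinical groups
#'
#' Two groups are compared with the two-sided Wilcoxon rank-sum test (exact
#' for small tie-free samples, normal approximation with continuity
#' correction otherwise); three or more groups dispatch to a one-way ANOVA
#' F-test. Group medians and sizes are reported alongside the test.
#'
#' @param scores numeric per-sample values.
#' @param labels factor (or coercible) of group labels, aligned to `scores`.
#' @return List: `statistic`, `p_value`, `method`, `medians`, `n`.
#' @export
compare_groups <- function(scores, labels) {
  labels <- factor(labels)
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- droplevels(labels[keep])
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two groups")
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("group(s) with fewer than 2 samples: ",
         paste(small, collapse = ","))
  medians <- tapply(scores, labels, stats::median)
  if (length(tab) == 2) {
    ht <- suppressWarnings(
      stats::wilcox.test(scores ~ labels, correct = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "wilcoxon", medians = medians, n = as.vector(tab))
  } else {
    fit <- stats::aov(scores ~ labels)
    sm <- summary(fit)[[1]]
    list(statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
         method = "anova", medians = medians, n = as.vector(tab))
  }
}

#' Phospho-to-total protein ratio on the log scale
#'
#' Protein-array tables arrive log10-transformed, so the phospho/total ratio
#' is the difference of the log10 columns (the log10 of the raw ratio). Set
#' `log_input = FALSE` for raw-scale tables, in which case the log10 ratio
#' of the raw values is returned.
#'
#' @param protein_table `data.frame` or matrix, samples in rows, antibodies
#'   in columns.
#' @param phospho,total column names of the phospho- and total-protein
#'   antibodies.
#' @param log_input whether the table is already log10 (default `TRUE`).
#' @return Named numeric vector, one log10 ratio per sample.
#' @export
phospho_total_ratio <- function(protein_table, phospho, total,
                                log_input = TRUE) {
  missing_cols <- setdiff(c(phospho, total), colnames(protein_table))
  if (length(missing_cols))
    stop("antibody column(s) not found: ", paste(missing_cols, collapse = ","))
  p <- protein_table[, phospho]
  t <- protein_table[, total]
  out <- if (log_input) p - t else log10(p / t)
  stats::setNames(as.numeric(out), rownames(protein_table))
}

#' Stratify samples at a DRS of zero
#'
#' Samples with a positive score form the `"high"` group and negative scores
#' the `"low"` group; scores exactly zero belong to neither and are excluded
#' (returned as `NA`) with a message.
#'
#' @param drs numeric per-sample scores.
#' @return Factor with levels `"low"`, `"high"`, `NA` for excluded samples.
#' @export
stratify_at_zero <- function(drs) {
  g <- ifelse(drs > 0, "high", ifelse(drs < 0, "low", NA))
  n_zero <- sum(drs == 0, na.rm = TRUE)
  if (n_zero)
    message(sprintf("stratify_at_zero: %d sample(s) at exactly 0 excluded",
                    n_zero))
  if (!any(g == "high", na.rm = TRUE) || !any(g == "low", na.rm = TRUE))
    stop("stratification leaves an empty group")
  factor(g, levels = c("low", "high"))
}

#' Split samples at the median of a covariate
#'
#' Used for confounder stratification (e.g. high vs low expression of a
#' modifier gene). Values strictly above the median go to `"high"`; ties at
#' the median go to `"low"` and their count is reported.
#'
#' @param x numeric per-sample values.
#' @return Factor with levels `"low"`, `"high"`.
#' @export
split_at_median <- function(x) {
  m <- stats::median(x, na.rm = TRUE)
  n_tie <- sum(x == m, na.rm = TRUE)
  if (n_tie)
    message(sprintf("split_at_median: %d tie(s) at the median assigned low",
                    n_tie))
  factor(ifelse(x > m, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier curves and log-rank test for a two-group split
#'
#' Fits per-group Kaplan-Meier estimators and tests the survival difference
#' with the two-sided log-rank test.
#'
#' @param clinical `data.frame` with columns `time` and `event` (0/1).
#' @param groups factor aligned to `clinical` rows; `NA` rows are dropped.
#' @return List: `fit` (the `survfit` object), `curves` (`data.frame` of
#'   `group`, `time`, `surv`, `n_risk`), `chisq`, `p_value`, `n`.
#' @export
km_logrank <- function(clinical, groups) {
  stopifnot(all(c("time", "event") %in% names(clinical)))
  groups <- factor(groups)
  keep <- !is.na(groups) & !is.na(clinical$time) & !is.na(clinical$event)
  dat <- data.frame(time = clinical$time[keep],
                    event = clinical$event[keep],
                    group = droplevels(groups[keep]))
  if (nlevels(dat$group) != 2) stop("need exactly two non-empty groups")
  if (sum(dat$event) == 0) stop("no events in either group")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk)
  list(fit = fit, curves = curves, chisq = unname(sd_$chisq), p_value = p,
       n = table(dat$group))
}

#' Univariate Cox proportional-hazards fit on a continuous score
#'
#' Fits `Surv(time, event) ~ score` and reports the log-hazard coefficient,
#' its standard error, the hazard ratio and the Wald p-value.
#' Non-convergence is flagged in the result rather than raised.
#'
#' @param clinical `data.frame` with `time` and `event`.
#' @param score numeric per-sample values aligned to `clinical` rows.
#' @return List: `coef`, `se`, `hr`, `p_value`, `n`, `n_events`,
#'   `converged`.
#' @export
cox_univariate <- function(clinical, score) {
  stopifnot(all(c("time", "event") %in% names(clinical)))
  keep <- !is.na(score) & !is.na(clinical$time) & !is.na(clinical$event)
  dat <- data.frame(time = clinical$time[keep], event = clinical$event[keep],
                    score = score[keep])
  if (sum(dat$event) < 2) stop("need at least 2 events")
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ score, data = dat),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  list(coef = unname(stats::coef(fit)["score"]),
       se = unname(sm$coefficients[, "se(coef)"]),
       hr = unname(exp(stats::coef(fit)["score"])),
       p_value = unname(sm$coefficients[, "Pr(>|z|)"]),
       n = nrow(dat), n_events = sum(dat$event), converged = converged)
}

#' Batched univariate Cox fits with Benjamini-Hochberg adjustment
#'
#' Runs [cox_univariate()] on each column of a score table (e.g. one DRS per
#' drug signature) and adjusts the Wald p-values across fits with the
#' Benjamini-Hochberg procedure.
#'
#' @param clinical `data.frame` with `time` and `event`.
#' @param scores numeric matrix or `data.frame`, samples x score columns.
#' @return `data.frame`: `score_id`, `coef`, `se`, `hr`, `p_value`,
#'   `adjusted_p`, `n`, `n_events`, `converged`.
#' @export
cox_batch <- function(clinical, scores) {
  scores <- as.data.frame(scores)
  rows <- lapply(names(scores), function(nm) {
    r <- cox_univariate(clinical, scores[[nm]])
    data.frame(score_id = nm, coef = r$coef, se = r$se, hr = r$hr,
               p_value = r$p_value, n = r$n, n_events = r$n_events,
               converged = r$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("score_id", "coef", "se", "hr", "p_value", "adjusted_p", "n",
          "n_events", "converged")]
}

#' Correlate two per-sample vectors
#'
#' Pearson or Spearman correlation on pairwise-complete observations with a
#' two-sided p-value.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `estimate`, `p_value`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ht$estimate), p_value = ht$p.value,
       n = length(x), method = method)
}

#' Drug-sensitivity correlation screen with FDR control
#'
#' Correlates a per-cell-line DRS with the IC50 of every drug in a response
#' table, adjusts p-values across drugs with Benjamini-Hochberg, and splits
#' the drugs selected at `adjusted_p < alpha` into positively and negatively
#' correlated lists. Drugs with fewer than `min_pairs` complete pairs are
#' reported as skipped, not tested.
#'
#' @param drs named numeric vector of scores (names are cell-line ids).
#' @param ic50 numeric matrix or `data.frame`, cell lines x drugs, rownames
#'   matching `names(drs)`.
#' @param method correlation method, default `"spearman"`.
#' @param subset optional character vector of cell lines to restrict to
#'   (e.g. one tissue).
#' @param alpha FDR level for selection (default 0.05).
#' @param min_pairs minimum complete pairs per drug (default 3).
#' @return List: `results` (`data.frame` of `drug_id`, `correlation`,
#'   `p_value`, `adjusted_p`, `n`, `method`), `positive`, `negative`
#'   (selected drug ids by correlation sign), `skipped`.
#' @export
drug_screen <- function(drs, ic50, method = c("spearman", "pearson"),
                        subset = NULL, alpha = 0.05, min_pairs = 3) {
  method <- match.arg(method)
  ic50 <- as.matrix(ic50)
  if (!nrow(ic50) || !ncol(ic50)) stop("empty IC50 table")
  if (is.null(names(drs)) || is.null(rownames(ic50)))
    stop("drs must be named and ic50 must have rownames (cell lines)")
  lines <- intersect(names(drs), rownames(ic50))
  if (!is.null(subset)) lines <- intersect(lines, subset)
  if (length(lines) < min_pairs)
    stop(sprintf("only %d cell line(s) in common", length(lines)))
  x <- drs[lines]
  rows <- list()
  skipped <- character()
  for (drug in colnames(ic50)) {
    y <- ic50[lines, drug]
    n_ok <- sum(is.finite(x) & is.finite(y))
    if (n_ok < min_pairs || stats::sd(y[is.finite(x) & is.finite(y)]) == 0) {
      skipped <- c(skipped, drug)
      next
    }
    r <- correlate(x, y, method = method)
    rows[[drug]] <- data.frame(drug_id = drug, correlation = r$estimate,
                               p_value = r$p_value, n = r$n,
                               method = method, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no drug had enough complete pairs")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[, c("drug_id", "correlation", "p_value", "adjusted_p", "n",
                 "method")]
  sel <- res[res$adjusted_p < alpha, ]
  list(results = res,
       positive = sel$drug_id[sel$correlation > 0],
       negative = sel$drug_id[sel$correlation < 0],
       skipped = skipped)
}

#' Cross-validated random-forest classification of a binary burden label
#'
#' Trains a random forest on one or more per-sample features with stratified
#' k-fold cross-validation and pools the out-of-fold class probabilities
#' into a single ROC curve and AUC. The common use is a single DRS feature
#' against a residual-cancer-burden style low/high label.
#'
#' @param features numeric vector, matrix or `data.frame` of per-sample
#'   features.
#' @param labels two-level factor (or coercible); the second level is
#'   treated as the positive class.
#' @param n_folds cross-validation folds (default 10).
#' @param seed integer seed controlling fold assignment and forest fitting.
#' @param ... passed to [randomForest::randomForest()].
#' @return List: `auc`, `roc` (`data.frame` of `fpr`, `tpr`), `predictions`
#'   (`data.frame` of `label`, `prob`, `fold`), `positive_class`, `seed`.
#' @export
classify_rcb <- function(features, labels, n_folds = 10, seed = 1, ...) {
  feat <- as.data.frame(features)
  if (is.null(names(feat)) || any(names(feat) == ""))
    names(feat) <- paste0("f", seq_along(feat))
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("labels must have exactly two levels, got: ",
         paste(levels(labels), collapse = ","))
  if (any(table(labels) < n_folds))
    stop("each class needs at least n_folds samples for stratified folds")
  n <- nrow(feat)
  if (length(labels) != n) stop("features and labels lengths differ")
  pos <- levels(labels)[2]
  folds <- integer(n)
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    prob <- numeric(n)
    for (k in seq_len(n_folds)) {
      test <- folds == k
      fit <- randomForest::randomForest(feat[!test, , drop = FALSE],
                                        labels[!test], ...)
      prob[test] <- stats::predict(fit, feat[test, , drop = FALSE],
                                   type = "prob")[, pos]
    }
  })
  roc <- roc_points(prob, labels == pos)
  list(auc = auc_rank(prob, labels == pos), roc = roc,
       predictions = data.frame(label = labels, prob = prob, fold = folds),
       positive_class = pos, seed = seed)
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' @param score numeric predicted scores.
#' @param positive logical vector marking positive-class samples.
#' @return AUC in [0, 1]; ties in `score` contribute 1/2.
#' @export
auc_rank <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("need both classes for AUC")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points from scores and class labels
#'
#' @inheritParams auc_rank
#' @return `data.frame` of `fpr`, `tpr`, ordered from (0,0) to (1,1).
#' @export
roc_points <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(positive[ord])
  fp <- cumsum(!positive[ord])
  keep <- !duplicated(score[ord], fromLast = TRUE)
  data.frame(fpr = c(0, fp[keep] / sum(!positive)),
             tpr = c(0, tp[keep] / sum(positive)))
}
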