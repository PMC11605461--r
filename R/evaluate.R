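#' Confusion counts at a decision threshold
#'
#' The decision rule is `score >= threshold` predicts positive.
#'
#' @param scores probabilities in `[0,1]`.
#' @param labels 0/1 labels.
#' @param threshold decision threshold.
#' @return named integer vector `c(TP, FP, TN, FN)`; the four counts
#'   partition the sample.
#' @export
confusionAtThreshold <- function(scores, labels, threshold) {
  if (!length(scores)) stop("empty input")
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0, 1)))
  pred <- scores >= threshold
  c(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
    TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1))
}

#' Ratio metrics from confusion counts
#'
#' `ppv = TP/(TP+FP)` (precision), `sensitivity = TP/(TP+FN)` (recall),
#' `specificity = TN/(TN+FP)`, `npv = TN/(TN+FN)`, and `f1Score` the
#' harmonic mean of PPV and sensitivity. A zero denominator yields `NA`
#' (undefined, not 0).
#'
#' @param TP,FP,TN,FN counts.
#' @return proportion in `[0,1]` or `NA`.
#' @export
ppv <- function(TP, FP) if ((TP + FP) == 0) NA_real_ else TP / (TP + FP)

#' @rdname ppv
#' @export
sensitivity <- function(TP, FN) if ((TP + FN) == 0) NA_real_ else TP / (TP + FN)

#' @rdname ppv
#' @export
specificity <- function(TN, FP) if ((TN + FP) == 0) NA_real_ else TN / (TN + FP)

#' @rdname ppv
#' @export
npv <- function(TN, FN) if ((TN + FN) == 0) NA_real_ else TN / (TN + FN)

#' @rdname ppv
#' @param precision,recall proportions.
#' @export
f1Score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || (precision + recall) == 0)
    return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability a random positive
#' scores above a random negative, ties counted 1/2. Equivalent to
#' O(n^2) pair counting but computed in O(n log n) via midranks, and
#' invariant under strictly increasing transforms of the scores.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in `[0,1]`.
#' @export
aurocScore <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUROC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for a score metric
#'
#' Nonparametric patient-level resampling. A resample in which the metric
#' is undefined (e.g. single-class for AUROC) is redrawn, and the number
#' of redraws reported.
#'
#' @param scores,labels the evaluated predictions.
#' @param metric function `(scores, labels) -> scalar`, e.g.
#'   [aurocScore()].
#' @param n_boot resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; identical seed gives an identical interval.
#' @return list with `lower`, `upper`, `point`, `n_boot`, `redraws`.
#' @export
bootstrapCi <- function(scores, labels, metric = aurocScore,
                        n_boot = 1000L, level = 0.95, seed = 1L) {
  n <- length(scores)
  if (n < 20L) stop("need at least 20 observations")
  set.seed(seed)
  vals <- numeric(n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(metric(scores[i], labels[i]), error = function(e) NA_real_)
      if (!is.na(v)) break
      redraws <- redraws + 1L
      if (redraws > 100L * n_boot) stop("metric undefined in most resamples")
    }
    vals[b] <- v
  }
  a <- (1 - level) / 2
  q <- stats::quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
  list(lower = q[1L], upper = q[2L], point = metric(scores, labels),
       n_boot = n_boot, redraws = redraws)
}

#' DeLong comparison of two correlated AUROCs
#'
#' Fast structural-component estimator of the variance of the difference
#' between the AUROCs of two models scored on the same patients, with a
#' two-sided normal test.
#'
#' @param scores_a,scores_b paired scores on identical patients.
#' @param labels shared 0/1 labels.
#' @return list with `auc_a`, `auc_b`, `difference`, `variance`, `z`,
#'   `p_value`.
#' @export
delongTest <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L) stop("DeLong needs both classes")
  comp <- function(s) {
    # placement values: V10[i] = P(s_pos_i > s_neg) with ties 1/2
    sp <- s[pos]; sn <- s[neg]
    r <- rank(c(sp, sn), ties.method = "average")
    rp <- r[seq_len(m)]; rn <- r[m + seq_len(n)]
    auc <- (sum(rp) - m * (m + 1) / 2) / (m * n)
    v10 <- (rp - rank(sp, ties.method = "average")) / n
    v01 <- 1 - (rn - rank(sn, ties.method = "average")) / m
    list(auc = auc, v10 = v10, v01 = v01)
  }
  A <- comp(scores_a); B <- comp(scores_b)
  s10 <- stats::cov(cbind(A$v10, B$v10))
  s01 <- stats::cov(cbind(A$v01, B$v01))
  S <- s10 / m + s01 / n
  d <- A$auc - B$auc
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (v <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = A$auc, auc_b = B$auc, difference = d, variance = v,
       z = z, p_value = p)
}

#' Operating-point sweep
#'
#' One row per threshold mirroring the study's threshold table: number
#' predicted positive, number correctly predicted, total positives,
#' sensitivity and PPV. The default grid is 0.40 to 0.70 in steps of
#' 0.05; the 0.4 operating point corresponds to the NICE fast-track
#' convention of accepting a PPV of at least 3%.
#'
#' @param scores,labels the evaluated predictions.
#' @param thresholds sorted thresholds.
#' @return `data.frame` of threshold rows.
#' @export
thresholdSweep <- function(scores, labels,
                           thresholds = seq(0.40, 0.70, by = 0.05)) {
  rows <- lapply(thresholds, function(t) {
    cm <- confusionAtThreshold(scores, labels, t)
    data.frame(threshold = t,
               n_predicted_positive = cm[["TP"]] + cm[["FP"]],
               n_true_positive = cm[["TP"]],
               n_positives = cm[["TP"]] + cm[["FN"]],
               sensitivity = sensitivity(cm[["TP"]], cm[["FN"]]),
               ppv = ppv(cm[["TP"]], cm[["FP"]]))
  })
  do.call(rbind, rows)
}

#' Full metrics report at an operating point
#'
#' @param scores,labels the evaluated predictions.
#' @param threshold operating point (default 0.4).
#' @param n_boot bootstrap resamples for the CIs (0 disables).
#' @param seed bootstrap seed.
#' @return list with per-class precision/recall/F1, specificity, NPV,
#'   AUROC, 95% CIs where requested, and the threshold used.
#' @export
metricsReport <- function(scores, labels, threshold = 0.4,
                          n_boot = 1000L, seed = 1L) {
  cm <- confusionAtThreshold(scores, labels, threshold)
  prec1 <- ppv(cm[["TP"]], cm[["FP"]])
  rec1 <- sensitivity(cm[["TP"]], cm[["FN"]])
  prec0 <- npv(cm[["TN"]], cm[["FN"]])
  rec0 <- specificity(cm[["TN"]], cm[["FP"]])
  out <- list(threshold = threshold, confusion = cm,
              auroc = aurocScore(scores, labels),
              positive = list(precision = prec1, recall = rec1,
                              f1 = f1Score(prec1, rec1)),
              negative = list(precision = prec0, recall = rec0,
                              f1 = f1Score(prec0, rec0)),
              specificity = rec0, npv = prec0)
  if (n_boot > 0L) {
    out$auroc_ci <- bootstrapCi(scores, labels, aurocScore,
                                n_boot = n_boot, seed = seed)[c("lower", "upper")]
    # PPV can be undefined (no predicted positives) in essentially every
    # resample; report a not-applicable interval rather than fail
    out$ppv_ci <- tryCatch(
      bootstrapCi(
        scores, labels,
        function(s, l) {
          c2 <- confusionAtThreshold(s, l, threshold)
          v <- ppv(c2[["TP"]], c2[["FP"]])
          if (is.na(v)) stop("undefined") else v
        }, n_boot = n_boot, seed = seed)[c("lower", "upper")],
      error = function(e) list(lower = NA_real_, upper = NA_real_))
  }
  out
}

#' Lookback-by-trimming sensitivity grid
#'
#' Re-derives pathways, retrains and re-evaluates a model for every
#' combination of lookback window and pre-index trimming, with only the
#' window changed between cells — the bias-sensitivity analysis that
#' motivates the study's selected configuration of a 36-month lookback
#' with the immediate month removed.
#'
#' @param curated_events curated event table for all patients.
#' @param code_lists list with `lung`, `other_cancer`, `respiratory` and
#'   optionally `diagnostic` group-code vectors.
#' @param train_ids,test_ids patient-id split.
#' @param trainScore function `(train_pathways, test_pathways) -> scores`
#'   for the test pathways; called once per cell.
#' @param lookbacks,trims month grids (defaults 12/24/36 and 0/1/3).
#' @param min_codes minimum-pathway filter applied within each cell.
#' @param min_cases cells with fewer eligible cases are flagged
#'   (`viable = FALSE`), never silently dropped.
#' @return `data.frame` with one row per cell: window, n, AUROC, viability
#'   flag, and `selected` marking the (36, 1) study configuration.
#' @export
sensitivityGrid <- function(curated_events, code_lists, train_ids, test_ids,
                            trainScore, lookbacks = c(12L, 24L, 36L),
                            trims = c(0L, 1L, 3L), min_codes = 10L,
                            min_cases = 10L) {
  rows <- list()
  for (lb in lookbacks) for (tm in trims) {
    pw <- buildPathways(curated_events, code_lists$lung,
                        code_lists$other_cancer, code_lists$respiratory,
                        diagnostic_codes = code_lists$diagnostic,
                        lookback_months = lb, trim_months = tm)
    pw <- filterMinCodes(stripLabelCodes(pw, code_lists$lung,
                                         code_lists$other_cancer),
                         min_codes)
    info <- pathwayInfo(pw)
    tr <- pw[which(info$patient_id %in% train_ids)]
    te <- pw[which(info$patient_id %in% test_ids)]
    viable <- sum(pathwayLabels(tr)) >= min_cases &&
      sum(pathwayLabels(te)) >= 2L &&
      length(unique(pathwayLabels(tr))) == 2L
    auc <- NA_real_
    if (viable) {
      sc <- trainScore(tr, te)
      auc <- aurocScore(sc, pathwayLabels(te))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      lookback_months = lb, trim_months = tm,
      n_train = length(tr), n_test = length(te),
      auroc = auc, viable = viable,
      selected = lb == 36L && tm == 1L)
  }
  do.call(rbind, rows)
}

#' Metrics by patient subgroup
#'
#' Descriptive per-group reports (no multiplicity adjustment) by, e.g.,
#' sex and ethnicity. Groups below `min_size` are flagged.
#'
#' @param scores,labels the evaluated predictions.
#' @param groups character/factor vector of group membership per patient.
#' @param threshold operating point.
#' @param min_size flag groups smaller than this.
#' @return `data.frame`: one row per group with n, confusion counts,
#'   PPV, sensitivity, AUROC (NA if one-class) and a `small` flag.
#' @export
subgroupReport <- function(scores, labels, groups, threshold = 0.4,
                           min_size = 20L) {
  rows <- lapply(split(seq_along(scores), groups), function(i) {
    cm <- confusionAtThreshold(scores[i], labels[i], threshold)
    auc <- tryCatch(aurocScore(scores[i], labels[i]),
                    error = function(e) NA_real_)
    data.frame(n = length(i), TP = cm[["TP"]], FP = cm[["FP"]],
               TN = cm[["TN"]], FN = cm[["FN"]],
               ppv = ppv(cm[["TP"]], cm[["FP"]]),
               sensitivity = sensitivity(cm[["TP"]], cm[["FN"]]),
               auroc = auc, small = length(i) < min_size)
  })
  out <- do.call(rbind, rows)
  out <- cbind(group = names(rows), out)
  rownames(out) <- NULL
  out
}
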