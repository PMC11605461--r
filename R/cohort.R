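#' Random patient-level train/validation split
#'
#' Splitting is at patient level (a patient contributes pathways to one
#' arm only, preventing leakage) and invariant to the input ordering:
#' ids are canonically sorted before the seeded draw.
#'
#' @param patient_ids unique ids.
#' @param train_fraction fraction assigned to training (study value 0.7);
#'   the training arm gets `round(train_fraction * N)` ids.
#' @param seed integer seed.
#' @param eval_size ids drawn from the training arm as the evaluation
#'   subset used for model selection (study value 600; 0 disables).
#' @param validation_sample_size ids drawn from the validation arm as the
#'   validation sample (study value 50,000; `NULL` keeps the whole arm).
#' @return list with `training`, `validation`, `evaluation`
#'   (subset of training) and `validation_sample` (subset of validation).
#' @export
splitPopulation <- function(patient_ids, train_fraction = 0.7, seed = 1L,
                            eval_size = 0L, validation_sample_size = NULL) {
  ids <- sort(unique(as.character(patient_ids)))
  if (length(ids) != length(patient_ids)) stop("patient ids must be unique")
  if (length(ids) < 2L) stop("need at least 2 patients to split")
  n_train <- round(train_fraction * length(ids))
  set.seed(seed)
  tr <- sort(sampleVec(ids, n_train))
  va <- setdiff(ids, tr)
  ev <- if (eval_size > 0L) sort(sampleVec(tr, min(eval_size, length(tr))))
        else character(0)
  vs <- if (!is.null(validation_sample_size))
    sort(sampleVec(va, min(validation_sample_size, length(va)))) else va
  list(training = tr, validation = va, evaluation = ev,
       validation_sample = vs)
}

#' Assemble the nested case-control training set
#'
#' Includes every eligible case and samples controls per stratum quota
#' without replacement (controls are over-selected from other-cancer and
#' chronic-respiratory strata so the model learns to separate these
#' look-alike pathways). Sampling is seeded and performed after a
#' canonical id sort, so it is invariant to input ordering.
#'
#' @param pathways a [PathwaySet-class] with strata in its info.
#' @param quotas named integer vector of absolute control counts per
#'   stratum, e.g. `c(respiratory = 2932, other_cancer = 2030,
#'   other = 2279)` (the study composition).
#' @param seed integer seed.
#' @return list with `pathways` (the selected [PathwaySet-class]) and
#'   `composition` (per-stratum counts and fractions; fractions sum to 1).
#' @export
buildCaseControl <- function(pathways, quotas, seed = 1L) {
  info <- pathwayInfo(pathways)
  keep_ids <- info$patient_id[info$label == 1L]
  set.seed(seed)
  for (st in names(quotas)) {
    q <- quotas[[st]]
    pool <- sort(info$patient_id[info$stratum == st & info$label == 0L])
    if (q > length(pool))
      stop("quota ", q, " exceeds available patients (", length(pool),
           ") in stratum '", st, "'")
    if (q > 0L) keep_ids <- c(keep_ids, sampleVec(pool, q))
  }
  sel <- pathways[match(keep_ids, info$patient_id)]
  comp <- as.data.frame(table(stratum = pathwayInfo(sel)$stratum),
                        stringsAsFactors = FALSE)
  names(comp)[2L] <- "n"
  comp$fraction <- comp$n / sum(comp$n)
  list(pathways = sel, composition = comp)
}
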