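#' @describeIn Vocabulary-class group tokens in id order (ids 4..V-1).
#' @export
setMethod("vocabTokens", "Vocabulary", function(object) object@tokens)

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d group tokens + 4 specials (total %d ids)\n",
              length(object@tokens), length(object@tokens) + 4L))
})

#' Build a Vocabulary from curated group tokens
#'
#' Special tokens occupy fixed ids ([PAD]=0, [UNK]=1, [CLS]=2, [MASK]=3);
#' group tokens are sorted and take contiguous ids from 4.
#'
#' @param group_tokens character vector of curated group ids.
#' @return a [Vocabulary-class].
#' @export
buildVocabulary <- function(group_tokens) {
  methods::new("Vocabulary", tokens = sort(unique(as.character(group_tokens))))
}

#' Total id count of a vocabulary (specials included)
#' @param vocabulary a [Vocabulary-class].
#' @export
vocabSize <- function(vocabulary) length(vocabulary@tokens) + 4L

#' Map tokens to 0-based ids (and back)
#' @param vocabulary a [Vocabulary-class].
#' @param tokens character vector; unknown tokens map to `[UNK]` (id 1).
#' @export
tokenToId <- function(vocabulary, tokens) {
  i <- match(tokens, vocabulary@tokens)
  ifelse(is.na(i), UNK_ID, i + 3L)
}

#' @rdname tokenToId
#' @param ids integer vector of 0-based ids.
#' @export
idToToken <- function(vocabulary, ids) {
  out <- character(length(ids))
  sp <- ids < 4L
  out[sp] <- SPECIAL_TOKENS[ids[sp] + 1L]
  out[!sp] <- vocabulary@tokens[ids[!sp] - 3L]
  out
}

## ---- PathwaySet accessors ----------------------------------------------

#' @describeIn PathwaySet-class list of ordered token vectors.
#' @export
setMethod("pathwayTokens", "PathwaySet", function(object) object@tokens)

#' @describeIn PathwaySet-class per-pathway metadata `data.frame`.
#' @export
setMethod("pathwayInfo", "PathwaySet", function(object) object@info)

#' @describeIn PathwaySet-class integer 0/1 labels.
#' @export
setMethod("pathwayLabels", "PathwaySet", function(object)
  as.integer(object@info$label))

#' @describeIn PathwaySet-class number of pathways.
#' @param x a `PathwaySet`.
#' @export
setMethod("length", "PathwaySet", function(x) length(x@tokens))

#' @describeIn PathwaySet-class subset by index or patient id.
#' @param i index vector.
#' @param j,drop,... unused.
#' @export
setMethod("[", "PathwaySet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$patient_id)
  methods::new("PathwaySet", tokens = x@tokens[i],
               info = x@info[i, , drop = FALSE])
})

setMethod("show", "PathwaySet", function(object) {
  n <- length(object)
  cat(sprintf("PathwaySet: %d pathways (%d cases), median %d tokens\n",
              n, sum(object@info$label == 1L),
              if (n) as.integer(stats::median(lengths(object@tokens))) else 0L))
})

## ---- pathway construction ----------------------------------------------

#' Select a patient's index date and stratum
#'
#' The pathway endpoint. A lung-cancer diagnostic code takes precedence
#' over any other cancer: the index is then the date of the *first* lung
#' code. Otherwise the first other-cancer code sets the index. Otherwise
#' the patient is a non-cancer control and the *most recent*
#' diagnosis-category event is the endpoint, with the stratum set by
#' respiratory code-list membership.
#'
#' @param events `data.frame` of one patient's curated or raw events with
#'   columns `event_date` (Date) and the code column named by `code_col`.
#' @param lung_codes,cancer_codes,respiratory_codes character code lists
#'   (on the same coding level as `code_col`).
#' @param diagnostic_codes codes counting as "diagnostic" for the control
#'   endpoint rule; defaults to the union of the three lists.
#' @param code_col column holding the code (default `"group_id"`).
#' @return `list(index_date, stratum, index_code)` or `NULL` when the
#'   patient has no diagnostic code (excluded upstream).
#' @export
selectIndexDate <- function(events, lung_codes, cancer_codes,
                            respiratory_codes = character(),
                            diagnostic_codes = NULL, code_col = "group_id") {
  stopifnot(code_col %in% names(events))
  code <- events[[code_col]]
  date <- events$event_date
  hit <- function(set) which(code %in% set)
  il <- hit(lung_codes)
  if (length(il)) {
    k <- il[which.min(date[il])]
    return(list(index_date = date[k], stratum = "lung", index_code = code[k]))
  }
  ic <- hit(cancer_codes)
  if (length(ic)) {
    k <- ic[which.min(date[ic])]
    return(list(index_date = date[k], stratum = "other_cancer",
                index_code = code[k]))
  }
  dxc <- diagnostic_codes %||%
    unique(c(lung_codes, cancer_codes, respiratory_codes))
  id <- hit(dxc)
  if (!length(id)) return(NULL)
  k <- id[which.max(date[id])]
  stratum <- if (code[k] %in% respiratory_codes ||
                 any(code[id] %in% respiratory_codes)) "respiratory" else "other"
  list(index_date = date[k], stratum = stratum, index_code = code[k])
}

#' Derive one pathway's tokens from curated events
#'
#' Retains exactly the events dated in `[index - lookback_months,
#' index - trim_months)` (calendar-month arithmetic, closed below, open
#' above) and orders them by event date, breaking same-day ties by group id
#' and then input row order so the result is deterministic.
#'
#' @param events one patient's curated events (`event_date`, `group_id`),
#'   in input row order.
#' @param index_date the pathway endpoint.
#' @param lookback_months window length (default 36).
#' @param trim_months months removed immediately before the index to guard
#'   against post-diagnosis coding bias (study choice: 1).
#' @return character vector of ordered group tokens.
#' @export
derivePathway <- function(events, index_date, lookback_months = 36L,
                          trim_months = 0L) {
  if (trim_months >= lookback_months)
    stop("trim_months must be smaller than lookback_months")
  lo <- monthsBefore(index_date, lookback_months)
  hi <- monthsBefore(index_date, trim_months)
  keep <- events$event_date >= lo & events$event_date < hi
  ev <- events[keep, , drop = FALSE]
  ord <- order(ev$event_date, ev$group_id, seq_len(nrow(ev)))
  as.character(ev$group_id[ord])
}

#' Build a PathwaySet for a cohort
#'
#' Applies [selectIndexDate()] and [derivePathway()] per patient. Patients
#' with no diagnostic code are dropped. The label is 1 for the `lung`
#' stratum, 0 otherwise.
#'
#' @param curated_events curated events for all patients (`patient_id`,
#'   `event_date`, `group_id`).
#' @param lung_codes,cancer_codes,respiratory_codes group-level code lists.
#' @param diagnostic_codes groups counting as diagnostic for the control
#'   endpoint rule (default: union of the three lists).
#' @param lookback_months,trim_months window, as in [derivePathway()].
#' @param append_index_code append the index-date diagnostic group as the
#'   final token (pretraining keeps the endpoint code; fine-tuning strips
#'   it again via [stripLabelCodes()]).
#' @return a [PathwaySet-class].
#' @export
buildPathways <- function(curated_events, lung_codes, cancer_codes,
                          respiratory_codes = character(),
                          diagnostic_codes = NULL,
                          lookback_months = 36L, trim_months = 0L,
                          append_index_code = FALSE) {
  split_ev <- split(curated_events, curated_events$patient_id)
  toks <- list(); rows <- list()
  for (pid in names(split_ev)) {
    ev <- split_ev[[pid]]
    sel <- selectIndexDate(ev, lung_codes, cancer_codes, respiratory_codes,
                           diagnostic_codes = diagnostic_codes)
    if (is.null(sel)) next
    tt <- derivePathway(ev, sel$index_date, lookback_months, trim_months)
    if (append_index_code) tt <- c(tt, sel$index_code)
    toks[[pid]] <- tt
    rows[[pid]] <- data.frame(
      patient_id = pid, index_date = sel$index_date,
      label = as.integer(sel$stratum == "lung"), stratum = sel$stratum,
      stringsAsFactors = FALSE)
  }
  info <- do.call(rbind, rows)
  rownames(info) <- NULL
  methods::new("PathwaySet", tokens = unname(toks), info = info)
}

#' Drop pathways with too few curated codes
#'
#' The study excluded patients with fewer than ten curated codes in the
#' three years before diagnosis; a pathway with exactly `min_codes` tokens
#' is retained.
#'
#' @param pathways a [PathwaySet-class].
#' @param min_codes minimum token count (default 10).
#' @return the filtered [PathwaySet-class].
#' @export
filterMinCodes <- function(pathways, min_codes = 10L) {
  keep <- lengths(pathways@tokens) >= min_codes
  pathways[which(keep)]
}

#' Remove diagnostic label codes from pathways
#'
#' For fine-tuning and inference the lung-cancer diagnostic groups and the
#' non-lung cancer diagnostic groups are excluded from the input, so the
#' classifier cannot read the label off the sequence. Order is preserved.
#'
#' @param pathways a [PathwaySet-class] (or a single character token
#'   vector).
#' @param lung_codes,other_cancer_codes group-level diagnostic code lists.
#' @return same type as `pathways`.
#' @export
stripLabelCodes <- function(pathways, lung_codes, other_cancer_codes) {
  drop <- unique(c(lung_codes, other_cancer_codes))
  if (is.character(pathways)) return(pathways[!pathways %in% drop])
  pathways@tokens <- lapply(pathways@tokens, function(tt)
    tt[!tt %in% drop])
  pathways
}

#' Encode a pathway as integer ids
#'
#' Output is `[CLS]` followed by the mapped ids. Sequences longer than
#' `max_len` keep the *most recent* `max_len - 1` tokens (recent events are
#' the most predictive). Unknown groups map to `[UNK]`.
#'
#' @param tokens character token vector (one pathway).
#' @param vocabulary a [Vocabulary-class].
#' @param max_len maximum output length including `[CLS]` (default 512).
#' @return integer vector of 0-based ids, length `<= max_len`.
#' @export
tokenizePathway <- function(tokens, vocabulary, max_len = 512L) {
  ids <- tokenToId(vocabulary, tokens)
  if (length(ids) > max_len - 1L)
    ids <- ids[(length(ids) - (max_len - 2L)):length(ids)]
  as.integer(c(CLS_ID, ids))
}

#' @rdname tokenizePathway
#' @param pathways a [PathwaySet-class].
#' @return `tokenizePathways` returns a list of id vectors.
#' @export
tokenizePathways <- function(pathways, vocabulary, max_len = 512L) {
  lapply(pathwayTokens(pathways), tokenizePathway, vocabulary = vocabulary,
         max_len = max_len)
}
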