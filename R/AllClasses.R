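#' @import methods
NULL

CODE_CATEGORIES <- c("symptom", "diagnosis", "medication", "procedure",
                     "encounter_site", "test")

#' CodeMap: raw-code to curated-group dictionary
#'
#' Maps raw terminology codes many-to-one onto curated clinical code
#' groups, carrying a category per group and a flag marking purely
#' administrative codes that curation drops. The distinct non-administrative
#' group ids form the curated vocabulary (450 groups in the bundled demo
#' map).
#'
#' @slot map a `data.frame` with columns `raw_code`, `group_id`,
#'   `group_label`, `category`, `is_administrative`.
#' @export
setClass("CodeMap", representation(map = "data.frame"))

setValidity("CodeMap", function(object) {
  m <- object@map
  need <- c("raw_code", "group_id", "group_label", "category",
            "is_administrative")
  if (!all(need %in% names(m)))
    return(paste("map must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(m$raw_code))
    return("raw_code values must be unique (mapping must be a function)")
  if (!all(m$category %in% c(CODE_CATEGORIES, "administrative")))
    return("unknown category value")
  if (!is.logical(m$is_administrative))
    return("is_administrative must be logical")
  TRUE
})

#' Vocabulary: token/integer-id dictionary for sequence models
#'
#' Fixed special tokens occupy ids 0..3 ([PAD]=0, [UNK]=1, [CLS]=2,
#' [MASK]=3); curated group tokens follow contiguously from id 4. Token ids
#' are zero-based throughout the package (the convention of the sequence
#' models the encoder follows); the model layer converts to R's one-based
#' indexing internally.
#'
#' @slot tokens character vector of group tokens (ids `4:(3+length)`).
#' @export
setClass("Vocabulary", representation(tokens = "character"))

setValidity("Vocabulary", function(object) {
  if (anyDuplicated(object@tokens)) return("duplicate group tokens")
  if (any(object@tokens %in% SPECIAL_TOKENS))
    return("group tokens may not collide with special tokens")
  TRUE
})

SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[MASK]")
PAD_ID <- 0L; UNK_ID <- 1L; CLS_ID <- 2L; MASK_ID <- 3L

#' PathwaySet: a cohort of pathways to diagnosis
#'
#' One pathway per patient: the temporally ordered curated code tokens
#' observed inside the lookback window before the patient's index date,
#' together with the label (1 = lung cancer, 0 = non-lung) and the control
#' stratum.
#'
#' @slot tokens list of character vectors, one ordered token sequence per
#'   pathway.
#' @slot info `data.frame` with one row per pathway: `patient_id`,
#'   `index_date`, `label`, `stratum`.
#' @export
setClass("PathwaySet", representation(tokens = "list", info = "data.frame"))

setValidity("PathwaySet", function(object) {
  if (length(object@tokens) != nrow(object@info))
    return("tokens and info must have one entry per pathway")
  need <- c("patient_id", "index_date", "label", "stratum")
  if (!all(need %in% names(object@info)))
    return(paste("info must have columns", paste(need, collapse = ", ")))
  if (!all(object@info$label %in% c(0L, 1L)))
    return("label must be 0 or 1")
  TRUE
})

#' SeqModel: shared-parameter transformer encoder state
#'
#' Holds the model configuration (see [seqModelConfig()]) and the full
#' parameter set: factorized token embeddings, learned position embeddings,
#' the (optionally cross-layer shared) attention and feed-forward blocks,
#' the masked-code prediction head and the logistic classification head.
#'
#' @slot config list produced by [seqModelConfig()].
#' @slot params nested list of numeric arrays.
#' @export
setClass("SeqModel", representation(config = "list", params = "list"))
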