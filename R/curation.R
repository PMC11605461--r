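#' @describeIn CodeMap-class number of distinct non-administrative group
#'   ids (the curated vocabulary size; 450 in the demo map).
#' @export
setMethod("vocabularySize", "CodeMap", function(object) {
  length(unique(object@map$group_id[!object@map$is_administrative]))
})

#' @describeIn CodeMap-class sorted distinct non-administrative group ids.
#' @export
setMethod("groupIds", "CodeMap", function(object) {
  sort(unique(object@map$group_id[!object@map$is_administrative]))
})

setMethod("show", "CodeMap", function(object) {
  cat(sprintf("CodeMap: %d raw codes -> %d curated groups (+%d administrative rows)\n",
              nrow(object@map), vocabularySize(object),
              sum(object@map$is_administrative)))
})

#' Load a code-curation map
#'
#' The map file is `raw_code,group_id,group_label,category,is_administrative`
#' (CSV, header row, `is_administrative` 0/1). Duplicate `raw_code` rows
#' with conflicting targets are an error; exact duplicate rows collapse.
#' The vocabulary size (distinct non-administrative groups) is reported.
#'
#' @param path file path.
#' @param quiet suppress the vocabulary-size message.
#' @return a [CodeMap-class].
#' @export
loadCodeMap <- function(path, quiet = FALSE) {
  df <- readDelimited(path, c("raw_code", "group_id", "group_label",
                              "category", "is_administrative"))
  df <- unique(df)
  if (anyDuplicated(df$raw_code)) {
    bad <- df$raw_code[duplicated(df$raw_code)][1L]
    stop("conflicting duplicate mapping for raw code '", bad, "'")
  }
  df$is_administrative <- df$is_administrative %in% c("1", "TRUE", "true")
  cm <- methods::new("CodeMap", map = df)
  if (!quiet)
    message("code map: ", nrow(df), " raw codes, vocabulary size ",
            vocabularySize(cm))
  cm
}

#' @rdname loadCodeMap
#' @param code_map a [CodeMap-class] to write.
#' @export
writeCodeMap <- function(code_map, path) {
  df <- code_map@map
  df$is_administrative <- as.integer(df$is_administrative)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a CodeMap from a data.frame
#' @param map `data.frame` with the five map columns.
#' @return a [CodeMap-class].
#' @export
codeMap <- function(map) {
  map$is_administrative <- as.logical(map$is_administrative)
  methods::new("CodeMap", map = map)
}

#' Curate raw coded events
#'
#' Drops events with administrative codes, replaces the remaining raw
#' codes by their curated `group_id`, and handles unmapped raw codes per
#' `unknown_policy`: `"drop"` (default; the curated vocabulary is closed,
#' unmapped codes are noise) or `"map_to_unknown_token"` (kept as
#' `"[UNK]"`). Input order is preserved.
#'
#' @param events `data.frame` with `patient_id`, `event_date`, `raw_code`.
#' @param code_map a [CodeMap-class].
#' @param unknown_policy `"drop"` or `"map_to_unknown_token"`.
#' @return `data.frame` with `patient_id`, `event_date`, `group_id`.
#' @export
curateEvents <- function(events, code_map,
                         unknown_policy = c("drop", "map_to_unknown_token")) {
  unknown_policy <- match.arg(unknown_policy)
  m <- code_map@map
  i <- match(events$raw_code, m$raw_code)
  group <- m$group_id[i]
  admin <- !is.na(i) & m$is_administrative[i]
  unknown <- is.na(i)
  if (unknown_policy == "map_to_unknown_token") {
    group[unknown] <- "[UNK]"
    keep <- !admin
  } else {
    keep <- !admin & !unknown
  }
  data.frame(patient_id = events$patient_id[keep],
             event_date = events$event_date[keep],
             group_id = group[keep],
             stringsAsFactors = FALSE)
}

#' The bundled demonstration code map
#'
#' A synthetic 450-group curation map in the shipped format: 450
#' non-administrative curated groups (`G001`..`G450`), three raw codes per
#' group (`<group>r1..r3`, raw codes being finer-grained terms that map
#' many-to-one up to their group), categories cycling over the six
#' clinical categories, plus `n_admin` administrative groups whose events
#' curation removes. The first groups are reserved for diagnosis
#' definitions: `G001` lung cancer, `G002`-`G004` other cancers,
#' `G005`-`G007` chronic respiratory conditions, `G008` other chronic
#' conditions. The same constructor backs the copy under
#' `inst/extdata/demo_codemap.csv`.
#'
#' @param n_groups curated (non-administrative) group count.
#' @param raw_per_group raw codes per group.
#' @param n_admin administrative group count.
#' @return a [CodeMap-class].
#' @export
demoCodeMap <- function(n_groups = 450L, raw_per_group = 3L, n_admin = 8L) {
  gid <- sprintf("G%03d", seq_len(n_groups))
  cat6 <- rep(c("diagnosis", "symptom", "medication", "procedure",
                "encounter_site", "test"), length.out = n_groups)
  cat6[1:8] <- "diagnosis"  # reserved diagnosis-definition groups
  rows <- data.frame(
    raw_code = paste0(rep(gid, each = raw_per_group), "r",
                      seq_len(raw_per_group)),
    group_id = rep(gid, each = raw_per_group),
    group_label = rep(paste0("group ", gid), each = raw_per_group),
    category = rep(cat6, each = raw_per_group),
    is_administrative = FALSE, stringsAsFactors = FALSE)
  if (n_admin > 0L) {
    aid <- sprintf("ADM%02d", seq_len(n_admin))
    rows <- rbind(rows, data.frame(
      raw_code = paste0(rep(aid, each = raw_per_group), "r",
                        seq_len(raw_per_group)),
      group_id = rep(aid, each = raw_per_group),
      group_label = rep(paste0("administrative ", aid), each = raw_per_group),
      category = "administrative",
      is_administrative = TRUE, stringsAsFactors = FALSE))
  }
  methods::new("CodeMap", map = rows)
}

#' Group-level diagnosis code lists of the demo map
#'
#' @return list with `lung`, `other_cancer`, `respiratory` group-id
#'   vectors matching [demoCodeMap()]'s reserved groups.
#' @export
demoCodeLists <- function() {
  list(lung = "G001",
       other_cancer = c("G002", "G003", "G004"),
       respiratory = c("G005", "G006", "G007"))
}
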